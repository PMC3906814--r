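# Metagenomic read recruitment: best-hit mapping, windowed coverage/identity
# tracks, metagenomic island (MGI) and conserved-region calling.

#' Recruit metagenomic reads onto a reference genome
#'
#' Maps each read (both strands) by seed-and-extend ungapped alignment and
#' keeps the single best hit per read (most matching bases; ties broken by
#' leftmost reference coordinate, then lexicographic replicon id).  Identity
#' is computed over all aligned columns.  Hits below
#' `min_identity_report` percent identity are discarded, as are reads shorter
#' than 50 bp.
#'
#' @param reads data.frame from [simulate_metagenome()] (columns `read_id`,
#'   `seq`) or a named character vector
#' @param reference character string or named character vector of replicons
#' @param min_seed seed k-mer length (default 15)
#' @param min_identity_report report cutoff, percent (default 25)
#' @param min_read_frac minimum fraction of the read covered by the local
#'   alignment (default 0.5); discards bare seed matches of unrelated reads
#' @return data.frame with `read`, `ref`, 0-based half-open `ref_start` /
#'   `ref_end`, `strand`, `identity`, `read_aln_frac`
#' @export
recruit <- function(reads, reference, min_seed = 15, min_identity_report = 25,
                    min_read_frac = 0.5) {
  if (length(reference) == 0 || all(nchar(reference) == 0)) {
    stop("empty reference")
  }
  if (is.data.frame(reads)) {
    ids <- reads$read_id
    seqs <- reads$seq
  } else {
    ids <- names(reads) %||% sprintf("read_%07d", seq_along(reads))
    seqs <- unname(reads)
  }
  keep <- nchar(seqs) >= 50
  ids <- ids[keep]; seqs <- seqs[keep]
  ref_ids <- names(reference) %||% sprintf("replicon_%d", seq_along(reference))
  ref_ids_sorted <- sort(ref_ids)
  best <- NULL
  for (ri in ref_ids_sorted) {
    sq <- reference[[match(ri, ref_ids)]]
    h <- cpp_seed_map(seqs, sq, k = min_seed,
                      min_identity = min_identity_report,
                      min_frac = min_read_frac, max_hits = 1L)
    if (nrow(h) == 0) next
    h$ref <- ri
    if (is.null(best)) {
      best <- h
    } else {
      m <- match(h$query, best$query)
      new <- is.na(m)
      best <- rbind(best, h[new, , drop = FALSE])
      old <- which(!new)
      if (length(old)) {
        # better matches win; ties keep the earlier (lexicographically
        # smaller replicon, then leftmost handled inside the mapper)
        b <- m[old]
        upd <- h$matches[old] > best$matches[b] |
          (h$matches[old] == best$matches[b] & h$ref_start[old] < best$ref_start[b])
        best[b[upd], ] <- h[old[upd], , drop = FALSE]
      }
    }
  }
  if (is.null(best) || nrow(best) == 0) {
    return(data.frame(read = character(0), ref = character(0),
                      ref_start = integer(0), ref_end = integer(0),
                      strand = character(0), identity = numeric(0),
                      read_aln_frac = numeric(0), stringsAsFactors = FALSE))
  }
  out <- data.frame(read = ids[best$query], ref = best$ref,
                    ref_start = best$ref_start, ref_end = best$ref_end,
                    q_start = best$q_start, q_end = best$q_end,
                    strand = best$strand, identity = best$identity,
                    read_aln_frac = best$aln_frac, stringsAsFactors = FALSE)
  out[order(out$ref, out$ref_start), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Windowed recruitment track
#'
#' Tiles each replicon with non-overlapping windows and reports, per window,
#' the mean read depth (aligned bases per position), the fraction of
#' positions covered by at least one hit, and the overlap-weighted mean
#' alignment identity (positions under no hit are excluded; windows with no
#' hits have `mean_identity = NA`).
#'
#' @param hits data.frame from [recruit()]
#' @param reference character string or named character vector of replicons
#' @param window window size in bases (>= 100; default 1000)
#' @return object of class `recruitment_track` with `windows` data.frame
#'   (`ref`, `start`, `end`, `depth`, `covered_frac`, `mean_identity`)
#' @export
build_track <- function(hits, reference, window = 1000) {
  if (window < 100) stop("window must be >= 100")
  ref_ids <- names(reference) %||% sprintf("replicon_%d", seq_along(reference))
  out <- lapply(seq_along(reference), function(i) {
    L <- nchar(reference[[i]])
    ws <- seq(0L, max(0L, L - 1L), by = window)
    we <- pmin(ws + window, L)
    win <- data.frame(ref = ref_ids[i], start = ws, end = we,
                      depth = 0, covered_frac = 0, mean_identity = NA_real_,
                      stringsAsFactors = FALSE)
    hh <- hits[hits$ref == ref_ids[i], , drop = FALSE]
    if (nrow(hh) == 0) return(win)
    hr <- IRanges::IRanges(hh$ref_start + 1L, hh$ref_end)
    wr <- IRanges::IRanges(ws + 1L, we)
    ov <- IRanges::findOverlaps(hr, wr)
    ow <- IRanges::width(IRanges::pintersect(
      hr[S4Vectors::queryHits(ov)], wr[S4Vectors::subjectHits(ov)]))
    wi <- S4Vectors::subjectHits(ov)
    win$depth <- as.vector(tapply(ow, factor(wi, levels = seq_along(ws)), sum,
                                  default = 0)) / (we - ws)
    idw <- as.vector(tapply(ow * hh$identity[S4Vectors::queryHits(ov)],
                            factor(wi, levels = seq_along(ws)), sum, default = 0))
    tot <- as.vector(tapply(ow, factor(wi, levels = seq_along(ws)), sum,
                            default = 0))
    win$mean_identity <- as.numeric(ifelse(tot > 0, idw / tot, NA_real_))
    bin <- IRanges::coverage(hr, width = L)
    S4Vectors::runValue(bin) <- as.numeric(S4Vectors::runValue(bin) > 0)
    covered <- IRanges::viewSums(IRanges::Views(bin, wr))
    win$covered_frac <- as.numeric(covered) / (we - ws)
    win
  })
  structure(list(windows = do.call(rbind, out), window = window,
                 reference_lengths = stats::setNames(nchar(reference), ref_ids)),
            class = "recruitment_track")
}

#' @export
print.recruitment_track <- function(x, ...) {
  w <- x$windows
  cat(sprintf("recruitment_track: %d windows of %d bp; mean depth %.2f; mean identity %.2f%%\n",
              nrow(w), x$window, mean(w$depth),
              mean(w$mean_identity, na.rm = TRUE)))
  invisible(x)
}

# merge adjacent flagged windows of one replicon into intervals
#' @noRd
merge_flagged <- function(w, flag) {
  out <- list()
  for (ref in unique(w$ref)) {
    sel <- w$ref == ref
    f <- flag[sel]
    if (!any(f)) next
    r <- rle(f)
    endi <- cumsum(r$lengths)
    starti <- endi - r$lengths + 1L
    ww <- w[sel, , drop = FALSE]
    for (j in which(r$values)) {
      out[[length(out) + 1]] <- data.frame(
        ref = ref, start = ww$start[starti[j]], end = ww$end[endi[j]],
        first_window = starti[j], last_window = endi[j],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(ref = character(0), start = integer(0), end = integer(0),
                      first_window = integer(0), last_window = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Call metagenomic islands (MGIs) from a recruitment track
#'
#' A window is flagged iff its mean identity is below `max_identity` percent
#' (windows without any hit count as low-coverage) OR its covered fraction is
#' below `max_covered_frac`; adjacent flagged windows are merged.  Boundary
#' equality is not an island (strict comparisons).
#'
#' @param track [build_track()] result
#' @param max_identity identity threshold, percent (default 25)
#' @param max_covered_frac covered-fraction threshold (default 0.25)
#' @param genes optional gene table used to count overlapped genes
#' @return data.frame of islands (`ref`, 0-based half-open `start`/`end`,
#'   `cause` in low_identity/low_coverage/both, `n_genes_overlapped`)
#' @export
call_mgis <- function(track, max_identity = 25, max_covered_frac = 0.25,
                      genes = NULL) {
  w <- track$windows
  id_flag <- !is.na(w$mean_identity) & w$mean_identity < max_identity
  cov_flag <- w$covered_frac < max_covered_frac
  flag <- id_flag | cov_flag
  isl <- merge_flagged(w, flag)
  if (nrow(isl) == 0) {
    isl$cause <- character(0)
    isl$n_genes_overlapped <- integer(0)
    return(isl)
  }
  isl$cause <- vapply(seq_len(nrow(isl)), function(i) {
    sel <- w$ref == isl$ref[i] & w$start >= isl$start[i] & w$end <= isl$end[i]
    has_id <- any(id_flag[sel]); has_cov <- any(cov_flag[sel])
    if (has_id && has_cov) "both" else if (has_id) "low_identity" else "low_coverage"
  }, character(1))
  isl$n_genes_overlapped <- if (is.null(genes)) NA_integer_ else {
    vapply(seq_len(nrow(isl)), function(i) {
      sum(genes$start < isl$end[i] & isl$start[i] < genes$end)
    }, integer(1))
  }
  isl$first_window <- NULL; isl$last_window <- NULL
  isl
}

#' Call conserved (ancestral-candidate) regions from a recruitment track
#'
#' Maximal runs of windows with mean identity strictly above `min_identity`
#' percent and depth of at least `min_depth`.
#'
#' @param track [build_track()] result
#' @param min_identity identity threshold, percent (default 90)
#' @param min_depth depth threshold in mean reads per base (default 8)
#' @return data.frame of intervals (`ref`, 0-based half-open `start`/`end`)
#' @export
call_conserved <- function(track, min_identity = 90, min_depth = 8) {
  w <- track$windows
  flag <- !is.na(w$mean_identity) & w$mean_identity > min_identity &
    w$depth >= min_depth
  res <- merge_flagged(w, flag)
  res$first_window <- NULL; res$last_window <- NULL
  res
}
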