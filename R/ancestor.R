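# Ancestral gene-content reconstruction: ORF calling, the per-gene decision
# rule (ortholog membership + island/foreign exclusion + metagenome support),
# and mapping the reconstructed genotype back onto genomes.

#' Find open reading frames on both strands
#'
#' Maximal ORFs (first ATG after the previous in-frame stop, through the next
#' stop, standard genetic code) of at least `min_len` bases, on both strands
#' and all frames.  Overlapping ORFs on the same strand are resolved to the
#' longer one.
#'
#' @param genome character string
#' @param min_len minimum ORF length in bases, stop included (default 90)
#' @return gene table: `gene_id`, 0-based half-open `start`/`end`, `strand`,
#'   `length`
#' @export
find_orfs <- function(genome, min_len = 90) {
  if (nchar(genome) == 0) stop("empty genome")
  L <- nchar(genome)
  scan_strand <- function(s, strand) {
    out <- list()
    for (frame in 0:2) {
      n_cod <- (nchar(s) - frame) %/% 3
      if (n_cod < 2) next
      st <- frame + 3 * (seq_len(n_cod) - 1) + 1
      cods <- substring(s, st, st + 2)
      stops <- which(cods %in% STOP_CODONS)
      atgs <- which(cods == "ATG")
      if (!length(stops) || !length(atgs)) next
      prev <- c(0L, head(stops, -1))
      # first ATG strictly after the previous stop and before this stop
      ai <- findInterval(prev, atgs) + 1L
      ok <- ai <= length(atgs) & atgs[pmin(ai, length(atgs))] < stops
      if (!any(ok)) next
      a <- atgs[ai[ok]]
      e <- stops[ok]
      len <- 3L * (e - a + 1L)
      keep <- len >= min_len
      if (!any(keep)) next
      a <- a[keep]; e <- e[keep]; len <- len[keep]
      s0 <- frame + 3L * (a - 1L)          # 0-based start on this strand
      e0 <- frame + 3L * e                 # 0-based half-open end
      if (strand == "+") {
        out[[length(out) + 1]] <- data.frame(start = s0, end = e0,
                                             strand = "+", length = len)
      } else {
        out[[length(out) + 1]] <- data.frame(start = L - e0, end = L - s0,
                                             strand = "-", length = len)
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  res <- rbind(scan_strand(genome, "+"),
               scan_strand(seq_revcomp(genome), "-"))
  if (is.null(res) || nrow(res) == 0) {
    return(data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      length = integer(0), stringsAsFactors = FALSE))
  }
  # same-strand overlap resolution: longer ORF wins
  keep <- rep(TRUE, nrow(res))
  for (str in c("+", "-")) {
    idx <- which(res$strand == str)
    if (length(idx) < 2) next
    ir <- IRanges::IRanges(res$start[idx] + 1L, res$end[idx])
    o <- order(-res$length[idx])
    claimed <- IRanges::IRanges()
    for (i in o) {
      if (length(claimed) &&
          length(IRanges::findOverlaps(ir[i], claimed)) > 0) {
        keep[idx[i]] <- FALSE
      } else {
        claimed <- c(claimed, ir[i])
      }
    }
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$start), , drop = FALSE]
  res$gene_id <- sprintf("orf_%05d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("gene_id", "start", "end", "strand", "length")]
}

# length-weighted mean of a per-window track statistic over one interval
#' @noRd
interval_track_stat <- function(track, start, end, stat) {
  w <- track$windows
  sel <- w$end > start & w$start < end
  if (!any(sel)) return(NA_real_)
  ww <- w[sel, , drop = FALSE]
  ov <- pmin(ww$end, end) - pmax(ww$start, start)
  v <- ww[[stat]]
  ok <- !is.na(v)
  if (stat == "depth") {
    # positions in windows without hits contribute zero depth
    sum(v[ok] * ov[ok]) / sum(ov)
  } else {
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * ov[ok]) / sum(ov[ok])
  }
}

#' Apply the ancestral-gene decision rule
#'
#' A gene on genome A is called ancestral iff it lies in an orthologous
#' segment shared with genome B, does not overlap a metagenomic island or a
#' compositionally foreign region on either genome (genome-B intervals are
#' lifted to A through the segment map), and is supported by the metagenome
#' at mean identity > `min_identity` percent and mean depth >= `min_depth`
#' (length-weighted over recruitment-track windows).  Every exclusion records
#' its causes.
#'
#' @param genes_a gene table on genome A
#' @param synteny [chain_anchors()] result for A vs B
#' @param mgi_a,mgi_b island intervals (data.frames with `start`, `end`) on A
#'   and B
#' @param foreign_a,foreign_b foreign-gene intervals on A and B
#' @param track_a recruitment track on genome A
#' @param genome_a optional genome A sequence; when given, the reconstructed
#'   genotype includes gene sequences
#' @param min_identity metagenome identity threshold, percent (default 90)
#' @param min_depth metagenome depth threshold (default 8)
#' @param full_containment require the gene to lie fully inside one segment
#'   (default TRUE); otherwise any overlap counts
#' @return list with `calls` (per-gene data.frame with provenance flags,
#'   verdict and `exclusion_causes`) and `genotype` (list with `genes`,
#'   `sequences`, `total_genes`, `total_bases`)
#' @export
infer_ancestral <- function(genes_a, synteny, mgi_a = NULL, mgi_b = NULL,
                            foreign_a = NULL, foreign_b = NULL, track_a,
                            genome_a = NULL, min_identity = 90, min_depth = 8,
                            full_containment = TRUE) {
  segs <- synteny$segments
  n <- nrow(genes_a)
  # lift B-side exclusion intervals onto A once
  lift_or_empty <- function(tab) {
    if (is.null(tab) || nrow(tab) == 0) {
      return(data.frame(start = numeric(0), end = numeric(0)))
    }
    lf <- lift_intervals(synteny, tab, from = "B")
    lf[!is.na(lf$start), c("start", "end"), drop = FALSE]
  }
  mgi_b_on_a <- lift_or_empty(mgi_b)
  foreign_b_on_a <- lift_or_empty(foreign_b)

  calls <- data.frame(
    gene_id = genes_a$gene_id, start = genes_a$start, end = genes_a$end,
    strand = genes_a$strand, in_ortholog = FALSE,
    partner_start = NA_real_, partner_end = NA_real_,
    in_mgi_a = FALSE, in_mgi_b = FALSE, foreign_a = FALSE, foreign_b = FALSE,
    meta_mean_identity = NA_real_, meta_mean_depth = NA_real_,
    verdict = "excluded", exclusion_causes = "", stringsAsFactors = FALSE)

  for (i in seq_len(n)) {
    s <- genes_a$start[i]; e <- genes_a$end[i]
    causes <- character(0)
    if (full_containment) {
      inseg <- which(segs$a_start <= s & e <= segs$a_end)
    } else {
      inseg <- which(segs$a_start < e & s < segs$a_end)
    }
    # genes sitting entirely inside a chain gap (no anchored homology at
    # all, e.g. an insertion spanned by the chain) are not orthologous
    inseg <- inseg[vapply(inseg, function(k) {
      ch <- synteny$chains[[k]]
      any(ch$a_start < e & s < ch$a_end)
    }, logical(1))]
    if (length(inseg)) {
      calls$in_ortholog[i] <- TRUE
      p <- lift_intervals(synteny, data.frame(start = s, end = e), from = "A")
      if (is.na(p$start[1])) {
        causes <- c(causes, "unmappable")
      } else {
        calls$partner_start[i] <- p$start[1]
        calls$partner_end[i] <- p$end[1]
      }
    } else {
      causes <- c(causes, "not_in_ortholog")
    }
    calls$in_mgi_a[i] <- overlaps_any(s, e, mgi_a)
    calls$foreign_a[i] <- overlaps_any(s, e, foreign_a)
    calls$in_mgi_b[i] <- overlaps_any(s, e, mgi_b_on_a)
    calls$foreign_b[i] <- overlaps_any(s, e, foreign_b_on_a)
    if (calls$in_mgi_a[i]) causes <- c(causes, "in_mgi_a")
    if (calls$in_mgi_b[i]) causes <- c(causes, "in_mgi_b")
    if (calls$foreign_a[i]) causes <- c(causes, "foreign_a")
    if (calls$foreign_b[i]) causes <- c(causes, "foreign_b")
    mid <- interval_track_stat(track_a, s, e, "mean_identity")
    mdp <- interval_track_stat(track_a, s, e, "depth")
    if (is.na(mdp)) {
      stop(sprintf("gene %s lies on a replicon absent from the track",
                   genes_a$gene_id[i]))
    }
    calls$meta_mean_identity[i] <- mid
    calls$meta_mean_depth[i] <- mdp
    if (is.na(mid) || mid <= min_identity) causes <- c(causes, "low_identity")
    if (mdp < min_depth) causes <- c(causes, "low_coverage")
    if (!length(causes)) calls$verdict[i] <- "ancestral"
    calls$exclusion_causes[i] <- paste(causes, collapse = ",")
  }
  anc <- calls$verdict == "ancestral"
  geno_genes <- genes_a[anc, , drop = FALSE]
  seqs <- if (!is.null(genome_a)) gene_sequences(genome_a, geno_genes) else NULL
  genotype <- list(genes = geno_genes, sequences = seqs,
                   total_genes = sum(anc),
                   total_bases = sum(geno_genes$end - geno_genes$start))
  list(calls = calls, genotype = genotype)
}

#' Map a reconstructed genotype onto target sequence sets
#'
#' Aligns each genotype gene against each target; a gene is present in a
#' target iff its best hit reaches `min_identity` percent identity over at
#' least `min_cov` of the gene length.
#'
#' @param genotype_seqs named character vector of gene sequences
#' @param targets named list/vector of target sequences
#' @param min_identity presence identity cutoff, percent (default 80)
#' @param min_cov presence coverage cutoff, fraction of gene length
#'   (default 0.80)
#' @param k seed k-mer length
#' @return list of matrices `presence` (logical), `identity`, `coverage`
#'   (genes x targets)
#' @export
map_genotype <- function(genotype_seqs, targets, min_identity = 80,
                         min_cov = 0.80, k = 13) {
  if (length(targets) == 0) stop("no targets")
  tn <- names(targets) %||% sprintf("target_%d", seq_along(targets))
  gn <- names(genotype_seqs) %||% sprintf("gene_%05d", seq_along(genotype_seqs))
  pres <- matrix(FALSE, length(genotype_seqs), length(targets),
                 dimnames = list(gn, tn))
  idm <- covm <- matrix(NA_real_, length(genotype_seqs), length(targets),
                        dimnames = list(gn, tn))
  for (t in seq_along(targets)) {
    h <- cpp_seed_map(unname(genotype_seqs), targets[[t]], k = k, max_hits = 1L)
    if (nrow(h) == 0) next
    idm[h$query, t] <- h$identity
    covm[h$query, t] <- h$aln_frac
    pres[h$query, t] <- h$identity >= min_identity & h$aln_frac >= min_cov
  }
  list(presence = pres, identity = idm, coverage = covm)
}
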