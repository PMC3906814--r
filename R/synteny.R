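# Spaced-seed homology anchors between two genomes and collinear chaining
# into orthologous segments, with monotone A<->B coordinate lifting.

#' Construct a spaced seed pattern
#'
#' A binary pattern of given length and weight (number of match positions).
#' The first and last positions are always match positions; don't-care
#' positions are spread evenly across the interior.
#'
#' @param weight number of match (1) positions (default 30)
#' @param length total pattern length (default 40)
#' @return character string over `{1,0}`
#' @export
spaced_seed <- function(weight = 30, length = 40) {
  stopifnot(weight >= 2, length >= weight)
  n_zero <- length - weight
  pat <- rep("1", length)
  if (n_zero > 0) {
    pos <- unique(round(seq(2, length - 1, length.out = n_zero + 2)))[-1]
    pos <- head(pos, n_zero)
    # fallback for crowded patterns: first free interior slots
    while (base::length(pos) < n_zero) {
      free <- setdiff(2:(length - 1), pos)
      pos <- c(pos, free[1])
    }
    pat[pos] <- "0"
  }
  paste0(pat, collapse = "")
}

#' Find spaced-seed homology anchors between two genomes
#'
#' Reports all positions whose seed-masked words match between genome A and
#' either strand of genome B; overlapping hits on the same diagonal are
#' merged into maximal anchors whose score is the number of matching bases
#' over the merged span.  Anchors scoring below the seed weight are dropped.
#'
#' @param genome_a,genome_b character strings
#' @param seed spaced-seed pattern from [spaced_seed()]
#' @return data.frame with 0-based half-open `a_start`/`a_end`,
#'   `b_start`/`b_end`, `strand`, `score`
#' @export
find_anchors <- function(genome_a, genome_b, seed = spaced_seed()) {
  if (nchar(genome_a) == 0 || nchar(genome_b) == 0) stop("empty genome")
  weight <- sum(strsplit(seed, "")[[1]] == "1")
  a <- cpp_spaced_anchors(genome_a, genome_b, seed)
  a <- a[a$score >= weight, , drop = FALSE]
  rownames(a) <- NULL
  a
}

# chain score under the affine gap model used by cpp_chain_best
#' @noRd
chain_score <- function(anchors, idx, minus, gap_open, gap_ext, indel_ext) {
  sc <- sum(anchors$score[idx])
  if (length(idx) > 1) {
    for (t in 2:length(idx)) {
      i <- idx[t]; j <- idx[t - 1]
      ga <- anchors$a_start[i] - anchors$a_end[j]
      gb <- if (!minus) anchors$b_start[i] - anchors$b_end[j]
            else anchors$b_start[j] - anchors$b_end[i]
      sc <- sc - (gap_open + gap_ext * max(ga, gb) + indel_ext * abs(ga - gb))
    }
  }
  sc
}

#' Chain anchors into collinear orthologous segments
#'
#' Maximum-score collinear chains under an affine gap penalty
#' (`gap_open + gap_ext * gap`, gap = the larger of the two genome gaps;
#' gaps above `max_gap` forbidden), extracted greedily by score.  Chains
#' scoring below `min_segment_score` are dropped.  Segments are trimmed to
#' their outermost anchors and are non-overlapping on both genomes.
#'
#' @param anchors data.frame from [find_anchors()]
#' @param max_gap maximum within-chain gap in bases (default 20000)
#' @param min_segment_score minimum chain score (default 2000; roughly the
#'   anchored-base count, so this acts as a minimum segment size)
#' @param gap_open,gap_ext,indel_ext affine gap penalty parameters; the
#'   `indel_ext` term prices diagonal drift per base, so chains break at
#'   large insertions and do not absorb off-diagonal repeat anchors
#' @param end_pad bases added to each segment end (default 40, one seed
#'   length): a seed window cannot straddle a breakpoint, so raw outermost
#'   anchors systematically stop up to one seed length short of the true
#'   homology boundary
#' @return object of class `synteny_segments`: list with `segments`
#'   data.frame (`segment_id`, `a_start`, `a_end`, `b_start`, `b_end`,
#'   `strand`, `score`, `n_anchors`) and `chains` (per-segment anchor tables)
#' @export
chain_anchors <- function(anchors, max_gap = 20000, min_segment_score = 2000,
                          gap_open = 30, gap_ext = 0.01, indel_ext = 0.5,
                          end_pad = 40) {
  segs <- list(); chains <- list()
  remaining <- anchors
  claimed_a <- data.frame(start = numeric(0), end = numeric(0))
  claimed_b <- data.frame(start = numeric(0), end = numeric(0))
  while (nrow(remaining) > 0) {
    best <- NULL
    for (str in intersect(c("+", "-"), unique(remaining$strand))) {
      sub <- which(remaining$strand == str)
      r <- remaining[sub, , drop = FALSE]
      ch <- cpp_chain_best(r$a_start, r$a_end, r$b_start, r$b_end, r$score,
                           minus_strand = (str == "-"), max_gap = max_gap,
                           gap_open = gap_open, gap_ext = gap_ext,
                           indel_ext = indel_ext)
      if (length(ch$chain) == 0) next
      if (is.null(best) || ch$score > best$score) {
        best <- list(score = ch$score, idx = sub[ch$chain], strand = str)
      }
    }
    if (is.null(best) || best$score < min_segment_score) break
    ca <- remaining[best$idx, , drop = FALSE]
    minus <- best$strand == "-"
    # a chain may jump across an already-claimed region; keep only its best
    # contiguous run between crossings so accepted segments never overlap
    crosses <- vapply(seq_len(nrow(ca)), function(i) {
      if (i == 1) return(FALSE)
      overlaps_any(ca$a_end[i - 1], ca$a_start[i], claimed_a) ||
        (if (!minus) overlaps_any(ca$b_end[i - 1], ca$b_start[i], claimed_b)
         else overlaps_any(ca$b_end[i], ca$b_start[i - 1], claimed_b))
    }, logical(1))
    if (any(crosses)) {
      runs <- split(seq_len(nrow(ca)), cumsum(crosses))
      scores <- vapply(runs, function(ix) {
        chain_score(ca, ix, minus, gap_open, gap_ext, indel_ext)
      }, numeric(1))
      if (max(scores) < min_segment_score) {
        remaining <- remaining[-best$idx, , drop = FALSE]
        next
      }
      ca <- ca[runs[[which.max(scores)]], , drop = FALSE]
      best$score <- max(scores)
    }
    seg <- data.frame(
      segment_id = sprintf("seg_%03d", length(segs) + 1L),
      a_start = min(ca$a_start), a_end = max(ca$a_end),
      b_start = min(ca$b_start), b_end = max(ca$b_end),
      strand = best$strand, score = best$score, n_anchors = nrow(ca),
      stringsAsFactors = FALSE)
    segs[[length(segs) + 1]] <- seg
    chains[[length(chains) + 1]] <- ca
    claimed_a <- rbind(claimed_a, data.frame(start = seg$a_start, end = seg$a_end))
    claimed_b <- rbind(claimed_b, data.frame(start = seg$b_start, end = seg$b_end))
    keep <- !vapply(seq_len(nrow(remaining)), function(i) {
      overlaps_any(remaining$a_start[i], remaining$a_end[i], claimed_a) ||
        overlaps_any(remaining$b_start[i], remaining$b_end[i], claimed_b)
    }, logical(1))
    remaining <- remaining[keep, , drop = FALSE]
  }
  if (!length(segs)) {
    segments <- data.frame(segment_id = character(0), a_start = integer(0),
                           a_end = integer(0), b_start = integer(0),
                           b_end = integer(0), strand = character(0),
                           score = numeric(0), n_anchors = integer(0),
                           stringsAsFactors = FALSE)
  } else {
    segments <- do.call(rbind, segs)
    o <- order(segments$a_start)
    segments <- segments[o, , drop = FALSE]
    chains <- chains[o]
    segments$segment_id <- sprintf("seg_%03d", seq_len(nrow(segments)))
    rownames(segments) <- NULL
    # pad segment ends by one seed length (a seed window cannot straddle a
    # breakpoint, so raw outermost anchors stop systematically short of the
    # true homology boundary), clipped so segments never overlap
    if (end_pad > 0 && nrow(segments) > 0) {
      n <- nrow(segments)
      segments$a_start <- pmax(segments$a_start - end_pad,
                               c(0, segments$a_end[-n]))
      segments$a_end <- pmin(segments$a_end + end_pad,
                             c(segments$a_start[-1], Inf))
      bo <- order(segments$b_start)
      bs <- segments$b_start[bo]; be <- segments$b_end[bo]
      bs <- pmax(bs - end_pad, c(0, be[-n]))
      be <- pmin(be + end_pad, c(bs[-1], Inf))
      segments$b_start[bo] <- bs; segments$b_end[bo] <- be
    }
  }
  structure(list(segments = segments, chains = chains),
            class = "synteny_segments")
}

#' @export
print.synteny_segments <- function(x, ...) {
  cat(sprintf("synteny_segments: %d segments covering %d bp on A\n",
              nrow(x$segments), sum(x$segments$a_end - x$segments$a_start)))
  invisible(x)
}

# piecewise-linear lift of a single point through one chain.
# from = "B": x is a B coordinate, returns the A coordinate (and vice versa).
#' @noRd
lift_point <- function(chain, strand, x, from = "B") {
  if (strand == "+") {
    bx <- c(chain$b_start, chain$b_end - 1L)
    ax <- c(chain$a_start, chain$a_end - 1L)
  } else {
    bx <- c(chain$b_start, chain$b_end - 1L)
    ax <- c(chain$a_end - 1L, chain$a_start)
  }
  if (from == "B") { xs <- bx; ys <- ax } else { xs <- ax; ys <- bx }
  o <- order(xs)
  xs <- xs[o]; ys <- ys[o]
  if (x < min(xs) || x > max(xs)) return(NA_real_)
  round(stats::approx(xs, ys, xout = x, ties = "ordered")$y)
}

#' Lift intervals between genome coordinate systems through segments
#'
#' Maps intervals from genome B onto genome A (or the reverse) using the
#' monotone piecewise-linear map defined by each segment's anchors.  Only the
#' part of an interval falling inside a segment is mapped; intervals outside
#' all segments return NA rows.
#'
#' @param synteny [chain_anchors()] result
#' @param intervals data.frame with 0-based half-open `start`, `end`
#' @param from "B" (default) to map B -> A, or "A" for A -> B
#' @return data.frame with `start`, `end` in the target coordinate system
#'   (NA when unmapped), plus `segment_id`
#' @export
lift_intervals <- function(synteny, intervals, from = "B") {
  segs <- synteny$segments
  res <- lapply(seq_len(nrow(intervals)), function(i) {
    s <- intervals$start[i]; e <- intervals$end[i]
    for (k in seq_len(nrow(segs))) {
      lo <- if (from == "B") segs$b_start[k] else segs$a_start[k]
      hi <- if (from == "B") segs$b_end[k] else segs$a_end[k]
      cs <- max(s, lo); ce <- min(e, hi)
      if (cs >= ce) next
      p1 <- lift_point(synteny$chains[[k]], segs$strand[k], cs, from)
      p2 <- lift_point(synteny$chains[[k]], segs$strand[k], ce - 1L, from)
      if (is.na(p1) || is.na(p2)) next
      return(data.frame(start = min(p1, p2), end = max(p1, p2) + 1L,
                        segment_id = segs$segment_id[k],
                        stringsAsFactors = FALSE))
    }
    data.frame(start = NA_real_, end = NA_real_, segment_id = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
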