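# Independent brute-force oracles, deliberately written without reusing the
# package's code paths.

BASES4 <- c("A", "C", "G", "T")

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# windowed k-mer counting over sequence + reverse complement, N-windows skipped
oracle_count_kmers <- function(s, k) {
  words <- s
  kmers <- sort(apply(expand.grid(rep(list(BASES4), k))[, k:1, drop = FALSE],
                      1, paste, collapse = ""))
  cnt <- stats::setNames(integer(4^k), kmers)
  for (sq in c(s, oracle_revcomp(s))) {
    n <- nchar(sq)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      w <- substr(sq, i, i + k - 1)
      if (w %in% kmers) cnt[w] <- cnt[w] + 1L
    }
  }
  cnt
}

# tetranucleotide z-scores directly from the three-count formula
oracle_tetra_z <- function(s) {
  n2 <- oracle_count_kmers(s, 2)
  n3 <- oracle_count_kmers(s, 3)
  n4 <- oracle_count_kmers(s, 4)
  z <- stats::setNames(numeric(256), names(n4))
  for (w in names(n4)) {
    den <- n2[substr(w, 2, 3)]
    if (den == 0) next
    E <- n3[substr(w, 1, 3)] * n3[substr(w, 2, 4)] / den
    v <- E * (den - n3[substr(w, 1, 3)]) * (den - n3[substr(w, 2, 4)]) / den^2
    if (v > 0) z[w] <- (n4[w] - E) / sqrt(v)
  }
  z
}

# exhaustive best collinear chain by enumerating every subset in order
oracle_best_chain <- function(anchors, minus, max_gap = 20000, gap_open = 30,
                              gap_ext = 0.01, indel_ext = 0.5) {
  n <- nrow(anchors)
  ord <- order(anchors$a_start)
  best <- -Inf
  score_chain <- function(idx) {
    sc <- sum(anchors$score[idx])
    if (length(idx) > 1) for (t in 2:length(idx)) {
      i <- idx[t]; j <- idx[t - 1]
      if (anchors$a_end[j] > anchors$a_start[i]) return(NA_real_)
      ga <- anchors$a_start[i] - anchors$a_end[j]
      gb <- if (!minus) anchors$b_start[i] - anchors$b_end[j]
            else anchors$b_start[j] - anchors$b_end[i]
      if ((!minus && anchors$b_end[j] > anchors$b_start[i]) ||
          (minus && anchors$b_end[i] > anchors$b_start[j])) return(NA_real_)
      if (max(ga, gb) > max_gap) return(NA_real_)
      sc <- sc - (gap_open + gap_ext * max(ga, gb) + indel_ext * abs(ga - gb))
    }
    sc
  }
  for (mask in 1:(2^n - 1)) {
    idx <- ord[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    sc <- score_chain(idx)
    if (!is.na(sc) && sc > best) best <- sc
  }
  best
}

# NG86 by direct recursive pathway enumeration and per-codon site fractions
oracle_ng86 <- function(cod_a, cod_b) {
  GC <- Biostrings::GENETIC_CODE
  stops <- names(GC)[GC == "*"]
  site_S <- function(cd) {
    s <- 0; tot <- 0
    for (p in 1:3) for (b in setdiff(BASES4, substr(cd, p, p))) {
      alt <- cd; substr(alt, p, p) <- b
      if (alt %in% stops) next
      tot <- tot + 1
      if (GC[[alt]] == GC[[cd]]) s <- s + 1
    }
    3 * s / tot
  }
  paths <- function(c1, c2, allow_stop) {
    d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(d)) return(list(c(0, 0)))
    out <- list()
    for (p in d) {
      mid <- c1; substr(mid, p, p) <- substr(c2, p, p)
      if (mid %in% stops && mid != c2 && !allow_stop) next
      syn <- !(mid %in% stops) && !(c1 %in% stops) && GC[[mid]] == GC[[c1]]
      step <- if (syn) c(1, 0) else c(0, 1)
      for (rest in paths(mid, c2, allow_stop)) {
        out[[length(out) + 1]] <- step + rest
      }
    }
    out
  }
  S <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(cod_a)) {
    S <- S + (site_S(cod_a[i]) + site_S(cod_b[i])) / 2
    pw <- paths(cod_a[i], cod_b[i], allow_stop = FALSE)
    if (!length(pw)) pw <- paths(cod_a[i], cod_b[i], allow_stop = TRUE)
    m <- do.call(rbind, pw)
    Sd <- Sd + mean(m[, 1]); Nd <- Nd + mean(m[, 2])
  }
  N <- 3 * length(cod_a) - S
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       dS = jc(if (S > 0) Sd / S else NA), dN = jc(if (N > 0) Nd / N else NA))
}

# all-pairs ungapped overlap search over every diagonal and both orientations
oracle_overlap_edges <- function(reads, min_frac = 0.4, min_identity = 80) {
  enc <- function(s) match(strsplit(s, "")[[1]], BASES4)
  fw <- lapply(reads, enc)
  rc <- lapply(reads, function(s) enc(oracle_revcomp(s)))
  n <- length(reads)
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    li <- length(fw[[i]]); lj <- length(fw[[j]])
    need <- min_frac * min(li, lj)
    found <- FALSE
    for (q in list(fw[[i]], rc[[i]])) {
      if (found) break
      for (d in (-li + 1):(lj - 1)) {
        qs <- max(1, 1 - d); qe <- min(li, lj - d)
        if (qe - qs + 1 < need) next
        m <- sum(q[qs:qe] == fw[[j]][(qs + d):(qe + d)])
        if (100 * m / (qe - qs + 1) >= min_identity) { found <- TRUE; break }
      }
    }
    if (found) out[[length(out) + 1]] <- c(i, j)
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, out)
}

# brute-force spaced-seed anchors: compare every masked word of A against
# every position of B on both strands, then merge same-diagonal runs
oracle_spaced_anchors <- function(a, b, pattern) {
  care <- which(strsplit(pattern, "")[[1]] == "1")
  L <- nchar(pattern)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  brc <- strsplit(oracle_revcomp(b), "")[[1]]
  hits <- list()
  for (ori in 1:2) {
    bb <- if (ori == 1) bv else brc
    for (i in seq_len(length(av) - L + 1)) {
      wa <- av[i + care - 1]
      for (j in seq_len(length(bb) - L + 1)) {
        if (all(wa == bb[j + care - 1])) {
          hits[[length(hits) + 1]] <- data.frame(
            apos = i - 1L, bpos = j - 1L, strand = if (ori == 1) "+" else "-")
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      strand = character(0), score = integer(0)))
  }
  h <- do.call(rbind, hits)
  h <- h[order(h$strand, h$apos - h$bpos, h$apos), ]
  res <- list()
  i <- 1
  while (i <= nrow(h)) {
    j <- i
    while (j + 1 <= nrow(h) && h$strand[j + 1] == h$strand[i] &&
           (h$apos[j + 1] - h$bpos[j + 1]) == (h$apos[i] - h$bpos[i]) &&
           h$apos[j + 1] <= h$apos[j] + L) j <- j + 1
    as <- h$apos[i]; ae <- h$apos[j] + L
    span <- ae - as
    bb <- if (h$strand[i] == "+") bv else brc
    b0 <- h$bpos[i]
    sc <- sum(av[(as + 1):ae] == bb[(b0 + 1):(b0 + span)])
    bs <- if (h$strand[i] == "+") b0 else length(bv) - (b0 + span)
    res[[length(res) + 1]] <- data.frame(
      a_start = as, a_end = ae, b_start = bs, b_end = bs + span,
      strand = h$strand[i], score = sc, stringsAsFactors = FALSE)
    i <- j + 1
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
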