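# Internal helpers: sequence generation, codon machinery, RNG scoping.

BASES <- c("A", "C", "G", "T")

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @noRd
all_codons <- function() {
  as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
}

#' @noRd
sense_codons <- function() setdiff(all_codons(), STOP_CODONS)

#' @noRd
codon_aa <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codons])
}

# Run code with a private RNG stream, restoring the caller's stream after.
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# i.i.d. random sequence at a target GC fraction
#' @noRd
random_seq <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste0(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Order-3 Markov transition table (64 trinucleotide contexts) with
# per-context multiplicative noise around a GC-tilted base distribution.
# One table = one genome-wide compositional signature.  Order 3 matters:
# tetranucleotide z-scores measure exactly the 4-mer structure that tri- and
# dinucleotide counts cannot explain, so an order-<=2 background would carry
# no tetra signal at all.
#' @noRd
markov_trans <- function(gc = 0.5, context_sd = 0.4) {
  base_p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  trans <- matrix(0, nrow = 64, ncol = 4)
  for (i in seq_len(64)) {
    w <- base_p * exp(rnorm(4, 0, context_sd))
    trans[i, ] <- w / sum(w)
  }
  trans
}

#' @noRd
markov_seq <- function(n, gc = 0.5, context_sd = 0.4, trans = NULL) {
  if (n <= 0) return("")
  base_p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  if (is.null(trans)) trans <- markov_trans(gc, context_sd)
  out <- integer(n)
  for (i in seq_len(min(3, n))) out[i] <- sample.int(4, 1, prob = base_p)
  if (n >= 4) {
    cum <- t(apply(trans, 1, cumsum))
    u <- runif(n)
    for (i in 4:n) {
      ci <- (out[i - 3] - 1L) * 16L + (out[i - 2] - 1L) * 4L + out[i - 1]
      out[i] <- findInterval(u[i], cum[ci, ]) + 1L
    }
  }
  paste0(BASES[out], collapse = "")
}

#' @noRd
seq_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Codon usage over sense codons whose base composition is tilted to a target
# GC; optional per-codon multiplicative jitter makes distinct donor tables.
#' @noRd
codon_usage_from_gc <- function(gc, jitter = 0) {
  codons <- sense_codons()
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  w <- vapply(codons, function(cd) {
    prod(p[strsplit(cd, "")[[1]]])
  }, numeric(1))
  if (jitter > 0) w <- w * exp(rnorm(length(w), 0, jitter))
  w / sum(w)
}

# Random in-frame coding sequence: ATG + body codons from `usage` (stop-free
# by construction) + a stop codon.  n_codons counts start and stop.
#' @noRd
random_cds <- function(n_codons, usage) {
  stopifnot(n_codons >= 3)
  body <- sample(names(usage), n_codons - 2, replace = TRUE, prob = usage)
  paste0("ATG", paste0(body, collapse = ""), sample(STOP_CODONS, 1))
}

# expected GC fraction of sequence drawn from a codon usage table
#' @noRd
usage_gc <- function(usage) {
  gcc <- vapply(names(usage), function(cd) {
    sum(strsplit(cd, "")[[1]] %in% c("G", "C")) / 3
  }, numeric(1))
  sum(usage * gcc)
}

# substitute string `ins` into `s` at 0-based position `pos` (insertion)
#' @noRd
str_insert <- function(s, pos, ins) {
  paste0(substr(s, 1, pos), ins, substr(s, pos + 1, nchar(s)))
}

# overwrite `s` with `repl` starting at 0-based position `pos`
#' @noRd
str_overwrite <- function(s, pos, repl) {
  paste0(substr(s, 1, pos), repl, substr(s, pos + 1 + nchar(repl), nchar(s)))
}

# any-overlap test between one interval and a table of intervals
# (all 0-based half-open)
#' @noRd
overlaps_any <- function(start, end, tab) {
  if (is.null(tab) || nrow(tab) == 0) return(FALSE)
  any(tab$start < end & start < tab$end)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# flip bases at random allowed positions until the realized GC matches the
# target (to within one base); used to pin a Markov-generated background to
# an exact genome GC without touching genes or their guard codons
#' @noRd
adjust_gc <- function(genome, target, allowed) {
  x <- strsplit(genome, "")[[1]]
  isgc <- x %in% c("G", "C")
  need <- round(target * length(x)) - sum(isgc)
  if (need > 0) {
    cand <- which(allowed & !isgc)
    n <- min(need, length(cand))
    if (n > 0) {
      pos <- sample(cand, n)
      x[pos] <- sample(c("G", "C"), n, replace = TRUE)
    }
  } else if (need < 0) {
    cand <- which(allowed & isgc)
    n <- min(-need, length(cand))
    if (n > 0) {
      pos <- sample(cand, n)
      x[pos] <- sample(c("A", "T"), n, replace = TRUE)
    }
  }
  paste0(x, collapse = "")
}
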