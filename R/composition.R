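# Compositional signatures: k-mer counts, tetranucleotide z-score profiles,
# %GC, codon-usage foreign-gene detection, tetra + %GC contig binning.

#' Count k-mers over a sequence and its reverse complement
#'
#' Counts are taken on both strands (the sequence and its reverse
#' complement); windows containing non-ACGT characters are skipped, so the
#' total equals twice the number of valid windows.
#'
#' @param sequence character string (or character vector of sequences whose
#'   counts are summed)
#' @param k word length (>= 1)
#' @return named integer vector of length `4^k` in lexicographic A<C<G<T order
#' @export
count_kmers <- function(sequence, k) {
  if (k < 1) stop("k must be >= 1")
  total <- NULL
  for (s in sequence) {
    d <- Biostrings::DNAString(s)
    cnt <- Biostrings::oligonucleotideFrequency(d, k) +
      Biostrings::oligonucleotideFrequency(Biostrings::reverseComplement(d), k)
    total <- if (is.null(total)) cnt else total + cnt
  }
  total
}

#' Tetranucleotide z-score profile
#'
#' For each tetranucleotide w1w2w3w4, the observed count (over both strands)
#' is compared with its maximal-order Markov expectation from the embedded
#' trinucleotides: E = n(w1w2w3) n(w2w3w4) / n(w2w3), with variance
#' E (n(w2w3) - n(w1w2w3)) (n(w2w3) - n(w2w3w4)) / n(w2w3)^2.  Cells whose
#' denominator is zero (or with non-positive variance) are set to z = 0.
#'
#' @param sequence character string or vector of sequences (counts summed,
#'   e.g. all replicons of one genome, or all contigs of one bin)
#' @param id profile identifier
#' @return object of class `tetra_profile`: list with `id`, `z` (named
#'   256-vector), `n_tetramers`
#' @export
tetra_zscores <- function(sequence, id = "seq") {
  if (length(sequence) == 0 || all(nchar(sequence) == 0)) {
    stop("empty sequence")
  }
  if (sum(nchar(sequence)) < 5000) {
    warning("sequence shorter than 5 kb: tetranucleotide z-scores will be noisy")
  }
  n2 <- count_kmers(sequence, 2)
  n3 <- count_kmers(sequence, 3)
  n4 <- count_kmers(sequence, 4)
  w123 <- substr(names(n4), 1, 3)
  w234 <- substr(names(n4), 2, 4)
  w23 <- substr(names(n4), 2, 3)
  denom <- n2[w23]
  E <- ifelse(denom > 0, n3[w123] * n3[w234] / denom, 0)
  v <- ifelse(denom > 0,
              E * (denom - n3[w123]) * (denom - n3[w234]) / denom^2, 0)
  z <- ifelse(v > 0, (n4 - E) / sqrt(v), 0)
  names(z) <- names(n4)
  structure(list(id = id, z = z, n_tetramers = sum(n4)),
            class = "tetra_profile")
}

#' @export
print.tetra_profile <- function(x, ...) {
  cat(sprintf("tetra_profile '%s': %d tetramers, z in [%.2f, %.2f]\n",
              x$id, x$n_tetramers, min(x$z), max(x$z)))
  invisible(x)
}

#' Pearson correlation between two tetranucleotide profiles
#' @param p,q `tetra_profile` objects
#' @return correlation in `[-1, 1]`
#' @export
tetra_correlation <- function(p, q) {
  stopifnot(inherits(p, "tetra_profile"), inherits(q, "tetra_profile"))
  if (stats::sd(p$z) == 0 || stats::sd(q$z) == 0) {
    stop("zero-variance tetranucleotide profile")
  }
  cor(p$z, q$z)
}

#' GC content of a sequence
#'
#' Non-ACGT characters are excluded from the denominator.
#' @param sequence character string or vector (pooled)
#' @return fraction in `[0, 1]`
#' @export
gc_content <- function(sequence) {
  x <- Biostrings::DNAStringSet(sequence)
  f <- colSums(Biostrings::letterFrequency(x, c("A", "C", "G", "T")))
  if (sum(f) == 0) stop("no ACGT bases in sequence")
  unname((f["G"] + f["C"]) / sum(f))
}

#' @noRd
codon_split <- function(cds) {
  n <- nchar(cds) %/% 3
  substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

# extract strand-aware CDS sequences for a gene table (0-based half-open)
#' @noRd
gene_sequences <- function(genome, genes) {
  if (nrow(genes) == 0) return(character(0))
  s <- substring(genome, genes$start + 1L, genes$end)
  mi <- genes$strand == "-"
  if (any(mi)) {
    s[mi] <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s[mi])))
  }
  stats::setNames(s, genes$gene_id)
}

#' Bundled donor codon-usage tables
#'
#' Synthetic donor tables (GC-tilted at 30/40/50% plus uniform usage) against
#' which native codon usage is contrasted in [foreign_gene_scan()]; they play
#' the role of a donor-taxonomy reference.
#' @return named list of usage vectors over the 61 sense codons
#' @export
donor_usage_tables <- function() {
  tabs <- lapply(c(donor_gc30 = 0.30, donor_gc40 = 0.40, donor_gc50 = 0.50),
                 codon_usage_from_gc)
  u <- rep(1 / 61, 61)
  names(u) <- sense_codons()
  c(tabs, list(donor_uniform = u))
}

#' Codon-usage scan for compositionally foreign genes
#'
#' Scores each gene by the per-codon log-odds of the genome's pooled (native)
#' codon usage against the best-fitting donor usage table; negative scores
#' mean a donor model fits better.  The calling threshold is
#' `min(0, quantile(scores, 1 - sensitivity))`, so under an all-native genome
#' essentially nothing is called, while a substantial foreign fraction pulls
#' the quantile down.  Calls are smoothed along the genome: runs of >= 2
#' adjacent sub-threshold genes are kept as called, isolated singletons need
#' an extra 0.05 nats/codon of evidence.  Genes shorter than 30 codons are
#' scored 0, called native and flagged.
#'
#' @param genes gene table (`gene_id`, `start`, `end`, `strand`; 0-based
#'   half-open)
#' @param genome character string
#' @param sensitivity detection sensitivity knob in `(0, 1)`; default 0.7
#' @param donors donor usage tables, default [donor_usage_tables()]
#' @return data.frame with `gene_id`, `n_codons`, `score` (nats/codon),
#'   `call` ("native"/"foreign"), `flagged_short`
#' @export
foreign_gene_scan <- function(genes, genome, sensitivity = 0.7,
                              donors = donor_usage_tables()) {
  if (is.null(genes) || nrow(genes) == 0) {
    return(data.frame(gene_id = character(0), n_codons = integer(0),
                      score = numeric(0), call = character(0),
                      flagged_short = logical(0), stringsAsFactors = FALSE))
  }
  genes <- genes[order(genes$start), , drop = FALSE]
  cds <- gene_sequences(genome, genes)
  cods <- lapply(cds, codon_split)
  sense <- sense_codons()
  p_don <- lapply(donors, function(u) log(u[sense] + 1e-12))
  n_cod <- vapply(cods, length, integer(1))
  score_with <- function(p_nat) {
    vapply(seq_along(cods), function(i) {
      cc <- cods[[i]][cods[[i]] %in% sense]
      if (length(cc) < 30) return(0)
      ll_nat <- sum(p_nat[cc])
      ll_don <- max(vapply(p_don, function(pd) sum(pd[cc]), numeric(1)))
      (ll_nat - ll_don) / length(cc)
    }, numeric(1))
  }
  usage_of <- function(which_genes) {
    pool <- table(factor(unlist(cods[which_genes]), levels = sense))
    p <- log((as.numeric(pool) + 0.5) / sum(as.numeric(pool) + 0.5))
    names(p) <- sense
    p
  }
  # two-pass native estimation: the first pooled table is contaminated by
  # whatever foreign genes are present; refit it on genes the first pass
  # considers native, then rescore
  score <- score_with(usage_of(seq_along(cods)))
  clean <- score >= 0
  if (any(clean) && any(!clean)) score <- score_with(usage_of(clean))
  short <- n_cod < 30
  eligible <- !short
  thr <- if (any(eligible)) {
    min(0, unname(quantile(score[eligible], 1 - sensitivity)))
  } else 0
  raw <- eligible & score < thr
  # run-length smoothing over gene order along the genome
  r <- rle(raw)
  keep <- raw
  endi <- cumsum(r$lengths)
  starti <- endi - r$lengths + 1L
  for (j in which(r$values & r$lengths == 1)) {
    i <- starti[j]
    if (score[i] >= thr - 0.05) keep[i] <- FALSE
  }
  data.frame(gene_id = genes$gene_id, n_codons = n_cod, score = score,
             call = ifelse(keep, "foreign", "native"),
             flagged_short = short, stringsAsFactors = FALSE, row.names = NULL)
}

#' Reference composition profile for binning
#' @param sequence reference genome sequence(s)
#' @param id reference identifier
#' @return list with `id`, `profile` ([tetra_zscores()]), `gc`
#' @export
reference_profile <- function(sequence, id) {
  list(id = id, profile = tetra_zscores(sequence, id), gc = gc_content(sequence))
}

#' Bin contigs against reference composition profiles
#'
#' A contig is assigned to the reference with the highest squared Pearson
#' correlation of tetranucleotide z-scores, provided R^2 >= `r2_cutoff` and
#' the absolute GC difference is <= `gc_tolerance`; otherwise it is unbinned.
#' Contigs shorter than 1 kb are flagged and left unbinned.
#'
#' @param contigs named character vector of contig sequences
#' @param references list of [reference_profile()] objects
#' @param r2_cutoff squared-correlation cutoff (default 0.9)
#' @param gc_tolerance absolute GC difference tolerance (default 0.05)
#' @return data.frame with `contig`, `bin` (reference id or NA), `r2`,
#'   `delta_gc`, `status`
#' @export
bin_contigs <- function(contigs, references, r2_cutoff = 0.9,
                        gc_tolerance = 0.05) {
  ids <- names(contigs) %||% sprintf("contig_%05d", seq_along(contigs))
  ref_ids <- vapply(references, `[[`, character(1), "id")
  res <- lapply(seq_along(contigs), function(i) {
    if (nchar(contigs[[i]]) < 1000) {
      return(data.frame(contig = ids[i], bin = NA_character_, r2 = NA_real_,
                        delta_gc = NA_real_, status = "too_short",
                        stringsAsFactors = FALSE))
    }
    prof <- suppressWarnings(tetra_zscores(contigs[[i]], ids[i]))
    gcc <- gc_content(contigs[[i]])
    r2 <- vapply(references, function(r) tetra_correlation(prof, r$profile)^2,
                 numeric(1))
    best <- which.max(r2)
    dgc <- abs(gcc - references[[best]]$gc)
    if (r2[best] >= r2_cutoff && dgc <= gc_tolerance) {
      data.frame(contig = ids[i], bin = ref_ids[best], r2 = r2[best],
                 delta_gc = dgc, status = "binned", stringsAsFactors = FALSE)
    } else {
      data.frame(contig = ids[i], bin = NA_character_, r2 = r2[best],
                 delta_gc = dgc, status = "unbinned", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
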