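# Codon-aware alignment and Nei-Gojobori (1986) dN/dS estimation, pairwise
# and pooled across recruited metagenome reads.

# --- cached NG86 machinery -------------------------------------------------

.ng86_cache <- new.env(parent = emptyenv())

# per-codon expected synonymous site count by mutation-fate enumeration.
# Mutations to stop codons are excluded from the fate space and the
# synonymous fraction is rescaled to 3 sites per codon, so that
# S + N = 3 * n_codons exactly and the site counts describe the same
# mutation space in which coding sequences actually evolve (stop-creating
# changes are purged by selection).
#' @noRd
syn_sites <- function() {
  if (!is.null(.ng86_cache$S)) return(.ng86_cache$S)
  aa <- Biostrings::GENETIC_CODE
  codons <- sense_codons()
  S <- vapply(codons, function(cd) {
    s <- 0; tot <- 0
    for (pos in 1:3) {
      b <- substr(cd, pos, pos)
      for (nb in setdiff(BASES, b)) {
        new <- cd
        substr(new, pos, pos) <- nb
        if (new %in% STOP_CODONS) next
        tot <- tot + 1
        if (aa[[new]] == aa[[cd]]) s <- s + 1
      }
    }
    3 * s / tot
  }, numeric(1))
  .ng86_cache$S <- S
  S
}

# average synonymous/nonsynonymous difference counts over all equally
# weighted shortest substitution pathways between two sense codons; pathways
# passing through a stop codon are excluded (unless all do, in which case all
# pathways are used with steps to/from stops counted as nonsynonymous)
#' @noRd
pathway_counts <- function(c1, c2) {
  key <- paste(sort(c(c1, c2)), collapse = "|")
  hit <- .ng86_cache[[key]]
  if (!is.null(hit)) return(hit)
  aa <- Biostrings::GENETIC_CODE
  diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  res <- if (length(diffs) == 0) c(sd = 0, nd = 0) else {
    perms <- if (length(diffs) == 1) list(diffs) else {
      if (length(diffs) == 2) {
        list(diffs, rev(diffs))
      } else {
        p <- list()
        for (i in 1:3) for (j in setdiff(1:3, i)) {
          p[[length(p) + 1]] <- diffs[c(i, j, setdiff(1:3, c(i, j)))]
        }
        p
      }
    }
    score_path <- function(ord, allow_stop) {
      cur <- c1; sd <- 0; nd <- 0
      for (pos in ord) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        if (nxt %in% STOP_CODONS && nxt != c2 && !allow_stop) return(NULL)
        syn <- !(cur %in% STOP_CODONS) && !(nxt %in% STOP_CODONS) &&
          aa[[nxt]] == aa[[cur]]
        if (syn) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    }
    paths <- Filter(Negate(is.null), lapply(perms, score_path, allow_stop = FALSE))
    if (!length(paths)) paths <- lapply(perms, score_path, allow_stop = TRUE)
    m <- do.call(rbind, paths)
    c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]))
  }
  assign(key, res, envir = .ng86_cache)
  res
}

# --- codon alignments ------------------------------------------------------

#' Zip two equal-length in-frame CDSs into a codon alignment
#' @param cds_a,cds_b coding sequences of equal length divisible by 3
#' @return object of class `codon_alignment`
#' @export
codon_alignment <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) stop("coding sequences differ in length")
  if (nchar(cds_a) %% 3 != 0) stop("length not divisible by 3")
  a <- codon_split(cds_a); b <- codon_split(cds_b)
  # trailing stop pair trimmed; internal stops are not allowed
  n <- length(a)
  if (n > 0 && (a[n] %in% STOP_CODONS || b[n] %in% STOP_CODONS)) {
    a <- a[-n]; b <- b[-n]
  }
  if (any(a %in% STOP_CODONS) || any(b %in% STOP_CODONS)) {
    stop("internal stop codon in codon alignment")
  }
  structure(list(codons_a = a, codons_b = b, n_codons = length(a)),
            class = "codon_alignment")
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Expands each aligned amino-acid column to its source codon; columns
#' containing a gap in either row are dropped.  The translated CDSs must
#' match the ungapped protein rows exactly (trailing stop trimmed).
#'
#' @param protein_alignment character vector of 2 aligned protein rows
#'   (with `-` gaps)
#' @param cds_a,cds_b the source coding sequences
#' @return object of class `codon_alignment`
#' @export
backtranslate <- function(protein_alignment, cds_a, cds_b) {
  stopifnot(length(protein_alignment) == 2)
  check_row <- function(row, cds, label) {
    prot <- gsub("-", "", row)
    tr <- as.character(suppressWarnings(
      Biostrings::translate(Biostrings::DNAString(cds))))
    tr <- sub("\\*$", "", tr)
    if (nchar(tr) != nchar(prot)) {
      stop(sprintf("translation of cds_%s has %d residues, protein row has %d",
                   label, nchar(tr), nchar(prot)))
    }
    mism <- which(strsplit(tr, "")[[1]] != strsplit(prot, "")[[1]])
    if (length(mism)) {
      stop(sprintf("cds_%s does not translate to its protein row at position %d",
                   label, mism[1]))
    }
    prot
  }
  check_row(protein_alignment[1], cds_a, "a")
  check_row(protein_alignment[2], cds_b, "b")
  row_a <- strsplit(protein_alignment[1], "")[[1]]
  row_b <- strsplit(protein_alignment[2], "")[[1]]
  if (length(row_a) != length(row_b)) stop("alignment rows differ in length")
  cod_a <- codon_split(cds_a); cod_b <- codon_split(cds_b)
  ia <- cumsum(row_a != "-"); ib <- cumsum(row_b != "-")
  keep <- row_a != "-" & row_b != "-"
  a <- cod_a[ia[keep]]; b <- cod_b[ib[keep]]
  drop <- a %in% STOP_CODONS | b %in% STOP_CODONS
  a <- a[!drop]; b <- b[!drop]
  structure(list(codons_a = a, codons_b = b, n_codons = length(a)),
            class = "codon_alignment")
}

# --- NG86 estimation -------------------------------------------------------

#' @noRd
jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' @noRd
dnds_from_counts <- function(S, N, Sd, Nd, n_codons, codons_used = n_codons) {
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- jc_correct(pS); dN <- jc_correct(pN)
  flags <- character(0)
  if (!is.na(pS) && pS >= 0.75) flags <- c(flags, "pS_saturated")
  if (!is.na(pN) && pN >= 0.75) flags <- c(flags, "pN_saturated")
  omega <- if (is.na(dS) || is.na(dN) || dS == 0) {
    if (!is.na(dS) && dS == 0) flags <- c(flags, "dS_zero")
    NA_real_
  } else dN / dS
  structure(list(dN = dN, dS = dS, omega = omega, S_sites = S, N_sites = N,
                 Sd = Sd, Nd = Nd, n_codons = n_codons,
                 codons_used = codons_used, flags = flags),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("NG86: dN = %.4f, dS = %.4f, omega = %s (S = %.1f, N = %.1f, %d codons)%s\n",
              x$dN, x$dS,
              if (is.na(x$omega)) "undefined" else sprintf("%.3f", x$omega),
              x$S_sites, x$N_sites, x$n_codons,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Nei-Gojobori (1986) dN/dS for a codon alignment
#'
#' Counts synonymous and nonsynonymous sites per codon by mutation-fate
#' enumeration (mutations to stop codons are excluded from the fate space and
#' the fractions rescaled, so `S_sites + N_sites = 3 * n_codons` exactly;
#' site counts averaged over the two sequences) and substitution differences
#' by equal weighting of all shortest pathways.  Proportions are Jukes-Cantor corrected,
#' `d = -3/4 log(1 - 4p/3)`; p >= 3/4 and dS = 0 are flagged.
#'
#' @param aln a `codon_alignment`
#' @return object of class `dnds_result`
#' @export
ng86_dnds <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  n <- aln$n_codons
  if (n < 1) stop("empty codon alignment")
  if (n < 10) warning("fewer than 10 codons: estimates will be unstable")
  Stab <- syn_sites()
  S <- (sum(Stab[aln$codons_a]) + sum(Stab[aln$codons_b])) / 2
  N <- 3 * n - S
  Sd <- 0; Nd <- 0
  for (i in seq_len(n)) {
    pc <- pathway_counts(aln$codons_a[i], aln$codons_b[i])
    Sd <- Sd + pc["sd"]; Nd <- Nd + pc["nd"]
  }
  dnds_from_counts(S, N, unname(Sd), unname(Nd), n)
}

#' Pooled dN/dS from recruited metagenome reads over one gene
#'
#' Compares every read codon that fully covers a reference codon of the gene
#' with that reference codon, classifying substitutions by NG86 pathway
#' counting, and pools counts across reads into one estimate.  Reference
#' codons covered by fewer than `min_depth` reads are excluded; only the
#' aligned portion of each hit contributes.
#'
#' @param gene one-row gene table (`start`, `end`, `strand`, 0-based
#'   half-open) on the reference
#' @param hits [recruit()] output for reads against the reference
#' @param reads read table from [simulate_metagenome()] or a named character
#'   vector of read sequences
#' @param reference the reference genome sequence (single replicon)
#' @param min_depth minimum reads covering a codon (default 4)
#' @return `dnds_result`; flagged `empty` when no codon meets the depth
#' @export
read_dnds <- function(gene, hits, reads, reference, min_depth = 4) {
  read_seq <- if (is.data.frame(reads)) {
    stats::setNames(reads$seq, reads$read_id)
  } else reads
  g0 <- gene$start[1]; g1 <- gene$end[1]; strand <- gene$strand[1]
  glen <- g1 - g0
  stopifnot(glen %% 3 == 0)
  n_cod <- glen %/% 3
  hh <- hits[hits$ref_end > g0 & hits$ref_start < g1 &
               hits$read_aln_frac >= 0.3, , drop = FALSE]
  ref_cds <- gene_sequences(reference, data.frame(
    gene_id = "g", start = g0, end = g1, strand = strand,
    stringsAsFactors = FALSE))
  ref_cod <- codon_split(ref_cds)
  oriented <- vapply(seq_len(nrow(hh)), function(i) {
    s <- read_seq[[hh$read[i]]]
    if (hh$strand[i] == "-") seq_revcomp(s) else s
  }, character(1))
  Stab <- syn_sites()
  S <- 0; N <- 0; Sd <- 0; Nd <- 0; used <- 0L
  for (i in seq_len(n_cod)) {
    rc <- ref_cod[i]
    if (!(rc %in% names(Stab))) next    # reference codon is a stop: skip
    cs <- if (strand == "+") g0 + 3 * (i - 1) else g1 - 3 * i
    ce <- cs + 3
    cov <- which(hh$ref_start <= cs & hh$ref_end >= ce)
    if (length(cov) < min_depth) next
    used <- used + 1L
    for (j in cov) {
      off <- hh$q_start[j] + (cs - hh$ref_start[j])
      trip <- substr(oriented[j], off + 1, off + 3)
      if (strand == "-") trip <- seq_revcomp(trip)
      if (trip %in% STOP_CODONS || grepl("[^ACGT]", trip)) next
      pc <- pathway_counts(rc, trip)
      Sd <- Sd + pc["sd"]; Nd <- Nd + pc["nd"]
      S <- S + Stab[[rc]]; N <- N + (3 - Stab[[rc]])
    }
  }
  if (used == 0L) {
    res <- dnds_from_counts(0, 0, 0, 0, n_cod, codons_used = 0L)
    res$flags <- c(res$flags, "empty")
    return(res)
  }
  dnds_from_counts(S, N, unname(Sd), unname(Nd), n_cod, codons_used = used)
}
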