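# Synthetic bacterial evolution: ancestor genome, diverged descendants with
# planted islands and transposons, mixed-community metagenome, truth tables.

#' Simulate an ancestor genome with planted protein-coding genes
#'
#' Generates an intergenic background from a single genome-wide order-3
#' Markov model (so the genome carries a coherent tetranucleotide signature,
#' as real genomes do) and plants non-overlapping ORFs (ATG .. stop, length
#' divisible by 3) drawn from a GC-matched, biased codon usage on both
#' strands.  Each gene gets an adjacent in-frame stop codon immediately
#' upstream, so the planted gene is the maximal ORF of its frame and can be
#' recovered with exact coordinates.  After assembly, intergenic bases are
#' adjusted so the realized genome GC matches the target to within one base.
#'
#' @param length genome length in bases
#' @param gc target GC fraction in `[0, 1]`
#' @param n_genes number of genes to plant; default fills ~65% of the genome
#' @param mean_gene_len mean gene length in bases (start and stop included)
#' @param seed integer seed; fixed seeds give byte-identical output
#' @return list with `seq` (character), `genes` (data.frame with `gene_id`,
#'   0-based half-open `start`/`end`, `strand`), `gc`, and `usage` (the native
#'   codon usage table used for gene bodies)
#' @export
simulate_ancestor <- function(length, gc = 0.63, n_genes = NULL,
                              mean_gene_len = 900, seed = 1) {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  if (is.null(n_genes)) {
    n_genes <- max(0L, floor(0.65 * length / (mean_gene_len + 150)))
  }
  if (n_genes * mean_gene_len > 0.95 * length) {
    stop("infeasible gene packing: n_genes * mean_gene_len exceeds 95% of genome length")
  }
  with_seed(seed, {
    usage <- codon_usage_from_gc(gc, jitter = 1.0)
    if (n_genes == 0) {
      trans <- markov_trans(gc, 1.2)
      sq <- markov_seq(length, gc, trans = trans)
      sq <- adjust_gc(sq, gc, rep(TRUE, length))
      return(list(seq = sq, genes = empty_gene_table(), gc = gc,
                  usage = usage))
    }
    n_cod <- pmax(31L, as.integer(round(rnorm(n_genes, mean_gene_len / 3, mean_gene_len / 9))))
    glen <- 3L * n_cod
    slack <- length - sum(glen)
    min_gap <- 30L
    if (slack < min_gap * (n_genes + 1)) {
      stop("infeasible gene packing: not enough intergenic room")
    }
    extra <- slack - min_gap * (n_genes + 1L)
    gaps <- min_gap + as.vector(rmultinom(1, extra, runif(n_genes + 1) + 0.01))
    starts <- cumsum(c(gaps[1], head(glen + gaps[-1], -1)))  # 0-based
    ends <- starts + glen
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)

    gene_seq <- vapply(n_cod, random_cds, character(1), usage = usage)
    # solve intergenic GC so the whole genome hits the target
    gc_genes <- sum(vapply(gene_seq, function(s) {
      sum(strsplit(s, "")[[1]] %in% c("G", "C"))
    }, numeric(1)))
    int_bases <- length - sum(glen)
    gc_int <- (gc * length - gc_genes) / int_bases
    gc_int <- min(max(gc_int, 0.02), 0.98)

    # one Markov table for the whole intergenic background, so the genome
    # carries a coherent genome-wide compositional signature
    trans <- markov_trans(gc_int, 1.2)
    pieces <- character(2 * n_genes + 1)
    pieces[1] <- markov_seq(gaps[1], gc_int, trans = trans)
    for (i in seq_len(n_genes)) {
      pieces[2 * i] <- if (strand[i] == "+") gene_seq[i] else seq_revcomp(gene_seq[i])
      pieces[2 * i + 1] <- markov_seq(gaps[i + 1], gc_int, trans = trans)
    }
    genome <- paste0(pieces, collapse = "")
    # in-frame upstream stop guard adjacent to each gene
    for (i in seq_len(n_genes)) {
      if (strand[i] == "+") {
        genome <- str_overwrite(genome, starts[i] - 3L, "TAA")
      } else {
        genome <- str_overwrite(genome, ends[i], "TTA")
      }
    }
    # pin realized GC to the target using intergenic positions only
    allowed <- rep(TRUE, length)
    for (i in seq_len(n_genes)) {
      lo <- starts[i] - 3L; hi <- ends[i] + 3L   # gene plus guard margin
      allowed[max(1L, lo + 1L):min(length, hi)] <- FALSE
    }
    genome <- adjust_gc(genome, gc, allowed)
    genes <- data.frame(
      gene_id = sprintf("anc_%04d", seq_len(n_genes)),
      start = starts, end = ends, strand = strand,
      origin = "ancestral", stringsAsFactors = FALSE)
    list(seq = genome, genes = genes, gc = gc, usage = usage)
  })
}

#' @noRd
empty_gene_table <- function() {
  data.frame(gene_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), origin = character(0),
             stringsAsFactors = FALSE)
}

#' Bundled synthetic mobile-element marker genes
#'
#' Reads the small synthetic marker FASTA shipped with the package.  These
#' CDSs play the role of laterally transferred catabolic genes (lin-like
#' markers) carried by simulated transposons; they stand in for an
#' IS-element/marker reference database.
#'
#' @param path optional path to a user-supplied marker FASTA
#' @return named character vector of marker CDS sequences
#' @export
marker_genes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "markers.fasta", package = "metalca")
  }
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

# island payload: mini-genome with donor-usage genes and Markov intergenic DNA
#' @noRd
generate_island <- function(len, gc, usage) {
  n_genes <- max(1L, floor(len / 1200))
  n_cod <- pmax(60L, round(rnorm(n_genes, 260, 40)))
  glen <- 3L * n_cod
  while (sum(glen) > 0.85 * len) {
    n_genes <- n_genes - 1L
    if (n_genes == 0) { glen <- integer(0); break }
    glen <- glen[seq_len(n_genes)]
  }
  slack <- len - sum(glen)
  gaps <- 15L + as.vector(rmultinom(1, max(0, slack - 15L * (n_genes + 1L)),
                                    runif(n_genes + 1) + 0.01))
  starts <- if (n_genes > 0) cumsum(c(gaps[1], head(glen + gaps[-1], -1))) else integer(0)
  trans <- markov_trans(gc, 0.4)
  pieces <- character(2 * n_genes + 1)
  pieces[1] <- markov_seq(gaps[1], gc, trans = trans)
  strand <- if (n_genes > 0) sample(c("+", "-"), n_genes, replace = TRUE) else character(0)
  for (i in seq_len(n_genes)) {
    cds <- random_cds(n_cod[i], usage)
    pieces[2 * i] <- if (strand[i] == "+") cds else seq_revcomp(cds)
    pieces[2 * i + 1] <- markov_seq(gaps[i + 1], gc, trans = trans)
  }
  sq <- paste0(pieces, collapse = "")
  for (i in seq_len(n_genes)) {
    sq <- if (strand[i] == "+") str_overwrite(sq, starts[i] - 3L, "TAA")
          else str_overwrite(sq, starts[i] + glen[i], "TTA")
  }
  genes <- data.frame(start = starts, end = starts + glen, strand = strand,
                      stringsAsFactors = FALSE)
  # trim/pad to exact length (gap arithmetic is exact, defensive only)
  sq <- substr(sq, 1, len)
  list(seq = sq, genes = genes)
}

# base sequence of one transposable element; near-identical copies are
# derived from this by light mutation.  Body composition is Markov at a GC
# distinct from typical hosts so the element carries a compositional signal.
#' @noRd
generate_element <- function(len, marker = NULL, gc = 0.45) {
  body <- markov_seq(len, gc)
  if (!is.null(marker)) {
    mlen <- nchar(marker)
    if (len < mlen + 60) stop("transposon too short to carry its marker gene")
    mstart <- as.integer(ceiling((len - mlen) / 2))   # 0-based marker start
    sq <- str_overwrite(body, mstart, marker)
    sq <- str_overwrite(sq, mstart - 3L, "TAA")
    list(seq = sq, marker_start = mstart, marker_end = mstart + mlen)
  } else {
    list(seq = body, marker_start = NA, marker_end = NA)
  }
}

#' @noRd
mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  x <- strsplit(s, "")[[1]]
  pos <- which(runif(length(x)) < rate & x %in% BASES)
  if (length(pos)) {
    idx <- (match(x[pos], BASES) - 1L + sample.int(3L, length(pos), replace = TRUE)) %% 4L + 1L
    x[pos] <- BASES[idx]
  }
  paste0(x, collapse = "")
}

#' Evolve a descendant genome from a simulated ancestor
#'
#' Applies i.i.d. per-site substitutions (no indels outside planted
#' insertions), then inserts genomic islands (independent Markov composition
#' with their own GC and donor codon usage) and near-identical transposon
#' copies (optionally carrying a marker gene) at intergenic positions.
#' Ancestor gene models are lifted through the insertions and all planted
#' material is recorded in a truth table.
#'
#' @param ancestor result of [simulate_ancestor()]
#' @param substitution_rate expected substitutions per site, in `[0, 0.25]`
#' @param islands data.frame with columns `length`, `gc`, `codon_usage_id`
#' @param transposons data.frame with columns `element_id`, `length`,
#'   `copy_count`, `carries_marker`
#' @param seed integer seed
#' @param markers named character vector of marker CDSs (default: bundled set)
#' @return list with `seq`, `genes` (lifted ancestral + island + marker gene
#'   models with an `origin` column), and `truth` (a truth table with
#'   `true_ancestral_genes`, `planted_islands`, `planted_transposon_loci`,
#'   `per_site_substitutions`; intervals 0-based half-open in descendant
#'   coordinates)
#' @export
evolve_descendant <- function(ancestor, substitution_rate = 0.01,
                              islands = NULL, transposons = NULL, seed = 1,
                              markers = NULL) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 0.25)
  with_seed(seed, {
    L <- nchar(ancestor$seq)
    x <- strsplit(ancestor$seq, "")[[1]]
    sub_pos <- which(runif(L) < substitution_rate & x %in% BASES)
    if (length(sub_pos)) {
      idx <- (match(x[sub_pos], BASES) - 1L +
                sample.int(3L, length(sub_pos), replace = TRUE)) %% 4L + 1L
      x[sub_pos] <- BASES[idx]
    }
    genome <- paste0(x, collapse = "")

    # --- build insertion payloads ---
    payloads <- list()   # each: list(seq, type, id, genes (relative), ...)
    if (!is.null(islands) && nrow(islands) > 0) {
      usage_cache <- list()
      for (i in seq_len(nrow(islands))) {
        uid <- as.character(islands$codon_usage_id[i])
        if (is.null(usage_cache[[uid]])) {
          usage_cache[[uid]] <- with_seed(
            1e6 + sum(utf8ToInt(uid)),
            codon_usage_from_gc(islands$gc[i], jitter = 0.3))
        }
        isl <- generate_island(islands$length[i], islands$gc[i], usage_cache[[uid]])
        payloads[[length(payloads) + 1]] <- list(
          seq = isl$seq, type = "island", id = sprintf("isl%02d", i),
          genes = isl$genes)
      }
    }
    if (!is.null(transposons) && nrow(transposons) > 0) {
      if (is.null(markers)) markers <- marker_genes()
      for (i in seq_len(nrow(transposons))) {
        eid <- as.character(transposons$element_id[i])
        mk <- if (isTRUE(transposons$carries_marker[i])) {
          markers[[(i - 1L) %% length(markers) + 1L]]
        } else NULL
        base <- with_seed(2e6 + sum(utf8ToInt(eid)),
                          generate_element(transposons$length[i], mk))
        for (cp in seq_len(transposons$copy_count[i])) {
          payloads[[length(payloads) + 1]] <- list(
            seq = mutate_seq(base$seq, 0.002), type = "transposon",
            id = eid, copy = cp,
            marker_start = base$marker_start, marker_end = base$marker_end)
        }
      }
    }

    lifted <- ancestor$genes
    truth <- list(
      true_ancestral_genes = ancestor$genes$gene_id,
      planted_islands = data.frame(island_id = character(0), start = integer(0),
                                   end = integer(0), stringsAsFactors = FALSE),
      planted_transposon_loci = data.frame(element_id = character(0),
                                           copy = integer(0), start = integer(0),
                                           end = integer(0), stringsAsFactors = FALSE),
      per_site_substitutions = sub_pos - 1L)
    extra_genes <- empty_gene_table()

    if (length(payloads)) {
      # candidate intergenic points: one per gap wide enough to take an insert
      g <- ancestor$genes[order(ancestor$genes$start), , drop = FALSE]
      bnd_lo <- c(0L, g$end)
      bnd_hi <- c(g$start, L)
      ok <- bnd_hi - bnd_lo >= 16L
      lo <- bnd_lo[ok] + 8L
      hi <- bnd_hi[ok] - 8L
      if (sum(ok) < length(payloads)) {
        stop("insertion cannot be placed intergenically: not enough intergenic gaps")
      }
      # insertion sites are kept >= 400 bp apart so that the junctions of
      # neighbouring insertions are resolvable at short-read length
      cand <- sample(seq_along(lo))
      pts <- integer(0)
      for (j in cand) {
        p <- as.integer(lo[j] + sample.int(max(1L, hi[j] - lo[j] + 1L), 1L) - 1L)
        if (!length(pts) || min(abs(pts - p)) >= 400L) pts <- c(pts, p)
        if (length(pts) == length(payloads)) break
      }
      if (length(pts) < length(payloads)) {
        stop("insertion cannot be placed intergenically: not enough intergenic gaps")
      }
      o <- order(pts)
      pts <- pts[o]
      payloads <- payloads[o]   # pair payloads with sorted points
      plens <- vapply(payloads, function(p) nchar(p$seq), integer(1))
      shift_before <- cumsum(c(0L, head(plens, -1)))
      planted_start <- pts + shift_before
      # assemble
      pieces <- substring(genome, c(1L, pts + 1L), c(pts, L))
      out <- character(length(pieces) + length(payloads))
      out[seq(1, length(out), by = 2)] <- pieces
      out[seq(2, length(out) - 1, by = 2)] <-
        vapply(payloads, `[[`, character(1), "seq")
      genome <- paste0(out, collapse = "")
      # lift ancestor gene models (shifts computed from pre-insertion coords)
      shift <- vapply(lifted$start, function(g) sum(plens[pts <= g]), numeric(1))
      lifted$start <- lifted$start + as.integer(shift)
      lifted$end <- lifted$end + as.integer(shift)
      # truth intervals + payload gene models in descendant coordinates
      for (k in seq_along(payloads)) {
        p <- payloads[[k]]
        s0 <- planted_start[k]
        if (p$type == "island") {
          truth$planted_islands <- rbind(truth$planted_islands, data.frame(
            island_id = p$id, start = s0, end = s0 + plens[k],
            stringsAsFactors = FALSE))
          if (nrow(p$genes)) {
            extra_genes <- rbind(extra_genes, data.frame(
              gene_id = sprintf("%s_g%02d", p$id, seq_len(nrow(p$genes))),
              start = p$genes$start + s0, end = p$genes$end + s0,
              strand = p$genes$strand, origin = "island",
              stringsAsFactors = FALSE))
          }
        } else {
          truth$planted_transposon_loci <- rbind(
            truth$planted_transposon_loci, data.frame(
              element_id = p$id, copy = p$copy, start = s0, end = s0 + plens[k],
              stringsAsFactors = FALSE))
          if (!is.na(p$marker_start)) {
            extra_genes <- rbind(extra_genes, data.frame(
              gene_id = sprintf("%s_c%d_marker", p$id, p$copy),
              start = s0 + p$marker_start, end = s0 + p$marker_end,
              strand = "+", origin = "marker", stringsAsFactors = FALSE))
          }
        }
      }
    }
    genes <- rbind(lifted, extra_genes)
    genes <- genes[order(genes$start), , drop = FALSE]
    rownames(genes) <- NULL
    list(seq = genome, genes = genes, truth = truth)
  })
}

#' Simulate a shotgun metagenome from a mixed community
#'
#' Draws reads multinomially across community members by relative abundance,
#' from uniform positions and random strands, and applies i.i.d. per-base
#' substitution errors.  Read headers retain the ground-truth source label,
#' start and strand, for truth-aware evaluation only (pipeline code never
#' reads them).
#'
#' @param members list of `list(id =, seq =, abundance =)`; abundances must
#'   sum to 1
#' @param n_reads total read count
#' @param read_length single length or `c(min, max)` (sampled uniformly);
#'   must be >= 50
#' @param error_rate per-base substitution probability
#' @param seed integer seed
#' @return data.frame with `read_id`, `seq`, `source`, `start`, `strand`
#' @export
simulate_metagenome <- function(members, n_reads, read_length = 150,
                                error_rate = 0.01, seed = 1) {
  ab <- vapply(members, `[[`, numeric(1), "abundance")
  if (abs(sum(ab) - 1) > 1e-6) stop("member abundances must sum to 1")
  if (min(read_length) < 50) stop("read_length must be >= 50")
  with_seed(seed, {
    counts <- as.vector(rmultinom(1, n_reads, ab))
    out <- vector("list", length(members))
    gi <- 0L
    for (m in seq_along(members)) {
      cnt <- counts[m]
      if (cnt == 0) { out[[m]] <- NULL; next }
      sq <- members[[m]]$seq
      L <- nchar(sq)
      rl <- if (length(read_length) == 2) {
        sample(read_length[1]:read_length[2], cnt, replace = TRUE)
      } else rep(read_length, cnt)
      rl <- pmin(rl, L)
      starts <- vapply(rl, function(r) sample.int(L - r + 1L, 1L) - 1L, integer(1))
      reads <- substring(sq, starts + 1L, starts + rl)
      strand <- sample(c("+", "-"), cnt, replace = TRUE)
      mi <- strand == "-"
      if (any(mi)) {
        reads[mi] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(reads[mi])))
      }
      if (error_rate > 0) {
        nerr <- rbinom(cnt, rl, error_rate)
        for (i in which(nerr > 0)) {
          x <- strsplit(reads[i], "")[[1]]
          pos <- sample.int(rl[i], nerr[i])
          idx <- (match(x[pos], BASES) - 1L +
                    sample.int(3L, nerr[i], replace = TRUE)) %% 4L + 1L
          x[pos] <- BASES[idx]
          reads[i] <- paste0(x, collapse = "")
        }
      }
      out[[m]] <- data.frame(
        read_id = sprintf("r%07d|%s|%d|%s", gi + seq_len(cnt),
                          members[[m]]$id, starts, strand),
        seq = reads, source = members[[m]]$id, start = starts,
        strand = strand, stringsAsFactors = FALSE)
      gi <- gi + cnt
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Simulate a pair of coding sequences under a target dN/dS
#'
#' Starts from a uniform-random sense-codon sequence and evolves two lineages
#' independently.  Proposed single-base changes that would create a stop
#' codon are rejected; nonsynonymous changes are accepted with relative
#' probability `omega` versus 1 for synonymous changes, realizing the target
#' dN/dS under a uniform codon background.
#'
#' @param omega target dN/dS ratio (> 0)
#' @param n_codons number of codons (>= 50)
#' @param t total expected proposals per site across the pair
#' @param seed integer seed
#' @return list with `a`, `b` (coding sequences) and `n_codons`
#' @export
simulate_codon_pairs <- function(omega, n_codons, t = 0.2, seed = 1) {
  stopifnot(omega > 0, n_codons >= 50)
  with_seed(seed, {
    aa_of <- Biostrings::GENETIC_CODE
    root <- sample(sense_codons(), n_codons, replace = TRUE)
    evolve <- function(cod) {
      n_prop <- rpois(1, (t / 2) * 3 * n_codons)
      acc_syn <- min(1, 1 / omega)
      acc_non <- min(1, omega)
      for (i in seq_len(n_prop)) {
        ci <- sample.int(n_codons, 1)
        pos <- sample.int(3L, 1)
        old <- cod[ci]
        b <- substr(old, pos, pos)
        nb <- sample(setdiff(BASES, b), 1)
        new <- old
        substr(new, pos, pos) <- nb
        if (new %in% STOP_CODONS) next
        syn <- aa_of[[new]] == aa_of[[old]]
        if (runif(1) < (if (syn) acc_syn else acc_non)) cod[ci] <- new
      }
      cod
    }
    list(a = paste0(evolve(root), collapse = ""),
         b = paste0(evolve(root), collapse = ""),
         n_codons = n_codons)
  })
}

#' Write sequences to FASTA
#' @param seqs named character vector of sequences
#' @param path output file
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write simulated reads to FASTQ (Phred+33, constant quality)
#' @param reads data.frame from [simulate_metagenome()]
#' @param path output file
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(reads$seq, reads$read_id))
  q <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}
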