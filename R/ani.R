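# Fragment-based average nucleotide identity and dendrograms with bootstrap.

#' Cut a genome into consecutive fragments
#'
#' Tiles each replicon with non-overlapping fragments of `fragment_length`
#' bases; a trailing fragment is kept if it is at least 100 bp.
#'
#' @param genome character string or named character vector of replicons
#' @param fragment_length fragment size in bases (default 1020)
#' @return data.frame with `replicon`, 0-based half-open `start`/`end`, `seq`
#' @export
fragment_genome <- function(genome, fragment_length = 1020) {
  if (length(genome) == 0 || all(nchar(genome) == 0)) stop("empty genome")
  reps <- names(genome) %||% sprintf("replicon_%d", seq_along(genome))
  out <- lapply(seq_along(genome), function(i) {
    L <- nchar(genome[[i]])
    starts <- seq(0L, max(0L, L - 1L), by = fragment_length)
    ends <- pmin(starts + fragment_length, L)
    keep <- ends - starts >= 100 | (ends - starts == L)  # tiny replicon kept whole
    starts <- starts[keep]; ends <- ends[keep]
    data.frame(replicon = reps[i], start = starts, end = ends,
               seq = substring(genome[[i]], starts + 1L, ends),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @noRd
directed_ani <- function(ga, gb, fragment_length, min_identity, min_aln_frac, k) {
  fr <- fragment_genome(ga, fragment_length)
  best_id <- rep(NA_real_, nrow(fr))
  best_m <- rep(-1L, nrow(fr))
  for (rep_b in if (is.null(names(gb))) seq_along(gb) else names(gb)) {
    h <- cpp_seed_map(fr$seq, gb[[rep_b]], k = k, min_identity = min_identity,
                      min_frac = min_aln_frac, max_hits = 1L)
    if (nrow(h) == 0) next
    upd <- h$matches > best_m[h$query]
    best_id[h$query[upd]] <- h$identity[upd]
    best_m[h$query[upd]] <- h$matches[upd]
  }
  used <- !is.na(best_id)
  list(ani = if (any(used)) mean(best_id[used]) else NA_real_,
       n_used = sum(used), aligned_fraction = mean(used))
}

#' Fragment-based average nucleotide identity between two genomes
#'
#' Each genome is cut into fragments (default 1020 bp) that are aligned
#' against the other genome; fragments are retained iff their best alignment
#' has identity >= `min_identity` percent over >= `min_aln_frac` of the
#' fragment.  Directed ANI is the mean identity of retained fragments, and
#' the reported ANI is the mean of the two directions.
#'
#' @param genome_a,genome_b character strings or named character vectors of
#'   replicons
#' @param fragment_length fragment size (default 1020)
#' @param min_identity retention cutoff, percent (default 30)
#' @param min_aln_frac minimum aligned fraction of the fragment (default 0.70)
#' @param k seed k-mer length used by the fragment aligner
#' @return object of class `ani_result` with `ani`, the directed values
#'   `ani_ab`/`ani_ba`, `n_fragments_used`, `aligned_fraction`
#' @export
compute_ani <- function(genome_a, genome_b, fragment_length = 1020,
                        min_identity = 30, min_aln_frac = 0.70, k = 13) {
  ab <- directed_ani(genome_a, genome_b, fragment_length, min_identity,
                     min_aln_frac, k)
  ba <- directed_ani(genome_b, genome_a, fragment_length, min_identity,
                     min_aln_frac, k)
  ani <- if (ab$n_used + ba$n_used == 0) NA_real_ else mean(c(ab$ani, ba$ani), na.rm = TRUE)
  structure(list(ani = ani, ani_ab = ab$ani, ani_ba = ba$ani,
                 n_fragments_used = ab$n_used + ba$n_used,
                 aligned_fraction = ab$aligned_fraction,
                 undefined = ab$n_used + ba$n_used == 0),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  if (x$undefined) {
    cat("ANI undefined: no fragment passed the retention cutoffs\n")
  } else {
    cat(sprintf("ANI = %.2f%% (directed %.2f / %.2f; %d fragments, aligned fraction %.2f)\n",
                x$ani, x$ani_ab, x$ani_ba, x$n_fragments_used, x$aligned_fraction))
  }
  invisible(x)
}

#' Hierarchical clustering of a distance matrix with bootstrap support
#'
#' Agglomerative clustering (stats::hclust) of a symmetric distance matrix.
#' When the feature matrix underlying the distances is supplied (e.g. the 256
#' tetranucleotide dimensions, or ANI fragment identity columns), per-node
#' support is estimated by resampling feature columns with replacement,
#' recomputing the Euclidean distance matrix and the tree, and counting how
#' often each internal-node bipartition recurs.
#'
#' @param distance_matrix square symmetric matrix with zero diagonal
#' @param features optional numeric matrix (rows = the same labeled items,
#'   columns = resampled dimensions)
#' @param n_bootstrap bootstrap replicates (default 1000)
#' @param linkage linkage method for hclust (default "average")
#' @return list with `hclust`, `phylo` (ape tree, node labels = support),
#'   `support` (per internal node, in `[0, 1]`)
#' @export
cluster_matrix <- function(distance_matrix, features = NULL,
                           n_bootstrap = 1000, linkage = "average") {
  d <- as.matrix(distance_matrix)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-8)) stop("distance matrix must have zero diagonal")
  hc <- hclust(as.dist(d), method = linkage)
  phy <- ape::as.phylo(hc)
  n_internal <- phy$Nnode
  if (nrow(d) == 2) {
    support <- 1.0
  } else if (is.null(features)) {
    support <- rep(NA_real_, n_internal)
  } else {
    features <- as.matrix(features)
    stopifnot(nrow(features) == nrow(d))
    rownames(features) <- rownames(d) %||% labels(as.dist(d))
    boot <- vector("list", n_bootstrap)
    for (b in seq_len(n_bootstrap)) {
      cols <- sample.int(ncol(features), replace = TRUE)
      db <- as.matrix(stats::dist(features[, cols, drop = FALSE]))
      boot[[b]] <- ape::as.phylo(hclust(as.dist(db), method = linkage))
    }
    cl <- ape::prop.clades(phy, boot, rooted = TRUE)
    cl[is.na(cl)] <- 0
    support <- cl / n_bootstrap
  }
  phy$node.label <- formatC(support, digits = 3, format = "f")
  list(hclust = hc, phylo = phy, support = support)
}

#' Write a dendrogram as Newick with support values
#' @param tree result of [cluster_matrix()]
#' @param path output file
#' @export
write_dendrogram <- function(tree, path) {
  ape::write.tree(tree$phylo, path)
  invisible(path)
}
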