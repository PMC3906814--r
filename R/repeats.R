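# De-novo repeat/mobile-element discovery: read overlap graph, connected-
# component clustering with greedy consensus, cluster merging, marker
# annotation, and metagenome validation + high-identity tracing onto genomes.

#' Build a read overlap graph
#'
#' Detects pairwise read overlaps (both orientations) with a shared-k-mer
#' prefilter followed by ungapped alignment at the best diagonal.  An edge is
#' kept iff the overlap spans at least `min_frac` of the shorter read and has
#' identity >= `min_identity` percent.  Reads shorter than 33 bp are dropped.
#'
#' @param reads named character vector of read sequences, or a read table
#'   from [simulate_metagenome()]
#' @param min_frac minimum overlap as a fraction of the shorter read
#'   (default 0.40)
#' @param min_identity minimum overlap identity, percent (default 80)
#' @param k prefilter k-mer length
#' @return object of class `overlap_graph`: list with `reads` (named vector)
#'   and `edges` (data.frame `from`, `to`, `overlap_length`, `identity`,
#'   `orient`)
#' @export
build_overlap_graph <- function(reads, min_frac = 0.40, min_identity = 80,
                                k = 12) {
  if (is.data.frame(reads)) reads <- stats::setNames(reads$seq, reads$read_id)
  if (is.null(names(reads))) names(reads) <- sprintf("read_%06d", seq_along(reads))
  reads <- reads[nchar(reads) >= 33]
  edges <- cpp_overlap_edges(unname(reads), min_frac = min_frac,
                             min_identity = min_identity, k = k)
  edges$from <- names(reads)[edges$from]
  edges$to <- names(reads)[edges$to]
  structure(list(reads = reads, edges = edges), class = "overlap_graph")
}

# iterative greedy consensus of one read set: backbone read extended by
# overhanging reads, then polished by per-position majority vote.  The
# backbone defaults to the longest read; for repeat components the caller
# passes the best-connected read so the consensus is anchored inside the
# repeat rather than in a flank.
#' @noRd
greedy_consensus <- function(reads, k = 12, min_identity = 80,
                             backbone = NULL) {
  reads <- unname(reads)
  if (length(reads) == 1) return(reads)
  cons <- if (is.null(backbone)) reads[which.max(nchar(reads))] else backbone
  for (iter in seq_len(100)) {
    h <- cpp_seed_map(reads, cons, k = k, min_identity = min_identity,
                      min_frac = 0.1, max_hits = 1L)
    if (nrow(h) == 0) break
    blen <- nchar(cons)
    # extend with the best-anchored overhanging read per side: the candidate
    # with the longest alignment into the current consensus, so short chance
    # matches cannot splice unrelated sequence onto the ends
    # candidates may be trimmed up to 2 bp short of the consensus end (a
    # terminal consensus error otherwise blocks extension for good); the
    # unsupported terminal bases are overwritten by the extending read
    left <- ""; lcut <- 0L; lgain <- 0L
    right <- ""; rcut <- blen; rgain <- 0L
    ok <- h$aln_len >= 40 & h$identity >= 90
    for (i in which(ok)) {
      rlen <- nchar(reads[h$query[i]])
      orr <- if (h$strand[i] == "-") seq_revcomp(reads[h$query[i]]) else reads[h$query[i]]
      gl <- h$q_start[i] - h$ref_start[i]
      gr <- (rlen - h$q_end[i]) - (blen - h$ref_end[i])
      if (h$ref_start[i] <= 2 && gl > lgain) {
        left <- substr(orr, 1, h$q_start[i])
        lcut <- h$ref_start[i]; lgain <- gl
      } else if (h$ref_end[i] >= blen - 2 && gr > rgain) {
        right <- substr(orr, h$q_end[i] + 1, rlen)
        rcut <- h$ref_end[i]; rgain <- gr
      }
    }
    if (lgain == 0 && rgain == 0) break
    cons <- paste0(left, substr(cons, lcut + 1, rcut), right)
  }
  # polish: majority vote over aligned read bases
  h <- cpp_seed_map(reads, cons, k = k, min_identity = min_identity,
                    min_frac = 0.1, max_hits = 1L)
  blen <- nchar(cons)
  votes <- matrix(0L, 4, blen)
  for (i in seq_len(nrow(h))) {
    orr <- if (h$strand[i] == "-") seq_revcomp(reads[h$query[i]]) else reads[h$query[i]]
    frag <- substr(orr, h$q_start[i] + 1, h$q_end[i])
    b <- match(strsplit(frag, "")[[1]], BASES)
    pos <- h$ref_start[i] + seq_len(h$aln_len[i])
    ok <- !is.na(b)
    idx <- cbind(b[ok], pos[ok])
    votes[idx] <- votes[idx] + 1L
  }
  called <- apply(votes, 2, function(v) if (sum(v) == 0) NA_integer_ else which.max(v))
  out <- strsplit(cons, "")[[1]]
  out[!is.na(called)] <- BASES[called[!is.na(called)]]
  # trim the consensus ends back to well-supported sequence.  Two signals:
  # depth (single-copy flanks sit far below the multi-copy plateau) and vote
  # agreement (positions past a repeat's boundary mix the different flanking
  # sequences of its copies, so no base wins a clear majority).  Ends only --
  # internal dips never split the consensus.
  depth <- colSums(votes)
  agree <- ifelse(depth > 0, apply(votes, 2, max) / pmax(depth, 1), 1)
  if (length(depth) > 101) {
    depth <- stats::runmed(depth, 101)
    agree <- stats::runmed(agree, 51)
  }
  thr <- 0.5 * as.numeric(quantile(depth[depth > 0], 0.9))
  good <- which(depth >= thr & agree >= 0.8)
  if (length(good)) out <- out[good[1]:good[length(good)]]
  paste0(out, collapse = "")
}

#' Cluster the overlap graph into repeat clusters
#'
#' Connected components of the overlap graph (components of >= 2 reads) with
#' a greedy consensus per component.  A component is flagged repetitive when
#' its read density (read bases per consensus base) is at least
#' `repeat_depth_factor` times the median component density, the overlap-
#' graph analogue of exceeding the genome-average read depth.
#'
#' @param graph an `overlap_graph`
#' @param repeat_depth_factor density multiple for the repetitive flag
#'   (default 3)
#' @param min_degree_factor when set, reads whose overlap degree is below
#'   `min_degree_factor * median(degree)` are dropped before taking
#'   components.  A read's degree grows with the local copy number, so this
#'   restricts clustering to repeat cores and stops neighbouring elements
#'   from being conflated through contiguous single-copy flanks.  NULL
#'   (default) clusters the full graph.
#' @return object of class `repeat_clusters`: `clusters` data.frame
#'   (`cluster_id`, `n_reads`, `fraction_of_reads`, `consensus_length`,
#'   `density`, `repetitive`, `annotation`), `members` (list of read ids),
#'   `consensus` (named character vector)
#' @export
cluster_graph <- function(graph, repeat_depth_factor = 3,
                          min_degree_factor = NULL) {
  n_total <- length(graph$reads)
  if (nrow(graph$edges) == 0) {
    return(structure(list(
      clusters = data.frame(cluster_id = character(0), n_reads = integer(0),
                            fraction_of_reads = numeric(0),
                            consensus_length = integer(0), density = numeric(0),
                            repetitive = logical(0), annotation = character(0),
                            stringsAsFactors = FALSE),
      members = list(), consensus = character(0), n_total_reads = n_total,
      read_lengths = nchar(graph$reads)),
      class = "repeat_clusters"))
  }
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = names(graph$reads)))
  if (!is.null(min_degree_factor)) {
    deg_all <- igraph::degree(g)
    keep <- names(deg_all)[deg_all >= min_degree_factor * median(deg_all)]
    g <- igraph::induced_subgraph(g, keep)
  }
  comp <- igraph::components(g)
  sizes <- table(comp$membership)
  big <- as.integer(names(sizes)[sizes >= 2])
  members <- lapply(big, function(ci) names(comp$membership)[comp$membership == ci])
  deg <- igraph::degree(g)
  consensus <- vapply(members, function(m) {
    anchor <- m[order(-deg[m], -nchar(graph$reads[m]))][1]
    greedy_consensus(graph$reads[m], backbone = graph$reads[[anchor]])
  }, character(1))
  ids <- sprintf("cluster_%03d", seq_along(big))
  names(consensus) <- ids
  dens <- vapply(seq_along(big), function(i) {
    sum(nchar(graph$reads[members[[i]]])) / nchar(consensus[i])
  }, numeric(1))
  cl <- data.frame(
    cluster_id = ids, n_reads = lengths(members),
    fraction_of_reads = lengths(members) / n_total,
    consensus_length = nchar(unname(consensus)), density = dens,
    repetitive = dens >= repeat_depth_factor * median(dens),
    annotation = NA_character_, stringsAsFactors = FALSE)
  names(members) <- ids
  structure(list(clusters = cl, members = members, consensus = consensus,
                 n_total_reads = n_total, read_lengths = nchar(graph$reads)),
            class = "repeat_clusters")
}

#' @export
print.repeat_clusters <- function(x, ...) {
  cat(sprintf("repeat_clusters: %d clusters over %d reads (%.0f%% of reads clustered)\n",
              nrow(x$clusters), x$n_total_reads,
              100 * sum(x$clusters$n_reads) / max(1, x$n_total_reads)))
  invisible(x)
}

#' Annotate cluster consensi against a marker gene database
#'
#' Assigns each cluster the best-matching marker whose alignment reaches
#' `min_identity` percent over at least `min_cov` of the marker length.
#'
#' @param clusters a `repeat_clusters` object
#' @param markers named character vector of marker sequences (default the
#'   bundled synthetic set, [marker_genes()])
#' @param min_identity annotation identity cutoff, percent (default 80)
#' @param min_cov fraction of marker length that must align (default 0.80)
#' @return the `repeat_clusters` object with `annotation` filled in
#' @export
annotate_clusters <- function(clusters, markers = marker_genes(),
                              min_identity = 80, min_cov = 0.80) {
  for (i in seq_along(clusters$consensus)) {
    h <- cpp_seed_map(unname(markers), clusters$consensus[i], k = 13,
                      min_identity = min_identity, min_frac = min_cov,
                      max_hits = 1L)
    if (nrow(h)) {
      best <- h[which.max(h$matches), ]
      clusters$clusters$annotation[i] <- names(markers)[best$query]
    }
  }
  clusters
}

#' Merge clusters whose consensi align or that share an annotation
#'
#' Clusters whose consensus sequences overlap by at least `min_overlap_frac`
#' of the shorter consensus at >= `min_identity` percent identity are
#' unioned, as are clusters annotated with the same marker (fragments of one
#' element recovered as separate clusters); the merged consensus is rebuilt
#' from the member consensi.  Idempotent on already-merged sets.
#'
#' @param clusters a `repeat_clusters` object
#' @param min_overlap_frac minimum overlap fraction (default 0.40)
#' @param min_identity minimum identity, percent (default 80)
#' @return a merged `repeat_clusters` object
#' @export
merge_clusters <- function(clusters, min_overlap_frac = 0.40,
                           min_identity = 80) {
  nc <- length(clusters$consensus)
  if (nc <= 1) return(clusters)
  ed <- cpp_overlap_edges(unname(clusters$consensus),
                          min_frac = min_overlap_frac,
                          min_identity = min_identity, k = 12)[, c("from", "to")]
  ann <- clusters$clusters$annotation
  for (a in unique(stats::na.omit(ann))) {
    ix <- which(!is.na(ann) & ann == a)
    if (length(ix) > 1) {
      ed <- rbind(ed, data.frame(from = ix[-length(ix)], to = ix[-1]))
    }
  }
  if (nrow(ed) == 0) return(clusters)
  g <- igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(nc))))
  comp <- igraph::components(g)$membership
  groups <- split(seq_len(nc), comp)
  members <- list(); consensus <- character(0); annotation <- character(0)
  for (gi in seq_along(groups)) {
    ix <- groups[[gi]]
    members[[gi]] <- unique(unlist(clusters$members[ix]))
    consensus[gi] <- if (length(ix) == 1) clusters$consensus[ix] else {
      greedy_consensus(unname(clusters$consensus[ix]))
    }
    ann <- stats::na.omit(clusters$clusters$annotation[ix])
    annotation[gi] <- if (length(ann)) ann[1] else NA_character_
  }
  ids <- sprintf("cluster_%03d", seq_along(groups))
  names(members) <- ids; names(consensus) <- ids
  n_reads <- lengths(members)
  dens <- vapply(seq_along(groups), function(i) {
    sum(clusters$read_lengths[members[[i]]]) / nchar(consensus[i])
  }, numeric(1))
  cl <- data.frame(
    cluster_id = ids, n_reads = n_reads,
    fraction_of_reads = n_reads / clusters$n_total_reads,
    consensus_length = nchar(unname(consensus)), density = dens,
    repetitive = dens >= 3 * median(dens), annotation = annotation,
    stringsAsFactors = FALSE)
  structure(list(clusters = cl, members = members, consensus = consensus,
                 n_total_reads = clusters$n_total_reads,
                 read_lengths = clusters$read_lengths),
            class = "repeat_clusters")
}

#' Validate clusters against the metagenome and trace them onto genomes
#'
#' Annotated clusters with consensus >= 200 bp are retained iff the
#' metagenome covers their consensus at mean depth >= `min_meta_depth`; the
#' retained consensi are then located on each genome wherever they align at
#' >= `min_trace_identity` percent identity over >= `min_cov` of the
#' consensus length.
#'
#' @param clusters a `repeat_clusters` object (after [annotate_clusters()])
#' @param metagenome_reads read table or named character vector
#' @param genomes named list/vector of genome sequences
#' @param min_meta_depth metagenome coverage cutoff (default 8)
#' @param min_trace_identity tracing identity cutoff, percent (default 97)
#' @param min_cov fraction of consensus that must align when tracing
#'   (default 0.80)
#' @param annotated_only consider only marker-annotated clusters
#'   (default TRUE)
#' @return list with `validated` (data.frame `cluster_id`, `annotation`,
#'   `meta_depth`, `validated`) and `loci` (data.frame `element_id`,
#'   `target`, `start`, `end`, `identity`)
#' @export
validate_and_trace <- function(clusters, metagenome_reads, genomes,
                               min_meta_depth = 8, min_trace_identity = 97,
                               min_cov = 0.80, annotated_only = TRUE) {
  if (is.data.frame(metagenome_reads)) {
    meta <- metagenome_reads$seq
  } else meta <- unname(metagenome_reads)
  cand <- which(nchar(clusters$consensus) >= 200 &
                  (!annotated_only | !is.na(clusters$clusters$annotation)))
  val <- data.frame(cluster_id = clusters$clusters$cluster_id[cand],
                    annotation = clusters$clusters$annotation[cand],
                    meta_depth = rep(NA_real_, length(cand)),
                    validated = rep(FALSE, length(cand)),
                    stringsAsFactors = FALSE)
  loci <- data.frame(element_id = character(0), target = character(0),
                     start = integer(0), end = integer(0),
                     identity = numeric(0), stringsAsFactors = FALSE)
  gn <- names(genomes) %||% sprintf("genome_%d", seq_along(genomes))
  for (i in seq_along(cand)) {
    cons <- clusters$consensus[cand[i]]
    h <- cpp_seed_map(meta, cons, k = 15, min_identity = 90, min_frac = 0.9,
                      max_hits = 1L)
    depth <- if (nrow(h)) sum(h$aln_len) / nchar(cons) else 0
    val$meta_depth[i] <- depth
    if (depth < min_meta_depth) next
    val$validated[i] <- TRUE
    for (t in seq_along(genomes)) {
      # local segments at tracing identity; nearby segments are merged into
      # one locus (small consensus indels split an ungapped alignment into
      # adjacent diagonal pieces) which must jointly cover >= min_cov of the
      # consensus
      ht <- cpp_seed_map(cons, genomes[[t]], k = 15,
                         min_identity = min_trace_identity,
                         min_frac = 0.05, max_hits = 500L)
      if (nrow(ht) == 0) next
      ht <- ht[order(ht$ref_start), , drop = FALSE]
      grp <- cumsum(c(1, tail(ht$ref_start, -1) -
                        head(ht$ref_end, -1) > 200))
      for (gl in split(ht, grp)) {
        covered <- min(sum(gl$aln_len), nchar(cons))
        if (covered / nchar(cons) < min_cov) next
        loci <- rbind(loci, data.frame(
          element_id = val$cluster_id[i], target = gn[t],
          start = min(gl$ref_start), end = max(gl$ref_end),
          identity = sum(gl$identity * gl$aln_len) / sum(gl$aln_len),
          stringsAsFactors = FALSE))
      }
    }
  }
  list(validated = val, loci = loci)
}
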