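test_that("overlap edges require both overlap length and identity", {
  r <- metalca:::with_seed(1, metalca:::random_seq(80, 0.5))
  g <- build_overlap_graph(c(x = r, y = r))
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$overlap_length, 80)
  expect_equal(g$edges$identity, 100)

  # reads tiling a single-copy region at 1x form a path
  src <- metalca:::with_seed(2, metalca:::markov_seq(1000, 0.5))
  starts <- seq(0, 900, by = 100)
  reads <- stats::setNames(substring(src, starts + 1, starts + 150),
                           paste0("t", seq_along(starts)))
  reads <- reads[nchar(reads) == 150]
  gp <- build_overlap_graph(reads, min_frac = 0.3)
  deg <- table(c(gp$edges$from, gp$edges$to))
  expect_lte(max(deg), 2)          # only neighbours overlap
  expect_equal(nrow(gp$edges), length(reads) - 1)
})

test_that("overlap graph edges equal brute-force all-pairs alignment", {
  src <- metalca:::with_seed(3, metalca:::markov_seq(1500, 0.55))
  reads <- metalca:::with_seed(4, {
    starts <- sample.int(1500 - 60, 80)
    r <- substring(src, starts, starts + 59)
    flip <- sample(c(TRUE, FALSE), 80, replace = TRUE)
    r[flip] <- vapply(r[flip], metalca:::seq_revcomp, character(1))
    r
  })
  got <- metalca:::cpp_overlap_edges(reads, 0.4, 80, 12)
  exp <- oracle_overlap_edges(reads, 0.4, 80)
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  expect_setequal(key(got$from, got$to), key(exp[, 1], exp[, 2]))
})

test_that("cluster partition ignores read order and empty graphs give no clusters", {
  g0 <- build_overlap_graph(c(a = strrep("ACGTA", 12), b = strrep("TTGCA", 12)))
  expect_equal(nrow(cluster_graph(g0)$clusters), 0)

  sim <- repeats_sim()
  sub <- sim$greads[1:400, ]
  g1 <- build_overlap_graph(sub)
  g2 <- build_overlap_graph(sub[rev(seq_len(nrow(sub))), ])
  c1 <- cluster_graph(g1)
  c2 <- cluster_graph(g2)
  part <- function(cl) sort(unname(vapply(cl$members, function(m)
    paste(sort(m), collapse = ","), character(1))))
  expect_identical(part(c1), part(c2))
})

test_that("multicopy elements show proportionally higher cluster read density", {
  # one element at 8 copies vs single-copy background, reads at 5x
  anc <- simulate_ancestor(15000, gc = 0.6, n_genes = 10, seed = 91)
  tn <- data.frame(element_id = "E8", length = 900, copy_count = 8,
                   carries_marker = TRUE)
  d <- evolve_descendant(anc, 0, transposons = tn, seed = 92)
  rd <- simulate_metagenome(list(list(id = "g", seq = d$seq, abundance = 1)),
                            n_reads = round(5 * nchar(d$seq) / 150),
                            read_length = 150, error_rate = 0.005, seed = 93)
  cl <- annotate_clusters(cluster_graph(build_overlap_graph(rd)))
  el <- which(!is.na(cl$clusters$annotation))
  expect_gte(length(el), 1)
  el_dens <- max(cl$clusters$density[el])
  other <- cl$clusters$density[-el]
  expect_gt(el_dens, 3 * median(other))
  expect_true(all(cl$clusters$repetitive[which.max(cl$clusters$density)]))
})

test_that("merging unions overlapping or same-annotation clusters and is idempotent", {
  # two clusters built from 5' and 3' halves of one element merge into one
  el <- metalca:::with_seed(5, metalca:::markov_seq(1200, 0.5))
  mk_reads <- function(lo, hi, tag) {
    starts <- seq(lo, hi - 150, by = 40)
    stats::setNames(substring(el, starts + 1, starts + 150),
                    paste0(tag, seq_along(starts)))
  }
  g <- build_overlap_graph(c(mk_reads(0, 800, "l"), mk_reads(400, 1200, "r")))
  cl <- cluster_graph(g)
  # force a split by removing bridging edges, then check merge repairs it
  halves <- list(names(g$reads)[startsWith(names(g$reads), "l")],
                 names(g$reads)[startsWith(names(g$reads), "r")])
  split_cl <- structure(list(
    clusters = data.frame(cluster_id = c("c1", "c2"), n_reads = lengths(halves),
                          fraction_of_reads = lengths(halves) / length(g$reads),
                          consensus_length = NA, density = NA,
                          repetitive = NA, annotation = NA_character_,
                          stringsAsFactors = FALSE),
    members = stats::setNames(halves, c("c1", "c2")),
    consensus = c(c1 = metalca:::greedy_consensus(g$reads[halves[[1]]]),
                  c2 = metalca:::greedy_consensus(g$reads[halves[[2]]])),
    n_total_reads = length(g$reads),
    read_lengths = nchar(g$reads)), class = "repeat_clusters")
  merged <- merge_clusters(split_cl)
  expect_equal(nrow(merged$clusters), 1)
  expect_gte(nchar(merged$consensus[1]), 1100)
  again <- merge_clusters(merged)
  expect_equal(nrow(again$clusters), 1)

  # disjoint consensi stay apart
  other <- metalca:::with_seed(6, metalca:::markov_seq(800, 0.5))
  split_cl$consensus <- c(c1 = el, c2 = other)
  expect_equal(nrow(merge_clusters(split_cl)$clusters), 2)
})

test_that("validation needs metagenome depth and tracing needs 97% identity", {
  sim <- repeats_sim()
  cl <- sim$clusters
  res <- validate_and_trace(cl, sim$meta,
                            genomes = list(genome_a = sim$a$seq,
                                           genome_b = sim$b$seq))
  expect_equal(sum(res$validated$validated), 8)
  # loci only on the genome that carries the elements
  expect_gt(sum(res$loci$target == "genome_a"), 0)
  expect_equal(sum(res$loci$target == "genome_b"), 0)
  expect_true(all(res$loci$identity >= 97))

  # every planted copy is recovered by some locus
  tl <- sim$a$truth$planted_transposon_loci
  hit <- vapply(seq_len(nrow(tl)), function(i) {
    any(res$loci$target == "genome_a" & res$loci$start < tl$end[i] &
          tl$start[i] < res$loci$end)
  }, logical(1))
  expect_true(all(hit))

  # an impossible tracing threshold yields no loci
  res2 <- validate_and_trace(cl, sim$meta,
                             genomes = list(genome_a = sim$a$seq),
                             min_trace_identity = 101)
  expect_equal(nrow(res2$loci), 0)
})
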