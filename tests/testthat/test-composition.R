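test_that("count_kmers counts both strands and skips N windows", {
  k4 <- count_kmers("AAAA", 4)
  expect_equal(unname(k4["AAAA"]), 1)
  expect_equal(unname(k4["TTTT"]), 1)
  expect_equal(sum(k4), 2)

  expect_equal(sum(count_kmers("ANA", 2)), 0)
  expect_error(count_kmers("ACGT", 0), "k")

  k2 <- count_kmers("ACGTACGT", 2)
  expect_equal(as.integer(k2), as.integer(oracle_count_kmers("ACGTACGT", 2)))
})

test_that("tetra z-scores match the three-count formula oracle on a toy sequence", {
  toy <- metalca:::with_seed(11, metalca:::markov_seq(2000, 0.55))
  p <- suppressWarnings(tetra_zscores(toy))
  z <- oracle_tetra_z(toy)
  expect_equal(unname(p$z), unname(z[names(p$z)]), tolerance = 1e-12)
})

test_that("tetra profiles behave under the null and under symmetries", {
  rnd <- metalca:::with_seed(6, metalca:::random_seq(1e6, 0.5))
  p <- tetra_zscores(rnd)
  expect_gt(mean(p$z), -0.1); expect_lt(mean(p$z), 0.1)
  expect_gt(sd(p$z), 0.8); expect_lt(sd(p$z), 1.2)

  s <- substring(rnd, 1, 50000)
  expect_equal(tetra_zscores(s)$z, tetra_zscores(metalca:::seq_revcomp(s))$z)

  # rotation changes counts only at the edges
  rot <- paste0(substring(s, 20001), substring(s, 1, 20000))
  expect_gt(cor(tetra_zscores(s)$z, tetra_zscores(rot)$z), 0.999)

  # multi-sequence profile = profile of summed counts
  halves <- c(substring(s, 1, 25000), substring(s, 25001))
  p2 <- tetra_zscores(halves)
  manual <- count_kmers(halves[1], 4) + count_kmers(halves[2], 4)
  expect_equal(p2$n_tetramers, sum(manual))

  expect_error(tetra_zscores(""), "empty")
})

test_that("tetra_correlation separates relatives from composition-distinct donors", {
  sim <- divergence_sim()
  pa <- tetra_zscores(sim$a$seq, "a")
  pb <- tetra_zscores(sim$b$seq, "b")
  expect_equal(tetra_correlation(pa, pa), 1.0)
  expect_gte(tetra_correlation(pa, pb), 0.99)
  island <- metalca:::with_seed(5, metalca:::markov_seq(100000, 0.40))
  expect_lt(tetra_correlation(pa, tetra_zscores(island)), 0.9)
  flat <- pa; flat$z <- rep(0, 256)
  expect_error(tetra_correlation(pa, flat), "variance")
})

test_that("gc_content handles N and degenerate input", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("ACGTN"), 0.5)
  expect_error(gc_content("NNN"), "ACGT")
})

test_that("foreign_gene_scan keeps the null call rate low and recovers planted islands", {
  # null: all genes native
  anc <- simulate_ancestor(80000, gc = 0.63, n_genes = 60, seed = 31)
  fs <- foreign_gene_scan(anc$genes, anc$seq, sensitivity = 0.7)
  expect_lte(mean(fs$call == "foreign"), 0.05)

  # planted ~10-gene island with donor codon usage
  d <- evolve_descendant(anc, 0.01,
                         islands = data.frame(length = 12000, gc = 0.40,
                                              codon_usage_id = "don"),
                         seed = 32)
  fs2 <- foreign_gene_scan(d$genes, d$seq, sensitivity = 0.7)
  isl_ids <- d$genes$gene_id[d$genes$origin == "island"]
  calls <- fs2$call[match(isl_ids, fs2$gene_id)]
  expect_gte(sum(calls == "foreign") / length(calls), 0.8)

  # short genes flagged, empty input tolerated
  g30 <- data.frame(gene_id = "tiny", start = anc$genes$start[1],
                    end = anc$genes$start[1] + 45, strand = "+")
  fs3 <- foreign_gene_scan(g30, anc$seq)
  expect_true(fs3$flagged_short)
  expect_equal(fs3$call, "native")
  expect_equal(fs3$score, 0)
  expect_equal(nrow(foreign_gene_scan(anc$genes[0, ], anc$seq)), 0)
})

test_that("bin_contigs assigns by best squared correlation with GC guard", {
  gA <- simulate_ancestor(100000, gc = 0.63, n_genes = 0, seed = 41)$seq
  gB <- simulate_ancestor(100000, gc = 0.50, n_genes = 0, seed = 42)$seq
  refs <- list(reference_profile(gA, "A"), reference_profile(gB, "B"))

  # contigs cut from the references themselves: all binned correctly
  frA <- fragment_genome(gA, 25000); frA <- frA$seq[frA$end - frA$start == 25000]
  frB <- fragment_genome(gB, 25000); frB <- frB$seq[frB$end - frB$start == 25000]
  ct <- c(stats::setNames(frA, paste0("a", seq_along(frA))),
          stats::setNames(frB, paste0("b", seq_along(frB))))
  res <- suppressWarnings(bin_contigs(ct, refs))
  expect_true(all(res$status == "binned"))
  expect_true(all(res$bin == ifelse(grepl("^a", res$contig), "A", "B")))

  # reads-assembled descendant contigs + background: precision >= 0.9
  anc <- list(seq = gA, genes = metalca:::empty_gene_table())
  dA <- evolve_descendant(anc, 0.01, seed = 43)
  frD <- fragment_genome(dA$seq, 25000); frD <- frD$seq[frD$end - frD$start == 25000]
  ct2 <- c(stats::setNames(frD, paste0("d", seq_along(frD))),
           stats::setNames(frB, paste0("b", seq_along(frB))))
  res2 <- suppressWarnings(bin_contigs(ct2, refs))
  binned <- res2[res2$status == "binned", ]
  expect_gt(nrow(binned), 0)
  correct <- binned$bin == ifelse(grepl("^d", binned$contig), "A", "B")
  expect_gte(mean(correct), 0.9)

  # threshold boundary: nothing can reach r^2 > 1
  res3 <- suppressWarnings(bin_contigs(ct, refs, r2_cutoff = 1.01))
  expect_true(all(res3$status != "binned"))

  # short contigs flagged; assignment stable under reordering
  res4 <- suppressWarnings(bin_contigs(c(ct, tiny = "ACGT"), refs))
  expect_equal(res4$status[res4$contig == "tiny"], "too_short")
  resR <- suppressWarnings(bin_contigs(rev(ct), refs))
  m <- match(res$contig, resR$contig)
  expect_identical(res$bin, resR$bin[m])
})
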