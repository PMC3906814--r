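test_that("error-free reads recruit perfectly; unrelated reads barely at all", {
  anc <- simulate_ancestor(30000, gc = 0.6, n_genes = 20, seed = 61)
  rd <- simulate_metagenome(list(list(id = "m", seq = anc$seq, abundance = 1)),
                            n_reads = 500, read_length = 100,
                            error_rate = 0, seed = 1)
  h <- recruit(rd, c(g = anc$seq))
  expect_equal(nrow(h), 500)
  expect_true(all(h$identity == 100))

  rd1 <- simulate_metagenome(list(list(id = "m", seq = anc$seq, abundance = 1)),
                             n_reads = 1000, read_length = 100,
                             error_rate = 0.01, seed = 2)
  h1 <- recruit(rd1, c(g = anc$seq))
  expect_gte(mean(h1$identity), 98.5)
  expect_lte(mean(h1$identity), 99.9)

  rnd <- metalca:::with_seed(3, metalca:::random_seq(30000, 0.5))
  rdu <- simulate_metagenome(list(list(id = "u", seq = rnd, abundance = 1)),
                             n_reads = 1000, read_length = 100,
                             error_rate = 0, seed = 4)
  hu <- recruit(rdu, c(g = anc$seq))
  expect_lte(nrow(hu) / 1000, 0.01)

  expect_error(recruit(rd, ""), "empty")
})

test_that("tracks summarize depth, coverage and identity per window", {
  ref <- c(g = metalca:::with_seed(5, metalca:::random_seq(5000, 0.5)))
  empty <- recruit(data.frame(read_id = character(0), seq = character(0)), ref)
  tr0 <- build_track(empty, ref, window = 1000)
  expect_true(all(tr0$windows$depth == 0))
  expect_true(all(tr0$windows$covered_frac == 0))
  expect_true(all(is.na(tr0$windows$mean_identity)))

  one <- data.frame(read = "r1", ref = "g", ref_start = 100L, ref_end = 200L,
                    strand = "+", identity = 100, read_aln_frac = 1,
                    stringsAsFactors = FALSE)
  tr1 <- build_track(one, ref, window = 1000)
  expect_equal(tr1$windows$covered_frac[1], 0.1)
  expect_equal(tr1$windows$depth[1], 0.1)
  expect_equal(tr1$windows$mean_identity[1], 100)

  expect_error(build_track(one, ref, window = 50), "window")

  # ~10x uniform coverage: per-window depth concentrates around 10
  anc <- simulate_ancestor(30000, gc = 0.6, n_genes = 20, seed = 66)
  rd <- simulate_metagenome(list(list(id = "m", seq = anc$seq, abundance = 1)),
                            n_reads = 3000, read_length = 100,
                            error_rate = 0, seed = 6)
  tr <- build_track(recruit(rd, c(g = anc$seq)), c(g = anc$seq))
  expect_gt(mean(tr$windows$depth), 9)
  expect_lt(mean(tr$windows$depth), 11)
  expect_lte(sd(tr$windows$depth) / mean(tr$windows$depth), 0.2)

  # read input order does not matter
  rd_rev <- rd[rev(seq_len(nrow(rd))), ]
  tr2 <- build_track(recruit(rd_rev, c(g = anc$seq)), c(g = anc$seq))
  expect_equal(tr$windows, tr2$windows)
})

test_that("doubling read depth doubles track depth but not island calls", {
  anc <- simulate_ancestor(20000, gc = 0.62, n_genes = 12, seed = 71)
  ratios <- sapply(1:10, function(i) {
    r1 <- simulate_metagenome(list(list(id = "m", seq = anc$seq, abundance = 1)),
                              n_reads = 1500, read_length = 100, seed = i)
    r2 <- simulate_metagenome(list(list(id = "m", seq = anc$seq, abundance = 1)),
                              n_reads = 3000, read_length = 100, seed = i + 50)
    t1 <- build_track(recruit(r1, c(g = anc$seq)), c(g = anc$seq))
    t2 <- build_track(recruit(r2, c(g = anc$seq)), c(g = anc$seq))
    expect_identical(nrow(call_mgis(t1)), nrow(call_mgis(t2)))
    mean(t2$windows$depth) / mean(t1$windows$depth)
  })
  expect_lt(abs(mean(ratios) - 2), 0.2)
})

test_that("call_mgis flags low-identity/low-coverage windows and merges them", {
  # fully covered, high identity: no islands
  tr <- toy_track(50, depth = 10, identity = 98)
  expect_equal(nrow(call_mgis(tr)), 0)

  # no hits at all: one island spanning the reference
  tr0 <- toy_track(50, depth = 0, identity = NA_real_)
  tr0$windows$covered_frac <- 0
  isl <- call_mgis(tr0)
  expect_equal(nrow(isl), 1)
  expect_equal(isl$start, 0)
  expect_equal(isl$end, 50000)
  expect_equal(isl$cause, "low_coverage")

  # boundary equality is not an island (strict <)
  trb <- toy_track(10, depth = 10, identity = 25)
  trb$windows$covered_frac <- 0.25
  expect_equal(nrow(call_mgis(trb)), 0)
})

test_that("planted islands are recovered with window-resolution breakpoints", {
  run <- default_run()
  truth <- run$descendant_a$truth$planted_islands
  called <- run$mgi_a
  expect_gte(interval_jaccard(called[c("start", "end")],
                              truth[c("start", "end")]), 0.9)
  # each planted island is hit by exactly one called island overlapping it,
  # with breakpoints within one window
  w <- run$config$window
  for (i in seq_len(nrow(truth))) {
    ov <- called[called$start < truth$end[i] & truth$start[i] < called$end, ]
    expect_equal(nrow(ov), 1)
    expect_lte(abs(ov$start - truth$start[i]), w)
    expect_lte(abs(ov$end - truth$end[i]), w)
  }
})

test_that("call_conserved selects deep high-identity runs disjoint from MGIs", {
  expect_equal(nrow(call_conserved(toy_track(20, 5, 98))), 0)  # depth below 8
  tr <- toy_track(20, 10, 98)
  cons <- call_conserved(tr)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$end - cons$start, 20000)

  run <- default_run()
  mgi <- run$mgi_a; cons <- run$conserved_a
  if (nrow(mgi) && nrow(cons)) {
    ov <- sum(vapply(seq_len(nrow(cons)), function(i) {
      any(mgi$start < cons$end[i] & cons$start[i] < mgi$end)
    }, logical(1)))
    expect_equal(ov, 0)
  }
  # conserved regions cover >= 95% of the non-island genome
  truth <- run$descendant_a$truth
  L <- nchar(run$descendant_a$seq)
  isl_bp <- sum(truth$planted_islands$end - truth$planted_islands$start)
  expect_gte(sum(cons$end - cons$start) / (L - isl_bp), 0.95)
})
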