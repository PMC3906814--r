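test_that("simulate_ancestor honors length, GC, gene constraints and determinism", {
  anc <- simulate_ancestor(1000, gc = 0.5, n_genes = 0, seed = 1)
  expect_equal(nchar(anc$seq), 1000)
  expect_equal(nrow(anc$genes), 0)

  a1 <- simulate_ancestor(100000, gc = 0.65, n_genes = 80, seed = 7)
  a2 <- simulate_ancestor(100000, gc = 0.65, n_genes = 80, seed = 7)
  expect_identical(a1$seq, a2$seq)
  expect_identical(a1$genes, a2$genes)

  gc <- gc_content(a1$seq)
  expect_gte(gc, 0.645)
  expect_lte(gc, 0.655)

  g <- a1$genes
  expect_true(all((g$end - g$start) %% 3 == 0))
  expect_true(all(diff(g$start[order(g$start)]) > 0))
  o <- order(g$start)
  expect_true(all(g$start[o][-1] >= g$end[o][-nrow(g)]))  # non-overlapping
  cds <- metalca:::gene_sequences(a1$seq, g)
  expect_true(all(substr(cds, 1, 3) == "ATG"))
  expect_true(all(substring(cds, nchar(cds) - 2) %in% c("TAA", "TAG", "TGA")))

  expect_error(simulate_ancestor(1000, n_genes = 50, mean_gene_len = 900),
               "infeasible")
})

test_that("evolve_descendant applies substitutions at the target rate", {
  anc <- simulate_ancestor(100000, gc = 0.63, n_genes = 60, seed = 3)
  d0 <- evolve_descendant(anc, 0, seed = 5)
  expect_identical(d0$seq, anc$seq)
  expect_identical(d0$genes$start, anc$genes$start)

  d <- evolve_descendant(anc, 0.01, seed = 5)
  # drawn substitutions always change the base: expected mismatches = rate * L
  mm <- sum(strsplit(anc$seq, "")[[1]] != strsplit(d$seq, "")[[1]])
  expect_lt(abs(mm - 1000), 3 * sqrt(1000 * 0.99))
  expect_equal(mm, length(d$truth$per_site_substitutions))
})

test_that("planted islands carry a distinct GC and are recorded in the truth table", {
  anc <- simulate_ancestor(60000, gc = 0.65, n_genes = 40, seed = 9)
  d <- evolve_descendant(anc, 0,
                         islands = data.frame(length = 5000, gc = 0.40,
                                              codon_usage_id = "u1"),
                         seed = 10)
  isl <- d$truth$planted_islands
  expect_equal(nrow(isl), 1)
  expect_equal(isl$end - isl$start, 5000)
  gc_isl <- gc_content(substring(d$seq, isl$start + 1, isl$end))
  gc_left <- gc_content(substring(d$seq, max(1, isl$start - 5000), isl$start))
  gc_right <- gc_content(substring(d$seq, isl$end + 1,
                                   min(nchar(d$seq), isl$end + 5000)))
  expect_gt(abs(gc_isl - gc_left), 0.15)
  expect_gt(abs(gc_isl - gc_right), 0.15)
})

test_that("insertion lifting keeps gene models consistent (rate 0 round-trip)", {
  anc <- simulate_ancestor(50000, gc = 0.62, n_genes = 30, seed = 13)
  tn <- data.frame(element_id = c("E1", "E2"), length = c(900, 1100),
                   copy_count = c(2, 3), carries_marker = TRUE)
  d <- evolve_descendant(anc, 0,
                         islands = data.frame(length = c(4000, 6000),
                                              gc = c(0.4, 0.42),
                                              codon_usage_id = c("u", "v")),
                         transposons = tn, seed = 14)
  # every lifted/planted gene re-extracts to a clean ORF (marker genes ride
  # on transposon copies that are lightly mutated by design, so they are
  # checked for interval consistency below but not for codon integrity)
  clean <- d$genes[d$genes$origin != "marker", ]
  cds <- metalca:::gene_sequences(d$seq, clean)
  expect_true(all(substr(cds, 1, 3) == "ATG"))
  expect_true(all(substring(cds, nchar(cds) - 2) %in% c("TAA", "TAG", "TGA")))
  internal_stop <- vapply(cds, function(s) {
    cod <- metalca:::codon_split(s)
    any(cod[-length(cod)] %in% c("TAA", "TAG", "TGA"))
  }, logical(1))
  expect_false(any(internal_stop))
  mk <- d$genes[d$genes$origin == "marker", ]
  expect_true(all(mk$start >= 0 & mk$end <= nchar(d$seq)))
  # planted intervals lie within bounds and exclude ancestral genes
  tt <- d$truth
  L <- nchar(d$seq)
  ints <- rbind(tt$planted_islands[c("start", "end")],
                tt$planted_transposon_loci[c("start", "end")])
  expect_true(all(ints$start >= 0 & ints$end <= L))
  anc_genes <- d$genes[d$genes$origin == "ancestral", ]
  for (i in seq_len(nrow(ints))) {
    expect_false(any(anc_genes$start < ints$end[i] &
                       ints$start[i] < anc_genes$end))
  }
  # transposon copies are near-identical (>= 99% pairwise)
  loci <- tt$planted_transposon_loci
  e1 <- loci[loci$element_id == "E1", ]
  s1 <- substring(d$seq, e1$start + 1, e1$end)
  mm <- sum(strsplit(s1[1], "")[[1]] != strsplit(s1[2], "")[[1]])
  expect_lt(mm / nchar(s1[1]), 0.01)
})

test_that("simulate_metagenome draws reads by abundance with controlled errors", {
  anc <- simulate_ancestor(20000, gc = 0.6, n_genes = 0, seed = 17)
  src <- anc$seq
  # single member, no error: every read is an exact substring
  rd <- simulate_metagenome(list(list(id = "m", seq = src, abundance = 1)),
                            n_reads = 100, read_length = 100,
                            error_rate = 0, seed = 1)
  ok <- vapply(seq_len(nrow(rd)), function(i) {
    s <- rd$seq[i]
    if (rd$strand[i] == "-") s <- metalca:::seq_revcomp(s)
    substring(src, rd$start[i] + 1, rd$start[i] + 100) == s
  }, logical(1))
  expect_true(all(ok))

  # minority member read count within the binomial interval
  other <- simulate_ancestor(20000, gc = 0.45, n_genes = 0, seed = 18)$seq
  rd2 <- simulate_metagenome(list(list(id = "A", seq = src, abundance = 0.99),
                                  list(id = "B", seq = other, abundance = 0.01)),
                             n_reads = 100000, read_length = 80,
                             error_rate = 0, seed = 2)
  nb <- sum(rd2$source == "B")
  expect_gte(nb, 800); expect_lte(nb, 1200)

  # error rate realized per base
  rd3 <- simulate_metagenome(list(list(id = "m", seq = src, abundance = 1)),
                             n_reads = 2000, read_length = 100,
                             error_rate = 0.01, seed = 3)
  mm <- vapply(seq_len(nrow(rd3)), function(i) {
    s <- rd3$seq[i]
    if (rd3$strand[i] == "-") s <- metalca:::seq_revcomp(s)
    sum(strsplit(s, "")[[1]] !=
          strsplit(substring(src, rd3$start[i] + 1, rd3$start[i] + 100), "")[[1]])
  }, numeric(1))
  expect_gt(mean(mm), 0.9); expect_lt(mean(mm), 1.1)

  expect_error(simulate_metagenome(list(list(id = "m", seq = src, abundance = 0.5)),
                                   10), "sum to 1")
  expect_error(simulate_metagenome(list(list(id = "m", seq = src, abundance = 1)),
                                   10, read_length = 40), ">= 50")
})

test_that("fixed seeds give byte-identical FASTA/FASTQ", {
  anc <- simulate_ancestor(5000, gc = 0.6, n_genes = 3, seed = 30)
  rd <- simulate_metagenome(list(list(id = "m", seq = anc$seq, abundance = 1)),
                            n_reads = 50, read_length = c(75, 320), seed = 4)
  rd2 <- simulate_metagenome(list(list(id = "m", seq = anc$seq, abundance = 1)),
                             n_reads = 50, read_length = c(75, 320), seed = 4)
  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile()
  write_fasta(c(g = anc$seq), f1)
  write_fastq(rd, f2); write_fastq(rd2, f3)
  expect_identical(unname(tools::md5sum(f2)), unname(tools::md5sum(f3)))
  expect_true(all(nchar(rd$seq) >= 75 & nchar(rd$seq) <= 320))
  unlink(c(f1, f2, f3))
})

test_that("simulate_codon_pairs realizes the target selection regime", {
  p0 <- simulate_codon_pairs(omega = 1, n_codons = 100, t = 0, seed = 1)
  expect_identical(p0$a, p0$b)
  p <- simulate_codon_pairs(omega = 0.5, n_codons = 200, t = 0.3, seed = 2)
  expect_false(grepl("TAA|TAG|TGA",
                     paste(metalca:::codon_split(p$a), collapse = " ")))
  # omega separation checked in depth by the acceptance suite; spot-check here
  lo <- mean(sapply(1:20, function(s) {
    pr <- simulate_codon_pairs(0.2, 300, t = 0.2, seed = s)
    ng86_dnds(codon_alignment(pr$a, pr$b))$omega
  }), na.rm = TRUE)
  hi <- mean(sapply(1:20, function(s) {
    pr <- simulate_codon_pairs(2.0, 300, t = 0.2, seed = s)
    ng86_dnds(codon_alignment(pr$a, pr$b))$omega
  }), na.rm = TRUE)
  expect_lt(lo, hi)
})
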