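test_that("codon_alignment and backtranslate validate their inputs", {
  ca <- codon_alignment("ATGAAATTT", "ATGAAGTTT")
  expect_equal(ca$n_codons, 3)
  expect_error(codon_alignment("ATGTAAAAA", "ATGAAAAAA"), "stop")
  expect_error(codon_alignment("ATGAAA", "ATGAAAT"), "length")

  # ungapped identical proteins: codon alignment = zipped CDS
  bt <- backtranslate(c("MKF", "MKF"), "ATGAAATTT", "ATGAAGTTC")
  expect_equal(bt$codons_a, c("ATG", "AAA", "TTT"))
  expect_equal(bt$codons_b, c("ATG", "AAG", "TTC"))

  # one gap column drops one codon
  bt2 <- backtranslate(c("MKF", "M-F"), "ATGAAATTT", "ATGTTC")
  expect_equal(bt2$n_codons, 2)

  # translation mismatch names the offending position
  expect_error(backtranslate(c("MKF", "MQF"), "ATGAAATTT", "ATGAAGTTC"),
               "position 2")

  # round-trip on a simulated pair: re-translating reproduces the rows
  p <- simulate_codon_pairs(1, 60, t = 0.3, seed = 5)
  prot <- vapply(c(p$a, p$b), function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s)))
  }, character(1))
  bt3 <- backtranslate(unname(prot), p$a, p$b)
  expect_equal(paste(unname(Biostrings::GENETIC_CODE[bt3$codons_a]),
                     collapse = ""), unname(prot[1]))
  expect_equal(paste(unname(Biostrings::GENETIC_CODE[bt3$codons_b]),
                     collapse = ""), unname(prot[2]))
})

test_that("NG86 counting matches the exhaustive pathway oracle exactly", {
  # identical sequences
  r0 <- ng86_dnds(codon_alignment("ATGAAATTTGGGCCCTGGAAACCCGGGATG",
                                  "ATGAAATTTGGGCCCTGGAAACCCGGGATG"))
  expect_equal(r0$dN, 0); expect_equal(r0$dS, 0)
  expect_true("dS_zero" %in% r0$flags)

  # hand-enumerated single change: TTT (Phe) -> TTA (Leu), nonsynonymous,
  # embedded among identical codons
  a <- c("TTT", rep("AAA", 9)); b <- c("TTA", rep("AAA", 9))
  aln <- structure(list(codons_a = a, codons_b = b, n_codons = 10),
                   class = "codon_alignment")
  r1 <- suppressWarnings(ng86_dnds(aln))
  expect_equal(r1$Nd, 1)
  expect_equal(r1$Sd, 0)
  expect_equal(r1$S_sites + r1$N_sites, 30)
  orc <- oracle_ng86(a, b)
  expect_equal(r1$S_sites, orc$S)
  expect_equal(r1$Sd, orc$Sd)
  expect_equal(r1$Nd, orc$Nd)

  # randomized alignments of <= 5 codons, exact equality with the oracle
  sense <- metalca:::sense_codons()
  for (s in 1:25) {
    cods <- metalca:::with_seed(s, {
      n <- sample(2:5, 1)
      list(a = sample(sense, n, replace = TRUE),
           b = sample(sense, n, replace = TRUE))
    })
    aln <- structure(list(codons_a = cods$a, codons_b = cods$b,
                          n_codons = length(cods$a)),
                     class = "codon_alignment")
    got <- suppressWarnings(ng86_dnds(aln))
    orc <- oracle_ng86(cods$a, cods$b)
    expect_equal(got$S_sites, orc$S, tolerance = 1e-12)
    expect_equal(got$N_sites, orc$N, tolerance = 1e-12)
    expect_equal(got$Sd, orc$Sd, tolerance = 1e-12)
    expect_equal(got$Nd, orc$Nd, tolerance = 1e-12)
    if (!is.na(orc$dS) && !is.na(got$dS)) {
      expect_equal(got$dS, orc$dS, tolerance = 1e-12)
    }
  }
})

test_that("ng86_dnds is symmetric and flags saturation", {
  p <- simulate_codon_pairs(1, 100, t = 0.4, seed = 9)
  r_ab <- ng86_dnds(codon_alignment(p$a, p$b))
  r_ba <- ng86_dnds(codon_alignment(p$b, p$a))
  expect_equal(r_ab$dN, r_ba$dN)
  expect_equal(r_ab$dS, r_ba$dS)
  expect_equal(r_ab$S_sites, r_ba$S_sites)

  # saturated synonymous proportion is flagged undefined
  aln <- structure(list(codons_a = c("TTA", "CTA", "GGA", "CCA"),
                        codons_b = c("TTG", "CTG", "GGG", "CCG"),
                        n_codons = 4), class = "codon_alignment")
  r <- suppressWarnings(ng86_dnds(aln))
  expect_true(is.na(r$dS))
  expect_true("pS_saturated" %in% r$flags)
})

test_that("read_dnds pools codon comparisons across recruited reads", {
  anc <- simulate_ancestor(20000, gc = 0.6, n_genes = 12, seed = 3)
  gene <- anc$genes[3, ]

  # error-free reads from the reference itself: dN = dS = 0
  rd0 <- simulate_metagenome(list(list(id = "p", seq = anc$seq, abundance = 1)),
                             3000, 100, error_rate = 0, seed = 5)
  h0 <- recruit(rd0, c(g = anc$seq))
  r0 <- read_dnds(gene, h0, rd0, anc$seq)
  expect_equal(r0$dN, 0); expect_equal(r0$dS, 0)
  expect_gt(r0$codons_used, 0)

  # reads overlapping only non-coding flanks: flagged empty
  o <- order(anc$genes$start)
  gap_lo <- anc$genes$end[o][3] + 2
  flank <- data.frame(read = "rf", ref = "g", ref_start = gap_lo,
                      ref_end = gap_lo + 5, q_start = 0L, q_end = 5L,
                      strand = "+", identity = 100,
                      read_aln_frac = 1, stringsAsFactors = FALSE)
  remp <- read_dnds(gene, flank, c(rf = "ACGTA"), anc$seq, min_depth = 1)
  expect_true("empty" %in% remp$flags)

  # diverged population: pooled estimate is positive and finite
  popseq <- evolve_descendant(anc, 0.02, seed = 4)$seq
  rd <- simulate_metagenome(list(list(id = "p", seq = popseq, abundance = 1)),
                            3000, 100, error_rate = 0, seed = 6)
  h <- recruit(rd, c(g = anc$seq))
  r <- read_dnds(gene, h, rd, anc$seq)
  expect_gt(r$dN + r$dS, 0)
  expect_gt(r$S_sites, 0)
  expect_gt(r$N_sites, 0)
})

test_that("read_dnds detects positive selection in a diverged population", {
  # build a gene whose population copies evolved under omega = 2, embedded in
  # a neutral backbone; pooled read-based omega should exceed 1 in most runs
  hits_above_1 <- 0; n_rep <- 12
  for (s in seq_len(n_rep)) {
    pair <- simulate_codon_pairs(2.0, 220, t = 0.25, seed = 200 + s)
    backbone <- metalca:::with_seed(300 + s, metalca:::markov_seq(4000, 0.55))
    ref <- paste0(substring(backbone, 1, 1000), pair$a, substring(backbone, 1001))
    popg <- paste0(substring(backbone, 1, 1000), pair$b, substring(backbone, 1001))
    rd <- simulate_metagenome(list(list(id = "p", seq = popg, abundance = 1)),
                              400, 100, error_rate = 0, seed = 400 + s)
    h <- recruit(rd, c(g = ref))
    gene <- data.frame(gene_id = "g1", start = 1000, end = 1000 + 3 * 220,
                       strand = "+", stringsAsFactors = FALSE)
    r <- read_dnds(gene, h, rd, ref)
    if (!is.na(r$omega) && r$omega > 1) hits_above_1 <- hits_above_1 + 1
  }
  expect_gte(hits_above_1 / n_rep, 0.9)
})
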