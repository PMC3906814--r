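# End-to-end orchestration of the desk-scale study: simulate an ancestor,
# two descendants and a metagenome, run recruitment, composition, synteny,
# the ancestral decision rule, dN/dS and repeat discovery, and score the
# results against the simulator's truth tables.

#' Default pipeline configuration
#'
#' Thresholds default to the study's printed values (25%/25% MGI rule,
#' >90%/8x ancestral support, R^2 = 0.9 binning, sensitivity 0.7 foreign-gene
#' scan, spaced seed weight 30 / length 40, 40%/80% overlap clustering, 97%
#' tracing).  Simulation defaults describe a desk-scale study: a 100-kb
#' ancestor, two descendants at 1% substitution each (expected ANI ~98%),
#' planted islands and marker-carrying transposons, and a 50,000-read
#' metagenome in which a descendant-like population yields ~10x coverage over
#' a random background community.
#'
#' @param seed master integer seed; all stage seeds derive from it
#' @return named list of configuration values
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    # ancestor & divergence
    ancestor_length = 100000, ancestor_gc = 0.63, n_genes = 80,
    mean_gene_len = 900, substitution_rate = 0.01,
    # planted material
    islands_a = data.frame(length = c(12000, 18000, 25000),
                           gc = c(0.40, 0.38, 0.42),
                           codon_usage_id = c("donorX", "donorY", "donorX"),
                           stringsAsFactors = FALSE),
    islands_b = data.frame(length = c(15000, 20000), gc = c(0.41, 0.39),
                           codon_usage_id = c("donorZ", "donorX"),
                           stringsAsFactors = FALSE),
    transposons = data.frame(element_id = c("IS_01", "IS_02"),
                             length = c(1300, 1500), copy_count = c(3, 2),
                             carries_marker = TRUE, stringsAsFactors = FALSE),
    # metagenome
    n_reads = 50000, read_length = 150, error_rate = 0.01,
    population_rate = 0.01, population_abundance = 0.2,
    background_length = 300000, background_gc = 0.50,
    # recruitment / islands / conserved
    window = 1000, recruit_min_seed = 15, recruit_min_identity = 25,
    mgi_max_identity = 25, mgi_max_covered_frac = 0.25,
    conserved_min_identity = 90, conserved_min_depth = 8,
    # composition
    sigi_sensitivity = 0.7, bin_r2 = 0.9, bin_gc_tolerance = 0.05,
    # synteny
    seed_weight = 30, seed_length = 40, chain_max_gap = 20000,
    min_segment_score = 2000,
    # ancestral rule
    anc_min_identity = 90, anc_min_depth = 8,
    # selection
    dnds_max_pairs = 25,
    # repeats
    repeat_genome_coverage = 5, repeat_overlap_frac = 0.40,
    repeat_overlap_identity = 80, repeat_min_degree_factor = 1.5,
    repeat_annotation_cov = 0.5, repeat_min_meta_depth = 8,
    trace_min_identity = 97,
    # gene models: "models" uses the simulator's emitted gene models (the
    # analogue of supplied GFF3), "orfs" calls ORFs de novo
    gene_source = "models")
}

#' Run the full desk-scale pipeline
#'
#' Simulates the study (ancestor, two descendants, metagenome), then runs
#' every analysis stage and scores recovery against the truth tables.
#' Identical seeds give identical results.
#'
#' @param config list from [default_config()]
#' @param outdir optional output directory; when given, stage outputs
#'   (FASTA/GFF3/TSV/BED) and a checksum manifest are written
#' @return list with per-stage outputs and an `evaluation` report
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL) {
  timings <- numeric(0)
  t_last <- proc.time()[["elapsed"]]
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[name] <<- t1 - t_last
    t_last <<- t1
  }
  sd <- config$seed

  # --- simulation ---
  anc <- simulate_ancestor(config$ancestor_length, config$ancestor_gc,
                           config$n_genes, config$mean_gene_len, seed = sd)
  desc_a <- evolve_descendant(anc, config$substitution_rate,
                              islands = config$islands_a,
                              transposons = config$transposons, seed = sd + 1)
  desc_b <- evolve_descendant(anc, config$substitution_rate,
                              islands = config$islands_b,
                              transposons = config$transposons, seed = sd + 2)
  pop <- evolve_descendant(anc, config$population_rate, islands = NULL,
                           transposons = config$transposons, seed = sd + 3)
  background <- with_seed(sd + 4,
                          markov_seq(config$background_length,
                                     config$background_gc, context_sd = 1.2))
  meta <- simulate_metagenome(
    members = list(
      list(id = "population", seq = pop$seq,
           abundance = config$population_abundance),
      list(id = "background", seq = background,
           abundance = 1 - config$population_abundance)),
    n_reads = config$n_reads, read_length = config$read_length,
    error_rate = config$error_rate, seed = sd + 5)
  tick("simulate")

  # --- composition & ANI ---
  prof_a <- tetra_zscores(desc_a$seq, "genome_a")
  prof_b <- tetra_zscores(desc_b$seq, "genome_b")
  tetra_r <- tetra_correlation(prof_a, prof_b)
  ani <- compute_ani(desc_a$seq, desc_b$seq)
  tick("ani_tetra")

  # --- recruitment, islands, conserved regions ---
  hits_a <- recruit(meta, c(genome_a = desc_a$seq),
                    min_seed = config$recruit_min_seed,
                    min_identity_report = config$recruit_min_identity)
  track_a <- build_track(hits_a, c(genome_a = desc_a$seq), config$window)
  mgi_a <- call_mgis(track_a, config$mgi_max_identity, config$mgi_max_covered_frac)
  conserved_a <- call_conserved(track_a, config$conserved_min_identity,
                                config$conserved_min_depth)
  hits_b <- recruit(meta, c(genome_b = desc_b$seq),
                    min_seed = config$recruit_min_seed,
                    min_identity_report = config$recruit_min_identity)
  track_b <- build_track(hits_b, c(genome_b = desc_b$seq), config$window)
  mgi_b <- call_mgis(track_b, config$mgi_max_identity, config$mgi_max_covered_frac)
  tick("recruitment")

  # --- gene models & foreign-gene scan ---
  if (config$gene_source == "models") {
    genes_a <- desc_a$genes[, c("gene_id", "start", "end", "strand")]
    genes_b <- desc_b$genes[, c("gene_id", "start", "end", "strand")]
  } else {
    genes_a <- find_orfs(desc_a$seq)
    genes_b <- find_orfs(desc_b$seq)
  }
  fs_a <- foreign_gene_scan(genes_a, desc_a$seq, config$sigi_sensitivity)
  fs_b <- foreign_gene_scan(genes_b, desc_b$seq, config$sigi_sensitivity)
  foreign_a <- merge(genes_a, fs_a[fs_a$call == "foreign", "gene_id", drop = FALSE],
                     by = "gene_id")[, c("start", "end")]
  foreign_b <- merge(genes_b, fs_b[fs_b$call == "foreign", "gene_id", drop = FALSE],
                     by = "gene_id")[, c("start", "end")]
  tick("composition_scan")

  # --- synteny ---
  anchors <- find_anchors(desc_a$seq, desc_b$seq,
                          spaced_seed(config$seed_weight, config$seed_length))
  synteny <- chain_anchors(anchors, max_gap = config$chain_max_gap,
                           min_segment_score = config$min_segment_score)
  tick("synteny")

  # --- ancestral decision rule ---
  inf <- infer_ancestral(genes_a, synteny, mgi_a = mgi_a, mgi_b = mgi_b,
                         foreign_a = foreign_a, foreign_b = foreign_b,
                         track_a = track_a, genome_a = desc_a$seq,
                         min_identity = config$anc_min_identity,
                         min_depth = config$anc_min_depth)
  tick("ancestor")

  # --- pairwise dN/dS over ortholog pairs ---
  anc_calls <- inf$calls[inf$calls$verdict == "ancestral" &
                           !is.na(inf$calls$partner_start), , drop = FALSE]
  n_pairs <- min(config$dnds_max_pairs, nrow(anc_calls))
  dnds <- NULL
  if (n_pairs > 0) {
    pick <- with_seed(sd + 7, sample(seq_len(nrow(anc_calls)), n_pairs))
    rows <- lapply(pick, function(i) {
      g <- anc_calls[i, ]
      seg <- synteny$segments[synteny$segments$a_start <= g$start &
                                g$end <= synteny$segments$a_end, , drop = FALSE]
      if (nrow(seg) == 0) return(NULL)
      seg <- seg[1, ]
      pstrand <- if (seg$strand == "+") g$strand else c("+" = "-", "-" = "+")[g$strand]
      glen <- g$end - g$start
      # pin the partner window to the gene length (the lift interpolates
      # between anchors, so raw endpoints can be off by a base or two)
      ps <- if (seg$strand == "+") g$partner_start else g$partner_end - glen
      cds_a <- gene_sequences(desc_a$seq, data.frame(
        gene_id = g$gene_id, start = g$start, end = g$end, strand = g$strand,
        stringsAsFactors = FALSE))
      cds_b <- gene_sequences(desc_b$seq, data.frame(
        gene_id = g$gene_id, start = ps, end = ps + glen,
        strand = unname(pstrand), stringsAsFactors = FALSE))
      if (nchar(cds_a) != nchar(cds_b) || nchar(cds_a) %% 3 != 0) return(NULL)
      res <- tryCatch(ng86_dnds(codon_alignment(cds_a, cds_b)),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(gene_id = g$gene_id, dN = res$dN, dS = res$dS,
                 omega = res$omega, n_codons = res$n_codons,
                 stringsAsFactors = FALSE)
    })
    dnds <- do.call(rbind, Filter(Negate(is.null), rows))
  }
  tick("dnds")

  # --- repeats ---
  n_greads <- round(config$repeat_genome_coverage * nchar(desc_a$seq) /
                      config$read_length)
  greads <- simulate_metagenome(
    members = list(list(id = "genome_a", seq = desc_a$seq, abundance = 1)),
    n_reads = n_greads, read_length = config$read_length,
    error_rate = 0.005, seed = sd + 6)
  og <- build_overlap_graph(greads, min_frac = config$repeat_overlap_frac,
                            min_identity = config$repeat_overlap_identity)
  clusters <- annotate_clusters(
    cluster_graph(og, min_degree_factor = config$repeat_min_degree_factor),
    min_cov = config$repeat_annotation_cov)
  clusters <- merge_clusters(clusters, config$repeat_overlap_frac,
                             config$repeat_overlap_identity)
  repeats <- validate_and_trace(
    clusters, meta, genomes = list(genome_a = desc_a$seq, genome_b = desc_b$seq),
    min_meta_depth = config$repeat_min_meta_depth,
    min_trace_identity = config$trace_min_identity)
  tick("repeats")

  # --- contig binning demo on simulated contigs ---
  ga_contigs <- fragment_genome(desc_a$seq, 30000)
  pop_contigs <- fragment_genome(pop$seq, 30000)
  bg_contigs <- fragment_genome(background, 30000)
  contigs <- c(stats::setNames(ga_contigs$seq,
                               sprintf("ga_%03d", seq_len(nrow(ga_contigs)))),
               stats::setNames(pop_contigs$seq,
                               sprintf("pop_%03d", seq_len(nrow(pop_contigs)))),
               stats::setNames(bg_contigs$seq,
                               sprintf("bg_%03d", seq_len(nrow(bg_contigs)))))
  # reference profile from the MGI-free genome: binning runs after
  # recruitment, so strain-specific islands are already known and masked
  mask_mgi <- function(genome, mgi) {
    keep_lo <- c(0, mgi$end)
    keep_hi <- c(mgi$start, nchar(genome))
    ok <- keep_hi > keep_lo
    substring(genome, keep_lo[ok] + 1L, keep_hi[ok])
  }
  refs <- list(
    suppressWarnings(reference_profile(mask_mgi(desc_a$seq, mgi_a), "genome_a")),
    suppressWarnings(reference_profile(background, "background_ref")))
  bins <- suppressWarnings(bin_contigs(contigs, refs, config$bin_r2,
                                       config$bin_gc_tolerance))
  tick("binning")

  # --- evaluation against the truth tables ---
  evaluation <- evaluate(inf$calls, desc_a$truth,
                         gene_origins = desc_a$genes,
                         mgis = mgi_a, trace_loci = repeats$loci,
                         ani = ani$ani)
  tick("evaluate")

  out <- list(config = config, ancestor = anc, descendant_a = desc_a,
              descendant_b = desc_b, population = pop, metagenome = meta,
              ani = ani, tetra_correlation = tetra_r,
              track_a = track_a, track_b = track_b,
              mgi_a = mgi_a, mgi_b = mgi_b, conserved_a = conserved_a,
              foreign_a = fs_a, foreign_b = fs_b, synteny = synteny,
              calls = inf$calls, genotype = inf$genotype, dnds = dnds,
              repeat_clusters = clusters, repeats = repeats, bins = bins,
              evaluation = evaluation, timings = unlist(timings))
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

#' Score pipeline calls against the simulator's truth table
#'
#' Precision and recall are computed over gene verdicts: a call is a true
#' positive when it is ancestral and its gene id is in the truth table's
#' ancestral set.  Island recovery is the base-pair Jaccard between called
#' and planted islands; transposon recovery counts planted loci overlapped by
#' traced element loci.
#'
#' @param calls per-gene calls from [infer_ancestral()]
#' @param truth truth table from [evolve_descendant()]
#' @param gene_origins optional gene table with an `origin` column (used to
#'   score marker-gene exclusion)
#' @param mgis optional called islands
#' @param trace_loci optional traced element loci from [validate_and_trace()]
#' @param ani optional ANI estimate to carry in the report
#' @return list of class `evaluation_report`
#' @export
evaluate <- function(calls, truth, gene_origins = NULL, mgis = NULL,
                     trace_loci = NULL, ani = NULL) {
  known <- calls$gene_id %in% truth$true_ancestral_genes
  if (nrow(calls) > 0 && !any(known) && !is.null(gene_origins) &&
      !any(calls$gene_id %in% gene_origins$gene_id)) {
    stop("truth/calls id mismatch: no call gene id matches the truth table")
  }
  pos <- calls$verdict == "ancestral"
  tp <- sum(pos & known)
  fp <- sum(pos & !known)
  fn <- sum(!pos & known)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  marker_excluded <- NA_real_
  if (!is.null(gene_origins) && any(gene_origins$origin == "marker")) {
    mk <- gene_origins$gene_id[gene_origins$origin == "marker"]
    mk <- intersect(mk, calls$gene_id)
    if (length(mk)) {
      marker_excluded <- mean(calls$verdict[match(mk, calls$gene_id)] == "excluded")
    }
  }
  island_jaccard <- NA_real_
  if (!is.null(mgis) && nrow(truth$planted_islands) > 0) {
    island_jaccard <- interval_jaccard(
      mgis[, c("start", "end")], truth$planted_islands[, c("start", "end")])
  }
  transposons_recovered <- NA_integer_
  if (!is.null(trace_loci) && nrow(truth$planted_transposon_loci) > 0) {
    tl <- truth$planted_transposon_loci
    hit <- vapply(seq_len(nrow(tl)), function(i) {
      any(trace_loci$target == "genome_a" &
            trace_loci$start < tl$end[i] & tl$start[i] < trace_loci$end)
    }, logical(1))
    transposons_recovered <- length(unique(tl$element_id[hit]))
  }
  structure(list(precision = precision, recall = recall,
                 tp = tp, fp = fp, fn = fn,
                 marker_gene_exclusion = marker_excluded,
                 island_jaccard = island_jaccard,
                 transposons_recovered = transposons_recovered,
                 ani = ani),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation vs truth table\n")
  cat(sprintf("  ancestral precision: %.3f  recall: %.3f (TP %d / FP %d / FN %d)\n",
              x$precision, x$recall, x$tp, x$fp, x$fn))
  if (!is.na(x$marker_gene_exclusion))
    cat(sprintf("  marker-gene exclusion: %.0f%%\n", 100 * x$marker_gene_exclusion))
  if (!is.na(x$island_jaccard))
    cat(sprintf("  island base-pair Jaccard: %.3f\n", x$island_jaccard))
  if (!is.na(x$transposons_recovered))
    cat(sprintf("  transposon elements recovered: %d\n", x$transposons_recovered))
  if (!is.null(x$ani)) cat(sprintf("  ANI estimate: %.2f%%\n", x$ani))
  invisible(x)
}

#' Base-pair Jaccard index between two interval sets
#' @param a,b data.frames with 0-based half-open `start`, `end`
#' @return intersection / union on base pairs, in `[0, 1]`
#' @export
interval_jaccard <- function(a, b) {
  ra <- IRanges::reduce(IRanges::IRanges(a$start + 1L, a$end))
  rb <- IRanges::reduce(IRanges::IRanges(b$start + 1L, b$end))
  inter <- sum(IRanges::width(IRanges::intersect(ra, rb)))
  uni <- sum(IRanges::width(IRanges::union(ra, rb)))
  if (uni == 0) return(NA_real_)
  inter / uni
}

# --- output writers --------------------------------------------------------

#' Write a gene table as GFF3
#' @param genes gene table (0-based half-open internally; written 1-based
#'   inclusive)
#' @param seqid sequence name
#' @param path output file
#' @export
write_gff3 <- function(genes, seqid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    writeLines(sprintf("%s\tmetalca\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                       seqid, genes$start + 1L, genes$end, genes$strand,
                       genes$gene_id), con)
  }
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#' @param intervals data.frame with `start`, `end` and optionally `ref`/names
#' @param path output file
#' @param ref reference name used when `intervals` has no `ref` column
#' @export
write_bed <- function(intervals, path, ref = "seq") {
  chrom <- if ("ref" %in% names(intervals)) intervals$ref else rep(ref, nrow(intervals))
  name <- if ("element_id" %in% names(intervals)) intervals$element_id
          else if ("cause" %in% names(intervals)) intervals$cause
          else rep(".", nrow(intervals))
  write.table(data.frame(chrom, intervals$start, intervals$end, name),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @noRd
write_pipeline_outputs <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_fasta(c(genome_a = out$descendant_a$seq,
                genome_b = out$descendant_b$seq), p("genomes.fasta"))
  write_fastq(out$metagenome, p("metagenome.fastq"))
  write_gff3(out$descendant_a$genes, "genome_a", p("genes_a.gff3"))
  write.table(out$track_a$windows, p("track_a.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_bed(out$mgi_a, p("mgi_a.bed"), ref = "genome_a")
  write_bed(out$conserved_a, p("conserved_a.bed"), ref = "genome_a")
  write.table(out$synteny$segments, p("segments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(out$calls, p("ancestral_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(out$genotype$sequences)) {
    write_fasta(out$genotype$sequences, p("ancestral_genotype.fasta"))
  }
  if (!is.null(out$dnds)) {
    write.table(out$dnds, p("dnds.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (nrow(out$repeats$loci)) write_bed(out$repeats$loci, p("element_loci.bed"))
  write.table(out$bins, p("bins.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- sort(list.files(outdir, full.names = TRUE))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(outdir)
}
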