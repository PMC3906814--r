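# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# default end-to-end pipeline run (the study conditions at desk scale)
default_run <- function() {
  fixture("default_run", function() run_pipeline(default_config(seed = 1)))
}

# plain two-descendant divergence fixture (no insertions), 100 kb
divergence_sim <- function() {
  fixture("divergence_sim", function() {
    anc <- simulate_ancestor(100000, gc = 0.63, n_genes = 80, seed = 7)
    list(anc = anc,
         a = evolve_descendant(anc, 0.01, seed = 11),
         b = evolve_descendant(anc, 0.01, seed = 12))
  })
}

# repeat-discovery scenario: 8 distinct marker-carrying elements, validated
# against a population metagenome
repeats_sim <- function() {
  fixture("repeats_sim", function() {
    tn <- data.frame(element_id = sprintf("IS_%02d", 1:8),
                     length = c(950, 1000, 1100, 1050, 900, 980, 1020, 1150),
                     copy_count = 3, carries_marker = TRUE,
                     stringsAsFactors = FALSE)
    anc <- simulate_ancestor(150000, gc = 0.63, n_genes = 60, seed = 21)
    a <- evolve_descendant(anc, 0.01, transposons = tn, seed = 22)
    b <- evolve_descendant(anc, 0.01, seed = 23)   # no elements on B
    pop <- evolve_descendant(anc, 0.01, transposons = tn, seed = 24)
    meta <- simulate_metagenome(
      list(list(id = "pop", seq = pop$seq, abundance = 1)),
      n_reads = round(12 * nchar(pop$seq) / 150), read_length = 150,
      error_rate = 0.01, seed = 25)
    greads <- simulate_metagenome(
      list(list(id = "ga", seq = a$seq, abundance = 1)),
      n_reads = round(5 * nchar(a$seq) / 150), read_length = 150,
      error_rate = 0.005, seed = 26)
    # repeat clusters of the genome read set, marker-annotated and merged
    g <- build_overlap_graph(greads)
    clusters <- merge_clusters(
      annotate_clusters(cluster_graph(g, min_degree_factor = 1.5),
                        min_cov = 0.5))
    list(transposons = tn, a = a, b = b, meta = meta, greads = greads,
         clusters = clusters)
  })
}

# hand-built recruitment track covering one replicon with given stats
toy_track <- function(n_windows, depth, identity, ref = "g", window = 1000) {
  structure(list(
    windows = data.frame(ref = ref, start = (seq_len(n_windows) - 1) * window,
                         end = seq_len(n_windows) * window,
                         depth = rep_len(depth, n_windows),
                         covered_frac = ifelse(rep_len(depth, n_windows) > 0, 1, 0),
                         mean_identity = rep_len(identity, n_windows),
                         stringsAsFactors = FALSE),
    window = window,
    reference_lengths = stats::setNames(n_windows * window, ref)),
    class = "recruitment_track")
}
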