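# A small planted-signal dataset shared across test files, generated once
# per test run (halophile vs non-halophile, 8 organisms per class, 50
# proteins each, default effect profiles).

.shared <- new.env(parent = emptyenv())

shared_halo_data <- function() {
  if (is.null(.shared$halo)) {
    cfg <- default_sim_config("halophilicity", n_per_class = 8,
                              proteins_per_organism = 50, seed = 42)
    ds <- generate_dataset(cfg)
    features <- feature_matrix(ds$records)
    corr <- rank_correlation_matrix(features)
    clustering <- select_representatives(upgma_cluster(corr, 0.9), corr)
    reduced <- reduce_matrix(features, clustering)
    labels <- build_case_labels(ds$manifest, "halophilicity")
    .shared$halo <- list(dataset = ds, features = features, corr = corr,
                         clustering = clustering, reduced = reduced,
                         labels = labels,
                         X = reduced[labels$organism_ids, , drop = FALSE])
  }
  .shared$halo
}

fast_tree_config <- function(n_repeats = 5L, seed = 1L, n_trees = 200L) {
  evaluation_config(n_repeats = n_repeats, seed = seed,
                    classifier = classifier_spec("tree_ensemble",
                                                 n_trees = n_trees))
}
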