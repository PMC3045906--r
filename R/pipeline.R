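# End-to-end orchestration: simulate (or load) -> extract features ->
# reduce once -> evaluate each classification case (with both permutation
# controls) -> rank feature importance. A single reduced feature set is
# shared by all cases, and a provenance record with every seed is written
# so a run can be re-executed identically.

#' Run the full niche-signature pipeline
#'
#' Executes all stages into `out_dir`. Inputs are either a synthetic
#' dataset configuration (`sim_config`) or a manifest TSV of real
#' proteome FASTA files (`manifest_path`). Feature reduction is performed
#' once and the identical representative feature set feeds every
#' requested classification case (the single-feature-set contract). For
#' each case the repeated-split evaluation, the two permutation controls,
#' and a permutation-importance ranking are computed and written as TSV
#' and JSON.
#'
#' @param out_dir output directory (created if needed).
#' @param sim_config a [simulation_config()] (mutually exclusive with
#'   `manifest_path`).
#' @param manifest_path path to a manifest TSV whose `fasta_path` column
#'   points at per-organism FASTA files.
#' @param cases classification cases to run (subset of
#'   `c("domain_of_life", "halophilicity", "thermophilicity")`); cases
#'   whose labels have fewer than two represented classes are skipped
#'   with a message.
#' @param table an [aaindex_table()].
#' @param sets a [residue_sets()].
#' @param scheme a [class_scheme()].
#' @param threshold correlation threshold of the reduction step.
#' @param classifier a [classifier_spec()].
#' @param n_repeats repeated splits per evaluation.
#' @param n_shuffles shuffles per feature for importance.
#' @param seed global integer seed; all stage seeds derive from it.
#' @return (Invisibly) a list with `features`, `reduced`, `clustering`,
#'   and per-case `reports` (`evaluation`, `controls`, `importance`).
#' @export
run_full <- function(out_dir,
                     sim_config = NULL, manifest_path = NULL,
                     cases = c("domain_of_life", "halophilicity",
                               "thermophilicity"),
                     table = default_aaindex_table(),
                     sets = residue_sets(),
                     scheme = class_scheme(),
                     threshold = 0.9,
                     classifier = classifier_spec("tree_ensemble"),
                     n_repeats = 10L,
                     n_shuffles = 10L,
                     seed = 1L) {
  if (is.null(sim_config) == is.null(manifest_path))
    stop("give exactly one of sim_config or manifest_path")
  cases <- match.arg(cases, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(sim_config)) {
    message("stage simulate: ", sum(sim_config$n_organisms_per_class),
            " organisms")
    ds <- generate_dataset(sim_config, dir = file.path(out_dir, "data"))
    records <- ds$records
    manifest <- ds$manifest
  } else {
    manifest <- read_manifest(manifest_path, scheme)
    records <- lapply(seq_len(nrow(manifest)), function(i)
      read_proteome(manifest$fasta_path[i], manifest$organism_id[i]))
    names(records) <- manifest$organism_id
  }

  message("stage features: ", length(records), " proteomes x ",
          length(feature_codes(table)), " features")
  features <- feature_matrix(records, table = table, sets = sets)
  write_feature_matrix(features, file.path(out_dir, "features.tsv"))

  message("stage reduce: threshold ", threshold)
  corr <- rank_correlation_matrix(features)
  clustering <- select_representatives(upgma_cluster(corr, threshold), corr)
  reduced <- reduce_matrix(features, clustering)
  write_feature_matrix(reduced, file.path(out_dir, "reduced.tsv"))
  write_cluster_report(clustering, corr, file.path(out_dir, "clusters.tsv"))

  reports <- list()
  for (case in cases) {
    labels <- tryCatch(build_case_labels(manifest, case), error = function(e) {
      message("case ", case, " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(labels)) next
    message("stage classify: ", case)
    X <- reduced[labels$organism_ids, , drop = FALSE]
    cfg <- evaluation_config(n_repeats = n_repeats, seed = seed,
                             classifier = classifier)
    n_classes <- sum(labels$class_counts > 0)
    if (n_classes == 2) {
      evaluation <- evaluate_case(X, labels$labels, cfg, case = case)
      controls <- list(
        feature_permutation = permutation_control(
          X, labels$labels, cfg, "feature_values", case = case),
        label_permutation = permutation_control(
          X, labels$labels, cfg, "class_labels", case = case))
      importance <- case_importance(X, labels$labels, cfg,
                                    n_shuffles = n_shuffles, case = case)
    } else {
      evaluation <- one_against_one_multiclass(X, labels$labels, cfg,
                                               case = case)
      # controls and importance on the most populous pair
      top2 <- names(sort(labels$class_counts, decreasing = TRUE))[1:2]
      idx <- labels$labels %in% top2
      y2 <- droplevels(labels$labels[idx])
      controls <- list(
        feature_permutation = permutation_control(
          X[idx, , drop = FALSE], y2, cfg, "feature_values", case = case),
        label_permutation = permutation_control(
          X[idx, , drop = FALSE], y2, cfg, "class_labels", case = case))
      importance <- case_importance(X[idx, , drop = FALSE], y2, cfg,
                                    n_shuffles = n_shuffles, case = case)
    }
    reports[[case]] <- list(evaluation = evaluation, controls = controls,
                            importance = importance)
    write_case_report(reports[[case]], file.path(out_dir, case))
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("nichesig")),
    seed = seed, threshold = threshold, cases = names(reports),
    classifier = unclass(classifier), n_repeats = n_repeats,
    n_shuffles = n_shuffles,
    n_organisms = length(records),
    feature_codes = colnames(reduced),
    simulated = !is.null(sim_config),
    sim_seed = if (!is.null(sim_config)) sim_config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(features = features, reduced = reduced,
                 clustering = clustering, reports = reports))
}

write_case_report <- function(report, prefix) {
  ev <- report$evaluation
  out <- if (inherits(ev, "evaluation_report")) {
    list(mean_auc = ev$mean_auc, per_repeat_aucs = ev$per_repeat_aucs)
  } else {
    list(pairwise_mean_aucs = as.list(ev$pairwise_mean_aucs),
         average_auc = ev$average_auc,
         one_vs_all_mean_aucs = as.list(ev$one_vs_all_mean_aucs))
  }
  out$control_aucs <- list(
    feature_permutation = report$controls$feature_permutation$mean_auc,
    label_permutation = report$controls$label_permutation$mean_auc)
  out$importance_top <- report$importance$top_k
  jsonlite::write_json(out, paste0(prefix, "_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  imp <- report$importance
  utils::write.table(
    data.frame(feature = imp$ranking,
               score = unname(imp$scores[imp$ranking]),
               rank = seq_along(imp$ranking)),
    paste0(prefix, "_importance.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  curves <- if (inherits(ev, "evaluation_report")) ev$roc_curves else
    unlist(lapply(ev$pairwise, function(p) p$roc_curves), recursive = FALSE)
  pts <- do.call(rbind, lapply(seq_along(curves), function(i)
    cbind(repeat_id = i, curves[[i]]$points)))
  utils::write.table(pts, paste0(prefix, "_roc_points.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
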