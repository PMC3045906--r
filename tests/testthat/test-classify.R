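test_that("stratified splits preserve class proportions within one organism", {
  labels <- factor(rep(c("A", "B"), c(90, 9)))
  sp <- stratified_split(labels, 2 / 3, seed = 1)
  expect_identical(sum(labels[sp$train] == "A"), 60L)
  expect_identical(sum(labels[sp$train] == "B"), 6L)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)

  survey <- factor(rep(c("non-halophile", "halophile"), c(129, 63)))
  sp2 <- stratified_split(survey, 2 / 3, seed = 2)
  expect_true(abs(length(sp2$train) - 128) <= 1)
  for (s in 1:5) {
    spp <- stratified_split(survey, 2 / 3, seed = s)
    for (cl in levels(survey)) {
      n_cl <- sum(survey == cl)
      expect_lte(abs(sum(survey[spp$train] == cl) - 2 / 3 * n_cl), 1)
    }
  }
})

test_that("splits are deterministic given the seed and vary across seeds", {
  labels <- factor(rep(c("A", "B"), c(20, 20)))
  expect_identical(stratified_split(labels, 2 / 3, seed = 5),
                   stratified_split(labels, 2 / 3, seed = 5))
  trains <- lapply(1:10, function(s)
    stratified_split(labels, 2 / 3, seed = s)$train)
  expect_gt(length(unique(trains)), 5)
  expect_error(stratified_split(factor(c("A", "A", "B")), 2 / 3),
               "at least 2")
})

test_that("min-max normalization is fitted on train and applied to test", {
  train <- cbind(x = c(2, 4, 6), y = c(1, 1, 1))
  test <- cbind(x = c(8, 2), y = c(5, 1))
  nm <- minmax_normalize(train, test)
  expect_equal(unname(nm$train[, "x"]), c(0, 0.5, 1))
  expect_equal(unname(nm$test[, "x"]), c(1.5, 0))  # extrapolation, no clipping
  expect_equal(unname(nm$train[, "y"]), c(0, 0, 0))  # constant -> 0, flagged
  expect_equal(unname(nm$test[, "y"]), c(0, 0))
  expect_identical(attr(nm, "constant_features"), "y")
})

test_that("ROC/AUC equals brute-force pair counting", {
  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c("p", "p", "n", "n"),
                       positive = "p")
  expect_equal(perfect$auc, 1)
  ties <- roc_curve(rep(0.5, 6), rep(c("p", "n"), 3), positive = "p")
  expect_equal(ties$auc, 0.5)
  mixed <- roc_curve(c(0.9, 0.4, 0.35, 0.8), c("p", "n", "p", "n"),
                     positive = "p")
  expect_equal(mixed$auc, 0.5)
  expect_equal(mixed$auc,
               oracle_mw_auc(c(0.9, 0.4, 0.35, 0.8),
                             c("p", "n", "p", "n"), "p"))
  expect_error(roc_curve(1:3, c("p", "p", "p"), positive = "p"),
               "single class")

  set.seed(10)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    labels <- c("p", "n", sample(c("p", "n"), n - 2, replace = TRUE))
    expect_equal(roc_curve(scores, labels, "p")$auc,
                 oracle_mw_auc(scores, labels, "p"))
  }
})

test_that("ROC curves are monotone staircases from (0,0) to (1,1)", {
  set.seed(11)
  for (i in 1:30) {
    n <- sample(4:30, 1)
    rc <- roc_curve(round(runif(n), 2),
                    c("p", "n", sample(c("p", "n"), n - 2, TRUE)), "p")
    pts <- rc$points
    expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(pts$fpr) >= 0))
    expect_true(all(diff(pts$tpr) >= 0))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- runif(40)
  labels <- sample(c("p", "n"), 40, replace = TRUE, prob = c(0.4, 0.6))
  ours <- roc_curve(scores, labels, "p")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                        levels = c("n", "p"), quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref)
})

test_that("repeated-split evaluation separates the planted classes", {
  sh <- shared_halo_data()
  cfg <- fast_tree_config(n_repeats = 5, seed = 3)
  rep <- evaluate_case(sh$X, sh$labels$labels, cfg, case = "halophilicity")
  expect_length(rep$per_repeat_aucs, 5)
  expect_equal(rep$mean_auc, mean(rep$per_repeat_aucs))
  expect_gt(rep$mean_auc, 0.95)
  expect_true(all(rep$per_repeat_aucs >= 0 & rep$per_repeat_aucs <= 1))
  # deterministic under the same configuration
  rep2 <- evaluate_case(sh$X, sh$labels$labels, cfg, case = "halophilicity")
  expect_identical(rep$per_repeat_aucs, rep2$per_repeat_aucs)
  # the SVM adapter separates the same data
  svm_cfg <- evaluation_config(
    n_repeats = 2, seed = 3,
    classifier = classifier_spec("rbf_max_margin",
                                 cost_grid = 2^seq(-1, 7, 2),
                                 gamma_grid = 2^seq(-9, 1, 2)))
  rep3 <- evaluate_case(sh$X, sh$labels$labels, svm_cfg)
  expect_gt(rep3$mean_auc, 0.95)
})

test_that("one-against-one reduction yields all pairwise and one-vs-all panels", {
  cfg <- default_sim_config("thermophilicity", n_per_class = 6,
                            proteins_per_organism = 40, seed = 21)
  ds <- generate_dataset(cfg)
  fm <- feature_matrix(ds$records)
  corr <- rank_correlation_matrix(fm)
  cl <- select_representatives(upgma_cluster(corr, 0.9), corr)
  red <- reduce_matrix(fm, cl)
  lab <- build_case_labels(ds$manifest, "thermophilicity")
  rep <- one_against_one_multiclass(red[lab$organism_ids, ], lab$labels,
                                    fast_tree_config(n_repeats = 2, seed = 4,
                                                     n_trees = 100),
                                    case = "thermophilicity")
  expect_length(rep$pairwise, 3)
  expect_length(rep$one_vs_all, 3)
  expect_equal(rep$average_auc, mean(rep$pairwise_mean_aucs))
  expect_named(rep$pairwise,
               c("mesophile_vs_mesothermophile", "mesophile_vs_thermophile",
                 "mesothermophile_vs_thermophile"))
  # strongly tilted extremes separate well even at this size
  expect_gt(rep$pairwise_mean_aucs[["mesophile_vs_thermophile"]], 0.9)
})

test_that("indistinguishable classes score near chance", {
  p <- function(lbl) class_effect_profile(lbl, "bacteria", "non-halophile",
                                          "mesophile",
                                          proteins_per_organism = 60L)
  cfg <- simulation_config(c(a = 8, b = 8),
                           profiles = list(a = p("a"), b = p("b")), seed = 31)
  ds <- generate_dataset(cfg)
  fm <- feature_matrix(ds$records)
  y <- factor(ds$ground_truth$class_label)
  rep <- evaluate_case(fm, y, fast_tree_config(n_repeats = 5, seed = 5))
  expect_gt(rep$mean_auc, 0.2)
  expect_lt(rep$mean_auc, 0.8)
})

test_that("permutation controls destroy the planted association", {
  sh <- shared_halo_data()
  cfg <- fast_tree_config(n_repeats = 5, seed = 6)
  fp <- permutation_control(sh$X, sh$labels$labels, cfg, "feature_values")
  lp <- permutation_control(sh$X, sh$labels$labels, cfg, "class_labels")
  expect_identical(fp$control_mode, "feature_values")
  expect_identical(lp$control_mode, "class_labels")
  # at n = 16 the chance band is wide; both must fall far below the
  # unpermuted AUC of ~1
  expect_lt(fp$mean_auc, 0.85)
  expect_lt(lp$mean_auc, 0.85)
})
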