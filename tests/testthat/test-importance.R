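make_planted_matrix <- function(n = 60, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("a", "b"), each = n / 2))
  X <- cbind(det = ifelse(y == "b", 2, 0) + rnorm(n, sd = 0.3),
             n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n), n4 = rnorm(n))
  list(X = X, y = y)
}

test_that("a determining feature outranks pure noise in almost every run", {
  wins <- 0L
  for (s in 1:20) {
    d <- make_planted_matrix(seed = s)
    sp <- stratified_split(d$y, 2 / 3, seed = s)
    model <- fit_classifier(classifier_spec("tree_ensemble", n_trees = 200),
                            d$X[sp$train, ], d$y[sp$train], seed = s)
    imp <- permutation_importance(model, d$X[sp$test, ], d$y[sp$test],
                                  n_shuffles = 5, seed = s, positive = "b")
    if (imp$ranking[1] == "det") wins <- wins + 1L
    expect_gt(imp$scores[["det"]], max(imp$scores[c("n1", "n2", "n3", "n4")]))
  }
  expect_gte(wins, 19L)
})

test_that("permuting a constant feature has exactly zero importance", {
  d <- make_planted_matrix(seed = 3)
  X <- cbind(d$X, const = 1)
  sp <- stratified_split(d$y, 2 / 3, seed = 3)
  model <- fit_classifier(classifier_spec("tree_ensemble", n_trees = 100),
                          X[sp$train, ], d$y[sp$train], seed = 3)
  imp <- permutation_importance(model, X[sp$test, ], d$y[sp$test],
                                n_shuffles = 3, seed = 3, positive = "b")
  expect_identical(imp$scores[["const"]], 0)
})

test_that("importance scores do not depend on feature column order", {
  d <- make_planted_matrix(seed = 4)
  sp <- stratified_split(d$y, 2 / 3, seed = 4)
  model <- fit_classifier(classifier_spec("tree_ensemble", n_trees = 100),
                          d$X[sp$train, ], d$y[sp$train], seed = 4)
  imp1 <- permutation_importance(model, d$X[sp$test, ], d$y[sp$test],
                                 n_shuffles = 5, seed = 4, positive = "b")
  shuffled <- d$X[sp$test, rev(colnames(d$X))]
  imp2 <- permutation_importance(model, shuffled, d$y[sp$test],
                                 n_shuffles = 5, seed = 4, positive = "b")
  expect_equal(imp1$scores, imp2$scores[names(imp1$scores)])
})

test_that("an acidic-composition feature tops the halophile importance list", {
  sh <- shared_halo_data()
  imp <- case_importance(sh$X, sh$labels$labels,
                         fast_tree_config(n_repeats = 1, seed = 7),
                         n_shuffles = 5, case = "halophilicity")
  expect_identical(imp$case, "halophilicity")
  expect_length(imp$top_k, 10)
  expect_identical(imp$ranking[order(imp$scores[imp$ranking],
                                     decreasing = TRUE)], imp$ranking)
  # representatives of the clusters holding the planted acidic features
  planted <- c("comp_D", "comp_E", "r_neg_all", "charge")
  planted_reps <- unique(vapply(planted, function(f) {
    i <- which(vapply(sh$clustering$clusters, function(cl) f %in% cl, TRUE))
    sh$clustering$representatives[[i]]
  }, ""))
  expect_true(any(planted_reps %in% imp$top_k))
})

paper_shaped_reports <- function() {
  # top-10 lists shaped like the three published feature-selection panels
  domain10 <- c("Gln_content", "Leu_content", "extended_structure",
                "negative_charge", "avg_protein_size", "Glu_content",
                "charge", "His_content", "charged_noncharged_ratio",
                "Cys_content")
  halo10 <- c("negative_charge", "charge", "hydrophilicity",
              "positive_charge", "Gln_content", "Glu_content",
              "charged_noncharged_ratio", "beta_turn", "Asp_content",
              "Phe_content")
  thermo10 <- c("Gln_content", "loop_information", "Glu_content",
                "Val_content", "extended_structure", "hydrophilicity",
                "Tyr_content", "Asp_content", "negative_charge",
                "coil_parameter")
  universe <- unique(c(domain10, halo10, thermo10, "filler1", "filler2"))
  mk <- function(top10) {
    scores <- stats::setNames(rep(0, length(universe)), universe)
    scores[top10] <- seq(1, 0.1, length.out = 10)
    nichesig:::importance_report(scores, k = 10)
  }
  list(domain_of_life = mk(domain10), halophilicity = mk(halo10),
       thermophilicity = mk(thermo10))
}

test_that("unique/shared signatures reproduce the published pattern", {
  sig <- case_signatures(paper_shaped_reports(), k = 10)
  expect_length(sig$unique$domain_of_life, 4)
  expect_length(sig$unique$halophilicity, 3)
  expect_length(sig$unique$thermophilicity, 4)
  expect_setequal(sig$unique$domain_of_life,
                  c("Leu_content", "avg_protein_size", "His_content",
                    "Cys_content"))
  expect_setequal(sig$unique$halophilicity,
                  c("positive_charge", "beta_turn", "Phe_content"))
  expect_setequal(sig$unique$thermophilicity,
                  c("loop_information", "Val_content", "Tyr_content",
                    "coil_parameter"))
  expect_setequal(sig$shared,
                  c("Gln_content", "Glu_content", "negative_charge"))
  for (cs in names(sig$unique))
    expect_length(intersect(sig$unique[[cs]], sig$shared), 0)
})

test_that("signature edge cases: disjoint and identical top lists", {
  universe <- paste0("f", 1:30)
  mk <- function(top) {
    scores <- stats::setNames(rep(0, 30), universe)
    scores[top] <- seq(1, 0.1, length.out = length(top))
    nichesig:::importance_report(scores, k = 10)
  }
  disjoint <- list(a = mk(universe[1:10]), b = mk(universe[11:20]),
                   c = mk(universe[21:30]))
  sig <- case_signatures(disjoint)
  expect_length(sig$shared, 0)
  expect_identical(sig$unique$a, universe[1:10])

  same <- list(a = mk(universe[1:10]), b = mk(universe[1:10]),
               c = mk(universe[1:10]))
  sig2 <- case_signatures(same)
  expect_setequal(sig2$shared, universe[1:10])
  expect_true(all(lengths(sig2$unique) == 0))

  mismatched <- list(a = mk(universe[1:10]), b = mk(universe[1:10]),
                     c = nichesig:::importance_report(
                       stats::setNames(rep(0, 5), paste0("g", 1:5))))
  expect_error(case_signatures(mismatched), "different feature sets")
})

test_that("box-and-whisker summaries follow the Tukey convention", {
  bw <- box_whisker(1:100)
  expect_equal(bw$median, 50.5)
  expect_equal(bw$q1, 25.75)
  expect_equal(bw$q3, 75.25)
  expect_length(bw$outliers, 0)
  expect_equal(bw$whisker_low, 1)
  expect_equal(bw$whisker_high, 100)

  one <- box_whisker(5)
  expect_equal(one$median, 5)
  expect_equal(one$q1, 5)
  expect_equal(one$whisker_low, 5)
  expect_length(one$outliers, 0)

  spiked <- box_whisker(c(1:20, 100))
  expect_identical(spiked$outliers, 100)
  expect_lte(spiked$whisker_high, 20)
  expect_true(bw$q1 <= bw$median && bw$median <= bw$q3)
})

test_that("per-class box summaries normalize across classes when asked", {
  values <- c(1:10, 101:110)
  classes <- rep(c("lo", "hi"), each = 10)
  bw <- box_whisker_by_class(values, classes, normalize = TRUE)
  expect_equal(bw$lo$whisker_low, 0)
  expect_equal(bw$hi$whisker_high, 1)
  raw <- box_whisker_by_class(values, classes)
  expect_equal(raw$lo$median, 5.5)
})
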