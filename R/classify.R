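# Repeated stratified split evaluation protocol with ROC/AUC, classifier
# adapters (probability random forest, RBF SVM with internal grid search),
# and the two permutation controls (feature-value permutation and decoy
# classification by label permutation).

#' Classifier adapter specification
#'
#' Thin contract over the two base learners. `tree_ensemble` is a
#' probability random forest (\pkg{ranger}, default 1000 trees, other
#' parameters at package defaults); `rbf_max_margin` is an RBF-kernel
#' support vector machine (\pkg{e1071}) whose `cost` and `gamma` are tuned
#' by grid search with internal cross-validation on the training split
#' only. The learning algorithms themselves are third-party; the package
#' contributes the evaluation protocol around them.
#'
#' @param kind `"tree_ensemble"` or `"rbf_max_margin"`.
#' @param n_trees forest size (tree_ensemble).
#' @param cost_grid,gamma_grid candidate values for the SVM grid search;
#'   defaults `2^(-5), 2^(-3), ..., 2^15` and `2^(-15), ..., 2^3`.
#' @param cv_folds folds of the internal cross-validation used to score
#'   grid points (default 10).
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("tree_ensemble", "rbf_max_margin"),
                            n_trees = 1000L,
                            cost_grid = 2^seq(-5, 15, by = 2),
                            gamma_grid = 2^seq(-15, 3, by = 2),
                            cv_folds = 10L) {
  kind <- match.arg(kind)
  stopifnot(n_trees >= 1, length(cost_grid) >= 1, length(gamma_grid) >= 1,
            cv_folds >= 2)
  structure(list(kind = kind, n_trees = as.integer(n_trees),
                 cost_grid = cost_grid, gamma_grid = gamma_grid,
                 cv_folds = as.integer(cv_folds)),
            class = "classifier_spec")
}

#' Evaluation protocol configuration
#'
#' @param train_fraction fraction of organisms in each training split
#'   (default 2/3).
#' @param n_repeats number of independent stratified splits (default 10).
#' @param seed integer seed; every split, fit and permutation derives its
#'   seed deterministically from it.
#' @param classifier a [classifier_spec()].
#' @param normalization only `"train_minmax"`: per-feature min-max scaling
#'   fitted on the training portion and applied to the test portion.
#' @return Object of class `evaluation_config`.
#' @export
evaluation_config <- function(train_fraction = 2 / 3, n_repeats = 10L,
                              seed = 1L,
                              classifier = classifier_spec(),
                              normalization = "train_minmax") {
  stopifnot(train_fraction > 0, train_fraction < 1, n_repeats >= 1)
  normalization <- match.arg(normalization)
  structure(list(train_fraction = train_fraction,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 classifier = classifier, normalization = normalization),
            class = "evaluation_config")
}

#' Stratified train/test split without replacement
#'
#' Samples `train_fraction` of each class (rounded) into the training set,
#' so per-class proportions are preserved within one organism.
#'
#' @param labels factor of class labels.
#' @param train_fraction fraction per class in the training set.
#' @param seed optional integer seed for the draw.
#' @return List with sorted integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 2 / 3, seed = NULL) {
  labels <- droplevels(as.factor(labels))
  counts <- table(labels)
  if (any(counts < 2))
    stop("every class needs at least 2 members for a stratified split")
  if (!is.null(seed)) set.seed(seed)
  train <- unlist(lapply(levels(labels), function(cl) {
    idx <- which(labels == cl)
    n_tr <- min(max(round(train_fraction * length(idx)), 1L), length(idx) - 1L)
    sample(idx)[seq_len(n_tr)]
  }), use.names = FALSE)
  list(train = sort(train), test = sort(setdiff(seq_along(labels), train)))
}

#' Min-max normalization fitted on the training split
#'
#' Per feature, an affine map sending the training minimum to 0 and the
#' training maximum to 1, applied unchanged to the test matrix (test
#' values may fall outside `[0, 1]`; no clipping). A feature constant on
#' the training split maps to 0 everywhere and is flagged.
#'
#' @param train,test numeric matrices with identical columns (`test` may
#'   be `NULL`).
#' @return List `train`, `test`, `min`, `max`; attribute
#'   `constant_features` lists flagged feature codes.
#' @export
minmax_normalize <- function(train, test = NULL) {
  mins <- apply(train, 2, min)
  maxs <- apply(train, 2, max)
  span <- maxs - mins
  constant <- span == 0
  span[constant] <- 1  # arbitrary: numerator is 0 for train, offset for test
  norm <- function(m) {
    out <- sweep(sweep(m, 2, mins, "-"), 2, span, "/")
    out[, constant] <- 0
    out
  }
  out <- list(train = norm(train),
              test = if (!is.null(test)) norm(test),
              min = mins, max = maxs)
  attr(out, "constant_features") <- colnames(train)[constant]
  out
}

#' Fit a classifier adapter
#'
#' @param spec a [classifier_spec()].
#' @param X numeric training matrix (organisms x features), already
#'   normalized.
#' @param y factor of training labels.
#' @param seed integer seed (forest bootstrap / CV fold assignment).
#' @return Object of class `niche_classifier`.
#' @seealso [predict_scores()]
#' @export
fit_classifier <- function(spec, X, y, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("training labels contain a single class")
  fit <- switch(spec$kind,
    tree_ensemble = ranger::ranger(
      x = as.data.frame(X), y = y, num.trees = spec$n_trees,
      probability = TRUE, min.node.size = 1L, seed = seed,
      num.threads = 1L),
    rbf_max_margin = fit_rbf_svm(spec, X, y, seed))
  structure(list(kind = spec$kind, fit = fit, levels = levels(y),
                 feature_codes = colnames(X)),
            class = "niche_classifier")
}

fit_rbf_svm <- function(spec, X, y, seed) {
  grid <- expand.grid(cost = spec$cost_grid, gamma = spec$gamma_grid)
  folds <- min(spec$cv_folds, min(table(y)) * 2L, length(y))
  set.seed(seed)
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    m <- e1071::svm(x = X, y = y, kernel = "radial", scale = FALSE,
                    cost = grid$cost[i], gamma = grid$gamma[i], cross = folds)
    m$tot.accuracy
  }, 0)
  best <- grid[which.max(acc), ]
  set.seed(seed)
  fit <- e1071::svm(x = X, y = y, kernel = "radial", scale = FALSE,
                    cost = best$cost, gamma = best$gamma, probability = TRUE)
  attr(fit, "tuned") <- best
  fit
}

#' Per-class probability scores of a fitted adapter
#'
#' @param model a [fit_classifier()] result.
#' @param X numeric matrix to score (same columns, same normalization as
#'   the training matrix).
#' @return Numeric matrix, rows matching `X`, one column per class level,
#'   values in `[0, 1]` (forest vote fractions or SVM probability
#'   outputs).
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "niche_classifier"))
  if (!is.null(colnames(X)) && !is.null(model$feature_codes)) {
    if (!setequal(colnames(X), model$feature_codes))
      stop("feature codes of X do not match the training matrix")
    X <- X[, model$feature_codes, drop = FALSE]
  }
  p <- switch(model$kind,
    tree_ensemble = stats::predict(model$fit, data = as.data.frame(X),
                                   num.threads = 1L)$predictions,
    rbf_max_margin = attr(stats::predict(model$fit, newdata = X,
                                         probability = TRUE),
                          "probabilities"))
  p[, model$levels, drop = FALSE]
}

#' ROC curve and AUC from scores
#'
#' Sweeps the decision threshold over the distinct score values and
#' records (false positive rate, true positive rate) points; the AUC is
#' the trapezoidal area under the resulting staircase, which equals the
#' Mann–Whitney statistic: the fraction of (positive, negative) pairs with
#' the positive scored higher, counting ties one half.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels factor/character of true labels; both classes must occur.
#' @param positive the positive class label (default: second factor
#'   level).
#' @return Object of class `roc_curve`: `points` (data.frame `fpr`,
#'   `tpr`, from (0,0) to (1,1)), `auc`, `positive`.
#' @export
roc_curve <- function(scores, labels, positive = NULL) {
  labels <- droplevels(as.factor(labels))
  if (is.null(positive)) positive <- levels(labels)[nlevels(labels)]
  is_pos <- labels == positive
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC undefined: labels contain a single class")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yp <- is_pos[ord]
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, cumsum(yp)[last_of_tie] / n_pos)
  fpr <- c(0, cumsum(!yp)[last_of_tie] / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc,
                 positive = positive),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("roc_curve: AUC =", round(x$auc, 4), "(positive class:", x$positive, ")\n")
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "s",
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Repeated stratified-split evaluation of one binary case
#'
#' Runs `n_repeats` independent stratified 2/3–1/3 splits. Each repeat:
#' min-max normalization is fitted on the training portion and applied to
#' the test portion, the classifier adapter is fitted on the training
#' organisms, the held-out organisms are scored with class probabilities,
#' and a ROC curve with its AUC is computed. Reported are the per-repeat
#' AUCs, their mean, and the per-repeat curves.
#'
#' @param features numeric feature matrix (organisms x features), row
#'   order matching `labels`.
#' @param labels factor with exactly two represented classes.
#' @param config an [evaluation_config()].
#' @param positive positive class (default: second factor level).
#' @param case optional case name carried into the report.
#' @return Object of class `evaluation_report`: `case`,
#'   `per_repeat_aucs`, `mean_auc`, `roc_curves`, `positive`, `config`.
#' @export
evaluate_case <- function(features, labels, config = evaluation_config(),
                          positive = NULL, case = NULL) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2)
    stop("evaluate_case() handles binary cases; use ",
         "one_against_one_multiclass() for 3 classes")
  if (nrow(features) != length(labels))
    stop("features and labels disagree in length")
  if (is.null(positive)) positive <- levels(labels)[2]
  curves <- vector("list", config$n_repeats)
  aucs <- numeric(config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    rseed <- config$seed + 7919L * r
    sp <- stratified_split(labels, config$train_fraction, seed = rseed)
    nm <- minmax_normalize(features[sp$train, , drop = FALSE],
                           features[sp$test, , drop = FALSE])
    model <- fit_classifier(config$classifier, nm$train, labels[sp$train],
                            seed = rseed + 1L)
    sc <- predict_scores(model, nm$test)[, positive]
    curves[[r]] <- roc_curve(sc, labels[sp$test], positive)
    aucs[r] <- curves[[r]]$auc
  }
  structure(list(case = case, per_repeat_aucs = aucs, mean_auc = mean(aucs),
                 roc_curves = curves, positive = positive, config = config),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report", if (!is.null(x$case)) paste0("[", x$case, "]"),
      "-", length(x$per_repeat_aucs), "repeats, mean AUC =",
      round(x$mean_auc, 4), "\n")
  invisible(x)
}

#' One-against-one (and one-against-all) evaluation of a 3-class case
#'
#' Reduces the three-class problem to binary problems: for each unordered
#' class pair, the evaluation is restricted to organisms of those two
#' classes and run with [evaluate_case()]; the three pairwise mean AUCs
#' and their average are reported. One-against-all curves (each class
#' vs. the rest) are computed as well, giving the six panels of the
#' standard presentation.
#'
#' @inheritParams evaluate_case
#' @param labels factor with three represented classes.
#' @return Object of class `multiclass_report`: `pairwise` (named list of
#'   [evaluate_case()] reports), `pairwise_mean_aucs`, `average_auc`
#'   (arithmetic mean of the three pairwise means), `one_vs_all`,
#'   `one_vs_all_mean_aucs`.
#' @export
one_against_one_multiclass <- function(features, labels,
                                       config = evaluation_config(),
                                       case = NULL) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 3) stop("expected exactly 3 represented classes")
  lv <- levels(labels)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  pairwise <- list()
  for (p in pairs) {
    idx <- which(labels %in% p)
    nm <- paste(p, collapse = "_vs_")
    sub_labels <- factor(labels[idx], levels = p)
    if (any(table(sub_labels) < 2)) {
      warning("pair ", nm, " skipped: a class has < 2 members")
      next
    }
    pairwise[[nm]] <- evaluate_case(features[idx, , drop = FALSE], sub_labels,
                                    config, positive = p[2],
                                    case = paste0(case, ":", nm))
  }
  one_vs_all <- lapply(lv, function(cl) {
    y <- factor(ifelse(labels == cl, cl, "rest"), levels = c("rest", cl))
    evaluate_case(features, y, config, positive = cl,
                  case = paste0(case, ":", cl, "_vs_rest"))
  })
  names(one_vs_all) <- paste0(lv, "_vs_rest")
  pw_means <- vapply(pairwise, function(r) r$mean_auc, 0)
  structure(list(case = case, pairwise = pairwise,
                 pairwise_mean_aucs = pw_means,
                 average_auc = mean(pw_means),
                 one_vs_all = one_vs_all,
                 one_vs_all_mean_aucs = vapply(one_vs_all,
                                               function(r) r$mean_auc, 0)),
            class = "multiclass_report")
}

#' @export
print.multiclass_report <- function(x, ...) {
  cat("multiclass_report", if (!is.null(x$case)) paste0("[", x$case, "]"), "\n")
  for (nm in names(x$pairwise_mean_aucs))
    cat("  ", nm, ": mean AUC =", round(x$pairwise_mean_aucs[nm], 4), "\n")
  cat("  average of pairwise AUCs:", round(x$average_auc, 4), "\n")
  invisible(x)
}

#' Permutation controls for a classification case
#'
#' Two negative controls run through the identical evaluation protocol:
#' `"feature_values"` independently permutes each feature column across
#' organisms (destroying every feature–label association while preserving
#' the feature marginals); `"class_labels"` permutes the label vector
#' (decoy classification). Either way the mean AUC drops to approximately
#' 0.5 when the unpermuted run carries real signal. A fresh permutation
#' is drawn for every repeat: under a single frozen permutation all
#' repeats share the same accidental associations, which makes the mean
#' control AUC an unnecessarily noisy estimate of chance level.
#'
#' @inheritParams evaluate_case
#' @param mode `"feature_values"` or `"class_labels"`.
#' @param perm_seed base seed of the permutation draws (default derived
#'   from `config$seed`); repeat `r` permutes with `perm_seed + r`.
#' @return An [evaluate_case()]-style report with `$control_mode` set.
#' @export
permutation_control <- function(features, labels, config = evaluation_config(),
                                mode = c("feature_values", "class_labels"),
                                perm_seed = config$seed + 99991L,
                                positive = NULL, case = NULL) {
  mode <- match.arg(mode)
  curves <- vector("list", config$n_repeats)
  aucs <- numeric(config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    set.seed(perm_seed + r)
    if (mode == "feature_values") {
      feat_r <- apply(features, 2, sample)
      lab_r <- labels
    } else {
      feat_r <- features
      lab_r <- sample(labels)
    }
    cfg_r <- config
    cfg_r$n_repeats <- 1L
    cfg_r$seed <- config$seed + 7919L * (r - 1L)
    one <- evaluate_case(feat_r, lab_r, cfg_r, positive = positive)
    curves[[r]] <- one$roc_curves[[1]]
    aucs[r] <- one$per_repeat_aucs[1]
  }
  structure(list(case = paste0(case, ":control_", mode),
                 per_repeat_aucs = aucs, mean_auc = mean(aucs),
                 roc_curves = curves, positive = curves[[1]]$positive,
                 config = config, control_mode = mode),
            class = "evaluation_report")
}
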