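# Classifier-agnostic permutation feature importance, top-k signature
# extraction across the three classification cases, and box-and-whisker
# per-class summaries.

#' Permutation feature importance on held-out data
#'
#' For each feature, its values in the held-out matrix are shuffled
#' `n_shuffles` times; the importance is the mean increase in prediction
#' error relative to the unshuffled matrix. A feature the model does not
#' rely on leaves the error unchanged; a relevant feature makes it rise.
#' The input matrix is never modified in place. Computed on held-out data
#' (rather than out-of-bag samples) so the same procedure applies to any
#' adapter.
#'
#' The default error is the Brier score of the positive-class
#' probability, a strictly proper scoring rule that registers loss of
#' confidence even while the score *ranking* stays intact. The
#' rank-based alternative `"one_minus_auc"` matches the evaluation
#' module's metric but saturates on well-separated data: when several
#' features each separate the classes on their own, permuting one leaves
#' the AUC at 1 and every importance at exactly zero.
#'
#' @param model a fitted [fit_classifier()] adapter.
#' @param X numeric held-out feature matrix (same columns and
#'   normalization as training).
#' @param y factor of true labels for `X`.
#' @param n_shuffles shuffles per feature (default 10).
#' @param seed integer seed for the shuffles.
#' @param positive positive class (default: the model's second level).
#' @param k size of the reported top list (default 10).
#' @param error_metric `"brier"` (default) or `"one_minus_auc"`.
#' @return Object of class `importance_report`: `scores` (named, in
#'   column order), `ranking` (codes sorted by decreasing score),
#'   `top_k`, `error_before`, `case`.
#' @export
permutation_importance <- function(model, X, y, n_shuffles = 10L, seed = 1L,
                                   positive = NULL, k = 10L,
                                   error_metric = c("brier",
                                                    "one_minus_auc")) {
  stopifnot(inherits(model, "niche_classifier"))
  error_metric <- match.arg(error_metric)
  y <- droplevels(as.factor(y))
  if (is.null(positive)) positive <- model$levels[length(model$levels)]
  err <- switch(error_metric,
    brier = function(m) {
      p <- predict_scores(model, m)[, positive]
      mean((p - as.numeric(y == positive))^2)
    },
    one_minus_auc = function(m)
      1 - roc_curve(predict_scores(model, m)[, positive], y, positive)$auc)
  err_before <- err(X)
  # the same seeded shuffle sequence is used for every feature, so scores
  # do not depend on feature column order
  scores <- vapply(seq_len(ncol(X)), function(j) {
    set.seed(seed)
    mean(vapply(seq_len(n_shuffles), function(s) {
      Xp <- X
      Xp[, j] <- sample(Xp[, j])
      err(Xp)
    }, 0)) - err_before
  }, 0)
  names(scores) <- colnames(X)
  importance_report(scores, k = k, error_before = err_before)
}

importance_report <- function(scores, k = 10L, error_before = NA_real_,
                              case = NULL) {
  ranking <- names(sort(scores, decreasing = TRUE))
  structure(list(case = case, scores = scores, ranking = ranking,
                 top_k = ranking[seq_len(min(k, length(ranking)))],
                 error_before = error_before),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat("importance_report", if (!is.null(x$case)) paste0("[", x$case, "]"),
      "- top features:\n")
  for (f in x$top_k)
    cat(sprintf("  %-24s %+.4f\n", f, x$scores[f]))
  invisible(x)
}

#' Split, fit, and rank feature importance for one case
#'
#' Convenience wrapper following the evaluation protocol: for each of
#' `config$n_repeats` stratified splits, normalization is fitted on the
#' training portion, the adapter is fitted, and
#' [permutation_importance()] is computed on the held-out portion; the
#' per-split scores are averaged. Averaging over splits stabilizes the
#' ranking, which on one small held-out set is dominated by split noise.
#'
#' @inheritParams evaluate_case
#' @inheritParams permutation_importance
#' @param n_shuffles shuffles per feature and split.
#' @param k top-list size.
#' @return An `importance_report` (with `$case` filled in).
#' @export
case_importance <- function(features, labels, config = evaluation_config(),
                            n_shuffles = 10L, k = 10L, positive = NULL,
                            case = NULL,
                            error_metric = c("brier", "one_minus_auc")) {
  error_metric <- match.arg(error_metric)
  labels <- droplevels(as.factor(labels))
  if (is.null(positive)) positive <- levels(labels)[nlevels(labels)]
  score_sum <- NULL
  err_sum <- 0
  for (r in seq_len(config$n_repeats)) {
    rseed <- config$seed + 7919L * r
    sp <- stratified_split(labels, config$train_fraction, seed = rseed)
    nm <- minmax_normalize(features[sp$train, , drop = FALSE],
                           features[sp$test, , drop = FALSE])
    model <- fit_classifier(config$classifier, nm$train, labels[sp$train],
                            seed = rseed + 1L)
    rep <- permutation_importance(model, nm$test, labels[sp$test],
                                  n_shuffles = n_shuffles,
                                  seed = rseed + 2L,
                                  positive = positive, k = k,
                                  error_metric = error_metric)
    score_sum <- if (is.null(score_sum)) rep$scores else score_sum + rep$scores
    err_sum <- err_sum + rep$error_before
  }
  out <- importance_report(score_sum / config$n_repeats, k = k,
                           error_before = err_sum / config$n_repeats,
                           case = case)
  out
}

#' Unique and shared top features across the three classification cases
#'
#' From the three cases' top-k importance lists: `shared` features appear
#' in all three lists; a case's `unique` features are its top-k minus the
#' union of the other two cases' top-k lists (default), or minus the
#' three-way intersection only (`mode = "shared_only"`). The remaining
#' top-k features are neither shared nor unique.
#'
#' @param reports named list of three `importance_report`s on the same
#'   feature set.
#' @param k top-list size (default 10).
#' @param mode `"union"` or `"shared_only"` — what a case's unique set
#'   excludes.
#' @return Object of class `case_signatures`: `shared` plus per-case
#'   `unique` lists.
#' @export
case_signatures <- function(reports, k = 10L, mode = c("union", "shared_only")) {
  mode <- match.arg(mode)
  stopifnot(length(reports) == 3)
  featsets <- lapply(reports, function(r) sort(names(r$scores)))
  if (!all(vapply(featsets[-1], identical, TRUE, featsets[[1]])))
    stop("importance reports use different feature sets")
  tops <- lapply(reports, function(r) r$ranking[seq_len(min(k, length(r$ranking)))])
  shared <- Reduce(intersect, tops)
  uniq <- lapply(seq_along(tops), function(i) {
    excl <- if (mode == "union") unique(unlist(tops[-i])) else shared
    setdiff(tops[[i]], excl)
  })
  names(uniq) <- names(reports)
  structure(list(shared = shared, unique = uniq, top_k = tops, k = k,
                 mode = mode),
            class = "case_signatures")
}

#' @export
print.case_signatures <- function(x, ...) {
  cat("case_signatures (k =", x$k, ", mode =", x$mode, ")\n")
  cat("  shared:", if (length(x$shared)) paste(x$shared, collapse = ", ")
      else "(none)", "\n")
  for (nm in names(x$unique))
    cat("  unique to", nm, ":",
        if (length(x$unique[[nm]])) paste(x$unique[[nm]], collapse = ", ")
        else "(none)", "\n")
  invisible(x)
}

#' Box-and-whisker summary (Tukey convention)
#'
#' Quartiles by linear interpolation (quantile type 7), whiskers to the
#' most extreme observation within 1.5 IQR of the box, points beyond the
#' whiskers listed as outliers.
#'
#' @param values numeric vector (length >= 1).
#' @return List `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`, `n`.
#' @export
box_whisker <- function(values) {
  stopifnot(length(values) >= 1, !anyNA(values))
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  in_fence <- values >= q[1] - 1.5 * iqr & values <= q[3] + 1.5 * iqr
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(values[in_fence]),
       whisker_high = max(values[in_fence]),
       outliers = sort(values[!in_fence]), n = length(values))
}

#' Per-class box-and-whisker summaries of one feature
#'
#' @param values numeric feature values across organisms.
#' @param classes factor of class labels, matching `values`.
#' @param normalize if `TRUE`, min-max normalize `values` to `[0, 1]`
#'   across all classes first (the convention used when plotting feature
#'   signatures side by side).
#' @return Named list of [box_whisker()] summaries, one per class.
#' @export
box_whisker_by_class <- function(values, classes, normalize = FALSE) {
  stopifnot(length(values) == length(classes))
  if (normalize) {
    rng <- range(values)
    values <- if (diff(rng) == 0) rep(0, length(values))
              else (values - rng[1]) / diff(rng)
  }
  lapply(split(values, droplevels(as.factor(classes))), box_whisker)
}
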