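# Feature redundancy reduction: Spearman rank correlation between all
# feature pairs, UPGMA clustering on d = 1 - |rho|, cut so that clusters
# group features whose average absolute rank correlation is at least the
# threshold (default 0.9), then one representative (medoid) per cluster.

#' Rank (Spearman) correlation matrix between features
#'
#' Spearman correlation with average ranks on ties, computed across
#' organisms for every pair of feature columns. Constant features carry no
#' rank information; their correlation to every other feature is set to 0
#' and their codes are recorded in the `constant_features` attribute.
#'
#' @param features numeric matrix, organisms x features (>= 3 organisms,
#'   no missing values).
#' @return Symmetric correlation matrix of class `correlation_matrix` with
#'   unit diagonal.
#' @export
rank_correlation_matrix <- function(features) {
  if (nrow(features) < 3) stop("need at least 3 organisms for rank correlations")
  if (anyNA(features)) stop("feature matrix contains missing values")
  constant <- apply(features, 2, function(x) diff(range(x)) == 0)
  rho <- suppressWarnings(stats::cor(features, method = "spearman"))
  rho[constant, ] <- 0
  rho[, constant] <- 0
  diag(rho) <- 1
  structure(rho, constant_features = colnames(features)[constant],
            class = c("correlation_matrix", "matrix"))
}

#' UPGMA clustering of features by absolute rank correlation
#'
#' Hierarchical agglomeration of features with distance `d = 1 - |rho|`
#' and unweighted pair-group average (UPGMA) linkage, cut at height
#' `1 - threshold`: merges are allowed while the average-linkage height is
#' at most `1 - threshold`, so every cluster groups features whose mean
#' absolute rank correlation is at least the threshold.
#'
#' @param corr a [rank_correlation_matrix()] (or any symmetric correlation
#'   matrix with feature codes as dimnames).
#' @param threshold correlation threshold in `[0, 1]` (default 0.9).
#' @return Object of class `feature_clustering`: `threshold`, `clusters`
#'   (named list of feature-code vectors), `linkage` (merge table and
#'   heights from [stats::hclust()]), `hclust`, and `representatives`
#'   (`NULL` until [select_representatives()] is applied).
#' @export
upgma_cluster <- function(corr, threshold = 0.9) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr),
            threshold >= 0, threshold <= 1)
  codes <- colnames(corr)
  if (is.null(codes)) stop("correlation matrix needs feature codes as dimnames")
  if (length(codes) == 1L) {
    return(structure(list(threshold = threshold,
                          clusters = stats::setNames(list(codes), "c1"),
                          linkage = NULL, hclust = NULL,
                          representatives = NULL),
                     class = "feature_clustering"))
  }
  d <- stats::as.dist(1 - abs(corr))
  h <- stats::hclust(d, method = "average")
  membership <- stats::cutree(h, h = 1 - threshold)
  clusters <- split(codes, membership)
  names(clusters) <- paste0("c", seq_along(clusters))
  structure(list(threshold = threshold, clusters = clusters,
                 linkage = list(merge = h$merge, height = h$height,
                                labels = h$labels),
                 hclust = h, representatives = NULL),
            class = "feature_clustering")
}

#' @export
print.feature_clustering <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat("feature_clustering:", sum(sizes), "features in", length(sizes),
      "clusters (threshold", x$threshold, ")\n")
  if (!is.null(x$representatives))
    cat("  representatives selected:", length(x$representatives), "\n")
  invisible(x)
}

#' Select one representative feature per cluster
#'
#' For clusters of two or more features the representative is the medoid
#' under mean absolute rank correlation: the member with the largest mean
#' `|rho|` to the other members ("closest to the center" — no coordinate
#' centroid exists in correlation space). Singletons represent themselves.
#' Ties are broken by the lexicographically smallest feature code, so the
#' choice is deterministic.
#'
#' @param clustering a [upgma_cluster()] result.
#' @param corr the correlation matrix the clustering was computed from.
#' @return The `feature_clustering` with `representatives` filled in
#'   (named character vector, one feature code per cluster).
#' @export
select_representatives <- function(clustering, corr) {
  stopifnot(inherits(clustering, "feature_clustering"))
  reps <- vapply(clustering$clusters, function(members) {
    if (length(members) == 1L) return(members)
    mean_abs <- vapply(members, function(m) {
      mean(abs(corr[m, setdiff(members, m)]))
    }, 0)
    best <- members[mean_abs == max(mean_abs)]
    sort(best)[1]
  }, "")
  clustering$representatives <- reps
  clustering
}

#' Restrict a feature matrix to the cluster representatives
#'
#' @param features full numeric feature matrix.
#' @param clustering a `feature_clustering` with representatives selected.
#' @return The matrix restricted to representative columns, in the
#'   original column order.
#' @export
reduce_matrix <- function(features, clustering) {
  reps <- clustering$representatives
  if (is.null(reps)) stop("select_representatives() has not been applied")
  missing <- setdiff(reps, colnames(features))
  if (length(missing))
    stop("representative(s) absent from feature matrix: ",
         paste(missing, collapse = ", "))
  keep <- colnames(features)[colnames(features) %in% reps]
  features[, keep, drop = FALSE]
}

#' Write a clustering report as TSV
#'
#' One row per cluster: cluster id, member feature codes, representative,
#' and the mean within-cluster absolute rank correlation.
#'
#' @param clustering a `feature_clustering` with representatives.
#' @param corr the correlation matrix used.
#' @param path output TSV path.
#' @export
write_cluster_report <- function(clustering, corr, path) {
  reps <- clustering$representatives
  if (is.null(reps)) stop("select_representatives() has not been applied")
  rows <- lapply(seq_along(clustering$clusters), function(i) {
    members <- clustering$clusters[[i]]
    mean_rho <- if (length(members) > 1) {
      sub <- abs(corr[members, members])
      mean(sub[upper.tri(sub)])
    } else 1
    data.frame(cluster_id = names(clustering$clusters)[i],
               n_members = length(members),
               members = paste(members, collapse = ","),
               representative = reps[i],
               mean_abs_rho = mean_rho)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export the feature dendrogram in Newick format
#'
#' @param clustering a `feature_clustering` (with at least two features).
#' @param path output file path.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  if (is.null(clustering$hclust)) stop("no dendrogram: single-feature clustering")
  if (!requireNamespace("ape", quietly = TRUE))
    stop("Newick export requires the 'ape' package")
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  invisible(path)
}
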