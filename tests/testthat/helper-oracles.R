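# Independent oracles used to cross-check the package implementations.
# Each is written from first principles against the defining formula, not
# by calling the code under test.

# AUC as the Mann-Whitney statistic: fraction of (positive, negative)
# score pairs with the positive scored higher, ties counted one half.
oracle_mw_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Isoelectric point by dense grid scan of the net-charge curve.
oracle_grid_pi <- function(sequence, pka = pka_set(), step = 1e-4) {
  chars <- strsplit(sequence, "")[[1]]
  n <- function(a) sum(chars == a)
  pH <- seq(0, 14, by = step)
  z <- 1 / (1 + 10^(pH - pka[["Nterm"]])) +
    n("H") / (1 + 10^(pH - pka[["H"]])) +
    n("K") / (1 + 10^(pH - pka[["K"]])) +
    n("R") / (1 + 10^(pH - pka[["R"]])) -
    1 / (1 + 10^(pka[["Cterm"]] - pH)) -
    n("C") / (1 + 10^(pka[["C"]] - pH)) -
    n("D") / (1 + 10^(pka[["D"]] - pH)) -
    n("E") / (1 + 10^(pka[["E"]] - pH)) -
    n("Y") / (1 + 10^(pka[["Y"]] - pH))
  i <- which(z <= 0)[1]  # z is non-increasing; first non-positive point
  (pH[i - 1] + pH[i]) / 2
}

# Brute-force UPGMA: clusters of feature names agglomerated by average
# pairwise distance over the ORIGINAL distance matrix, merging while the
# smallest average distance is at most cut_height (UPGMA is monotone, so
# this equals cutting the full tree at that height). Returns a canonical
# partition: sorted members, clusters ordered by first member.
oracle_upgma <- function(d, cut_height) {
  labs <- colnames(d)
  clusters <- lapply(labs, identity)
  repeat {
    if (length(clusters) == 1) break
    best <- NULL
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        if (avg < best_d) { best_d <- avg; best <- c(j, i) }
      }
    }
    if (best_d > cut_height) break
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  canonical_partition(clusters)
}

canonical_partition <- function(clusters) {
  clusters <- unname(lapply(clusters, function(x) sort(unname(x))))
  clusters[order(vapply(clusters, `[`, "", 1))]
}

random_aa_sequence <- function(len, prob = NULL) {
  paste(sample(AA_ALPHABET, len, replace = TRUE, prob = prob), collapse = "")
}
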