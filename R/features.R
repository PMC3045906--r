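# Per-protein physico-chemical descriptors and their proteome-level
# aggregation. The full default feature set has 79 entries:
# 20 residue frequencies + 48 amino-acid index scale means + isoelectric
# point + protein length + 8 residue-class frequency ratios + total charged
# fraction. Every descriptor is order-independent: it depends on a
# sequence's composition (and length) only.

RATIO_CODES <- c("r_charged_noncharged", "r_charged_all", "r_polar_nonpolar",
                 "r_polar_all", "r_disorder_order", "r_disorder_all",
                 "r_neg_pos", "r_neg_all")

#' Feature codes of the full feature set
#'
#' @param table an [aaindex_table()]; its row names become the index-mean
#'   feature codes.
#' @return Character vector of feature codes: `comp_A` ... `comp_Y`, the
#'   index codes, `pI`, `protein_length`, the eight ratio codes, `charge`.
#' @export
feature_codes <- function(table = default_aaindex_table()) {
  c(paste0("comp_", AA_ALPHABET), rownames(table), "pI", "protein_length",
    RATIO_CODES, "charge")
}

#' Residue composition of a protein sequence
#'
#' @param sequence single sanitized amino-acid string (uppercase canonical
#'   alphabet), length >= 1.
#' @return Named numeric 20-vector of residue frequencies `f(aa)`
#'   (counts / length), summing to 1.
#' @examples
#' residue_composition("ACDG")
#' @export
residue_composition <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("cannot compute composition of an empty sequence")
  chars <- strsplit(sequence, "")[[1]]
  if (!all(chars %in% AA_ALPHABET))
    stop("sequence contains non-canonical characters; sanitize first")
  tab <- table(factor(chars, levels = AA_ALPHABET))
  stats::setNames(as.numeric(tab) / length(chars), AA_ALPHABET)
}

#' Mean amino-acid index value over a sequence
#'
#' The mean of an index (physico-chemical scale) over all residues of a
#' sequence, i.e. `sum_aa f(aa) * value(aa)`.
#'
#' @param sequence sanitized amino-acid string.
#' @param index_values named numeric vector of per-residue index values;
#'   must define every residue present in the sequence.
#' @return Single numeric value.
#' @export
index_mean <- function(sequence, index_values) {
  comp <- residue_composition(sequence)
  v <- index_values[names(comp)]
  if (any(is.na(v) & comp > 0))
    stop("index does not define all residues present in the sequence")
  v[is.na(v)] <- 0
  sum(comp * v)
}

#' Isoelectric point of a protein sequence
#'
#' pH at which the modeled net charge
#' \deqn{Z(pH) = \sum_{basic} \frac{n_i}{1+10^{pH-pKa_i}} -
#'       \sum_{acidic} \frac{n_i}{1+10^{pKa_i-pH}}}
#' crosses zero. Basic groups: N-terminus, His, Lys, Arg; acidic groups:
#' C-terminus, Cys, Asp, Glu, Tyr. Since both termini are always present,
#' `Z(0) > 0 > Z(14)` and Z is monotonically non-increasing in pH, so the
#' root is unique; it is located by bisection on [0, 14].
#'
#' @param sequence sanitized amino-acid string.
#' @param pka a [pka_set()].
#' @param tol bisection stopping width in pH units (default 1e-3).
#' @return The pI in pH units.
#' @examples
#' isoelectric_point("GGGGG")  # midpoint of the two termini pKa values
#' @export
isoelectric_point <- function(sequence, pka = pka_set(), tol = 1e-3) {
  comp <- residue_composition(sequence)  # validates
  n <- nchar(sequence)
  cnt <- matrix(comp[c("C", "D", "E", "H", "K", "R", "Y")] * n, nrow = 1,
                dimnames = list(NULL, c("C", "D", "E", "H", "K", "R", "Y")))
  pi_from_counts(cnt, pka = pka, tol = tol)[1]
}

# Vectorized bisection for many proteins at once; cnt is a matrix with
# columns C, D, E, H, K, R, Y of ionizable side-chain counts (one row per
# protein; termini are added internally).
pi_from_counts <- function(cnt, pka = pka_set(), tol = 1e-3) {
  lo <- rep(0, nrow(cnt)); hi <- rep(14, nrow(cnt))
  while (max(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    z <- net_charge_from_counts(mid, cnt, pka)
    up <- z > 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  (lo + hi) / 2
}

net_charge_from_counts <- function(pH, cnt, pka) {
  basic <- 1 / (1 + 10^(pH - pka[["Nterm"]])) +
    cnt[, "H"] / (1 + 10^(pH - pka[["H"]])) +
    cnt[, "K"] / (1 + 10^(pH - pka[["K"]])) +
    cnt[, "R"] / (1 + 10^(pH - pka[["R"]]))
  acidic <- 1 / (1 + 10^(pka[["Cterm"]] - pH)) +
    cnt[, "C"] / (1 + 10^(pka[["C"]] - pH)) +
    cnt[, "D"] / (1 + 10^(pka[["D"]] - pH)) +
    cnt[, "E"] / (1 + 10^(pka[["E"]] - pH)) +
    cnt[, "Y"] / (1 + 10^(pka[["Y"]] - pH))
  basic - acidic
}

#' Residue-class frequency ratio features
#'
#' The eight ratios of residue-class frequencies: charged/non-charged,
#' charged/all, polar/non-polar, polar/all,
#' disorder-promoting/order-promoting, disorder-promoting/all,
#' negative/positive, negative/all. Since `f(all) = 1`, the `/all` ratios
#' are plain class frequencies. A zero denominator is regularized by adding
#' the pseudocount `1/(length+1)`, so a zero numerator still yields 0 and
#' the feature matrix stays complete.
#'
#' @param composition named 20-vector from [residue_composition()].
#' @param sets a [residue_sets()].
#' @param length sequence length in residues (sets the pseudocount scale).
#' @return Named numeric 8-vector (codes `r_charged_noncharged`, ...,
#'   `r_neg_all`).
#' @export
ratio_features <- function(composition, sets = residue_sets(), length = 100L) {
  stopifnot(abs(sum(composition) - 1) < 1e-6)
  f <- function(set) sum(composition[set])
  pc <- 1 / (length + 1)
  div <- function(num, den) if (den == 0) num / (den + pc) else num / den
  chg <- f(sets$charged); pol <- f(sets$polar)
  dis <- f(sets$disorder_promoting); ord <- f(sets$order_promoting)
  neg <- f(sets$negatively_charged); pos <- f(sets$positively_charged)
  c(r_charged_noncharged = div(chg, 1 - chg),
    r_charged_all = chg,
    r_polar_nonpolar = div(pol, 1 - pol),
    r_polar_all = pol,
    r_disorder_order = div(dis, ord),
    r_disorder_all = dis,
    r_neg_pos = div(neg, pos),
    r_neg_all = neg)
}

#' Full per-protein feature vector
#'
#' Assembles the complete descriptor vector for one protein: residue
#' composition, all index-scale means, isoelectric point, length, the
#' eight frequency ratios, and the total charged fraction
#' (`charge = f(D)+f(E)+f(K)+f(R)`; note this is the charged *content*,
#' not a net charge — net-charge information is carried by `r_neg_pos`).
#'
#' @param sequence sanitized amino-acid string.
#' @param table an [aaindex_table()].
#' @param sets a [residue_sets()].
#' @param pka a [pka_set()].
#' @return Named numeric vector over [feature_codes()] (length 79 with the
#'   default table), with attribute `derived_charges` carrying
#'   `negative_charge`, `positive_charge` and `charge`.
#' @export
protein_features <- function(sequence, table = default_aaindex_table(),
                             sets = residue_sets(), pka = pka_set()) {
  m <- protein_feature_rows(sequence, table = table, sets = sets, pka = pka)
  out <- m[1, ]
  comp <- out[paste0("comp_", AA_ALPHABET)]
  names(comp) <- AA_ALPHABET
  attr(out, "derived_charges") <- c(
    negative_charge = sum(comp[sets$negatively_charged]),
    positive_charge = sum(comp[sets$positively_charged]),
    charge = sum(comp[sets$charged]))
  out
}

# Vectorized workhorse: one row of features per protein sequence.
protein_feature_rows <- function(sequences, table = default_aaindex_table(),
                                 sets = residue_sets(), pka = pka_set()) {
  stopifnot(inherits(table, "aaindex_table"))
  if (length(sequences) < 1L) stop("no sequences given")
  if (any(!nzchar(sequences))) stop("empty sequence")
  aas <- Biostrings::AAStringSet(sequences)
  counts <- Biostrings::letterFrequency(aas, letters = AA_ALPHABET)
  colnames(counts) <- AA_ALPHABET
  len <- Biostrings::width(aas)
  if (any(rowSums(counts) != len))
    stop("sequences contain non-canonical characters; sanitize first")
  comp <- counts / len
  idx <- comp %*% t(unclass(table)[, AA_ALPHABET, drop = FALSE])
  pI <- pi_from_counts(counts[, c("C", "D", "E", "H", "K", "R", "Y"), drop = FALSE],
                       pka = pka)
  rs <- function(set) rowSums(comp[, set, drop = FALSE])
  pc <- 1 / (len + 1)
  div <- function(num, den) ifelse(den == 0, num / (den + pc), num / den)
  chg <- rs(sets$charged); pol <- rs(sets$polar)
  dis <- rs(sets$disorder_promoting); ord <- rs(sets$order_promoting)
  neg <- rs(sets$negatively_charged); pos <- rs(sets$positively_charged)
  ratios <- cbind(div(chg, 1 - chg), chg, div(pol, 1 - pol), pol,
                  div(dis, ord), dis, div(neg, pos), neg)
  out <- cbind(comp, idx, pI, len, ratios, chg)
  colnames(out) <- feature_codes(table)
  out
}

#' Proteome-level feature vector
#'
#' Aggregates per-protein descriptors to one vector per organism by the
#' unweighted arithmetic mean over proteins. Every feature — including the
#' isoelectric point and protein length — is computed per protein and then
#' averaged, not recomputed on the pooled residue content; with unequal
#' protein lengths the two differ.
#'
#' @param record a [proteome_record()].
#' @inheritParams protein_features
#' @return Named numeric vector over [feature_codes()].
#' @export
proteome_features <- function(record, table = default_aaindex_table(),
                              sets = residue_sets(), pka = pka_set()) {
  stopifnot(inherits(record, "proteome_record"))
  colMeans(protein_feature_rows(record$sequences, table = table,
                                sets = sets, pka = pka))
}

#' Feature matrix for a set of proteomes
#'
#' @param records list of [proteome_record()] objects.
#' @inheritParams protein_features
#' @return Numeric matrix, organisms x features; row names are organism
#'   ids, column names are [feature_codes()]. No missing values.
#' @export
feature_matrix <- function(records, table = default_aaindex_table(),
                           sets = residue_sets(), pka = pka_set()) {
  stopifnot(length(records) >= 1L)
  rows <- lapply(records, proteome_features, table = table, sets = sets, pka = pka)
  out <- do.call(rbind, rows)
  rownames(out) <- unname(vapply(records, function(r) r$organism_id, ""))
  if (anyDuplicated(rownames(out))) stop("duplicate organism ids")
  if (anyNA(out)) stop("feature matrix contains missing values")
  out
}

#' Read / write a feature matrix as TSV
#'
#' Layout mirrors a deposited feature table: one row per organism, first
#' column `organism_id`, remaining columns named by feature code.
#'
#' @param path TSV file path.
#' @return `read_feature_matrix()` returns the numeric matrix.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot("organism_id" %in% names(df))
  m <- as.matrix(df[, setdiff(names(df), "organism_id"), drop = FALSE])
  rownames(m) <- df$organism_id
  storage.mode(m) <- "double"
  m
}

#' @rdname read_feature_matrix
#' @param features numeric feature matrix with organism-id row names.
#' @export
write_feature_matrix <- function(features, path) {
  df <- data.frame(organism_id = rownames(features), features,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
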