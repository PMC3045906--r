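# Amino-acid index (physico-chemical scale) tables.
#
# An aaindex_table is a numeric matrix (index codes x 20 residues, columns
# in AA_ALPHABET order) plus per-index descriptions. The default table is
# assembled from the AAindex database as shipped with the seqinr package.

#' Construct an amino-acid index table
#'
#' @param values numeric matrix, one row per index, 20 columns named by
#'   one-letter residue codes (any order; reordered to [AA_ALPHABET]).
#'   Row names are the index codes.
#' @param descriptions character vector of per-index descriptions, same
#'   length/order as `nrow(values)` (optional).
#' @return An `aaindex_table`: the value matrix with a `descriptions`
#'   attribute.
#' @seealso [default_aaindex_table()], [read_aaindex_table()]
#' @export
aaindex_table <- function(values, descriptions = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("index codes (row names) must be present and unique")
  if (!setequal(colnames(values), AA_ALPHABET))
    stop("index table must define values for exactly the 20 canonical residues")
  values <- values[, AA_ALPHABET, drop = FALSE]
  if (anyNA(values)) stop("index table contains missing residue values")
  if (is.null(descriptions)) descriptions <- rownames(values)
  if (length(descriptions) != nrow(values))
    stop("one description per index required")
  names(descriptions) <- rownames(values)
  structure(values, descriptions = descriptions, class = c("aaindex_table", "matrix"))
}

# The 48 default scales: AAindex accessions pinned by code. The six scales
# highlighted in the feature-signature analyses (extended structure,
# beta-turn, information measure for loop, Chou-Fasman coil, Hopp-Woods
# hydrophilicity, Grantham polarity) come first; the remainder is a curated
# spread over hydrophobicity, volume/bulk, accessibility, charge, secondary
# structure propensity, flexibility and composition scales.
DEFAULT_INDEX_CODES <- c(
  "MAXF760102", "CHOP780101", "ROBB760113", "CHAM830101", "HOPT810101",
  "GRAR740102",
  "KYTJ820101", "EISD840101", "ZIMJ680101", "JOND750101", "MANP780101",
  "PRAM900101", "BIGC670101", "ZIMJ680102", "FAUJ880103", "GRAR740103",
  "CHOC760101", "JANJ780101", "ROSG850101", "RADA880101", "WOLR810101",
  "KLEP840101", "FAUJ880111", "FAUJ880112", "CHOP780201", "CHOP780202",
  "LIFS790101", "CHAM810101", "CHAM820101", "COHE430101", "FASG760101",
  "HUTJ700102", "BHAR880101", "KARP850101", "VINM940101", "DAYM780101",
  "GRAR740101", "OOBM770101", "ZIMJ680104", "ZIMJ680103", "LEVM760101",
  "ROSM880101", "GOLD730101", "PONP800101", "SNEP660101", "WERD780101",
  "KRIW790101", "BULH740101")

#' Default table of 48 physico-chemical amino-acid scales
#'
#' Builds the default [aaindex_table()] from the AAindex database bundled
#' with \pkg{seqinr}, using a fixed list of 48 accession codes
#' (`DEFAULT_INDEX_CODES`). The set includes the scales that recur in
#' niche-signature analyses — normalized frequency of extended structure
#' (MAXF760102), normalized frequency of beta-turn (CHOP780101),
#' information measure for loop (ROBB760113), the Chou–Fasman coil
#' parameter (CHAM830101), Hopp–Woods hydrophilicity (HOPT810101) and
#' Grantham polarity (GRAR740102) — plus a curated remainder. The choice of
#' scales is configuration, not a claim: any table with the same shape can
#' be substituted throughout the pipeline.
#'
#' @param codes character vector of AAindex accession codes
#'   (default `DEFAULT_INDEX_CODES`).
#' @return An `aaindex_table` with `length(codes)` rows.
#' @examples
#' tab <- default_aaindex_table()
#' nrow(tab)  # 48
#' @export
default_aaindex_table <- function(codes = DEFAULT_INDEX_CODES) {
  aaidx <- get_seqinr_aaindex()
  missing <- setdiff(codes, names(aaidx))
  if (length(missing))
    stop("accession(s) not in the AAindex data: ", paste(missing, collapse = ", "))
  vals <- t(vapply(codes, function(cc) {
    v <- aaidx[[cc]]$I
    names(v) <- vapply(names(v), function(a3) seqinr::a(a3), "")
    v[AA_ALPHABET]
  }, numeric(length(AA_ALPHABET))))
  colnames(vals) <- AA_ALPHABET
  descr <- vapply(codes, function(cc) aaidx[[cc]]$D, "")
  aaindex_table(vals, descr)
}

# seqinr ships aaindex as a lazy-loaded dataset; fetch it into a local env.
get_seqinr_aaindex <- function() {
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  env$aaindex
}

#' Read / write an amino-acid index table as TSV
#'
#' The TSV layout is one row per index: `index_code`, `description`, then
#' twenty residue columns named by one-letter code.
#'
#' @param path file path.
#' @return `read_aaindex_table()` returns an `aaindex_table`;
#'   `write_aaindex_table()` returns `path` invisibly.
#' @export
read_aaindex_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("index_code", "description", AA_ALPHABET)
  if (!all(need %in% names(df)))
    stop("aaindex TSV must have columns: ", paste(need, collapse = ", "))
  vals <- as.matrix(df[, AA_ALPHABET])
  rownames(vals) <- df$index_code
  aaindex_table(vals, df$description)
}

#' @rdname read_aaindex_table
#' @param table an `aaindex_table`.
#' @export
write_aaindex_table <- function(table, path) {
  stopifnot(inherits(table, "aaindex_table"))
  df <- data.frame(index_code = rownames(table),
                   description = attr(table, "descriptions"),
                   unclass(table)[, AA_ALPHABET, drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
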