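# Proteome FASTA and organism-manifest I/O, plus derivation of the three
# classification-case labels from environmental metadata.

#' Construct a proteome record
#'
#' One organism's set of protein sequences. Sequences are uppercased and
#' must be non-empty strings over the 20-letter canonical alphabet; use
#' [read_proteome()] to sanitize raw FASTA input.
#'
#' @param organism_id single string, unique organism identifier.
#' @param sequences character vector of amino-acid sequences.
#' @param removed_counts optional named integer vector counting characters
#'   stripped during sanitization (kept for logging).
#' @return An object of class `proteome_record` with elements
#'   `organism_id`, `sequences`, `n_proteins`, `removed_counts`.
#' @export
proteome_record <- function(organism_id, sequences, removed_counts = integer()) {
  stopifnot(is.character(organism_id), length(organism_id) == 1L, nzchar(organism_id))
  sequences <- toupper(as.character(sequences))
  if (length(sequences) < 1L) stop("a proteome needs at least one protein")
  if (any(!nzchar(sequences))) stop("empty sequence in proteome '", organism_id, "'")
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), sequences)
  if (any(bad))
    stop("non-canonical characters in ", sum(bad), " sequence(s) of '",
         organism_id, "'; use read_proteome() to sanitize")
  structure(list(organism_id = organism_id, sequences = unname(sequences),
                 n_proteins = length(sequences),
                 removed_counts = removed_counts),
            class = "proteome_record")
}

#' @export
print.proteome_record <- function(x, ...) {
  cat("proteome_record:", x$organism_id, "-", x$n_proteins, "proteins, mean length",
      round(mean(nchar(x$sequences)), 1), "\n")
  invisible(x)
}

#' Read a protein multi-FASTA file as a proteome record
#'
#' Sequences are uppercased; characters outside the 20 canonical residues
#' (ambiguity codes B/J/O/U/X/Z, stop `*`, gaps, ...) are removed and
#' counted, so composition denominators are explicit. Sequences that become
#' empty after sanitization are dropped with a warning.
#'
#' @param path FASTA file path.
#' @param organism_id organism identifier; default is the file name without
#'   extension.
#' @return A [proteome_record()]; the counts of removed characters are in
#'   `$removed_counts`.
#' @export
read_proteome <- function(path, organism_id = sub("\\.[^.]*$", "", basename(path))) {
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) stop("no sequences in FASTA file: ", path)
  raw <- toupper(as.character(aas))
  clean <- gsub(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), "", raw)
  removed <- removed_character_counts(raw, clean)
  empty <- !nzchar(clean)
  if (any(empty)) {
    warning(sum(empty), " sequence(s) in '", path,
            "' empty after sanitization; dropped")
    clean <- clean[!empty]
  }
  if (length(clean) == 0L) stop("no usable sequences in FASTA file: ", path)
  proteome_record(organism_id, clean, removed_counts = removed)
}

removed_character_counts <- function(raw, clean) {
  if (sum(nchar(raw)) == sum(nchar(clean))) return(integer())
  stripped <- gsub(paste0("[", paste(AA_ALPHABET, collapse = ""), "]"), "",
                   paste(raw, collapse = ""))
  tab <- table(strsplit(stripped, "")[[1]])
  stats::setNames(as.integer(tab), names(tab))
}

#' Write a proteome record as multi-FASTA
#'
#' Headers are `>organism_id|proteinN`, sequences wrapped at 60 columns.
#'
#' @param record a [proteome_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(record, path) {
  stopifnot(inherits(record, "proteome_record"))
  aas <- Biostrings::AAStringSet(record$sequences)
  names(aas) <- paste0(record$organism_id, "|protein", seq_along(aas))
  Biostrings::writeXStringSet(aas, path, width = 60L)
  invisible(path)
}

#' Classification scheme for thermophilicity
#'
#' The mesophilic/thermophilic boundary: thermophiles are organisms whose
#' whole optimal growth temperature range lies above the threshold
#' (default 55 degrees C).
#'
#' @param thermophile_threshold boundary temperature in degrees C.
#' @return Object of class `class_scheme`.
#' @export
class_scheme <- function(thermophile_threshold = 55) {
  stopifnot(is.numeric(thermophile_threshold), thermophile_threshold > 0)
  structure(list(thermophile_threshold = thermophile_threshold),
            class = "class_scheme")
}

#' Assign the thermophilicity class from a growth temperature range
#'
#' An organism is a mesophile if its entire optimal growth range lies in
#' the mesophilic region (`temp_max <= threshold`), a thermophile if the
#' entire range lies in the thermophilic region (`temp_min > threshold`),
#' and a mesothermophile if the range starts in the mesophilic region and
#' ends in the thermophilic one. A range touching the threshold exactly at
#' its maximum counts as mesophile, and at its minimum as mesothermophile,
#' because the thermophilic region is strictly above the threshold.
#' Missing ranges give `"unknown"`.
#'
#' @param temp_min,temp_max numeric vectors, range bounds in degrees C
#'   (recycled to common length). `NA` allowed.
#' @param scheme a [class_scheme()].
#' @return Character vector in
#'   `c("mesophile", "mesothermophile", "thermophile", "unknown")`.
#' @examples
#' assign_thermo_class(c(20, 37, 60), c(40, 70, 90))
#' @export
assign_thermo_class <- function(temp_min, temp_max, scheme = class_scheme()) {
  n <- max(length(temp_min), length(temp_max))
  temp_min <- rep_len(temp_min, n); temp_max <- rep_len(temp_max, n)
  thr <- scheme$thermophile_threshold
  ok <- !is.na(temp_min) & !is.na(temp_max)
  if (any(temp_min[ok] > temp_max[ok]))
    stop("temp_min must not exceed temp_max")
  out <- rep("unknown", n)
  out[ok & temp_max <= thr] <- "mesophile"
  out[ok & temp_min > thr] <- "thermophile"
  out[ok & temp_min <= thr & temp_max > thr] <- "mesothermophile"
  out
}

MANIFEST_COLUMNS <- c("organism_id", "domain", "temp_min", "temp_max",
                      "halophile", "fasta_path")

#' Read / write the organism manifest
#'
#' The manifest is a TSV with header
#' `organism_id  domain  temp_min  temp_max  halophile  fasta_path`;
#' missing values are empty fields. `domain` is `bacteria`/`archaea`,
#' `halophile` is `halophile`/`non-halophile` or empty, temperatures are
#' the optimal growth range in degrees C. Reading derives the
#' `thermo_class` column via [assign_thermo_class()].
#'
#' @param path TSV file path.
#' @param scheme a [class_scheme()] used to derive `thermo_class`.
#' @return A `data.frame` with the manifest columns plus `thermo_class`.
#' @export
read_manifest <- function(path, scheme = class_scheme()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!all(MANIFEST_COLUMNS[1:5] %in% names(df)))
    stop("manifest must have columns: ", paste(MANIFEST_COLUMNS, collapse = ", "))
  if (is.null(df$fasta_path)) df$fasta_path <- NA_character_
  df$fasta_path <- as.character(df$fasta_path)
  # FASTA paths may be relative to the manifest's own directory
  rel <- !is.na(df$fasta_path) & !file.exists(df$fasta_path)
  rel[is.na(rel)] <- FALSE
  df$fasta_path[rel] <- file.path(dirname(path), df$fasta_path[rel])
  validate_manifest(df, scheme)
}

#' @rdname read_manifest
#' @param manifest a manifest `data.frame`.
#' @export
write_manifest <- function(manifest, path) {
  out <- manifest[, MANIFEST_COLUMNS]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

validate_manifest <- function(df, scheme = class_scheme()) {
  if (anyDuplicated(df$organism_id)) stop("duplicate organism_id in manifest")
  bad <- setdiff(stats::na.omit(unique(df$domain)), c("bacteria", "archaea"))
  if (length(bad)) stop("unknown domain value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(stats::na.omit(unique(df$halophile)),
                 c("halophile", "non-halophile"))
  if (length(bad)) stop("unknown halophile value(s): ", paste(bad, collapse = ", "))
  df$thermo_class <- assign_thermo_class(df$temp_min, df$temp_max, scheme)
  df
}

#' Derive a halophilicity label from a tolerated NaCl range
#'
#' Optional helper for manifests that carry NaCl ranges instead of a binary
#' label: an organism is called a halophile if the top of its tolerated
#' NaCl range reaches `molarity_threshold` (mol/L).
#'
#' @param nacl_max numeric vector, maximum tolerated NaCl concentration
#'   (mol/L); `NA` gives `NA`.
#' @param molarity_threshold threshold in mol/L (default 1).
#' @return Character vector `"halophile"`/`"non-halophile"`/`NA`.
#' @export
halophile_from_nacl <- function(nacl_max, molarity_threshold = 1) {
  ifelse(is.na(nacl_max), NA_character_,
         ifelse(nacl_max >= molarity_threshold, "halophile", "non-halophile"))
}

CASE_NAMES <- c("domain_of_life", "halophilicity", "thermophilicity")

#' Build the labeled organism list for one classification case
#'
#' Selects the organisms usable for a case (`domain_of_life`,
#' `halophilicity`, or `thermophilicity`), excluding rows whose label for
#' that case is missing or `"unknown"`. Exclusion is per case only: an
#' organism missing its temperature range still participates in the
#' halophilicity case.
#'
#' @param manifest manifest `data.frame` (from [read_manifest()] or
#'   [generate_dataset()]), containing a `thermo_class` column.
#' @param case one of `"domain_of_life"`, `"halophilicity"`,
#'   `"thermophilicity"`.
#' @return A list of class `case_labels`: `case`, `organism_ids`, `labels`
#'   (factor; level order puts the reference class first — bacteria,
#'   non-halophile, then increasing thermophilicity), `class_counts`,
#'   `excluded_ids`.
#' @export
build_case_labels <- function(manifest, case = CASE_NAMES) {
  case <- match.arg(case)
  levels <- switch(case,
    domain_of_life = c("bacteria", "archaea"),
    halophilicity = c("non-halophile", "halophile"),
    thermophilicity = c("mesophile", "mesothermophile", "thermophile"))
  raw <- switch(case,
    domain_of_life = manifest$domain,
    halophilicity = manifest$halophile,
    thermophilicity = manifest$thermo_class)
  keep <- !is.na(raw) & raw %in% levels
  labels <- factor(raw[keep], levels = levels)
  counts <- table(labels)
  if (sum(counts > 0) < 2)
    stop("case '", case, "' has fewer than 2 represented classes")
  structure(list(case = case,
                 organism_ids = manifest$organism_id[keep],
                 labels = labels,
                 class_counts = counts,
                 excluded_ids = manifest$organism_id[!keep]),
            class = "case_labels")
}

#' @export
print.case_labels <- function(x, ...) {
  cat("case_labels:", x$case, "-", length(x$organism_ids), "organisms (",
      paste(names(x$class_counts), x$class_counts, sep = "=", collapse = ", "),
      "),", length(x$excluded_ids), "excluded\n")
  invisible(x)
}
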