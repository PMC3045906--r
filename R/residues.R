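#' The 20 canonical amino acids
#'
#' One-letter codes of the canonical residues, in alphabetical order. All
#' composition vectors and amino-acid index tables in this package are
#' indexed by this vector.
#'
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Residue class definitions for ratio features
#'
#' Defines the residue classes used by the eight frequency-ratio features.
#' Negatively charged (acidic) residues are Asp and Glu; positively charged
#' (basic) residues are Lys and Arg — His is treated as neutral at
#' physiological pH, so that His content remains an independent composition
#' feature. Polar/non-polar follows the standard chemical classification and
#' the disorder-/order-promoting split follows the Dunker convention.
#'
#' @param charged,positively_charged,negatively_charged,polar,non_polar,
#'   disorder_promoting,order_promoting,acidic,basic character vectors of
#'   one-letter residue codes overriding the defaults.
#' @return An object of class `residue_sets`: a named list of character
#'   vectors.
#' @examples
#' sets <- residue_sets()
#' sets$negatively_charged
#' @export
residue_sets <- function(charged = c("D", "E", "K", "R"),
                         positively_charged = c("K", "R"),
                         negatively_charged = c("D", "E"),
                         polar = c("R", "N", "D", "C", "Q", "E", "H", "K", "S", "T", "Y"),
                         non_polar = setdiff(AA_ALPHABET, polar),
                         disorder_promoting = c("A", "R", "G", "Q", "S", "P", "E", "K"),
                         order_promoting = c("W", "C", "F", "I", "Y", "V", "L", "N"),
                         acidic = negatively_charged,
                         basic = positively_charged) {
  sets <- list(charged = charged,
               positively_charged = positively_charged,
               negatively_charged = negatively_charged,
               polar = polar, non_polar = non_polar,
               disorder_promoting = disorder_promoting,
               order_promoting = order_promoting,
               acidic = acidic, basic = basic)
  for (nm in names(sets)) {
    bad <- setdiff(sets[[nm]], AA_ALPHABET)
    if (length(bad))
      stop("residue set '", nm, "' contains non-canonical codes: ",
           paste(bad, collapse = ", "))
  }
  if (!all(c(positively_charged, negatively_charged) %in% charged))
    stop("positively/negatively charged residues must be a subset of 'charged'")
  if (length(intersect(polar, non_polar)))
    stop("'polar' and 'non_polar' must be disjoint")
  if (!setequal(union(polar, non_polar), AA_ALPHABET))
    stop("'polar' and 'non_polar' must cover all 20 residues")
  structure(sets, class = "residue_sets")
}

#' pKa values for isoelectric-point computation
#'
#' Dissociation constants of the ionizable groups used by
#' [isoelectric_point()]. Defaults are the EMBOSS values. `Nterm`/`Cterm`
#' are the free termini; `C`, `D`, `E`, `Y` are acidic side chains and
#' `H`, `K`, `R` basic side chains.
#'
#' @param Nterm,Cterm,C,D,E,H,K,R,Y pKa values (pH units).
#' @return Named numeric vector of class `pka_set`.
#' @export
pka_set <- function(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
                    H = 6.5, K = 10.8, R = 12.5, Y = 10.1) {
  x <- c(Nterm = Nterm, Cterm = Cterm, C = C, D = D, E = E,
         H = H, K = K, R = R, Y = Y)
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 14))
    stop("pKa values must lie in (0, 14)")
  structure(x, class = "pka_set")
}
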