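## Monoisotopic masses of the elements found in peptides and small-molecule
## drugs (CODATA/IUPAC values, u).
MONOISOTOPIC_MASS <- c(
  C = 12, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
  S = 31.97207069, P = 30.97376151, Se = 79.9165218, Na = 22.98976928,
  K = 38.9637064864, Cl = 34.968852682, F = 18.9984031627, Br = 78.9183376,
  I = 126.9044719
)
PROTON_MASS <- 1.007276466

#' Precursor m/z of a protonated molecular ion
#'
#' Computes the monoisotopic m/z of `[M + zH]^(z+)` from a molecular formula,
#' e.g. the singly protonated abacavir ion (C14H18N6O) monitored at m/z 287.2
#' when tracking drug co-purification with MHC I complexes.
#'
#' @param formula molecular formula as a Hill-style string (`"C14H18N6O"`) or
#'   a named count vector (`c(C = 14, H = 18, N = 6, O = 1)`). An empty
#'   formula gives the mass of the bare proton(s) over the charge.
#' @param charge positive integer charge state.
#' @return monoisotopic m/z in Thomson.
#' @examples
#' precursor_mz("C14H18N6O")  # abacavir, 287.16
#' @export
precursor_mz <- function(formula = "C14H18N6O", charge = 1L) {
  check_that(is.numeric(charge) && length(charge) == 1 && charge >= 1 &&
               charge == as.integer(charge), "charge", "must be a positive integer")
  counts <- parse_formula(formula)
  unknown <- setdiff(names(counts), names(MONOISOTOPIC_MASS))
  if (length(unknown) > 0) {
    abort(sprintf("unknown element symbol(s): %s", paste(unknown, collapse = ", ")))
  }
  mass <- sum(MONOISOTOPIC_MASS[names(counts)] * counts)
  (mass + charge * PROTON_MASS) / charge
}

parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    if (length(formula) > 0 && is.null(names(formula))) {
      abort("numeric formula must be a named element-count vector")
    }
    return(formula)
  }
  check_that(is.character(formula) && length(formula) == 1, "formula",
             "must be a formula string or named count vector")
  if (formula == "") return(setNames(numeric(0), character(0)))
  parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    abort(sprintf("cannot parse molecular formula '%s'", formula))
  }
  elements <- sub("[0-9]*$", "", parts)
  digits <- sub("^[A-Za-z]+", "", parts)
  counts <- ifelse(digits == "", 1, suppressWarnings(as.numeric(digits)))
  c(tapply(counts, elements, sum))
}
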