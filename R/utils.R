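#' Round half-up
#'
#' Deterministic half-up rounding (0.005 -> 0.01 at 2 digits), the
#' convention used for all printed percentages in this package.  Base R's
#' `round()` rounds half to even, which cannot reproduce figures such as
#' "91.18" obtained from 62/68.
#'
#' @param x numeric vector (non-negative).
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # small epsilon guards binary-float representations that sit a hair
  # below an exact .5 boundary
  floor(x * p + 0.5 + 1e-9) / p
}

#' Convert a mass dose to a molar dose
#'
#' Converts mg/kg to umol/kg given a molecular weight.  The default
#' molecular weight is tamoxifen free base (371.52 g/mol), for which
#' 1 mg/kg corresponds to 2.7 umol/kg at one-decimal rounding.
#'
#' @param mg_per_kg dose in mg per kg body weight.
#' @param mw_g_per_mol molecular weight in g/mol.
#' @param digits decimals for half-up rounding; `NA` for no rounding.
#' @return dose in umol/kg.
#' @export
dose_umol_per_kg <- function(mg_per_kg, mw_g_per_mol = 371.52, digits = 1) {
  stopifnot(mg_per_kg >= 0, mw_g_per_mol > 0)
  x <- mg_per_kg / mw_g_per_mol * 1000
  if (is.na(digits)) x else round_half_up(x, digits)
}

# shared stage vocabulary
ESTROUS_STAGES <- c("proestrus", "estrus", "metestrus", "diestrus")
GRADE_LEVELS <- c("0", "I", "II", "III")

stop_adq <- function(...) stop(..., call. = FALSE)
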