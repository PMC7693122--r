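#' Physical constants used throughout the package
#'
#' Single source of truth for the CODATA constants entering the
#' rubber-elasticity and Stokes--Einstein expressions.
#'
#' @return A list with elements `R` (molar gas constant, J mol^-1 K^-1),
#'   `N_A` (Avogadro constant, mol^-1) and `k_B` (Boltzmann constant,
#'   J K^-1).
#' @examples
#' physical_constants()$R
#' @export
physical_constants <- function() {
  list(
    R   = 8.314,        # J mol^-1 K^-1
    N_A = 6.02214e23,   # mol^-1
    k_B = 1.380649e-23  # J K^-1
  )
}

# complementary error function; base R exposes it only through pnorm
erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

stopifnot_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and strictly positive", name),
         call. = FALSE)
  }
  invisible(x)
}
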