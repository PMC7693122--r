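#' Turbidity spectrum from a transmittance spectrum
#'
#' Converts transmittance to optical density,
#' \eqn{OD(\lambda) = -\log_{10} T(\lambda)}, and to turbidity per unit
#' path, \eqn{\tau(\lambda) = \ln(10)\, OD(\lambda)/L} (cm^-1). Points
#' with transmittance outside (0, 1] are physically impossible and are
#' dropped with a warning.
#'
#' @param wavelength Wavelength in nm, ascending.
#' @param transmittance Fractional transmittance in (0, 1].
#' @param path_cm Optical path length in cm (default 1, a 10 mm cuvette).
#' @return A data frame of class `turbidity_spectrum` with columns
#'   `wavelength`, `transmittance`, `OD`, `turbidity`.
#' @examples
#' turbidity_spectrum(c(700, 750, 800), c(0.9, 0.92, 0.94))
#' @export
turbidity_spectrum <- function(wavelength, transmittance, path_cm = 1) {
  stopifnot_positive(wavelength, "wavelength")
  if (is.unsorted(wavelength)) stop("`wavelength` must be ascending",
                                    call. = FALSE)
  stopifnot(length(wavelength) == length(transmittance))
  stopifnot_positive(path_cm, "path_cm")
  bad <- !(transmittance > 0 & transmittance <= 1)
  if (any(bad)) {
    warning(sum(bad), " point(s) with transmittance outside (0, 1] dropped")
    wavelength <- wavelength[!bad]; transmittance <- transmittance[!bad]
  }
  od <- -log10(transmittance)
  structure(data.frame(wavelength = wavelength,
                       transmittance = transmittance,
                       OD = od,
                       turbidity = log(10) * od / path_cm),
            path_cm = path_cm,
            class = c("turbidity_spectrum", "data.frame"))
}

#' @rdname turbidity_spectrum
#' @param spectrum Data frame with `wavelength` and `transmittance`
#'   columns.
#' @export
to_turbidity <- function(spectrum, path_cm = 1) {
  turbidity_spectrum(spectrum$wavelength, spectrum$transmittance, path_cm)
}

#' Wavelength exponent of a turbidity spectrum
#'
#' Ordinary least-squares slope of \eqn{\log_{10}\tau} on
#' \eqn{\log_{10}\lambda} over an inclusive wavelength window (default
#' 700--800 nm, where the gel components do not absorb). The slope encodes
#' the size of the average scattering unit; -4 is the Rayleigh
#' (point-scatterer) limit.
#'
#' @param spectrum A [turbidity_spectrum()].
#' @param range Inclusive fit window in nm.
#' @return An object of class `turbidity_fit` with `exponent`,
#'   `r_squared`, `range`, `n_points`.
#' @export
wavelength_exponent <- function(spectrum, range = c(700, 800)) {
  idx <- spectrum$wavelength >= range[1] & spectrum$wavelength <= range[2]
  if (sum(idx) < 5) stop("need at least 5 points in the fit range",
                         call. = FALSE)
  tau <- spectrum$turbidity[idx]
  if (any(tau <= 0)) stop("non-positive turbidity in the fit range",
                          call. = FALSE)
  lw <- log10(spectrum$wavelength[idx]); lt <- log10(tau)
  fit <- stats::lm(lt ~ lw)
  ss_tot <- sum((lt - mean(lt))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 r_squared = r2,
                 range = range, n_points = sum(idx)),
            class = "turbidity_fit")
}

#' @export
print.turbidity_fit <- function(x, ...) {
  cat("Turbidity wavelength exponent:", signif(x$exponent, 5),
      sprintf("(R^2 = %.4f, %d points in %g-%g nm)\n", x$r_squared,
              x$n_points, x$range[1], x$range[2]))
  invisible(x)
}

#' Map a wavelength exponent to an effective correlation length
#'
#' Interpolates a user-supplied monotone exponent-to-length calibration
#' table (linear in log-length), giving the effective mesh size determined
#' from turbidimetry. No extrapolation: an exponent outside the table
#' domain is an error. The calibration data themselves are external input
#' (e.g. a published exponent-length relation for the gel system at hand);
#' the package ships no numbers.
#'
#' @param exponent Wavelength exponent (from [wavelength_exponent()], or a
#'   `turbidity_fit`).
#' @param mapping Data frame with columns `exponent` and `length_um`,
#'   strictly monotone in both columns.
#' @return Correlation length in um.
#' @examples
#' map <- data.frame(exponent = c(-4, -3, -2), length_um = c(0.05, 0.2, 0.8))
#' correlation_length(-2.5, map)
#' @export
correlation_length <- function(exponent, mapping) {
  if (inherits(exponent, "turbidity_fit")) exponent <- exponent$exponent
  stopifnot(is.data.frame(mapping),
            all(c("exponent", "length_um") %in% names(mapping)))
  mapping <- mapping[order(mapping$exponent), ]
  dl <- diff(mapping$length_um)
  if (any(diff(mapping$exponent) <= 0) || !(all(dl > 0) || all(dl < 0)))
    stop("mapping table must be strictly monotone", call. = FALSE)
  if (exponent < min(mapping$exponent) || exponent > max(mapping$exponent))
    stop("exponent ", signif(exponent, 4),
         " outside the mapping domain [", min(mapping$exponent), ", ",
         max(mapping$exponent), "]; no extrapolation", call. = FALSE)
  10^stats::approx(mapping$exponent, log10(mapping$length_um),
                   xout = exponent)$y
}
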