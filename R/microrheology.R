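#' Tracer mean-square-displacement trace
#'
#' 3-D MSD of tracer particles versus lag time, the raw output of a
#' DLS-microrheology run.
#'
#' @param lag Lag time in s, strictly increasing, positive.
#' @param msd Mean square displacement in m^2, positive.
#' @param tracer_radius Tracer radius in m (50 nm for the 100 nm nominal
#'   polystyrene tracers).
#' @param temperature Temperature in K.
#' @return A data frame of class `msd_trace`.
#' @export
msd_trace <- function(lag, msd, tracer_radius = 50e-9, temperature = 298.15) {
  stopifnot_positive(lag, "lag")
  if (is.unsorted(lag, strictly = TRUE))
    stop("`lag` must be strictly increasing", call. = FALSE)
  stopifnot_positive(msd, "msd")
  stopifnot(length(lag) == length(msd))
  stopifnot_positive(tracer_radius, "tracer_radius")
  stopifnot_positive(temperature, "temperature")
  structure(data.frame(lag = lag, msd = msd),
            tracer_radius = tracer_radius, temperature = temperature,
            class = c("msd_trace", "data.frame"))
}

#' Local logarithmic slope of an MSD trace
#'
#' \eqn{\alpha(t) = d\ln\langle\Delta r^2\rangle / d\ln t} by centered
#' differences on the log-log grid (one-sided at the endpoints), clipped to
#' the physically admissible range \[0, 1\] of subdiffusive-to-diffusive
#' motion. Clipping is reported through the `clipped` attribute.
#'
#' @param trace An [msd_trace()] with at least 5 points.
#' @return Numeric vector of local exponents, one per lag point.
#' @examples
#' tr <- gen_msd_trace("viscous", generator_spec(1, noise_none()), eta = 1e-3)
#' range(local_slope(tr))
#' @export
local_slope <- function(trace) {
  if (nrow(trace) < 5) stop("need at least 5 lag points", call. = FALSE)
  lt <- log(trace$lag); lm_ <- log(trace$msd)
  n <- length(lt)
  a <- numeric(n)
  a[1] <- (lm_[2] - lm_[1]) / (lt[2] - lt[1])
  a[n] <- (lm_[n] - lm_[n - 1]) / (lt[n] - lt[n - 1])
  i <- 2:(n - 1)
  a[i] <- (lm_[i + 1] - lm_[i - 1]) / (lt[i + 1] - lt[i - 1])
  clipped <- a < 0 | a > 1
  a <- pmin(pmax(a, 0), 1)
  attr(a, "clipped") <- which(clipped)
  a
}

#' Viscoelastic moduli from an MSD trace (generalized Stokes--Einstein)
#'
#' Mason's local power-law approximation of the generalized
#' Stokes--Einstein relation:
#' \deqn{|G^*(\omega)| = \frac{k_B T}
#'   {\pi a \,\langle\Delta r^2(1/\omega)\rangle\, \Gamma[1 + \alpha(1/\omega)]}}
#' with \eqn{G' = |G^*|\cos(\pi\alpha/2)} and
#' \eqn{G'' = |G^*|\sin(\pi\alpha/2)}, where \eqn{\alpha} is the local
#' logarithmic slope of the MSD and \eqn{a} the tracer radius. The
#' frequency grid is the reciprocal lag grid (\eqn{\omega = 1/t}, rad/s) of
#' the discrete correlator -- no interpolation or oversampling. The MSD is
#' taken as a 3-D displacement; for 2-D particle-tracking data rescale by
#' 3/2 before calling.
#'
#' @param trace An [msd_trace()].
#' @return A data frame of class `gser_spectrum` with columns `omega`
#'   (rad/s), `f` (Hz), `alpha`, `G_storage`, `G_loss` plus the derived
#'   `G_complex`, `phase_angle`, `complex_viscosity` columns computed via
#'   [derived_spectrum()] for cross-scale consistency.
#' @examples
#' tr <- gen_msd_trace("viscous", generator_spec(1, noise_none()), eta = 8.9e-4)
#' head(gser_moduli(tr))
#' @export
gser_moduli <- function(trace) {
  alpha <- local_slope(trace)
  const <- physical_constants()
  a <- attr(trace, "tracer_radius")
  temp <- attr(trace, "temperature")
  gstar <- const$k_B * temp / (pi * a * trace$msd * gamma(1 + alpha))
  gp <- gstar * cos(pi * alpha / 2)
  gl <- gstar * sin(pi * alpha / 2)
  omega <- 1 / trace$lag
  ord <- order(omega)
  sw <- frequency_sweep(omega[ord] / (2 * pi), gp[ord], gl[ord],
                        temperature = temp)
  der <- derived_spectrum(sw)
  structure(data.frame(omega = omega[ord], f = sw$f, alpha = alpha[ord],
                       G_storage = gp[ord], G_loss = gl[ord],
                       G_complex = der$G_complex,
                       phase_angle = der$phase_angle,
                       complex_viscosity = der$complex_viscosity),
            tracer_radius = a, temperature = temp,
            class = c("gser_spectrum", "data.frame"))
}
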