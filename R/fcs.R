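#' FCS autocorrelation curve
#'
#' @param tau Correlation lag in s, strictly increasing, positive.
#' @param G Autocorrelation amplitude (dimensionless, finite).
#' @param w0 Lateral beam waist of the confocal volume in m (calibration).
#' @param kappa Axial-to-lateral structure parameter (> 1).
#' @return A data frame of class `fcs_curve`.
#' @export
fcs_curve <- function(tau, G, w0 = 0.3e-6, kappa = 5) {
  stopifnot_positive(tau, "tau")
  if (is.unsorted(tau, strictly = TRUE))
    stop("`tau` must be strictly increasing", call. = FALSE)
  stopifnot(length(tau) == length(G), all(is.finite(G)))
  stopifnot_positive(w0, "w0")
  if (kappa <= 1) stop("`kappa` must exceed 1", call. = FALSE)
  structure(data.frame(tau = tau, G = G), w0 = w0, kappa = kappa,
            class = c("fcs_curve", "data.frame"))
}

# single-component free 3-D diffusion through a Gaussian focal volume
fcs_model <- function(tau, N, tauD, kappa) {
  (1 / N) / ((1 + tau / tauD) * sqrt(1 + tau / (kappa^2 * tauD)))
}

#' Fit the single-component 3-D diffusion model to an FCS curve
#'
#' Least-squares fit of
#' \eqn{G(\tau) = N^{-1}(1+\tau/\tau_D)^{-1}(1+\tau/(\kappa^2\tau_D))^{-1/2}}
#' with the structure parameter \eqn{\kappa} fixed from the curve's
#' calibration (it is not separately identifiable from a single curve).
#' The self-diffusion coefficient follows from the beam-waist calibration
#' as \eqn{D_s = w_0^2 / (4\tau_D)}.
#'
#' @param curve An [fcs_curve()] with at least 10 lag points; a warning is
#'   issued when the lag grid does not bracket the fitted \eqn{\tau_D} by
#'   a decade on each side.
#' @return An object of class `fcs_fit` with `N`, `tauD` (s), `Ds`
#'   (um^2 s^-1), `rss`, `converged`.
#' @examples
#' cv <- gen_fcs_acf(2, 65.6e-6, spec = generator_spec(1, noise_none()))
#' fit_fcs(cv)
#' @export
fit_fcs <- function(curve) {
  if (nrow(curve) < 10) stop("need at least 10 lag points", call. = FALSE)
  kappa <- attr(curve, "kappa"); w0 <- attr(curve, "w0")
  tau <- curve$tau; g <- curve$G
  N0 <- max(1 / max(g[g > 0], 1e-12), 1e-6)
  tauD0 <- tau[which.min(abs(g - max(g) / 2))]
  resid_fn <- function(logp)
    fcs_model(tau, exp(logp[1]), exp(logp[2]), kappa) - g
  fit <- minpack.lm::nls.lm(par = c(log(N0), log(tauD0)), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  if (!fit$info %in% 1:4)
    stop("FCS fit did not converge: ", fit$message, call. = FALSE)
  N <- exp(fit$par[1]); tauD <- exp(fit$par[2])
  if (min(tau) > tauD / 10 || max(tau) < tauD * 10)
    warning("lag grid does not span tauD by a decade on each side")
  Ds_m2 <- w0^2 / (4 * tauD)
  structure(list(N = N, tauD = tauD, Ds = Ds_m2 * 1e12, w0 = w0,
                 kappa = kappa, rss = sum(fit$fvec^2), converged = TRUE),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat("FCS fit: N =", signif(x$N, 5), "; tauD =", signif(x$tauD * 1e6, 5),
      "us; Ds =", signif(x$Ds, 5), "um^2 s^-1\n")
  invisible(x)
}

#' TCSPC decay histogram
#'
#' @param t_ns Bin centers in ns, ascending.
#' @param counts Photon counts per bin (non-negative).
#' @return A data frame of class `decay_histogram`.
#' @export
decay_histogram <- function(t_ns, counts) {
  stopifnot(is.numeric(t_ns), is.numeric(counts),
            length(t_ns) == length(counts))
  if (is.unsorted(t_ns, strictly = TRUE))
    stop("`t_ns` must be strictly increasing", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(data.frame(t_ns = t_ns, counts = counts),
            class = c("decay_histogram", "data.frame"))
}

#' Mono-exponential tail fit of a fluorescence decay
#'
#' Fits \eqn{n(t) = A\exp(-t/\tau_{fl}) + b} on the decay tail starting
#' `tail_start` ns past the histogram peak. Tail fitting side-steps the
#' instrument response function, which distorts only the rising edge and
#' the region around the peak.
#'
#' @param decay A [decay_histogram()].
#' @param tail_start Offset of the fit window start beyond the peak, in ns
#'   (default 1 ns); at least 20 bins must remain in the tail.
#' @return An object of class `lifetime_fit` with `tau_fl` (ns),
#'   `amplitude`, `background`, `rss`.
#' @examples
#' d <- gen_tcspc_decay(4.21, 1e4, spec = generator_spec(1))
#' fit_lifetime(d)
#' @export
fit_lifetime <- function(decay, tail_start = 1) {
  peak_t <- decay$t_ns[which.max(decay$counts)]
  idx <- decay$t_ns >= peak_t + tail_start
  if (sum(idx) < 20) stop("need at least 20 bins in the tail", call. = FALSE)
  t <- decay$t_ns[idx]; y <- decay$counts[idx]
  if (max(y) <= 0) stop("decay tail contains no signal", call. = FALSE)
  # log-linear start on above-background bins
  pos <- y > 0
  sl <- stats::lm(log(y[pos]) ~ t[pos])
  tau0 <- max(-1 / unname(stats::coef(sl)[2]), 0.1)
  A0 <- exp(unname(stats::coef(sl)[1]))
  b0 <- max(min(y), 1e-3)
  resid_fn <- function(p) exp(p[1]) * exp(-t / exp(p[2])) + exp(p[3]) - y
  fit <- minpack.lm::nls.lm(par = log(c(A0, tau0, b0)), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  structure(list(tau_fl = exp(fit$par[2]), amplitude = exp(fit$par[1]),
                 background = exp(fit$par[3]), rss = sum(fit$fvec^2),
                 tail_start_ns = peak_t + tail_start,
                 converged = fit$info %in% 1:4),
            class = "lifetime_fit")
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat("Lifetime fit: tau =", signif(x$tau_fl, 4), "ns (tail from",
      signif(x$tail_start_ns, 3), "ns; background",
      signif(x$background, 3), ")\n")
  invisible(x)
}
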