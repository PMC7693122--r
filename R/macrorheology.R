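#' Oscillatory frequency sweep
#'
#' Container for storage/loss moduli versus oscillation frequency, the raw
#' output of a plate-plate frequency sweep in the linear viscoelastic
#' region.
#'
#' @param f Oscillation frequency in Hz, strictly increasing, positive.
#' @param G_storage Storage modulus G' in Pa (non-negative).
#' @param G_loss Loss modulus G'' in Pa (non-negative).
#' @param sample_id Optional sample label.
#' @param temperature Temperature in K.
#' @return A data frame of class `frequency_sweep`.
#' @export
frequency_sweep <- function(f, G_storage, G_loss, sample_id = NA_character_,
                            temperature = 298.15) {
  stopifnot_positive(f, "f")
  if (is.unsorted(f, strictly = TRUE))
    stop("`f` must be strictly increasing", call. = FALSE)
  stopifnot(length(f) == length(G_storage), length(f) == length(G_loss))
  if (any(G_storage < 0) || any(G_loss < 0))
    stop("moduli must be non-negative", call. = FALSE)
  structure(data.frame(f = f, G_storage = G_storage, G_loss = G_loss),
            sample_id = sample_id, temperature = temperature,
            class = c("frequency_sweep", "data.frame"))
}

#' Derive complex modulus, phase angle and complex viscosity
#'
#' From the measured moduli, computes \eqn{|G^*| = \sqrt{G'^2 + G''^2}},
#' \eqn{\delta = \arctan(G''/G')} (degrees; 0 = ideal solid, 90 = ideal
#' liquid, 45 = gel point) and the complex viscosity
#' \eqn{|\eta^*| = |G^*| / (2\pi f)}. Points where both moduli vanish have
#' an undefined phase and are flagged (`NA` phase).
#'
#' @param sweep A [frequency_sweep()].
#' @return A data frame of class `viscoelastic_spectrum` with columns `f`,
#'   `G_complex`, `phase_angle`, `complex_viscosity`.
#' @examples
#' sw <- frequency_sweep(c(0.1, 1), c(3, 3), c(4, 4))
#' derived_spectrum(sw)
#' @export
derived_spectrum <- function(sweep) {
  gp <- sweep$G_storage; gl <- sweep$G_loss
  both_zero <- gp == 0 & gl == 0
  if (any(both_zero))
    warning(sum(both_zero), " point(s) with G' = G'' = 0: phase undefined")
  gc <- sqrt(gp^2 + gl^2)
  delta <- atan2(gl, gp) * 180 / pi
  delta[both_zero] <- NA_real_
  structure(data.frame(f = sweep$f, G_complex = gc, phase_angle = delta,
                       complex_viscosity = gc / (2 * pi * sweep$f)),
            class = c("viscoelastic_spectrum", "data.frame"))
}

#' Invert a viscoelastic spectrum back to storage/loss moduli
#'
#' Exact inverse of [derived_spectrum()]:
#' \eqn{G' = |G^*|\cos\delta}, \eqn{G'' = |G^*|\sin\delta}.
#'
#' @param spectrum A `viscoelastic_spectrum`.
#' @return A [frequency_sweep()].
#' @export
spectrum_to_sweep <- function(spectrum) {
  rad <- spectrum$phase_angle * pi / 180
  frequency_sweep(spectrum$f,
                  spectrum$G_complex * cos(rad),
                  spectrum$G_complex * sin(rad))
}

# generalized Maxwell model curves
maxwell_storage <- function(f, Gi, lambdai) {
  w <- outer(2 * pi * f, lambdai)       # (2 pi f) lambda_i
  as.vector((w^2 / (1 + w^2)) %*% Gi)
}

maxwell_loss <- function(f, Gi, lambdai) {
  w <- outer(2 * pi * f, lambdai)
  as.vector((w / (1 + w^2)) %*% Gi)
}

# joint relative residuals on both moduli for log-parameters p
maxwell_residuals <- function(logp, f, gp, gl) {
  n <- length(logp) / 2
  Gi <- exp(logp[seq_len(n)])
  li <- exp(logp[n + seq_len(n)])
  c((maxwell_storage(f, Gi, li) - gp) / gp,
    (maxwell_loss(f, Gi, li) - gl) / gl)
}

#' Fit a generalized Maxwell model to a frequency sweep
#'
#' Jointly fits
#' \eqn{G'(f) = \sum_i G_i (2\pi f\lambda_i)^2/(1+(2\pi f\lambda_i)^2)} and
#' \eqn{G''(f) = \sum_i G_i (2\pi f\lambda_i)/(1+(2\pi f\lambda_i)^2)} by
#' least squares on the relative residuals of both moduli (relative
#' weighting handles the decade-spanning magnitudes). Positivity of all
#' parameters is enforced by optimizing in log space; relaxation times are
#' initialized log-spaced across the observable window
#' \eqn{[1/2\pi f_{max}, 1/2\pi f_{min}]} and up to `restarts` jittered
#' multi-starts are tried before declaring failure.
#'
#' @param sweep A [frequency_sweep()] with positive moduli.
#' @param n Number of Maxwell elements (>= 1); the sweep must contain at
#'   least `2n + 1` frequency points.
#' @param restarts Number of jittered restarts.
#' @return An object of class `maxwell_model` with elements `n`, `Gi`,
#'   `lambdai` (sorted by relaxation time), `G_total = sum(Gi)`, `rss`
#'   (residual sum of squares of relative residuals), `dof`, `converged`.
#' @examples
#' sw <- gen_frequency_sweep(1000, 0.1, generator_spec(1, noise_none()))
#' fit_maxwell(sw, n = 1)
#' @export
fit_maxwell <- function(sweep, n, restarts = 5) {
  stopifnot(n >= 1)
  m <- nrow(sweep)
  if (m < 2 * n + 1)
    stop("need at least 2n + 1 frequency points", call. = FALSE)
  f <- sweep$f; gp <- sweep$G_storage; gl <- sweep$G_loss
  if (any(gp <= 0) || any(gl <= 0))
    stop("relative-residual fitting requires strictly positive moduli",
         call. = FALSE)
  lam_hi <- 1 / (2 * pi * min(f)); lam_lo <- 1 / (2 * pi * max(f))
  lam0 <- if (n == 1) sqrt(lam_lo * lam_hi) else
    exp(seq(log(lam_lo), log(lam_hi), length.out = n))
  G0 <- rep(max(gp) / n, n)
  best <- NULL
  for (r in seq_len(restarts)) {
    start <- c(log(G0), log(lam0))
    # deterministic jitter keeps the fit a pure function of its inputs
    if (r > 1) start <- start +
      with_seed(1000L + r, stats::rnorm(length(start), 0, 0.3 * (r - 1)))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = maxwell_residuals,
                         f = f, gp = gp, gl = gl,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    if (best$rss < 1e-16) break
  }
  if (is.null(best))
    stop("Maxwell fit failed to converge after ", restarts, " restarts",
         call. = FALSE)
  p <- best$fit$par
  Gi <- exp(p[seq_len(n)]); li <- exp(p[n + seq_len(n)])
  ord <- order(li)
  structure(list(n = n, Gi = Gi[ord], lambdai = li[ord],
                 G_total = sum(Gi), rss = best$rss,
                 dof = 2 * m - 2 * n,
                 converged = best$fit$info %in% 1:4),
            class = "maxwell_model")
}

#' @export
print.maxwell_model <- function(x, ...) {
  cat("Generalized Maxwell model (", x$n, " element",
      if (x$n > 1) "s", ")\n", sep = "")
  print(data.frame(i = seq_len(x$n), G_Pa = signif(x$Gi, 5),
                   lambda_s = signif(x$lambdai, 5)), row.names = FALSE)
  cat("G_total =", signif(x$G_total, 6), "Pa; RSS =", signif(x$rss, 4),
      "on", x$dof, "dof\n")
  invisible(x)
}

#' Predict moduli from a fitted Maxwell model
#' @param object A `maxwell_model`.
#' @param f Frequencies in Hz.
#' @param ... Unused.
#' @return Data frame with `f`, `G_storage`, `G_loss`.
#' @export
predict.maxwell_model <- function(object, f, ...) {
  data.frame(f = f,
             G_storage = maxwell_storage(f, object$Gi, object$lambdai),
             G_loss = maxwell_loss(f, object$Gi, object$lambdai))
}

#' Choose the number of Maxwell elements by nested F-tests
#'
#' Starting from one element, the model with `n + 1` elements is accepted
#' only if the reduction in residual sum of squares passes an F-test at
#' `alpha`; the smallest adequate `n` is returned (a standard
#' nested-model selection for mechanical spectra).
#'
#' @param sweep A [frequency_sweep()].
#' @param n_max Largest element count to consider; must satisfy
#'   `n_max <= (points - 1) / 2`.
#' @param alpha Significance level of the incremental F-test.
#' @return The selected integer `n` in `[1, n_max]`.
#' @export
select_n <- function(sweep, n_max, alpha = 0.05) {
  stopifnot(n_max >= 1)
  if (n_max > (nrow(sweep) - 1) / 2)
    stop("`n_max` exceeds (points - 1)/2", call. = FALSE)
  fit_cur <- fit_maxwell(sweep, 1)
  n <- 1
  while (n < n_max) {
    fit_next <- fit_maxwell(sweep, n + 1)
    d1 <- fit_cur$dof - fit_next$dof
    Fstat <- ((fit_cur$rss - fit_next$rss) / d1) /
      (fit_next$rss / fit_next$dof)
    if (!is.finite(Fstat) || Fstat <= 0) break
    p <- stats::pf(Fstat, d1, fit_next$dof, lower.tail = FALSE)
    if (p >= alpha) break
    fit_cur <- fit_next
    n <- n + 1
  }
  n
}

#' Crosslink density and rubber-elasticity mesh size
#'
#' Under rubber-elasticity theory the shear modulus (sum of Maxwell spring
#' constants) maps to a crosslink density \eqn{\rho_x = G/(RT)} and an
#' average network mesh size \eqn{\xi = (6/(\pi \rho_x N_A))^{1/3}}.
#'
#' @param model A `maxwell_model`, or a single shear modulus in Pa.
#' @param temperature Temperature in K.
#' @return An object of class `network_estimate` with `rho_x`
#'   (mol m^-3), `xi` (m) and `temperature`.
#' @examples
#' network_estimate(1000, 298.15)  # rho_x ~ 0.4034 mol/m^3, xi ~ 19.9 nm
#' @export
network_estimate <- function(model, temperature = 298.15) {
  G <- if (inherits(model, "maxwell_model")) model$G_total else model
  stopifnot_positive(G, "G_total")
  stopifnot_positive(temperature, "temperature")
  const <- physical_constants()
  rho_x <- G / (const$R * temperature)
  xi <- (6 / (pi * rho_x * const$N_A))^(1 / 3)
  structure(list(rho_x = rho_x, xi = xi, temperature = temperature),
            class = "network_estimate")
}

#' @export
print.network_estimate <- function(x, ...) {
  cat("Network estimate at T =", x$temperature, "K\n")
  cat("  crosslink density rho_x =", signif(x$rho_x, 5), "mol m^-3\n")
  cat("  mesh size xi =", signif(x$xi * 1e9, 4), "nm\n")
  invisible(x)
}
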