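#' Solute concentration profile in a gel
#'
#' Concentration of the diffusing solute versus depth below the
#' solution/gel interface after a diffusion time `t_h`.
#'
#' @param x_mm Distance from the interface in mm, ascending, >= 0.
#' @param c Concentration in g m^-3 (negative values may occur in noisy
#'   read-outs and are retained for unbiased fitting).
#' @param t_h Diffusion time in hours (> 0).
#' @param composition Optional composition label (grouping key).
#' @param replicate Optional replicate id.
#' @return A data frame of class `concentration_profile`.
#' @export
concentration_profile <- function(x_mm, c, t_h, composition = NA_character_,
                                  replicate = NA_integer_) {
  stopifnot(is.numeric(x_mm), is.numeric(c), length(x_mm) == length(c))
  if (any(x_mm < 0)) stop("`x_mm` must be non-negative", call. = FALSE)
  if (is.unsorted(x_mm)) stop("`x_mm` must be ascending", call. = FALSE)
  stopifnot_positive(t_h, "t_h")
  structure(data.frame(x_mm = x_mm, c = c),
            t_h = t_h, composition = composition, replicate = replicate,
            class = c("concentration_profile", "data.frame"))
}

#' Absorbance-to-concentration calibration from reference gels
#'
#' Builds a linear calibration from reference gels containing known,
#' homogeneously dispersed solute. Each reference spectrum is first
#' baseline-corrected: a straight line fitted over the scattering-dominated
#' 650--800 nm window (where the solute does not absorb) is subtracted, a
#' standard turbid-sample correction that removes the light-scattering
#' background; the peak absorbance within `peak_range` is then regressed on
#' concentration.
#'
#' @param spectra A list of data frames with columns `wavelength` (nm) and
#'   `absorbance`, one per reference gel.
#' @param concentrations Known concentrations in g m^-3 (>= 3 levels).
#' @param peak_range Wavelength window (nm) containing the absorption peak.
#' @param baseline_range Scattering window (nm) used for the linear
#'   baseline.
#' @return An object of class `calibration_curve` with `slope` (absorbance
#'   per g m^-3), `intercept`, `r_squared` and `predict_conc(absorbance)`.
#' @export
calibrate <- function(spectra, concentrations,
                      peak_range = c(480, 560),
                      baseline_range = c(650, 800)) {
  if (length(spectra) < 3 || length(concentrations) < 3)
    stop("need at least 3 reference levels", call. = FALSE)
  stopifnot(length(spectra) == length(concentrations))
  peak_abs <- vapply(spectra, function(sp) {
    base_idx <- sp$wavelength >= baseline_range[1] &
      sp$wavelength <= baseline_range[2]
    if (sum(base_idx) >= 2) {
      bl <- stats::lm(absorbance ~ wavelength, data = sp[base_idx, ])
      corrected <- sp$absorbance -
        stats::predict(bl, newdata = sp["wavelength"])
    } else corrected <- sp$absorbance
    in_peak <- sp$wavelength >= peak_range[1] & sp$wavelength <= peak_range[2]
    max(corrected[in_peak])
  }, numeric(1))
  if (any(diff(peak_abs[order(concentrations)]) <= 0))
    stop("calibration is not monotone in concentration", call. = FALSE)
  fit <- stats::lm(peak_abs ~ concentrations)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope <= 0) stop("calibration slope must be positive", call. = FALSE)
  ss_tot <- sum((peak_abs - mean(peak_abs))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r2,
                 reference = data.frame(concentration = concentrations,
                                        absorbance = peak_abs),
                 predict_conc = function(absorbance)
                   (absorbance - intercept) / slope),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Calibration: A =", signif(x$slope, 5), "* c +",
      signif(x$intercept, 5), " (R^2 =", signif(x$r_squared, 5), ")\n")
  invisible(x)
}

#' Fit the semi-infinite diffusion solution to a concentration profile
#'
#' Least-squares fit of
#' \eqn{c(x) = c_0\,\mathrm{erfc}\!\left(x / \sqrt{4 D_{eff} t}\right)}
#' for the effective diffusion coefficient \eqn{D_{eff}} and the boundary
#' concentration \eqn{c_0}; the partition coefficient
#' \eqn{\varepsilon = c_0 / c_{sol}} is attached. The fit is joint and
#' unweighted; positivity is enforced by optimizing log-parameters. A
#' warning is issued when the penetration depth \eqn{\sqrt{4 D_{eff} t}}
#' exceeds 80\% of the scanned depth, where the semi-infinite assumption
#' degrades.
#'
#' @param profile A [concentration_profile()] with at least 8 positions.
#' @param csol Source-solution concentration in g m^-3 (default 10, i.e.
#'   a 0.01 g/dm^3 dye bath).
#' @return An object of class `diffusion_fit` with `Deff` (um^2 s^-1),
#'   `c0` (g m^-3), `epsilon`, `csol`, `rss`, `t_h`, `composition`.
#' @examples
#' pr <- gen_concentration_profiles(389, 53, 24, generator_spec(1, noise_none()))[[1]]
#' fit_profile(pr)
#' @export
fit_profile <- function(profile, csol = 10) {
  if (nrow(profile) < 8) stop("need at least 8 positions", call. = FALSE)
  if (all(profile$c == 0)) stop("all-zero profile", call. = FALSE)
  stopifnot_positive(csol, "csol")
  t_s <- attr(profile, "t_h") * 3600
  x_m <- profile$x_mm * 1e-3
  cobs <- profile$c
  # starting values: c0 from the first point, Deff from the depth where
  # c drops to erfc(1) ~ 0.157 of c0
  c0_0 <- max(cobs[1], max(cobs) * 0.5, 1e-12)
  xhalf <- x_m[which.min(abs(cobs - 0.157 * c0_0))]
  D0 <- max(xhalf^2 / (4 * t_s), 1e-14)
  resid_fn <- function(logp) {
    c0 <- exp(logp[1]); D <- exp(logp[2])
    c0 * erfc(x_m / sqrt(4 * D * t_s)) - cobs
  }
  fit <- minpack.lm::nls.lm(par = c(log(c0_0), log(D0)), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  c0 <- exp(fit$par[1]); Deff_m2 <- exp(fit$par[2])
  depth <- sqrt(4 * Deff_m2 * t_s)
  if (depth > 0.8 * max(x_m))
    warning("penetration depth ", signif(depth * 1e3, 3),
            " mm exceeds 80% of the scanned depth: ",
            "semi-infinite assumption may be violated")
  structure(list(Deff = Deff_m2 * 1e12, c0 = c0,
                 epsilon = partition(c0, csol), csol = csol,
                 rss = sum(fit$fvec^2), t_h = attr(profile, "t_h"),
                 composition = attr(profile, "composition"),
                 converged = fit$info %in% 1:4),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat("Diffusion fit (t =", x$t_h, "h)\n")
  cat("  Deff =", signif(x$Deff, 5), "um^2 s^-1\n")
  cat("  c0 =", signif(x$c0, 5), "g m^-3;  epsilon = c0/csol =",
      signif(x$epsilon, 4), "\n")
  invisible(x)
}

#' Partition coefficient
#'
#' Ratio of the solute concentration in the gel at the interface to the
#' source-solution concentration, \eqn{\varepsilon = c_0 / c_{sol}}.
#'
#' @param c0 Interface concentration in the gel, g m^-3.
#' @param csol Source-solution concentration, g m^-3 (> 0).
#' @return The dimensionless partition coefficient.
#' @examples
#' partition(53, 10)   # 5.3
#' @export
partition <- function(c0, csol) {
  stopifnot_positive(csol, "csol")
  c0 / csol
}

#' Aggregate replicate diffusion fits
#'
#' Mean and sample standard deviation of `Deff`, `c0` and `epsilon` per
#' composition, pooling diffusion times and replicates as in a
#' three-time/duplicate experimental design.
#'
#' @param fits A list of `diffusion_fit` objects (>= 2).
#' @param by Grouping key: `"composition"` (requires consistent labels) or
#'   `"none"` to pool everything.
#' @return A data frame with one row per group: n, mean and sd of each
#'   parameter.
#' @export
aggregate_fits <- function(fits, by = c("composition", "none")) {
  by <- match.arg(by)
  if (length(fits) < 2) stop("need at least 2 fits to aggregate", call. = FALSE)
  df <- do.call(rbind, lapply(fits, function(f)
    data.frame(composition = if (is.null(f$composition)) NA else f$composition,
               Deff = f$Deff, c0 = f$c0, epsilon = f$epsilon)))
  if (by == "composition") {
    if (anyNA(df$composition) && length(unique(df$composition)) > 1)
      stop("mixed compositions without a grouping key", call. = FALSE)
    df$composition[is.na(df$composition)] <- "all"
    groups <- split(df, df$composition, drop = TRUE)
  } else groups <- list(all = df)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    d <- groups[[g]]
    data.frame(composition = g, n = nrow(d),
               Deff_mean = mean(d$Deff), Deff_sd = stats::sd(d$Deff),
               c0_mean = mean(d$c0), c0_sd = stats::sd(d$c0),
               epsilon_mean = mean(d$epsilon), epsilon_sd = stats::sd(d$epsilon))
  }))
  rownames(out) <- NULL
  out
}
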