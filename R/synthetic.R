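#' Specify a seeded synthetic-data generation run
#'
#' A `generator_spec` bundles the random seed, the noise model and an
#' optional abscissa grid shared by all synthetic generators. With a fixed
#' seed every generator is a pure function of its arguments: the same spec
#' produces bit-identical output, and `noise_none()` reproduces the
#' closed-form model exactly.
#'
#' @param seed Integer random seed.
#' @param noise A noise model from [noise_none()], [noise_additive()],
#'   [noise_multiplicative()] or [noise_poisson()]. `NULL` lets each
#'   generator fall back to its modality-typical default.
#' @param grid Optional numeric abscissa grid (units depend on modality);
#'   `NULL` uses the generator's default grid.
#' @return An object of class `generator_spec`.
#' @examples
#' generator_spec(1, noise_none())
#' @export
generator_spec <- function(seed, noise = NULL, grid = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (!is.null(grid)) stopifnot(is.numeric(grid), !is.unsorted(grid))
  structure(list(seed = as.integer(seed), noise = noise, grid = grid),
            class = "generator_spec")
}

#' Noise models for the synthetic generators
#'
#' @param sd Standard deviation of the perturbation. For
#'   `noise_additive()` it is in the units of the signal unless
#'   `relative = TRUE`, in which case it is a fraction of a reference scale
#'   chosen by the generator (e.g. the boundary concentration for diffusion
#'   profiles). For `noise_multiplicative()` it is always relative.
#' @param relative Interpret `sd` as a fraction of the generator's
#'   reference scale.
#' @return A list describing the noise model.
#' @name noise_models
NULL

#' @rdname noise_models
#' @export
noise_none <- function() list(type = "none")

#' @rdname noise_models
#' @export
noise_additive <- function(sd, relative = FALSE) {
  stopifnot_positive(sd, "sd")
  list(type = "additive", sd = sd, relative = isTRUE(relative))
}

#' @rdname noise_models
#' @export
noise_multiplicative <- function(sd) {
  stopifnot_positive(sd, "sd")
  list(type = "multiplicative", sd = sd)
}

#' @rdname noise_models
#' @export
noise_poisson <- function() list(type = "poisson")

# evaluate expr under a private RNG stream, restoring global state after
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# perturb a clean signal according to a noise model; `scale` is the
# reference magnitude used by relative additive noise
apply_noise <- function(y, noise, scale = NULL) {
  if (is.null(noise) || noise$type == "none") return(y)
  switch(noise$type,
    additive = {
      sd <- if (noise$relative) {
        if (is.null(scale)) stop("relative additive noise needs a scale")
        noise$sd * scale
      } else noise$sd
      y + stats::rnorm(length(y), 0, sd)
    },
    multiplicative = y * (1 + stats::rnorm(length(y), 0, noise$sd)),
    poisson = stats::rpois(length(y), pmax(y, 0)),
    stop("unknown noise model: ", noise$type)
  )
}

ground_truth <- function(modality, params) {
  structure(list(modality = modality, params = params),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth (", x$modality, ")\n", sep = "")
  for (nm in names(x$params)) {
    v <- x$params[[nm]]
    if (is.numeric(v) && length(v) <= 6)
      cat("  ", nm, ": ", paste(signif(v, 6), collapse = ", "), "\n", sep = "")
    else cat("  ", nm, ": <", class(v)[1], ">\n", sep = "")
  }
  invisible(x)
}

#' Extract the ground truth attached to a synthetic object
#' @param x A synthetic object produced by one of the `gen_*` generators.
#' @return A `ground_truth` object, or `NULL` for real data.
#' @export
truth <- function(x) attr(x, "ground_truth")

# default oscillation grid: 0.01-20 Hz, 6 points per decade, decimal log
default_frequency_grid <- function() {
  10^seq(log10(0.01), log10(20), by = 1 / 6)
}

#' Generate a synthetic oscillatory frequency sweep
#'
#' Evaluates the generalized Maxwell storage and loss moduli
#' \eqn{G'(f) = \sum_i G_i (2\pi f \lambda_i)^2 / (1 + (2\pi f \lambda_i)^2)}
#' and
#' \eqn{G''(f) = \sum_i G_i (2\pi f \lambda_i) / (1 + (2\pi f \lambda_i)^2)}
#' on a frequency grid and perturbs both moduli with the spec's noise model
#' (default: 5\% multiplicative, typical of duplicate-run reproducibility of
#' rotational rheometers).
#'
#' @param Gi Spring constants of the Maxwell elements (Pa), all positive.
#' @param lambdai Relaxation times (s), same length as `Gi`, all positive.
#' @param spec A [generator_spec()]. Its `grid` is the frequency grid in Hz
#'   (default 0.01--20 Hz, 6 points per decade).
#' @param temperature Sample temperature in K (metadata).
#' @return A [frequency_sweep()] with a `ground_truth` attribute carrying
#'   `Gi`, `lambdai` and `G_total`.
#' @examples
#' sw <- gen_frequency_sweep(1000, 0.1, generator_spec(1, noise_none()))
#' head(sw)
#' @export
gen_frequency_sweep <- function(Gi, lambdai, spec,
                                temperature = 298.15) {
  stopifnot_positive(Gi, "Gi")
  stopifnot_positive(lambdai, "lambdai")
  stopifnot(length(Gi) == length(lambdai))
  f <- if (is.null(spec$grid)) default_frequency_grid() else spec$grid
  stopifnot_positive(f, "frequencies")
  noise <- if (is.null(spec$noise)) noise_multiplicative(0.05) else spec$noise
  gp <- maxwell_storage(f, Gi, lambdai)
  gl <- maxwell_loss(f, Gi, lambdai)
  out <- with_seed(spec$seed, {
    data.frame(f = f,
               G_storage = apply_noise(gp, noise, scale = max(gp)),
               G_loss    = apply_noise(gl, noise, scale = max(gl)))
  })
  sw <- frequency_sweep(out$f, out$G_storage, out$G_loss,
                        temperature = temperature)
  attr(sw, "ground_truth") <- ground_truth("frequency_sweep",
    list(Gi = Gi, lambdai = lambdai, G_total = sum(Gi)))
  sw
}

#' Generate synthetic solute concentration profiles
#'
#' Evaluates the semi-infinite diffusion solution
#' \eqn{c(x,t) = c_0\,\mathrm{erfc}(x/\sqrt{4 D_{eff} t})} at one or more
#' diffusion times and adds noise (default: additive Gaussian with standard
#' deviation 2\% of \eqn{c_0}, emulating photometric read-out noise).
#'
#' @param Deff Effective diffusion coefficient in um^2 s^-1.
#' @param c0 Boundary (interface) concentration in g m^-3.
#' @param times_h Diffusion times in hours (default the 24/48/72 h sampling
#'   of a three-day cuvette experiment).
#' @param spec A [generator_spec()]; its `grid` is the depth grid in mm
#'   (default 0--10 mm in 0.25 mm steps, a vertically scanned cuvette).
#' @return A list of [concentration_profile()] objects, one per time, each
#'   carrying ground truth (`Deff`, `c0`).
#' @examples
#' pr <- gen_concentration_profiles(389, 53, spec = generator_spec(1, noise_none()))
#' pr[[1]][1:3, ]
#' @export
gen_concentration_profiles <- function(Deff, c0, times_h = c(24, 48, 72),
                                       spec = generator_spec(1)) {
  stopifnot_positive(Deff, "Deff")
  stopifnot_positive(c0, "c0")
  stopifnot_positive(times_h, "times_h")
  x_mm <- if (is.null(spec$grid)) seq(0, 10, by = 0.25) else spec$grid
  if (any(x_mm < 0)) stop("depth grid must be non-negative", call. = FALSE)
  noise <- if (is.null(spec$noise)) noise_additive(0.02, relative = TRUE) else spec$noise
  Deff_m2 <- Deff * 1e-12          # um^2/s -> m^2/s
  x_m <- x_mm * 1e-3
  with_seed(spec$seed, lapply(times_h, function(th) {
    t_s <- th * 3600
    c_clean <- c0 * erfc(x_m / sqrt(4 * Deff_m2 * t_s))
    c_obs <- apply_noise(c_clean, noise, scale = c0)
    pr <- concentration_profile(x_mm = x_mm, c = c_obs, t_h = th)
    attr(pr, "ground_truth") <- ground_truth("concentration_profile",
      list(Deff = Deff, c0 = c0))
    pr
  }))
}

#' Generate a synthetic tracer mean-square-displacement trace
#'
#' Three idealized media are available: a Newtonian fluid
#' (`"viscous"`, \eqn{\langle\Delta r^2\rangle = 6 D t} with
#' \eqn{D = k_B T / 6\pi\eta a}), an elastic cage (`"plateau"`, constant
#' \eqn{\Delta^2}) and a power-law material (`"power_law"`,
#' \eqn{A t^\alpha} with \eqn{0 \le \alpha \le 1}).
#'
#' @param model One of `"viscous"`, `"plateau"`, `"power_law"`.
#' @param spec A [generator_spec()]; `grid` is the lag-time grid in s
#'   (default 30 points per decade over 1e-5--10 s).
#' @param eta Viscosity in Pa s (viscous model).
#' @param delta2 Plateau MSD in m^2 (plateau model).
#' @param A,alpha Power-law prefactor (m^2 s^-alpha) and exponent.
#' @param tracer_radius Tracer radius in m (default 50 nm, i.e. 100 nm
#'   nominal particle diameter).
#' @param temperature Temperature in K.
#' @return An [msd_trace()] carrying ground truth.
#' @examples
#' tr <- gen_msd_trace("viscous", generator_spec(1, noise_none()), eta = 8.9e-4)
#' @export
gen_msd_trace <- function(model = c("viscous", "plateau", "power_law"),
                          spec = generator_spec(1),
                          eta = NULL, delta2 = NULL, A = NULL, alpha = NULL,
                          tracer_radius = 50e-9, temperature = 298.15) {
  model <- match.arg(model)
  stopifnot_positive(tracer_radius, "tracer_radius")
  stopifnot_positive(temperature, "temperature")
  lag <- if (is.null(spec$grid)) 10^seq(-5, 1, by = 1 / 30) else spec$grid
  stopifnot_positive(lag, "lag")
  noise <- if (is.null(spec$noise)) noise_multiplicative(0.02) else spec$noise
  k_B <- physical_constants()$k_B
  msd <- switch(model,
    viscous = {
      stopifnot_positive(eta, "eta")
      D <- k_B * temperature / (6 * pi * eta * tracer_radius)  # m^2/s
      6 * D * lag
    },
    plateau = {
      stopifnot_positive(delta2, "delta2")
      rep(delta2, length(lag))
    },
    power_law = {
      stopifnot_positive(A, "A")
      if (is.null(alpha) || alpha < 0 || alpha > 1)
        stop("`alpha` must lie in [0, 1]", call. = FALSE)
      A * lag^alpha
    })
  obs <- with_seed(spec$seed, apply_noise(msd, noise, scale = max(msd)))
  tr <- msd_trace(lag, obs, tracer_radius = tracer_radius,
                  temperature = temperature)
  gt <- switch(model,
    viscous = list(eta = eta,
                   D = k_B * temperature / (6 * pi * eta * tracer_radius)),
    plateau = list(delta2 = delta2),
    power_law = list(A = A, alpha = alpha))
  attr(tr, "ground_truth") <- ground_truth(paste0("msd_", model), gt)
  tr
}

#' Generate a synthetic FCS autocorrelation curve
#'
#' Single-component free 3-D diffusion through a Gaussian confocal volume:
#' \eqn{G(\tau) = N^{-1} (1+\tau/\tau_D)^{-1} (1+\tau/(\kappa^2\tau_D))^{-1/2}}.
#'
#' @param N Mean number of molecules in the focal volume.
#' @param tauD Diffusion time in s.
#' @param kappa Axial-to-lateral ratio of the focal volume (> 1).
#' @param spec A [generator_spec()]; `grid` is the lag grid in s (default
#'   24 points per decade over 1e-7--1 s). Default noise: 1\% multiplicative.
#' @param w0 Lateral beam waist in m (calibration metadata).
#' @return An [fcs_curve()] carrying ground truth (`N`, `tauD`).
#' @examples
#' g <- gen_fcs_acf(2, 65.6e-6, spec = generator_spec(1, noise_none()))
#' @export
gen_fcs_acf <- function(N, tauD, kappa = 5, spec = generator_spec(1),
                        w0 = 0.3e-6) {
  stopifnot_positive(N, "N")
  stopifnot_positive(tauD, "tauD")
  if (kappa <= 1) stop("`kappa` must exceed 1", call. = FALSE)
  tau <- if (is.null(spec$grid)) 10^seq(-7, 0, by = 1 / 24) else spec$grid
  stopifnot_positive(tau, "tau")
  noise <- if (is.null(spec$noise)) noise_multiplicative(0.01) else spec$noise
  g <- fcs_model(tau, N, tauD, kappa)
  obs <- with_seed(spec$seed, apply_noise(g, noise, scale = 1 / N))
  cv <- fcs_curve(tau, obs, w0 = w0, kappa = kappa)
  attr(cv, "ground_truth") <- ground_truth("fcs_acf", list(N = N, tauD = tauD))
  cv
}

#' Generate a synthetic TCSPC photon-count decay
#'
#' Mono-exponential fluorescence decay
#' \eqn{n(t) = A \exp(-t/\tau_{fl}) + b} histogrammed into time bins,
#' by default with Poisson counting noise.
#'
#' @param tau_fl Fluorescence lifetime in ns.
#' @param amplitude Peak expected counts.
#' @param background Constant background counts per bin.
#' @param spec A [generator_spec()]; `grid` is the bin-center grid in ns
#'   (default 0--50 ns in 1024 bins).
#' @return A [decay_histogram()] carrying ground truth.
#' @examples
#' d <- gen_tcspc_decay(4.21, 1e4, spec = generator_spec(1, noise_none()))
#' @export
gen_tcspc_decay <- function(tau_fl, amplitude, background = 0,
                            spec = generator_spec(1)) {
  stopifnot_positive(tau_fl, "tau_fl")
  stopifnot_positive(amplitude, "amplitude")
  if (background < 0) stop("`background` must be non-negative", call. = FALSE)
  t_ns <- if (is.null(spec$grid)) seq(0, 50, length.out = 1024) else spec$grid
  noise <- if (is.null(spec$noise)) noise_poisson() else spec$noise
  mu <- amplitude * exp(-t_ns / tau_fl) + background
  counts <- with_seed(spec$seed, apply_noise(mu, noise, scale = amplitude))
  d <- decay_histogram(t_ns, counts)
  attr(d, "ground_truth") <- ground_truth("tcspc_decay",
    list(tau_fl = tau_fl, amplitude = amplitude, background = background))
  d
}

#' Generate a synthetic turbidity spectrum
#'
#' Power-law turbidity \eqn{\tau(\lambda) = c\,\lambda^{\beta}} with the
#' transmittance back-computed through
#' \eqn{\tau = \ln(10)\,\mathrm{OD}/L}, \eqn{\mathrm{OD} = -\log_{10} T},
#' so the synthetic spectrum exercises the same transmittance-to-turbidity
#' path as instrument data.
#'
#' @param prefactor Power-law prefactor (positive; turbidity in cm^-1 at
#'   lambda = 1 nm).
#' @param exponent Wavelength exponent beta (dimensionless, typically
#'   negative; -4 is the Rayleigh limit).
#' @param spec A [generator_spec()]; `grid` is the wavelength grid in nm
#'   (default 300--800 nm in 2 nm steps). Default noise: 1\% multiplicative.
#' @param path_cm Optical path length in cm (default 1 cm cuvette).
#' @return A [turbidity_spectrum()]; samples whose implied transmittance
#'   falls outside (0, 1] are flagged in the `flagged` column.
#' @examples
#' ts <- gen_turbidity_spectrum(1e10, -4, generator_spec(1, noise_none()))
#' @export
gen_turbidity_spectrum <- function(prefactor, exponent,
                                   spec = generator_spec(1), path_cm = 1) {
  stopifnot_positive(prefactor, "prefactor")
  stopifnot_positive(path_cm, "path_cm")
  wl <- if (is.null(spec$grid)) seq(300, 800, by = 2) else spec$grid
  stopifnot_positive(wl, "wavelength")
  noise <- if (is.null(spec$noise)) noise_multiplicative(0.01) else spec$noise
  tau <- prefactor * wl^exponent
  tau_obs <- with_seed(spec$seed, apply_noise(tau, noise, scale = max(tau)))
  od <- tau_obs * path_cm / log(10)
  transmittance <- 10^(-od)
  flagged <- !(transmittance > 0 & transmittance <= 1)
  ts <- turbidity_spectrum(wl, transmittance, path_cm = path_cm)
  ts$flagged <- flagged
  attr(ts, "ground_truth") <- ground_truth("turbidity_spectrum",
    list(prefactor = prefactor, exponent = exponent))
  ts
}

#' Generate a synthetic porous-structure image
#'
#' Three kinds are available. `"disks"` draws non-overlapping filled disks
#' (exact per-object ground truth: count, pixel areas); `"bars_and_crosses"`
#' draws axis-aligned bars and plus-crosses with known skeleton topology
#' (branch and junction counts); `"random_field"` thresholds a Gaussian
#' random field smoothed to a stated correlation length, for which the
#' ground truth is statistical (target porosity) because per-pore truth is
#' ill-defined for a connected random structure.
#'
#' @param kind One of `"disks"`, `"bars_and_crosses"`, `"random_field"`.
#' @param spec A [generator_spec()].
#' @param side Image side in px (square, >= 64).
#' @param pixel_size Physical pixel size in nm/px.
#' @param centers,radii Disk centers (2-column matrix, px) and radii (px).
#'   `NULL` places `n_disks` random non-overlapping disks.
#' @param n_disks Number of random disks when `centers` is `NULL`.
#' @param bars Data frame with columns `x0`, `y0`, `length`, `width`,
#'   `orientation` ("h"/"v") for the bar kind; `NULL` uses a default layout.
#' @param correlation_length Smoothing length of the random field in px.
#' @param porosity Target foreground (pore) fraction of the random field.
#' @param grayscale_noise SD of additive Gaussian gray noise (0 = binary).
#' @return A [pore_image()]; structured kinds carry exact expected
#'   statistics in their ground truth.
#' @examples
#' img <- gen_pore_image("disks", generator_spec(1), n_disks = 5)
#' @export
gen_pore_image <- function(kind = c("disks", "bars_and_crosses",
                                    "random_field"),
                           spec = generator_spec(1), side = 512,
                           pixel_size = 20,
                           centers = NULL, radii = NULL, n_disks = 10,
                           bars = NULL,
                           correlation_length = 8, porosity = 0.4,
                           grayscale_noise = 0) {
  kind <- match.arg(kind)
  if (side < 64) stop("image side must be at least 64 px", call. = FALSE)
  stopifnot_positive(pixel_size, "pixel_size")
  img <- matrix(0, side, side)
  gt <- NULL
  xg <- matrix(rep(seq_len(side), each = side), side, side)   # column index
  yg <- matrix(rep(seq_len(side), times = side), side, side)  # row index

  if (kind == "disks") {
    if (is.null(centers)) {
      placed <- with_seed(spec$seed, {
        cs <- matrix(numeric(0), 0, 2); rs <- numeric(0)
        tries <- 0
        while (nrow(cs) < n_disks && tries < 10000) {
          tries <- tries + 1
          r <- stats::runif(1, side / 40, side / 12)
          cx <- stats::runif(1, r + 2, side - r - 1)
          cy <- stats::runif(1, r + 2, side - r - 1)
          if (nrow(cs) == 0 ||
              all(sqrt((cs[, 1] - cx)^2 + (cs[, 2] - cy)^2) > rs + r + 2)) {
            cs <- rbind(cs, c(cx, cy)); rs <- c(rs, r)
          }
        }
        list(centers = cs, radii = rs)
      })
      centers <- placed$centers; radii <- placed$radii
    } else {
      centers <- as.matrix(centers)
      if (nrow(centers) > 1) {
        dd <- as.matrix(stats::dist(centers))
        rsum <- outer(radii, radii, "+")
        if (any(dd[upper.tri(dd)] < rsum[upper.tri(rsum)]))
          stop("overlapping disks are not allowed when ground truth is requested",
               call. = FALSE)
      }
    }
    areas <- integer(nrow(centers))
    for (i in seq_len(nrow(centers))) {
      mask <- (xg - centers[i, 1])^2 + (yg - centers[i, 2])^2 <= radii[i]^2
      areas[i] <- sum(mask)
      img[mask] <- 1
    }
    gt <- ground_truth("pore_image_disks",
      list(count = nrow(centers), radii = radii, areas_px2 = areas,
           analytic_areas_px2 = pi * radii^2))
  } else if (kind == "bars_and_crosses") {
    if (is.null(bars)) {
      bars <- data.frame(
        x0 = c(round(side * 0.1), round(side * 0.55)),
        y0 = c(round(side * 0.25), round(side * 0.6)),
        length = c(round(side * 0.4), round(side * 0.3)),
        width = c(5, 5),
        orientation = c("h", "v"),
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(bars))) {
      b <- bars[i, ]
      if (b$orientation == "h") {
        img[b$y0:(b$y0 + b$width - 1), b$x0:(b$x0 + b$length - 1)] <- 1
      } else {
        img[b$y0:(b$y0 + b$length - 1), b$x0:(b$x0 + b$width - 1)] <- 1
      }
    }
    gt <- ground_truth("pore_image_bars",
      list(n_bars = nrow(bars), bar_lengths = bars$length))
  } else { # random_field
    img <- with_seed(spec$seed, {
      field <- matrix(stats::rnorm(side * side), side, side)
      sm <- gaussian_smooth_fft(field, sigma = correlation_length)
      thr <- stats::quantile(sm, 1 - porosity)
      (sm > thr) * 1
    })
    gt <- ground_truth("pore_image_random_field",
      list(porosity = porosity, correlation_length = correlation_length))
  }

  if (grayscale_noise > 0) {
    img <- with_seed(spec$seed + 1L,
      pmin(pmax(img * 0.8 + 0.1 +
                  stats::rnorm(length(img), 0, grayscale_noise), 0), 1))
    dim(img) <- c(side, side)
  }
  pi_ <- pore_image(img, pixel_size = pixel_size)
  attr(pi_, "ground_truth") <- gt
  pi_
}

# periodic Gaussian smoothing via FFT (used by the random-field generator)
gaussian_smooth_fft <- function(m, sigma) {
  n <- nrow(m); stopifnot(ncol(m) == n)
  k <- c(0:(n %/% 2), -((n - (n %/% 2 + 1)):1)) / n   # cycles per pixel
  kernel_hat <- exp(-2 * pi^2 * sigma^2 * outer(k^2, k^2, "+"))
  Re(stats::fft(stats::fft(m) * kernel_hat, inverse = TRUE)) / n^2
}
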