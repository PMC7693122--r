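test_that("generators are pure functions of (parameters, seed)", {
  sp <- generator_spec(42)
  pairs <- list(
    list(gen_frequency_sweep(c(100, 500), c(0.01, 1), sp),
         gen_frequency_sweep(c(100, 500), c(0.01, 1), sp)),
    list(gen_concentration_profiles(389, 53, spec = sp),
         gen_concentration_profiles(389, 53, spec = sp)),
    list(gen_msd_trace("viscous", sp, eta = 1e-3),
         gen_msd_trace("viscous", sp, eta = 1e-3)),
    list(gen_fcs_acf(2, 65.6e-6, spec = sp),
         gen_fcs_acf(2, 65.6e-6, spec = sp)),
    list(gen_tcspc_decay(4.2, 1e4, spec = sp),
         gen_tcspc_decay(4.2, 1e4, spec = sp)),
    list(gen_turbidity_spectrum(1e8, -3, sp),
         gen_turbidity_spectrum(1e8, -3, sp)),
    list(gen_pore_image("random_field", sp, side = 64),
         gen_pore_image("random_field", sp, side = 64)))
  for (p in pairs) expect_identical(p[[1]], p[[2]])
})

test_that("generation does not disturb the global RNG stream", {
  set.seed(99)
  a <- runif(3)
  set.seed(99)
  invisible(gen_frequency_sweep(100, 0.1, generator_spec(1)))
  b <- runif(3)
  expect_identical(a, b)
})

test_that("noise-free sweeps follow the Maxwell closed form", {
  # crossover of a single element: at 2*pi*f*lambda = 1, G' = G'' = G1/2
  lam <- 0.5
  f_cross <- 1 / (2 * pi * lam)
  sw <- gen_frequency_sweep(800, lam,
    generator_spec(1, noise_none(), grid = f_cross))
  expect_equal(sw$G_storage, 400, tolerance = 1e-12)
  expect_equal(sw$G_loss, 400, tolerance = 1e-12)
  # high-frequency plateau of a 4-element model approaches sum(Gi)
  Gi <- c(100, 300, 800, 2000); li <- c(0.003, 0.03, 0.3, 3)
  f_hi <- 1e3 / (2 * pi * min(li))
  sw2 <- gen_frequency_sweep(Gi, li,
    generator_spec(1, noise_none(), grid = f_hi))
  expect_equal(sw2$G_storage, sum(Gi), tolerance = 1e-4)
})

test_that("noise-free profiles equal the erfc solution at landmark depths", {
  Deff <- 389; c0 <- 53; t_h <- 24
  x_star_mm <- sqrt(4 * Deff * 1e-12 * t_h * 3600) * 1e3
  pr <- gen_concentration_profiles(Deff, c0, t_h,
    generator_spec(1, noise_none(), grid = c(0, x_star_mm)))[[1]]
  expect_equal(pr$c[1], c0)                      # erfc(0) = 1
  expect_equal(pr$c[2], c0 * 0.157299207050285,  # tabulated erfc(1)
               tolerance = 1e-9)
})

test_that("MSD models obey their closed forms and limits", {
  spec <- generator_spec(1, noise_none())
  # Stokes-Einstein slope: eta = 8.9e-4 Pa s, a = 50 nm, T = 298.15 K
  tr <- gen_msd_trace("viscous", spec, eta = 8.9e-4)
  D <- truth(tr)$params$D
  expect_equal(D * 1e12, 4.91, tolerance = 2e-3)  # ~4.91 um^2/s
  expect_equal(tr$msd, 6 * D * tr$lag, tolerance = 1e-12)
  # plateau is constant
  tp <- gen_msd_trace("plateau", spec, delta2 = 1e-14)
  expect_true(all(tp$msd == 1e-14))
  # power law with alpha = 1 reduces to the viscous form with A = 6D
  tpl <- gen_msd_trace("power_law", spec, A = 6 * D, alpha = 1)
  expect_equal(tpl$msd, tr$msd, tolerance = 1e-12)
  expect_error(gen_msd_trace("power_law", spec, A = 1, alpha = 1.2),
               "alpha")
})

test_that("FCS and TCSPC generators obey their limiting forms", {
  spec0 <- function(grid) generator_spec(1, noise_none(), grid = grid)
  # G(tau -> 0) = 1/N
  cv <- gen_fcs_acf(2, 65.6e-6, spec = spec0(1e-12))
  expect_equal(cv$G, 0.5, tolerance = 1e-6)
  # at tau = tauD with kappa -> infinity only the lateral factor remains
  cv2 <- gen_fcs_acf(2, 65.6e-6, kappa = 1e8, spec = spec0(65.6e-6))
  expect_equal(cv2$G, 1 / (2 * 2), tolerance = 1e-6)
  expect_error(gen_fcs_acf(2, 65.6e-6, kappa = 0.9), "kappa")
  # background-free decay: log-counts linear with slope -1/tau_fl
  d <- gen_tcspc_decay(4.21, 1e4, background = 0,
                       spec = generator_spec(1, noise_none()))
  sl <- coef(lm(log(d$counts) ~ d$t_ns))[2]
  expect_equal(unname(sl), -1 / 4.21, tolerance = 1e-9)
})

test_that("turbidity generator: power-law slopes and round-trip", {
  ts <- gen_turbidity_spectrum(1e10, -4, generator_spec(1, noise_none()))
  fit <- wavelength_exponent(ts)
  expect_equal(fit$exponent, -4, tolerance = 1e-10)
  ts0 <- gen_turbidity_spectrum(0.5, 0, generator_spec(1, noise_none()))
  expect_equal(wavelength_exponent(ts0)$exponent, 0, tolerance = 1e-10)
  # turbidity -> transmittance -> turbidity is the identity
  tau_in <- 1e10 * ts$wavelength^-4
  expect_equal(ts$turbidity, tau_in, tolerance = 1e-12)
})

test_that("structured pore images carry exact ground truth", {
  # three disjoint axis-aligned squares (as radius-free disks via bars)
  img <- matrix(0, 128, 128)
  img[5:14, 5:14] <- 1; img[30:49, 30:49] <- 1; img[70:99, 70:99] <- 1
  st <- analyze_pores(pore_image(img))
  expect_equal(st$count, 3L)
  expect_setequal(st$table$area_px2, c(100, 400, 900))
  # disks refuse overlapping geometry when ground truth is requested
  expect_error(
    gen_pore_image("disks", generator_spec(1), side = 64,
                   centers = rbind(c(20, 20), c(25, 20)), radii = c(8, 8)),
    "overlap")
})

test_that("noise spread shrinks monotonically as sigma -> 0", {
  sds <- sapply(c(0.05, 0.01, 0), function(sg) {
    noise <- if (sg == 0) noise_none() else noise_additive(sg, relative = TRUE)
    d <- sapply(1:50, function(s) {
      pr <- gen_concentration_profiles(389, 53, 24,
        generator_spec(s, noise))[[1]]
      suppressWarnings(fit_profile(pr))$Deff
    })
    sd(d)
  })
  expect_true(sds[1] > sds[2])
  expect_true(sds[2] > sds[3])
  expect_equal(sds[3], 0, tolerance = 1e-9)
})
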