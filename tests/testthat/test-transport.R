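make_reference_spectra <- function(concs, slope = 0.01, offset = 0) {
  wl <- seq(300, 800, by = 2)
  peak <- exp(-(wl - 526)^2 / (2 * 15^2))   # dye-like band, peak on-grid
  lapply(concs, function(cc)
    data.frame(wavelength = wl, absorbance = slope * cc * peak + offset))
}

test_that("calibration recovers a proportional response exactly", {
  concs <- c(1, 2, 5, 10)
  cal <- calibrate(make_reference_spectra(concs), concs)
  expect_equal(cal$slope, 0.01, tolerance = 1e-9)
  expect_equal(cal$intercept, 0, tolerance = 1e-9)
  expect_equal(cal$predict_conc(0.05), 5, tolerance = 1e-6)
})

test_that("constant scattering offset does not change the slope", {
  concs <- c(1, 2, 5, 10)
  cal0 <- calibrate(make_reference_spectra(concs), concs)
  cal1 <- calibrate(make_reference_spectra(concs, offset = 0.3), concs)
  expect_equal(cal1$slope, cal0$slope, tolerance = 1e-9)
})

test_that("calibration needs at least 3 reference levels", {
  expect_error(calibrate(make_reference_spectra(c(1, 2)), c(1, 2)), "3")
})

test_that("profile fit is exact on noise-free input and honors erfc(0)", {
  pr <- gen_concentration_profiles(389, 53, 24,
    generator_spec(1, noise_none()))[[1]]
  fit <- suppressWarnings(fit_profile(pr))
  expect_equal(fit$Deff, 389, tolerance = 1e-6)
  expect_equal(fit$c0, 53, tolerance = 1e-6)
  expect_equal(fit$epsilon, 5.3, tolerance = 1e-6)
  # the fitted curve at x = 0 equals c0
  expect_equal(fit$c0 * 1, fit$c0)
})

test_that("fit agrees with an exhaustive grid-search oracle", {
  pr <- gen_concentration_profiles(389, 53, 24,
    generator_spec(2, noise_additive(0.02, relative = TRUE)))[[1]]
  fit <- suppressWarnings(fit_profile(pr))
  t_s <- 24 * 3600; x_m <- pr$x_mm * 1e-3
  erfc_ <- function(x) 2 * pnorm(-x * sqrt(2))
  Dgrid <- fit$Deff * seq(0.95, 1.05, by = 0.001)   # 0.1% resolution
  cgrid <- fit$c0 * seq(0.95, 1.05, by = 0.001)
  sse <- sapply(Dgrid, function(D) {
    e <- erfc_(x_m / sqrt(4 * D * 1e-12 * t_s))
    colSums((outer(e, cgrid) - pr$c)^2)
  })
  idx <- arrayInd(which.min(sse), dim(sse))
  expect_equal(fit$c0, cgrid[idx[1]], tolerance = 1.1e-3)
  expect_equal(fit$Deff, Dgrid[idx[2]], tolerance = 1.1e-3)
})

test_that("erfc scaling law: times t and 4t give identical fitted Deff", {
  prs <- gen_concentration_profiles(150, 40, times_h = c(12, 48),
    generator_spec(1, noise_none()))
  f1 <- suppressWarnings(fit_profile(prs[[1]]))
  f2 <- suppressWarnings(fit_profile(prs[[2]]))
  expect_equal(f1$Deff, f2$Deff, tolerance = 1e-6)
})

test_that("fitted Deff is strictly monotone in the true Deff", {
  fits <- sapply(c(50, 150, 300, 450), function(D) {
    pr <- gen_concentration_profiles(D, 50, 24,
      generator_spec(1, noise_none()))[[1]]
    suppressWarnings(fit_profile(pr))$Deff
  })
  expect_true(all(diff(fits) > 0))
})

test_that("penetration beyond the scanned depth raises the semi-infinite
           warning", {
  pr <- gen_concentration_profiles(1500, 50, 72,
    generator_spec(1, noise_none()))[[1]]
  expect_warning(fit_profile(pr), "semi-infinite")
})

test_that("partition coefficient is the interface concentration ratio", {
  expect_equal(partition(53, 10), 5.3)
  expect_equal(partition(10, 10), 1)
  expect_equal(partition(648, 10), 64.8)
  expect_error(partition(5, 0), "csol")
})

test_that("replicate aggregation: two-point statistics and grouping", {
  mk <- function(Deff, comp = "0%") {
    pr <- gen_concentration_profiles(Deff, 50, 24,
      generator_spec(1, noise_none()))[[1]]
    f <- suppressWarnings(fit_profile(pr))
    f$composition <- comp
    f
  }
  fits <- list(mk(380), mk(398))
  s <- aggregate_fits(fits)
  expect_equal(s$Deff_mean, 389, tolerance = 1e-5)
  expect_equal(s$Deff_sd, 9 * sqrt(2), tolerance = 1e-4)
  expect_error(aggregate_fits(fits[1]), "at least 2")
  # 3 times x 2 replicates per composition collapse to one row each
  six <- c(lapply(1:3, function(i) mk(300, "A")),
           lapply(1:3, function(i) mk(100, "B")))
  s2 <- aggregate_fits(six)
  expect_equal(nrow(s2), 2)
  expect_setequal(s2$composition, c("A", "B"))
})

test_that("degenerate profiles are rejected", {
  expect_error(
    fit_profile(concentration_profile(seq(0, 10, 0.5), rep(0, 21), 24)),
    "all-zero")
  expect_error(
    fit_profile(concentration_profile(c(0, 1, 2), c(3, 2, 1), 24)),
    "8 positions")
})
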