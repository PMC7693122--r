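test_that("derived spectrum: magnitude, phase and round-trip", {
  sw <- frequency_sweep(c(0.1, 1, 10), c(3, 5, 5), c(4, 0, 5))
  sp <- derived_spectrum(sw)
  expect_equal(sp$G_complex[1], 5)               # 3-4-5 triangle
  expect_equal(sp$phase_angle[1], atan(4 / 3) * 180 / pi)  # ~53.13 deg
  expect_equal(sp$phase_angle[2], 0)             # ideal solid
  expect_equal(sp$phase_angle[3], 45)            # gel point
  expect_equal(sp$complex_viscosity, sp$G_complex / (2 * pi * sw$f))
  back <- spectrum_to_sweep(sp)
  expect_equal(back$G_storage, sw$G_storage, tolerance = 1e-12)
  expect_equal(back$G_loss, sw$G_loss, tolerance = 1e-12)
})

test_that("both-zero moduli are flagged as undefined phase", {
  sw <- frequency_sweep(c(0.1, 1), c(0, 5), c(0, 5))
  expect_warning(sp <- derived_spectrum(sw), "undefined")
  expect_true(is.na(sp$phase_angle[1]))
})

test_that("single-element fit recovers ground truth and matches the
           closed-form oracle", {
  sw <- gen_frequency_sweep(750, 0.25, generator_spec(3, noise_none()))
  fit <- fit_maxwell(sw, 1)
  expect_equal(fit$Gi, 750, tolerance = 1e-6)
  expect_equal(fit$lambdai, 0.25, tolerance = 1e-6)
  # independent oracle: G1 is linear-in-parameters given lambda; scan lambda
  scan <- function(sweep, lams) {
    best <- c(Inf, NA, NA)
    for (l in lams) {
      w <- 2 * pi * sweep$f * l
      a <- w^2 / (1 + w^2); b <- w / (1 + w^2)
      num <- sum(a / sweep$G_storage) + sum(b / sweep$G_loss)
      den <- sum(a^2 / sweep$G_storage^2) + sum(b^2 / sweep$G_loss^2)
      G1 <- num / den
      rss <- sum((G1 * a - sweep$G_storage)^2 / sweep$G_storage^2) +
        sum((G1 * b - sweep$G_loss)^2 / sweep$G_loss^2)
      if (rss < best[1]) best <- c(rss, G1, l)
    }
    best
  }
  oracle <- function(sweep) {  # coarse scan then local refinement
    coarse <- scan(sweep, 10^seq(-4, 3, length.out = 4000))
    lc <- log10(coarse[3])
    scan(sweep, 10^seq(lc - 0.01, lc + 0.01, length.out = 4000))
  }
  swn <- gen_frequency_sweep(750, 0.25,
                             generator_spec(3, noise_multiplicative(0.03)))
  fitn <- fit_maxwell(swn, 1)
  orc <- oracle(swn)
  expect_equal(fitn$Gi, orc[2], tolerance = 1e-4)
  expect_equal(fitn$lambdai, orc[3], tolerance = 1e-4)
})

test_that("four-element fit recovers the total modulus", {
  Gi <- c(100, 300, 800, 2000); li <- c(0.01, 0.1, 1, 10)
  sw <- gen_frequency_sweep(Gi, li, generator_spec(1, noise_none()))
  fit <- fit_maxwell(sw, 4)
  expect_equal(fit$G_total, sum(Gi), tolerance = 1e-4)
  expect_equal(sum(fit$Gi), fit$G_total, tolerance = 1e-12)
  # fitted storage modulus is monotone non-decreasing in frequency
  pred <- predict(fit, 10^seq(-3, 3, by = 0.05))
  expect_true(all(diff(pred$G_storage) >= -1e-10))
})

test_that("fit guards: too few points, non-positive moduli", {
  sw <- frequency_sweep(c(0.1, 1, 10), c(1, 2, 3), c(1, 1, 1))
  expect_error(fit_maxwell(sw, 2), "2n \\+ 1")
  sw0 <- frequency_sweep(c(0.1, 1, 10), c(0, 2, 3), c(1, 1, 1))
  expect_error(fit_maxwell(sw0, 1), "positive")
})

test_that("element count selection finds the generating model order", {
  picks1 <- sapply(1:50, function(s) {
    sw <- gen_frequency_sweep(800, 0.3,
      generator_spec(s, noise_multiplicative(0.01)))
    select_n(sw, n_max = 3)
  })
  expect_gte(mean(picks1 == 1), 0.9)
  # relaxation times a decade apart, all inside the observable window
  picks4 <- sapply(1:10, function(s) {
    sw <- gen_frequency_sweep(c(300, 600, 1200, 2400),
                              c(0.01, 0.1, 1, 10),
      generator_spec(s, noise_multiplicative(0.005)))
    select_n(sw, n_max = 5)
  })
  expect_gte(mean(picks4 == 4), 0.9)
  sw <- gen_frequency_sweep(800, 0.3, generator_spec(1))
  expect_identical(select_n(sw, n_max = 1), 1)
})

test_that("crosslink density and mesh size follow rubber elasticity", {
  ne <- network_estimate(1000, 298.15)
  expect_equal(ne$rho_x, 1000 / (8.314 * 298.15), tolerance = 1e-12)
  expect_equal(ne$rho_x, 0.4034, tolerance = 1e-4)
  expect_equal(ne$xi, 19.88e-9, tolerance = 1e-3)
  # G -> 8G halves the mesh size (cube-root scaling)
  ne8 <- network_estimate(8000, 298.15)
  expect_equal(ne8$xi, ne$xi / 2, tolerance = 1e-12)
  expect_equal(ne8$rho_x, 8 * ne$rho_x, tolerance = 1e-12)  # linear in G
  # xi strictly decreasing in rho_x
  G <- seq(100, 5000, length.out = 20)
  xis <- sapply(G, function(g) network_estimate(g)$xi)
  expect_true(all(diff(xis) < 0))
})
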