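test_that("maximum-entropy threshold equals the brute-force entropy scan", {
  imgs <- list(
    gen_pore_image("disks", generator_spec(5), side = 64, n_disks = 3,
                   grayscale_noise = 0.08),
    gen_pore_image("random_field", generator_spec(6), side = 64,
                   grayscale_noise = 0.05),
    pore_image(matrix(seq(0, 1, length.out = 64 * 64), 64, 64)))
  for (img in imgs) {
    thr <- attr(threshold_maxentropy(img), "threshold")
    expect_identical(as.integer(thr), as.integer(kapur_bruteforce(img)))
  }
})

test_that("two-level images are separated exactly, single-level rejected", {
  m <- matrix(rep(c(50, 200) / 255, each = 50), 10, 10)
  bin <- threshold_maxentropy(pore_image(m), pore = "bright")
  expect_identical(unclass(bin) == 1, m > 100 / 255)
  expect_error(threshold_maxentropy(pore_image(matrix(0.5, 8, 8))),
               "2 gray levels")
})

test_that("inverting the image swaps the foreground/background partition", {
  # intensities placed at bin centers so inversion mirrors bins exactly
  set.seed(7)
  bins <- sample(0:255, 64 * 64, replace = TRUE, prob = (1:256)^0.5)
  img <- pore_image(matrix((bins + 0.5) / 256, 64, 64))
  inv <- pore_image(matrix((255 - bins + 0.5) / 256, 64, 64))
  b1 <- threshold_maxentropy(img, pore = "dark")
  b2 <- threshold_maxentropy(inv, pore = "bright")
  expect_equal(unclass(b1), unclass(b2), ignore_attr = TRUE)
})

test_that("particle analysis: counts, areas and unit conversion", {
  img <- matrix(0, 128, 128)
  img[5:14, 5:14] <- 1; img[30:49, 30:49] <- 1; img[70:99, 70:99] <- 1
  st <- analyze_pores(pore_image(img, pixel_size = 20))
  expect_equal(st$count, 3L)
  expect_setequal(st$table$area_px2, c(100, 400, 900))
  expect_equal(sort(st$table$area_nm2)[1], 100 * 400)  # 4.0e4 nm^2
  # diagonally touching pixels belong to one 8-connected component
  d <- matrix(0, 66, 66); d[10, 10] <- 1; d[11, 11] <- 1
  d[10, 11] <- 1; d[11, 10] <- 0; d[30, 30] <- 1  # L-shape + far pixel
  st2 <- analyze_pores(pore_image(d), min_area_px = 1)
  expect_equal(st2$count, 2L)
  # min_area_px filter suppresses single-pixel noise
  expect_warning(st3 <- analyze_pores(pore_image(d), min_area_px = 4),
                 "min_area_px")
  expect_equal(st3$count, 0L)
})

test_that("watershed splits touching disks into two pores", {
  pe <- matrix(0, 128, 128)
  xg <- col(pe); yg <- row(pe)
  pe[(xg - 50)^2 + (yg - 64)^2 <= 15^2] <- 1
  pe[(xg - 75)^2 + (yg - 64)^2 <= 15^2] <- 1
  expect_equal(analyze_pores(pore_image(pe))$count, 1L)
  expect_equal(analyze_pores(pore_image(pe), use_watershed = TRUE)$count, 2L)
})

test_that("segmented disk areas match the analytic circle area", {
  img <- gen_pore_image("disks", generator_spec(11), side = 128, n_disks = 4)
  gt <- truth(img)$params
  st <- analyze_pores(pore_image(unclass(img)))
  expect_equal(st$count, gt$count)
  areas <- sort(st$table$area_px2); analytic <- sort(gt$analytic_areas_px2)
  perims <- st$table$perimeter_px[order(st$table$area_px2)]
  # discretization bound: |counted - pi r^2| <= perimeter
  expect_true(all(abs(areas - analytic) <= perims))
})

test_that("empty foreground yields empty statistics with a warning", {
  expect_warning(st <- analyze_pores(pore_image(matrix(0, 64, 64))), "empty")
  expect_equal(st$count, 0L)
})

test_that("skeleton of a bar is its medial axis; crosses have one junction", {
  bar <- matrix(0, 128, 128); bar[60:64, 10:109] <- 1
  sk <- analyze_skeleton(pore_image(bar))
  expect_equal(sk$branch_count, 1L)
  expect_equal(sk$junction_count, 0L)
  # medial axis of an L x W rectangle spans about L - W px
  expect_gte(sk$branches$length_px, 100 - 2 * 5)
  expect_lte(sk$branches$length_px, 100 - 2)
  # plus sign from two 101-px one-px bars: 4 branches around 1 junction
  pl <- matrix(0, 128, 128); pl[64, 10:110] <- 1; pl[10:110, 60] <- 1
  sk2 <- suppressWarnings(analyze_skeleton(pore_image(pl)))
  expect_equal(sk2$branch_count, 4L)
  expect_equal(sk2$junction_count, 1L)
  expect_equal(sk2$endpoint_count, 4L)
  # empty image: zero branches
  sk0 <- analyze_skeleton(pore_image(matrix(0, 64, 64)))
  expect_equal(sk0$branch_count, 0L)
})

test_that("thinning is idempotent", {
  img <- gen_pore_image("random_field", generator_spec(13), side = 96,
                        porosity = 0.35)
  sk1 <- analyze_skeleton(img)
  sk2 <- suppressWarnings(
    analyze_skeleton(pore_image(sk1$skeleton,
                                attr(img, "pixel_size"))))
  expect_identical(sk2$skeleton, sk1$skeleton)
})

test_that("denser networks have shorter median skeleton branches", {
  med <- sapply(c(4, 12), function(cl) {
    img <- gen_pore_image("random_field", generator_spec(17), side = 128,
                          correlation_length = cl, porosity = 0.5)
    analyze_skeleton(img)$summary$median
  })
  expect_lt(med[1], med[2])
})

test_that("bandpass preprocessing removes illumination gradients and
           passes in-band structure", {
  n <- 128
  xg <- col(matrix(0, n, n)) / n
  sinus <- 0.25 * sin(2 * pi * 8 * xg)            # period 16 px, in band
  gradient <- 0.8 * xg                            # large-scale illumination
  low_power <- function(m) {
    sp <- Mod(fft(m - mean(m)))^2
    sum(sp[1:3, 1:3]) - sp[1, 1]                  # lowest non-DC modes
  }
  img <- pore_image((sinus + gradient - min(sinus + gradient)) /
                      diff(range(sinus + gradient)))
  out <- preprocess(img, band = c(3, 64), stretch = FALSE,
                    renormalize = FALSE)
  expect_gte(low_power(unclass(img)) / max(low_power(out), 1e-30), 10)
  # pure in-band sinusoid survives nearly unchanged
  img_s <- pore_image(0.5 + sinus)
  out_s <- preprocess(img_s, band = c(3, 64), stretch = FALSE,
                      renormalize = FALSE)
  amp_in <- max(unclass(img_s)) - min(unclass(img_s))
  amp_out <- max(out_s) - min(out_s)
  expect_equal(amp_out, amp_in, tolerance = 0.05)
  # filtering an already band-limited image is near-idempotent
  out2 <- preprocess(pore_image(out_s + 0.5), band = c(3, 64),
                     stretch = FALSE, renormalize = FALSE)
  expect_equal(out2, out_s, tolerance = 0.02)
  expect_warning(preprocess(pore_image(matrix(0.5, 64, 64))), "constant")
  expect_error(preprocess(img, band = c(1, 64)), "Nyquist")
})

test_that("box-plot summary uses interpolated quartiles and is
           order-invariant", {
  s <- summarize(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3); expect_equal(s$q1, 2); expect_equal(s$q3, 4)
  expect_equal(summarize(7)$min, 7)
  expect_equal(summarize(7)$mean, 7)
  x <- c(9, 1, 5, 3, 7, 2)
  expect_identical(summarize(x), summarize(sort(x)))
  expect_error(summarize(numeric(0)), "at least one")
})
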