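test_that("background is the median outside the dilated mask", {
  m <- disk_mask(20, 80)
  ch <- matrix(100, 80, 80); ch[m] <- 900
  expect_equal(background_level(ch, m), 100)
  ch2 <- ch; ch2[m] <- 5000                  # blob intensity is irrelevant
  expect_identical(background_level(ch2, m), background_level(ch, m))

  set.seed(8)
  chn <- matrix(rnorm(80 * 80, mean = 50, sd = 4), 80, 80)
  bg <- background_level(chn, m)
  n_bg <- sum(!(as.matrix(EBImage::dilate(m * 1,
                                          EBImage::makeBrush(11, "disc"))) > 0.5))
  expect_lt(abs(bg - 50), 3 * 4 / sqrt(n_bg) * sqrt(pi / 2) + 0.5)

  expect_error(background_level(ch, matrix(TRUE, 80, 80)), "background")
})

test_that("average intensity is background subtracted and linear", {
  m <- disk_mask(20, 80)
  ch <- matrix(100, 80, 80); ch[m] <- 500
  expect_equal(average_intensity(ch, m), 400)
  expect_equal(average_intensity(2 * ch, m), 800)
})

test_that("AP profiles are flat for uniform bars and recover gradients", {
  sm <- matrix(TRUE, 100, 30)
  flat <- ap_profile(matrix(7, 100, 30), sm)
  expect_lt(sd(flat$values) / mean(flat$values), 0.02)
  expect_equal(flat$coordinates, ((1:100) - 0.5) / 100)

  grad <- matrix(rep(2 + 3 * ((1:100) - 0.5) / 100, 30), 100, 30)
  pr <- ap_profile(grad, sm)
  slope <- unname(coef(lm(pr$values ~ pr$coordinates))[2])
  expect_equal(abs(slope), 3, tolerance = 0.03)

  # orientation convention: the maximum sits in the posterior half, and a
  # mirrored input gives the identical profile
  mirrored <- ap_profile(grad[100:1, ], sm)
  expect_equal(mirrored$values, pr$values)
  expect_gte(pr$coordinates[which.max(pr$values)], 0.5)
})

test_that("orthogonal profiles are centred on the midline", {
  sm <- matrix(TRUE, 100, 31)
  flat <- orthogonal_profile(matrix(4, 100, 31), sm)
  expect_equal(flat$coordinates[16], 0)
  expect_lt(sd(flat$values), 1e-12)

  sym <- matrix(rep(exp(-(((1:31) - 16) / 6)^2), each = 100), 100, 31)
  pr <- orthogonal_profile(sym, sm)
  expect_lt(max(abs(pr$values - rev(pr$values))) / max(pr$values), 0.02)

  stripe <- matrix(0, 100, 31); stripe[, 21] <- 5
  ps <- orthogonal_profile(stripe, sm)
  expect_equal(ps$coordinates[which.max(ps$values)], 5)
})

test_that("angular profiles find the pole and conserve total intensity", {
  m <- disk_mask(40, 120)
  flat <- angular_profile(matrix(3, 120, 120), m, background = 1)
  expect_lt(sd(flat$values) / mean(flat$values), 0.03)

  g <- synth_generate(synthetic_spec(
    "disk", fluorescence = list(ch1 = list(pattern = "angular_pole",
                                           theta_star = pi / 4)),
    seed = 8))
  ch <- g$image$pixels[2, , ]; gm <- g$mask$pixels
  bg <- background_level(ch, gm)
  ap <- angular_profile(ch, gm, background = bg)
  bin_w <- 2 * pi / 90
  expect_lt(abs(attr(ap, "theta_peak") - pi / 4), bin_w + 1e-9)
  expect_lt(abs(ap$coordinates[which.max(ap$values)]), bin_w)

  # conservation: sum(bin mean x n_pixels) equals the masked total
  expect_equal(sum(ap$values * ap$n_pixels, na.rm = TRUE),
               sum((ch - bg)[gm]))

  # rotating the image rotates the pre-alignment peak accordingly: the
  # transpose-and-flip below maps (x, y) -> (y, -x), a -90 degree rotation
  ap90 <- angular_profile(t(ch)[, nrow(ch):1], t(gm)[, nrow(gm):1],
                          background = bg)
  d <- abs(attr(ap90, "theta_peak") - (pi / 4 - pi / 2))
  expect_lt(min(d, 2 * pi - d), 2 * bin_w + 1e-9)

  expect_error(angular_profile(ch, gm, n_bins = 4), "n_bins")
})

test_that("radial profiles bin by normalized depth", {
  m <- disk_mask(40, 120)
  flat <- radial_profile(matrix(2, 120, 120), m)
  ok <- flat$n_pixels > 0
  expect_lt(max(abs(flat$values[ok] - 2)), 1e-9)
  expect_true(all(diff(flat$coordinates) > 0))

  g <- synth_generate(synthetic_spec(
    "disk", fluorescence = list(ch1 = list(pattern = "shell")), seed = 9))
  ch <- g$image$pixels[2, , ]
  rp <- radial_profile(ch, g$mask$pixels,
                       background = background_level(ch, g$mask$pixels))
  v <- rp$values[rp$n_pixels > 0]
  expect_lt(max(diff(v)), 0.02)   # monotone decreasing up to noise

  ann <- disk_mask(40, 120) & !disk_mask(20, 120)
  expect_silent(radial_profile(matrix(1, 120, 120), ann))
})

test_that("decay fitting recovers the cosh gradient parameters", {
  x <- ((1:60) - 0.5) / 60
  x0 <- x[54]
  y0 <- organoquant:::decay_model(x, 10, 0.2, x0, 1)
  f0 <- fit_decay(intensity_profile("ap", x, y0, rep(40, 60)))
  expect_lt(f0$rmse, 1e-8 * 10)
  expect_equal(f0$lambda, 0.2, tolerance = 1e-6)
  expect_equal(f0$x0, x0)
  expect_equal(f0$L, 1)

  # parameter recovery at 2% noise across decay lengths and seeds
  errs <- unlist(lapply(c(0.1, 0.2, 0.3), function(lam)
    vapply(1:17, function(s) {
      set.seed(1000 + s + round(lam * 100))
      y <- organoquant:::decay_model(x, 10, lam, x0, 1) +
        rnorm(60, sd = 0.2)
      f <- fit_decay(intensity_profile("ap", x, y, rep(40, 60)))
      abs(f$lambda - lam) / lam
    }, numeric(1))))
  expect_lt(median(errs), 0.05)

  # a flat profile leaves the decay length unconstrained and flags it
  ff <- fit_decay(intensity_profile("ap", x, rep(5, 60), rep(40, 60)))
  expect_gte(ff$lambda, 10)
  expect_true(ff$unconstrained)

  expect_error(fit_decay(intensity_profile("ap", x[1:5], rep(1, 5),
                                           rep(3, 5))), "10 valid bins")
})

test_that("profiles are exactly invariant to a constant added background", {
  g <- synth_generate(synthetic_spec(
    "disk", fluorescence = list(ch1 = list(pattern = "angular_pole",
                                           theta_star = 1)), seed = 12))
  ch <- g$image$pixels[2, , ]; m <- g$mask$pixels
  a1 <- angular_profile(ch, m, background = background_level(ch, m))
  ch2 <- ch + 0.2
  a2 <- angular_profile(ch2, m, background = background_level(ch2, m))
  expect_equal(a2$values, a1$values, tolerance = 1e-9)
})
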