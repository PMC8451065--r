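test_that("mask outlines are traced subpixel, counterclockwise and resampled", {
  ctr <- extract_contour(disk_mask(50, 130))
  pts <- rbind(ctr$points, ctr$points[1, ])
  len <- sum(sqrt(rowSums(diff(pts)^2)))
  expect_equal(len, 2 * pi * 50, tolerance = 0.01)

  x <- ctr$points[, 1]; y <- ctr$points[, 2]
  signed <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  expect_gt(signed, 0)

  sq <- rect_mask(80, 80, 40, 40)
  ctr2 <- extract_contour(sq)
  corners <- rbind(c(20.5, 20.5), c(20.5, 60.5), c(60.5, 20.5),
                   c(60.5, 60.5))
  for (i in 1:4)
    expect_lt(min(sqrt((ctr2$points[, 1] - corners[i, 1])^2 +
                         (ctr2$points[, 2] - corners[i, 2])^2)), 1)
})

# Independent oracle: Fourier coefficients of the arclength-parametrised
# closed curve by trapezoidal quadrature on a dense polygon.
fourier_quadrature <- function(pts, n_modes) {
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  T <- s[length(s)]
  mid_s <- (s[-1] + s[-length(s)]) / 2
  mid_x <- (closed[-1, 1] + closed[-nrow(closed), 1]) / 2
  mid_y <- (closed[-1, 2] + closed[-nrow(closed), 2]) / 2
  out <- list(a = numeric(n_modes), b = numeric(n_modes),
              c = numeric(n_modes), d = numeric(n_modes),
              A0 = sum(mid_x * seg) / T, C0 = sum(mid_y * seg) / T)
  for (n in seq_len(n_modes)) {
    cs <- cos(2 * pi * n * mid_s / T); sn <- sin(2 * pi * n * mid_s / T)
    out$a[n] <- 2 / T * sum(mid_x * cs * seg)
    out$b[n] <- 2 / T * sum(mid_x * sn * seg)
    out$c[n] <- 2 / T * sum(mid_y * cs * seg)
    out$d[n] <- 2 / T * sum(mid_y * sn * seg)
  }
  out
}

test_that("EFA coefficients match independent Fourier quadrature", {
  efa <- efa_coefficients(circle_contour(20, cx = 10, cy = -5), 10)
  expect_equal(c(efa$a[1], efa$d[1]), c(20, 20), tolerance = 1e-3)
  expect_equal(c(efa$b[1], efa$c[1]), c(0, 0), tolerance = 1e-3)
  expect_lt(max(abs(c(efa$a[-1], efa$b[-1], efa$c[-1], efa$d[-1]))),
            0.01 * 20)
  expect_equal(c(efa$A0, efa$C0), c(10, -5), tolerance = 1e-3)

  # ellipse: under arclength parametrisation the first harmonic is not
  # exactly diag(A, B); quadrature on a dense polygon is the reference
  th <- seq(0, 2 * pi, length.out = 4001)[-4001]
  pts <- cbind(30 * cos(th), 12 * sin(th))
  ref <- fourier_quadrature(pts, 8)
  ell <- structure(list(points = pts[seq(1, 4000, by = 10), ]),
                   class = "Contour")
  efa2 <- efa_coefficients(ell, 8)
  expect_equal(efa2$a, ref$a, tolerance = 0.01)
  expect_equal(efa2$d, ref$d, tolerance = 0.01)
  expect_lt(max(abs(c(efa2$b, efa2$c))), 0.01 * 30)
  # the fundamental stays close to the generating axes
  expect_equal(c(efa2$a[1], efa2$d[1]), c(30, 12), tolerance = 0.15)

  expect_error(efa_coefficients(circle_contour(10), n_modes = 1), "n_modes")
})

test_that("full reconstruction reproduces a lobed contour to subpixel accuracy", {
  flower <- flower_contour(25, 4, 0.2, n = 1000)
  efa <- efa_coefficients(flower, 30)
  rc <- reconstruct_contour(efa, 30, n_points = 1000)$points
  thd <- seq(0, 2 * pi, length.out = 20001)[-20001]
  rd <- 25 * (1 + 0.2 * cos(4 * thd))
  ref <- cbind(rd * cos(thd), rd * sin(thd))
  dev <- apply(rc, 1, function(q)
    min(sqrt((ref[, 1] - q[1])^2 + (ref[, 2] - q[2])^2)))
  expect_lt(max(dev), 0.01 * 25)

  # m = 0 degenerates to the offset
  r0 <- reconstruct_contour(efa, 0, n_points = 10)$points
  expect_lt(max(abs(r0[, 1] - efa$A0)), 1e-12)

  # partial-sum deviation shrinks as modes are added
  devs <- vapply(c(1, 3, 5, 30), function(m) {
    rc <- reconstruct_contour(efa, m, n_points = 400)$points
    max(apply(rc, 1, function(q)
      min(sqrt((ref[, 1] - q[1])^2 + (ref[, 2] - q[2])^2))))
  }, numeric(1))
  expect_true(all(diff(devs) <= 1e-9))
})

test_that("LOCO spectrum assigns a circle to mode 1 and p lobes to mode p", {
  sp <- loco_spectrum(efa_coefficients(circle_contour(20), 10))
  expect_equal(sp$L[2], 20, tolerance = 1e-3)
  expect_lt(max(sp$L[-(1:2)]), 0.01 * sp$L[2])
  expect_equal(coverage_cutoff(sp), 1L)

  for (p in c(3, 5, 7)) {
    sp <- loco_spectrum(efa_coefficients(flower_contour(30, p, 0.2), 20))
    expect_equal(which.max(sp$L[-(1:3)]) + 2L, p)
    # L_p = eps * R holds to first order in eps; arclength parametrisation
    # shifts a few percent of the amplitude into neighbouring modes
    expect_equal(sp$L[p + 1], 0.2 * 30, tolerance = 0.1)
  }
})

test_that("LOCO amplitudes are invariant to pose and linear in scale", {
  flower <- flower_contour(25, 4, 0.2)
  L0 <- loco_spectrum(efa_coefficients(flower, 15))$L

  rot <- 0.7
  Rm <- matrix(c(cos(rot), -sin(rot), sin(rot), cos(rot)), 2, 2)
  moved <- structure(list(points = flower$points %*% Rm +
                            matrix(c(100, -30), 400, 2, byrow = TRUE)),
                     class = "Contour")
  L1 <- loco_spectrum(efa_coefficients(moved, 15))$L
  expect_lt(max(abs(L1 - L0)) / max(L0), 1e-6)

  shifted <- structure(list(points = flower$points[c(101:400, 1:100), ]),
                       class = "Contour")
  L2 <- loco_spectrum(efa_coefficients(shifted, 15))$L
  expect_lt(max(abs(L2 - L0)) / max(L0), 1e-6)

  scaled <- structure(list(points = flower$points * 3), class = "Contour")
  L3 <- loco_spectrum(efa_coefficients(scaled, 15))$L
  expect_equal(L3, 3 * L0, tolerance = 1e-9)
})

test_that("coverage cutoff finds the smallest sufficient mode", {
  sp <- structure(list(L = c(0, 1, 0, 0, 0),
                       cumulative_coverage = c(0, 1, 1, 1, 1)),
                  class = "LocoSpectrum")
  expect_equal(coverage_cutoff(sp), 1L)
  expect_equal(coverage_cutoff(sp, threshold = 1), 1L)

  sp2 <- structure(list(L = c(0, 3, 1, 0.5, 0)),
                   class = "LocoSpectrum")
  pw <- sp2$L^2
  sp2$cumulative_coverage <- cumsum(pw) / sum(pw)
  expect_equal(coverage_cutoff(sp2, 1), 3L)   # last nonzero mode
  expect_equal(coverage_cutoff(sp2, 0.9), 2L)
})

test_that("full-mode reconstruction of generator masks stays within 0.5 px RMS", {
  for (shape in c("flower", "bent_bar")) {
    g <- synth_generate(synthetic_spec(shape, seed = 31))
    ctr <- extract_contour(g$mask$pixels)
    efa <- efa_coefficients(ctr)
    rc <- reconstruct_contour(efa, n_points = nrow(ctr$points))$points
    dev <- apply(rc, 1, function(q)
      min(sqrt((ctr$points[, 1] - q[1])^2 + (ctr$points[, 2] - q[2])^2)))
    expect_lt(sqrt(mean(dev^2)), 0.5)
  }
})
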