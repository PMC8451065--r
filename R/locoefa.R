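# Elliptical Fourier analysis of the mask outline and its lobe-contribution
# (LOCO) reassignment: each harmonic is split into two counter-rotating
# circular components; the component rotating with the fundamental at
# relative frequency +l and the counter-rotating one at -l both modulate the
# outline with l lobes, so their (phase-aware) combination defines the lobe
# amplitude L_l.

#' Subpixel outline of a mask
#'
#' The mask is lightly Gaussian-smoothed and the 0.5 iso-contour traced by
#' marching squares ([grDevices::contourLines()]); when several closed
#' contours exist only the outer boundary (largest enclosed area) is kept.
#' The polygon is resampled to uniform arclength spacing and oriented
#' counterclockwise (positive signed area) in `(x = col, y = row)`
#' coordinates.
#'
#' @param mask a `BinaryMask` or logical matrix.
#' @param smooth_sigma Gaussian presmoothing width in px.
#' @param n_points number of resampled contour points.
#' @return A `Contour`: `list(points)`, an `n_points x 2` matrix (x, y);
#'   closure is implicit (last point connects to first).
#' @export
extract_contour <- function(mask, smooth_sigma = 1, n_points = 400L) {
  m <- as_mask_matrix(mask)
  if (!any(m)) stopf("degenerate mask: no foreground pixels")
  z <- if (smooth_sigma > 0) gaussian_smooth(m * 1, smooth_sigma) else m * 1
  cl <- contourLines(seq_len(nrow(m)), seq_len(ncol(m)), z, levels = 0.5)
  if (length(cl) == 0) stopf("no 0.5 iso-contour found")
  poly_area <- function(p) {
    x <- p$y; y <- p$x   # (x = col, y = row)
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2)
  }
  piece <- cl[[which.max(vapply(cl, poly_area, numeric(1)))]]
  pts <- cbind(x = piece$y, y = piece$x)
  if (nrow(pts) > 1 && all(pts[1, ] == pts[nrow(pts), ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  if (nrow(pts) < 16) stopf("contour too short (%d points)", nrow(pts))
  pts <- resample_closed(pts, n_points)
  x <- pts[, 1]; y <- pts[, 2]
  signed <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  if (signed < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  structure(list(points = unname(pts)), class = "Contour")
}

# Resample a closed polygon to n points at uniform arclength.
resample_closed <- function(pts, n) {
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  si <- seq(0, L, length.out = n + 1L)[-(n + 1L)]
  cbind(approx(s, closed[, 1], xout = si)$y,
        approx(s, closed[, 2], xout = si)$y)
}

contour_points <- function(contour) {
  if (inherits(contour, "Contour")) contour$points else as.matrix(contour)
}

#' Elliptical Fourier coefficients of a closed contour
#'
#' Classical arclength-parametrised elliptical Fourier decomposition
#' (Kuhl-Giardina): per harmonic `n` the four coefficients
#' `(a_n, b_n, c_n, d_n)` of `x(t)` and `y(t)`, plus the offset `(A0, C0)`.
#'
#' @param contour a `Contour` (or `n x 2` point matrix, implicitly closed).
#' @param n_modes number of harmonics `N >= 2`; default
#'   `min(50, floor(n_points / 2) - 1)`.
#' @return An `EFACoefficients` list: `A0`, `C0`, and vectors `a`, `b`, `c`,
#'   `d` of length `N`.
#' @export
efa_coefficients <- function(contour, n_modes = NULL) {
  pts <- contour_points(contour)
  K <- nrow(pts)
  if (is.null(n_modes)) n_modes <- min(50L, floor(K / 2) - 1L)
  if (n_modes < 2) stopf("n_modes must be >= 2")
  closed <- rbind(pts, pts[1, ])
  dx <- diff(closed[, 1]); dy <- diff(closed[, 2])
  dt <- sqrt(dx^2 + dy^2)
  ok <- dt > 1e-12
  dx <- dx[ok]; dy <- dy[ok]; dt <- dt[ok]
  if (length(dt) < 3) stopf("degenerate contour: zero length")
  t1 <- cumsum(dt); t0 <- c(0, t1[-length(t1)])
  T <- t1[length(t1)]
  a <- b <- cc <- d <- numeric(n_modes)
  for (n in seq_len(n_modes)) {
    w <- 2 * pi * n / T
    f <- T / (2 * n^2 * pi^2)
    dcos <- cos(w * t1) - cos(w * t0)
    dsin <- sin(w * t1) - sin(w * t0)
    a[n] <- f * sum(dx / dt * dcos)
    b[n] <- f * sum(dx / dt * dsin)
    cc[n] <- f * sum(dy / dt * dcos)
    d[n] <- f * sum(dy / dt * dsin)
  }
  xi <- c(0, cumsum(dx)[-length(dx)]) - dx / dt * t0
  delta <- c(0, cumsum(dy)[-length(dy)]) - dy / dt * t0
  A0 <- pts[1, 1] + sum(dx / (2 * dt) * (t1^2 - t0^2) + xi * (t1 - t0)) / T
  C0 <- pts[1, 2] + sum(dy / (2 * dt) * (t1^2 - t0^2) + delta * (t1 - t0)) / T
  structure(list(A0 = A0, C0 = C0, a = a, b = b, c = cc, d = d,
                 n_modes = n_modes),
            class = "EFACoefficients")
}

#' Partial-sum reconstruction of a contour from EFA coefficients
#'
#' @param efa an `EFACoefficients` object.
#' @param upto_mode highest harmonic included (`0` gives the offset point).
#' @param n_points points on the reconstructed outline.
#' @return A `Contour`.
#' @export
reconstruct_contour <- function(efa, upto_mode = efa$n_modes,
                                n_points = 400L) {
  stopifnot(inherits(efa, "EFACoefficients"))
  upto_mode <- min(upto_mode, efa$n_modes)
  t <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  x <- rep(efa$A0, n_points); y <- rep(efa$C0, n_points)
  for (n in seq_len(upto_mode)) {
    x <- x + efa$a[n] * cos(n * t) + efa$b[n] * sin(n * t)
    y <- y + efa$c[n] * cos(n * t) + efa$d[n] * sin(n * t)
  }
  structure(list(points = cbind(x, y)), class = "Contour")
}

#' Lobe-contribution (LOCO) spectrum from EFA coefficients
#'
#' Harmonic `n` is written as two counter-rotating circular motions with
#' complex amplitudes `c+_n = ((a_n + d_n) + i(c_n - b_n)) / 2` (frequency
#' `+n`) and `c-_n = ((a_n - d_n) + i(c_n + b_n)) / 2` (frequency `-n`).
#' Relative to the fundamental rotation, frequency `+(l+1)` and frequency
#' `-(l-1)` both modulate the outline radius with `l` lobes, so
#' `L_l = |c+_{l+1} e^{-i z1} + Conj(c-_{l-1}) e^{+i z1}|` with
#' `z1 = Arg(c+_1)`; `L_1` combines the fundamental circle `|c+_1|` with the
#' 1-lobe component `|c+_2|` in quadrature, and `L_0 = 0` (translation is
#' excluded, making the spectrum translation invariant). A circle of radius
#' `R` gives `L_1 = R`; a p-lobed flower `r = R(1 + eps cos(p theta))` gives
#' `L_p = eps R`. The spectrum is invariant under rotation, translation and
#' starting-point shifts, and scales linearly with the contour.
#'
#' Cumulative coverage is power-based:
#' `coverage_n = sum_{m<=n} L_m^2 / sum_m L_m^2`.
#'
#' @param efa an `EFACoefficients` object.
#' @return A `LocoSpectrum`: `list(L, cumulative_coverage)`, both indexed by
#'   mode `0..N`.
#' @export
loco_spectrum <- function(efa) {
  stopifnot(inherits(efa, "EFACoefficients"))
  N <- efa$n_modes
  cplus <- complex(real = (efa$a + efa$d) / 2,
                   imaginary = (efa$c - efa$b) / 2)
  cminus <- complex(real = (efa$a - efa$d) / 2,
                    imaginary = (efa$c + efa$b) / 2)
  z1 <- Arg(cplus[1])
  L <- numeric(N + 1L)                     # L[l + 1] = L_l
  L[2] <- sqrt(Mod(cplus[1])^2 + (if (N >= 2) Mod(cplus[2])^2 else 0))
  for (l in 2:N) {
    tp <- if (l + 1 <= N) cplus[l + 1] else 0 + 0i
    tm <- Conj(cminus[l - 1])
    L[l + 1] <- Mod(tp * exp(-1i * z1) + tm * exp(1i * z1))
  }
  pw <- L^2
  structure(list(L = L, cumulative_coverage = cumsum(pw) / sum(pw)),
            class = "LocoSpectrum")
}

#' Smallest mode covering a given fraction of the shape power
#'
#' @param spectrum a `LocoSpectrum`.
#' @param threshold cumulative power fraction, default 0.95.
#' @return The smallest mode index `n` whose cumulative coverage reaches the
#'   threshold.
#' @export
coverage_cutoff <- function(spectrum, threshold = 0.95) {
  stopifnot(inherits(spectrum, "LocoSpectrum"))
  cov <- spectrum$cumulative_coverage
  which(cov >= threshold - 1e-12)[1] - 1L
}

#' Full LOCO-EFA analysis of a mask
#'
#' Convenience wrapper: outline extraction, EFA decomposition, LOCO spectrum
#' and coverage cutoff.
#'
#' @inheritParams extract_contour
#' @inheritParams efa_coefficients
#' @inheritParams coverage_cutoff
#' @return `list(L, cutoff_mode, spectrum, efa, contour)`.
#' @export
locoefa_analysis <- function(mask, n_modes = NULL, threshold = 0.95,
                             smooth_sigma = 1, n_points = 400L) {
  ctr <- extract_contour(mask, smooth_sigma = smooth_sigma,
                         n_points = n_points)
  efa <- efa_coefficients(ctr, n_modes = n_modes)
  sp <- loco_spectrum(efa)
  list(L = sp$L, cutoff_mode = coverage_cutoff(sp, threshold),
       spectrum = sp, efa = efa, contour = ctr)
}
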