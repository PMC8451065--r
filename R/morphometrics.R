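# Shape descriptors, skeleton-based midline extraction and computational
# straightening along the midline meshgrid.

#' Basic shape descriptors of a mask
#'
#' Area is the foreground pixel count; perimeter is the length of the
#' subpixel outline polygon (see [extract_contour()]); form factor is
#' `4 * pi * A / P^2` (1 for a circle); eccentricity, axis lengths and
#' orientation come from the ellipse with matching second central moments
#' (with the 1/12 px^2 pixel-variance correction, so a solid rectangle of
#' side L has variance exactly L^2/12).
#'
#' @param mask a `BinaryMask` or logical matrix with a single connected
#'   component.
#' @return A `MorphoRecord` list: `area`, `perimeter`, `form_factor`,
#'   `eccentricity`, `major_axis`, `minor_axis`, `centroid` (row, col),
#'   `orientation` (radians).
#' @export
basic_descriptors <- function(mask) {
  m <- as_mask_matrix(mask)
  if (!any(m)) stopf("degenerate mask: no foreground pixels")
  area <- sum(m)
  ctr <- extract_contour(m)
  pts <- rbind(ctr$points, ctr$points[1, ])
  perim <- sum(sqrt(rowSums(diff(pts)^2)))
  rr <- row(m)[m]; cc <- col(m)[m]
  cr <- mean(rr); ccol <- mean(cc)
  mu20 <- mean((rr - cr)^2) + 1 / 12
  mu02 <- mean((cc - ccol)^2) + 1 / 12
  mu11 <- mean((rr - cr) * (cc - ccol))
  tr <- mu20 + mu02
  dt <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (tr + dt) / 2; l2 <- (tr - dt) / 2
  structure(list(
    area = area, perimeter = perim,
    form_factor = 4 * pi * area / perim^2,
    eccentricity = sqrt(max(0, 1 - l2 / l1)),
    major_axis = 4 * sqrt(l1), minor_axis = 4 * sqrt(max(0, l2)),
    centroid = c(row = cr, col = ccol),
    orientation = 0.5 * atan2(2 * mu11, mu02 - mu20)),
    class = "MorphoRecord")
}

# BFS over the 8-connected skeleton-pixel graph from node `start`; returns
# distances and parents (index into `coords`).
skeleton_bfs <- function(node_id, coords, start) {
  n <- nrow(coords)
  dist <- rep(NA_integer_, n); parent <- rep(NA_integer_, n)
  dist[start] <- 0L
  queue <- integer(n); queue[1] <- start; qh <- 1L; qt <- 1L
  nr <- nrow(node_id); nc <- ncol(node_id)
  while (qh <= qt) {
    v <- queue[qh]; qh <- qh + 1L
    r <- coords[v, 1]; cc <- coords[v, 2]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rn <- r + dr; cn <- cc + dc
      if (rn < 1 || rn > nr || cn < 1 || cn > nc) next
      u <- node_id[rn, cn]
      if (u > 0L && is.na(dist[u])) {
        dist[u] <- dist[v] + 1L
        parent[u] <- v
        qt <- qt + 1L; queue[qt] <- u
      }
    }
  }
  list(dist = dist, parent = parent)
}

#' Extract the midline of an elongated mask
#'
#' The mask is thinned to a 1-px skeleton (Guo-Hall); side branches --
#' typically spawned near the poles -- are pruned by keeping the single
#' longest geodesic path through the skeleton graph. The retained path is
#' spline-smoothed, extended from both ends along the mean terminal tangent
#' until it crosses the mask boundary, and resampled to ~1 px spacing. The
#' pole with the lower column index comes first.
#'
#' @param mask a single-component `BinaryMask` or logical matrix.
#' @return A `Midline`: `list(points, arclength)` with `points` an `n x 2`
#'   matrix of subpixel (row, col) coordinates.
#' @export
extract_midline <- function(mask) {
  m <- as_mask_matrix(mask)
  if (!any(m)) stopf("degenerate mask: no foreground pixels")
  mf <- as.matrix(EBImage::fillHull(m * 1)) > 0.5
  skel_in <- mf * 1L; storage.mode(skel_in) <- "integer"
  skel <- .thin_guo_hall(skel_in)
  coords <- which(skel > 0L, arr.ind = TRUE)
  if (nrow(coords) == 0) stopf("mask too thin: empty skeleton")
  node_id <- matrix(0L, nrow(m), ncol(m))
  node_id[coords] <- seq_len(nrow(coords))
  b1 <- skeleton_bfs(node_id, coords, 1L)
  a <- which.max(b1$dist)
  b2 <- skeleton_bfs(node_id, coords, a)
  b <- which.max(b2$dist)
  path <- integer(); v <- b
  while (!is.na(v)) { path <- c(path, v); v <- b2$parent[v] }
  pts <- coords[rev(path), , drop = FALSE]

  # Prune pole branches: near the poles the thinning runs off the medial
  # ridge towards the contour (corner bisectors at flat ends, side branches
  # at junctions). Off-ridge segments are recognisable by the steep climb of
  # the interior radius (distance transform) along the path (~0.7 px/px on a
  # corner bisector vs ~0 on the ridge); such terminal segments are dropped
  # -- the tangential extension below replaces them. The search is limited
  # to ~2 interior radii from each end so mid-path branches never truncate
  # the midline.
  if (nrow(pts) >= 5) {
    dmap <- as.matrix(EBImage::distmap(mf * 1))
    dtv <- dmap[cbind(pmin(pmax(round(pts[, 1]), 1), nrow(mf)),
                      pmin(pmax(round(pts[, 2]), 1), ncol(mf)))]
    n <- nrow(pts)
    k5 <- pmin(pmax(seq_len(n), 3L), n - 2L)
    sm_dtv <- (dtv[k5 - 2] + dtv[k5 - 1] + dtv[k5] + dtv[k5 + 1] +
                 dtv[k5 + 2]) / 5
    seg <- sqrt(rowSums(diff(pts)^2))
    s_start <- c(0, cumsum(seg))
    s_end <- s_start[n] - s_start
    slope <- rep(0, n)
    i3 <- 3:(n - 2)
    slope[i3] <- (sm_dtv[i3 + 2] - sm_dtv[i3 - 2]) /
      pmax(s_start[i3 + 2] - s_start[i3 - 2], 1e-9)
    window <- 2 * max(dtv)
    lo <- 1L; hi <- n
    cand <- which(slope >= 0.35 & s_start <= window)
    if (length(cand)) lo <- max(cand) + 1L
    cand <- which(slope <= -0.35 & s_end <= window)
    if (length(cand)) hi <- min(cand) - 1L
    if (hi - lo + 1L >= 5) pts <- pts[lo:hi, , drop = FALSE]
  }

  if (nrow(pts) < 5) {
    # Near-round mask: skeleton collapses to a point or a stub. Anchor the
    # midline at the skeleton centre along the mask's principal axis.
    ctr <- colMeans(pts[, 1:2, drop = FALSE])
    d <- basic_descriptors(mf)
    ang <- d$orientation
    dir <- c(sin(ang), cos(ang))     # (row, col) unit vector
    pts <- rbind(ctr - 0.5 * dir, ctr + 0.5 * dir)
  } else {
    t0 <- seq_len(nrow(pts))
    df <- min(max(4, round(nrow(pts) / 12)), 25)
    if (nrow(pts) > df + 2) {
      sr <- smooth.spline(t0, pts[, 1], df = df)
      sc <- smooth.spline(t0, pts[, 2], df = df)
      pts <- cbind(predict(sr, t0)$y, predict(sc, t0)$y)
    }
  }
  pts <- resample_polyline(pts, spacing = 1)

  extend_end <- function(pts, from_start) {
    if (from_start) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
    n <- nrow(pts)
    k <- min(10L, n - 1L)
    tang <- colMeans(pts[n, , drop = FALSE][rep(1, k), ] -
                       pts[(n - k):(n - 1), , drop = FALSE]) / ((k + 1) / 2)
    tang <- tang / sqrt(sum(tang^2))
    p <- pts[n, ]
    add <- NULL
    for (s in seq(0.5, sum(dim(m)), by = 0.5)) {
      q <- p + s * tang
      inside <- bilinear_sample(mf * 1, q[1], q[2], fill = 0) >= 0.5
      if (!inside) break
      add <- rbind(add, q)
    }
    out <- rbind(pts, add)
    if (from_start) out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
    out
  }
  pts <- extend_end(pts, from_start = FALSE)
  pts <- extend_end(pts, from_start = TRUE)
  pts <- resample_polyline(pts, spacing = 1)
  if (pts[1, 2] > pts[nrow(pts), 2])
    pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  seg <- sqrt(rowSums(diff(pts)^2))
  structure(list(points = unname(pts), arclength = sum(seg)),
            class = "Midline")
}

# Resample an open polyline to (approximately) uniform spacing.
resample_polyline <- function(pts, spacing = 1) {
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  keep <- c(TRUE, seg > 1e-9)
  pts <- pts[keep, , drop = FALSE]; s <- s[keep]
  if (nrow(pts) < 2) return(pts)
  L <- s[length(s)]
  n_out <- max(2L, round(L / spacing) + 1L)
  si <- seq(0, L, length.out = n_out)
  cbind(approx(s, pts[, 1], xout = si)$y, approx(s, pts[, 2], xout = si)$y)
}

#' Build the orthogonal sampling meshgrid along a midline
#'
#' For every midline point, a segment orthogonal to the local tangent is
#' sampled at 1 px steps out to `half_width` on both sides. With
#' `half_width = "auto"`, the half-width is the maximum of the mask's
#' Euclidean distance transform (the deepest interior radius) plus 2 px.
#'
#' @param midline a `Midline`.
#' @param mask the mask the midline was extracted from.
#' @param half_width integer or `"auto"`.
#' @return A `Meshgrid`: `list(midline, rows, cols, half_width)` where `rows`
#'   and `cols` are `(n_midline x (2 * half_width + 1))` coordinate matrices.
#' @export
build_meshgrid <- function(midline, mask, half_width = "auto") {
  stopifnot(inherits(midline, "Midline"))
  m <- as_mask_matrix(mask)
  if (identical(half_width, "auto"))
    half_width <- ceiling(max(EBImage::distmap(m * 1))) + 2L
  pts <- midline$points
  n <- nrow(pts)
  tang <- rbind(pts[2, ] - pts[1, ],
                (pts[3:n, , drop = FALSE] - pts[1:(n - 2), , drop = FALSE]) / 2,
                pts[n, ] - pts[n - 1, ])
  len <- sqrt(rowSums(tang^2)); len[len < 1e-12] <- 1
  tang <- tang / len
  normal <- cbind(-tang[, 2], tang[, 1])
  off <- seq(-half_width, half_width)
  rows <- outer(pts[, 1], rep(1, length(off))) + outer(normal[, 1], off)
  cols <- outer(pts[, 2], rep(1, length(off))) + outer(normal[, 2], off)
  structure(list(midline = midline, rows = rows, cols = cols,
                 half_width = as.integer(half_width)),
            class = "Meshgrid")
}

#' Computationally straighten an image or mask along a meshgrid
#'
#' Output pixel `(i, j)` is the input sampled at orthogonal offset `j` of
#' midline point `i`: rows run along the midline (the anteroposterior axis),
#' columns across it (mediolateral). Intensities are interpolated bilinearly;
#' with `mask = TRUE` the result is thresholded at 0.5 back to binary.
#' Samples outside the image get `fill`.
#'
#' @param x 2D matrix (intensity channel or binary mask).
#' @param mesh a `Meshgrid` from [build_meshgrid()].
#' @param mask is `x` a binary mask?
#' @param fill fill value for out-of-image samples.
#' @return A matrix of size `(n_midline, 2 * half_width + 1)`; logical when
#'   `mask = TRUE`.
#' @export
straighten <- function(x, mesh, mask = FALSE, fill = 0) {
  stopifnot(inherits(mesh, "Meshgrid"))
  if (mask) x <- as_mask_matrix(x) * 1
  v <- bilinear_sample(x, as.vector(mesh$rows), as.vector(mesh$cols),
                       fill = fill)
  out <- matrix(v, nrow(mesh$rows), ncol(mesh$rows))
  if (mask) out <- out >= 0.5
  out
}

#' Shape descriptors of a straightened mask
#'
#' On the straightened frame the anteroposterior length is directly the
#' number of midline rows containing foreground and the width the mean
#' foreground run per row, so `major_axis`/`minor_axis` are reported as
#' these lengths; the remaining descriptors are recomputed on the
#' straightened mask.
#'
#' @param straight_mask logical matrix from [straighten()] with
#'   `mask = TRUE`.
#' @return A `MorphoRecord` (see [basic_descriptors()]).
#' @export
descriptors_straightened <- function(straight_mask) {
  m <- as_mask_matrix(straight_mask)
  if (!any(m)) stopf("degenerate mask: no foreground pixels")
  rec <- basic_descriptors(m)
  widths <- rowSums(m)
  rec$major_axis <- sum(widths > 0)
  rec$minor_axis <- mean(widths[widths > 0])
  rec
}
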