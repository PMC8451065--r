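# Per-pixel feature extraction for the three-class pixel classifiers.

gaussian_smooth <- function(img, sigma) {
  # EBImage's gblur wants radius >= 2*sigma for accuracy; the kernel is
  # capped at the image size (truncating the Gaussian) so large widths also
  # work on small crops. Borders are padded by replication.
  r <- 2 * ceiling(2 * sigma) + 1
  mx <- min(dim(img))
  if (r > mx) r <- mx - (1 - mx %% 2)
  as.matrix(EBImage::gblur(img, sigma = sigma, radius = r))
}

conv2 <- function(img, kernel) {
  as.matrix(EBImage::filter2(img, kernel, boundary = "replicate"))
}

laplacian_of <- function(img) {
  k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  conv2(img, k)
}

gradient_magnitude_of <- function(img) {
  kx <- matrix(c(-0.5, 0, 0.5), 1, 3)  # along columns
  ky <- matrix(c(-0.5, 0, 0.5), 3, 1)  # along rows
  sqrt(conv2(img, ky)^2 + conv2(img, kx)^2)
}

#' Ilastik-style per-pixel filter features
#'
#' For each filter width sigma: Gaussian smoothing, Laplacian of Gaussian and
#' Gaussian gradient magnitude; plus a difference of Gaussians for every
#' unordered pair of widths. With `k` widths this yields
#' `3k + k(k-1)/2` features -- 18 for the default widths `c(1, 2, 5, 15)`.
#'
#' @param image 2D numeric matrix (the segmentation channel).
#' @param widths strictly increasing positive filter widths (sigma, px).
#' @return A `FeatureStack`: `list(features = (feature, row, col) array,
#'   names = character)`.
#' @export
ilastik_features <- function(image, widths = c(1, 2, 5, 15)) {
  if (length(widths) == 0) stopf("at least one filter width is required")
  if (any(widths <= 0) || is.unsorted(widths, strictly = TRUE))
    stopf("filter widths must be strictly increasing and positive")
  k <- length(widths)
  smoothed <- lapply(widths, function(s) gaussian_smooth(image, s))
  feats <- list(); nms <- character()
  for (i in seq_len(k)) {
    feats <- c(feats, list(smoothed[[i]]))
    nms <- c(nms, sprintf("gauss_s%g", widths[i]))
  }
  for (i in seq_len(k)) {
    feats <- c(feats, list(laplacian_of(smoothed[[i]])))
    nms <- c(nms, sprintf("log_s%g", widths[i]))
  }
  for (i in seq_len(k)) {
    feats <- c(feats, list(gradient_magnitude_of(smoothed[[i]])))
    nms <- c(nms, sprintf("gradmag_s%g", widths[i]))
  }
  if (k >= 2) for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    feats <- c(feats, list(smoothed[[i]] - smoothed[[j]]))
    nms <- c(nms, sprintf("dog_s%g_s%g", widths[i], widths[j]))
  }
  arr <- array(0, dim = c(length(feats), dim(image)))
  for (f in seq_along(feats)) arr[f, , ] <- feats[[f]]
  structure(list(features = arr, names = nms), class = "FeatureStack")
}

# Shift a matrix by integer (dr, dc), clamping at the borders (replication).
shift_clamped <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci]
}

#' DAISY-style dense texture descriptors plus filter features
#'
#' Dense gradient-orientation histograms in the DAISY construction: rectified
#' directional gradients are Gaussian-pooled at a central scale and at one or
#' more ring scales, and the ring maps are sampled at equally spaced points
#' around each pixel. The descriptor is appended to the [ilastik_features()]
#' stack with names prefixed `daisy_`.
#'
#' @inheritParams ilastik_features
#' @param radius ring radius in pixels (the descriptor footprint is
#'   `2 * radius + 1`).
#' @param orientations number of gradient orientations.
#' @param ring_points sample points on the ring.
#' @param sigma_center,sigma_ring Gaussian pooling scales.
#' @return A `FeatureStack` of `3k + k(k-1)/2 + orientations * (1 +
#'   ring_points)` features.
#' @export
daisy_features <- function(image, widths = c(1, 2, 5, 15), radius = 8L,
                           orientations = 4L, ring_points = 6L,
                           sigma_center = 2.5, sigma_ring = 5) {
  if (min(dim(image)) < 2L * radius + 1L)
    stopf("image (%d x %d) is smaller than the DAISY footprint (%d px)",
          nrow(image), ncol(image), 2L * radius + 1L)
  base <- ilastik_features(image, widths)
  sm <- gaussian_smooth(image, 1)
  gx <- conv2(sm, matrix(c(-0.5, 0, 0.5), 1, 3))
  gy <- conv2(sm, matrix(c(-0.5, 0, 0.5), 3, 1))
  thetas <- (seq_len(orientations) - 1) * 2 * pi / orientations
  feats <- list(); nms <- character()
  for (q in seq_len(orientations)) {
    o <- pmax(cos(thetas[q]) * gx + sin(thetas[q]) * gy, 0)
    feats <- c(feats, list(gaussian_smooth(o, sigma_center)))
    nms <- c(nms, sprintf("daisy_c_o%d", q))
    ring <- gaussian_smooth(o, sigma_ring)
    for (p in seq_len(ring_points)) {
      phi <- (p - 1) * 2 * pi / ring_points
      dr <- round(radius * sin(phi)); dc <- round(radius * cos(phi))
      feats <- c(feats, list(shift_clamped(ring, dr, dc)))
      nms <- c(nms, sprintf("daisy_r1_p%d_o%d", p, q))
    }
  }
  arr <- array(0, dim = c(dim(base$features)[1] + length(feats), dim(image)))
  arr[seq_len(dim(base$features)[1]), , ] <- base$features
  for (f in seq_along(feats)) arr[dim(base$features)[1] + f, , ] <- feats[[f]]
  structure(list(features = arr, names = c(base$names, nms)),
            class = "FeatureStack")
}

#' Extract features according to a model configuration
#'
#' @param image 2D matrix.
#' @param feature_mode `"ilastik"` or `"daisy"`.
#' @param widths filter widths.
#' @param daisy list of DAISY parameters (`radius`, `orientations`,
#'   `ring_points`).
#' @return A `FeatureStack`.
#' @export
extract_features <- function(image, feature_mode = c("ilastik", "daisy"),
                             widths = c(1, 2, 5, 15),
                             daisy = list(radius = 8L, orientations = 4L,
                                          ring_points = 6L)) {
  feature_mode <- match.arg(feature_mode)
  if (feature_mode == "ilastik") ilastik_features(image, widths)
  else daisy_features(image, widths, radius = daisy$radius,
                      orientations = daisy$orientations,
                      ring_points = daisy$ring_points)
}

#' Resize an image for training/prediction
#'
#' Anti-aliased downscale by `factor` (in `(0, 1]`). Masks or probability
#' maps produced at the reduced scale are mapped back with
#' [upscale_nearest()] before post-processing.
#'
#' @param image 2D matrix.
#' @param factor scale factor, `0 < factor <= 1`; 1 is the identity.
#' @return The resized matrix.
#' @export
resize_for_training <- function(image, factor) {
  if (factor <= 0 || factor > 1) stopf("resize factor must be in (0, 1]")
  if (factor == 1) return(image)
  as.matrix(EBImage::resize(image, w = round(nrow(image) * factor),
                            h = round(ncol(image) * factor),
                            antialias = TRUE))
}

#' @rdname resize_for_training
#' @param target_dim integer `(rows, cols)` of the original image.
#' @export
upscale_nearest <- function(image, target_dim) {
  nr <- target_dim[1]; nc <- target_dim[2]
  ri <- pmin(pmax(round(seq_len(nr) * nrow(image) / nr), 1L), nrow(image))
  ci <- pmin(pmax(round(seq_len(nc) * ncol(image) / nc), 1L), ncol(image))
  image[ri, ci]
}
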