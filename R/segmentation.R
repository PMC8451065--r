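# Three-class pixel classification: training-set assembly, model fitting,
# probability prediction, mask derivation and morphological post-processing.

features_to_matrix <- function(fs) {
  nf <- dim(fs$features)[1]
  X <- t(matrix(fs$features, nrow = nf))
  colnames(X) <- fs$names
  X
}

#' Three-class label image from a binary mask
#'
#' The mask is dilated and eroded by `edge_width`; the band between the two
#' (straddling the contour) is the organoid-edge class, the eroded interior is
#' organoid proper, the rest background.
#'
#' @param mask a `BinaryMask` or logical matrix.
#' @param edge_width half-width of the edge band in pixels.
#' @return Integer matrix with 0 = background, 1 = organoid, 2 = edge.
#' @export
make_three_class_labels <- function(mask, edge_width = 2L) {
  m <- as_mask_matrix(mask)
  if (edge_width < 1) stopf("edge_width must be >= 1")
  if (!any(m)) stopf("degenerate mask: no foreground pixels")
  br <- disc_brush(edge_width)
  dil <- as.matrix(EBImage::dilate(m * 1, br)) > 0.5
  ero <- as.matrix(EBImage::erode(m * 1, br)) > 0.5
  lab <- matrix(0L, nrow(m), ncol(m))
  lab[dil & !ero] <- 2L
  lab[ero] <- 1L
  lab
}

#' Sample pixels into a training set
#'
#' A fraction of pixels (default 50%) is drawn at random; foreground classes
#' (organoid and edge) can be oversampled by `bias`, useful when the organoid
#' occupies a small part of the frame. Selection probabilities are
#' renormalised so the expected sample count stays `fraction * n_pixels`.
#'
#' @param features a `FeatureStack` from [extract_features()].
#' @param labels three-class label matrix from [make_three_class_labels()].
#' @param fraction fraction of pixels to draw, in `(0, 1]`.
#' @param bias foreground oversampling factor (>= 1).
#' @param seed optional RNG seed; sampling is deterministic given a seed.
#' @return A `TrainingSet`: `list(X, y, fraction, bias)` where `X` is the
#'   pixel-by-feature matrix and `y` holds classes 0/1/2.
#' @export
sample_pixels <- function(features, labels, fraction = 0.5, bias = 1,
                          seed = NULL) {
  if (fraction <= 0 || fraction > 1) stopf("fraction must be in (0, 1]")
  if (bias < 1) stopf("bias must be >= 1")
  y_all <- as.integer(labels)
  if (!all(0:2 %in% y_all))
    stopf("missing class in labels: need background, organoid and edge pixels")
  n <- length(y_all)
  w <- ifelse(y_all > 0L, bias, 1)
  p_sel <- pmin(fraction * n * w / sum(w), 1)
  sel <- with_seed(seed, runif(n) < p_sel)
  X <- features_to_matrix(features)[sel, , drop = FALSE]
  structure(list(X = X, y = y_all[sel], fraction = fraction, bias = bias),
            class = "TrainingSet")
}

#' @export
print.TrainingSet <- function(x, ...) {
  cat(sprintf("TrainingSet: %d pixels x %d features; classes %s\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%d:%d", 0:2, tabulate(x$y + 1L, 3L)),
                    collapse = " ")))
  invisible(x)
}

#' Train a three-class pixel classifier
#'
#' Either a multinomial logistic regression (via [nnet::multinom()]) or a
#' multilayer perceptron with exactly two hidden layers. Edge pixels receive a
#' higher training weight (default 2x) because they are the scarcest and the
#' most informative class. Features are standardised with training-set mean
#' and scale, which are stored in the bundle and re-applied at prediction.
#'
#' @param ts a `TrainingSet` from [sample_pixels()] or [build_training_set()].
#' @param kind `"logistic"` or `"mlp"`.
#' @param class_weights weights for classes (background, organoid, edge).
#' @param hidden hidden-layer sizes of the MLP (length 2).
#' @param maxit optimisation iterations.
#' @param seed RNG seed; training is deterministic given a seed.
#' @param feature_mode,filter_widths,resize_factor,edge_dilation_px,daisy
#'   feature-extraction configuration recorded in the bundle so prediction
#'   uses identical settings.
#' @return A `ModelBundle`.
#' @export
train_pixel_classifier <- function(ts, kind = c("logistic", "mlp"),
                                   class_weights = c(1, 1, 2),
                                   hidden = c(100, 50), maxit = 250L,
                                   seed = 1L,
                                   feature_mode = "ilastik",
                                   filter_widths = c(1, 2, 5, 15),
                                   resize_factor = 1,
                                   edge_dilation_px = 2L,
                                   daisy = list(radius = 8L,
                                                orientations = 4L,
                                                ring_points = 6L)) {
  kind <- match.arg(kind)
  stopifnot(inherits(ts, "TrainingSet"))
  if (length(unique(ts$y)) < 2)
    stopf("degenerate training set: a single class present")
  if (kind == "mlp" && length(hidden) != 2)
    stopf("the MLP uses exactly two hidden layers")
  mu <- colMeans(ts$X)
  sc <- apply(ts$X, 2, sd)
  sc[sc < 1e-12] <- 1
  Xs <- sweep(sweep(ts$X, 2, mu), 2, sc, "/")
  w <- class_weights[ts$y + 1L]
  if (kind == "logistic") {
    df <- data.frame(y = factor(ts$y, levels = 0:2), Xs)
    fit <- with_seed(seed,
      nnet::multinom(y ~ ., data = df, weights = w, trace = FALSE,
                     maxit = maxit, MaxNWts = 100000))
    beta <- rbind(0, coef(fit))   # baseline class 0 row of zeros
    weights <- list(beta = unname(beta))
  } else {
    weights <- mlp_train(Xs, ts$y + 1L, w, hidden = hidden, n_classes = 3L,
                         maxit = maxit, seed = seed)
  }
  structure(list(model_kind = kind, feature_mode = feature_mode,
                 filter_widths = filter_widths,
                 resize_factor = resize_factor,
                 edge_dilation_px = as.integer(edge_dilation_px),
                 class_weights = class_weights,
                 hidden_sizes = if (kind == "mlp") hidden else numeric(),
                 daisy = daisy,
                 feature_names = colnames(ts$X),
                 norm = list(mean = unname(mu), scale = unname(sc)),
                 weights = weights),
            class = "ModelBundle")
}

#' @export
print.ModelBundle <- function(x, ...) {
  cat(sprintf("ModelBundle: %s / %s features (widths %s), resize %g\n",
              x$model_kind, x$feature_mode,
              paste(x$filter_widths, collapse = ","), x$resize_factor))
  invisible(x)
}

#' Assemble a training set from images and masks
#'
#' Convenience wrapper: per image, optionally resize, extract features per the
#' configuration, derive three-class labels from the mask and sample pixels;
#' rows from all images are concatenated.
#'
#' @param images list of `ImageStack`s or matrices.
#' @param masks list of `BinaryMask`s or logical matrices (same length).
#' @param fraction,bias see [sample_pixels()].
#' @param seed RNG seed (per-image seeds are derived from it).
#' @inheritParams train_pixel_classifier
#' @return A `TrainingSet`.
#' @export
build_training_set <- function(images, masks, feature_mode = "ilastik",
                               filter_widths = c(1, 2, 5, 15),
                               resize_factor = 1, edge_dilation_px = 2L,
                               fraction = 0.5, bias = 1, seed = 1L,
                               daisy = list(radius = 8L, orientations = 4L,
                                            ring_points = 6L)) {
  stopifnot(length(images) == length(masks))
  parts <- vector("list", length(images))
  for (i in seq_along(images)) {
    img <- if (inherits(images[[i]], "ImageStack"))
      get_channel(images[[i]], 1L) else images[[i]]
    m <- as_mask_matrix(masks[[i]])
    if (resize_factor < 1) {
      img <- resize_for_training(img, resize_factor)
      m <- upscale_nearest(m, dim(img)) > 0.5
    }
    fs <- extract_features(img, feature_mode, filter_widths, daisy)
    labs <- make_three_class_labels(m, edge_dilation_px)
    parts[[i]] <- sample_pixels(fs, labs, fraction, bias,
                                seed = if (is.null(seed)) NULL else seed + i)
  }
  structure(list(X = do.call(rbind, lapply(parts, `[[`, "X")),
                 y = unlist(lapply(parts, `[[`, "y")),
                 fraction = fraction, bias = bias),
            class = "TrainingSet")
}

model_scores <- function(bundle, X) {
  Xs <- sweep(sweep(X, 2, bundle$norm$mean), 2, bundle$norm$scale, "/")
  if (bundle$model_kind == "logistic") {
    softmax_rows(cbind(1, Xs) %*% t(bundle$weights$beta))
  } else {
    mlp_predict(bundle$weights, Xs)
  }
}

#' Predict class probability maps for an image
#'
#' Features are extracted from the segmentation channel with the settings
#' stored in the bundle (including any resize factor; probability maps
#' computed at reduced scale are bilinearly upscaled and renormalised).
#'
#' @param image an `ImageStack` or a 2D matrix.
#' @param bundle a `ModelBundle`.
#' @param features optional precomputed `FeatureStack` (only honoured when the
#'   bundle's resize factor is 1).
#' @return A `ClassProbabilityMaps` object: array `(3, row, col)`, per-pixel
#'   probabilities of background / organoid / edge summing to 1.
#' @export
predict_probabilities <- function(image, bundle, features = NULL) {
  img <- if (inherits(image, "ImageStack")) get_channel(image, 1L) else image
  orig_dim <- dim(img)
  if (bundle$resize_factor < 1) {
    img <- resize_for_training(img, bundle$resize_factor)
    features <- NULL
  }
  if (is.null(features))
    features <- extract_features(img, bundle$feature_mode,
                                 bundle$filter_widths, bundle$daisy)
  X <- features_to_matrix(features)
  if (ncol(X) != length(bundle$norm$mean))
    stopf("feature count (%d) incompatible with model (%d features)",
          ncol(X), length(bundle$norm$mean))
  p <- model_scores(bundle, X)
  maps <- array(0, dim = c(3L, dim(img)))
  for (k in 1:3) maps[k, , ] <- matrix(p[, k], dim(img)[1], dim(img)[2])
  if (bundle$resize_factor < 1) {
    up <- array(0, dim = c(3L, orig_dim))
    for (k in 1:3)
      up[k, , ] <- as.matrix(EBImage::resize(maps[k, , ], w = orig_dim[1],
                                             h = orig_dim[2]))
    tot <- up[1, , ] + up[2, , ] + up[3, , ]
    for (k in 1:3) up[k, , ] <- up[k, , ] / tot
    maps <- up
  }
  structure(maps, class = "ClassProbabilityMaps")
}

#' Classifier mask: per-pixel argmax of the probability maps
#'
#' Foreground is every pixel whose most probable class is organoid proper or
#' edge. Ties go to the lowest class index, except that organoid proper is
#' preferred over edge.
#'
#' @param p a `ClassProbabilityMaps` array.
#' @return A `BinaryMask` with provenance `"classifier"`.
#' @export
classifier_mask <- function(p) {
  p0 <- p[1, , ]; p1 <- p[2, , ]; p2 <- p[3, , ]
  m <- pmax(p0, p1, p2)
  cls <- ifelse(p0 >= m, 0L, ifelse(p1 >= m, 1L, 2L))
  binary_mask(cls > 0L, provenance = "classifier")
}

#' Watershed mask from the edge-probability topography
#'
#' Priority flooding of the edge-probability map from two seeds: the centre
#' of mass of the organoid-proper probability map (interior seed) and the
#' image border (background seed). The foreground is the catchment basin of
#' the interior seed, so the basin boundary locks onto the edge-probability
#' ridge surrounding the organoid.
#'
#' @inheritParams classifier_mask
#' @return A `BinaryMask` with provenance `"watershed"`.
#' @export
watershed_mask <- function(p) {
  edge <- p[3, , ]; org <- p[2, , ]
  tot <- sum(org)
  if (!is.finite(tot) || tot <= 0)
    stopf("degenerate probability maps: organoid-proper map has no mass")
  nr <- nrow(org); nc <- ncol(org)
  ri <- round(sum(row(org) * org) / tot)
  ci <- round(sum(col(org) * org) / tot)
  if (ri < 1 || ri > nr || ci < 1 || ci > nc)
    stopf("degenerate probability maps: centre of mass outside the image")
  seeds <- matrix(0L, nr, nc)
  seeds[1, ] <- 2L; seeds[nr, ] <- 2L; seeds[, 1] <- 2L; seeds[, nc] <- 2L
  seeds[ri, ci] <- 1L
  basins <- .watershed_flood(edge, seeds)
  binary_mask(basins == 1L, provenance = "watershed")
}

#' Morphological post-processing to a single-object mask
#'
#' Fills holes, removes objects below `min_size`, applies an optional binary
#' dilation, then keeps only the largest connected component (any additional
#' component -- including those touching the image border -- is discarded;
#' the largest object itself is retained even when it touches the border).
#'
#' @param mask a `BinaryMask` or logical matrix.
#' @param fill_holes fill internal holes?
#' @param min_size minimum object area in px^2.
#' @param dilation_px radius of a final binary dilation (0 = none).
#' @return A `BinaryMask` with at most one connected component. If nothing
#'   survives, the mask is empty and carries the attribute
#'   `empty_after_postprocess = TRUE`.
#' @export
postprocess_mask <- function(mask, fill_holes = TRUE, min_size = 100L,
                             dilation_px = 0L) {
  prov <- if (inherits(mask, "BinaryMask")) mask$provenance else "manual"
  m <- as_mask_matrix(mask)
  if (fill_holes && any(m))
    m <- as.matrix(EBImage::fillHull(m * 1)) > 0.5
  if (any(m) && min_size > 0) {
    lab <- label_components(m)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_size)
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  if (any(m) && dilation_px > 0)
    m <- as.matrix(EBImage::dilate(m * 1, disc_brush(dilation_px))) > 0.5
  if (any(m)) {
    lab <- label_components(m)
    sizes <- tabulate(lab[lab > 0])
    m <- lab == which.max(sizes)
  }
  out <- binary_mask(m, provenance = prov)
  if (!any(m)) attr(out, "empty_after_postprocess") <- TRUE
  out
}
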