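# Synthetic single-organoid images with full ground truth. Channel 1 mimics
# bright-field imaging: a textured interior bounded by a darker defocused
# rim on a noisy, unevenly illuminated background with optional debris --
# the features a three-class (background / organoid / edge) pixel classifier
# has to learn. Fluorescence channels are rendered from prescribed spatial
# patterns (uniform, angular pole, axial cosh gradient, shell).

#' Specification of a synthetic organoid image
#'
#' @param shape `"disk"`, `"ellipse"`, `"flower"` or `"bent_bar"`.
#' @param canvas image size `(rows, cols)` in px.
#' @param radius disk/flower base radius, px.
#' @param axes ellipse semi-axes `(a, b)`, px.
#' @param angle ellipse orientation, radians.
#' @param p,eps flower lobe count and relative lobe amplitude
#'   (`r = radius (1 + eps cos(p theta))`).
#' @param length,width,curvature bent-bar centerline length, bar width and
#'   centerline curvature (1/px; 0 = straight).
#' @param center object centre `(row, col)`; default canvas centre.
#' @param fg_level,bg_level,rim_level,rim_width bright-field rendering:
#'   interior and background grey levels, rim grey level and full rim width
#'   (px); the dark rim straddles the object boundary as a defocused edge
#'   does.
#' @param texture_sd,noise_sd smooth interior texture amplitude and additive
#'   Gaussian pixel noise.
#' @param illumination relative amplitude of a multiplicative left-to-right
#'   illumination tilt.
#' @param n_debris,debris_radius number of debris specks (placed outside the
#'   organoid, possibly touching the border) and their radius range, px.
#' @param fluorescence named list of fluorescence channel specs; each is a
#'   list with `pattern` (`"uniform"`, `"angular_pole"`, `"axial_gradient"`,
#'   `"shell"`) and its parameters (`base`, `amp`, and per pattern:
#'   `theta_star`/`kappa`, `lambda_frac`/`x0_frac`).
#' @param seed RNG seed; the spec plus seed fully determines the image.
#' @return A `SyntheticSpec`.
#' @export
synthetic_spec <- function(shape = c("disk", "ellipse", "flower", "bent_bar"),
                           canvas = c(192L, 192L),
                           radius = 58, axes = c(66, 44), angle = pi / 6,
                           p = 5L, eps = 0.2,
                           length = 120, width = 40, curvature = 0.006,
                           center = NULL,
                           fg_level = 0.56, bg_level = 0.45,
                           rim_level = 0.25, rim_width = 3,
                           texture_sd = 0.04, noise_sd = 0.02,
                           illumination = 0.08,
                           n_debris = 3L, debris_radius = c(2, 5),
                           fluorescence = list(), seed = 1L) {
  shape <- match.arg(shape)
  if (is.null(center)) center <- (canvas + 1) / 2
  structure(list(shape = shape, canvas = as.integer(canvas), radius = radius,
                 axes = axes, angle = angle, p = as.integer(p), eps = eps,
                 length = length, width = width, curvature = curvature,
                 center = center, fg_level = fg_level, bg_level = bg_level,
                 rim_level = rim_level, rim_width = rim_width,
                 texture_sd = texture_sd, noise_sd = noise_sd,
                 illumination = illumination, n_debris = n_debris,
                 debris_radius = debris_radius, fluorescence = fluorescence,
                 seed = seed),
            class = "SyntheticSpec")
}

# Truth mask, analytic area and axis metadata for a spec.
synth_shape <- function(spec) {
  nr <- spec$canvas[1]; nc <- spec$canvas[2]
  r0 <- spec$center[1]; c0 <- spec$center[2]
  R <- matrix(seq_len(nr), nr, nc) - r0
  C <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - c0
  meta <- list(shape = spec$shape)
  axis_s <- NULL    # normalized axial coordinate per pixel (for gradients)
  if (spec$shape == "disk") {
    mask <- R^2 + C^2 <= spec$radius^2
    meta$area_true <- pi * spec$radius^2
    meta$radius <- spec$radius
    axis_s <- (C + spec$radius) / (2 * spec$radius)
  } else if (spec$shape == "ellipse") {
    a <- spec$axes[1]; b <- spec$axes[2]; an <- spec$angle
    X <- C * cos(an) - R * sin(an); Y <- C * sin(an) + R * cos(an)
    mask <- (X / a)^2 + (Y / b)^2 <= 1
    meta$area_true <- pi * a * b
    meta$axes <- spec$axes; meta$angle <- an
    axis_s <- (X + a) / (2 * a)
  } else if (spec$shape == "flower") {
    theta <- atan2(-R, C)
    rad <- sqrt(R^2 + C^2)
    mask <- rad <= spec$radius * (1 + spec$eps * cos(spec$p * theta))
    meta$area_true <- pi * spec$radius^2 * (1 + spec$eps^2 / 2)
    meta$p <- spec$p; meta$eps <- spec$eps; meta$radius <- spec$radius
    axis_s <- (C + spec$radius) / (2 * spec$radius)
  } else {  # bent_bar
    len <- spec$length; w <- spec$width; kap <- spec$curvature
    if (kap < 1e-8) {
      d_axis <- abs(R)
      s_along <- C
      inside_span <- abs(s_along) <= len / 2
      dist_end <- pmin(sqrt((C - len / 2)^2 + R^2),
                       sqrt((C + len / 2)^2 + R^2))
      mask <- (inside_span & d_axis <= w / 2) | dist_end <= w / 2
      # axial coordinate runs pole to pole (end caps included)
      s_norm <- (s_along + len / 2 + w / 2) / (len + w)
      alpha <- seq(-len / 2, len / 2, by = 1)
      centerline <- cbind(row = rep(r0, length(alpha)), col = c0 + alpha)
    } else {
      Rc <- 1 / kap
      phi <- len / Rc
      if (phi > pi * 1.2) stopf("bent bar arc exceeds the canvas geometry")
      # arc centre below the canvas centre; shift up by half the sagitta so
      # the bar is vertically centred
      Or <- r0 + Rc - Rc * (1 - cos(phi / 2)) / 2
      rho <- sqrt((R - (Or - r0))^2 + C^2)
      beta <- atan2(C, (Or - r0) - R)     # angle about the arc centre
      in_band <- abs(rho - Rc) <= w / 2 & abs(beta) <= phi / 2
      ends <- cbind(Or - Rc * cos(c(-1, 1) * phi / 2) - r0,
                    Rc * sin(c(-1, 1) * phi / 2))
      dist_end <- pmin(sqrt((R - ends[1, 1])^2 + (C - ends[1, 2])^2),
                       sqrt((R - ends[2, 1])^2 + (C - ends[2, 2])^2))
      mask <- in_band | dist_end <= w / 2
      # axial coordinate pole to pole: beta extends smoothly into the caps
      s_norm <- (beta * Rc + len / 2 + w / 2) / (len + w)
      alpha <- seq(-phi / 2, phi / 2, length.out = max(2, round(len)))
      centerline <- cbind(row = Or - Rc * cos(alpha),
                          col = c0 + Rc * sin(alpha))
    }
    meta$area_true <- len * w + pi * (w / 2)^2
    meta$length <- len; meta$width <- w; meta$curvature <- kap
    # pole-to-pole midline length: the rounded end caps extend the spine by
    # w/2 at each pole
    meta$length_total <- len + w
    meta$centerline <- centerline
    axis_s <- pmin(pmax(s_norm, 0), 1)
  }
  if (!any(mask) || any(mask[1, ]) || any(mask[nrow(mask), ]) ||
      any(mask[, 1]) || any(mask[, ncol(mask)]))
    stopf("shape exceeds the canvas")
  list(mask = mask, meta = meta, axis_s = axis_s)
}

smooth_noise <- function(dims, sigma, sd) {
  gaussian_smooth(matrix(rnorm(prod(dims)), dims[1], dims[2]), sigma) *
    sd / (1 / (2 * sigma * sqrt(pi)))   # renormalize to ~unit variance
}

quantize16 <- function(x) round(pmin(pmax(x, 0), 1) * 65535) / 65535

#' Generate a synthetic organoid image with ground truth
#'
#' @param spec a [synthetic_spec()].
#' @return `list(image, mask, metadata)`: an `ImageStack` (bright-field plus
#'   any fluorescence channels), the ground-truth `BinaryMask`, and metadata
#'   holding every true parameter (analytic area, centerline, pole angle,
#'   decay length, ...).
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  with_seed(spec$seed, {
    sh <- synth_shape(spec)
    mask <- sh$mask
    nr <- nrow(mask); nc <- ncol(mask)
    dm <- as.matrix(EBImage::distmap(mask * 1))
    # defocused bright-field edge: the dark rim straddles the object
    # boundary, extending ~rim_width/2 both inward and outward
    dm_out <- as.matrix(EBImage::distmap((!mask) * 1))
    hw <- spec$rim_width / 2
    rim <- (mask & dm <= hw + 0.5) | (!mask & dm_out <= hw + 0.5)

    bf <- matrix(spec$bg_level, nr, nc)
    bf[mask] <- spec$fg_level
    bf <- bf + smooth_noise(c(nr, nc), 3, spec$texture_sd) * mask
    bf[rim] <- spec$rim_level
    # debris: dark specks outside the (dilated) organoid, may touch borders
    dil <- as.matrix(EBImage::dilate(mask * 1, disc_brush(6L))) > 0.5
    placed <- 0L; tries <- 0L
    debris_mask <- matrix(FALSE, nr, nc)
    while (placed < spec$n_debris && tries < 200L) {
      tries <- tries + 1L
      dr <- runif(1, spec$debris_radius[1], spec$debris_radius[2])
      pr <- runif(1, 1, nr); pc <- runif(1, 1, nc)
      if (pr >= 1 && pr <= nr && pc >= 1 && pc <= nc &&
          !dil[round(pr), round(pc)]) {
        R <- matrix(seq_len(nr), nr, nc) - pr
        C <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - pc
        speck <- R^2 + C^2 <= dr^2 & !dil
        debris_mask <- debris_mask | speck
        placed <- placed + 1L
      }
    }
    bf[debris_mask] <- spec$rim_level + 0.05
    tilt <- 1 + spec$illumination *
      (matrix(seq_len(nc), nr, nc, byrow = TRUE) / nc - 0.5)
    bf <- bf * tilt + matrix(rnorm(nr * nc, sd = spec$noise_sd), nr, nc)

    channels <- list(ch0 = quantize16(bf))
    meta <- sh$meta
    meta$mask_area <- sum(mask)
    meta$fluorescence <- list()
    for (nm in names(spec$fluorescence)) {
      fl <- spec$fluorescence[[nm]]
      base <- if (is.null(fl$base)) 0.1 else fl$base
      amp <- if (is.null(fl$amp)) 0.5 else fl$amp
      img <- matrix(base, nr, nc)
      if (fl$pattern == "uniform") {
        img[mask] <- base + amp
      } else if (fl$pattern == "angular_pole") {
        kappa <- if (is.null(fl$kappa)) 4 else fl$kappa
        rr <- row(mask) - mean(row(mask)[mask])
        cc <- col(mask) - mean(col(mask)[mask])
        theta <- atan2(-rr, cc)
        img[mask] <- base +
          amp * exp(kappa * (cos(theta[mask] - fl$theta_star) - 1))
        meta$fluorescence[[nm]] <- list(pattern = "angular_pole",
                                        theta_star = fl$theta_star,
                                        kappa = kappa)
      } else if (fl$pattern == "axial_gradient") {
        lam <- fl$lambda_frac; x0 <- fl$x0_frac
        img[mask] <- base + amp * decay_model(sh$axis_s[mask], 1, lam, x0, 1)
        meta$fluorescence[[nm]] <- list(pattern = "axial_gradient",
                                        lambda_frac = lam, x0_frac = x0)
      } else if (fl$pattern == "shell") {
        img[mask] <- base + amp * (1 - dm[mask] / max(dm))
        meta$fluorescence[[nm]] <- list(pattern = "shell")
      } else stopf("unknown fluorescence pattern '%s'", fl$pattern)
      if (is.null(meta$fluorescence[[nm]]))
        meta$fluorescence[[nm]] <- list(pattern = fl$pattern)
      meta$fluorescence[[nm]]$base <- base
      meta$fluorescence[[nm]]$amp <- amp
      noise <- if (is.null(fl$noise_sd)) spec$noise_sd else fl$noise_sd
      img <- img + matrix(rnorm(nr * nc, sd = noise), nr, nc)
      channels[[nm]] <- quantize16(img)
    }
    pix <- array(0, dim = c(length(channels), nr, nc))
    for (k in seq_along(channels)) pix[k, , ] <- channels[[k]]
    list(image = image_stack(pix, channel_names = names(channels)),
         mask = binary_mask(mask, provenance = "manual"),
         metadata = meta)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n` multi-channel TIFFs plus ground-truth masks, a `manifest.csv`
#' (image id, files, training flag, condition/replicate/timepoint) and a
#' `metadata.json` with the per-image ground truth, following the dataset
#' folder convention used by [run_pipeline()]. The first `train_n` images
#' are flagged as the training set.
#'
#' @param n number of images.
#' @param folder output folder.
#' @param shapes shape kinds cycled over the images.
#' @param seed master seed; per-image seeds are derived deterministically.
#' @param train_n number of training images.
#' @param fluorescence fluorescence channel specs applied to every image.
#' @param canvas canvas size.
#' @return The manifest data frame, invisibly.
#' @export
generate_dataset <- function(n, folder,
                             shapes = c("disk", "ellipse", "flower",
                                        "bent_bar"),
                             seed = 1L, train_n = 3L,
                             fluorescence = list(), canvas = c(192L, 192L)) {
  dir.create(folder, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(folder, "trainingset"), showWarnings = FALSE)
  rows <- list(); metas <- list()
  sc <- min(canvas) / 192   # shape defaults are sized for the 192 px canvas
  for (i in seq_len(n)) {
    shape <- shapes[((i - 1L) %% length(shapes)) + 1L]
    sp <- synthetic_spec(shape = shape, canvas = canvas,
                         radius = if (shape == "flower") 52 * sc else 58 * sc,
                         axes = c(66, 44) * sc,
                         length = 120 * sc, width = 40 * sc,
                         curvature = 0.006 / sc,
                         fluorescence = fluorescence,
                         seed = seed * 1000L + i)
    gen <- synth_generate(sp)
    id <- sprintf("img_%03d", i)
    img_file <- file.path(folder, paste0(id, ".tif"))
    mask_file <- file.path(folder, paste0(id, "_truth.tif"))
    write_image(gen$image, img_file)
    write_mask(gen$mask, mask_file)
    training <- i <= train_n
    if (training) {
      write_image(gen$image, file.path(folder, "trainingset",
                                       paste0(id, ".tif")))
      write_mask(gen$mask, file.path(folder, "trainingset",
                                     paste0(id, "_mask.tif")))
    }
    rows[[i]] <- data.frame(image_id = id, file = basename(img_file),
                            truth_file = basename(mask_file),
                            training = training, shape = shape,
                            condition = "synthetic", replicate = "r1",
                            timepoint = i, stringsAsFactors = FALSE)
    metas[[id]] <- gen$metadata
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(folder, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(metas, file.path(folder, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
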