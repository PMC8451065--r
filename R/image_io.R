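#' Multi-channel image stack
#'
#' Container for a single-organoid 2D image. Pixels are stored channel-first
#' (`[channel, row, col]`); channel 1 is the segmentation channel (typically
#' bright-field), remaining channels are fluorescence.
#'
#' @param pixels a numeric matrix (promoted to one channel) or a 3D array
#'   `(channel, row, col)` of non-negative intensities.
#' @param channel_names optional character vector, one name per channel.
#' @param pixel_size optional physical pixel size (micrometres per pixel).
#' @return An object of class `ImageStack`.
#' @export
image_stack <- function(pixels, channel_names = NULL, pixel_size = NULL) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(1L, dim(pixels)))
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stopf("pixels must be a matrix or a (channel, row, col) array")
  nch <- dim(pixels)[1]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nch) - 1L)
  if (length(channel_names) != nch)
    stopf("channel_names length (%d) != number of channels (%d)",
          length(channel_names), nch)
  structure(list(pixels = pixels, channel_names = channel_names,
                 pixel_size = pixel_size),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("ImageStack: %d channel(s), %d x %d px [%s]\n",
              d[1], d[2], d[3], paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' @rdname image_stack
#' @param x an `ImageStack`.
#' @param channel channel index (1-based).
#' @export
get_channel <- function(x, channel = 1L) {
  stopifnot(inherits(x, "ImageStack"))
  x$pixels[channel, , ]
}

#' Binary segmentation mask
#'
#' @param pixels logical matrix (or 0/1 numeric matrix).
#' @param provenance one of `"classifier"`, `"watershed"`, `"manual"`,
#'   `"imported"`.
#' @return An object of class `BinaryMask` with fields `pixels` (logical
#'   matrix) and `provenance`. A post-processing step that empties the mask
#'   sets the attribute `empty_after_postprocess`.
#' @export
binary_mask <- function(pixels, provenance = c("classifier", "watershed",
                                               "manual", "imported")) {
  provenance <- match.arg(provenance)
  structure(list(pixels = as_mask_matrix(pixels), provenance = provenance),
            class = "BinaryMask")
}

#' @export
print.BinaryMask <- function(x, ...) {
  cat(sprintf("BinaryMask (%s): %d x %d px, area %d\n", x$provenance,
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

#' Read a multi-channel TIFF image
#'
#' Multi-page TIFFs become one channel per page; single-page files are
#' promoted to 1-channel stacks. Per-pixel sample planes of a single page are
#' interpreted as channels.
#'
#' @param path path to a TIFF file.
#' @inheritParams image_stack
#' @return An [image_stack()].
#' @export
read_image <- function(path, channel_names = NULL, pixel_size = NULL) {
  if (!file.exists(path)) stopf("cannot read image: no such file '%s'", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stopf("unreadable TIFF '%s': %s",
                                              path, conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  planes <- list()
  for (p in pages) {
    nd <- length(dim(p))
    if (is.null(dim(p)) || nd > 3L)
      stopf("unsupported layout in '%s': expected (channel, row, col)", path)
    if (nd == 3L) {
      if (length(pages) > 1L)
        stopf("unsupported layout in '%s': multi-page with multi-sample pages",
              path)
      planes <- lapply(seq_len(dim(p)[3]), function(k) p[, , k])
    } else planes <- c(planes, list(p))
  }
  shp <- dim(planes[[1]])
  if (!all(vapply(planes, function(m) identical(dim(m), shp), logical(1))))
    stopf("channel pages of '%s' differ in shape", path)
  pix <- array(0, dim = c(length(planes), shp))
  for (k in seq_along(planes)) pix[k, , ] <- planes[[k]]
  image_stack(pix, channel_names = channel_names, pixel_size = pixel_size)
}

#' Write an image stack to a multi-page TIFF
#'
#' Intensities must lie in `[0, 1]`; they are quantised to the requested bit
#' depth (16-bit by default, which round-trips exactly for values on the
#' 16-bit grid).
#'
#' @param x an `ImageStack` or a matrix.
#' @param path output path.
#' @param bits bits per sample (8 or 16).
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path, bits = 16L) {
  if (is.matrix(x)) x <- image_stack(x)
  pages <- lapply(seq_len(dim(x$pixels)[1]), function(k) {
    m <- x$pixels[k, , ]
    if (min(m) < 0 || max(m) > 1)
      stopf("intensities must be within [0, 1] for TIFF export")
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' @rdname write_image
#' @param mask a `BinaryMask` or logical matrix.
#' @export
write_mask <- function(mask, path) {
  m <- as_mask_matrix(mask)
  tiff::writeTIFF(m * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_image
#' @param provenance provenance recorded on the mask read back.
#' @export
read_mask <- function(path, provenance = "imported") {
  binary_mask(tiff::readTIFF(path) > 0.5, provenance = provenance)
}

#' Compile per-channel image files into multi-channel TIFFs
#'
#' High-content screening systems often emit one file per channel. Files named
#' `<stem><channel_suffix><ext>` are grouped by stem and written as one
#' multi-page TIFF per stem, channels in the order of `channel_suffixes`
#' (segmentation channel first).
#'
#' @param folder directory holding the per-channel files.
#' @param channel_suffixes character vector of filename suffixes, e.g.
#'   `c("_ch0", "_ch1")`.
#' @param out_dir output directory (created if needed); defaults to `folder`.
#' @param ext filename extension of the input files.
#' @return Character vector of the written file paths.
#' @export
compile_channels <- function(folder, channel_suffixes, out_dir = folder,
                             ext = ".tif") {
  stopifnot(length(channel_suffixes) >= 1)
  files <- list.files(folder, pattern = paste0("\\", ext, "$"))
  suff1 <- paste0(channel_suffixes[1], ext)
  stems <- sub(paste0(suff1, "$"), "",
               files[endsWith(files, suff1)])
  if (length(stems) == 0) stopf("no files matching '*%s' in %s", suff1, folder)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  missing <- character(); bad_shape <- character()
  out <- character()
  for (stem in stems) {
    paths <- file.path(folder, paste0(stem, channel_suffixes, ext))
    if (!all(file.exists(paths))) { missing <- c(missing, stem); next }
    mats <- lapply(paths, function(p) get_channel(read_image(p), 1L))
    shp <- dim(mats[[1]])
    if (!all(vapply(mats, function(m) identical(dim(m), shp), logical(1)))) {
      bad_shape <- c(bad_shape, stem); next
    }
    pix <- array(0, dim = c(length(mats), shp))
    for (k in seq_along(mats)) pix[k, , ] <- mats[[k]]
    p_out <- file.path(out_dir, paste0(stem, ext))
    write_image(image_stack(pix), p_out)
    out <- c(out, p_out)
  }
  if (length(missing))
    stopf("missing channel files for stem(s): %s",
          paste(missing, collapse = ", "))
  if (length(bad_shape))
    stopf("channel shape mismatch for stem(s): %s",
          paste(bad_shape, collapse = ", "))
  out
}

#' Split a multi-object image into single-object crops
#'
#' For images holding several organoids with a pre-made labelled mask
#' (e.g. from thresholding or third-party software), each labelled object is
#' cropped with a margin and paired with its binary mask, ready for
#' per-organoid quantification.
#'
#' @param image an `ImageStack`.
#' @param labeled_mask integer matrix, 0 = background, positive = object label.
#' @param margin padding around each object's bounding box, in pixels; crops
#'   are clipped to the image bounds.
#' @param out_dir if non-`NULL`, crops are also written as
#'   `<prefix>_<label>.tif` / `<prefix>_<label>_mask.tif`.
#' @param prefix filename prefix when writing.
#' @return List with one element per object:
#'   `list(image, mask, label, bbox)`. An empty label image yields an empty
#'   list.
#' @export
split_objects <- function(image, labeled_mask, margin = 20L, out_dir = NULL,
                          prefix = "object") {
  stopifnot(inherits(image, "ImageStack"))
  if (any(labeled_mask < 0) || any(labeled_mask != round(labeled_mask)))
    stopf("labeled_mask must hold non-negative integers")
  labs <- sort(setdiff(unique(as.integer(labeled_mask)), 0L))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  nr <- nrow(labeled_mask); nc <- ncol(labeled_mask)
  out <- vector("list", length(labs))
  for (k in seq_along(labs)) {
    idx <- which(labeled_mask == labs[k], arr.ind = TRUE)
    r0 <- max(1L, min(idx[, 1]) - margin); r1 <- min(nr, max(idx[, 1]) + margin)
    c0 <- max(1L, min(idx[, 2]) - margin); c1 <- min(nc, max(idx[, 2]) + margin)
    crop <- image$pixels[, r0:r1, c0:c1, drop = FALSE]
    m <- labeled_mask[r0:r1, c0:c1] == labs[k]
    stack <- image_stack(crop, channel_names = image$channel_names,
                         pixel_size = image$pixel_size)
    mask <- binary_mask(m, provenance = "imported")
    if (!is.null(out_dir)) {
      write_image(stack, file.path(out_dir,
                                   sprintf("%s_%03d.tif", prefix, labs[k])))
      write_mask(mask, file.path(out_dir,
                                 sprintf("%s_%03d_mask.tif", prefix, labs[k])))
    }
    out[[k]] <- list(image = stack, mask = mask, label = labs[k],
                     bbox = c(r0, r1, c0, c1))
  }
  out
}

# ---- model persistence ------------------------------------------------------

serialize_vec <- function(x) paste(num_chr(x), collapse = ";")
deserialize_vec <- function(s) as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])

#' Persist a trained segmentation model as CSV files
#'
#' The model folder holds three plain-text files: `model_info.csv`
#' (key/value configuration: model kind, feature mode, filter widths, resize
#' factor, edge dilation, class weights, hidden sizes), `normalization.csv`
#' (per-feature mean and scale) and `weights.csv` (long-format numeric
#' parameters, one row per matrix entry). Doubles are written with 17
#' significant digits, so `load_model(save_model(b))` reproduces predictions
#' bit-identically.
#'
#' @param bundle a `ModelBundle` as returned by [train_pixel_classifier()].
#' @param folder model folder (created if needed).
#' @return `folder`, invisibly.
#' @export
save_model <- function(bundle, folder) {
  stopifnot(inherits(bundle, "ModelBundle"))
  dir.create(folder, showWarnings = FALSE, recursive = TRUE)
  info <- data.frame(
    key = c("model_kind", "feature_mode", "filter_widths", "resize_factor",
            "edge_dilation_px", "class_weights", "hidden_sizes",
            "daisy_radius", "daisy_orientations", "daisy_ring_points",
            "feature_names"),
    value = c(bundle$model_kind, bundle$feature_mode,
              serialize_vec(bundle$filter_widths),
              num_chr(bundle$resize_factor),
              as.character(bundle$edge_dilation_px),
              serialize_vec(bundle$class_weights),
              serialize_vec(bundle$hidden_sizes),
              as.character(bundle$daisy$radius),
              as.character(bundle$daisy$orientations),
              as.character(bundle$daisy$ring_points),
              paste(bundle$feature_names, collapse = ";")),
    stringsAsFactors = FALSE)
  write.csv(info, file.path(folder, "model_info.csv"), row.names = FALSE)
  norm <- data.frame(feature = bundle$feature_names,
                     mean = num_chr(bundle$norm$mean),
                     scale = num_chr(bundle$norm$scale),
                     stringsAsFactors = FALSE)
  write.csv(norm, file.path(folder, "normalization.csv"), row.names = FALSE)
  rows <- do.call(rbind, lapply(names(bundle$weights), function(nm) {
    w <- bundle$weights[[nm]]
    idx <- which(!is.na(w) | TRUE, arr.ind = TRUE)
    data.frame(matrix = nm, row = idx[, 1], col = idx[, 2],
               nrow = nrow(w), ncol = ncol(w),
               value = num_chr(w[idx]), stringsAsFactors = FALSE)
  }))
  write.csv(rows, file.path(folder, "weights.csv"), row.names = FALSE)
  invisible(folder)
}

#' @rdname save_model
#' @export
load_model <- function(folder) {
  for (f in c("model_info.csv", "normalization.csv", "weights.csv"))
    if (!file.exists(file.path(folder, f)))
      stopf("cannot load model: missing '%s' in %s", f, folder)
  info <- read.csv(file.path(folder, "model_info.csv"),
                   stringsAsFactors = FALSE, colClasses = "character")
  kv <- setNames(info$value, info$key)
  need <- c("model_kind", "feature_mode", "filter_widths", "resize_factor",
            "edge_dilation_px", "class_weights")
  miss <- setdiff(need, names(kv))
  if (length(miss))
    stopf("corrupt model_info.csv: missing field(s) %s",
          paste(miss, collapse = ", "))
  norm <- read.csv(file.path(folder, "normalization.csv"),
                   stringsAsFactors = FALSE, colClasses = "character")
  wtab <- read.csv(file.path(folder, "weights.csv"),
                   stringsAsFactors = FALSE,
                   colClasses = c(value = "character"))
  weights <- lapply(split(wtab, wtab$matrix), function(d) {
    w <- matrix(0, d$nrow[1], d$ncol[1])
    w[cbind(d$row, d$col)] <- as.numeric(d$value)
    w
  })
  # preserve layer order (W1, b1, W2, ...) rather than alphabetical
  ord <- unique(wtab$matrix)
  weights <- weights[ord]
  structure(list(
    model_kind = kv[["model_kind"]],
    feature_mode = kv[["feature_mode"]],
    filter_widths = deserialize_vec(kv[["filter_widths"]]),
    resize_factor = as.numeric(kv[["resize_factor"]]),
    edge_dilation_px = as.integer(kv[["edge_dilation_px"]]),
    class_weights = deserialize_vec(kv[["class_weights"]]),
    hidden_sizes = deserialize_vec(kv[["hidden_sizes"]]),
    daisy = list(radius = as.integer(kv[["daisy_radius"]]),
                 orientations = as.integer(kv[["daisy_orientations"]]),
                 ring_points = as.integer(kv[["daisy_ring_points"]])),
    feature_names = strsplit(kv[["feature_names"]], ";", fixed = TRUE)[[1]],
    norm = list(mean = as.numeric(norm$mean), scale = as.numeric(norm$scale)),
    weights = weights), class = "ModelBundle")
}

# ---- quantification records -------------------------------------------------

#' Quantification record for one image
#'
#' @param image_id image identifier (filename stem).
#' @param morphometrics named numeric vector/list of shape descriptors.
#' @param profiles named list; per fluorescence channel a list with elements
#'   `average`, `background` and `profiles` (named [intensity_profile()]s),
#'   optionally `decay` (a [fit_decay()] result).
#' @param locoefa optional list `list(L = numeric, cutoff_mode = int)`.
#' @param condition,replicate,timepoint group labels.
#' @return An object of class `QuantRecord`.
#' @export
quant_record <- function(image_id, morphometrics = list(), profiles = list(),
                         locoefa = NULL, condition = NA_character_,
                         replicate = NA_character_, timepoint = NA_real_) {
  structure(list(image_id = image_id, condition = condition,
                 replicate = replicate, timepoint = timepoint,
                 morphometrics = as.list(morphometrics),
                 locoefa = locoefa, channels = profiles),
            class = "QuantRecord")
}

flatten_quant <- function(records) {
  rows <- list()
  add <- function(rec, field, coordinate, value, n_pixels = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      image_id = rec$image_id, condition = rec$condition,
      replicate = rec$replicate, timepoint = rec$timepoint,
      field = field, coordinate = coordinate, value = value,
      n_pixels = n_pixels, stringsAsFactors = FALSE)
  }
  for (rec in records) {
    for (nm in names(rec$morphometrics))
      add(rec, paste0("morpho.", nm), NA_real_,
          as.numeric(rec$morphometrics[[nm]]))
    if (!is.null(rec$locoefa)) {
      L <- rec$locoefa$L
      add(rec, "locoefa.cutoff_mode", NA_real_, rec$locoefa$cutoff_mode)
      for (i in seq_along(L)) add(rec, "locoefa.L", i - 1, L[i])
    }
    for (ch in names(rec$channels)) {
      cd <- rec$channels[[ch]]
      if (!is.null(cd$average)) add(rec, paste0(ch, ".average"), NA, cd$average)
      if (!is.null(cd$background))
        add(rec, paste0(ch, ".background"), NA, cd$background)
      for (pk in names(cd$profiles)) {
        pr <- cd$profiles[[pk]]
        for (i in seq_along(pr$coordinates))
          add(rec, paste0(ch, ".", pk), pr$coordinates[i], pr$values[i],
              pr$n_pixels[i])
      }
      if (!is.null(cd$decay))
        for (nm in c("A0", "lambda", "x0", "L", "rmse"))
          add(rec, paste0(ch, ".decay.", nm), NA, cd$decay[[nm]])
    }
  }
  if (length(rows) == 0)
    return(data.frame(image_id = character(), condition = character(),
                      replicate = character(), timepoint = numeric(),
                      field = character(), coordinate = numeric(),
                      value = numeric(), n_pixels = numeric()))
  do.call(rbind, rows)
}

#' Export quantification records
#'
#' JSON preserves the nested record structure; `csv` flattens to a long table
#' with one row per scalar or per profile sample (with its axis coordinate).
#' `xls` writes the same table as tab-separated text, which spreadsheet
#' programs open directly; `csv` is the canonical tabular form.
#'
#' @param records list of [quant_record()]s.
#' @param format `"json"`, `"csv"` or `"xls"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_quant <- function(records, format = c("json", "csv", "xls"), path) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stopf("unknown export format '%s'",
                                               format[1]))
  if (format == "json") {
    unclass_deep <- function(x) {
      if (is.object(x)) x <- unclass(x)
      if (is.list(x)) lapply(x, unclass_deep) else x
    }
    jsonlite::write_json(unclass_deep(records), path, auto_unbox = TRUE,
                         digits = NA, na = "null", null = "null")
  } else {
    tab <- flatten_quant(records)
    if (format == "csv") write.csv(tab, path, row.names = FALSE)
    else utils::write.table(tab, path, sep = "\t", row.names = FALSE)
  }
  invisible(path)
}
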