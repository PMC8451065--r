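# End-to-end orchestration over a dataset folder:
# train -> predict -> postprocess -> quantify -> export, with group
# summaries and kymograph assembly.
#
# Dataset folder convention:
#   <dataset>/                  multi-channel TIFFs, one organoid per image
#   <dataset>/trainingset/      <id>.tif + <id>_mask.tif pairs
#   <dataset>/model/            persisted model (save_model)
#   <dataset>/result_segmentation/   <id>_mask.tif + quantification files
#   <dataset>/manifest.csv      optional: image_id, file, condition,
#                               replicate, timepoint (manifest wins over
#                               folder inference)

list_dataset_images <- function(dataset) {
  files <- list.files(dataset, pattern = "\\.tif$")
  files[!grepl("_(mask|truth)\\.tif$", files)]
}

read_manifest <- function(dataset) {
  mf <- file.path(dataset, "manifest.csv")
  if (file.exists(mf)) {
    m <- read.csv(mf, stringsAsFactors = FALSE)
    if (!"image_id" %in% names(m)) stopf("manifest.csv lacks 'image_id'")
    if (!"file" %in% names(m)) m$file <- paste0(m$image_id, ".tif")
    for (col in c("condition", "replicate")) if (!col %in% names(m))
      m[[col]] <- NA_character_
    if (!"timepoint" %in% names(m)) m$timepoint <- seq_len(nrow(m))
    m
  } else {
    files <- list_dataset_images(dataset)
    data.frame(image_id = tools::file_path_sans_ext(files), file = files,
               condition = NA_character_, replicate = NA_character_,
               timepoint = seq_along(files), stringsAsFactors = FALSE)
  }
}

load_training_pairs <- function(dataset) {
  tdir <- file.path(dataset, "trainingset")
  imgs <- list.files(tdir, pattern = "\\.tif$")
  imgs <- imgs[!grepl("_mask\\.tif$", imgs)]
  if (length(imgs) == 0)
    stopf(paste0("no training images: expected <id>.tif with <id>_mask.tif ",
                 "under %s"), tdir)
  masks <- file.path(tdir, sub("\\.tif$", "_mask.tif", imgs))
  missing <- masks[!file.exists(masks)]
  if (length(missing))
    stopf("missing training mask(s): %s", paste(missing, collapse = ", "))
  list(images = lapply(file.path(tdir, imgs), read_image),
       masks = lapply(masks, read_mask))
}

quantify_image <- function(image, mask, info, straighten_mode = "auto",
                           locoefa_modes = NULL, locoefa_threshold = 0.95,
                           profiles = c("ap", "orthogonal", "angular",
                                        "radial"),
                           angular_bins = 90L, radial_bins = 20L) {
  m <- mask$pixels
  morpho <- basic_descriptors(m)
  rec_m <- list(area = morpho$area, perimeter = morpho$perimeter,
                form_factor = morpho$form_factor,
                eccentricity = morpho$eccentricity,
                major_axis = morpho$major_axis,
                minor_axis = morpho$minor_axis,
                orientation = morpho$orientation,
                centroid_row = morpho$centroid[["row"]],
                centroid_col = morpho$centroid[["col"]])
  loco <- locoefa_analysis(m, n_modes = locoefa_modes,
                           threshold = locoefa_threshold)
  do_straight <- switch(straighten_mode, on = TRUE, off = FALSE,
                        auto = morpho$eccentricity >= 0.6)
  mesh <- NULL
  if (do_straight) {
    mid <- extract_midline(m)
    mesh <- build_meshgrid(mid, m)
    smask <- straighten(m, mesh, mask = TRUE)
    sm <- descriptors_straightened(smask)
    rec_m$straight_length <- sm$major_axis
    rec_m$straight_width <- sm$minor_axis
    rec_m$straight_area <- sm$area
    rec_m$midline_length <- mid$arclength
  }
  chans <- list()
  nch <- dim(image$pixels)[1]
  if (nch > 1) for (k in 2:nch) {
    ch <- image$pixels[k, , ]
    bg <- background_level(ch, m)
    entry <- list(average = average_intensity(ch, m, background = bg),
                  background = bg, profiles = list())
    if ("angular" %in% profiles)
      entry$profiles$angular <- angular_profile(ch, m, background = bg,
                                                n_bins = angular_bins)
    if ("radial" %in% profiles)
      entry$profiles$radial <- radial_profile(ch, m, background = bg,
                                              n_bins = radial_bins)
    if (do_straight && any(c("ap", "orthogonal") %in% profiles)) {
      sch <- straighten(ch, mesh)
      smask2 <- straighten(m, mesh, mask = TRUE)
      if ("ap" %in% profiles) {
        app <- ap_profile(sch, smask2, background = bg)
        entry$profiles$ap <- app
        entry$decay <- tryCatch(unclass(fit_decay(app)),
                                error = function(e) NULL)
      }
      if ("orthogonal" %in% profiles)
        entry$profiles$orthogonal <- orthogonal_profile(sch, smask2,
                                                        background = bg)
    }
    chans[[image$channel_names[k]]] <- entry
  }
  quant_record(info$image_id, morphometrics = rec_m, profiles = chans,
               locoefa = list(L = loco$L, cutoff_mode = loco$cutoff_mode),
               condition = info$condition, replicate = info$replicate,
               timepoint = info$timepoint)
}

#' Run the full segmentation + quantification pipeline over a dataset
#'
#' Trains a pixel classifier on the images under `<dataset>/trainingset/`,
#' predicts and post-processes a mask for every image in the dataset,
#' quantifies morphology (including LOCO-EFA and, for elongated masks,
#' midline straightening) and fluorescence, and writes masks, a
#' quantification JSON/CSV and a per-group summary under
#' `<dataset>/result_segmentation/`. Deterministic for a fixed `seed`.
#'
#' @param dataset dataset folder (see layout above).
#' @param model_kind `"logistic"` or `"mlp"`.
#' @param feature_mode `"ilastik"` or `"daisy"`.
#' @param filter_widths filter widths sigma in px.
#' @param resize_factor training/prediction resize factor in `(0, 1]`.
#' @param fraction,bias training-pixel sampling (see [sample_pixels()]).
#' @param edge_width edge-band half-width for the three-class labels.
#' @param mask_source `"classifier"`, `"watershed"`, or `"file"` (re-use
#'   masks already present in `result_segmentation/`).
#' @param fill_holes,min_size,dilation_px post-processing (see
#'   [postprocess_mask()]).
#' @param straighten_mode `"auto"` (straighten when eccentricity >= 0.6),
#'   `"on"` or `"off"`.
#' @param profiles fluorescence profile kinds to compute.
#' @param locoefa_threshold LOCO coverage threshold.
#' @param seed RNG seed for sampling and training.
#' @return Invisibly, `list(records, summary, model, masks)`.
#' @export
run_pipeline <- function(dataset, model_kind = c("logistic", "mlp"),
                         feature_mode = c("ilastik", "daisy"),
                         filter_widths = c(1, 2, 5, 15), resize_factor = 1,
                         fraction = 0.5, bias = 1, edge_width = 2L,
                         mask_source = c("classifier", "watershed", "file"),
                         fill_holes = TRUE, min_size = 100L, dilation_px = 0L,
                         straighten_mode = c("auto", "on", "off"),
                         profiles = c("ap", "orthogonal", "angular",
                                      "radial"),
                         locoefa_threshold = 0.95, seed = 1L) {
  model_kind <- match.arg(model_kind)
  feature_mode <- match.arg(feature_mode)
  mask_source <- match.arg(mask_source)
  straighten_mode <- match.arg(straighten_mode)
  res_dir <- file.path(dataset, "result_segmentation")
  dir.create(res_dir, showWarnings = FALSE, recursive = TRUE)

  tp <- load_training_pairs(dataset)
  ts <- build_training_set(tp$images, tp$masks, feature_mode = feature_mode,
                           filter_widths = filter_widths,
                           resize_factor = resize_factor,
                           edge_dilation_px = edge_width,
                           fraction = fraction, bias = bias, seed = seed)
  bundle <- train_pixel_classifier(ts, kind = model_kind,
                                   feature_mode = feature_mode,
                                   filter_widths = filter_widths,
                                   resize_factor = resize_factor,
                                   edge_dilation_px = edge_width,
                                   seed = seed)
  save_model(bundle, file.path(dataset, "model"))

  manifest <- read_manifest(dataset)
  records <- list(); masks <- list()
  for (i in seq_len(nrow(manifest))) {
    info <- manifest[i, ]
    img <- read_image(file.path(dataset, info$file))
    mask_file <- file.path(res_dir, paste0(info$image_id, "_mask.tif"))
    if (mask_source == "file" && file.exists(mask_file)) {
      mask <- read_mask(mask_file, provenance = "manual")
    } else {
      p <- predict_probabilities(img, bundle)
      raw <- if (mask_source == "watershed") watershed_mask(p)
             else classifier_mask(p)
      mask <- postprocess_mask(raw, fill_holes = fill_holes,
                               min_size = min_size,
                               dilation_px = dilation_px)
      write_mask(mask, mask_file)
    }
    masks[[info$image_id]] <- mask
    records[[info$image_id]] <-
      quantify_image(img, mask, info, straighten_mode = straighten_mode,
                     locoefa_threshold = locoefa_threshold,
                     profiles = profiles)
  }
  export_quant(records, "json", file.path(res_dir, "quantification.json"))
  export_quant(records, "csv", file.path(res_dir, "quantification.csv"))
  summ <- summarize_groups(records)
  write.csv(summ, file.path(res_dir, "summary.csv"), row.names = FALSE)
  invisible(list(records = records, summary = summ, model = bundle,
                 masks = masks))
}

#' Per-group summary of morphometric quantities
#'
#' Mean and standard deviation of every morphometric field per
#' (condition, timepoint) group.
#'
#' @param records list of [quant_record()]s.
#' @return A data frame `condition`, `timepoint`, `field`, `n`, `mean`,
#'   `sd`.
#' @export
summarize_groups <- function(records) {
  rows <- list()
  for (rec in records) for (nm in names(rec$morphometrics))
    rows[[length(rows) + 1L]] <- data.frame(
      condition = if (is.na(rec$condition)) "all" else rec$condition,
      timepoint = rec$timepoint, field = nm,
      value = as.numeric(rec$morphometrics[[nm]]), stringsAsFactors = FALSE)
  long <- do.call(rbind, rows)
  agg <- aggregate(value ~ condition + timepoint + field, data = long,
                   FUN = function(v) c(n = length(v), mean = mean(v),
                                       sd = sd(v)))
  out <- data.frame(agg[c("condition", "timepoint", "field")],
                    n = agg$value[, "n"], mean = agg$value[, "mean"],
                    sd = agg$value[, "sd"])
  out[order(out$condition, out$timepoint, out$field), ]
}

#' Stack profiles over time into a kymograph matrix
#'
#' Profiles of one kind (e.g. the AP profile of a channel) are linearly
#' resampled onto a common coordinate grid and stacked into a
#' time-by-coordinate matrix, ordered by timepoint.
#'
#' @param records list of [quant_record()]s (one per timepoint).
#' @param channel fluorescence channel name.
#' @param kind profile kind (`"ap"`, `"orthogonal"`, `"angular"`,
#'   `"radial"`).
#' @param n_grid number of coordinate samples.
#' @return Numeric matrix `(timepoints x n_grid)` with timepoints as
#'   rownames and grid coordinates as colnames.
#' @export
kymograph <- function(records, channel, kind = "ap", n_grid = 100L) {
  recs <- records[order(vapply(records, function(r)
    as.numeric(r$timepoint), numeric(1)))]
  profs <- lapply(recs, function(r) r$channels[[channel]]$profiles[[kind]])
  keep <- !vapply(profs, is.null, logical(1))
  recs <- recs[keep]; profs <- profs[keep]
  if (length(profs) == 0) stopf("no '%s' profiles found for channel '%s'",
                                kind, channel)
  lo <- min(vapply(profs, function(p) min(p$coordinates), numeric(1)))
  hi <- max(vapply(profs, function(p) max(p$coordinates), numeric(1)))
  grid <- seq(lo, hi, length.out = n_grid)
  mat <- t(vapply(profs, function(p) {
    ok <- is.finite(p$values)
    approx(p$coordinates[ok], p$values[ok], xout = grid, rule = 2)$y
  }, numeric(n_grid)))
  rownames(mat) <- vapply(recs, function(r) as.character(r$timepoint),
                          character(1))
  colnames(mat) <- signif(grid, 6)
  mat
}
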