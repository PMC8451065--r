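# Benchmarking metrics for segmentation masks against ground truth.

#' Pixel-wise confusion counts between two masks
#'
#' @param pred,truth `BinaryMask`s or logical matrices of equal shape.
#' @return A `ConfusionCounts` list `tp`, `tn`, `fp`, `fn` summing to the
#'   pixel count.
#' @export
mask_confusion <- function(pred, truth) {
  p <- as_mask_matrix(pred); t <- as_mask_matrix(truth)
  if (!identical(dim(p), dim(t))) stopf("masks differ in shape")
  structure(list(tp = sum(p & t), tn = sum(!p & !t),
                 fp = sum(p & !t), fn = sum(!p & t)),
            class = "ConfusionCounts")
}

#' Jaccard distance between two masks
#'
#' `J = |XOR| / (|XOR| + |AND|) = 1 - |intersection| / |union|`; 0 means
#' perfect agreement. Defined as 0 when both masks are empty.
#'
#' @inheritParams mask_confusion
#' @return Scalar in `[0, 1]`.
#' @export
jaccard_distance <- function(pred, truth) {
  p <- as_mask_matrix(pred); t <- as_mask_matrix(truth)
  if (!identical(dim(p), dim(t))) stopf("masks differ in shape")
  x <- sum(xor(p, t)); a <- sum(p & t)
  if (x + a == 0) return(0)
  x / (x + a)
}

#' Precision and accuracy from confusion counts
#'
#' `P = tp / (tp + fp)`; `A = (tp + tn) / (tp + tn + fp + fn)`. Precision is
#' `NA` with attribute `undefined = TRUE` when nothing was predicted
#' positive.
#'
#' @param counts a `ConfusionCounts` from [mask_confusion()].
#' @return Scalar.
#' @export
mask_precision <- function(counts) {
  stopifnot(inherits(counts, "ConfusionCounts"))
  if (counts$tp + counts$fp == 0)
    return(structure(NA_real_, undefined = TRUE))
  counts$tp / (counts$tp + counts$fp)
}

#' @rdname mask_precision
#' @export
mask_accuracy <- function(counts) {
  stopifnot(inherits(counts, "ConfusionCounts"))
  with(counts, (tp + tn) / (tp + tn + fp + fn))
}

#' Evaluate predicted masks against ground truth
#'
#' @param pred,truth lists of masks (same length and order) or two folders
#'   holding mask TIFFs with matching filenames.
#' @return A data frame with one row per mask pair: `id`, `jaccard`,
#'   `precision`, `accuracy`.
#' @export
evaluate_masks <- function(pred, truth) {
  if (is.character(pred)) {
    ids <- sort(list.files(pred, pattern = "\\.tif$"))
    pred <- lapply(file.path(pred, ids), read_mask)
    truth <- lapply(file.path(truth, ids), read_mask)
  } else ids <- as.character(seq_along(pred))
  stopifnot(length(pred) == length(truth))
  rows <- lapply(seq_along(pred), function(i) {
    cm <- mask_confusion(pred[[i]], truth[[i]])
    data.frame(id = ids[i],
               jaccard = jaccard_distance(pred[[i]], truth[[i]]),
               precision = as.numeric(mask_precision(cm)),
               accuracy = mask_accuracy(cm),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
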