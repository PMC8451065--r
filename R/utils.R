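# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_binary_matrix <- function(m) {
  is.matrix(m) && (is.logical(m) || all(m %in% c(0, 1)))
}

as_mask_matrix <- function(mask) {
  if (inherits(mask, "BinaryMask")) mask <- mask$pixels
  if (!is_binary_matrix(mask)) stopf("expected a binary mask matrix")
  if (!is.logical(mask)) mask <- mask > 0.5
  mask
}

# Odd-sized disc brush of radius r (EBImage convention).
disc_brush <- function(r) {
  EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
}

# Connected-component labelling, 8-connectivity, background = 0.
label_components <- function(mask) {
  m <- as_mask_matrix(mask)
  lab <- EBImage::bwlabel(m * 1)
  storage.mode(lab) <- "integer"
  array(lab, dim = dim(m))
}

# Bilinear sampling of matrix `img` at fractional (row, col) positions.
# Out-of-bounds samples return `fill`.
bilinear_sample <- function(img, r, cc, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(fill, length(r))
  ok <- r >= 1 & r <= nr & cc >= 1 & cc <= nc & is.finite(r) & is.finite(cc)
  if (!any(ok)) return(out)
  r <- r[ok]; cc <- cc[ok]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(cc), nc - 1L)
  fr <- r - r0; fc <- cc - c0
  i00 <- r0 + (c0 - 1) * nr
  v <- (1 - fr) * (1 - fc) * img[i00] +
    fr * (1 - fc) * img[i00 + 1] +
    (1 - fr) * fc * img[i00 + nr] +
    fr * fc * img[i00 + nr + 1]
  out[ok] <- v
  out
}

# Full-precision numeric formatting for text persistence (round-trips doubles).
num_chr <- function(x) sprintf("%.17g", x)
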