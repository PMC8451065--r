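# Shared in-code fixtures. Everything is generated programmatically; the
# heavier ones are memoised so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

disk_mask <- function(r, size = 2 * r + 21, center = (size + 1) / 2) {
  m <- matrix(FALSE, size, size)
  m[(row(m) - center)^2 + (col(m) - center)^2 <= r^2] <- TRUE
  m
}

rect_mask <- function(nr, nc, h, w) {
  m <- matrix(FALSE, nr, nc)
  r0 <- floor((nr - h) / 2); c0 <- floor((nc - w) / 2)
  m[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w)] <- TRUE
  m
}

# analytic closed contours (counterclockwise)
circle_contour <- function(R, cx = 0, cy = 0, n = 300) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  structure(list(points = cbind(cx + R * cos(th), cy + R * sin(th))),
            class = "Contour")
}

flower_contour <- function(R, p, eps, n = 400) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- R * (1 + eps * cos(p * th))
  structure(list(points = cbind(r * cos(th), r * sin(th))),
            class = "Contour")
}

# a tiny trained classifier shared across io/segmentation tests
tiny_trained <- function(kind = "logistic") {
  memo(paste0("tiny_trained_", kind), {
    gens <- lapply(1:2, function(i)
      synth_generate(synthetic_spec("disk", canvas = c(96L, 96L),
                                    radius = 28, n_debris = 1L,
                                    seed = 100L + i)))
    ts <- build_training_set(lapply(gens, `[[`, "image"),
                             lapply(gens, `[[`, "mask"),
                             fraction = 0.5, seed = 5L)
    train_pixel_classifier(ts, kind, seed = 5L, maxit = 200L)
  })
}
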