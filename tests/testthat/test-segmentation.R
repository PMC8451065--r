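test_that("three-class labels partition the image with a contour band", {
  m <- disk_mask(50, 120)
  lab <- make_three_class_labels(m, edge_width = 2L)
  expect_setequal(unique(as.integer(lab)), 0:2)
  expect_equal(length(lab), sum(tabulate(lab + 1L, 3L)))

  # the original mask contour lies inside the edge band
  boundary <- m & !(as.matrix(EBImage::erode(m * 1,
                                             EBImage::makeBrush(3, "disc"))) > 0.5)
  expect_true(all(lab[boundary] == 2L))

  # distance-to-contour oracle: pixels well inside are organoid, well
  # outside background
  dm_in <- as.matrix(EBImage::distmap(m * 1))
  dm_out <- as.matrix(EBImage::distmap((!m) * 1))
  expect_true(all(lab[dm_in > 3] == 1L))
  expect_true(all(lab[dm_out > 3] == 0L))

  expect_error(make_three_class_labels(matrix(FALSE, 10, 10)), "degenerate")
})

test_that("pixel sampling respects fraction, bias and the seed", {
  g <- synth_generate(synthetic_spec("disk", canvas = c(96L, 96L),
                                     radius = 28, seed = 21))
  fs <- extract_features(get_channel(g$image), widths = c(1, 2))
  lab <- make_three_class_labels(g$mask, 2L)

  full <- sample_pixels(fs, lab, fraction = 1, bias = 1)
  expect_equal(nrow(full$X), length(lab))
  expect_equal(tabulate(full$y + 1L, 3L), tabulate(lab + 1L, 3L))

  s1 <- sample_pixels(fs, lab, fraction = 0.5, seed = 9L)
  s2 <- sample_pixels(fs, lab, fraction = 0.5, seed = 9L)
  expect_identical(s1$X, s2$X)

  # across seeds the sample size matches the binomial expectation (3 sigma)
  n <- length(lab)
  counts <- vapply(1:10, function(s)
    nrow(sample_pixels(fs, lab, fraction = 0.5, seed = s)$X), numeric(1))
  expect_lt(abs(mean(counts) - 0.5 * n),
            3 * sqrt(0.25 * n) / sqrt(10))

  # strong bias exhausts the foreground classes before the background
  # (the budget fraction * n exceeds the foreground count here)
  sb <- sample_pixels(fs, lab, fraction = 0.5, bias = 1e6, seed = 1L)
  expect_equal(sum(sb$y > 0), sum(lab > 0))
  expect_lt(sum(sb$y == 0), 0.01 * sum(lab == 0))

  expect_error(sample_pixels(fs, matrix(1L, 96, 96), 0.5), "missing class")
})

test_that("both model kinds separate linearly separable classes", {
  set.seed(3)
  n <- 900
  y <- rep(0:2, each = n / 3)
  X <- cbind(rnorm(n, mean = c(0, 4, 8)[y + 1], sd = 0.5),
             rnorm(n, sd = 0.5), rnorm(n, sd = 0.5))
  colnames(X) <- paste0("f", 1:3)
  ts <- structure(list(X = X, y = y, fraction = 1, bias = 1),
                  class = "TrainingSet")
  for (kind in c("logistic", "mlp")) {
    b <- train_pixel_classifier(ts, kind, seed = 7L)
    acc <- mean(max.col(organoquant:::model_scores(b, X)) - 1L == y)
    expect_gt(acc, 0.99)
    b2 <- train_pixel_classifier(ts, kind, seed = 7L)
    expect_identical(b$weights, b2$weights)    # same seed, same parameters
  }
  expect_error(train_pixel_classifier(
    structure(list(X = X, y = rep(1L, n), fraction = 1, bias = 1),
              class = "TrainingSet"), "logistic"), "degenerate")
  expect_error(train_pixel_classifier(ts, "mlp", hidden = c(10, 10, 10)),
               "two hidden layers")
})

test_that("a logistic fit recovers a known decision-boundary orientation", {
  set.seed(4)
  y <- rep(0:2, each = 200)
  dirv <- c(cos(pi / 6), sin(pi / 6))
  u <- rnorm(600); t_ <- rnorm(600)
  offset <- c(-2, 2, 10)[y + 1]
  X <- cbind(dirv[1] * offset - dirv[2] * u + dirv[1] * 0.3 * t_,
             dirv[2] * offset + dirv[1] * u + dirv[2] * 0.3 * t_)
  colnames(X) <- c("f1", "f2")
  ts <- structure(list(X = X, y = y, fraction = 1, bias = 1),
                  class = "TrainingSet")
  b <- train_pixel_classifier(ts, "logistic", seed = 1L)
  w <- (b$weights$beta[2, -1] - b$weights$beta[1, -1]) / b$norm$scale
  angle <- atan2(w[2], w[1]) * 180 / pi
  expect_lt(abs(angle - 30), 5)
})

test_that("probability maps form a simplex and match the training labels", {
  g <- synth_generate(synthetic_spec("disk", canvas = c(96L, 96L),
                                     radius = 28, n_debris = 0L, seed = 101))
  b <- tiny_trained("logistic")
  p <- predict_probabilities(g$image, b)
  expect_equal(dim(p), c(3L, 96L, 96L))
  expect_lt(max(abs(p[1, , ] + p[2, , ] + p[3, , ] - 1)), 1e-6)
  expect_true(min(p) >= 0 && max(p) <= 1)

  # self-consistency: argmax classes agree with the three-class labels
  lab <- make_three_class_labels(g$mask, 2L)
  cls <- apply(array(p, dim = dim(p)), c(2, 3), which.max) - 1L
  expect_gt(mean(cls == lab), 0.95)

  bad <- b; bad$norm$mean <- bad$norm$mean[-1]; bad$norm$scale <- bad$norm$scale[-1]
  expect_error(predict_probabilities(g$image, bad), "incompatible")
})

test_that("classifier mask equals the argmax-foreground oracle", {
  set.seed(6)
  p <- array(runif(3 * 30 * 30), dim = c(3, 30, 30))
  tot <- p[1, , ] + p[2, , ] + p[3, , ]
  for (k in 1:3) p[k, , ] <- p[k, , ] / tot
  m <- classifier_mask(structure(p, class = "ClassProbabilityMaps"))
  oracle <- apply(p, c(2, 3), which.max) != 1L
  expect_identical(m$pixels, oracle)

  empty <- array(0, dim = c(3, 10, 10)); empty[1, , ] <- 1
  expect_false(any(classifier_mask(
    structure(empty, class = "ClassProbabilityMaps"))$pixels))

  edge_only <- array(0, dim = c(3, 10, 10)); edge_only[3, , ] <- 1
  expect_true(all(classifier_mask(
    structure(edge_only, class = "ClassProbabilityMaps"))$pixels))
})

test_that("seeded watershed recovers a disk from a ring-shaped edge map", {
  nr <- 120
  rad <- sqrt((row(diag(nr)) - 60)^2 + (col(diag(nr)) - 60)^2)
  p <- array(0, dim = c(3, nr, nr))
  p[3, , ] <- exp(-((rad - 40) / 3)^2)
  p[2, , ] <- exp(-(rad / 20)^2)
  p[1, , ] <- pmax(1 - p[2, , ] - p[3, , ], 0)
  wm <- watershed_mask(structure(p, class = "ClassProbabilityMaps"))
  expect_lt(jaccard_distance(wm$pixels, rad <= 40), 0.05)
  expect_true(wm$pixels[60, 60])          # contains the interior seed
  expect_identical(wm$provenance, "watershed")

  p0 <- array(0, dim = c(3, 20, 20))
  expect_error(watershed_mask(structure(p0,
                                        class = "ClassProbabilityMaps")),
               "degenerate")
})

test_that("post-processing keeps a single clean object", {
  m <- disk_mask(30, 100)
  m[5:8, 40:43] <- TRUE                  # debris speck
  m[90:92, 10:12] <- TRUE                # debris speck
  m[45:60, 1:6] <- TRUE                  # partial neighbour at the border
  m[50, 50] <- FALSE                     # internal hole
  pp <- postprocess_mask(m, fill_holes = TRUE, min_size = 100L)
  expect_true(pp$pixels[50, 50])
  lab <- EBImage::bwlabel(pp$pixels * 1)
  expect_equal(max(lab), 1)
  expect_equal(sum(pp$pixels), sum(disk_mask(30, 100)))

  # the largest object is retained even when it touches the border
  mb <- matrix(FALSE, 60, 60); mb[1:40, 10:50] <- TRUE
  mb[55:57, 55:57] <- TRUE
  ppb <- postprocess_mask(mb, min_size = 5L)
  expect_true(any(ppb$pixels[1, ]))
  expect_false(any(ppb$pixels[55:57, 55:57]))

  pe <- postprocess_mask(matrix(FALSE, 20, 20))
  expect_true(isTRUE(attr(pe, "empty_after_postprocess")))
})
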