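test_that("TIFF stacks round-trip and single planes are promoted", {
  g <- synth_generate(synthetic_spec(
    "disk", canvas = c(100L, 120L), radius = 30,
    fluorescence = list(ch1 = list(pattern = "uniform")), seed = 2))
  f <- tempfile(fileext = ".tif")
  write_image(g$image, f)
  back <- read_image(f)
  expect_equal(dim(back$pixels), c(2L, 100L, 120L))
  expect_identical(back$pixels, g$image$pixels)   # 16-bit grid values

  one <- matrix(round(runif(30 * 40) * 65535) / 65535, 30, 40)
  f1 <- tempfile(fileext = ".tif")
  write_image(one, f1)
  s <- read_image(f1)
  expect_equal(dim(s$pixels), c(1L, 30L, 40L))
  expect_identical(s$pixels[1, , ], one)

  expect_error(read_image(tempfile(fileext = ".tif")), "no such file")
})

test_that("masks round-trip through TIFF", {
  m <- disk_mask(12, 40)
  f <- tempfile(fileext = ".tif")
  write_mask(binary_mask(m, "manual"), f)
  expect_identical(read_mask(f)$pixels, m)
})

test_that("per-channel files are compiled into multi-channel stacks", {
  dir <- tempfile("compile"); dir.create(dir)
  for (stem in c("a", "b", "c")) for (ch in c("_ch0", "_ch1")) {
    m <- matrix(round(runif(20 * 25) * 255) / 255, 20, 25)
    write_image(m, file.path(dir, paste0(stem, ch, ".tif")), bits = 8L)
  }
  out_dir <- tempfile("compiled")
  out <- compile_channels(dir, c("_ch0", "_ch1"), out_dir)
  expect_length(out, 3L)
  expect_equal(dim(read_image(out[1])$pixels)[1], 2L)

  file.remove(file.path(dir, "b_ch1.tif"))
  expect_error(compile_channels(dir, c("_ch0", "_ch1"), tempfile()),
               "missing channel.*b")
})

test_that("split_objects crops every labelled object and conserves area", {
  lab <- matrix(0L, 80, 90)
  lab[10:20, 10:25] <- 1L
  lab[50:70, 60:85] <- 2L
  img <- image_stack(matrix(0.5, 80, 90))
  crops <- split_objects(img, lab, margin = 5L)
  expect_length(crops, 2L)
  for (cr in crops)
    expect_equal(max(EBImage::bwlabel(cr$mask$pixels * 1)), 1)

  # object touching the border: crop clipped to image bounds
  lab2 <- matrix(0L, 40, 40); lab2[1:8, 1:8] <- 1L
  cr <- split_objects(image_stack(matrix(0, 40, 40)), lab2, margin = 10L)
  expect_equal(cr[[1]]$bbox[c(1, 3)], c(1, 1))

  # area conservation over random non-overlapping blobs
  set.seed(42)
  lab3 <- matrix(0L, 120, 120)
  centers <- cbind(c(20, 20, 60, 100, 100), c(20, 100, 60, 20, 100))
  for (k in 1:5) {
    r <- sample(4:8, 1)
    sel <- (row(lab3) - centers[k, 1])^2 +
      (col(lab3) - centers[k, 2])^2 <= r^2
    lab3[sel] <- k
  }
  crops <- split_objects(image_stack(matrix(0, 120, 120)), lab3)
  expect_length(crops, 5L)
  expect_equal(sum(vapply(crops, function(cr) sum(cr$mask$pixels),
                          numeric(1))),
               sum(lab3 > 0))

  expect_identical(split_objects(img, matrix(0L, 80, 90)), list())
})

test_that("model bundles round-trip losslessly through CSV persistence", {
  for (kind in c("logistic", "mlp")) {
    b <- tiny_trained(kind)
    folder <- tempfile("model")
    save_model(b, folder)
    b2 <- load_model(folder)
    X <- matrix(rnorm(40 * length(b$norm$mean)), 40)
    colnames(X) <- b$feature_names
    expect_identical(organoquant:::model_scores(b, X),
                     organoquant:::model_scores(b2, X))
    expect_identical(b2$model_kind, kind)
  }
  b <- tiny_trained("logistic")
  b$feature_mode <- "daisy"
  folder <- tempfile("model")
  save_model(b, folder)
  expect_identical(load_model(folder)$feature_mode, "daisy")

  expect_error(load_model(tempfile("empty")), "missing")
})

test_that("quantification records export to JSON and CSV without loss", {
  rec <- quant_record(
    "img_001",
    morphometrics = list(area = 1234, form_factor = 0.87654321987),
    profiles = list(ch1 = list(
      average = 12.3456789, background = 3.21,
      profiles = list(ap = intensity_profile(
        "ap", c(0.25, 0.75), c(1.111111111, 2.222222222), c(10, 12))))),
    locoefa = list(L = c(0, 5, 0.1), cutoff_mode = 1L),
    timepoint = 1)
  fj <- tempfile(fileext = ".json")
  export_quant(list(rec), "json", fj)
  back <- jsonlite::read_json(fj)
  expect_equal(back[[1]]$morphometrics$area, 1234)
  expect_equal(back[[1]]$morphometrics$form_factor, 0.87654321987)

  fc <- tempfile(fileext = ".csv")
  export_quant(list(rec), "csv", fc)
  tab <- read.csv(fc)
  expect_equal(tab$value[tab$field == "morpho.form_factor"],
               0.87654321987, tolerance = 1e-9)
  expect_equal(tab$value[tab$field == "ch1.ap"],
               c(1.111111111, 2.222222222), tolerance = 1e-9)
  expect_equal(tab$coordinate[tab$field == "ch1.ap"], c(0.25, 0.75))

  fe <- tempfile(fileext = ".csv")
  export_quant(list(), "csv", fe)
  expect_equal(nrow(read.csv(fe)), 0L)

  expect_error(export_quant(list(rec), "parquet", tempfile()),
               "unknown export format")
})
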