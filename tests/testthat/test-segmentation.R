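# Gray-band extraction, contrast stretch, Otsu thresholding, labeling,
# mean-spectrum extraction, and the pixel-exact round trip on generator truth.

test_that("to_gray picks the nearest band and enforces the grid range", {
  cube <- hyper_cube(array(rep(1:3, each = 4), c(2, 2, 3)),
                     wavelength_grid(c(450, 700, 979)))
  expect_equal(as.vector(to_gray(cube, 700)), rep(2, 4))
  expect_equal(attr(to_gray(cube, 690), "band"), 2L)   # nearest neighbour
  expect_equal(attr(to_gray(cube, 460), "band"), 1L)
  expect_error(to_gray(cube, 1100), "outside")
})

test_that("enhance is an affine stretch onto [0, 1]", {
  img <- matrix(c(0.2, 0.4, 0.2, 0.4), 2)
  expect_equal(sort(unique(as.vector(enhance(img, 0, 100)))), c(0, 1))
  spans <- matrix(seq(0, 1, length.out = 16), 4)
  expect_equal(enhance(spans, 0, 100), spans)
  expect_warning(out <- enhance(matrix(0.5, 3, 3)), "constant")
  expect_equal(as.vector(out), rep(0.5, 9))
})

test_that("enhance preserves pixel rank order", {
  set.seed(5)
  img <- matrix(stats::runif(400), 20)
  out <- enhance(img, 1, 99)
  # ranks may tie where clipped, but must never invert
  expect_true(all(diff(out[order(img)]) >= 0))
})

test_that("Otsu separates a perfectly bimodal image", {
  img <- matrix(rep(c(0.1, 0.8), each = 50), 10)
  thr <- otsu_threshold(img)
  expect_true(thr > 0.1 && thr < 0.8)
  expect_equal(img > thr, img == 0.8)
  expect_error(otsu_threshold(matrix(1, 4, 4)), "constant")
})

test_that("Otsu equals the exhaustive between-class-variance search", {
  for (s in 1:5) {
    set.seed(s)
    img <- matrix(c(stats::rnorm(150, 0.25, 0.06), stats::rnorm(100, 0.7, 0.08)),
                  25, 10)
    expect_equal(otsu_threshold(img), otsu_brute(img), label = paste("seed", s))
  }
})

test_that("label_seeds finds blobs in raster order and applies min_area", {
  m <- matrix(FALSE, 12, 12)
  m[2:4, 2:5] <- TRUE            # blob A (12 px, first in raster order)
  m[8:10, 7:10] <- TRUE          # blob B (12 px)
  sm <- label_seeds(m, min_area = 5)
  expect_equal(sm$seed_count, 2L)
  expect_equal(sm$areas, c(12L, 12L))
  expect_equal(sm$labels[2, 2], 1L)
  expect_equal(sm$labels[8, 7], 2L)
  expect_error(label_seeds(matrix(FALSE, 5, 5)), "empty mask")
  tiny <- matrix(FALSE, 5, 5); tiny[2, 2:4] <- TRUE
  expect_error(label_seeds(tiny, min_area = 5), "min_area")
})

test_that("connectivity setting splits or joins diagonal touches", {
  m <- matrix(FALSE, 6, 6)
  m[1:2, 1:2] <- TRUE
  m[3:4, 3:4] <- TRUE            # touches the first blob only diagonally
  expect_equal(label_seeds(m, min_area = 1, connectivity = 8)$seed_count, 1L)
  expect_equal(label_seeds(m, min_area = 1, connectivity = 4)$seed_count, 2L)
})

test_that("mean_spectra averages region pixels bandwise", {
  vals <- array(0, c(3, 3, 2))
  vals[1, 1, ] <- c(0.2, 0.4)
  vals[3, 3, ] <- c(0.6, 0.8)
  vals[3, 2, ] <- c(0.4, 0.6)
  cube <- hyper_cube(vals, wavelength_grid(c(500, 600)), calibrated = TRUE)
  lab <- matrix(0L, 3, 3); lab[1, 1] <- 1L; lab[3, 2:3] <- 2L
  mask <- structure(list(labels = lab, seed_count = 2L, areas = c(1L, 2L)),
                    class = "seed_mask")
  tab <- mean_spectra(cube, mask, labels = c(1, 3))
  expect_equal(tab$spectra[1, ], c(0.2, 0.4), ignore_attr = TRUE)     # single pixel
  expect_equal(tab$spectra[2, ], c(0.5, 0.7), ignore_attr = TRUE)     # two-pixel mean
  expect_equal(tab$labels, c(1L, 3L))
  raw <- hyper_cube(vals, cube$grid, calibrated = FALSE)
  expect_error(mean_spectra(raw, mask, c(1, 3)), "calibrated")
})

test_that("segmentation recovers generator truth pixel-exactly without noise", {
  cfg <- synth_config(class_sizes = c(2L, 2L, 2L), n_bands = 12,
                      noise_sd = 0, severity_sd = 0,
                      scatter_range = c(1, 1), baseline_range = c(0, 0),
                      seed = 9)
  layout <- gen_layout(rep(1:3, 2), axes = c(4, 5))
  out <- gen_cube(cfg, layout)
  cal <- calibrate(out$raw, out$dark, out$white)
  sm <- segment_cube(cal, 700, min_area = 10)
  expect_equal(sm$seed_count, 6L)
  expect_equal(sm$labels, out$truth$labels)
  # noiseless mean spectra equal the class-mean curves exactly
  tab <- mean_spectra(cal, sm, layout$classes)
  truth <- gen_spectra(cfg)$truth$class_means
  expect_equal(tab$spectra, truth[layout$classes, ],
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("recovered seed means obey the law of large numbers", {
  cfg <- synth_config(class_sizes = c(2L, 2L, 2L), n_bands = 10,
                      severity_sd = 0, scatter_range = c(1, 1),
                      baseline_range = c(0, 0), noise_sd = 0.01, seed = 21)
  layout <- gen_layout(rep(1:3, 2), axes = c(6, 8))
  out <- gen_cube(cfg, layout)
  cal <- calibrate(out$raw, out$dark, out$white)
  sm <- label_seeds(out$truth$labels > 0, min_area = 10)
  tab <- mean_spectra(cal, sm, layout$classes)
  truth <- gen_spectra(cfg)$truth$class_means
  for (i in seq_len(6)) {
    tol <- 3 * cfg$noise_sd / sqrt(sm$areas[i])
    expect_true(all(abs(tab$spectra[i, ] - truth[layout$classes[i], ]) < tol))
  }
})
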