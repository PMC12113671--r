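# SPA chain and selection, 2DCOS synchronous spectra and peak extraction,
# wavelength fusion.

test_that("SPA chain walks orthogonal columns in descending norm order", {
  # zero-mean, mutually orthogonal columns with norms 3 > 2 > 1
  v1 <- c(1, -1, 0, 0) / sqrt(2)
  v2 <- c(1, 1, -2, 0) / sqrt(6)
  v3 <- c(1, 1, 1, -3) / sqrt(12)
  X <- cbind(1 * v3, 3 * v1, 2 * v2)      # norms: col1 = 1, col2 = 3, col3 = 2
  expect_equal(spa_chain(X, start_band = 2, max_len = 3), c(2L, 3L, 1L))
})

test_that("a duplicated column is never selected right after its twin", {
  set.seed(3)
  base <- matrix(stats::rnorm(6 * 4), 6)
  X <- cbind(base, base[, 2])              # column 5 duplicates column 2
  chain <- spa_chain(X, start_band = 2, max_len = 3)
  expect_false(5L %in% chain[2])
  expect_false(2L %in% chain[-1])
})

test_that("SPA chain matches the explicit Gram-Schmidt recursion", {
  for (s in 1:6) {
    set.seed(s)
    X <- matrix(stats::rnorm(30), 6, 5)
    for (start in 1:5)
      expect_equal(spa_chain(X, start, 5), spa_chain_brute(X, start, 5),
                   label = sprintf("seed %d start %d", s, start))
  }
})

test_that("SPA chain is invariant to common positive rescaling", {
  set.seed(11)
  X <- matrix(stats::rnorm(48), 8, 6)
  expect_equal(spa_chain(X, 1, 6), spa_chain(1000 * X, 1, 6))
})

test_that("single-band SPA selection equals the exhaustive CV search", {
  set.seed(12)
  g <- gen_spectra(synth_config(class_sizes = c(20L, 20L, 20L), n_bands = 12,
                                seed = 12))
  X <- g$table$spectra; y <- g$table$labels
  sel <- spa_select(X, y, k_min = 1, k_max = 1, grid = g$table$grid)
  # oracle: CV-score every single band directly with MASS::lda
  fold <- folds_oracle(y, 5)
  errs <- sapply(seq_len(ncol(X)), function(b) {
    wrong <- 0
    for (f in 1:5) {
      fit <- MASS::lda(X[fold != f, b, drop = FALSE], grouping = y[fold != f])
      pred <- stats::predict(fit, X[fold == f, b, drop = FALSE])$class
      wrong <- wrong + sum(as.integer(as.character(pred)) != y[fold == f])
    }
    wrong / length(y)
  })
  expect_equal(sel$band_indices, which.min(errs))
  expect_equal(attr(sel, "cv_error"), min(errs))
})

test_that("SPA finds planted signal bands among pure noise", {
  signal_bands <- c(3L, 8L, 13L)
  hits <- 0L
  n_rep <- 40L
  for (r in seq_len(n_rep)) {
    set.seed(r)
    n <- 90; B <- 15
    y <- rep(1:3, each = 30)
    X <- matrix(stats::rnorm(n * B, sd = 1), n, B)
    # one class-indicator contrast per signal band, all other bands pure noise
    for (cl in 1:3)
      X[, signal_bands[cl]] <- X[, signal_bands[cl]] + 2.5 * (y == cl)
    sel <- spa_select(X, y, k_max = 6)
    if (all(signal_bands %in% sel$band_indices)) hits <- hits + 1L
    expect_true(length(sel) >= 1 && length(sel) <= 6)
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("synchronous spectrum matches the hand-computed 2x2 case", {
  series <- rbind(c(0, 0), c(2, 4))
  phi <- sync_spectrum(series)$phi
  expect_equal(phi, matrix(c(2, 4, 4, 8), 2), ignore_attr = TRUE)
})

test_that("synchronous spectrum is a symmetric PSD-diagonal covariance", {
  set.seed(13)
  series <- matrix(stats::rnorm(5 * 20), 5)
  sy <- sync_spectrum(series)
  expect_lt(max(abs(sy$phi - t(sy$phi))), 1e-10)
  expect_true(all(diag(sy$phi) >= 0))
  expect_equal(sy$phi, sync_brute(series), ignore_attr = TRUE)
  # zero dynamics
  same <- matrix(rep(stats::runif(20), each = 3), 3)
  expect_equal(max(abs(sync_spectrum(same)$phi)), 0)
  expect_error(sync_spectrum(series[1, , drop = FALSE]), "at least 2")
})

test_that("autocorrelation peaks sit at planted diagonal bumps", {
  grid <- wavelength_grid(seq(450, 979, length.out = 200))
  wl <- as.numeric(grid)
  one_bump <- sqrt(exp(-((wl - wl[100])^2) / (2 * 15^2)))
  sy1 <- sync_spectrum(rbind(one_bump, -one_bump), grid)
  p1 <- autocorr_peaks(sy1)
  expect_equal(p1$band_indices, 100L)

  two <- sqrt(exp(-((wl - 550)^2) / 450) + exp(-((wl - 850)^2) / 450))
  sy2 <- sync_spectrum(rbind(two, -two), grid)
  p2 <- autocorr_peaks(sy2)
  expect_equal(length(p2), 2L)
  expect_equal(sort(wl[p2$band_indices]), c(550, 850), tolerance = 0.01)

  flat <- sync_spectrum(rbind(rep(1, 200), rep(1, 200)), grid)
  expect_equal(length(autocorr_peaks(flat)), 0L)
})

test_that("fusion is a sorted de-duplicated union with provenance", {
  grid <- wavelength_grid(c(743, 839, 848, 903, 949, 974, 979))
  a <- selection_result("SPA", match(c(839, 903, 949, 979), as.numeric(grid)), grid)
  b <- selection_result("2DCOS", match(c(743, 848, 974), as.numeric(grid)), grid)
  fu <- fuse_selections(a, b)
  expect_equal(fu$method, "SPA+2DCOS")
  expect_equal(fu$wavelengths_nm, c(743, 839, 848, 903, 949, 974, 979))
  expect_equal(length(fu), 7L)
  expect_setequal(unique(fu$provenance), c("SPA", "2DCOS"))

  # overlap dedup: {a,b} U {b,c} = {a,b,c}, shared wavelength tagged with both
  g2 <- wavelength_grid(c(500, 600, 700))
  x <- selection_result("SPA", c(1L, 2L), g2)
  z <- selection_result("2DCOS", c(2L, 3L), g2)
  u <- fuse_selections(x, z)
  expect_equal(u$band_indices, 1:3)
  expect_equal(u$provenance[2], "SPA+2DCOS")

  # empty selection is the identity element
  e <- selection_result("2DCOS", integer(0), g2)
  expect_equal(fuse_selections(x, e)$band_indices, x$band_indices)

  g3 <- wavelength_grid(c(400, 500, 600))
  expect_error(fuse_selections(x, selection_result("2DCOS", 1L, g3)),
               "different wavelength grids")
})

test_that("fused size is |a| + |b| minus the overlap", {
  set.seed(14)
  grid <- wavelength_grid(seq(450, 979, length.out = 50))
  for (r in 1:5) {
    ia <- sort(sample(50, 8)); ib <- sort(sample(50, 5))
    fu <- fuse_selections(selection_result("SPA", ia, grid),
                          selection_result("2DCOS", ib, grid))
    expect_equal(length(fu), length(ia) + length(ib) - length(intersect(ia, ib)))
  }
})
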