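# Kennard-Stone splitting, the three classifiers, and the metric suite.

sep_table <- function(n_per = 12, gap = 8, seed = 1) {
  # three well-separated Gaussian blobs in 6 bands
  set.seed(seed)
  X <- do.call(rbind, lapply(1:3, function(cl)
    matrix(stats::rnorm(n_per * 6, mean = gap * cl, sd = 0.5), n_per)))
  spectra_table(X, wavelength_grid(seq(500, 900, length.out = 6)),
                labels = rep(1:3, each = n_per))
}

test_that("2:1 Kennard-Stone split reproduces the benchmark class counts", {
  g <- gen_spectra(synth_config(class_sizes = c(800L, 640L, 480L),
                                n_bands = 8, seed = 4))
  sp <- ks_split(g$table)
  y <- g$table$labels
  expect_equal(as.vector(table(y[sp$train_rows])), c(533, 427, 320))
  expect_equal(as.vector(table(y[sp$test_rows])), c(267, 213, 160))
  expect_equal(sort(c(sp$train_rows, sp$test_rows)), seq_along(y))
})

test_that("Kennard-Stone starts from the farthest pair", {
  X <- cbind(c(0, 1, 10), c(0, 1, 10))     # collinear; farthest pair = rows 1, 3
  tab <- spectra_table(X, wavelength_grid(c(500, 600)), labels = rep(1L, 3))
  sp <- ks_split(tab, train_fraction = 2 / 3)
  expect_equal(sp$train_rows, c(1L, 3L))
  expect_equal(sp$test_rows, 2L)
})

test_that("Kennard-Stone equals the naive greedy oracle and is deterministic", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(stats::rnorm(6 * 3), 6)
    tab <- spectra_table(X, wavelength_grid(c(1, 2, 3)), labels = rep(1L, 6))
    sp <- ks_split(tab, train_fraction = 4 / 6)
    expect_equal(sp$train_rows, ks_brute(X, 4L), label = paste("seed", s))
    expect_identical(sp, ks_split(tab, train_fraction = 4 / 6))
  }
})

test_that("Kennard-Stone rejects undersized classes", {
  tab <- spectra_table(matrix(1:4, 2), wavelength_grid(c(1, 2)),
                       labels = c(1L, 1L))
  expect_error(ks_split(tab), "at least 3")
})

test_that("every model separates well-separated classes", {
  tab <- sep_table()
  sp <- ks_split(tab)
  for (kind in c("knn", "lda", "svm_rbf")) {
    cms <- fit_predict(tab, sp, NULL, model_spec(kind))
    expect_gte(accuracy(cms$train), 99, label = kind)
    expect_gte(accuracy(cms$test), 99, label = kind)
    expect_equal(sum(cms$train), length(sp$train_rows))
    expect_equal(sum(cms$test), length(sp$test_rows))
  }
})

test_that("1-NN resubstitution is perfect by construction", {
  g <- gen_spectra(synth_config(class_sizes = c(15L, 12L, 9L), n_bands = 10,
                                seed = 6))
  sp <- ks_split(g$table)
  cms <- fit_predict(g$table, sp, NULL, model_spec("knn", k = 1))
  expect_equal(accuracy(cms$train), 100)
})

test_that("fit_predict validates selection and stratification", {
  tab <- sep_table()
  sp <- ks_split(tab)
  empty <- selection_result("SPA", integer(0), tab$grid)
  expect_error(fit_predict(tab, sp, empty), "empty")
  bad_split <- sp
  bad_split$train_rows <- which(tab$labels != 2)
  bad_split$test_rows <- which(tab$labels == 2)
  expect_error(fit_predict(tab, bad_split, NULL), "absent")
})

test_that("metrics behave on canonical matrices", {
  ident <- confusion_matrix(diag(c(10, 20, 30)))
  expect_equal(accuracy(ident), 100)
  expect_equal(sensitivity(ident), rep(100, 3), ignore_attr = TRUE)
  off <- confusion_matrix(matrix(c(0, 5, 5, 5, 0, 5, 5, 5, 0), 3))
  expect_equal(accuracy(off), 0)
  expect_equal(sensitivity(confusion_matrix(rbind(c(0, 5, 5), c(0, 9, 1),
                                                  c(0, 0, 10))))[1], 0,
               ignore_attr = TRUE)
  unif <- confusion_matrix(matrix(7, 3, 3))
  expect_equal(accuracy_rnd(unif), 100 / 3)
  # balanced perfect classifier: skill above chance = 100 - 33.3 = 66.7
  bal <- confusion_matrix(diag(rep(20, 3)))
  rep_ <- eval_report(bal)
  expect_equal(rep_$display$accuracy_minus_rnd, 100 - 33.3)
  expect_error(accuracy(confusion_matrix(matrix(0, 2, 2))), "empty")
})

test_that("accuracy and chance accuracy are permutation-invariant", {
  set.seed(15)
  m <- matrix(sample(0:30, 9), 3)
  cm <- confusion_matrix(m)
  p <- c(3, 1, 2)
  cmp <- confusion_matrix(m[p, p])
  expect_equal(accuracy(cm), accuracy(cmp))
  expect_equal(accuracy_rnd(cm), accuracy_rnd(cmp))
  expect_equal(sort(sensitivity(cm)), sort(sensitivity(cmp)),
               ignore_attr = TRUE)
})

test_that("label-shuffled models score at chance level", {
  devs <- sapply(1:30, function(s) {
    g <- gen_spectra(synth_config(class_sizes = c(40L, 32L, 24L), n_bands = 12,
                                  seed = s))
    tab <- g$table
    sp <- ks_split(tab)                    # split fixed before permuting
    set.seed(s)
    tab$labels <- sample(tab$labels)       # break any spectrum-label link
    cms <- fit_predict(tab, sp, NULL, model_spec("lda"))
    accuracy(cms$test) - accuracy_rnd(cms$test)
  })
  expect_lt(abs(mean(devs)), 3)
})
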