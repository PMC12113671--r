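# Kennard-Stone partitioning and the three classifiers (KNN, LDA, SVM-RBF).

#' Kennard-Stone train/test split
#'
#' Deterministic max-min Euclidean sample selection, run independently within
#' each freeze-damage class (stratified): the first two training samples of a
#' class are its two mutually farthest spectra; each subsequent pick
#' maximises its minimum distance to the already-chosen set. Selection stops
#' at `round(n_c * train_fraction)` samples per class (round half up); the
#' remainder becomes the testing set. Ties take the lowest row index, so the
#' split is fully reproducible.
#'
#' With the 2:1 ratio and class sizes 800/640/480 this yields training
#' counts 533/427/320 and testing counts 267/213/160.
#'
#' @param table A [spectra_table()]; every class present must have >= 3 rows.
#' @param train_fraction Target training fraction (default 2/3).
#' @return A `split_index`: list with integer vectors `train_rows` and
#'   `test_rows` (global row indices) and the `train_fraction`.
#' @export
ks_split <- function(table, train_fraction = 2 / 3) {
  stopifnot(inherits(table, "spectra_table"))
  X <- table$spectra
  y <- table$labels
  train <- integer(0)
  for (cl in sort(unique(y))) {
    rows <- which(y == cl)
    n_c <- length(rows)
    if (n_c < 3L)
      stop("class ", cl, " has only ", n_c,
           " samples; Kennard-Stone needs at least 3 per class", call. = FALSE)
    n_train <- as.integer(floor(n_c * train_fraction + 0.5))
    n_train <- max(2L, min(n_train, n_c - 1L))
    sel <- .ks_maxmin(X[rows, , drop = FALSE], n_train)
    train <- c(train, rows[sel])
  }
  train <- sort(train)
  structure(list(train_rows = train,
                 test_rows = setdiff(seq_len(nrow(X)), train),
                 train_fraction = train_fraction),
            class = "split_index")
}

# greedy max-min selection of n_sel rows of X; ties -> lowest index
.ks_maxmin <- function(X, n_sel) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  # farthest pair, lowest (i, j) on ties
  best <- c(1L, 2L); best_d <- -Inf
  for (i in seq_len(n - 1L)) {
    j_rel <- which.max(D[i, (i + 1L):n])
    d <- D[i, i + j_rel]
    if (d > best_d) { best_d <- d; best <- c(i, i + j_rel) }
  }
  sel <- best
  min_d <- pmin(D[, sel[1]], D[, sel[2]])
  while (length(sel) < n_sel) {
    min_d[sel] <- -Inf
    nxt <- which.max(min_d)
    sel <- c(sel, nxt)
    min_d <- pmin(min_d, D[, nxt])
  }
  sort(sel)
}

#' @export
print.split_index <- function(x, ...) {
  cat(sprintf("<split_index> %d training / %d testing rows (target fraction %.3f)\n",
              length(x$train_rows), length(x$test_rows), x$train_fraction))
  invisible(x)
}

#' Classifier specification
#'
#' @param kind `"knn"`, `"lda"` or `"svm_rbf"`.
#' @param k Neighbour count for KNN (default 5).
#' @param n_components Discriminant components used by LDA predictions
#'   (default 2, which is also the maximum for 3 classes).
#' @param gamma RBF kernel width for the SVM; `NULL` (default) uses
#'   `1 / (n_bands * var(training X))`.
#' @param cost SVM cost parameter (default 10).
#' @param seed RNG seed used for KNN tie-breaking (default 1).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kind = c("knn", "lda", "svm_rbf"), k = 5L,
                       n_components = 2L, gamma = NULL, cost = 10,
                       seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, k = as.integer(k),
                 n_components = as.integer(n_components),
                 gamma = gamma, cost = cost, seed = as.integer(seed)),
            class = "model_spec")
}

#' Fit a classifier and predict both partitions
#'
#' Restricts the spectra to the selected wavelengths (or the full band set),
#' fits the requested model on the training rows, predicts both partitions,
#' and returns the two confusion matrices (rows = actual class, columns =
#' predicted class).
#'
#' @param table A [spectra_table()].
#' @param split A `split_index` from [ks_split()].
#' @param selection A `selection_result`, or `NULL` for the full band set.
#' @param model A [model_spec()].
#' @return List with `train` and `test` [confusion_matrix()]s.
#' @export
fit_predict <- function(table, split, selection = NULL, model = model_spec()) {
  stopifnot(inherits(table, "spectra_table"), inherits(split, "split_index"),
            inherits(model, "model_spec"))
  cols <- if (is.null(selection)) seq_len(ncol(table$spectra))
          else selection$band_indices
  if (!length(cols))
    stop("empty wavelength selection", call. = FALSE)
  if (max(cols) > ncol(table$spectra))
    stop("selection indices exceed the table's band count", call. = FALSE)
  X <- table$spectra[, cols, drop = FALSE]
  y <- table$labels
  tr <- split$train_rows; te <- split$test_rows
  classes <- sort(unique(y))
  if (!all(classes %in% y[tr]))
    stop("a class is absent from the training partition", call. = FALSE)
  ytr <- factor(y[tr], levels = classes)
  pred <- switch(model$kind,
    knn = {
      set.seed(model$seed)   # KNN distance ties are broken at random
      list(train = class::knn(X[tr, , drop = FALSE], X[tr, , drop = FALSE],
                              ytr, k = model$k),
           test = class::knn(X[tr, , drop = FALSE], X[te, , drop = FALSE],
                             ytr, k = model$k))
    },
    lda = {
      # collinearity warnings are expected for full-band spectra (B >> n)
      fit <- suppressWarnings(MASS::lda(X[tr, , drop = FALSE], grouping = ytr))
      dimen <- min(model$n_components, length(fit$svd))
      list(train = stats::predict(fit, X[tr, , drop = FALSE], dimen = dimen)$class,
           test = stats::predict(fit, X[te, , drop = FALSE], dimen = dimen)$class)
    },
    svm_rbf = {
      g <- model$gamma
      if (is.null(g)) {
        v <- stats::var(as.vector(X[tr, , drop = FALSE]))
        g <- 1 / (ncol(X) * max(v, .Machine$double.eps))
      }
      fit <- e1071::svm(X[tr, , drop = FALSE], ytr, kernel = "radial",
                        gamma = g, cost = model$cost, scale = FALSE)
      list(train = stats::predict(fit, X[tr, , drop = FALSE]),
           test = stats::predict(fit, X[te, , drop = FALSE]))
    })
  list(train = confusion_matrix(.count_confusion(y[tr], pred$train, classes)),
       test = confusion_matrix(.count_confusion(y[te], pred$test, classes)))
}

.count_confusion <- function(actual, predicted, classes) {
  actual <- factor(actual, levels = classes)
  predicted <- factor(predicted, levels = classes)
  m <- table(actual, predicted)
  mat <- matrix(as.integer(m), nrow = length(classes),
                dimnames = list(actual = as.character(classes),
                                predicted = as.character(classes)))
  mat
}
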