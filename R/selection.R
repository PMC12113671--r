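# Feature-wavelength selection: successive projections algorithm (SPA),
# 2DCOS synchronous-spectrum autocorrelation peaks, and their fusion.

#' Construct a selection result
#'
#' An ordered set of selected wavelengths with the method that produced it
#' and a per-wavelength provenance tag (which selector contributed it —
#' useful after fusion).
#'
#' @param method `"SPA"`, `"2DCOS"` or `"SPA+2DCOS"`.
#' @param band_indices Integer band indices (1-based into the grid).
#' @param grid [wavelength_grid()] the indices refer to.
#' @param provenance Character vector of source tags, one per band
#'   (default: `method` for all).
#' @return An object of class `selection_result`, indices sorted ascending.
#' @export
selection_result <- function(method, band_indices, grid, provenance = NULL) {
  if (!inherits(grid, "wavelength_grid")) grid <- wavelength_grid(grid)
  band_indices <- as.integer(band_indices)
  if (anyDuplicated(band_indices))
    stop("band indices must be unique", call. = FALSE)
  if (length(band_indices) &&
      (min(band_indices) < 1L || max(band_indices) > length(grid)))
    stop("band indices out of range for the grid", call. = FALSE)
  if (is.null(provenance)) provenance <- rep(method, length(band_indices))
  ord <- order(band_indices)
  structure(list(method = method,
                 band_indices = band_indices[ord],
                 wavelengths_nm = as.numeric(grid)[band_indices[ord]],
                 provenance = provenance[ord],
                 grid = grid),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d wavelength(s)\n  %s nm\n",
              x$method, length(x$band_indices),
              paste(round(x$wavelengths_nm), collapse = ", ")))
  invisible(x)
}

#' @export
length.selection_result <- function(x) length(x$band_indices)

#' SPA projection chain
#'
#' The successive projections algorithm's forward recursion. Columns of `X`
#' are mean-centred; starting from `start_band`, each step projects every
#' unselected column onto the orthogonal complement of the span of the
#' selected columns and appends the column with the largest projected norm.
#' The chain therefore accumulates wavelengths with minimal collinearity.
#'
#' @param X Numeric `n x B` spectra matrix (rows = samples).
#' @param start_band 1-based index of the first selected column.
#' @param max_len Maximum chain length (`<= B`). The chain stops early if all
#'   remaining projected norms are numerically zero (exhausted column space).
#' @return Integer vector of band indices in selection order.
#' @export
spa_chain <- function(X, start_band, max_len) {
  X <- as.matrix(X)
  B <- ncol(X)
  if (max_len > B || max_len < 1L)
    stop("max_len must be in [1, ", B, "]", call. = FALSE)
  if (start_band < 1L || start_band > B)
    stop("start_band out of range", call. = FALSE)
  R <- sweep(X, 2L, colMeans(X))        # residual matrix, deflated in place
  chain <- integer(0)
  j <- as.integer(start_band)
  tol <- max(abs(R)) * 1e-10 + 1e-300
  for (step in seq_len(max_len)) {
    chain <- c(chain, j)
    if (step == max_len) break
    pj <- R[, j]
    nj2 <- sum(pj^2)
    if (nj2 > tol^2)
      R <- R - pj %*% crossprod(pj, R) / nj2   # Gram-Schmidt deflation
    norms <- sqrt(colSums(R^2))
    norms[chain] <- -Inf
    if (max(norms) <= tol) break               # column space exhausted
    j <- which.max(norms)                      # lowest index on ties
  }
  chain
}

# deterministic stratified fold assignment: within each class, rows are taken
# in index order and dealt to folds cyclically
.stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    if (length(idx) < folds)
      stop("class ", cl, " has ", length(idx), " samples, fewer than ", folds,
           " folds; reduce the fold count", call. = FALSE)
    fold[idx] <- ((seq_along(idx) - 1L) %% folds) + 1L
  }
  fold
}

# cross-validated misclassification rate of LDA on the given columns
.cv_lda_error <- function(X, y, cols, fold) {
  folds <- max(fold)
  wrong <- 0L
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- tryCatch(
      suppressWarnings(MASS::lda(X[tr, cols, drop = FALSE], grouping = y[tr])),
      error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    pred <- tryCatch(
      stats::predict(fit, X[!tr, cols, drop = FALSE])$class,
      error = function(e) NULL)
    if (is.null(pred)) return(Inf)
    wrong <- wrong + sum(as.integer(as.character(pred)) != y[!tr])
  }
  wrong / length(y)
}

#' SPA wavelength selection
#'
#' Runs the SPA chain ([spa_chain()]) from every candidate start band and
#' scores every prefix of length `k_min..k_max` by the stratified
#' cross-validated misclassification rate of a linear discriminant fitted on
#' those bands. The subset with the lowest error wins; ties prefer fewer
#' wavelengths, then the smaller first band index. Selection must be run on
#' the training partition only so that no test information leaks into the
#' wavelength choice.
#'
#' @param X Numeric `n x B` training spectra.
#' @param y Integer class labels (one per row).
#' @param k_min,k_max Subset-size range searched (defaults 1 and 20).
#' @param grid [wavelength_grid()] for the columns of `X`.
#' @param folds Cross-validation folds (default 5, deterministic stratified
#'   assignment in row order).
#' @param starts Candidate start bands (default: every band).
#' @return A `selection_result` with `method = "SPA"`. The winning CV error
#'   is attached as attribute `"cv_error"`.
#' @export
spa_select <- function(X, y, k_min = 1L, k_max = 20L, grid = NULL,
                       folds = 5L, starts = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  B <- ncol(X)
  k_max <- min(k_max, B)
  if (k_min < 1L || k_min > k_max)
    stop("need 1 <= k_min <= k_max <= ncol(X)", call. = FALSE)
  if (is.null(grid)) grid <- wavelength_grid(seq_len(B) + 0.0)
  if (is.null(starts)) starts <- seq_len(B)
  fold <- .stratified_folds(y, folds)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  best <- list(err = Inf, k = Inf, first = Inf, cols = NULL)
  for (s in starts) {
    chain <- spa_chain(X, s, k_max)
    for (k in seq.int(k_min, min(k_max, length(chain)))) {
      cols <- chain[seq_len(k)]
      key <- paste(sort(cols), collapse = ",")
      if (!is.null(seen[[key]])) {
        err <- seen[[key]]
      } else {
        err <- .cv_lda_error(X, y, cols, fold)
        seen[[key]] <- err
      }
      better <- err < best$err ||
        (err == best$err && (k < best$k ||
                             (k == best$k && cols[1] < best$first)))
      if (better) best <- list(err = err, k = k, first = cols[1], cols = cols)
    }
  }
  if (is.null(best$cols))
    stop("SPA found no scorable subset (LDA failed everywhere)", call. = FALSE)
  res <- selection_result("SPA", best$cols, grid)
  attr(res, "cv_error") <- best$err
  res
}

#' 2DCOS synchronous spectrum
#'
#' Two-dimensional correlation spectroscopy treats an ordered series of
#' spectra (here: the class-mean spectra ordered by freeze-damage severity)
#' as the response to an external perturbation. The synchronous spectrum is
#' the covariance of the dynamic (series-mean-removed) spectra:
#' `phi(v1, v2) = 1/(m-1) * sum_j ytilde_j(v1) * ytilde_j(v2)`.
#'
#' @param series Numeric `m x B` matrix: `m >= 2` spectra in perturbation
#'   order.
#' @param grid [wavelength_grid()] for the columns.
#' @return A `sync_spectrum`: list with `phi` (`B x B`, symmetric,
#'   non-negative diagonal), `grid`, and `series_length`.
#' @export
sync_spectrum <- function(series, grid = NULL) {
  series <- as.matrix(series)
  m <- nrow(series)
  if (m < 2L)
    stop("a perturbation series needs at least 2 spectra", call. = FALSE)
  if (is.null(grid)) grid <- wavelength_grid(seq_len(ncol(series)) + 0.0)
  if (!inherits(grid, "wavelength_grid")) grid <- wavelength_grid(grid)
  if (length(grid) != ncol(series))
    stop("grid length does not match the number of bands", call. = FALSE)
  dyn <- sweep(series, 2L, colMeans(series))
  phi <- crossprod(dyn) / (m - 1)
  structure(list(phi = phi, grid = grid, series_length = m),
            class = "sync_spectrum")
}

#' @export
print.sync_spectrum <- function(x, ...) {
  cat(sprintf("<sync_spectrum> %d x %d synchronous matrix from a series of %d spectra\n",
              nrow(x$phi), ncol(x$phi), x$series_length))
  invisible(x)
}

# topographic prominence of local maxima of a curve, scipy-style: walk out
# from the peak to the nearest higher point (or the boundary) on each side
# and take the lowest valley found; prominence = peak - higher of the two
# valley floors
.peak_prominences <- function(d, peaks) {
  vapply(peaks, function(p) {
    h <- d[p]
    i <- p; left_min <- h
    while (i > 1L && d[i - 1L] <= h) {
      i <- i - 1L
      if (d[i] < left_min) left_min <- d[i]
    }
    i <- p; right_min <- h
    n <- length(d)
    while (i < n && d[i + 1L] <= h) {
      i <- i + 1L
      if (d[i] < right_min) right_min <- d[i]
    }
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Autocorrelation-peak wavelength selection (2DCOS)
#'
#' The diagonal of the synchronous spectrum, `phi(v, v)`, is the
#' autocorrelation curve: it measures how strongly each wavelength responds
#' to the perturbation. Local maxima of this curve whose topographic
#' prominence reaches `min_rel_prominence` times the curve's maximum are
#' returned as the selected wavelengths.
#'
#' @param sync A `sync_spectrum` from [sync_spectrum()].
#' @param min_rel_prominence Minimum peak prominence as a fraction of the
#'   diagonal maximum (default 0.05).
#' @return A `selection_result` with `method = "2DCOS"`; empty (no error) if
#'   the diagonal is flat.
#' @export
autocorr_peaks <- function(sync, min_rel_prominence = 0.05) {
  stopifnot(inherits(sync, "sync_spectrum"))
  d <- diag(sync$phi)
  n <- length(d)
  if (max(d) <= 0 || n < 3L)
    return(selection_result("2DCOS", integer(0), sync$grid))
  # interior local maxima; a plateau is represented by its first point
  is_peak <- logical(n)
  for (i in 2:(n - 1L))
    is_peak[i] <- d[i] > d[i - 1L] && d[i] >= d[i + 1L]
  peaks <- which(is_peak)
  if (!length(peaks))
    return(selection_result("2DCOS", integer(0), sync$grid))
  prom <- .peak_prominences(d, peaks)
  keep <- peaks[prom >= min_rel_prominence * max(d)]
  selection_result("2DCOS", keep, sync$grid)
}

#' 2DCOS selection from a spectra table
#'
#' Convenience wrapper for the usual pipeline: the perturbation series is the
#' class-mean spectra ordered by freeze severity (normal, slight, severe);
#' the synchronous spectrum is formed and its autocorrelation peaks are
#' extracted. Use training rows only.
#'
#' @param table A [spectra_table()].
#' @param rows Row indices to use (default: all rows).
#' @inheritParams autocorr_peaks
#' @return A `selection_result` with `method = "2DCOS"`.
#' @export
cos2d_select <- function(table, rows = NULL, min_rel_prominence = 0.05) {
  stopifnot(inherits(table, "spectra_table"))
  if (is.null(rows)) rows <- seq_len(nrow(table$spectra))
  X <- table$spectra[rows, , drop = FALSE]
  y <- table$labels[rows]
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    stop("2DCOS needs at least 2 severity classes in the series", call. = FALSE)
  means <- t(vapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]),
                    numeric(ncol(X))))
  autocorr_peaks(sync_spectrum(means, table$grid), min_rel_prominence)
}

#' Fuse two wavelength selections
#'
#' Sorted, de-duplicated union of two selections on the same grid, keeping a
#' per-wavelength provenance tag (wavelengths found by both selectors are
#' tagged with both methods).
#'
#' @param a,b `selection_result`s on the same grid.
#' @return A `selection_result` with `method = "SPA+2DCOS"` (or
#'   `"<a>+<b>"` for other method pairs).
#' @export
fuse_selections <- function(a, b) {
  stopifnot(inherits(a, "selection_result"), inherits(b, "selection_result"))
  if (!isTRUE(all.equal(as.numeric(a$grid), as.numeric(b$grid))))
    stop("selections refer to different wavelength grids", call. = FALSE)
  idx <- sort(unique(c(a$band_indices, b$band_indices)))
  prov <- vapply(idx, function(i) {
    tags <- c(a$provenance[match(i, a$band_indices)],
              b$provenance[match(i, b$band_indices)])
    paste(unique(tags[!is.na(tags)]), collapse = "+")
  }, character(1))
  method <- if (setequal(c(a$method, b$method), c("SPA", "2DCOS")))
    "SPA+2DCOS" else paste(a$method, b$method, sep = "+")
  selection_result(method, idx, a$grid, provenance = prov)
}
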