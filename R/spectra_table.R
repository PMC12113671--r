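# Per-seed mean-spectra table: the working currency of the pipeline.

#' Construct a spectra table
#'
#' An `n x B` matrix of per-seed mean reflectance spectra together with its
#' wavelength grid, a freeze-damage class label per seed (1 = normal,
#' 2 = slightly damaged, 3 = severely damaged), the kernel face the spectra
#' were taken from, and a tag recording which preprocessing has been applied.
#'
#' @param spectra Numeric matrix, one row per seed, one column per band.
#' @param grid [wavelength_grid()] (or numeric centres) matching `ncol(spectra)`.
#' @param labels Integer vector in `{1, 2, 3}`, one per row.
#' @param side `"endosperm"` or `"embryo"`.
#' @param preprocessing `"none"`, `"snv"` or `"sg53"`.
#' @return An object of class `spectra_table`.
#' @export
spectra_table <- function(spectra, grid, labels,
                          side = c("endosperm", "embryo"),
                          preprocessing = c("none", "snv", "sg53")) {
  side <- match.arg(side)
  preprocessing <- match.arg(preprocessing)
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  if (!inherits(grid, "wavelength_grid")) grid <- wavelength_grid(grid)
  labels <- as.integer(labels)
  if (nrow(spectra) < 1L)
    stop("spectra table needs at least one row", call. = FALSE)
  if (ncol(spectra) != length(grid))
    stop("ncol(spectra) = ", ncol(spectra), " does not match grid length ",
         length(grid), call. = FALSE)
  if (length(labels) != nrow(spectra))
    stop("need one class label per spectrum", call. = FALSE)
  if (anyNA(spectra))
    stop("spectra contain missing values", call. = FALSE)
  if (!all(labels %in% 1:3))
    stop("labels must be 1 (normal), 2 (slight) or 3 (severe)", call. = FALSE)
  structure(list(spectra = spectra, grid = grid, labels = labels,
                 side = side, preprocessing = preprocessing),
            class = "spectra_table")
}

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf("<spectra_table> %d spectra x %d bands (%.1f-%.1f nm), side = %s, preprocessing = %s\n",
              nrow(x$spectra), ncol(x$spectra), min(x$grid), max(x$grid),
              x$side, x$preprocessing))
  cat("  class counts:",
      paste(sprintf("%d: %d", 1:3, tabulate(x$labels, 3L)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectra_table <- function(x) dim(x$spectra)

#' @rdname trim_bands
#' @export
trim_bands.spectra_table <- function(x, first_index, last_index) {
  .check_trim_idx(first_index, last_index, length(x$grid))
  keep <- seq.int(first_index, last_index)
  spectra_table(x$spectra[, keep, drop = FALSE],
                wavelength_grid(as.numeric(x$grid)[keep]),
                x$labels, side = x$side, preprocessing = x$preprocessing)
}

#' Write a spectra table to CSV
#'
#' One row per seed; wavelength columns are named `wl_<nm>`, followed by
#' `label`, `side` and `preprocessing` columns.
#'
#' @param table A [spectra_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(table, path) {
  stopifnot(inherits(table, "spectra_table"))
  df <- as.data.frame(table$spectra)
  names(df) <- sprintf("wl_%.4f", as.numeric(table$grid))
  df$label <- table$labels
  df$side <- table$side
  df$preprocessing <- table$preprocessing
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a spectra table from CSV
#'
#' @param path CSV written by [write_spectra_csv()] (wavelength columns
#'   `wl_<nm>` plus `label`, `side`, `preprocessing`).
#' @return A [spectra_table()].
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wl_cols <- grep("^wl_", names(df), value = TRUE)
  if (length(wl_cols) < 2L || !"label" %in% names(df))
    stop("not a spectra-table CSV (need wl_* columns and a label column): ",
         path, call. = FALSE)
  grid <- wavelength_grid(as.numeric(sub("^wl_", "", wl_cols)))
  side <- if ("side" %in% names(df)) as.character(df$side[1]) else "endosperm"
  prep <- if ("preprocessing" %in% names(df)) as.character(df$preprocessing[1]) else "none"
  spectra_table(as.matrix(df[, wl_cols, drop = FALSE]), grid, df$label,
                side = side, preprocessing = prep)
}

# internal: replace the spectra matrix, keeping metadata, with a new tag
.retag <- function(table, spectra, preprocessing) {
  out <- table
  out$spectra <- spectra
  out$preprocessing <- preprocessing
  out
}
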