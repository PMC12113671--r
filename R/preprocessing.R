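# Spectral preprocessing: standard normal variate and 5-point cubic smoothing.

#' Standard normal variate (SNV)
#'
#' Centers every spectrum to mean 0 and scales it to sample standard
#' deviation 1 (denominator `B - 1`), row by row. SNV removes per-seed
#' multiplicative scatter and additive baseline shifts caused by particle
#' size, surface scattering and optical-path variation, so
#' `snv(a * x + b) == snv(x)` for any `a > 0`.
#'
#' @param table A [spectra_table()]; every row must be non-constant.
#' @return The table with transformed spectra and `preprocessing = "snv"`.
#' @export
snv <- function(table) {
  stopifnot(inherits(table, "spectra_table"))
  X <- table$spectra
  mu <- rowMeans(X)
  sdv <- apply(X, 1L, stats::sd)
  if (any(sdv == 0))
    stop("constant spectrum in row(s) ",
         paste(which(sdv == 0), collapse = ", "),
         ": SNV is undefined", call. = FALSE)
  .retag(table, (X - mu) / sdv, "snv")
}

#' 5-point cubic Savitzky-Golay smoothing (5-3 smoothing)
#'
#' Least-squares smoothing with a 5-point window and a 3rd-order polynomial.
#' Interior points are the convolution with the kernel
#' `(-3, 12, 17, 12, -3) / 35`; the two points at each end are obtained by
#' fitting the boundary window's polynomial and evaluating it at the edge
#' positions, so a spectrum sampled from any cubic passes through unchanged.
#'
#' @param table A [spectra_table()] with at least 5 bands.
#' @param passes Number of smoothing passes (default 1).
#' @return The table with smoothed spectra and `preprocessing = "sg53"`.
#' @export
sg53 <- function(table, passes = 1L) {
  stopifnot(inherits(table, "spectra_table"))
  if (ncol(table$spectra) < 5L)
    stop("5-3 smoothing needs at least 5 bands", call. = FALSE)
  if (passes < 1L)
    stop("passes must be >= 1", call. = FALSE)
  X <- table$spectra
  for (p in seq_len(passes))
    X <- t(apply(X, 1L, signal::sgolayfilt, p = 3, n = 5))
  .retag(table, X, "sg53")
}

#' Apply a preprocessing arm by name
#'
#' @param table A [spectra_table()].
#' @param method `"none"`, `"snv"` or `"sg53"`.
#' @return The (possibly transformed) table.
#' @export
preprocess <- function(table, method = c("none", "snv", "sg53")) {
  method <- match.arg(method)
  switch(method, none = table, snv = snv(table), sg53 = sg53(table))
}
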