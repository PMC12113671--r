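# Seed segmentation: gray-band extraction, contrast stretch, Otsu threshold,
# connected-component labeling, per-seed mean spectra.

#' Extract the gray image at a wavelength
#'
#' Returns the single band whose centre is nearest to the requested
#' wavelength (700 nm is the usual segmentation band for the endosperm face,
#' 500 nm for the embryo face).
#'
#' @param cube A [hyper_cube()].
#' @param wavelength_nm Requested wavelength; must lie within the grid range.
#' @return A 2-D numeric matrix (line x sample). The band index used is
#'   attached as attribute `"band"`.
#' @export
to_gray <- function(cube, wavelength_nm) {
  stopifnot(inherits(cube, "hyper_cube"))
  wl <- as.numeric(cube$grid)
  if (wavelength_nm < min(wl) || wavelength_nm > max(wl))
    stop("wavelength ", wavelength_nm, " nm is outside the grid range [",
         min(wl), ", ", max(wl), "] nm", call. = FALSE)
  band <- which.min(abs(wl - wavelength_nm))
  structure(cube$values[, , band], band = band)
}

#' Percentile contrast stretch
#'
#' Linear stretch mapping the `low_pct` percentile to 0 and the `high_pct`
#' percentile to 1, clipping outside. A strictly monotone map, so it never
#' changes the pixel partition found by a threshold that is searched over the
#' stretched histogram.
#'
#' @param image 2-D numeric matrix.
#' @param low_pct,high_pct Percentiles in `[0, 100]`, `low_pct < high_pct`.
#' @return Matrix with values in `[0, 1]`. If the image is constant it is
#'   returned unchanged with a warning and attribute `constant = TRUE`.
#' @export
enhance <- function(image, low_pct = 1, high_pct = 99) {
  stopifnot(is.matrix(image), low_pct < high_pct)
  q <- stats::quantile(image, c(low_pct, high_pct) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    warning("constant (or near-constant) image; returning unchanged")
    return(structure(image, constant = TRUE))
  }
  out <- (image - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Otsu threshold
#'
#' Builds a 256-bin histogram over the image's value range and returns the
#' cut that maximises the between-class variance of the two resulting pixel
#' groups (bin centres weighted by counts). Pixels strictly above the
#' returned value form the foreground.
#'
#' @param image 2-D numeric matrix with at least two distinct values.
#' @param levels Number of histogram bins (default 256).
#' @return The threshold value (a bin edge). Ties take the lowest cut.
#' @export
otsu_threshold <- function(image, levels = 256L) {
  v <- as.vector(image)
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("cannot threshold a constant image", call. = FALSE)
  edges <- seq(rng[1], rng[2], length.out = levels + 1L)
  bin <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = levels)
  centers <- (edges[-1] + edges[-(levels + 1L)]) / 2
  w <- counts / length(v)
  mu <- centers * w
  cw <- cumsum(w)[-levels]        # background weight at cut after bin t
  cmu <- cumsum(mu)[-levels]      # background first moment
  mu_t <- sum(mu)
  valid <- cw > 0 & cw < 1
  # between-class variance: (mu_t*w0 - mu0)^2 / (w0*(1-w0))
  sigma_b <- rep(-Inf, levels - 1L)
  sigma_b[valid] <- (mu_t * cw[valid] - cmu[valid])^2 /
    (cw[valid] * (1 - cw[valid]))
  t_best <- which.max(sigma_b)    # lowest index on ties
  edges[t_best + 1L]
}

#' Label connected seed regions
#'
#' Connected-component labeling of a binary foreground mask. Components are
#' numbered in raster order (row-major) of their first pixel; components
#' smaller than `min_area` pixels (glare specks) are dropped.
#'
#' @param binary_mask 2-D logical (or 0/1) matrix, `TRUE` = seed pixel.
#' @param min_area Minimum component area in pixels (default 50).
#' @param connectivity 4 or 8 (default 8).
#' @return A `seed_mask`: list with `labels` (integer matrix, 0 = background),
#'   `seed_count`, and `areas` (pixels per seed).
#' @export
label_seeds <- function(binary_mask, min_area = 50L, connectivity = 8L) {
  stopifnot(is.matrix(binary_mask), connectivity %in% c(4L, 8L))
  fg <- binary_mask != 0
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 4L) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  }
  next_lab <- 0L
  # scan row-major so labels come out in raster order of the first pixel
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!fg[r, c] || lab[r, c] != 0L) next
    next_lab <- next_lab + 1L
    stack_r <- integer(nr * nc); stack_c <- integer(nr * nc)
    stack_r[1] <- r; stack_c[1] <- c; top <- 1L
    lab[r, c] <- next_lab
    while (top > 0L) {
      cr <- stack_r[top]; cc <- stack_c[top]; top <- top - 1L
      for (k in seq_along(dr)) {
        rr <- cr + dr[k]; ccn <- cc + dc[k]
        if (rr >= 1L && rr <= nr && ccn >= 1L && ccn <= nc &&
            fg[rr, ccn] && lab[rr, ccn] == 0L) {
          lab[rr, ccn] <- next_lab
          top <- top + 1L
          stack_r[top] <- rr; stack_c[top] <- ccn
        }
      }
    }
  }
  if (next_lab == 0L)
    stop("empty mask: no foreground component found", call. = FALSE)
  areas <- tabulate(lab[lab > 0L], nbins = next_lab)
  keep <- which(areas >= min_area)
  if (!length(keep))
    stop("empty mask: no component reaches min_area = ", min_area, call. = FALSE)
  remap <- integer(next_lab)
  remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  structure(list(labels = lab, seed_count = length(keep), areas = areas[keep]),
            class = "seed_mask")
}

#' @export
print.seed_mask <- function(x, ...) {
  cat(sprintf("<seed_mask> %d seed(s) on a %d x %d image, areas %s px\n",
              x$seed_count, nrow(x$labels), ncol(x$labels),
              paste(x$areas, collapse = "/")))
  invisible(x)
}

#' Per-seed mean spectra
#'
#' Averages the pixel spectra of every labeled seed region at every band,
#' yielding one mean spectrum per seed. The mean is the plain arithmetic mean
#' over the region's pixels, so the result does not depend on pixel
#' enumeration order.
#'
#' @param cube A calibrated [hyper_cube()].
#' @param mask A `seed_mask` from [label_seeds()] whose `labels` matrix
#'   matches the cube's spatial shape.
#' @param labels Freeze-damage class per seed (vector of length
#'   `mask$seed_count`, values in 1..3).
#' @param side `"endosperm"` or `"embryo"`.
#' @return A [spectra_table()] with one row per seed, in seed-label order.
#' @export
mean_spectra <- function(cube, mask, labels, side = c("endosperm", "embryo")) {
  side <- match.arg(side)
  stopifnot(inherits(cube, "hyper_cube"), inherits(mask, "seed_mask"))
  if (!cube$calibrated)
    stop("cube must be calibrated before extracting mean spectra", call. = FALSE)
  d <- dim(cube$values)
  if (!identical(dim(mask$labels), d[1:2]))
    stop("mask shape does not match the cube's spatial shape", call. = FALSE)
  lv <- as.vector(mask$labels)          # column-major, matches array reshaping
  pix <- matrix(cube$values, nrow = d[1] * d[2], ncol = d[3])
  counts <- tabulate(lv[lv > 0L], nbins = mask$seed_count)
  if (any(counts == 0L))
    stop("internal consistency error: seed with zero pixels", call. = FALSE)
  sums <- rowsum(pix[lv > 0L, , drop = FALSE], group = lv[lv > 0L])
  spectra_table(sums / counts, cube$grid, labels, side = side,
                preprocessing = "none")
}

#' One-call seed segmentation
#'
#' Convenience pipeline: gray band nearest `wavelength_nm` -> percentile
#' contrast stretch -> Otsu threshold -> connected-component labeling.
#'
#' @inheritParams to_gray
#' @inheritParams label_seeds
#' @param low_pct,high_pct Stretch percentiles passed to [enhance()].
#' @return A `seed_mask`.
#' @export
segment_cube <- function(cube, wavelength_nm, low_pct = 1, high_pct = 99,
                         min_area = 50L, connectivity = 8L) {
  g <- enhance(to_gray(cube, wavelength_nm), low_pct, high_pct)
  thr <- otsu_threshold(g)
  label_seeds(g > thr, min_area = min_area, connectivity = connectivity)
}
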