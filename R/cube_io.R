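# Hyperspectral cube container, ENVI I/O, reflectance calibration, band trimming.

#' Construct a wavelength grid
#'
#' A wavelength grid is the vector of band-centre wavelengths (nm) attached to
#' a hyperspectral cube or a spectra table. Centres must be strictly
#' increasing and there must be at least two bands.
#'
#' @param centers Numeric vector of band-centre wavelengths in nanometres.
#' @return A numeric vector of class `wavelength_grid`.
#' @examples
#' wavelength_grid(seq(450, 979, length.out = 420))
#' @export
wavelength_grid <- function(centers) {
  centers <- as.numeric(centers)
  if (length(centers) < 2L)
    stop("a wavelength grid needs at least 2 bands", call. = FALSE)
  if (anyNA(centers) || any(diff(centers) <= 0))
    stop("wavelength centers must be finite and strictly increasing", call. = FALSE)
  structure(centers, class = "wavelength_grid")
}

#' The instrument-emulating 477-band grid
#'
#' Visible/near-infrared imaging spectrometers of the class used for seed
#' inspection record 477 bands across 400-1000 nm. The exact band centres of
#' the instrument binning are not published, so an evenly spaced grid over
#' that range is used wherever a full-sensor grid is needed (band trimming
#' then reduces it to the 450-979 nm analysis window).
#'
#' @param n_bands Number of bands (default 477).
#' @param range_nm Length-2 numeric, wavelength range in nm (default 400-1000).
#' @return A `wavelength_grid`.
#' @export
instrument_grid <- function(n_bands = 477L, range_nm = c(400, 1000)) {
  wavelength_grid(seq(range_nm[1], range_nm[2], length.out = n_bands))
}

#' Construct a hyperspectral cube
#'
#' A cube stores reflectance (or raw-count) values on a
#' (line, sample, band) array together with its wavelength grid and a flag
#' recording whether dark/white reflectance calibration has been applied.
#'
#' @param values 3-D numeric array indexed (line, sample, band).
#' @param grid `wavelength_grid` (or numeric vector of centres) whose length
#'   equals the band dimension.
#' @param calibrated Logical; `TRUE` once [calibrate()] has been applied.
#' @return An object of class `hyper_cube`.
#' @export
hyper_cube <- function(values, grid, calibrated = FALSE) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3-D array (line, sample, band)", call. = FALSE)
  if (!inherits(grid, "wavelength_grid")) grid <- wavelength_grid(grid)
  if (dim(values)[3] != length(grid))
    stop("band dimension (", dim(values)[3], ") does not match grid length (",
         length(grid), ")", call. = FALSE)
  structure(list(values = values, grid = grid, calibrated = isTRUE(calibrated)),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hyper_cube> %d lines x %d samples x %d bands (%.1f-%.1f nm), %s\n",
              d[1], d[2], d[3], min(x$grid), max(x$grid),
              if (x$calibrated) "calibrated" else "raw"))
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$values)

# ENVI data-type codes handled by the reader/writer
.envi_types <- list(
  `1`  = list(what = "integer", size = 1L, signed = FALSE),
  `2`  = list(what = "integer", size = 2L, signed = TRUE),
  `3`  = list(what = "integer", size = 4L, signed = TRUE),
  `4`  = list(what = "double",  size = 4L, signed = TRUE),
  `5`  = list(what = "double",  size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

.parse_envi_header <- function(header_path) {
  txt <- readLines(header_path, warn = FALSE)
  if (!length(txt) || !grepl("^ENVI", txt[1]))
    stop("not an ENVI header (missing 'ENVI' magic): ", header_path, call. = FALSE)
  # join continuation lines of { ... } blocks onto their opening line
  joined <- character(0)
  balance <- 0L
  for (ln in txt[-1]) {
    if (balance > 0L) {
      joined[length(joined)] <- paste(joined[length(joined)], ln)
    } else {
      joined <- c(joined, ln)
    }
    balance <- balance +
      sum(charToRaw(ln) == charToRaw("{")) - sum(charToRaw(ln) == charToRaw("}"))
  }
  fields <- list()
  for (ln in joined) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 1L) next
    key <- tolower(trimws(substr(ln, 1L, eq - 1L)))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    if (nzchar(key)) fields[[key]] <- val
  }
  fields
}

.find_envi_raw <- function(header_path) {
  base <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
  cand <- c(base, paste0(base, c(".raw", ".dat", ".img", ".bil", ".bip", ".bsq")))
  hit <- cand[file.exists(cand) & cand != header_path]
  if (!length(hit))
    stop("no raw data file found next to header: ", header_path, call. = FALSE)
  hit[1]
}

#' Read an ENVI hyperspectral cube
#'
#' Reads an ASCII ENVI header (`.hdr`) and its sibling raw binary file
#' (band-interleaved BIL, BIP or BSQ; little- or big-endian; integer or
#' floating-point sample formats). The wavelength list in the header becomes
#' the cube's grid.
#'
#' @param header_path Path to the `.hdr` file. The raw file is located by
#'   stripping the `.hdr` extension (with `.raw`, `.dat`, `.img` and
#'   interleave-named fallbacks).
#' @return A [hyper_cube()] with `calibrated = FALSE`.
#' @seealso [write_envi()], [calibrate()]
#' @export
read_envi <- function(header_path) {
  if (!file.exists(header_path))
    stop("header file does not exist: ", header_path, call. = FALSE)
  h <- .parse_envi_header(header_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  if (length(miss))
    stop("ENVI header missing field(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(h[["wavelength"]]))
    stop("ENVI header has no wavelength list; cannot build the grid", call. = FALSE)
  ns <- as.integer(h[["samples"]]); nl <- as.integer(h[["lines"]])
  nb <- as.integer(h[["bands"]])
  dtype <- as.character(as.integer(h[["data type"]]))
  interleave <- tolower(h[["interleave"]])
  byte_order <- if (is.null(h[["byte order"]])) 0L else as.integer(h[["byte order"]])
  spec <- .envi_types[[dtype]]
  if (is.null(spec))
    stop("unsupported ENVI data type code: ", dtype, call. = FALSE)
  wl <- as.numeric(strsplit(gsub("[{}]", "", h[["wavelength"]]), ",")[[1]])
  if (length(wl) != nb)
    stop("header declares ", nb, " bands but lists ", length(wl), " wavelengths",
         call. = FALSE)
  raw_path <- .find_envi_raw(header_path)
  n_vox <- as.numeric(ns) * nl * nb
  expect_bytes <- n_vox * spec$size
  if (file.size(raw_path) != expect_bytes)
    stop("corrupt ENVI file: raw size ", file.size(raw_path),
         " bytes does not match header (", expect_bytes, " bytes for ",
         nl, "x", ns, "x", nb, ")", call. = FALSE)
  con <- file(raw_path, "rb"); on.exit(close(con))
  v <- readBin(con, what = spec$what, n = n_vox, size = spec$size,
               signed = spec$signed,
               endian = if (byte_order == 0L) "little" else "big")
  # raw vector order: fastest-varying index first
  a <- switch(interleave,
    bsq = aperm(array(v, dim = c(ns, nl, nb)), c(2, 1, 3)),
    bil = aperm(array(v, dim = c(ns, nb, nl)), c(3, 1, 2)),
    bip = aperm(array(v, dim = c(nb, ns, nl)), c(3, 2, 1)),
    stop("unsupported interleave: ", interleave, call. = FALSE))
  hyper_cube(a, wavelength_grid(wl), calibrated = FALSE)
}

#' Write a cube as an ENVI header + raw binary pair
#'
#' @param cube A [hyper_cube()].
#' @param header_path Output `.hdr` path; the raw file is written next to it
#'   with a `.raw` extension.
#' @param interleave One of `"bil"`, `"bip"`, `"bsq"`.
#' @param data_type ENVI data-type code; 5 (64-bit float, the default) round
#'   trips R doubles bitwise, 4 is 32-bit float.
#' @return `header_path`, invisibly.
#' @export
write_envi <- function(cube, header_path, interleave = c("bil", "bip", "bsq"),
                       data_type = 5L) {
  stopifnot(inherits(cube, "hyper_cube"))
  interleave <- match.arg(interleave)
  spec <- .envi_types[[as.character(data_type)]]
  if (is.null(spec) || spec$what != "double")
    stop("write_envi supports data type 4 or 5", call. = FALSE)
  d <- dim(cube$values)
  raw_path <- paste0(sub("\\.hdr$", "", header_path, ignore.case = TRUE), ".raw")
  v <- switch(interleave,
    bsq = as.vector(aperm(cube$values, c(2, 1, 3))),
    bil = as.vector(aperm(cube$values, c(2, 3, 1))),
    bip = as.vector(aperm(cube$values, c(3, 2, 1))))
  con <- file(raw_path, "wb")
  writeBin(v, con, size = spec$size, endian = "little")
  close(con)
  hdr <- c(
    "ENVI",
    "file type = ENVI Standard",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("wavelength = { %s }",
            paste(format(as.numeric(cube$grid), trim = TRUE, digits = 10),
                  collapse = ", ")))
  writeLines(hdr, header_path)
  invisible(header_path)
}

#' Dark/white reflectance calibration
#'
#' Converts raw sensor counts to relative reflectance using a dark-current
#' cube and a white-reference (e.g. Teflon board) cube:
#' `I = (I_o - I_B) / (I_W - I_B)` elementwise. This removes the dark current
#' of the sensor and the spatial/spectral non-uniformity of the light source.
#'
#' @param raw,dark,white [hyper_cube()]s of identical shape and grid.
#' @param zero_denominator Policy where `white - dark == 0`: `"error"`
#'   (default) aborts reporting the offending voxel count; `"mask"` sets those
#'   voxels to `NA`.
#' @return A calibrated [hyper_cube()].
#' @export
calibrate <- function(raw, dark, white, zero_denominator = c("error", "mask")) {
  zero_denominator <- match.arg(zero_denominator)
  for (x in list(raw, dark, white))
    stopifnot(inherits(x, "hyper_cube"))
  if (!identical(dim(raw$values), dim(dark$values)) ||
      !identical(dim(raw$values), dim(white$values)))
    stop("raw, dark and white cubes must share the same shape", call. = FALSE)
  if (!isTRUE(all.equal(as.numeric(raw$grid), as.numeric(dark$grid))) ||
      !isTRUE(all.equal(as.numeric(raw$grid), as.numeric(white$grid))))
    stop("raw, dark and white cubes must share the same wavelength grid",
         call. = FALSE)
  den <- white$values - dark$values
  bad <- den == 0
  if (any(bad)) {
    if (zero_denominator == "error")
      stop("calibration denominator (white - dark) is zero at ", sum(bad),
           " voxel(s); use zero_denominator = \"mask\" to set them NA",
           call. = FALSE)
    den[bad] <- NA_real_
  }
  hyper_cube((raw$values - dark$values) / den, raw$grid, calibrated = TRUE)
}

#' Trim to a contiguous band range
#'
#' Retains bands `first_index..last_index` inclusive (1-based, matching how
#' waveband ranges are quoted for this instrument: keeping bands 36-455 of a
#' 477-band sensor leaves 420 bands covering 450-979 nm).
#'
#' @param x A [hyper_cube()] or [spectra_table()].
#' @param first_index,last_index 1-based band indices, inclusive.
#' @return Object of the same class with `last_index - first_index + 1` bands.
#' @seealso [trim_wavelengths()] for trimming by wavelength value.
#' @export
trim_bands <- function(x, first_index, last_index) {
  UseMethod("trim_bands")
}

.check_trim_idx <- function(first_index, last_index, n) {
  if (length(first_index) != 1L || length(last_index) != 1L ||
      first_index < 1L || last_index > n || first_index > last_index)
    stop("invalid band range [", first_index, ", ", last_index,
         "] for ", n, " bands", call. = FALSE)
}

#' @export
trim_bands.hyper_cube <- function(x, first_index, last_index) {
  .check_trim_idx(first_index, last_index, length(x$grid))
  keep <- seq.int(first_index, last_index)
  hyper_cube(x$values[, , keep, drop = FALSE],
             wavelength_grid(as.numeric(x$grid)[keep]),
             calibrated = x$calibrated)
}

#' Trim to a wavelength window
#'
#' Keeps every band whose centre satisfies `min_nm <= center <= max_nm`.
#' This is the natural way to cut the low-response sensor edges when the
#' exact band indexing of an instrument is not known.
#'
#' @param x A [hyper_cube()] or [spectra_table()].
#' @param min_nm,max_nm Window bounds in nm, inclusive.
#' @return Object of the same class, trimmed.
#' @export
trim_wavelengths <- function(x, min_nm, max_nm) {
  grid <- if (inherits(x, "hyper_cube")) x$grid else x$grid
  keep <- which(as.numeric(grid) >= min_nm & as.numeric(grid) <= max_nm)
  if (length(keep) < 2L)
    stop("fewer than 2 bands fall inside [", min_nm, ", ", max_nm, "] nm",
         call. = FALSE)
  trim_bands(x, min(keep), max(keep))
}
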