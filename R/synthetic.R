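# Synthetic seed spectra and hyperspectral cubes with known ground truth.
#
# The generator emulates the statistical structure of VIS/NIR reflectance
# spectra of single corn seeds in three freeze-damage states: a smooth base
# reflectance curve rising through the red edge, additive severity offsets
# (unfrozen seeds darkest, severely frozen brightest), class-dependent
# absorption features concentrated in the 700-979 nm region, per-seed
# multiplicative scatter and additive baseline (so SNV has real work to do),
# and band-wise Gaussian noise.

# run code with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# smooth seed-like base reflectance: sigmoidal red-edge rise plus a mild
# near-infrared shoulder
.base_curve <- function(wl, lift = 0) {
  0.22 + lift + 0.30 / (1 + exp(-(wl - 660) / 45)) +
    0.03 * exp(-((wl - 910)^2) / (2 * 60^2))
}

#' Synthetic-data configuration
#'
#' Full parameterisation of the spectra/cube generator, including the RNG
#' seed, so identical configurations give bitwise-identical output.
#'
#' Defaults emulate the freeze-damage study conditions: 800/640/480 seeds in
#' the normal/slight/severe classes, a 420-band grid over 450-979 nm, mean
#' reflectance strictly increasing with freeze severity, and class-dependent
#' absorption features at 745/850/930 nm. The `"embryo"` profile uses larger
#' severity offsets and feature amplitudes (and a brighter base) than the
#' `"endosperm"` profile, reflecting the embryo's stronger spectral response
#' to freezing.
#'
#' @param class_sizes Seeds per class (normal, slight, severe).
#' @param n_bands,range_nm Wavelength grid specification.
#' @param side_profile `"endosperm"` or `"embryo"`.
#' @param severity_offsets Additive reflectance per class, strictly
#'   increasing; `NULL` picks the profile default.
#' @param severity_sd Within-class spread of the latent per-seed severity.
#'   Each seed draws a severity `s ~ N(class - 1, severity_sd)` and its mean
#'   curve interpolates the class curves at `s`, so adjacent damage classes
#'   overlap the way borderline seeds do in practice. The embryo face
#'   responds more distinctly to freezing, hence its smaller default spread.
#'   `NULL` picks the profile default (0.33 endosperm, 0.26 embryo); 0
#'   disables the overlap entirely.
#' @param feature_centers Centres (nm) of the class-dependent absorption
#'   features.
#' @param feature_width Gaussian width (nm) of those features.
#' @param feature_weights `3 x F` matrix of per-class feature weights;
#'   `NULL` uses a default giving each class a distinct spectral shape.
#' @param feature_amp Overall feature amplitude; `NULL` picks the profile
#'   default.
#' @param scatter_range Per-seed multiplicative gain range.
#' @param baseline_range Per-seed additive baseline range.
#' @param noise_sd Per-band Gaussian noise standard deviation.
#' @param background Background reflectance used when painting cubes.
#' @param dark_level,white_level Sensor dark-current and white-reference
#'   count levels used by [gen_cube()].
#' @param white_gradient Relative left-to-right gradient of the white field
#'   (0 = flat illumination).
#' @param seed RNG seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(class_sizes = c(800L, 640L, 480L),
                         n_bands = 420L, range_nm = c(450, 979),
                         side_profile = c("endosperm", "embryo"),
                         severity_offsets = NULL,
                         severity_sd = NULL,
                         feature_centers = c(745, 850, 930),
                         feature_width = 12,
                         feature_weights = NULL,
                         feature_amp = NULL,
                         scatter_range = c(0.9, 1.1),
                         baseline_range = c(-0.02, 0.02),
                         noise_sd = 0.008,
                         background = 0.02,
                         dark_level = 0.05, white_level = 0.9,
                         white_gradient = 0,
                         seed = 1L) {
  side_profile <- match.arg(side_profile)
  boost <- if (side_profile == "embryo") 1.8 else 1.0
  # class differences live mostly in the 700-979 nm absorption features;
  # the flat severity offsets are kept small so the synchronous-spectrum
  # diagonal peaks at the planted features rather than everywhere
  if (is.null(severity_offsets)) severity_offsets <- boost * c(0, 0.008, 0.016)
  if (is.null(feature_amp)) feature_amp <- boost * 0.05
  if (is.null(severity_sd))
    severity_sd <- if (side_profile == "embryo") 0.26 else 0.33
  if (severity_sd < 0) stop("severity_sd must be >= 0", call. = FALSE)
  if (is.null(feature_weights))
    feature_weights <- matrix(c(0.0, 0.0, 0.0,    # normal: no stress features
                                0.5, 1.0, 0.3,    # slight
                                1.0, 0.6, 1.0),   # severe
                              nrow = 3, byrow = TRUE)
  if (length(severity_offsets) != 3L || any(diff(severity_offsets) <= 0))
    stop("severity_offsets must be 3 values strictly increasing with severity",
         call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (nrow(feature_weights) != 3L ||
      ncol(feature_weights) != length(feature_centers))
    stop("feature_weights must be 3 x length(feature_centers)", call. = FALSE)
  structure(list(class_sizes = as.integer(class_sizes),
                 grid = wavelength_grid(seq(range_nm[1], range_nm[2],
                                            length.out = n_bands)),
                 side_profile = side_profile,
                 severity_offsets = severity_offsets,
                 severity_sd = severity_sd,
                 feature_centers = feature_centers,
                 feature_width = feature_width,
                 feature_weights = feature_weights,
                 feature_amp = feature_amp,
                 scatter_range = scatter_range,
                 baseline_range = baseline_range,
                 noise_sd = noise_sd,
                 background = background,
                 dark_level = dark_level,
                 white_level = white_level,
                 white_gradient = white_gradient,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# switch a config to the other face profile: profile-dependent fields that
# still hold their old profile's defaults are re-resolved for the new
# profile; explicit user overrides are kept
.with_side <- function(cfg, side) {
  stopifnot(inherits(cfg, "synth_config"), side %in% c("endosperm", "embryo"))
  if (cfg$side_profile == side) return(cfg)
  defaults <- function(profile) {
    boost <- if (profile == "embryo") 1.8 else 1.0
    list(severity_offsets = boost * c(0, 0.008, 0.016),
         feature_amp = boost * 0.05,
         severity_sd = if (profile == "embryo") 0.26 else 0.33)
  }
  old <- defaults(cfg$side_profile); new <- defaults(side)
  for (f in names(old))
    if (isTRUE(all.equal(cfg[[f]], old[[f]]))) cfg[[f]] <- new[[f]]
  cfg$side_profile <- side
  cfg
}

# B x F matrix of unit Gaussian absorption-feature shapes
.feature_shapes <- function(cfg) {
  wl <- as.numeric(cfg$grid)
  vapply(seq_along(cfg$feature_centers), function(f)
    exp(-((wl - cfg$feature_centers[f])^2) / (2 * cfg$feature_width^2)),
    numeric(length(wl)))
}

# mean reflectance curves at latent severities s (class c sits at s = c - 1);
# offsets and feature weights interpolate piecewise-linearly between the
# class values, clamped at the ends; returns length(s) x B
.severity_curves <- function(cfg, s) {
  wl <- as.numeric(cfg$grid)
  lift <- if (cfg$side_profile == "embryo") 0.05 else 0
  base <- .base_curve(wl, lift)
  G <- .feature_shapes(cfg)                      # B x F
  off <- stats::approx(0:2, cfg$severity_offsets, xout = s, rule = 2)$y
  W <- vapply(seq_len(ncol(G)), function(f)
    stats::approx(0:2, cfg$feature_weights[, f], xout = s, rule = 2)$y,
    numeric(length(s)))                          # length(s) x F
  W <- matrix(W, nrow = length(s))
  matrix(base, length(s), length(wl), byrow = TRUE) + off -
    cfg$feature_amp * W %*% t(G)
}

# 3 x B matrix of true class-mean reflectance curves (severities 0, 1, 2)
.class_means <- function(cfg) {
  .severity_curves(cfg, 0:2)
}

# band indices nearest the planted feature centres
.informative_bands <- function(cfg) {
  wl <- as.numeric(cfg$grid)
  vapply(cfg$feature_centers, function(cc) which.min(abs(wl - cc)), integer(1))
}

#' Generate synthetic per-seed spectra
#'
#' Each seed draws a latent severity `s ~ N(class - 1, severity_sd)` and its
#' spectrum is `gain * curve(s) + baseline + noise`, clipped to `[0, 1.2]`,
#' where `curve(s)` interpolates the class-mean curves at `s`, `gain` and
#' `baseline` are per-seed scatter draws and `noise` is band-wise Gaussian.
#' With `noise_sd = 0`, `severity_sd = 0` and scatter switched off
#' (`scatter_range = c(1, 1)`, `baseline_range = c(0, 0)`) every spectrum
#' equals its class-mean curve exactly.
#'
#' @param cfg A [synth_config()].
#' @return List with `table` (a [spectra_table()]) and `truth` (list:
#'   `class_means` 3 x B matrix, `informative_bands` indices of the planted
#'   feature centres, and the `config`).
#' @export
gen_spectra <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  .with_seed(cfg$seed, {
    means <- .class_means(cfg)
    labels <- rep.int(1:3, cfg$class_sizes)
    n <- length(labels)
    B <- length(cfg$grid)
    sev <- (labels - 1) + if (cfg$severity_sd > 0)
      stats::rnorm(n, sd = cfg$severity_sd) else 0
    gains <- stats::runif(n, cfg$scatter_range[1], cfg$scatter_range[2])
    bases <- stats::runif(n, cfg$baseline_range[1], cfg$baseline_range[2])
    noise <- if (cfg$noise_sd > 0)
      matrix(stats::rnorm(n * B, sd = cfg$noise_sd), n, B)
    else matrix(0, n, B)
    X <- gains * .severity_curves(cfg, sev) + bases + noise
    X[X < 0] <- 0
    X[X > 1.2] <- 1.2
    list(table = spectra_table(X, cfg$grid, labels, side = cfg$side_profile),
         truth = list(class_means = means,
                      informative_bands = .informative_bands(cfg),
                      config = cfg))
  })
}

#' Lay seeds out on a synthetic stage image
#'
#' Places non-overlapping ellipses ("seeds") on a rectangular grid over a
#' dark background, one per entry of `classes`.
#'
#' @param classes Integer vector of per-seed freeze-damage classes (1..3).
#' @param image_dim `c(lines, samples)` of the stage image.
#' @param axes `c(a_row, a_col)` ellipse semi-axes in pixels.
#' @return An object of class `cube_layout` (image size, per-seed ellipse
#'   centres/axes, classes).
#' @export
gen_layout <- function(classes, image_dim = NULL, axes = c(5, 7)) {
  n <- length(classes)
  per_row <- ceiling(sqrt(n))
  n_rows <- ceiling(n / per_row)
  cell <- 2 * (axes + 2)                      # bounding cell with margin
  if (is.null(image_dim))
    image_dim <- c(n_rows * cell[1], per_row * cell[2])
  centers <- t(vapply(seq_len(n) - 1L, function(i) {
    r <- i %/% per_row; c_ <- i %% per_row
    c(r * cell[1] + cell[1] / 2, c_ * cell[2] + cell[2] / 2)
  }, numeric(2)))
  layout <- structure(list(image_dim = as.integer(image_dim),
                           centers = centers,
                           axes = matrix(rep(axes, each = n), ncol = 2),
                           classes = as.integer(classes)),
                      class = "cube_layout")
  .check_layout(layout)
  layout
}

.check_layout <- function(layout) {
  n <- nrow(layout$centers)
  if (n > 1L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      gap <- abs(layout$centers[i, ] - layout$centers[j, ])
      reach <- layout$axes[i, ] + layout$axes[j, ]
      if (all(gap <= reach))
        stop("layout error: ellipses ", i, " and ", j, " overlap", call. = FALSE)
    }
  }
  invisible(layout)
}

#' Generate a synthetic raw/dark/white cube triple
#'
#' Builds a reflectance scene by painting per-seed spectra (drawn with the
#' [gen_spectra()] model, noise applied per pixel) into the layout's
#' ellipses over a flat dark background, then synthesises sensor counts as
#' `raw = dark + reflectance * (white - dark)` with a configurable dark level
#' and (optionally spatially graded) white field — so [calibrate()] inverts
#' the construction exactly, regardless of illumination gradients.
#'
#' @param cfg A [synth_config()].
#' @param layout A `cube_layout` from [gen_layout()].
#' @return List with `raw`, `dark`, `white` (uncalibrated [hyper_cube()]s),
#'   and `truth` (list: `labels` ground-truth seed-label matrix, `classes`,
#'   `scene` the painted reflectance array, `seed_spectra` the per-seed base
#'   spectra before pixel noise).
#' @export
gen_cube <- function(cfg, layout) {
  stopifnot(inherits(cfg, "synth_config"), inherits(layout, "cube_layout"))
  .check_layout(layout)
  .with_seed(cfg$seed, {
    L <- layout$image_dim[1]; S <- layout$image_dim[2]
    B <- length(cfg$grid)
    n <- nrow(layout$centers)
    sev <- (layout$classes - 1) + if (cfg$severity_sd > 0)
      stats::rnorm(n, sd = cfg$severity_sd) else 0
    gains <- stats::runif(n, cfg$scatter_range[1], cfg$scatter_range[2])
    bases <- stats::runif(n, cfg$baseline_range[1], cfg$baseline_range[2])
    seed_spectra <- gains * .severity_curves(cfg, sev) + bases
    scene <- array(cfg$background, dim = c(L, S, B))
    lab <- matrix(0L, L, S)
    rr <- row(lab); cc <- col(lab)
    for (i in seq_len(n)) {
      inside <- ((rr - layout$centers[i, 1]) / layout$axes[i, 1])^2 +
                ((cc - layout$centers[i, 2]) / layout$axes[i, 2])^2 <= 1
      if (any(lab[inside] != 0L))
        stop("layout error: painted ellipses overlap", call. = FALSE)
      lab[inside] <- i
      px <- which(inside)
      spec <- matrix(seed_spectra[i, ], length(px), B, byrow = TRUE)
      if (cfg$noise_sd > 0)
        spec <- spec + matrix(stats::rnorm(length(px) * B, sd = cfg$noise_sd),
                              length(px), B)
      spec[spec < 0] <- 0; spec[spec > 1.2] <- 1.2
      for (b in seq_len(B)) scene[px + (b - 1L) * L * S] <- spec[, b]
    }
    dark <- array(cfg$dark_level, dim = c(L, S, B))
    white_row <- cfg$white_level *
      (1 + cfg$white_gradient * (seq_len(S) / S - 0.5))
    white <- array(rep(rep(white_row, each = L), B), dim = c(L, S, B))
    raw <- dark + scene * (white - dark)
    list(raw = hyper_cube(raw, cfg$grid, calibrated = FALSE),
         dark = hyper_cube(dark, cfg$grid, calibrated = FALSE),
         white = hyper_cube(white, cfg$grid, calibrated = FALSE),
         truth = list(labels = lab, classes = layout$classes,
                      scene = scene, seed_spectra = seed_spectra))
  })
}
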