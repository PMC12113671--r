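# Experiment-grid orchestration: preprocessing x selection x model, per side.

#' Experiment-grid configuration
#'
#' @param sides Character vector of kernel faces to run (`"endosperm"`,
#'   `"embryo"`).
#' @param preprocessings Subset of `c("none", "snv", "sg53")`.
#' @param selections Subset of `c("full", "spa", "2dcos", "spa+2dcos")`.
#' @param models Subset of `c("knn", "lda", "svm_rbf")`.
#' @param train_fraction Kennard-Stone training fraction (default 2/3).
#' @param spa_k_max Maximum SPA subset size (default 20).
#' @param spa_starts Candidate SPA start bands (default: all bands).
#' @param peak_prominence 2DCOS peak-prominence fraction (default 0.05).
#' @param synth A [synth_config()] used when spectra are generated rather
#'   than loaded; its `side_profile` is overridden per side. `NULL` requires
#'   `tables` to be supplied to [run_grid()].
#' @param seed Global seed; per-side generator seeds are derived from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(sides = c("endosperm", "embryo"),
                       preprocessings = c("none", "snv", "sg53"),
                       selections = c("full", "spa", "2dcos", "spa+2dcos"),
                       models = c("knn", "lda", "svm_rbf"),
                       train_fraction = 2 / 3,
                       spa_k_max = 20L,
                       spa_starts = NULL,
                       peak_prominence = 0.05,
                       synth = synth_config(),
                       seed = 1L) {
  stopifnot(length(sides) >= 1L, length(preprocessings) >= 1L,
            length(selections) >= 1L, length(models) >= 1L)
  sides <- match.arg(sides, c("endosperm", "embryo"), several.ok = TRUE)
  preprocessings <- match.arg(preprocessings, c("none", "snv", "sg53"),
                              several.ok = TRUE)
  selections <- match.arg(selections, c("full", "spa", "2dcos", "spa+2dcos"),
                          several.ok = TRUE)
  models <- match.arg(models, c("knn", "lda", "svm_rbf"), several.ok = TRUE)
  structure(list(sides = sides, preprocessings = preprocessings,
                 selections = selections, models = models,
                 train_fraction = train_fraction,
                 spa_k_max = as.integer(spa_k_max),
                 spa_starts = spa_starts,
                 peak_prominence = peak_prominence,
                 synth = synth, seed = as.integer(seed)),
            class = "run_config")
}

# compute the selection for one (preprocessing, method) cell on training rows
.grid_selection <- function(method, table_p, split, cfg) {
  tr <- split$train_rows
  switch(method,
    full = NULL,
    spa = spa_select(table_p$spectra[tr, , drop = FALSE],
                     table_p$labels[tr], k_max = cfg$spa_k_max,
                     grid = table_p$grid, starts = cfg$spa_starts),
    `2dcos` = cos2d_select(table_p, rows = tr,
                           min_rel_prominence = cfg$peak_prominence),
    `spa+2dcos` = fuse_selections(
      spa_select(table_p$spectra[tr, , drop = FALSE], table_p$labels[tr],
                 k_max = cfg$spa_k_max, grid = table_p$grid,
                 starts = cfg$spa_starts),
      cos2d_select(table_p, rows = tr,
                   min_rel_prominence = cfg$peak_prominence)))
}

#' Run the full experiment grid
#'
#' For every side: one Kennard-Stone split (shared by all cells), then for
#' every preprocessing arm the wavelength selections are refit on the
#' training partition only, and every (selection, model) cell is fitted and
#' evaluated on both partitions. A failing cell is recorded with its error
#' message and the remaining cells continue.
#'
#' @param cfg A [run_config()].
#' @param tables Optional named list of [spectra_table()]s keyed by side;
#'   when `NULL` they are generated from `cfg$synth` with the side's profile.
#' @param out_dir Optional directory; when given, confusion matrices (CSV),
#'   metrics (JSON), selections (JSON) and a Markdown accuracy summary are
#'   written there.
#' @return A `grid_result`: list with `cells` (one entry per grid cell:
#'   selection, confusion matrices, train/test [eval_report()]s or an error
#'   message), `splits`, `selections`, and the `config`.
#' @export
run_grid <- function(cfg, tables = NULL, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  cells <- list()
  splits <- list()
  selections <- list()
  for (si in seq_along(cfg$sides)) {
    side <- cfg$sides[si]
    if (!is.null(tables)) {
      table <- tables[[side]]
      if (is.null(table)) stop("no table supplied for side ", side, call. = FALSE)
    } else {
      scfg <- .with_side(cfg$synth, side)
      scfg$seed <- cfg$seed + si - 1L
      table <- gen_spectra(scfg)$table
    }
    split <- ks_split(table, cfg$train_fraction)   # one split per side
    splits[[side]] <- split
    for (prep in cfg$preprocessings) {
      table_p <- preprocess(table, prep)
      for (selm in cfg$selections) {
        sel_key <- paste(side, prep, selm, sep = "/")
        sel <- tryCatch(.grid_selection(selm, table_p, split, cfg),
                        error = function(e) e)
        if (inherits(sel, "error")) {
          for (mod in cfg$models)
            cells[[paste(sel_key, mod, sep = "/")]] <-
              list(side = side, preprocessing = prep, selection_method = selm,
                   model = mod, error = conditionMessage(sel))
          next
        }
        selections[[sel_key]] <- sel
        for (mod in cfg$models) {
          key <- paste(sel_key, mod, sep = "/")
          cells[[key]] <- tryCatch({
            cms <- fit_predict(table_p, split, sel,
                               model_spec(mod, seed = cfg$seed))
            rep_ <- model_report(cms$train, cms$test)
            list(side = side, preprocessing = prep, selection_method = selm,
                 model = mod, selection = sel,
                 n_wavelengths = if (is.null(sel)) ncol(table_p$spectra)
                                 else length(sel$band_indices),
                 train = rep_$train, test = rep_$test)
          }, error = function(e)
            list(side = side, preprocessing = prep, selection_method = selm,
                 model = mod, error = conditionMessage(e)))
        }
      }
    }
  }
  res <- structure(list(cells = cells, splits = splits,
                        selections = selections, config = cfg),
                   class = "grid_result")
  if (!is.null(out_dir)) write_grid_results(res, out_dir)
  res
}

#' Summarise a grid run as a data frame
#'
#' One row per cell: side, preprocessing, selection method, model, number of
#' wavelengths, and train/test accuracy (1 d.p., the layout of the published
#' accuracy tables). Failed cells carry `NA` accuracies.
#'
#' @param result A `grid_result` from [run_grid()].
#' @return A data frame.
#' @export
summarize_grid <- function(result) {
  stopifnot(inherits(result, "grid_result"))
  rows <- lapply(result$cells, function(cell) {
    data.frame(side = cell$side, preprocessing = cell$preprocessing,
               selection = cell$selection_method, model = cell$model,
               n_wavelengths = if (is.null(cell$error)) cell$n_wavelengths else NA,
               train_accuracy = if (is.null(cell$error))
                 cell$train$display$accuracy else NA_real_,
               test_accuracy = if (is.null(cell$error))
                 cell$test$display$accuracy else NA_real_,
               error = if (is.null(cell$error)) "" else cell$error)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write grid results to disk
#'
#' @param result A `grid_result`.
#' @param out_dir Output directory (created if missing). Writes
#'   `summary.csv`, `summary.md`, `metrics.json`, `selections.json`, and one
#'   confusion-matrix CSV per successful cell under `confusions/`.
#' @return `out_dir`, invisibly.
#' @export
write_grid_results <- function(result, out_dir) {
  stopifnot(inherits(result, "grid_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "confusions"), showWarnings = FALSE)
  smry <- summarize_grid(result)
  utils::write.csv(smry, file.path(out_dir, "summary.csv"), row.names = FALSE)
  md <- c("| side | preprocessing | selection | model | n wl | train acc % | test acc % |",
          "|---|---|---|---|---|---|---|",
          sprintf("| %s | %s | %s | %s | %s | %s | %s |",
                  smry$side, smry$preprocessing, smry$selection, smry$model,
                  smry$n_wavelengths,
                  ifelse(is.na(smry$train_accuracy), "failed",
                         sprintf("%.1f", smry$train_accuracy)),
                  ifelse(is.na(smry$test_accuracy), "failed",
                         sprintf("%.1f", smry$test_accuracy))))
  writeLines(md, file.path(out_dir, "summary.md"))
  metrics <- lapply(result$cells, function(cell) {
    if (!is.null(cell$error)) return(list(error = cell$error))
    list(n_wavelengths = cell$n_wavelengths,
         train = list(accuracy = cell$train$accuracy,
                      sensitivity = cell$train$sensitivity,
                      accuracy_rnd = cell$train$accuracy_rnd,
                      accuracy_minus_rnd = cell$train$accuracy_minus_rnd),
         test = list(accuracy = cell$test$accuracy,
                     sensitivity = cell$test$sensitivity,
                     accuracy_rnd = cell$test$accuracy_rnd,
                     accuracy_minus_rnd = cell$test$accuracy_minus_rnd))
  })
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  sel_json <- lapply(result$selections, function(s) {
    if (is.null(s)) return(NULL)
    list(method = s$method, wavelengths_nm = s$wavelengths_nm,
         band_indices = s$band_indices, provenance = s$provenance)
  })
  jsonlite::write_json(sel_json, file.path(out_dir, "selections.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (key in names(result$cells)) {
    cell <- result$cells[[key]]
    if (!is.null(cell$error)) next
    fn <- file.path(out_dir, "confusions",
                    paste0(gsub("[/+]", "_", key), ".csv"))
    utils::write.csv(as.data.frame(unclass(cell$train$confusion)),
                     sub("\\.csv$", "_train.csv", fn))
    utils::write.csv(as.data.frame(unclass(cell$test$confusion)),
                     sub("\\.csv$", "_test.csv", fn))
  }
  invisible(out_dir)
}

#' @export
print.grid_result <- function(x, ...) {
  ok <- sum(vapply(x$cells, function(c) is.null(c$error), logical(1)))
  cat(sprintf("<grid_result> %d cell(s), %d succeeded, %d failed\n",
              length(x$cells), ok, length(x$cells) - ok))
  invisible(x)
}
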