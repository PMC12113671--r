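# Evaluation metrics: accuracy, per-class sensitivity, chance-corrected
# Accuracy RND, and the bundled report.

#' Construct a confusion matrix
#'
#' `K x K` non-negative integer counts with rows = actual class and
#' columns = predicted class.
#'
#' @param counts Square numeric matrix of non-negative counts.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stop("confusion matrix must be square", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion matrix entries must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  if (is.null(dimnames(counts)))
    dimnames(counts) <- list(actual = seq_len(nrow(counts)),
                             predicted = seq_len(ncol(counts)))
  structure(counts, class = c("confusion_matrix", "matrix", "array"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = actual, columns = predicted, N =", sum(x), "\n")
  print(unclass(x))
  invisible(x)
}

#' Overall accuracy
#'
#' Percentage of correctly classified samples: `100 * trace / N`.
#'
#' @param cm A [confusion_matrix()] with `N > 0`.
#' @return Accuracy in percent (unrounded).
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  N <- sum(cm)
  if (N == 0) stop("empty confusion matrix", call. = FALSE)
  100 * sum(diag(cm)) / N
}

#' Per-class sensitivity (recall)
#'
#' One-vs-rest recall per class: `100 * cm[c, c] / rowsum(c)` — the fraction
#' of class-`c` samples the model recognised as class `c`.
#'
#' @param cm A [confusion_matrix()] with every row sum positive.
#' @return Numeric vector of per-class percentages (unrounded).
#' @export
sensitivity <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  rs <- rowSums(cm)
  if (any(rs == 0))
    stop("sensitivity undefined: class ",
         paste(which(rs == 0), collapse = ", "), " has no samples",
         call. = FALSE)
  100 * diag(cm) / rs
}

#' Chance-agreement accuracy (Accuracy RND)
#'
#' The expected accuracy of a classifier that reproduces the model's
#' predicted-class marginals but assigns them at random:
#' `100 * sum_c(rowsum_c * colsum_c) / N^2`. For perfectly balanced classes
#' and marginals this is `100 / K`; `accuracy - accuracy_rnd` therefore
#' measures skill above chance and is robust to class imbalance.
#'
#' @param cm A [confusion_matrix()] with `N > 0`.
#' @return Chance accuracy in percent (unrounded).
#' @export
accuracy_rnd <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  N <- sum(cm)
  if (N == 0) stop("empty confusion matrix", call. = FALSE)
  100 * sum(rowSums(cm) * colSums(cm)) / N^2
}

#' Evaluation report for one partition
#'
#' Bundles accuracy, per-class sensitivity, Accuracy RND and
#' accuracy − Accuracy RND. Raw (unrounded) values are kept; the `display`
#' element holds the same numbers rounded to one decimal place, with the
#' difference computed from the rounded terms as results tables convention-
#' ally print it.
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `eval_report`.
#' @export
eval_report <- function(cm) {
  acc <- accuracy(cm)
  sens <- sensitivity(cm)
  rnd <- accuracy_rnd(cm)
  structure(list(
    accuracy = acc,
    sensitivity = sens,
    accuracy_rnd = rnd,
    accuracy_minus_rnd = acc - rnd,
    confusion = cm,
    display = list(accuracy = round(acc, 1),
                   sensitivity = round(sens, 1),
                   accuracy_rnd = round(rnd, 1),
                   accuracy_minus_rnd = round(acc, 1) - round(rnd, 1))),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  d <- x$display
  cat(sprintf("<eval_report> accuracy %.1f%% | sensitivity %s%% | Accuracy RND %.1f%% | above chance %.1f%%\n",
              d$accuracy, paste(sprintf("%.1f", d$sensitivity), collapse = "/"),
              d$accuracy_rnd, d$accuracy_minus_rnd))
  invisible(x)
}

#' Paired train/test evaluation report
#'
#' @param cm_train,cm_test [confusion_matrix()]s for the training and
#'   testing partitions.
#' @return List with `train` and `test` [eval_report()]s.
#' @export
model_report <- function(cm_train, cm_test) {
  list(train = eval_report(cm_train), test = eval_report(cm_test))
}
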