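# Published benchmark tables for the corn-seed freeze-damage application:
# the confusion matrices of the best model per kernel face, and the
# SPA / 2DCOS wavelength sets per preprocessing arm. These serve as worked
# examples and as fixed inputs for metric and fusion arithmetic.

#' Benchmark confusion matrices
#'
#' The reported confusion matrices of the best fused-wavelength model on
#' each kernel face (endosperm: SNV + SPA-2DCOS + SVM; embryo:
#' no preprocessing + SPA-2DCOS + LDA), for a 1280-sample training set and a
#' 640-sample testing set over the three freeze-damage classes.
#'
#' @return Nested list `$<side>$<partition>` of [confusion_matrix()]s with
#'   sides `endosperm`/`embryo` and partitions `train`/`test`.
#' @examples
#' accuracy(freeze_confusions()$endosperm$train)   # 92.9 (1 d.p.)
#' @export
freeze_confusions <- function() {
  m <- function(...) confusion_matrix(matrix(c(...), nrow = 3, byrow = TRUE))
  list(
    endosperm = list(
      train = m(533,   0,   0,
                  3, 392,  32,
                  7,  49, 264),
      test  = m(264,   1,   2,
                  2, 191,  20,
                  4,  27, 129)),
    embryo = list(
      train = m(533,   0,   0,
                  0, 413,  14,
                  2,  16, 302),
      test  = m(267,   0,   0,
                  0, 200,  13,
                  1,  19, 140)))
}

#' Benchmark selected-wavelength sets
#'
#' The reported SPA and 2DCOS feature wavelengths (nm) for each kernel face
#' and preprocessing arm, whose pairwise unions give the fused SPA-2DCOS
#' sets (counts 7/19/11 on the endosperm face and 15/17/16 on the embryo
#' face for none/SNV/5-3 smoothing).
#'
#' @return Nested list `$<side>$<preprocessing>$<method>` of numeric
#'   wavelength vectors, with sides `endosperm`/`embryo`, preprocessing
#'   `none`/`snv`/`sg53`, methods `spa`/`cos2d`.
#' @export
freeze_wavelengths <- function() {
  list(
    endosperm = list(
      none = list(spa = c(839, 903, 949, 979),
                  cos2d = c(743, 848, 974)),
      snv = list(spa = c(509, 523, 586, 705, 738, 770, 809, 820, 873, 879,
                         886, 904, 921),
                 cos2d = c(467, 589, 676, 745, 848, 899)),
      sg53 = list(spa = c(550, 576, 638, 696, 736, 832, 864, 949, 961),
                  cos2d = c(738, 850))),
    embryo = list(
      none = list(spa = c(450, 454, 467, 490, 504, 538, 636, 686, 800, 859,
                          891, 979),
                  cos2d = c(744, 848, 974)),
      snv = list(spa = c(509, 520, 554, 640, 703, 743, 800, 876, 886, 911,
                         922, 938),
                 cos2d = c(580, 676, 745, 846, 899)),
      sg53 = list(spa = c(450, 470, 487, 511, 532, 562, 700, 740, 825, 854,
                          876, 949, 962, 973),
                  cos2d = c(742, 850))))
}
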