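#' Reference confusion matrices from the INbreast density study
#'
#' Pooled 5-fold cross-validated confusion matrices reported for BI-RADS
#' density classification of the 409-image INbreast FFDM dataset, for the
#' individual multi-fractal descriptors, the LBP-family descriptors, the
#' cascaded (multi-fractal + MLBP) descriptors and the binary (low/high
#' density) task. Rows are actual classes, columns predicted. These serve as
#' worked-example inputs for [compute_metrics()]: e.g. the cascaded
#' Iso+MLBP matrix reproduces an accuracy of 84.6% and the binary MLBP
#' matrix 91.9%.
#'
#' @return named list of integer matrices with dimnames
#'   `list(actual, predicted)`.
#' @export
reference_confusion_matrices <- function() {
  cls <- c("I", "II", "III", "IV")
  m4 <- function(v) matrix(v, 4L, 4L, byrow = TRUE,
                           dimnames = list(actual = cls, predicted = cls))
  bin <- c("low", "high")
  m2 <- function(v) matrix(v, 2L, 2L, byrow = TRUE,
                           dimnames = list(actual = bin, predicted = bin))
  list(
    max = m4(c(113, 8, 11, 4,
               49, 51, 44, 2,
               20, 1, 73, 5,
               2, 0, 4, 22)),
    in_min = m4(c(98, 16, 18, 4,
                  38, 65, 39, 4,
                  18, 8, 65, 8,
                  5, 0, 7, 16)),
    iso = m4(c(119, 9, 5, 3,
               24, 91, 26, 5,
               15, 5, 72, 7,
               0, 1, 7, 20)),
    sum = m4(c(88, 21, 25, 2,
               41, 69, 36, 0,
               21, 10, 59, 9,
               1, 5, 12, 10)),
    lbp = m4(c(127, 0, 9, 0,
               48, 69, 29, 0,
               16, 3, 80, 0,
               0, 0, 14, 14)),
    elbp = m4(c(125, 5, 6, 0,
                49, 68, 29, 0,
                11, 3, 83, 2,
                0, 0, 9, 19)),
    mlbp = m4(c(129, 3, 4, 0,
                50, 72, 24, 0,
                11, 2, 85, 1,
                1, 0, 13, 14)),
    max_mlbp = m4(c(130, 2, 3, 1,
                    36, 95, 15, 0,
                    10, 2, 84, 3,
                    1, 0, 3, 24)),
    in_min_mlbp = m4(c(129, 3, 3, 1,
                       32, 88, 25, 1,
                       14, 4, 73, 8,
                       1, 0, 3, 24)),
    iso_mlbp = m4(c(128, 5, 2, 1,
                    18, 108, 19, 1,
                    8, 1, 84, 6,
                    0, 0, 2, 26)),
    sum_mlbp = m4(c(107, 10, 14, 5,
                    40, 76, 30, 0,
                    11, 4, 76, 8,
                    1, 1, 3, 23)),
    binary_mlbp = m2(c(259, 23,
                       10, 117)),
    binary_iso = m2(c(253, 29,
                      15, 112)),
    binary_iso_mlbp = m2(c(262, 20,
                           9, 118))
  )
}

#' Class sizes of the INbreast density labels
#'
#' 136, 146, 99 and 28 images in BI-RADS I--IV respectively (409 total);
#' collapsing to binary density gives 282 low and 127 high.
#'
#' @return named integer vector.
#' @export
reference_class_sizes <- function() {
  c(I = 136L, II = 146L, III = 99L, IV = 28L)
}
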