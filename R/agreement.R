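#' Bland-Altman method agreement
#'
#' Paired-difference agreement between two measurement methods: bias (mean
#' of the differences `b - a`), precision (SD of the differences), limits
#' of agreement at bias +/- 2 SD, Pearson's product-moment correlation, and
#' a percentage error. Two percentage-error conventions are provided:
#' `"bias"` reports 100 * bias / mean((a + b) / 2), and `"critchley"`
#' reports 100 * 1.96 * SD / mean((a + b) / 2).
#'
#' @param a,b paired numeric readings of equal length >= 3 (`a` is the
#'   reference, `b` the test method).
#' @param peMode percentage-error convention, "bias" (default) or
#'   "critchley".
#' @return list with `bias`, `precision`, `loaLow`, `loaHigh`,
#'   `percentageError`, `r` and `n`. `r` is `NA` when either vector is
#'   constant.
#' @examples
#' blandAltman(c(1, 2, 3, 4), c(2, 3, 4, 5))$bias  # 1
#' @export
blandAltman <- function(a, b, peMode = c("bias", "critchley")) {
  peMode <- match.arg(peMode)
  if (length(a) != length(b)) stop("length mismatch: paired readings required")
  if (length(a) < 3L) stop("need at least 3 pairs")
  d <- b - a
  bias <- mean(d)
  precision <- stats::sd(d)
  grand <- mean((a + b) / 2)
  pe <- if (peMode == "bias") 100 * bias / grand
        else 100 * 1.96 * precision / grand
  r <- if (stats::sd(a) > 0 && stats::sd(b) > 0) stats::cor(a, b) else NA_real_
  list(bias = bias, precision = precision,
       loaLow = bias - 2 * precision, loaHigh = bias + 2 * precision,
       percentageError = pe, r = r, n = length(a))
}

#' Area under the ROC curve
#'
#' AUC for continuous scores against binary labels by the rank (Mann-
#' Whitney) statistic; tied scores count one half.
#'
#' @param scores numeric predictor.
#' @param labels binary outcome (logical, or coercible to 0/1 with 1 the
#'   positive class).
#' @return AUC in [0, 1].
#' @examples
#' rocAUC(c(1, 2, 3, 4), c(0, 0, 1, 1))  # 1
#' @export
rocAUC <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
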