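# Model evaluation statistics: RMSE, MAE and Willmott's index of
# agreement, plus a regression-through-origin slope helper.

.check_pairs <- function(O, P) {
  if (length(O) != length(P)) {
    stop("observed and predicted series differ in length", call. = FALSE)
  }
  if (length(O) == 0L) stop("empty series", call. = FALSE)
  invisible(NULL)
}

#' Root mean square error
#'
#' @param O Observed values.
#' @param P Predicted values (same length).
#' @return \eqn{\sqrt{\sum (O_i - P_i)^2 / n}}.
#' @export
rmse <- function(O, P) {
  .check_pairs(O, P)
  sqrt(mean((O - P)^2))
}

#' Mean absolute error
#'
#' Standard MAE, \eqn{\frac{1}{n}\sum |O_i - P_i|}.  See [mae_literal()]
#' for the variant measuring scatter of the observations about the
#' prediction mean.
#'
#' @inheritParams rmse
#' @return Mean absolute pairwise difference.
#' @export
mae <- function(O, P) {
  .check_pairs(O, P)
  mean(abs(O - P))
}

#' Mean absolute deviation of observations from the prediction mean
#'
#' \eqn{\frac{1}{n}\sum |O_i - \bar P|}: a scatter measure occasionally
#' printed in place of the MAE; provided for comparison only.
#'
#' @inheritParams rmse
#' @return Mean absolute deviation from the prediction mean.
#' @export
mae_literal <- function(O, P) {
  .check_pairs(O, P)
  mean(abs(O - mean(P)))
}

#' Willmott's index of agreement
#'
#' \deqn{d_{IA} = 1 - \frac{\sum (O_i - P_i)^2}
#'   {\sum (|P_i - \bar O| + |O_i - \bar O|)^2} \in [0, 1],}
#' equal to 1 iff the two series agree elementwise.
#'
#' @inheritParams rmse
#' @return d_IA in \[0, 1\].
#' @export
index_of_agreement <- function(O, P) {
  .check_pairs(O, P)
  Obar <- mean(O)
  den <- sum((abs(P - Obar) + abs(O - Obar))^2)
  if (den == 0) {
    stop("index of agreement undefined: both series constant at the ",
         "observed mean", call. = FALSE)
  }
  1 - sum((O - P)^2) / den
}

#' Regression-through-origin slope
#'
#' Least-squares slope of `O` on `P` with no intercept,
#' \eqn{\sum O_i P_i / \sum P_i^2}; a plumbing helper for 1:1
#' comparisons of measured vs simulated series.
#'
#' @inheritParams rmse
#' @return The slope.
#' @export
slope_through_origin <- function(O, P) {
  .check_pairs(O, P)
  s2 <- sum(P^2)
  if (s2 == 0) stop("predicted series is identically zero", call. = FALSE)
  sum(O * P) / s2
}

#' Evaluation report for a pair of ET series
#'
#' @inheritParams rmse
#' @return An `et_metrics` object: list with `rmse`, `mae`, `d_ia`, `n`.
#' @export
et_metrics <- function(O, P) {
  .check_pairs(O, P)
  structure(
    list(rmse = rmse(O, P), mae = mae(O, P),
         d_ia = index_of_agreement(O, P), n = length(O)),
    class = "et_metrics"
  )
}

#' @export
print.et_metrics <- function(x, ...) {
  cat(sprintf("    RMSE %.4f   MAE %.4f   d_IA %.4f   (n = %d)\n",
              x$rmse, x$mae, x$d_ia, x$n))
  invisible(x)
}

#' @export
as.data.frame.et_metrics <- function(x, ...) {
  data.frame(rmse = x$rmse, mae = x$mae, d_ia = x$d_ia, n = x$n)
}
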