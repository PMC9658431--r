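# Path analysis: decomposition of each meteorological driver's
# correlation with ET into a direct (standardized regression) path and
# indirect paths routed through the other, correlated drivers, plus the
# decision coefficient 2*P*r - P^2.

#' Standardize a series to zero mean and unit variance
#'
#' Sample (n-1) standard deviation.  Errors on zero-variance input,
#' naming the variable when `name` is given.
#'
#' @param x Numeric vector.
#' @param name Variable name for error messages.
#' @return Standardized vector.
#' @export
standardize <- function(x, name = deparse(substitute(x))) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize '", name, "': zero variance", call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Direct path coefficients
#'
#' Standardized ordinary-least-squares coefficients of the response on
#' the drivers, solved from the normal equations
#' \eqn{R_{xx} P = r_{xy}} on the correlation scale (so no intercept is
#' needed).
#'
#' @param X Numeric matrix or data frame of drivers (columns named).
#' @param y Response vector.
#' @return Named vector of direct path coefficients P.
#' @export
direct_path_coefficients <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X)) {
    stop("need more observations than drivers", call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  zero <- !is.finite(sds) | sds == 0
  if (any(zero)) {
    stop("zero-variance driver(s): ",
         paste(colnames(X)[zero], collapse = ", "), call. = FALSE)
  }
  Rxx <- stats::cor(X)
  rxy <- as.vector(stats::cor(X, y))
  P <- tryCatch(
    solve(Rxx, rxy),
    error = function(e) {
      stop("singular driver correlation matrix (collinear drivers?): ",
           conditionMessage(e), call. = FALSE)
    }
  )
  stats::setNames(as.vector(P), colnames(X))
}

#' Indirect path coefficients
#'
#' Entry (i, j) is the effect of driver i routed through driver j,
#' \eqn{r_{ij} P_j}; the diagonal is empty (NA) and the total indirect
#' path of driver i is the off-diagonal row sum.
#'
#' @param R Correlation matrix of the drivers.
#' @param P Direct path coefficients (same order).
#' @return List with `indirect` (matrix, NA diagonal) and `total`
#'   (named vector of row sums).
#' @export
indirect_path_coefficients <- function(R, P) {
  R <- as.matrix(R)
  stopifnot(nrow(R) == ncol(R), length(P) == nrow(R))
  ind <- sweep(R, 2, P, `*`)
  diag(ind) <- NA_real_
  total <- rowSums(ind, na.rm = TRUE)
  if (!is.null(colnames(R))) names(total) <- colnames(R)
  list(indirect = ind, total = total)
}

#' Decision coefficients
#'
#' \eqn{R_d = 2 P r - P^2}: a driver's total determinative contribution,
#' combining its direct path with its correlation.
#'
#' @param P Direct path coefficients.
#' @param r Correlations of each driver with the response.
#' @return Vector of decision coefficients.
#' @export
decision_coefficients <- function(P, r) {
  stopifnot(length(P) == length(r))
  2 * P * r - P^2
}

#' Path analysis of hourly ET against its meteorological drivers
#'
#' Restricts the table to a daily hour window (default the ventilation
#' hours 9:00-16:00, both ends inclusive, i.e. 8 hourly rows per day),
#' then computes driver-response correlations, direct paths (standardized
#' OLS), the indirect-path matrix, total indirect paths, decision
#' coefficients, and the residual of the identity
#' \eqn{r_i = P_i + \sum_{j \ne i} r_{ij} P_j} (which holds to numerical
#' precision whenever the paths are solved from the same data).
#'
#' @param data Hourly data frame containing the response and driver
#'   columns plus `timestamp`.
#' @param response Response column name (default `"ET"`).
#' @param drivers Driver column names (default `c("Rn", "Ta", "VPD",
#'   "u2")`).
#' @param window Integer hour range, inclusive on both ends (default
#'   `c(9, 16)`); `NULL` uses all rows.
#' @return A `path_analysis` object: data frame `table` (one row per
#'   driver with `r`, `P`, `total_indirect`, `Rd`, `residual`), matrix
#'   `indirect`, the driver correlation matrix `R`, `n` rows used and the
#'   `window`.
#' @export
path_analysis <- function(data, response = "ET",
                          drivers = c("Rn", "Ta", "VPD", "u2"),
                          window = c(9, 16)) {
  miss <- setdiff(c(response, drivers), names(data))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  d <- data
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] <= window[2])
    if (!"timestamp" %in% names(d)) {
      stop("hour-window filtering needs a timestamp column", call. = FALSE)
    }
    hr <- as.integer(format(d$timestamp, "%H"))
    d <- d[hr >= window[1] & hr <= window[2], , drop = FALSE]
  }
  if (nrow(d) < length(drivers) + 1L) {
    stop("too few rows after window filtering (", nrow(d), ") for ",
         length(drivers), " drivers", call. = FALSE)
  }
  X <- as.matrix(d[, drivers, drop = FALSE])
  y <- d[[response]]
  P <- direct_path_coefficients(X, y)
  r <- stats::setNames(as.vector(stats::cor(X, y)), drivers)
  R <- stats::cor(X)
  ind <- indirect_path_coefficients(R, P)
  Rd <- decision_coefficients(P, r)
  tab <- data.frame(
    driver = drivers, r = r, P = P, total_indirect = ind$total,
    Rd = Rd, residual = r - (P + ind$total), row.names = NULL
  )
  structure(
    list(table = tab, indirect = ind$indirect, R = R, n = nrow(d),
         window = window, response = response),
    class = "path_analysis"
  )
}

#' @export
print.path_analysis <- function(x, digits = 3, ...) {
  cat(sprintf("Path analysis of %s on %d hourly rows%s\n", x$response, x$n,
              if (is.null(x$window)) "" else
                sprintf(" (hours %02d:00-%02d:00)", x$window[1], x$window[2])))
  tab <- x$table
  ind <- round(x$indirect, digits)
  colnames(ind) <- paste0("via_", colnames(ind))
  out <- cbind(
    driver = tab$driver,
    round(tab[, c("r", "P", "total_indirect")], digits),
    as.data.frame(ind),
    Rd = round(tab$Rd, digits),
    residual = round(tab$residual, digits)
  )
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.path_analysis <- function(x, ...) {
  cbind(x$table, as.data.frame(x$indirect))
}
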