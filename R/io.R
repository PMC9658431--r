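# Delimited time-series I/O and YAML run configuration.
# Conventions: CSV, comma separator, decimal point, ISO 8601 local
# timestamps (greenhouse-local clock; no timezone arithmetic).

#' Read a validated time-series table
#'
#' Reads a CSV with a header row and a `timestamp` (or `date`) column,
#' parses timestamps as ISO 8601, rejects duplicates and unparseable
#' rows (naming the offending row numbers), sorts by time, checks any
#' required columns, and flags gaps in an hourly grid via the
#' `"gaps"` attribute.
#'
#' @param path File path.
#' @param required Character vector of columns that must be present.
#' @param daily Treat the time column as a daily `date` rather than an
#'   hourly `timestamp`.
#' @return Sorted data frame; attribute `"gaps"` holds the number of
#'   missing steps on the regular grid (0 when complete).
#' @export
read_timeseries <- function(path, required = NULL, daily = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  tcol <- if (daily) "date" else "timestamp"
  if (!tcol %in% names(d)) {
    stop("'", path, "' has no '", tcol, "' column", call. = FALSE)
  }
  raw <- d[[tcol]]
  tv <- if (daily) {
    as.Date(raw, format = "%Y-%m-%d")
  } else {
    parsed <- rep(NA_real_, length(raw))
    for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                  "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
      todo <- is.na(parsed)
      if (!any(todo)) break
      parsed[todo] <- as.numeric(strptime(raw[todo], format = fmt,
                                          tz = "UTC"))
    }
    as.POSIXct(parsed, tz = "UTC", origin = "1970-01-01")
  }
  bad <- is.na(tv) & !is.na(raw)
  if (any(bad)) {
    stop("unparseable ", tcol, " in '", path, "' at row(s) ",
         paste(utils::head(which(bad), 10L), collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(tv)
  if (any(dup)) {
    stop("duplicated ", tcol, " in '", path, "' at row(s) ",
         paste(utils::head(which(dup), 10L), collapse = ", "),
         call. = FALSE)
  }
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    stop("'", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  d[[tcol]] <- tv
  d <- d[order(tv), , drop = FALSE]
  rownames(d) <- NULL
  step <- if (daily) 1 else 3600
  dt <- as.numeric(diff(d[[tcol]]), units = if (daily) "days" else "secs")
  attr(d, "gaps") <- sum(pmax(0, round(dt / step) - 1))
  d
}

#' Write a time-series table as CSV
#'
#' @param x Data frame (a `timestamp` column is formatted as ISO 8601).
#' @param path Output path (directories are created as needed).
#' @return Invisibly, `path`.
#' @export
write_timeseries <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if ("timestamp" %in% names(x)) {
    x$timestamp <- format(x$timestamp, "%Y-%m-%dT%H:%M:%S")
  }
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' A single human-readable file controlling a model run: site constants,
#' model parameters (any [ipt_params()] field), input file paths, the
#' path-analysis hour window and the output directory.  Every parameter
#' omitted from the file keeps its package default.
#'
#' @param path YAML file path.
#' @return List with elements `params` (an `ipt_params` object) and any
#'   further top-level entries of the file (`paths`, `window`, ...).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  par_fields <- cfg$params %||% list()
  if (!is.null(cfg$site)) {
    site <- cfg$site[intersect(names(cfg$site),
                               c("elevation", "theta_s", "theta_w"))]
    par_fields <- utils::modifyList(site, par_fields)
  }
  params <- do.call(ipt_params, par_fields)
  out <- cfg[setdiff(names(cfg), c("params", "site"))]
  out$params <- params
  out
}
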