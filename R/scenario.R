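# Season scenario configuration for the synthetic greenhouse generators.
# Presets for a 2019-like and a 2020-like tomato season ship as YAML files
# under inst/extdata/.

#' Build a greenhouse season scenario
#'
#' Loads a shipped season preset (stage calendar, per-stage climate
#' targets, diurnal shape, crop phenology knots, soil and noise settings)
#' and applies any overrides.  The presets mirror a two-season
#' drip-irrigated greenhouse tomato experiment: four contiguous growth
#' stages (initial, development, middle, late), stage-mean net radiation
#' around 103-154 W m^-2, air temperature 19-28 C, VPD 0.7-1.4 kPa and
#' wind below 0.15 m s^-1.
#'
#' @param year Preset to load, `"2019"` or `"2020"`.
#' @param start,end Optional `Date` window to restrict the season (both
#'   must lie within the preset span); stage boundaries are clipped.
#' @param ... Named overrides for top-level preset entries (e.g.
#'   `noise`, `soil`, `crop`, `diurnal`); list entries are merged.
#' @return A `gh_scenario` object (validated list).
#' @examples
#' sc <- greenhouse_scenario("2019")
#' sc$stage_means$middle$Rn  # 149.92 W/m2
#' @export
greenhouse_scenario <- function(year = c("2019", "2020"), start = NULL,
                                end = NULL, ...) {
  year <- match.arg(year)
  path <- system.file("extdata", paste0("scenario_", year, ".yaml"),
                      package = "iptet", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  cfg$start <- as.Date(cfg$start)
  cfg$end <- as.Date(cfg$end)
  for (s in names(cfg$stages)) {
    cfg$stages[[s]]$start <- as.Date(cfg$stages[[s]]$start)
    cfg$stages[[s]]$end <- as.Date(cfg$stages[[s]]$end)
  }
  if (!is.null(start)) {
    start <- as.Date(start)
    if (start < cfg$start || start > cfg$end) {
      stop("start outside the preset season span", call. = FALSE)
    }
    cfg$start <- start
  }
  if (!is.null(end)) {
    end <- as.Date(end)
    if (end < cfg$start || end > as.Date(cfg$end)) {
      stop("end outside the preset season span", call. = FALSE)
    }
    cfg$end <- end
  }
  validate_scenario(cfg)
}

validate_scenario <- function(cfg) {
  stopifnot(cfg$start <= cfg$end)
  ord <- c("initial", "development", "middle", "late")
  if (!identical(names(cfg$stages), ord)) {
    stop("stages must be exactly: ", paste(ord, collapse = ", "),
         call. = FALSE)
  }
  b <- lapply(cfg$stages, function(s) c(s$start, s$end))
  for (i in seq_along(b)) {
    if (b[[i]][1] > b[[i]][2]) stop("stage dates out of order", call. = FALSE)
    if (i > 1 && b[[i]][1] != b[[i - 1]][2] + 1L) {
      stop("stages must be contiguous", call. = FALSE)
    }
  }
  for (s in ord) {
    m <- cfg$stage_means[[s]]
    if (is.null(m) || !all(c("Rn", "Ta", "VPD", "u2") %in% names(m))) {
      stop("stage_means$", s, " needs Rn, Ta, VPD, u2", call. = FALSE)
    }
    if (m$Rn <= 0) stop("stage-mean Rn must be positive", call. = FALSE)
  }
  if (any(unlist(cfg$noise) < 0)) {
    stop("noise levels must be >= 0", call. = FALSE)
  }
  if (cfg$soil$theta_w >= cfg$soil$theta_s) {
    stop("theta_w must be below theta_s", call. = FALSE)
  }
  structure(cfg, class = "gh_scenario")
}

#' @export
print.gh_scenario <- function(x, ...) {
  cat(sprintf("Greenhouse season scenario (%s): %s to %s\n", x$year,
              format(x$start), format(x$end)))
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    m <- x$stage_means[[s]]
    cat(sprintf("  %-12s %s..%s  Rn %6.1f W/m2  Ta %5.1f C  VPD %5.2f kPa  u2 %5.2f m/s\n",
                s, format(st$start), format(st$end), m$Rn, m$Ta, m$VPD, m$u2))
  }
  invisible(x)
}

# stage label for each date (NA outside the calendar)
scenario_stage <- function(cfg, dates) {
  dates <- as.Date(dates)
  out <- rep(NA_character_, length(dates))
  for (s in names(cfg$stages)) {
    st <- cfg$stages[[s]]
    out[dates >= st$start & dates <= st$end] <- s
  }
  out
}

#' Reference stage-mean greenhouse climate table
#'
#' The per-stage mean net radiation (6:00-18:00 average), air
#' temperature, VPD and wind speed reported for the two greenhouse tomato
#' seasons that the synthetic presets emulate; used as generator targets
#' and in tests.
#'
#' @return Data frame with columns `year`, `stage`, `Rn`, `Ta`, `VPD`,
#'   `u2`.
#' @export
reference_stage_climate <- function() {
  utils::read.csv(system.file("extdata", "stage_climate.csv",
                              package = "iptet", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Reference path-analysis table for greenhouse tomato ET
#'
#' The published two-season path-analysis decomposition of hourly ET
#' against net radiation, air temperature, VPD and wind speed (r, direct
#' path P, indirect paths, totals and decision coefficients), as reported
#' for a drip-irrigated greenhouse tomato experiment.  Used for internal
#' consistency checks of the path-analysis arithmetic.
#'
#' @return Data frame with columns `year`, `factor`, `r`, `P`,
#'   `total_indirect`, `ind_Rn`, `ind_Ta`, `ind_VPD`, `ind_u2`, `Rd`.
#' @export
reference_path_table <- function() {
  utils::read.csv(system.file("extdata", "path_table_reference.csv",
                              package = "iptet", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Reference stage-mean daily ET
#'
#' Reported daily-mean ET (mm per day) at the initial and middle stages of
#' the two seasons the presets emulate.
#'
#' @return Data frame with columns `year`, `stage`, `et_mm_d`.
#' @export
reference_stage_et <- function() {
  utils::read.csv(system.file("extdata", "stage_et_reference.csv",
                              package = "iptet", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
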