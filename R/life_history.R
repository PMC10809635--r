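#' Developmental stages
#'
#' Ordered labels for the pre-adult stages and the adult stage of
#' *C. elegans*. `EGG` precedes `L1`--`L4`; `ADULT` is terminal.
#'
#' @return Character vector of stage labels in developmental order.
#' @export
#' @examples
#' colony_stages()
colony_stages <- function() {
  c("EGG", "L1", "L2", "L3", "L4", "ADULT")
}

#' Default life-history configuration for a colony on a food patch
#'
#' Assembles the parameterization of the colony projection model: stage
#' durations, the hourly egg-laying schedule, stage-specific food consumption
#' rates, and the food-patch setup. The defaults describe wild-type
#' hermaphrodite development at 25 degrees C:
#'
#' * stage durations (hours): EGG 9, L1 12, L2 7, L3 7, L4 9;
#' * egg laying over a 5-day reproductive span, 170 eggs in total, laid at a
#'   constant rate within each day with daily totals (15, 90, 45, 15, 5),
#'   i.e. peaking on the second day of adulthood;
#' * food consumption per worm per hour: 0 (egg), 1 (L1), 2 (L2), 4 (L3),
#'   8 (L4), 16 (adult), in the same virtual food units as the patch;
#' * a patch of 10 million food units, a 200-hour horizon, and founder
#'   numbers 1, 3, 10, 50 and 200.
#'
#' Eggs are closed systems and do not feed, hence the zero egg rate. Adults
#' past the reproductive span persist and keep consuming: there is no
#' mortality within the model horizon.
#'
#' @param stage_durations_hr Named integer vector of pre-adult stage durations
#'   in hours, names `EGG`, `L1`, `L2`, `L3`, `L4`. All entries must be >= 1.
#' @param fecundity_eggs_per_hr Numeric vector of eggs laid per hour, indexed
#'   by adult age in hours (element 1 = first hour after the L4-to-adult
#'   molt). Its length is the reproductive span.
#' @param consumption_units_per_hr Named numeric vector of food units consumed
#'   per worm per hour for `EGG`, `L1`, `L2`, `L3`, `L4`, `ADULT`.
#' @param patch_units Size of the virtual food patch, in food units.
#' @param horizon_hr Number of hours to project.
#' @param founder_numbers Integer vector of founder numbers for sweeps.
#' @param adult_tracking_hr Number of hourly adult age classes tracked; the
#'   last class is absorbing. Must be at least the reproductive span.
#' @param max_generations Number of generations tracked as separate state
#'   vectors; eggs laid by the last tracked generation are credited back to
#'   it (with a warning at simulation time).
#'
#' @return An object of class `colony_config`: a list with the components
#'   above plus `stage_of_class`, the stage label of every hourly age class.
#' @seealso [validate_config()], [simulate_colony()], [read_colony_config()]
#' @export
#' @examples
#' cfg <- colony_config()
#' cfg$patch_units
#' sum(cfg$fecundity_eggs_per_hr) # total brood per hermaphrodite
colony_config <- function(stage_durations_hr = c(EGG = 9L, L1 = 12L, L2 = 7L,
                                                 L3 = 7L, L4 = 9L),
                          fecundity_eggs_per_hr = default_fecundity(),
                          consumption_units_per_hr = c(EGG = 0, L1 = 1, L2 = 2,
                                                       L3 = 4, L4 = 8, ADULT = 16),
                          patch_units = 1e7,
                          horizon_hr = 200L,
                          founder_numbers = c(1L, 3L, 10L, 50L, 200L),
                          adult_tracking_hr = 160L,
                          max_generations = 4L) {
  pre <- colony_stages()[1:5]
  stage_durations_hr <- stage_durations_hr[pre]
  names(stage_durations_hr) <- pre
  cfg <- structure(
    list(
      stage_durations_hr = as.integer(stage_durations_hr),
      fecundity_eggs_per_hr = as.numeric(fecundity_eggs_per_hr),
      consumption_units_per_hr = consumption_units_per_hr[colony_stages()],
      patch_units = as.numeric(patch_units),
      horizon_hr = as.integer(horizon_hr),
      founder_numbers = as.integer(founder_numbers),
      adult_tracking_hr = as.integer(adult_tracking_hr),
      max_generations = as.integer(max_generations)
    ),
    class = "colony_config"
  )
  names(cfg$stage_durations_hr) <- pre
  names(cfg$consumption_units_per_hr) <- colony_stages()
  cfg$stage_of_class <- c(rep(pre, cfg$stage_durations_hr),
                          rep("ADULT", cfg$adult_tracking_hr))
  cfg
}

# 170 eggs over 5 reproductive days, peak on day 2, constant rate within a day
default_fecundity <- function(daily_totals = c(15, 90, 45, 15, 5)) {
  rep(daily_totals / 24, each = 24)
}

#' @export
print.colony_config <- function(x, ...) {
  cat("<colony_config>\n")
  cat("  stage durations (hr):",
      paste(names(x$stage_durations_hr), x$stage_durations_hr,
            sep = "=", collapse = " "), "\n")
  cat("  reproductive span  :", length(x$fecundity_eggs_per_hr), "hr, total brood",
      format(sum(x$fecundity_eggs_per_hr)), "\n")
  cat("  consumption (units/hr):",
      paste(names(x$consumption_units_per_hr), x$consumption_units_per_hr,
            sep = "=", collapse = " "), "\n")
  cat("  patch:", format(x$patch_units, big.mark = ","), "units; horizon",
      x$horizon_hr, "hr; founders:", paste(x$founder_numbers, collapse = ", "), "\n")
  invisible(x)
}

#' Validate a colony configuration
#'
#' Checks every structural invariant of a [colony_config()] object and
#' returns the violations as data, not errors: an empty tibble means the
#' configuration is valid.
#'
#' @param cfg A `colony_config` object (or a bare list with the same fields).
#' @return A tibble with columns `field` and `rule`, one row per violation.
#' @export
#' @examples
#' validate_config(colony_config()) # zero rows
#' bad <- colony_config()
#' bad$stage_durations_hr["L1"] <- 0L
#' validate_config(bad)
validate_config <- function(cfg) {
  v <- list()
  bad <- function(field, rule) list(field = field, rule = rule)
  dur <- cfg$stage_durations_hr
  for (s in names(dur)) {
    if (is.na(dur[[s]]) || dur[[s]] < 1) {
      v[[length(v) + 1]] <- bad(paste0("stage_durations_hr[", s, "]"),
                                "stage duration must be a positive number of hours")
    }
  }
  fec <- cfg$fecundity_eggs_per_hr
  if (length(fec) < 1) {
    v[[length(v) + 1]] <- bad("fecundity_eggs_per_hr", "reproductive span must be >= 1 hour")
  }
  if (any(is.na(fec)) || any(fec < 0)) {
    v[[length(v) + 1]] <- bad("fecundity_eggs_per_hr", "all hourly fecundities must be >= 0")
  }
  cons <- cfg$consumption_units_per_hr
  if (any(is.na(cons)) || any(cons < 0)) {
    v[[length(v) + 1]] <- bad("consumption_units_per_hr", "all consumption rates must be >= 0")
  }
  if (!is.na(cfg$patch_units) && cfg$patch_units < 0) {
    v[[length(v) + 1]] <- bad("patch_units", "patch size must be >= 0 food units")
  }
  if (is.na(cfg$horizon_hr) || cfg$horizon_hr < 1) {
    v[[length(v) + 1]] <- bad("horizon_hr", "horizon must be >= 1 hour")
  }
  if (!all(is.na(dur)) && sum(dur, na.rm = TRUE) >= cfg$horizon_hr) {
    v[[length(v) + 1]] <- bad("stage_durations_hr",
                              "total pre-adult duration must be shorter than the horizon")
  }
  if (length(cfg$founder_numbers) < 1 || any(cfg$founder_numbers < 0)) {
    v[[length(v) + 1]] <- bad("founder_numbers", "founder numbers must be non-negative")
  }
  if (is.na(cfg$adult_tracking_hr) || cfg$adult_tracking_hr < length(fec)) {
    v[[length(v) + 1]] <- bad("adult_tracking_hr",
                              "adult age classes must cover the reproductive span")
  }
  if (is.na(cfg$max_generations) || cfg$max_generations < 1) {
    v[[length(v) + 1]] <- bad("max_generations", "at least one generation must be tracked")
  }
  dplyr::bind_rows(v) %||% tibble::tibble(field = character(), rule = character())
}

stop_if_invalid <- function(cfg) {
  v <- validate_config(cfg)
  if (nrow(v) > 0) {
    stop("invalid colony configuration:\n",
         paste0("  - ", v$field, ": ", v$rule, collapse = "\n"),
         call. = FALSE)
  }
  invisible(cfg)
}

#' Read a colony configuration from a YAML or JSON file
#'
#' The file may set any subset of the keys `stage_durations_hr`,
#' `fecundity_eggs_per_hr`, `consumption_units_per_hr`, `patch_units`,
#' `horizon_hr`, `founder_numbers`, `adult_tracking_hr`, `max_generations`;
#' unset keys keep the package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `colony_config` object.
#' @export
read_colony_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("config file must be YAML or JSON: ", path, call. = FALSE)
  }
  args <- list()
  for (key in c("stage_durations_hr", "consumption_units_per_hr")) {
    if (!is.null(raw[[key]])) args[[key]] <- unlist(raw[[key]])
  }
  for (key in c("fecundity_eggs_per_hr", "patch_units", "horizon_hr",
                "founder_numbers", "adult_tracking_hr", "max_generations")) {
    if (!is.null(raw[[key]])) args[[key]] <- unlist(raw[[key]])
  }
  cfg <- do.call(colony_config, args)
  stop_if_invalid(cfg)
}

#' Write a colony configuration to YAML
#'
#' @param cfg A `colony_config` object.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_colony_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$stage_of_class <- NULL
  x$stage_durations_hr <- as.list(x$stage_durations_hr)
  x$consumption_units_per_hr <- as.list(x$consumption_units_per_hr)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}
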