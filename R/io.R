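plate_schema <- c(founder_number = "numeric", replicate_id = "character",
                  bust_hr = "numeric", timepoint_hr = "numeric",
                  count1 = "numeric", count2 = "numeric", count3 = "numeric",
                  volume_ml = "numeric", contaminated = "logical")
lawn_schema <- c(plate_id = "character", area_cm2 = "numeric",
                 od600 = "numeric")
length_schema <- c(timepoint_hr = "numeric", worm_id = "character",
                   length_um = "numeric")

check_header <- function(df, schema, file) {
  missing <- setdiff(names(schema), names(df))
  if (length(missing) > 0) {
    stop("file ", file, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

# row-level violations as data: tibble(file, row, column, problem)
check_rows <- function(df, file) {
  v <- list()
  flag <- function(rows, column, problem) {
    if (length(rows) > 0) {
      v[[length(v) + 1]] <<- tibble::tibble(file = file, row = rows,
                                            column = column, problem = problem)
    }
  }
  if (file == "plates") {
    for (cc in c("count1", "count2", "count3")) {
      flag(which(!is.na(df[[cc]]) & df[[cc]] < 0), cc,
           "aliquot count must be non-negative")
      flag(which(is.na(df[[cc]])), cc, "aliquot count is missing")
    }
    flag(which(is.na(df$volume_ml) | df$volume_ml <= 0), "volume_ml",
         "suspension volume must be positive")
    flag(which(!is.na(df$bust_hr) & df$bust_hr < 0), "bust_hr",
         "bust time must be non-negative")
    flag(which(is.na(df$founder_number) | df$founder_number < 1),
         "founder_number", "founder number must be a positive integer")
    flag(which(!is.na(df$timepoint_hr) & df$timepoint_hr < 0), "timepoint_hr",
         "timepoint must be non-negative")
  } else if (file == "lawn_qc") {
    flag(which(is.na(df$area_cm2) | df$area_cm2 <= 0), "area_cm2",
         "lawn area must be positive")
    flag(which(is.na(df$od600) | df$od600 <= 0), "od600",
         "optical density must be positive")
  } else if (file == "lengths") {
    flag(which(is.na(df$length_um) | df$length_um <= 0), "length_um",
         "dauer length must be positive")
    flag(which(is.na(df$timepoint_hr) | df$timepoint_hr < 0), "timepoint_hr",
         "timepoint must be non-negative")
  }
  dplyr::bind_rows(v) %||%
    tibble::tibble(file = character(), row = integer(),
                   column = character(), problem = character())
}

#' Read colony fitness assay CSV files
#'
#' Reads the plate table (and optionally the lawn QC and dauer length
#' tables) from headered, comma-separated, UTF-8 files. A missing required
#' column rejects the whole file; per-row violations are collected -- with
#' their row numbers -- rather than raised, and attached to the result.
#'
#' @param plates Path to `plates.csv` (columns `founder_number`,
#'   `replicate_id`, `bust_hr`, `timepoint_hr`, `count1`, `count2`, `count3`,
#'   `volume_ml`, `contaminated`).
#' @param lawn_qc Optional path to `lawn_qc.csv` (`plate_id`, `area_cm2`,
#'   `od600`).
#' @param lengths Optional path to `lengths.csv` (`timepoint_hr`, `worm_id`,
#'   `length_um`).
#' @param strict Stop if any row-level violation is found (default: warn and
#'   attach the violations).
#' @return An `assay_dataset` (see [generate_assay()]) with a `violations`
#'   tibble attribute.
#' @export
read_assay_csvs <- function(plates, lawn_qc = NULL, lengths = NULL,
                            strict = FALSE) {
  rd <- function(path) readr::read_csv(path, show_col_types = FALSE,
                                       progress = FALSE)
  p <- check_header(rd(plates), plate_schema, "plates")
  p$contaminated <- as.logical(p$contaminated)
  viol <- check_rows(p, "plates")
  ds <- list(plates = p, lawn_qc = NULL, lengths = NULL)
  if (!is.null(lawn_qc)) {
    ds$lawn_qc <- check_header(rd(lawn_qc), lawn_schema, "lawn_qc")
    viol <- dplyr::bind_rows(viol, check_rows(ds$lawn_qc, "lawn_qc"))
  }
  if (!is.null(lengths)) {
    ds$lengths <- check_header(rd(lengths), length_schema, "lengths")
    viol <- dplyr::bind_rows(viol, check_rows(ds$lengths, "lengths"))
  }
  if (nrow(viol) > 0) {
    msg <- paste0(nrow(viol), " row-level schema violation(s), e.g. ",
                  viol$file[1], ".csv row ", viol$row[1], " (", viol$column[1],
                  "): ", viol$problem[1])
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  structure(ds, class = "assay_dataset", violations = viol)
}

#' Write an assay dataset to CSV files
#'
#' Writes `plates.csv` and, when present, `lawn_qc.csv` and `lengths.csv`
#' into `dir`. Reading them back with [read_assay_csvs()] is lossless.
#'
#' @param ds An `assay_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_assay_csvs <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(plates = file.path(dir, "plates.csv"))
  readr::write_csv(ds$plates, paths[["plates"]], progress = FALSE)
  if (!is.null(ds$lawn_qc)) {
    paths[["lawn_qc"]] <- file.path(dir, "lawn_qc.csv")
    readr::write_csv(ds$lawn_qc, paths[["lawn_qc"]], progress = FALSE)
  }
  if (!is.null(ds$lengths)) {
    paths[["lengths"]] <- file.path(dir, "lengths.csv")
    readr::write_csv(ds$lengths, paths[["lengths"]], progress = FALSE)
  }
  invisible(paths)
}

#' Write analysis reports
#'
#' Writes the group summaries and trade-off table as TSV and the pairwise
#' comparisons as a JSON report.
#'
#' @param results A named list; recognized components: `summary` (a
#'   [summarize_assay()] result), `tradeoff` (a [tradeoff_table()]),
#'   `comparisons` (a named list of [compare_groups()] results),
#'   `timecourse` (a [yield_timecourse()]), `lawn` (a [lawn_qc()] tibble),
#'   `recovery` (a [recovery_check()]).
#' @param dir Output directory.
#' @return Character vector of files written, invisibly.
#' @export
write_reports <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  w <- function(df, name) {
    path <- file.path(dir, name)
    readr::write_tsv(df, path, progress = FALSE)
    written <<- c(written, path)
  }
  if (!is.null(results$summary)) {
    if (!is.null(results$summary$bust_hr)) w(results$summary$bust_hr,
                                             "bust_summary.tsv")
    if (!is.null(results$summary$dauer_yield)) w(results$summary$dauer_yield,
                                                 "yield_summary.tsv")
  }
  if (!is.null(results$tradeoff)) {
    tt <- results$tradeoff
    w(tibble::as_tibble(tt), "tradeoff.tsv")
  }
  if (!is.null(results$timecourse)) w(tibble::as_tibble(results$timecourse),
                                      "yield_timecourse.tsv")
  if (!is.null(results$lawn)) w(results$lawn, "lawn_qc_summary.tsv")
  if (!is.null(results$recovery)) w(results$recovery$by_timepoint,
                                    "length_by_timepoint.tsv")
  if (!is.null(results$comparisons)) {
    rep <- purrr::map(results$comparisons, function(cmp) {
      list(design = cmp$design, metric = cmp$metric,
           anova = glance(cmp), tukey = tidy(cmp))
    })
    path <- file.path(dir, "comparisons.json")
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    written <- c(written, path)
  }
  invisible(written)
}

#' Write a run manifest
#'
#' Every command-line run records what produced its outputs: command,
#' configuration digest, seed, timestamps, input/output paths, and the
#' package version.
#'
#' @param command Command name.
#' @param config The configuration object used (digested with [rlang::hash()]).
#' @param seed Seed used, or `NA`.
#' @param inputs,outputs Character vectors of paths.
#' @param path File to write (JSON).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(command, config, seed, inputs, outputs, path) {
  manifest <- list(
    command = command,
    config_digest = rlang::hash(config),
    seed = if (is.null(seed)) NA else seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = as.character(inputs),
    outputs = as.character(outputs),
    package_version = as.character(utils::packageVersion("colonyfit"))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null")
  invisible(manifest)
}
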