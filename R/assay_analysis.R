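#' Drop contaminated plates
#'
#' Plates on which bacterial or fungal contamination was detected carry no
#' usable counts and are excluded from every statistic. The number of
#' excluded plates is reported as a message.
#'
#' @param plates A plate table with a logical (or 0/1) `contaminated` column.
#' @param quiet Suppress the exclusion message.
#' @return The table without contaminated rows.
#' @export
drop_contaminated <- function(plates, quiet = FALSE) {
  n_bad <- sum(as.logical(plates$contaminated), na.rm = TRUE)
  if (n_bad > 0 && !quiet) {
    message("excluding ", n_bad, " contaminated plate(s)")
  }
  dplyr::filter(plates, !as.logical(.data$contaminated))
}

#' Scale aliquot dauer counts to whole-plate yields
#'
#' Dauers are counted in three 1 ml aliquots of the plate's worm suspension;
#' the plate-level yield is the mean of the three counts times the total
#' suspension volume in ml. Contaminated plates are refused: remove them
#' first with [drop_contaminated()].
#'
#' @param plates A plate table with columns `count1`, `count2`, `count3`
#'   (dauers per 1 ml aliquot), `volume_ml`, and `contaminated`.
#' @return The table with an added `dauer_yield` column.
#' @export
#' @examples
#' p <- tibble::tibble(count1 = 10, count2 = 12, count3 = 14,
#'                     volume_ml = 5, contaminated = FALSE)
#' scale_dauer_counts(p)$dauer_yield # 60
scale_dauer_counts <- function(plates) {
  if (any(as.logical(plates$contaminated), na.rm = TRUE)) {
    stop("refusing to scale counts from contaminated plates; ",
         "remove them first with drop_contaminated()", call. = FALSE)
  }
  counts <- cbind(plates$count1, plates$count2, plates$count3)
  if (any(counts < 0, na.rm = TRUE)) {
    stop("aliquot counts must be non-negative", call. = FALSE)
  }
  dplyr::mutate(plates,
                dauer_yield = rowMeans(counts) * .data$volume_ml)
}

#' Group summaries of the colony fitness metrics
#'
#' Mean, sample standard deviation, and group size for time to bust (per
#' founder number) and dauer yield (per founder number and post-bust
#' timepoint). Contaminated plates are excluded; plates with a missing
#' `bust_hr` are excluded from the bust summary only. Empty cells are simply
#' absent from the output -- nothing is imputed.
#'
#' @param plates A plate table; `dauer_yield` is computed on the fly if
#'   absent.
#' @param metric `"both"` (default), `"bust_hr"` or `"dauer_yield"`.
#' @return An object of class `fitness_summary`: a list with tibbles
#'   `bust_hr` (`founder_number`, `mean`, `sd`, `n`) and `dauer_yield`
#'   (`founder_number`, `timepoint_hr`, `mean`, `sd`, `n`); only the
#'   requested component(s) are non-`NULL`.
#' @export
summarize_assay <- function(plates,
                            metric = c("both", "bust_hr", "dauer_yield")) {
  metric <- match.arg(metric)
  plates <- drop_contaminated(plates, quiet = TRUE)
  if (!"dauer_yield" %in% names(plates)) {
    plates <- scale_dauer_counts(plates)
  }
  out <- list(bust_hr = NULL, dauer_yield = NULL)
  if (metric %in% c("both", "bust_hr")) {
    out$bust_hr <- plates |>
      dplyr::filter(!is.na(.data$bust_hr)) |>
      dplyr::group_by(.data$founder_number) |>
      dplyr::summarise(mean = mean(.data$bust_hr),
                       sd = stats::sd(.data$bust_hr),
                       n = dplyr::n(), .groups = "drop")
  }
  if (metric %in% c("both", "dauer_yield")) {
    out$dauer_yield <- plates |>
      dplyr::group_by(.data$founder_number, .data$timepoint_hr) |>
      dplyr::summarise(mean = mean(.data$dauer_yield),
                       sd = stats::sd(.data$dauer_yield),
                       n = dplyr::n(), .groups = "drop")
  }
  structure(out, class = "fitness_summary")
}

#' @export
print.fitness_summary <- function(x, ...) {
  cat("<fitness_summary>\n")
  if (!is.null(x$bust_hr)) {
    cat("time to bust (hr):\n"); print(x$bust_hr)
  }
  if (!is.null(x$dauer_yield)) {
    cat("dauer yield:\n"); print(x$dauer_yield)
  }
  invisible(x)
}

#' Compare groups by ANOVA with Tukey multiple comparisons
#'
#' One-way (founder-number effect) or two-way (founder number crossed with
#' post-bust timepoint) analysis of variance, followed by Tukey's multiple
#' comparisons over all pairs of group means (the Tukey--Kramer studentized
#' range procedure, valid for unbalanced groups). For the two-way design the
#' comparisons are over the founder-by-timepoint cell means.
#'
#' @param plates A plate table (uncontaminated rows are used; `dauer_yield`
#'   is computed if needed).
#' @param metric Response: `"bust_hr"` or `"dauer_yield"`.
#' @param design `"one_way"` (founder effect) or `"two_way"`
#'   (founder x timepoint; only meaningful for yield).
#' @param timepoint_hr For a one-way yield comparison, restrict to this
#'   timepoint (required when the table spans several).
#' @return An object of class `assay_comparison` with the `stats::aov` fit,
#'   the design, and tidied tables; see [tidy.assay_comparison()] and
#'   [glance.assay_comparison()].
#' @export
compare_groups <- function(plates, metric = c("bust_hr", "dauer_yield"),
                           design = c("one_way", "two_way"),
                           timepoint_hr = NULL) {
  metric <- match.arg(metric)
  design <- match.arg(design)
  plates <- drop_contaminated(plates, quiet = TRUE)
  if (metric == "dauer_yield" && !"dauer_yield" %in% names(plates)) {
    plates <- scale_dauer_counts(plates)
  }
  df <- dplyr::filter(plates, !is.na(.data[[metric]]))
  if (!is.null(timepoint_hr)) {
    tp <- timepoint_hr
    df <- dplyr::filter(df, .data$timepoint_hr == tp)
  }
  df$founder <- factor(df$founder_number)
  if (design == "two_way") {
    df$timepoint <- factor(df$timepoint_hr)
    sizes <- dplyr::count(df, .data$founder, .data$timepoint)
    grid <- tidyr::expand_grid(founder = levels(df$founder),
                               timepoint = levels(df$timepoint))
    if (nrow(sizes) < nrow(grid) || any(sizes$n < 2)) {
      low <- sizes[sizes$n < 2, , drop = FALSE]
      stop("degenerate design: every founder x timepoint cell needs n >= 2",
           if (nrow(low) > 0) paste0(" (offending cell: founder ",
                                     low$founder[1], ", ", low$timepoint[1],
                                     " hr)"),
           call. = FALSE)
    }
    fit <- stats::aov(stats::reformulate("founder * timepoint", metric),
                      data = df)
    tuk <- stats::TukeyHSD(fit, which = "founder:timepoint")
  } else {
    sizes <- dplyr::count(df, .data$founder)
    if (nrow(sizes) < 2) stop("need at least two groups", call. = FALSE)
    if (any(sizes$n < 2)) {
      stop("degenerate design: group with n < 2 (founder ",
           sizes$founder[which(sizes$n < 2)[1]], ")", call. = FALSE)
    }
    fit <- stats::aov(stats::reformulate("founder", metric), data = df)
    tuk <- stats::TukeyHSD(fit, which = "founder")
  }
  structure(list(fit = fit, tukey = tuk, metric = metric, design = design),
            class = "assay_comparison")
}

#' @export
print.assay_comparison <- function(x, ...) {
  cat("<assay_comparison> ", x$design, " ANOVA on ", x$metric, "\n", sep = "")
  print(glance(x))
  print(tidy(x), n = 10)
  invisible(x)
}

#' Pairwise Tukey comparisons of an assay ANOVA
#'
#' @param x An [compare_groups()] result.
#' @param ... Unused.
#' @return A tibble with `term`, `contrast`, `estimate` (difference of
#'   means), `conf.low`, `conf.high`, `adj.p.value`.
#' @export
tidy.assay_comparison <- function(x, ...) {
  purrr::imap(x$tukey, function(m, term) {
    tibble::tibble(term = term, contrast = rownames(m),
                   estimate = unname(m[, "diff"]),
                   conf.low = unname(m[, "lwr"]),
                   conf.high = unname(m[, "upr"]),
                   adj.p.value = unname(m[, "p adj"]))
  }) |> dplyr::bind_rows()
}

#' ANOVA table of an assay comparison
#'
#' @param x An [compare_groups()] result.
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `df`, `sumsq`,
#'   `meansq`, `statistic` (F), `p.value`.
#' @export
glance.assay_comparison <- function(x, ...) {
  tab <- summary(x$fit)[[1]]
  tibble::tibble(term = trimws(rownames(tab)), df = tab[["Df"]],
                 sumsq = tab[["Sum Sq"]], meansq = tab[["Mean Sq"]],
                 statistic = tab[["F value"]], p.value = tab[["Pr(>F)"]])
}

#' Dauer yield time course for one founder number
#'
#' Per-timepoint mean, standard deviation, and group size of the dauer
#' yield, with the peak timepoint. Ties in the mean break toward the earlier
#' timepoint (conservative about dauer loss after the peak).
#'
#' @param plates A plate table.
#' @param founder_number Founder number to extract.
#' @return A tibble (`timepoint_hr`, `mean`, `sd`, `n`, `is_peak`) with the
#'   attribute `peak_hr`; retrieve it with `peak_hr()`.
#' @export
#' @examples
#' ds <- generate_assay(assay_params(), seed = 1)
#' tc <- yield_timecourse(scale_dauer_counts(ds$plates), 3)
#' peak_hr(tc)
yield_timecourse <- function(plates, founder_number) {
  fn <- founder_number
  s <- summarize_assay(dplyr::filter(plates, .data$founder_number == fn),
                       metric = "dauer_yield")$dauer_yield
  s <- dplyr::arrange(s, .data$timepoint_hr)
  if (nrow(s) < 2) {
    warning("peak is undefined with fewer than two timepoints", call. = FALSE)
    peak <- NA_real_
  } else {
    peak <- s$timepoint_hr[which.max(s$mean)] # first max = earliest on ties
  }
  s$is_peak <- !is.na(peak) & s$timepoint_hr == peak
  s$founder_number <- NULL
  structure(s, peak_hr = peak, class = c("yield_timecourse", class(s)))
}

#' @rdname yield_timecourse
#' @param tc A `yield_timecourse` tibble.
#' @export
peak_hr <- function(tc) attr(tc, "peak_hr")

#' Dauer length recovery check
#'
#' Dauers seen late after bust may be recovering (resuming development),
#' which shows as increased body length. This check summarizes dauer lengths
#' per post-bust timepoint, runs a one-way ANOVA across timepoints, and
#' raises a flag when the latest timepoint's mean length exceeds the
#' earliest's. Groups smaller than `min_n` worms trigger a warning but the
#' analysis is still returned.
#'
#' @param lengths A table with columns `timepoint_hr` and `length_um`.
#' @param min_n Minimum worms per timepoint before warning.
#' @return A list of class `recovery_check`: `by_timepoint` (mean, sd, n per
#'   timepoint), `anova` (one-row F test tibble), and `increase_flag`.
#' @export
recovery_check <- function(lengths, min_n = 15) {
  stopifnot(nrow(lengths) > 0)
  by_tp <- lengths |>
    dplyr::group_by(.data$timepoint_hr) |>
    dplyr::summarise(mean = mean(.data$length_um),
                     sd = stats::sd(.data$length_um),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$timepoint_hr)
  if (nrow(by_tp) < 2) stop("need at least two timepoints", call. = FALSE)
  if (any(by_tp$n < min_n)) {
    warning("timepoint(s) with fewer than ", min_n, " worms: ",
            paste(by_tp$timepoint_hr[by_tp$n < min_n], collapse = ", "),
            " hr", call. = FALSE)
  }
  fit <- stats::aov(length_um ~ factor(timepoint_hr), data = lengths)
  tab <- summary(fit)[[1]]
  anova <- tibble::tibble(df = tab[["Df"]][1], statistic = tab[["F value"]][1],
                          p.value = tab[["Pr(>F)"]][1])
  flag <- by_tp$mean[nrow(by_tp)] > by_tp$mean[1]
  structure(list(by_timepoint = by_tp, anova = anova, increase_flag = flag),
            class = "recovery_check")
}

#' @export
print.recovery_check <- function(x, ...) {
  cat("<recovery_check> length increase at latest timepoint:",
      if (x$increase_flag) "YES" else "no", "\n")
  print(x$by_timepoint)
  invisible(x)
}

#' Bacterial lawn quality control
#'
#' Colony fitness assays need a constant food patch. This summarizes lawn
#' area and optical density across plates and checks them against tolerance
#' bands.
#'
#' @param qc A table with columns `area_cm2` and `od600`.
#' @param area_band,od_band Length-2 numeric vectors: acceptable range for
#'   the per-plate values.
#' @return A tibble with one row per variable: `variable`, `mean`, `sd`,
#'   `min`, `max`, `n`, `pass` (all plates within the band).
#' @export
lawn_qc <- function(qc, area_band = c(9, 12), od_band = c(0.30, 0.40)) {
  stopifnot(nrow(qc) >= 2)
  one <- function(v, band, nm) {
    tibble::tibble(variable = nm, mean = mean(v), sd = stats::sd(v),
                   min = min(v), max = max(v), n = length(v),
                   pass = all(v >= band[1] & v <= band[2]))
  }
  dplyr::bind_rows(one(qc$area_cm2, area_band, "area_cm2"),
                   one(qc$od600, od_band, "od600"))
}

#' Speed-versus-yield trade-off table
#'
#' Ranks founder numbers by resource-utilization speed (mean time to bust,
#' fastest = rank 1) and by efficiency (mean dauer yield at a reference
#' post-bust timepoint, highest = rank 1). A colony-level trade-off shows up
#' as a non-monotone yield: the best-yielding founder number is interior
#' rather than at an extreme, while speed always increases with founder
#' number.
#'
#' @param summary A [summarize_assay()] result containing both metrics.
#' @param reference_timepoint_hr Timepoint at which yields are compared.
#' @return A tibble of class `tradeoff_table`, one row per founder number:
#'   `founder_number`, `mean_bust_hr`, `speed_rank`, `mean_yield`,
#'   `yield_rank`; attributes `speed_monotone` (speed rank monotone in
#'   founder number) and `tradeoff_flag` (yield means non-monotone in
#'   founder number).
#' @export
#' @examples
#' plates <- tibble::tibble(
#'   founder_number = rep(c(1, 3, 10, 50, 200), each = 2),
#'   bust_hr = rep(c(159, 137, 112, 79, 51), each = 2),
#'   timepoint_hr = 72,
#'   dauer_yield = rep(c(1540, 2837, 310, 232, 1050), each = 2),
#'   contaminated = FALSE)
#' tradeoff_table(summarize_assay(plates), 72)
tradeoff_table <- function(summary, reference_timepoint_hr = 72) {
  stopifnot(inherits(summary, "fitness_summary"),
            !is.null(summary$bust_hr), !is.null(summary$dauer_yield))
  bust <- dplyr::arrange(summary$bust_hr, .data$founder_number)
  ref <- reference_timepoint_hr
  yld <- summary$dauer_yield |>
    dplyr::filter(.data$timepoint_hr == ref) |>
    dplyr::arrange(.data$founder_number)
  if (nrow(bust) < 3 || nrow(yld) < 3) {
    stop("need both metrics summarized for at least three founder numbers",
         call. = FALSE)
  }
  out <- dplyr::inner_join(
    dplyr::select(bust, "founder_number", mean_bust_hr = "mean"),
    dplyr::select(yld, "founder_number", mean_yield = "mean"),
    by = "founder_number"
  ) |>
    dplyr::mutate(speed_rank = rank(.data$mean_bust_hr, ties.method = "min"),
                  yield_rank = rank(-.data$mean_yield, ties.method = "min")) |>
    dplyr::select("founder_number", "mean_bust_hr", "speed_rank",
                  "mean_yield", "yield_rank")
  mono <- function(v) all(diff(v) >= 0) || all(diff(v) <= 0)
  structure(out,
            speed_monotone = mono(out$speed_rank),
            tradeoff_flag = !mono(out$mean_yield),
            class = c("tradeoff_table", class(out)))
}

#' @rdname tradeoff_table
#' @param x A `tradeoff_table`.
#' @export
tradeoff_flag <- function(x) attr(x, "tradeoff_flag")
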