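#' Default parameters for the synthetic assay generator
#'
#' The generator emulates the plate-level structure of a colony fitness
#' assay: per-founder bust times, post-bust dauer yield time courses, dauer
#' lengths, and lawn quality control. Default anchors are the conditions of
#' the assay being emulated:
#'
#' * mean time to bust 159 hr for 1 founder and 51 hr for 200 founders, with
#'   the intermediate founder numbers interpolated log-linearly in founder
#'   number (only the ordering is load-bearing); SD 8 hr;
#' * mean dauer yield at 72 hr post bust of 1540, 2837, 310, 232 and 1050
#'   for 1, 3, 10, 50 and 200 founders, a coefficient of variation of 0.4
#'   (the assay's between-replicate spread is wide, e.g. roughly 1400--4400
#'   around a mean of 2837), and a shared time-course shape rising from
#'   48 hr to a peak at 144 hr and declining by 168 hr;
#' * lawn area 9.9 +/- 0.48 cm^2 and OD600 0.346 +/- 0.020 over 10 plates;
#' * dauer lengths around 520 um with a +60 um shift from 144 hr post bust
#'   (recovering dauers grow), 20 worms per timepoint.
#'
#' @param founder_numbers Founder numbers to generate.
#' @param bust_anchors_hr Mean bust times at the smallest and largest founder
#'   numbers; intermediates are log-linear in founder number.
#' @param bust_sd_hr Between-plate SD of bust time, hours.
#' @param yield_72_means Mean yields at the 72 hr reference timepoint, one
#'   per founder number.
#' @param yield_cv Coefficient of variation of plate-level yield.
#' @param timepoints_hr Post-bust sampling times, hours.
#' @param timecourse_scale Multiplier applied to the 72 hr mean at each
#'   timepoint (same order as `timepoints_hr`).
#' @param replicates Plates per founder number and timepoint.
#' @param volume_ml Suspension volume per plate (the assay protocol does not
#'   fix one; counts are per 1 ml aliquot of this volume).
#' @param lawn_n,lawn_area_mean,lawn_area_sd,lawn_od_mean,lawn_od_sd Lawn QC
#'   parameters.
#' @param length_timepoints_hr,length_baseline_um,length_sd_um,length_shift_um,length_shift_from_hr,length_n
#'   Dauer length parameters: worms per timepoint, baseline and SD, and the
#'   late shift applied from `length_shift_from_hr` on.
#' @return A list of class `assay_params`.
#' @export
#' @examples
#' p <- assay_params()
#' p$bust_mean_hr        # 159 ... 51
#' p$yield_mean["3", "144"] # peak of the 3-founder time course
assay_params <- function(founder_numbers = c(1, 3, 10, 50, 200),
                         bust_anchors_hr = c(159, 51),
                         bust_sd_hr = 8,
                         yield_72_means = c(1540, 2837, 310, 232, 1050),
                         yield_cv = 0.4,
                         timepoints_hr = c(48, 72, 96, 120, 144, 168),
                         timecourse_scale = c(0.5, 1, 1.5, 2.05, 2.5, 2.1),
                         replicates = 3,
                         volume_ml = 5,
                         lawn_n = 10, lawn_area_mean = 9.9, lawn_area_sd = 0.48,
                         lawn_od_mean = 0.346, lawn_od_sd = 0.020,
                         length_timepoints_hr = c(48, 96, 144, 168),
                         length_baseline_um = 520, length_sd_um = 25,
                         length_shift_um = 60, length_shift_from_hr = 144,
                         length_n = 20) {
  stopifnot(length(yield_72_means) == length(founder_numbers),
            length(timecourse_scale) == length(timepoints_hr),
            bust_sd_hr >= 0, yield_cv >= 0, replicates >= 1)
  lf <- log(founder_numbers)
  w <- (lf - min(lf)) / (max(lf) - min(lf))
  bust_mean <- bust_anchors_hr[1] + (bust_anchors_hr[2] - bust_anchors_hr[1]) * w
  names(bust_mean) <- founder_numbers
  yield_mean <- outer(yield_72_means, timecourse_scale)
  dimnames(yield_mean) <- list(founder_numbers, timepoints_hr)
  structure(
    list(founder_numbers = founder_numbers,
         bust_mean_hr = bust_mean, bust_sd_hr = bust_sd_hr,
         yield_mean = yield_mean, yield_cv = yield_cv,
         timepoints_hr = timepoints_hr,
         replicates = replicates, volume_ml = volume_ml,
         lawn_n = lawn_n, lawn_area_mean = lawn_area_mean,
         lawn_area_sd = lawn_area_sd, lawn_od_mean = lawn_od_mean,
         lawn_od_sd = lawn_od_sd,
         length_timepoints_hr = length_timepoints_hr,
         length_baseline_um = length_baseline_um,
         length_sd_um = length_sd_um, length_shift_um = length_shift_um,
         length_shift_from_hr = length_shift_from_hr, length_n = length_n),
    class = "assay_params"
  )
}

#' Generate a synthetic colony fitness assay dataset
#'
#' Draws plate-level records with the statistical structure of the assay.
#' Each plate is an independent colony followed to bust and destructively
#' sampled at one post-bust timepoint:
#'
#' * bust time ~ Normal(mean, SD), truncated at 0;
#' * plate yield ~ lognormal with the cell's mean and the common coefficient
#'   of variation (matching the wide, strictly positive between-replicate
#'   spread of the assay);
#' * the three 1 ml aliquot counts ~ Poisson(yield / volume);
#' * dauer lengths ~ Normal, with the late shift from
#'   `length_shift_from_hr`;
#' * lawn area and OD ~ Normal.
#'
#' With `bust_sd_hr = 0` and `yield_cv = 0` the generator is deterministic:
#' every draw equals its mean (aliquot counts are then the rounded
#' per-aliquot yield rather than Poisson draws).
#'
#' @param params An [assay_params()] object.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A list of class `assay_dataset` with tibbles `plates`
#'   (`founder_number`, `replicate_id`, `bust_hr`, `timepoint_hr`, `count1`,
#'   `count2`, `count3`, `volume_ml`, `contaminated`), `lawn_qc` (`plate_id`,
#'   `area_cm2`, `od600`) and `lengths` (`timepoint_hr`, `worm_id`,
#'   `length_um`).
#' @export
#' @examples
#' ds <- generate_assay(assay_params(), seed = 1)
#' dplyr::count(ds$plates, founder_number)
generate_assay <- function(params, seed) {
  stopifnot(inherits(params, "assay_params"), !missing(seed))
  withr::with_seed(as.integer(seed), {
    grid <- tidyr::expand_grid(
      founder_number = params$founder_numbers,
      timepoint_hr = params$timepoints_hr,
      rep = seq_len(params$replicates)
    )
    m_bust <- params$bust_mean_hr[as.character(grid$founder_number)]
    if (params$bust_sd_hr > 0) {
      bust <- pmax(0, stats::rnorm(nrow(grid), m_bust, params$bust_sd_hr))
    } else {
      bust <- m_bust
    }
    m_yield <- params$yield_mean[cbind(as.character(grid$founder_number),
                                       as.character(grid$timepoint_hr))]
    if (params$yield_cv > 0) {
      sdlog <- sqrt(log(1 + params$yield_cv^2))
      yield <- stats::rlnorm(nrow(grid), log(m_yield) - sdlog^2 / 2, sdlog)
      lam <- yield / params$volume_ml
      counts <- matrix(stats::rpois(3 * nrow(grid), rep(lam, each = 3)),
                       ncol = 3, byrow = TRUE)
    } else {
      counts <- matrix(round(m_yield / params$volume_ml),
                       nrow = nrow(grid), ncol = 3)
    }
    plates <- tibble::tibble(
      founder_number = grid$founder_number,
      replicate_id = sprintf("f%d_t%d_r%d", grid$founder_number,
                             grid$timepoint_hr, grid$rep),
      bust_hr = round(as.numeric(bust), 1),
      timepoint_hr = grid$timepoint_hr,
      count1 = counts[, 1], count2 = counts[, 2], count3 = counts[, 3],
      volume_ml = params$volume_ml,
      contaminated = FALSE
    )
    lawn <- tibble::tibble(
      plate_id = sprintf("lawn_%02d", seq_len(params$lawn_n)),
      area_cm2 = stats::rnorm(params$lawn_n, params$lawn_area_mean,
                              params$lawn_area_sd),
      od600 = stats::rnorm(params$lawn_n, params$lawn_od_mean,
                           params$lawn_od_sd)
    )
    lg <- tidyr::expand_grid(timepoint_hr = params$length_timepoints_hr,
                             worm = seq_len(params$length_n))
    mu <- params$length_baseline_um +
      ifelse(lg$timepoint_hr >= params$length_shift_from_hr,
             params$length_shift_um, 0)
    lengths <- tibble::tibble(
      timepoint_hr = lg$timepoint_hr,
      worm_id = sprintf("t%d_w%02d", lg$timepoint_hr, lg$worm),
      length_um = stats::rnorm(nrow(lg), mu, params$length_sd_um)
    )
    structure(list(plates = plates, lawn_qc = lawn, lengths = lengths),
              class = "assay_dataset")
  })
}

#' @export
print.assay_dataset <- function(x, ...) {
  cat("<assay_dataset> ", nrow(x$plates), " plates, ",
      nrow(x$lawn_qc), " lawn QC plates, ",
      nrow(x$lengths), " dauer lengths\n", sep = "")
  invisible(x)
}

#' Generate-analyze round trip
#'
#' Runs the full assay pipeline on a freshly generated synthetic dataset and
#' reports how well the generator's parameters are recovered: per-group
#' errors of bust and yield means, the recovered peak timepoint per founder
#' number, whether the recovered speed ordering matches the generator's, and
#' whether the speed-versus-yield trade-off is flagged.
#'
#' @param params An [assay_params()] object.
#' @param seed Integer seed passed to [generate_assay()].
#' @param reference_timepoint_hr Timepoint for the trade-off comparison.
#' @return A list of class `assay_round_trip`: tibbles `bust` and `yield`
#'   (truth, recovered mean, absolute and relative error), `peak_hr` per
#'   founder number, and flags `speed_order_recovered`, `tradeoff_flag`,
#'   `length_increase_flag`.
#' @export
#' @examples
#' rt <- assay_round_trip(assay_params(), seed = 1)
#' rt$peak_hr
#' rt$tradeoff_flag
assay_round_trip <- function(params, seed, reference_timepoint_hr = 72) {
  ds <- generate_assay(params, seed)
  plates <- scale_dauer_counts(drop_contaminated(ds$plates, quiet = TRUE))
  fs <- summarize_assay(plates)
  bust <- fs$bust_hr |>
    dplyr::mutate(truth = params$bust_mean_hr[as.character(.data$founder_number)],
                  abs_error = abs(.data$mean - .data$truth),
                  rel_error = .data$abs_error / .data$truth)
  truth_yield <- tidyr::expand_grid(founder_number = params$founder_numbers,
                                    timepoint_hr = params$timepoints_hr)
  truth_yield$truth <- as.numeric(params$yield_mean[cbind(
    as.character(truth_yield$founder_number),
    as.character(truth_yield$timepoint_hr))])
  yield <- dplyr::inner_join(fs$dauer_yield, truth_yield,
                             by = c("founder_number", "timepoint_hr")) |>
    dplyr::mutate(abs_error = abs(.data$mean - .data$truth),
                  rel_error = .data$abs_error / .data$truth)
  peaks <- purrr::map_dbl(params$founder_numbers, function(f) {
    peak_hr(yield_timecourse(plates, f))
  })
  names(peaks) <- params$founder_numbers
  speed_order <- fs$bust_hr$founder_number[order(fs$bust_hr$mean)]
  truth_order <- params$founder_numbers[order(params$bust_mean_hr)]
  tt <- tradeoff_table(fs, reference_timepoint_hr)
  rc <- recovery_check(ds$lengths)
  structure(
    list(bust = bust, yield = yield, peak_hr = peaks,
         speed_order_recovered = identical(as.numeric(speed_order),
                                           as.numeric(truth_order)),
         tradeoff = tt,
         tradeoff_flag = tradeoff_flag(tt),
         length_increase_flag = rc$increase_flag),
    class = "assay_round_trip"
  )
}

#' @export
print.assay_round_trip <- function(x, ...) {
  cat("<assay_round_trip>\n")
  cat("  speed ordering recovered:", x$speed_order_recovered, "\n")
  cat("  trade-off flag:", x$tradeoff_flag, "\n")
  cat("  peak (hr) by founder number:",
      paste(names(x$peak_hr), x$peak_hr, sep = "=", collapse = " "), "\n")
  cat("  max relative error of yield means:",
      format(max(x$yield$rel_error), digits = 3), "\n")
  invisible(x)
}
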