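#' Population structure at a given hour
#'
#' Aggregates a trajectory's age classes into stage-by-generation counts at
#' one hour and computes relative proportions. Worm proportions are
#' normalized over all non-egg worms; eggs are tallied but reported as a
#' separate category with `NA` proportion, since an egg is not yet a feeding,
#' stageable worm.
#'
#' @param traj A `colony_trajectory`.
#' @param hour Hour to summarize, between 0 and the horizon.
#' @return A tibble of class `structure_summary` with columns `stage`
#'   (factor in developmental order), `generation`, `count`, `proportion`,
#'   and the attribute `hour`.
#' @export
#' @examples
#' traj <- simulate_colony(10, colony_config(), horizon_hr = 50)
#' structure_at(traj, 0) # 100% L4, generation 1
structure_at <- function(traj, hour) {
  horizon <- dim(traj$states)[1] - 1L
  if (hour < 0 || hour > horizon) {
    stop("hour must be between 0 and ", horizon, call. = FALSE)
  }
  cfg <- traj$config
  stage <- factor(cfg$stage_of_class, levels = colony_stages())
  s <- traj$states[hour + 1L, , , drop = FALSE]
  g_max <- dim(traj$states)[2]
  out <- tidyr::expand_grid(stage = factor(colony_stages(),
                                           levels = colony_stages()),
                            generation = seq_len(g_max))
  counts <- sapply(seq_len(g_max), function(g) tapply(s[1, g, ], stage, sum))
  out$count <- as.numeric(counts[cbind(as.integer(out$stage), out$generation)])
  worms <- out$stage != "EGG"
  total <- sum(out$count[worms])
  out$proportion <- NA_real_
  if (total > 0) out$proportion[worms] <- out$count[worms] / total
  structure(out, hour = hour, class = c("structure_summary", class(out)))
}

#' Dominant generation among L1 larvae
#'
#' The generation contributing the most L1 larvae to a structure summary --
#' the model's answer to "which generation would dauers form from", since
#' dauers arise from the L1 pool. Ties break toward the lower generation
#' index.
#'
#' @param s A [structure_at()] summary.
#' @return The generation index (1 = founders, 2 = first filial, ...).
#' @export
dominant_l1_generation <- function(s) {
  l1 <- s[s$stage == "L1", ]
  if (sum(l1$count) <= 0) {
    stop("dominant L1 generation is undefined: no L1 larvae present",
         call. = FALSE)
  }
  l1$generation[which.max(l1$count)] # which.max takes the first (lowest) on ties
}

#' Pre-dauer pool: L1 plus L2 larvae
#'
#' The number of L1 and L2 larvae, summed over generations -- the stages
#' young enough to still enter the dauer pathway when the food runs out, and
#' hence the model's proxy for potential dauer yield.
#'
#' @param s A [structure_at()] summary.
#' @return Total L1 + L2 count.
#' @export
predauer_pool <- function(s) {
  sum(s$count[s$stage %in% c("L1", "L2")])
}

#' Share of food consumption that was futile
#'
#' Futile consumption is food eaten that cannot contribute to dauer yield.
#' This statistic -- an explicit operationalization of that verbal concept --
#' counts two components of the consumption ledger up to bust:
#' post-reproductive adults (adult age at or beyond the reproductive span)
#' over the whole pre-bust period, plus every stage other than L1 and L2
#' during the final pre-bust window, when worms beyond L2 can no longer
#' reach the dauer decision point before the food is gone. The two
#' components are disjoint by construction (post-reproductive adults in the
#' window are counted once).
#'
#' @param traj A `colony_trajectory`.
#' @param bust_hr Bust hour, e.g. from [detect_bust()].
#' @param window_hr Length of the final pre-bust window, in hours.
#' @return Fraction of cumulative pre-bust consumption that was futile,
#'   in `[0, 1]`.
#' @export
futile_consumption_share <- function(traj, bust_hr, window_hr = 10) {
  if (is.na(bust_hr)) stop("bust_hr must be set", call. = FALSE)
  if (bust_hr < 1) return(0)
  cfg <- traj$config
  rates <- cfg$consumption_units_per_hr[cfg$stage_of_class]
  span <- length(cfg$fecundity_eggs_per_hr)
  d <- sum(cfg$stage_durations_hr)
  post_repro <- seq_along(cfg$stage_of_class) > d + span
  non_pool <- !(cfg$stage_of_class %in% c("L1", "L2"))
  window_start <- max(1, bust_hr - window_hr + 1)
  total <- 0
  futile <- 0
  g_max <- dim(traj$states)[2]
  for (t in seq_len(bust_hr)) {
    # consumption during (t-1, t] is by the state at t-1 (array slice t)
    per_class <- colSums(matrix(traj$states[t, , ], nrow = g_max)) * rates
    total <- total + sum(per_class)
    sel <- if (t >= window_start) post_repro | non_pool else post_repro
    futile <- futile + sum(per_class[sel])
  }
  if (total <= 0) return(0)
  futile / total
}
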