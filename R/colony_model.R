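#' Build the hourly aging transition matrix
#'
#' One generation of the colony is a vector of hourly age classes: one class
#' per hour of each pre-adult stage, followed by `adult_tracking_hr` adult
#' age classes. The transition matrix advances every class by one hour; the
#' terminal adult class is absorbing. There is no mortality, so every column
#' sums to one.
#'
#' @param cfg A [colony_config()] object.
#' @return A square numeric matrix of dimension
#'   `sum(stage_durations_hr) + adult_tracking_hr`.
#' @export
#' @examples
#' cfg <- colony_config(stage_durations_hr = c(EGG = 2L, L1 = 1L, L2 = 1L,
#'                                             L3 = 1L, L4 = 1L),
#'                      fecundity_eggs_per_hr = c(0, 0, 0),
#'                      adult_tracking_hr = 3L, horizon_hr = 20L)
#' m <- build_transition_matrix(cfg)
#' dim(m)           # 9 x 9
#' all(colSums(m) == 1)
build_transition_matrix <- function(cfg) {
  stop_if_invalid(cfg)
  k <- sum(cfg$stage_durations_hr) + cfg$adult_tracking_hr
  m <- matrix(0, k, k)
  m[cbind(2:k, 1:(k - 1))] <- 1 # age one hour
  m[k, k] <- 1                  # terminal adult class is absorbing
  m
}

#' Create a population state
#'
#' A population state holds expected worm counts per tracked generation and
#' hourly age class. Counts are real-valued expectations: the projection is
#' deterministic.
#'
#' @param cfg A [colony_config()] object.
#' @param founder_number Number of generation-1 founders placed in the final
#'   hourly class of the L4 stage (they molt to adult after one step).
#' @return A numeric matrix with `max_generations` rows (generations) and one
#'   column per age class, with the class attribute `population_state`.
#' @export
population_state <- function(cfg, founder_number = 0) {
  k <- length(cfg$stage_of_class)
  s <- matrix(0, cfg$max_generations, k,
              dimnames = list(generation = NULL, class = NULL))
  if (founder_number > 0) {
    s[1, sum(cfg$stage_durations_hr)] <- founder_number
  }
  structure(s, class = c("population_state", "matrix", "array"))
}

# column indices of the adult classes
adult_classes <- function(cfg) {
  d <- sum(cfg$stage_durations_hr)
  (d + 1):(d + cfg$adult_tracking_hr)
}

#' Advance a population state by one hour
#'
#' Each generation's age-class vector is advanced by the transition matrix,
#' and the eggs laid during the hour -- fecundity at each adult age times the
#' number of adults of that age, summed per generation -- are credited to the
#' next generation's first egg class. Eggs laid by the last tracked
#' generation are credited back to it, with a warning.
#'
#' @param state A `population_state` matrix.
#' @param tm Transition matrix from [build_transition_matrix()].
#' @param cfg The [colony_config()] the state was built from.
#' @param warn_overflow Warn when overflow eggs are credited back to the last
#'   tracked generation ([simulate_colony()] turns this off and warns once
#'   per run instead).
#' @return A list with `state`, the advanced `population_state`, and
#'   `eggs_laid`, the eggs laid during the hour by each generation.
#' @export
step_population <- function(state, tm, cfg, warn_overflow = TRUE) {
  fec <- rep(0, cfg$adult_tracking_hr)
  fec[seq_along(cfg$fecundity_eggs_per_hr)] <- cfg$fecundity_eggs_per_hr
  eggs <- as.numeric(state[, adult_classes(cfg), drop = FALSE] %*% fec)
  new_state <- state %*% t(tm)
  g_max <- nrow(state)
  for (g in seq_len(g_max)) {
    if (eggs[g] > 0) {
      target <- min(g + 1L, g_max)
      if (target == g && warn_overflow) {
        warning("eggs laid by the last tracked generation (", g,
                ") credited back to it; increase max_generations to resolve them",
                call. = FALSE)
      }
      new_state[target, 1] <- new_state[target, 1] + eggs[g]
    }
  }
  list(state = structure(new_state, class = class(state)), eggs_laid = eggs)
}

#' Hourly food consumption of a population state
#'
#' Sums, over generations and age classes, worm counts times the
#' stage-specific consumption rate.
#'
#' @inheritParams step_population
#' @return Food units consumed per hour, a single number.
#' @export
#' @examples
#' cfg <- colony_config()
#' s <- population_state(cfg, founder_number = 2) # two L4 worms
#' hourly_consumption(s, cfg)                     # 2 x 8 = 16 units
hourly_consumption <- function(state, cfg) {
  rates <- cfg$consumption_units_per_hr[cfg$stage_of_class]
  as.numeric(sum(state %*% rates))
}

#' Simulate a colony on a finite food patch
#'
#' Projects a colony founded by `founder_number` L4 hermaphrodites hour by
#' hour over the configured horizon, recording the full generation-by-age
#' structure and the food ledger. Worms present at the start of each hour eat
#' during it, so the consumption recorded at hour `t` is that of the state at
#' hour `t - 1`; nothing is eaten at hour 0. Dynamics are not truncated when
#' the patch runs out -- bust is detected post hoc with [detect_bust()] --
#' and development is food-independent throughout.
#'
#' @param founder_number Number of founders (>= 0).
#' @param cfg A [colony_config()] object.
#' @param horizon_hr Hours to simulate; defaults to `cfg$horizon_hr`.
#' @return An object of class `colony_trajectory`: a list with
#'   \describe{
#'     \item{states}{numeric array `[hour + 1, generation, age class]` of
#'       expected counts, hours 0..horizon;}
#'     \item{food}{tibble with `time_hr`, `hourly_consumption`,
#'       `cumulative_consumption`;}
#'     \item{eggs_laid}{matrix `[hour, generation]`: eggs laid during each
#'       hour by each source generation (credited to the next);}
#'     \item{founder_number}{the founder number;}
#'     \item{config}{the configuration used.}
#'   }
#' @seealso [detect_bust()], [structure_at()], [tidy.colony_trajectory()]
#' @export
#' @examples
#' traj <- simulate_colony(3, colony_config(), horizon_hr = 60)
#' glance(traj)
simulate_colony <- function(founder_number, cfg = colony_config(),
                            horizon_hr = cfg$horizon_hr) {
  stop_if_invalid(cfg)
  stopifnot(founder_number >= 0)
  horizon_hr <- as.integer(horizon_hr)
  tm <- build_transition_matrix(cfg)
  k <- length(cfg$stage_of_class)
  g_max <- cfg$max_generations
  rates <- cfg$consumption_units_per_hr[cfg$stage_of_class]

  states <- array(0, dim = c(horizon_hr + 1L, g_max, k),
                  dimnames = list(time_hr = 0:horizon_hr, generation = 1:g_max,
                                  class = NULL))
  eggs_laid <- matrix(0, horizon_hr, g_max)
  hourly <- numeric(horizon_hr + 1L)
  s <- population_state(cfg, founder_number)
  states[1, , ] <- s
  for (t in seq_len(horizon_hr)) {
    hourly[t + 1L] <- as.numeric(sum(s %*% rates)) # eaten during (t-1, t]
    stepped <- step_population(s, tm, cfg, warn_overflow = FALSE)
    s <- stepped$state
    eggs_laid[t, ] <- stepped$eggs_laid
    states[t + 1L, , ] <- s
  }
  if (any(eggs_laid[, g_max] > 0)) {
    warning("generation-", g_max + 1L, " eggs were credited to the last ",
            "tracked generation (", g_max, ") from hour ",
            min(which(eggs_laid[, g_max] > 0)),
            "; increase max_generations to resolve them", call. = FALSE)
  }
  structure(
    list(
      states = states,
      food = tibble::tibble(time_hr = 0:horizon_hr,
                            hourly_consumption = hourly,
                            cumulative_consumption = cumsum(hourly)),
      eggs_laid = eggs_laid,
      founder_number = founder_number,
      config = cfg
    ),
    class = "colony_trajectory"
  )
}

#' @export
print.colony_trajectory <- function(x, ...) {
  cat("<colony_trajectory> ", x$founder_number, " founder(s), ",
      nrow(x$food) - 1L, " hr\n", sep = "")
  b <- detect_bust(x)
  if (is.na(b$bust_hr)) {
    cat("  patch not exhausted within the horizon\n")
  } else {
    cat("  bust at hour ", b$bust_hr, " (patch ",
        format(x$config$patch_units, big.mark = ","), " units)\n", sep = "")
  }
  invisible(x)
}

#' Tidy a colony trajectory into a long tibble
#'
#' @param x A `colony_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time_hr`, `generation`, `stage`, `count`,
#'   aggregated over age classes within stage, plus the food ledger columns
#'   repeated per row.
#' @export
tidy.colony_trajectory <- function(x, ...) {
  cfg <- x$config
  stage <- factor(cfg$stage_of_class, levels = colony_stages())
  agg <- apply(x$states, c(1, 2), function(v) tapply(v, stage, sum))
  # agg: [stage, hour, generation]
  out <- tidyr::expand_grid(
    time_hr = 0:(dim(x$states)[1] - 1L),
    generation = seq_len(dim(x$states)[2]),
    stage = colony_stages()
  )
  out$count <- as.numeric(aperm(agg, c(3, 1, 2))[cbind(
    out$generation, match(out$stage, colony_stages()), out$time_hr + 1L)])
  dplyr::left_join(out, x$food, by = "time_hr")
}

#' One-line summary of a colony trajectory
#'
#' @param x A `colony_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble: founder number, horizon, bust hour, cumulative
#'   consumption at bust, total population and total eggs laid.
#' @export
glance.colony_trajectory <- function(x, ...) {
  b <- detect_bust(x)
  tibble::tibble(
    founder_number = x$founder_number,
    horizon_hr = nrow(x$food) - 1L,
    bust_hr = b$bust_hr,
    cumulative_at_bust = if (is.na(b$bust_hr)) NA_real_ else
      x$food$cumulative_consumption[b$bust_hr + 1L],
    final_population = sum(x$states[dim(x$states)[1], , ]),
    total_eggs_laid = sum(x$eggs_laid)
  )
}

#' Detect the bust hour of a trajectory
#'
#' Bust is the first hour at which cumulative food consumption reaches the
#' patch size. The trajectory itself is unaffected: the model runs the full
#' horizon and bust is read off afterwards.
#'
#' @param traj A `colony_trajectory`.
#' @param patch_units Patch size in food units; defaults to the trajectory's
#'   configuration.
#' @return A list of class `bust_summary`: `bust_hr` (integer, `NA` if the
#'   patch is never exhausted within the horizon), `founder_number`, and
#'   `state_at_bust` (the `population_state` at the bust hour, `NULL` if no
#'   bust).
#' @export
#' @examples
#' traj <- simulate_colony(200, colony_config())
#' detect_bust(traj)$bust_hr
detect_bust <- function(traj, patch_units = traj$config$patch_units) {
  hit <- which(traj$food$cumulative_consumption >= patch_units)
  bust_hr <- if (length(hit) == 0) NA_integer_ else traj$food$time_hr[hit[1]]
  state <- NULL
  if (!is.na(bust_hr)) {
    state <- structure(traj$states[bust_hr + 1L, , , drop = TRUE],
                       class = c("population_state", "matrix", "array"))
    if (is.null(dim(state))) { # single tracked generation
      state <- structure(matrix(state, nrow = 1),
                         class = c("population_state", "matrix", "array"))
    }
  }
  structure(list(bust_hr = bust_hr, state_at_bust = state,
                 founder_number = traj$founder_number),
            class = "bust_summary")
}

#' @export
print.bust_summary <- function(x, ...) {
  cat("<bust_summary> ", x$founder_number, " founder(s): ",
      if (is.na(x$bust_hr)) "no bust within horizon" else
        paste0("bust at hour ", x$bust_hr), "\n", sep = "")
  invisible(x)
}

#' Sweep colony simulations across founder numbers
#'
#' Runs [simulate_colony()] and [detect_bust()] for each founder number and
#' summarizes structure at bust. The projection is linear in the founder
#' number, so the sweep is deterministic.
#'
#' @param founder_numbers Integer vector; defaults to the configuration's.
#' @param cfg A [colony_config()] object.
#' @return A tibble with one row per founder number: `founder_number`,
#'   `bust_hr`, `cumulative_at_bust`, `dominant_l1_generation`,
#'   `predauer_pool` (L1 + L2 count at bust), and `trajectory`/`bust`
#'   list-columns holding the full objects.
#' @export
#' @examples
#' founder_sweep(c(1, 200), colony_config())[, 1:5]
founder_sweep <- function(founder_numbers = cfg$founder_numbers,
                          cfg = colony_config()) {
  stopifnot(length(founder_numbers) >= 1)
  rows <- purrr::map(founder_numbers, function(n) {
    traj <- simulate_colony(n, cfg)
    b <- detect_bust(traj)
    if (is.na(b$bust_hr)) {
      return(tibble::tibble(founder_number = n, bust_hr = NA_integer_,
                            cumulative_at_bust = NA_real_,
                            dominant_l1_generation = NA_integer_,
                            predauer_pool = NA_real_,
                            trajectory = list(traj), bust = list(b)))
    }
    s <- structure_at(traj, b$bust_hr)
    tibble::tibble(
      founder_number = n,
      bust_hr = b$bust_hr,
      cumulative_at_bust = traj$food$cumulative_consumption[b$bust_hr + 1L],
      dominant_l1_generation = dominant_l1_generation(s),
      predauer_pool = predauer_pool(s),
      trajectory = list(traj),
      bust = list(b)
    )
  })
  dplyr::bind_rows(rows)
}

#' Export a trajectory as long-format TSV
#'
#' @param traj A `colony_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  readr::write_tsv(tidy(traj), path)
  invisible(path)
}
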