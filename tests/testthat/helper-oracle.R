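# Individual-based enumeration oracle for the colony projection.
#
# Worms are tracked as cohorts (generation, hour of entering the egg stage,
# count); each hour every cohort ages by one and adult cohorts lay
# fecundity(adult age) eggs per worm, spawning a next-generation cohort.
# No matrices are involved, so this is an independent route to the same
# expected counts. With integer fecundities and counts everything is exact.

oracle_stage <- function(age, durations) {
  # age is 0-based hours since entering EGG; adult from sum(durations) on
  bounds <- cumsum(durations)
  stages <- c("EGG", "L1", "L2", "L3", "L4")
  for (i in seq_along(bounds)) {
    if (age < bounds[i]) return(stages[i])
  }
  "ADULT"
}

# returns list(counts = array [hour+1, gen, stage], cumulative = numeric)
oracle_simulate <- function(founders, durations, fecundity, rates,
                            horizon, max_gen = 4L) {
  d_total <- sum(durations)
  stages <- c("EGG", "L1", "L2", "L3", "L4", "ADULT")
  # founders enter at the final L4 hour: age d_total - 1 at hour 0
  cohorts <- data.frame(gen = 1, birth = -(d_total - 1), count = founders)
  cohorts <- cohorts[cohorts$count > 0, , drop = FALSE]
  counts <- array(0, dim = c(horizon + 1, max_gen, 6),
                  dimnames = list(NULL, NULL, stages))
  hourly <- numeric(horizon + 1)
  tally <- function(t) {
    for (i in seq_len(nrow(cohorts))) {
      st <- oracle_stage(t - cohorts$birth[i], durations)
      counts[t + 1, cohorts$gen[i], st] <<-
        counts[t + 1, cohorts$gen[i], st] + cohorts$count[i]
    }
  }
  tally(0)
  for (t in seq_len(horizon)) {
    # food eaten during (t-1, t] by worms present at t-1
    eaten <- 0
    for (i in seq_len(nrow(cohorts))) {
      st <- oracle_stage(t - 1 - cohorts$birth[i], durations)
      eaten <- eaten + cohorts$count[i] * rates[[st]]
    }
    hourly[t + 1] <- eaten
    # egg laying during the hour, based on the state at t-1
    spawned <- list()
    for (i in seq_len(nrow(cohorts))) {
      adult_age <- (t - 1 - cohorts$birth[i]) - d_total
      if (adult_age >= 0 && adult_age < length(fecundity) &&
          fecundity[adult_age + 1] > 0) {
        spawned[[length(spawned) + 1]] <- data.frame(
          gen = min(cohorts$gen[i] + 1, max_gen), birth = t,
          count = cohorts$count[i] * fecundity[adult_age + 1])
      }
    }
    if (length(spawned) > 0) {
      cohorts <- rbind(cohorts, do.call(rbind, spawned))
      # merge duplicate (gen, birth) keys to keep the frame small
      cohorts <- stats::aggregate(count ~ gen + birth, cohorts, sum)
    }
    tally(t)
  }
  list(counts = counts, cumulative = cumsum(hourly))
}

# a small random life-history configuration with integer fecundity,
# comparable exactly against the oracle
random_toy_config <- function() {
  durations <- c(EGG = sample(1:3, 1), L1 = sample(1:4, 1), L2 = sample(1:3, 1),
                 L3 = sample(1:3, 1), L4 = sample(1:3, 1))
  fec <- sample(0:3, sample(3:8, 1), replace = TRUE)
  if (all(fec == 0)) fec[1] <- 1
  colony_config(
    stage_durations_hr = durations,
    fecundity_eggs_per_hr = fec,
    patch_units = sample(50:500, 1),
    horizon_hr = sample(20:50, 1),
    founder_numbers = 1:5,
    adult_tracking_hr = length(fec) + sample(2:10, 1),
    max_generations = 3L
  )
}

# stage-by-generation counts of a trajectory at every hour, as an array
trajectory_stage_counts <- function(traj) {
  cfg <- traj$config
  stages <- c("EGG", "L1", "L2", "L3", "L4", "ADULT")
  stage <- factor(cfg$stage_of_class, levels = stages)
  hours <- dim(traj$states)[1]
  g_max <- dim(traj$states)[2]
  out <- array(0, dim = c(hours, g_max, 6), dimnames = list(NULL, NULL, stages))
  for (t in seq_len(hours)) {
    for (g in seq_len(g_max)) {
      out[t, g, ] <- tapply(traj$states[t, g, ], stage, sum)
    }
  }
  out
}
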