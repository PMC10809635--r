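toy_cfg <- function(...) {
  defaults <- list(
    stage_durations_hr = c(EGG = 2L, L1 = 1L, L2 = 1L, L3 = 1L, L4 = 1L),
    fecundity_eggs_per_hr = c(0, 0, 0),
    adult_tracking_hr = 3L, horizon_hr = 20L, patch_units = 100,
    max_generations = 3L
  )
  do.call(colony_config, utils::modifyList(defaults, list(...)))
}

test_that("transition matrix is a pure aging chain with absorbing adults", {
  cfg <- toy_cfg()
  m <- build_transition_matrix(cfg)
  expect_equal(dim(m), c(9, 9))
  expect_equal(sum(m[cbind(2:9, 1:8)]), 8)  # unit sub-diagonal
  expect_equal(m[9, 9], 1)                  # absorbing terminal class
  expect_equal(sum(m), 9)                   # and nothing else
  expect_true(all(colSums(m) == 1))         # no mortality

  # a worm placed as a fresh egg reaches L1 age 0 after two hours
  v <- rep(0, 9); v[1] <- 1
  expect_equal(as.numeric(m %*% (m %*% v)), c(0, 0, 1, rep(0, 6)))
})

test_that("stepping advances ages and credits eggs to the next generation", {
  cfg <- toy_cfg()
  tm <- build_transition_matrix(cfg)

  empty <- population_state(cfg)
  expect_equal(sum(step_population(empty, tm, cfg)$state), 0)

  # one adult of age 0 with zero fecundity just ages
  s <- population_state(cfg)
  s[1, 7] <- 1 # adult age 0 (6 pre-adult classes)
  out <- step_population(s, tm, cfg)
  expect_equal(sum(out$state), 1)
  expect_equal(out$state[1, 8], 1)
  expect_equal(out$eggs_laid, c(0, 0, 0))

  # two generation-1 adults at an age with fecundity 3 lay 6 gen-2 eggs
  cfg3 <- toy_cfg(fecundity_eggs_per_hr = c(0, 3, 0))
  s2 <- population_state(cfg3)
  s2[1, 8] <- 2 # adult age 1, fecundity 3
  out2 <- step_population(s2, build_transition_matrix(cfg3), cfg3)
  expect_equal(out2$eggs_laid[1], 6)
  expect_equal(out2$state[2, 1], 6) # gen-2 eggs at EGG age 0
  expect_equal(sum(out2$state), 8)
})

test_that("hourly consumption sums stage counts times stage rates", {
  cfg <- colony_config()
  s <- population_state(cfg)
  d <- cumsum(cfg$stage_durations_hr) # EGG 9 L1 21 L2 28 L3 35 L4 44
  s[1, 10] <- 1  # an L1
  s[1, 22] <- 1  # an L2
  s[1, 29] <- 1  # an L3
  s[1, 36] <- 1  # an L4
  s[1, 45] <- 1  # an adult
  expect_equal(hourly_consumption(s, cfg), 31)

  eggs <- population_state(cfg); eggs[1, 3] <- 10
  expect_equal(hourly_consumption(eggs, cfg), 0)

  mix <- population_state(cfg)
  mix[1, 12] <- 10  # ten L1
  mix[2, 50] <- 2   # two adults
  expect_equal(hourly_consumption(mix, cfg), 42)
})

test_that("zero founders give an all-zero trajectory", {
  traj <- simulate_colony(0, toy_cfg())
  expect_equal(sum(traj$states), 0)
  expect_equal(max(traj$food$cumulative_consumption), 0)
  expect_true(is.na(detect_bust(traj)$bust_hr))
})

test_that("projection matches the individual-based oracle exactly", {
  cfg <- colony_config(
    stage_durations_hr = c(EGG = 2L, L1 = 2L, L2 = 1L, L3 = 1L, L4 = 1L),
    fecundity_eggs_per_hr = c(1, 2, 0, 1),
    adult_tracking_hr = 8L, horizon_hr = 30L, patch_units = 1000,
    max_generations = 3L
  )
  traj <- suppressWarnings(simulate_colony(2, cfg))
  orc <- oracle_simulate(2, cfg$stage_durations_hr, cfg$fecundity_eggs_per_hr,
                         as.list(cfg$consumption_units_per_hr),
                         horizon = 30, max_gen = 3L)
  expect_equal(trajectory_stage_counts(traj), orc$counts)
  expect_equal(traj$food$cumulative_consumption, orc$cumulative)
})

test_that("population change per hour equals eggs laid (no deaths)", {
  cfg <- colony_config(horizon_hr = 120L)
  traj <- simulate_colony(10, cfg, horizon_hr = 120)
  totals <- apply(traj$states, 1, sum)
  expect_equal(unname(diff(totals)), rowSums(traj$eggs_laid), tolerance = 1e-9)
})

test_that("the projection is linear in founder number", {
  cfg <- colony_config(horizon_hr = 150L)
  t1 <- suppressWarnings(simulate_colony(3, cfg, horizon_hr = 150))
  t2 <- suppressWarnings(simulate_colony(6, cfg, horizon_hr = 150))
  expect_equal(t2$states, 2 * t1$states, tolerance = 1e-12)
  expect_equal(t2$food$cumulative_consumption,
               2 * t1$food$cumulative_consumption, tolerance = 1e-12)
})

test_that("bust detection finds the first crossing of the patch size", {
  cfg <- toy_cfg()
  traj <- simulate_colony(1, cfg)
  expect_equal(detect_bust(traj, patch_units = 0)$bust_hr, 0L)

  # a lone adult eats 16/hr: patch of 100 is gone during hour 7
  cfg_a <- toy_cfg(fecundity_eggs_per_hr = c(0, 0, 0))
  adult_traj <- simulate_colony(1, cfg_a) # founder is adult from hour 1
  # founder is L4 (8 units) in hour 1, adult (16) afterwards
  expect_equal(adult_traj$food$cumulative_consumption[1:4], c(0, 8, 24, 40))

  # constant consumption 31/hr crosses a patch of 100 at hour 4
  cfg31 <- colony_config()
  s31 <- population_state(cfg31)
  for (cls in c(10, 22, 29, 36, 45)) s31[1, cls] <- 1
  # synthetic steady ledger: 31, 62, 93, 124 ...
  fake <- list(food = tibble::tibble(
    time_hr = 0:10,
    hourly_consumption = c(0, rep(31, 10)),
    cumulative_consumption = cumsum(c(0, rep(31, 10)))),
    states = array(0, c(11, 1, length(cfg31$stage_of_class))),
    config = cfg31, founder_number = 1)
  class(fake) <- "colony_trajectory"
  b <- detect_bust(fake, patch_units = 100)
  expect_equal(b$bust_hr, 4L)
  expect_gte(fake$food$cumulative_consumption[5], 100)
  expect_lt(fake$food$cumulative_consumption[4], 100)
})

test_that("bust hour is monotone in founder number and patch size", {
  cfg <- toy_cfg(fecundity_eggs_per_hr = c(2, 2, 2), patch_units = 400,
                 horizon_hr = 40L)
  busts <- sapply(c(1, 2, 4, 8), function(n) {
    detect_bust(suppressWarnings(simulate_colony(n, cfg)))$bust_hr
  })
  expect_true(all(diff(busts) <= 0))

  traj <- suppressWarnings(simulate_colony(4, cfg))
  by_patch <- sapply(c(50, 200, 800), function(p) {
    detect_bust(traj, patch_units = p)$bust_hr
  })
  expect_true(all(diff(by_patch) >= 0))
})

test_that("founder sweep reproduces per-run simulations deterministically", {
  cfg <- toy_cfg(fecundity_eggs_per_hr = c(2, 2, 2), patch_units = 400,
                 horizon_hr = 40L)
  sw <- suppressWarnings(founder_sweep(c(2, 5), cfg))
  expect_equal(nrow(sw), 2)
  single <- suppressWarnings(simulate_colony(5, cfg))
  expect_equal(sw$bust_hr[2], detect_bust(single)$bust_hr)
  expect_equal(sw$trajectory[[2]]$states, single$states)

  one <- suppressWarnings(founder_sweep(7, cfg))
  expect_equal(nrow(one), 1)
})

test_that("trajectory tidiers and TSV export agree with the state array", {
  cfg <- toy_cfg(fecundity_eggs_per_hr = c(1, 1, 0))
  traj <- suppressWarnings(simulate_colony(2, cfg))
  td <- tidy(traj)
  expect_setequal(names(td), c("time_hr", "generation", "stage", "count",
                               "hourly_consumption", "cumulative_consumption"))
  # totals per hour agree with the raw array
  by_hour <- tapply(td$count, td$time_hr, sum)
  expect_equal(as.numeric(by_hour), as.numeric(apply(traj$states, 1, sum)))

  gl <- glance(traj)
  expect_equal(gl$founder_number, 2)
  expect_equal(gl$total_eggs_laid, sum(traj$eggs_laid))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory_tsv(traj, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(td))
  expect_equal(sum(back$count), sum(td$count))
})
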