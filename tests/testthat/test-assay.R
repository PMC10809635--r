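plate_row <- function(founder, bust, yield, timepoint = 72, volume = 5,
                      contaminated = FALSE) {
  tibble::tibble(founder_number = founder, replicate_id = NA_character_,
                 bust_hr = bust, timepoint_hr = timepoint,
                 count1 = yield / volume, count2 = yield / volume,
                 count3 = yield / volume, volume_ml = volume,
                 contaminated = contaminated)
}

test_that("aliquot counts scale to plate yields by mean times volume", {
  p <- tibble::tibble(count1 = c(10, 0, 7), count2 = c(12, 0, 7),
                      count3 = c(14, 0, 7), volume_ml = c(5, 5, 2),
                      contaminated = FALSE)
  expect_equal(scale_dauer_counts(p)$dauer_yield, c(60, 0, 14))

  p$contaminated[2] <- TRUE
  expect_error(scale_dauer_counts(p), "drop_contaminated")

  bad <- tibble::tibble(count1 = -1, count2 = 0, count3 = 0, volume_ml = 5,
                        contaminated = FALSE)
  expect_error(scale_dauer_counts(bad), "non-negative")
})

test_that("contaminated plates are dropped with a message", {
  p <- plate_row(c(1, 1, 3), c(150, 160, 140), c(100, 200, 300))
  p$contaminated[2] <- TRUE
  expect_message(out <- drop_contaminated(p), "1 contaminated")
  expect_equal(nrow(out), 2)
  expect_silent(drop_contaminated(p, quiet = TRUE))
  clean <- drop_contaminated(p, quiet = TRUE)
  expect_message(drop_contaminated(clean), NA)
})

test_that("assay summaries compute mean, sd, n per group", {
  p <- plate_row(rep(c(1, 200), each = 3),
                 bust = c(2, 4, 6, 10, 10, 10),
                 yield = c(100, 200, 300, 50, 50, 50))
  s <- summarize_assay(p)
  expect_equal(s$bust_hr$mean, c(4, 10))
  expect_equal(s$bust_hr$sd, c(2, 0))
  expect_equal(s$bust_hr$n, c(3L, 3L))
  expect_equal(s$dauer_yield$mean, c(200, 50))

  # missing bust drops from the bust summary only
  p$bust_hr[1] <- NA
  s2 <- summarize_assay(p)
  expect_equal(s2$bust_hr$n[1], 2L)
  expect_equal(s2$dauer_yield$n, c(3L, 3L))

  # contaminated plates are excluded from both metrics
  p$contaminated[4] <- TRUE
  s3 <- summarize_assay(p)
  expect_equal(s3$bust_hr$n, c(2L, 2L))

  only_bust <- summarize_assay(p, metric = "bust_hr")
  expect_null(only_bust$dauer_yield)
})

test_that("one-way ANOVA and Tukey agree with the brute-force oracle", {
  withr::with_seed(42, {
    # unbalanced on purpose: Tukey-Kramer territory
    g <- rep(c(1, 10, 50, 200), times = c(4, 7, 5, 9))
    x <- round(rnorm(length(g), mean = 100 + 10 * log(g), sd = 12), 2)
  })
  p <- plate_row(g, bust = x, yield = 1)
  cmp <- compare_groups(p, metric = "bust_hr", design = "one_way")
  orc <- oracle_oneway(x, g)

  gl <- glance(cmp)
  expect_equal(gl$statistic[1], orc$f, tolerance = 1e-8)
  expect_equal(gl$p.value[1], orc$p, tolerance = 1e-8)
  expect_equal(gl$sumsq, c(orc$ssb, orc$ssw), tolerance = 1e-8)
  expect_equal(gl$df, c(orc$df1, orc$df2))

  td <- dplyr::arrange(tidy(cmp), contrast)
  ot <- dplyr::arrange(orc$tukey, contrast)
  expect_equal(td$contrast, ot$contrast)
  expect_equal(td$estimate, ot$estimate, tolerance = 1e-8)
  expect_equal(td$conf.low, ot$conf.low, tolerance = 1e-8)
  expect_equal(td$conf.high, ot$conf.high, tolerance = 1e-8)
  expect_equal(td$adj.p.value, ot$adj.p.value, tolerance = 1e-8)
})

test_that("identical groups give p-values near one", {
  p <- plate_row(rep(c(1, 3, 10), each = 4),
                 bust = rep(c(5, 6, 7, 8), times = 3), yield = 1)
  cmp <- compare_groups(p, metric = "bust_hr")
  expect_gt(glance(cmp)$p.value[1], 0.999)
  expect_true(all(tidy(cmp)$adj.p.value > 0.999))
  expect_true(all(abs(tidy(cmp)$estimate) < 1e-12))
})

test_that("comparisons are invariant under row permutation", {
  ds <- generate_assay(assay_params(), seed = 7)
  p <- ds$plates
  shuffled <- p[withr::with_seed(1, sample(nrow(p))), ]
  c1 <- compare_groups(p, "dauer_yield", timepoint_hr = 72)
  c2 <- compare_groups(shuffled, "dauer_yield", timepoint_hr = 72)
  expect_equal(glance(c1), glance(c2))
  expect_equal(dplyr::arrange(tidy(c1), contrast),
               dplyr::arrange(tidy(c2), contrast))
})

test_that("marking plates contaminated equals removing them by hand", {
  ds <- generate_assay(assay_params(), seed = 11)
  p <- ds$plates
  bad <- withr::with_seed(2, sample(nrow(p), 10))
  marked <- p; marked$contaminated[bad] <- TRUE
  removed <- p[-bad, ]
  s_marked <- summarize_assay(marked)
  s_removed <- summarize_assay(removed)
  expect_equal(s_marked$bust_hr, s_removed$bust_hr)
  expect_equal(s_marked$dauer_yield, s_removed$dauer_yield)
  expect_equal(glance(compare_groups(marked, "bust_hr")),
               glance(compare_groups(removed, "bust_hr")))
})

test_that("degenerate designs are refused with the offending group named", {
  p <- plate_row(c(1, 1, 3), c(150, 160, 140), c(1, 1, 1))
  expect_error(compare_groups(p, "bust_hr"), "founder 3")
  one_group <- plate_row(c(1, 1, 1), c(150, 160, 140), c(1, 1, 1))
  expect_error(compare_groups(one_group, "bust_hr"), "two groups")

  # two-way: a founder x timepoint cell with a single plate
  two <- dplyr::bind_rows(
    plate_row(rep(c(1, 3), each = 4), bust = 1:8, yield = 1:8 * 10,
              timepoint = rep(c(48, 48, 72, 72), 2)),
    plate_row(1, 5, 10, timepoint = 96)
  )
  expect_error(compare_groups(two, "dauer_yield", design = "two_way"),
               "degenerate")
})

test_that("two-way cell-mean comparisons match hand-computed differences", {
  p <- plate_row(rep(c(1, 3), each = 4),
                 bust = 1, yield = c(10, 20, 30, 50, 5, 15, 100, 140),
                 timepoint = rep(c(48, 48, 72, 72), 2))
  cmp <- compare_groups(p, "dauer_yield", design = "two_way")
  td <- tidy(cmp)
  # cell means: 1x48 = 15, 1x72 = 40, 3x48 = 10, 3x72 = 120
  row <- td[td$contrast == "3:72-1:48", ]
  expect_equal(row$estimate, 120 - 15)
  expect_equal(nrow(td[td$term == "founder:timepoint", ]), choose(4, 2))
  gl <- glance(cmp)
  expect_setequal(gl$term[1:3], c("founder", "timepoint", "founder:timepoint"))
})

test_that("yield time course finds the peak, ties to the earlier timepoint", {
  p <- plate_row(rep(3, 6), bust = 100,
                 yield = c(10, 50, 30, 20, 50, 40),
                 timepoint = c(48, 72, 96, 120, 144, 168))
  tc <- yield_timecourse(scale_dauer_counts(p), 3)
  expect_equal(peak_hr(tc), 72) # ties with 144 hr break earlier
  expect_equal(tc$timepoint_hr[tc$is_peak], 72)

  single <- plate_row(3, 100, 10, timepoint = 72)
  expect_warning(tc1 <- yield_timecourse(scale_dauer_counts(single), 3),
                 "fewer than two")
  expect_true(is.na(peak_hr(tc1)))
})

test_that("recovery check flags a late length increase", {
  lengths <- tibble::tibble(
    timepoint_hr = rep(c(48, 144), each = 20),
    length_um = c(seq(510, 529, 1), seq(570, 589, 1))
  )
  rc <- recovery_check(lengths)
  expect_true(rc$increase_flag)
  expect_equal(rc$by_timepoint$mean, c(519.5, 579.5))
  expect_lt(rc$anova$p.value, 1e-6)

  flat <- lengths; flat$length_um <- rep(seq(510, 529, 1), 2)
  expect_false(recovery_check(flat)$increase_flag)

  small <- lengths[c(1:20, 21:25), ]
  expect_warning(recovery_check(small), "fewer than 15")
  expect_error(recovery_check(lengths[1:20, ]), "two timepoints")
})

test_that("lawn QC applies the tolerance bands", {
  qc <- tibble::tibble(area_cm2 = c(9.5, 10.0, 10.5),
                       od600 = c(0.33, 0.35, 0.34))
  out <- lawn_qc(qc)
  expect_true(all(out$pass))
  expect_equal(out$mean[out$variable == "area_cm2"], 10)
  expect_equal(out$sd[out$variable == "od600"], sd(qc$od600))

  qc$od600[2] <- 0.45
  out2 <- lawn_qc(qc)
  expect_true(out2$pass[out2$variable == "area_cm2"])
  expect_false(out2$pass[out2$variable == "od600"])
})

test_that("trade-off table ranks speed and yield and flags non-monotone yield", {
  plates <- plate_row(rep(c(1, 3, 10, 50, 200), each = 2),
                      bust = rep(c(159, 137, 112, 79, 51), each = 2),
                      yield = rep(c(1540, 2837, 310, 232, 1050), each = 2))
  tt <- tradeoff_table(summarize_assay(plates), 72)
  expect_equal(tt$speed_rank, c(5, 4, 3, 2, 1)) # more founders, faster bust
  expect_equal(tt$yield_rank, c(2, 1, 4, 5, 3)) # best yield at 3 founders
  expect_true(attr(tt, "speed_monotone"))
  expect_true(tradeoff_flag(tt)) # interior optimum = non-monotone yield

  mono <- plate_row(rep(c(1, 3, 10), each = 2),
                    bust = rep(c(150, 100, 50), each = 2),
                    yield = rep(c(300, 200, 100), each = 2))
  expect_false(tradeoff_flag(tradeoff_table(summarize_assay(mono), 72)))
})
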