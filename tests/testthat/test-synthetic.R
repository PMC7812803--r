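test_that("the packaged reference tables carry the published anchors", {
  fx <- gc_fixtures()
  expect_identical(sum(fx$clone_table$total), 162L)
  expect_identical(sum(fx$clone_table$unmutated), 14L)
  d7 <- fx$day7_census
  expect_equal(d7$mean[d7$population == "late_int"], 5009)
  expect_equal(d7$mean[d7$population == "dz"], 3691)
  # the lateCD23lo slot is flagged as not printed
  ll <- d7[d7$population == "late_lo", ]
  expect_false(ll$printed)
  expect_true(is.na(ll$mean))
  ctv <- fx$ctv_table
  e <- ctv[ctv$subpop == "EARLY", ]
  expect_equal(e$percent[e$compartment == "div4"], 34.5)
  expect_equal(e$percent[e$compartment == "div5"], 17.9)
  expect_equal(e$percent[e$compartment == "div6"], 9.30)
  expect_true(all(is.na(ctv$percent[ctv$subpop == "PREPB"])))
})

test_that("the pooled unmutated fraction matches the sequencing counts", {
  fx <- gc_fixtures()
  expect_equal(round(unmutated_fraction(fx$clone_table), 1), 8.6)
  all_un <- tibble::tibble(sort = 1, unmutated = 10L, total = 10L)
  expect_equal(unmutated_fraction(all_un), 100)
  two <- tibble::tibble(sort = 1:2, unmutated = c(1L, 1L),
                        total = c(10L, 10L))
  expect_equal(unmutated_fraction(two), 10)
  # invariant to row order and to merging sorts with the same pooled totals
  expect_equal(unmutated_fraction(two[2:1, ]),
               unmutated_fraction(tibble::tibble(sort = 1, unmutated = 2L,
                                                 total = 20L)))
  expect_error(unmutated_fraction(two[0, ]), "empty")
  expect_error(unmutated_fraction(tibble::tibble(unmutated = 1L,
                                                 total = 0L)), "positive")
  expect_error(unmutated_fraction(tibble::tibble(unmutated = 3L,
                                                 total = 2L)), "unmutated")
})

test_that("the calibration completes the census with flagged derived slots", {
  cal <- gc_calibration()
  a <- cal$anchors
  expect_false(any(a$derived[a$population %in%
                               c("early", "prepb", "late_int", "dz")]))
  expect_true(all(a$derived[a$population %in% c("late_lo", "cmyc", "gc")]))
  cmyc <- a$mean[a$population == "cmyc"]
  expect_equal(cmyc, sum(a$mean[a$population %in%
                                  c("early", "prepb", "late_int",
                                    "late_lo", "dz")]))
  expect_equal(a$mean[a$population == "gc"], cmyc / 0.05)
})

test_that("noise-free generation hits the anchors exactly on the anchor day", {
  cal <- gc_calibration()
  tc <- generate_timecourse(cal, days = c(5, 7), n_mice = 3, noise_cv = 0,
                            seed = 1, scale = 0.5)
  d7 <- tc[tc$time_h == 168, ]
  anchors <- stats::setNames(cal$anchors$mean, cal$anchors$population)
  expect_equal(d7$count,
               unname(anchors[d7$population]) * 0.5)
  # all mice identical without noise
  expect_identical(length(unique(tc$count[tc$population == "gc" &
                                            tc$time_h == 120])), 1L)
})

test_that("generated datasets are reproducible and rise-peak-decline shaped", {
  a <- generate_timecourse(seed = 3, n_mice = 2)
  b <- generate_timecourse(seed = 3, n_mice = 2)
  expect_identical(a$count, b$count)
  m <- generate_timecourse(days = c(4, 10, 21), noise_cv = 0, n_mice = 1)
  gc <- m$count[m$population == "gc"]
  expect_gt(gc[2], gc[1])
  expect_gt(gc[2], gc[3])
})

test_that("day-7 generated means converge to the calibration anchors", {
  cal <- gc_calibration()
  tc <- generate_timecourse(cal, days = 7, n_mice = 1000, noise_cv = 0.3,
                            seed = 7)
  obs <- tc |>
    dplyr::group_by(population) |>
    dplyr::summarise(m = mean(count))
  anchors <- cal$anchors
  printed <- anchors[!is.na(anchors$sem), ]
  for (i in seq_len(nrow(printed))) {
    got <- obs$m[obs$population == printed$population[i]]
    expect_lt(abs(got - printed$mean[i]), 2 * printed$sem[i])
  }
})

test_that("simulator-derived datasets carry provenance and exact zero-noise values", {
  cfg <- test_config(founders = 30)
  data <- generate_from_simulator(cfg, model_zero(), noise_cv = 0,
                                  seed = 13, days = 2)
  tc <- simulate_gc(cfg, model_zero(), seed = 13, replicates = 1, days = 2)
  agg <- aggregate_timecourse(tc)
  joined <- dplyr::inner_join(data, agg, by = c("time_h", "population"))
  expect_equal(joined$count, joined$mean)
  prov <- attr(data, "provenance")
  expect_identical(prov$topology, "model0")
  expect_equal(prov$params$t_split,
               model_zero()$params$hours[
                 model_zero()$params$name == "t_split"])
})

test_that("the transfer scenario configuration is valid and transfer-shaped", {
  cfg <- ctv_transfer_config()
  expect_s3_class(cfg, "gc_config")
  expect_gt(cfg$founder_delay_max, 0)
  expect_true(!is.null(cfg$founder_div_dist))
  expect_true(all(diff(cfg$founder_div_dist$weight) < 0))
})
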