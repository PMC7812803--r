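test_that("normalization divides all populations by one shared reference", {
  tc <- tibble::tibble(time_h = rep(c(0, 6), each = 2),
                       population = rep(c("gc", "cmyc"), 2),
                       count = c(10, 4, 20, 5))
  out <- normalize_timecourse(tc, 20)
  expect_equal(max(out$value[out$population == "gc"]), 1)
  # ratios between populations at each time are preserved
  expect_equal(out$value[2] / out$value[1], 4 / 10)
  expect_error(normalize_timecourse(tc, 0), "positive")
  expect_error(normalize_timecourse(tc, -1), "positive")
})

test_that("RSS is zero at equality, additive, and order-invariant", {
  sim <- tibble::tibble(time_h = rep(c(0, 6, 12), 2),
                        population = rep(c("a", "b"), each = 3),
                        value = c(1, 2, 3, 4, 5, 6))
  expect_equal(timecourse_rss(sim, sim), 0)
  data1 <- tibble::tibble(time_h = 6, population = "a", value = 2.5)
  expect_equal(timecourse_rss(sim, data1), 0.25)
  # adding a perfectly matched population changes nothing
  data2 <- dplyr::bind_rows(data1,
                            tibble::tibble(time_h = c(0, 6), population = "b",
                                           value = c(4, 5)))
  expect_equal(timecourse_rss(sim, data2), 0.25)
  # additive over populations, invariant to row order
  data3 <- tibble::tibble(time_h = c(6, 6), population = c("b", "a"),
                          value = c(5.5, 2.5))
  expect_equal(timecourse_rss(sim, data3), 0.25 + 0.25)
  expect_equal(timecourse_rss(sim, data3[2:1, ]),
               timecourse_rss(sim, data3))
  # interpolation hits intermediate times linearly
  data4 <- tibble::tibble(time_h = 3, population = "a", value = 1.5)
  expect_equal(timecourse_rss(sim, data4), 0)
  expect_error(timecourse_rss(sim, tibble::tibble(
    time_h = 0, population = "zz", value = 1)), "zz")
})

test_that("AICc matches the least-squares form and its guards", {
  expect_equal(aicc(2, 50, 0), 50 * log(2 / 50))
  expect_equal(aicc(2, 50, 3), 50 * log(0.04) + 6 + 24 / 46)
  expect_equal(aicc(2, 50, 3), -154.42, tolerance = 1e-4)
  # increasing k at fixed rss and large n always penalizes
  vals <- vapply(0:5, function(k) aicc(2, 1000, k), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_warning(na <- aicc(2, 4, 3), "n > k")
  expect_true(is.na(na))
  expect_error(aicc(0, 50, 1), "positive")
})

test_that("grid fitting returns the argmin and never worsens with more points", {
  cfg <- test_config(founders = 40, dt = 0.2)
  data <- generate_from_simulator(cfg, model_zero(), seed = 21, days = 3)
  g1 <- tibble::tibble(t_split = 12)
  f1 <- fit_topology(data, model_zero(), g1, cfg, replicates = 2,
                     seed = 31, days = 3)
  expect_equal(f1$params$t_split, 12)
  expect_identical(f1$k, 1L)
  g2 <- tibble::tibble(t_split = c(12, 8, 16))
  f2 <- fit_topology(data, model_zero(), g2, cfg, replicates = 2,
                     seed = 31, days = 3)
  expect_lte(f2$rss, f1$rss)
  expect_identical(nrow(tidy(f2)), 3L)
  expect_s3_class(glance(f2), "tbl_df")
  expect_error(fit_topology(data, model_zero(), g1[0, ], cfg), "grid")
})

test_that("model ranking sorts by AICc with RSS and name tie-breaks", {
  mk <- function(name, rss, aicc) structure(
    list(topology = name, rss = rss, n = 30, k = 2, aicc = aicc,
         grid_results = tibble::tibble(), replicates = 1, seed = 1),
    class = "gc_fit")
  r <- rank_models(list(mk("a", 1, -10), mk("b", 2, -20)))
  expect_identical(r$topology[1], "b")
  expect_identical(r$rank, 1:2)
  r2 <- rank_models(list(mk("x", 1.0, -15), mk("y", 0.5, -15)))
  expect_identical(r2$topology[1], "y")
  r3 <- rank_models(list(mk("n2", 1, -15), mk("n1", 1, -15)))
  expect_identical(r3$topology[1], "n1")
  expect_error(rank_models(list(mk("a", 1, 1))), "two")
})
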