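test_that("dual-label classes follow the EdU/BrdU combination", {
  cells <- tibble::tibble(edu = c(FALSE, TRUE, TRUE, FALSE),
                          brdu = c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(dual_label_classify(cells)$dual_label,
                   c("earlyS", "midlateS", "postS", "unlabeled"))
  counts <- dual_label_counts(cells)
  expect_identical(c(counts$n_earlyS, counts$n_midlateS, counts$n_postS,
                     counts$n_unlabeled), rep(1L, 4))
})

test_that("pulses label exactly the cells that touch S during the window", {
  cfg <- test_config(founders = 3, phase_jitter = 0,
                     pulses = tibble::tibble(label = "EdU",
                                             start = 0, end = 1))
  st <- seed_gc(cfg, seed = 1)
  # cell 1: in G1 for the whole window; cell 2: in S; cell 3: enters S
  # shortly after the window opens
  st$phase <- c(1L, 2L, 1L)
  st$ela <- c(0, 1, 1.8)
  st$dur <- c(2, 4, 2) # cell 3 finishes G1 at 0.2 h
  topo <- model_zero()
  for (k in 1:10) gc_step(st, cfg, topo)
  expect_identical(st$edu[1:3], c(FALSE, TRUE, TRUE))
})

test_that("labels are permanent and inherited by daughters", {
  cfg <- test_config(founders = 30,
                     pulses = tibble::tibble(label = "EdU",
                                             start = 0, end = 1))
  st <- seed_gc(cfg, seed = 2)
  topo <- model_zero()
  n_lab <- integer()
  for (k in 1:300) {
    gc_step(st, cfg, topo)
    if (k %% 50 == 0) n_lab <- c(n_lab, sum(st$edu[st$program > 0L]))
  }
  expect_gt(n_lab[1], 0)
  expect_true(all(diff(n_lab) >= 0)) # labeled lineages only grow
})

test_that("the S-phase duration estimator follows the count ratio", {
  expect_equal(s_phase_duration(list(n_midlateS = 100, n_postS = 100,
                                     interval = 1)), 1)
  expect_equal(s_phase_duration(list(n_midlateS = 300, n_postS = 100,
                                     interval = 1)), 3)
  expect_warning(
    ud <- s_phase_duration(list(n_midlateS = 10, n_postS = 0,
                                interval = 1)), "U.D.")
  expect_true(is.na(ud))
})

test_that("the estimator is monotone in the true S duration and near truth", {
  est <- function(ts, seed) {
    cfg <- gc_config(t_s = ts)
    x <- simulate_cycling(6000, hours = 2, config = cfg, seed = seed)
    s_phase_duration(dual_label_counts(x$cells, interval = 1))
  }
  e <- c(est(2, 1), est(4, 1), est(6, 1))
  expect_true(all(diff(e) > 0))
  expect_gte(e[2], 3)
  expect_lte(e[2], 5)
})

test_that("DNA content maps phases to ploidy", {
  cells <- tibble::tibble(
    phase = c("G0", "G1", "S", "S", "G2", "M"),
    phase_elapsed = c(0, 1, 2, 1, 0.5, 0.1),
    phase_duration = c(1, 2, 4, 4, 1.5, 0.5))
  expect_equal(dna_content(cells), c(2, 2, 3, 2.5, 4, 4))
})

test_that("post-S diploid fraction reads cytokinesis completion", {
  g2 <- tibble::tibble(edu = TRUE, brdu = FALSE, dna_content = 4)
  g1 <- tibble::tibble(edu = TRUE, brdu = FALSE, dna_content = 2)
  expect_equal(post_s_diploid_fraction(g2), 0)
  expect_equal(post_s_diploid_fraction(g1), 100)
  expect_warning(post_s_diploid_fraction(
    tibble::tibble(edu = FALSE, brdu = FALSE, dna_content = 2)), "post-S")
  # a fast G2/M (dark-zone-like) clears more post-S cells to 2n than a
  # slow G2/M (light-zone-like)
  fast <- simulate_cycling(4000, hours = 3,
                           config = gc_config(t_g2 = 1, t_m = 0.4), seed = 3)
  slow <- simulate_cycling(4000, hours = 3,
                           config = gc_config(t_g2 = 3, t_m = 1), seed = 3)
  expect_gt(post_s_diploid_fraction(fast$cells),
            post_s_diploid_fraction(slow$cells))
})

test_that("CTV dye mass is conserved through divisions", {
  x <- simulate_cycling(500, hours = 10, config = gc_config(),
                        pulses = NULL, seed = 5)
  expect_gt(nrow(x$cells), 500) # divisions happened
  expect_equal(sum(2^(-x$cells$ctv_generation)), 500)
})

test_that("CTV composition tables are complete and sum to 100 per compartment", {
  cells <- tibble::tibble(subpop = c("EARLY", "DZ_CMYC"),
                          ctv_generation = c(4L, 4L))
  comp <- ctv_composition(cells)
  expect_equal(comp$percent, c(50, 50))
  comp2 <- ctv_composition(default_cells())
  sums <- tapply(comp2$percent, comp2$compartment, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # cells below the first tracked division are excluded
  expect_false(any(grepl("div0|div1|div2|div3", comp2$compartment)))
})

test_that("transit fractions reproduce ratios on the reference table", {
  ref <- gc_fixtures()$ctv_table
  tf <- transit_fractions(ref)
  early45 <- tf[tf$subpop == "EARLY" & tf$boundary == "div4->div5", ]
  early56 <- tf[tf$subpop == "EARLY" & tf$boundary == "div5->div6", ]
  expect_equal(early45$ratio, 17.9 / 34.5, tolerance = 1e-9)
  expect_equal(early45$ratio, 0.519, tolerance = 1e-3)
  expect_equal(early56$ratio, 9.30 / 17.9, tolerance = 1e-9)
  # dark-zone share grows at both boundaries
  dz <- tf[tf$subpop == "DZ_CMYC", ]
  expect_true(all(dz$difference > 0))
  # identical consecutive rows give unit ratios
  flat <- tibble::tibble(compartment = c("div4", "div5"),
                         subpop = "EARLY", percent = c(10, 10))
  expect_error(transit_fractions(flat[1, ]), "two")
  expect_equal(transit_fractions(flat)$ratio, 1)
})
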