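test_that("seeding creates the expected founder population", {
  cfg <- test_config(founders = 100)
  st <- seed_gc(cfg, seed = 1)
  cen <- gc_census(st)
  expect_identical(cen$count[cen$population == "gc"], 100L)
  expect_true(all(st$zone == 1L)) # all in the dark zone
  cells <- gc_cells(st, cfg)
  expect_true(all(cells$affinity < 1))
  expect_true(all(cells$ctv_generation == 0L))
  expect_error(seed_gc(update_config(cfg, founders = 1)), NA)
  expect_error(seed_gc(update_config(cfg, founders = 0)), "founders")
})

test_that("identical config and seed reproduce the time course bit for bit", {
  cfg <- test_config(founders = 40)
  a <- simulate_gc(cfg, model_zero(), seed = 5, days = 3)
  b <- simulate_gc(cfg, model_zero(), seed = 5, days = 3)
  expect_identical(a$count, b$count)
  expect_identical(a$time_h, b$time_h)
})

test_that("census accounting identities hold at every sample", {
  tc <- default_sim()
  wide <- tidyr::pivot_wider(tc, names_from = "population",
                             values_from = "count")
  expect_true(all(wide$early + wide$prepb + wide$late_int +
                    wide$late_lo + wide$dz == wide$cmyc))
  expect_true(all(wide$cmyc <= wide$gc))
  expect_true(all(tc$count >= 0))
  expect_true(is.integer(tc$count))
})

test_that("zero simulated days yields only the initial census", {
  tc <- simulate_gc(test_config(founders = 20), model_zero(), seed = 1,
                    days = 0)
  expect_identical(unique(tc$time_h), 0)
  expect_identical(nrow(tc), 8L)
})

test_that("cell count balance: births - deaths - outputs = net change", {
  tc <- default_sim()
  for (r in 1:2) {
    ev <- attr(tc, "events")[[r]]
    outs <- sum(attr(tc, "outputs")$replicate == r)
    final <- tc$count[tc$population == "gc" & tc$replicate == r &
                        tc$time_h == max(tc$time_h)]
    founders <- attr(tc, "config")$founders
    expect_identical(founders + ev$births - ev$deaths - outs, final)
  }
})

test_that("with apoptosis disabled and no output the population never shrinks", {
  cfg <- test_config(founders = 30, cc_lifetime = 1e6,
                     p_recycle = 1, p_output = 0)
  tc <- simulate_gc(cfg, model_zero(), seed = 2, days = 4)
  gc <- tc$count[tc$population == "gc"]
  expect_true(all(diff(gc) >= 0))
  expect_identical(sum(attr(tc, "outputs")$replicate == 1), 0L)
})

test_that("a degenerate threshold selects every contacted centrocyte", {
  cfg <- test_config(founders = 30, selection_threshold = 0,
                     n_contacts_required = 0)
  st <- seed_gc(cfg, seed = 3)
  topo <- model_zero()
  for (k in 1:600) gc_step(st, cfg, topo)
  # every cell that ever received a contact must have been selected
  expect_identical(sum(st$ncon > 0L & st$program == 2L), 0L)
})

test_that("unselected centrocytes die at their lifetime, cMyc+ cells never do", {
  cfg <- test_config(founders = 40, cc_lifetime = 6)
  st <- seed_gc(cfg, seed = 4)
  topo <- model_zero(t_dzloss = 500) # cells stay cMyc+ through the DZ
  for (k in 1:1200) {
    gc_step(st, cfg, topo)
    if (k %% 100 == 0) {
      alive <- st$program[seq_len(st$n)] > 0L
      cc <- alive & st$program[seq_len(st$n)] == 2L
      overdue <- cc & (st$clock - st$lz_t[seq_len(st$n)]) >
        cfg$cc_lifetime + 2 * cfg$dt
      # the only survivors past the lifetime are cMyc+ (protected)
      expect_true(all(st$sub[seq_len(st$n)][overdue] > 0L))
    }
  }
  expect_gt(st$deaths, 0L)
})

test_that("the fate decision split matches 90:10 within binomial noise", {
  tc <- default_sim()
  ev <- attr(tc, "events")[[1]]
  n <- ev$n_recycle + ev$n_output
  expect_gt(n, 1000)
  p <- ev$n_recycle / n
  expect_lt(abs(p - 0.9), 3 * sqrt(0.9 * 0.1 / n))
})

test_that("subpopulation entry flow is conserved in the working topology", {
  tc <- default_sim()
  for (r in 1:2) {
    ev <- attr(tc, "events")[[r]]
    final <- tidyr::pivot_wider(
      dplyr::filter(tc, replicate == r, time_h == max(time_h)),
      names_from = "population", values_from = "count")
    # every EARLY entry leaves through the fate decision or is still EARLY;
    # daughters born inside a subpopulation count as entries
    expect_identical(ev$cum_entries[["EARLY"]],
                     as.integer(ev$n_recycle + ev$n_output + final$early))
  }
})

test_that("a hand-built census reports the constructed subpopulations", {
  st <- state_with_subpops(c("EARLY", "EARLY", "EARLY", "PREPB", "PREPB"))
  cen <- gc_census(st)
  expect_identical(cen$count[cen$population == "early"], 3L)
  expect_identical(cen$count[cen$population == "prepb"], 2L)
  expect_identical(cen$count[cen$population == "cmyc"], 5L)
})

test_that("derived cell observables are internally consistent", {
  cells <- default_cells()
  expect_true(all(cells$dna_content >= 2 & cells$dna_content <= 4))
  expect_true(all(cells$dna_content[cells$phase %in% c("G0", "G1")] == 2))
  expect_true(all(cells$dna_content[cells$phase %in% c("G2", "M")] == 4))
  expect_identical(cells$ph3, cells$phase == "M")
  # pH3+ fraction equals the M-phase fraction exactly
  expect_identical(mean(cells$ph3), mean(cells$phase == "M"))
  # reported cMyc level drops during mitosis, only there
  ph3pos <- cells$ph3 & cells$cmyc_level > 0
  expect_true(all(cells$cmyc_reported[ph3pos] <
                    cells$cmyc_level[ph3pos]))
  expect_identical(cells$cmyc_reported[!cells$ph3],
                   cells$cmyc_level[!cells$ph3])
})

test_that("replicate aggregation returns mean and sd per time and population", {
  tc <- default_sim()
  agg <- aggregate_timecourse(tc)
  expect_true(all(agg$n == 2L))
  expect_identical(nrow(agg), length(unique(tc$time_h)) * 8L)
  # replicates sharing a seed have zero spread
  dup <- dplyr::bind_rows(
    dplyr::mutate(dplyr::filter(tc, replicate == 1), replicate = 1L),
    dplyr::mutate(dplyr::filter(tc, replicate == 1), replicate = 2L))
  expect_true(all(aggregate_timecourse(dup)$sd == 0))
})

test_that("cMyc levels order along the subpopulation chain", {
  cells <- default_cells()
  lev <- cells |>
    dplyr::filter(subpop != "NONE") |>
    dplyr::group_by(subpop) |>
    dplyr::summarise(m = mean(cmyc_level))
  g <- stats::setNames(lev$m, lev$subpop)
  expect_true(g[["EARLY"]] > g[["LATE_INT"]])
  expect_true(g[["LATE_INT"]] > g[["LATE_LO"]])
  expect_true(g[["LATE_LO"]] > g[["DZ_CMYC"]])
  # prePB cells keep near-EARLY levels (within 25%)
  expect_lt(abs(g[["PREPB"]] - g[["EARLY"]]) / g[["EARLY"]], 0.25)
})

test_that("hand-set single-cell levels are averaged per subpopulation", {
  st <- state_with_subpops(c("EARLY", "PREPB", "LATE_INT", "LATE_LO"))
  st$level <- c(4, 3, 2, 1)
  cells <- gc_cells(st, gc_config(founders = 4))
  m <- tapply(cells$cmyc_level, cells$subpop, mean)
  expect_equal(as.vector(m[c("EARLY", "PREPB", "LATE_INT", "LATE_LO")]),
               c(4, 3, 2, 1))
})
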