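# Synthetic-data generators and packaged in vivo reference values, so every
# pipeline stage is testable without external data.

#' Packaged in vivo reference tables
#'
#' Loads the three plain-text reference tables shipped with the package:
#' * `clone_table` — unmutated / total sequenced clones of the cMyc+early
#'   subpopulation for three independent sorts;
#' * `day7_census` — day-7 splenic counts (mean, SEM) of the cMyc+
#'   subpopulations; the lateCD23lo slot was not printed in the source and
#'   is flagged `printed = FALSE` with `NA` values;
#' * `ctv_table` — percentage of each subpopulation among cMyc+ cells per
#'   CellTrace division compartment (div4-div6); prePB rows are flagged
#'   `printed = FALSE` (described only qualitatively).
#'
#' @return A list of tibbles `clone_table`, `day7_census`, `ctv_table`.
#' @export
gc_fixtures <- function() {
  ext <- function(f) system.file("extdata", f, package = "gcmyc",
                                 mustWork = TRUE)
  list(
    clone_table = readr::read_tsv(
      ext("clone_mutations.tsv"),
      col_types = readr::cols(sort = "i", unmutated = "i", total = "i")),
    day7_census = readr::read_tsv(
      ext("day7_census.tsv"),
      col_types = readr::cols(population = "c", mean = "d", sem = "d",
                              printed = "l")),
    ctv_table = readr::read_tsv(
      ext("ctv_composition.tsv"),
      col_types = readr::cols(compartment = "c", subpop = "c",
                              percent = "d", sem = "d", printed = "l"))
  )
}

#' Pooled unmutated-clone fraction
#'
#' Percentage of unmutated clones pooled across sorts:
#' `100 * sum(unmutated) / sum(total)`. Invariant to row order and to
#' splitting or merging sorts with the same pooled totals. Full precision is
#' returned; round to one decimal for display.
#'
#' @param table A tibble with integer columns `unmutated` and `total`
#'   (one row per sort), e.g. `gc_fixtures()$clone_table`.
#' @return A single percentage.
#' @examples
#' unmutated_fraction(gc_fixtures()$clone_table) # 8.64...
#' @export
unmutated_fraction <- function(table) {
  table <- tibble::as_tibble(table)
  if (!nrow(table)) stop("clone table is empty", call. = FALSE)
  if (any(table$total <= 0)) stop("totals must be positive", call. = FALSE)
  if (any(table$unmutated < 0 | table$unmutated > table$total))
    stop("need 0 <= unmutated <= total in every row", call. = FALSE)
  100 * sum(table$unmutated) / sum(table$total)
}

#' Day-7 census calibration
#'
#' Completes the printed day-7 census into a full set of population anchors
#' for the synthetic time-course generator. Two slots are not printed in the
#' source and are derived here (flagged `derived = TRUE`):
#' * the lateCD23lo count, from its compartment share `late_lo_share`
#'   (default 13.5%, the remainder after the printed shares of the other
#'   four subpopulations);
#' * the total GC size, from the cMyc+ fraction of the GC
#'   (`cmyc_frac_of_gc`, default 5%, the midpoint of the reported 3-7%
#'   range).
#'
#' @param census Day-7 census tibble (`population`, `mean`, `sem`); default
#'   the packaged reference.
#' @param day Anchor day.
#' @param late_lo_share Assumed share of lateCD23lo within the cMyc+
#'   compartment.
#' @param cmyc_frac_of_gc Assumed cMyc+ fraction of all GC B cells.
#' @return An object of class `gc_calibration`: list with `day` and
#'   `anchors` (tibble `population`, `mean`, `sem`, `derived`) including
#'   `cmyc` and `gc` totals.
#' @export
gc_calibration <- function(census = gc_fixtures()$day7_census, day = 7,
                           late_lo_share = 0.135, cmyc_frac_of_gc = 0.05) {
  stopifnot(late_lo_share > 0, late_lo_share < 1,
            cmyc_frac_of_gc > 0, cmyc_frac_of_gc < 1)
  census <- tibble::as_tibble(census)
  printed <- dplyr::filter(census, !is.na(.data$mean))
  if (!all(c("early", "prepb", "late_int", "dz") %in% printed$population))
    stop("census must provide early, prepb, late_int and dz anchors",
         call. = FALSE)
  printed_sum <- sum(printed$mean)
  late_lo <- census$mean[census$population == "late_lo"]
  late_lo_derived <- length(late_lo) == 0L || is.na(late_lo)
  if (late_lo_derived)
    late_lo <- printed_sum * late_lo_share / (1 - late_lo_share)
  cmyc <- printed_sum + late_lo
  anchors <- dplyr::bind_rows(
    dplyr::transmute(printed, population = .data$population,
                     mean = .data$mean, sem = .data$sem, derived = FALSE),
    tibble::tibble(population = "late_lo", mean = late_lo, sem = NA_real_,
                   derived = late_lo_derived),
    tibble::tibble(population = c("cmyc", "gc"),
                   mean = c(cmyc, cmyc / cmyc_frac_of_gc),
                   sem = NA_real_, derived = TRUE)
  )
  structure(list(day = day, anchors = anchors,
                 late_lo_share = late_lo_share,
                 cmyc_frac_of_gc = cmyc_frac_of_gc),
            class = "gc_calibration")
}

#' @export
print.gc_calibration <- function(x, ...) {
  cat("<gc_calibration> day ", x$day, " anchors (cells/spleen):\n", sep = "")
  print(x$anchors)
  invisible(x)
}

#' Generate synthetic per-mouse census time courses
#'
#' Per-mouse counts are drawn log-normally (coefficient of variation
#' `noise_cv`) around a smooth trajectory through the calibration anchors.
#' The trajectory is a log-normal-shaped pulse: rise from about day 4, peak
#' near `peak_day`, decline towards day 21 — the qualitative kinetics of a
#' GC response — scaled so every population passes exactly through its
#' anchor on the calibration day. All populations share the pulse shape, so
#' compartment shares are constant over time at their anchored values.
#'
#' @param calibration A [gc_calibration()].
#' @param days Numeric vector of sampling days.
#' @param n_mice Mice (replicates) per day.
#' @param noise_cv Per-mouse coefficient of variation (0 = deterministic).
#' @param seed Optional integer seed.
#' @param scale Global scale factor applied to all anchors; use it to
#'   express the dataset at per-GC (simulator) scale rather than per-spleen
#'   scale.
#' @param peak_day,width Peak location (days) and log-scale width of the
#'   pulse.
#' @return A tibble `replicate`, `time_h`, `population`, `count` (class
#'   `gc_timecourse`), with the generating settings in
#'   `attr(, "provenance")`.
#' @export
generate_timecourse <- function(calibration = gc_calibration(),
                                days = 4:21, n_mice = 5L, noise_cv = 0.3,
                                seed = NULL, scale = 1,
                                peak_day = 10, width = 0.35) {
  stopifnot(noise_cv >= 0, scale > 0, all(days > 0))
  if (!is.null(seed)) set.seed(seed)
  shape <- function(t) exp(-(log(t / peak_day))^2 / (2 * width^2))
  ref <- shape(calibration$day)
  grid <- tidyr::expand_grid(
    replicate = seq_len(n_mice),
    day = days,
    population = calibration$anchors$population
  )
  anchor <- stats::setNames(calibration$anchors$mean,
                            calibration$anchors$population)
  traj <- unname(anchor[grid$population]) * scale * shape(grid$day) / ref
  count <- if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    traj * stats::rlnorm(length(traj), -sdlog^2 / 2, sdlog)
  } else traj
  out <- tibble::tibble(replicate = grid$replicate,
                        time_h = grid$day * 24,
                        population = grid$population,
                        count = count)
  class(out) <- c("gc_timecourse", class(out))
  attr(out, "provenance") <- list(kind = "calibration_pulse",
                                  day = calibration$day,
                                  noise_cv = noise_cv, scale = scale,
                                  peak_day = peak_day, width = width,
                                  seed = seed)
  out
}

#' Generate observation data from the simulator itself
#'
#' Runs the agent-based model, averages the replicate censuses, applies
#' multiplicative log-normal observation noise, and returns the result in
#' the fitting schema with the generating topology and parameters recorded
#' as provenance. This is the ground-truth generator for the model- and
#' parameter-recovery experiments.
#'
#' @param config A [gc_config()].
#' @param topology A [gc_topology()].
#' @param noise_cv Observation coefficient of variation (0 = the exact
#'   simulated mean census).
#' @param seed Integer seed (used for both the simulation and the noise).
#' @param replicates Simulator replicates averaged before noise.
#' @param days Simulated days.
#' @return A tibble `time_h`, `population`, `count` with
#'   `attr(, "provenance")` holding the topology name and parameter point.
#' @export
generate_from_simulator <- function(config, topology = model_zero(),
                                    noise_cv = 0, seed = 1L,
                                    replicates = 1L,
                                    days = config$sim_days) {
  tc <- simulate_gc(config, topology, seed = seed, replicates = replicates,
                    days = days)
  out <- mean_curve(tc)
  out <- dplyr::rename(out, count = "value")
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    out$count <- out$count *
      stats::rlnorm(nrow(out), -sdlog^2 / 2, sdlog)
  }
  attr(out, "provenance") <- list(
    kind = "simulator", topology = topology$name,
    params = stats::setNames(as.list(topology$params$hours),
                             topology$params$name),
    noise_cv = noise_cv, seed = seed, replicates = replicates, days = days)
  out
}

#' Configuration of the division-tracked (dye-transfer) scenario
#'
#' Emulates an adoptive-transfer experiment: antigen-specific high-affinity
#' donor cells are stained with a division-tracking dye, activate
#' asynchronously over the first two days, differ heritably in proliferative
#' speed, and expand through a founder-specific division allowance whose
#' distribution declines with division number (large clonal bursts are
#' rarer). The GC is observed about 70 hours after staining; the cMyc+
#' subpopulation composition per division compartment is then read out with
#' [ctv_composition()] on the final cell table.
#'
#' Under these conditions the selection influx declines with division
#' number while light-zone divisions cascade older cMyc+ cells into deeper
#' compartments, so the expected share of the early subpopulation among
#' cMyc+ cells decreases from div4 to div6, mirroring division-coupled
#' progression through the subpopulation chain.
#'
#' @param founders Number of transferred founder cells.
#' @param ... Overrides passed to [gc_config()].
#' @return A [gc_config()].
#' @export
ctv_transfer_config <- function(founders = 1000L, ...) {
  gc_config(
    founders = founders,
    founder_delay_max = 48,
    founder_div_dist = tibble::tibble(divisions = c(4L, 5L, 6L),
                                      weight = c(0.68, 0.24, 0.08)),
    d_min = 1, d_max = 2,
    lz_div_high = 0.15, lz_div_low = 0.05,
    cycle_speed_range = c(0.6, 1.6),
    sim_days = 70 / 24,
    ...
  )
}
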