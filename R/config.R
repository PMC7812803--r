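#' Germinal-center simulation configuration
#'
#' All rates, durations, probabilities and thresholds of the agent-based GC
#' model. Fields flagged as free (`attr(cfg, "free")`) are fit targets of the
#' model-selection harness; everything else is treated as a fixed constant of
#' the study conditions. Defaults describe a 21-day response sampled every
#' 6 simulated hours.
#'
#' @param founders Number of founder centroblasts seeded at `t = 0`.
#' @param sim_days Simulated days.
#' @param dt Time step in hours; must not exceed the shortest cell-cycle
#'   phase.
#' @param t_g1,t_s,t_g2,t_m Cell-cycle phase durations in hours (defaults sum
#'   to 8 h, the upper end of the 6-8 h GC B-cell cycle).
#' @param phase_jitter Relative half-width of the uniform jitter applied to
#'   each phase duration per cell per phase (avoids artificial synchrony).
#' @param p_recycle,p_output Fate-decision split for positively selected
#'   cells: recycling to the dark zone vs differentiation into GC output.
#'   Fixed at 90%:10%; must sum to 1.
#' @param selection_threshold Integrated T-cell help ("tc signal") required
#'   for positive selection.
#' @param n_contacts_required Minimum number of TFH contacts before selection.
#' @param contact_gain Signal gained per TFH contact per unit of presented
#'   antigen.
#' @param cc_lifetime Hours an unselected centrocyte survives in the light
#'   zone before apoptosis.
#' @param tfh_capacity Maximum TFH contacts delivered per time step across
#'   the light zone (rationed help; free parameter).
#' @param lz_div_high,lz_div_low Per-hour probability that a cMyc+ light-zone
#'   cell of high / low affinity starts a division cycle (free parameters;
#'   affinity-dependent light-zone proliferation).
#' @param p_mut Per-daughter probability of a somatic hypermutation step at a
#'   dark-zone division.
#' @param founder_divisions Central division allowance of founders; each
#'   founder receives this number plus or minus one division (staggered
#'   first light-zone arrival).
#' @param founder_delay_max If positive, founders start quiescent and
#'   activate at a uniform random time in `[0, founder_delay_max]` hours
#'   (adoptive-transfer-like scenarios); 0 means all founders are cycling
#'   from the start.
#' @param cycle_speed_range Length-2 numeric: per-founder heritable
#'   cell-cycle duration multiplier drawn uniformly from this range
#'   (`c(1, 1)` = homogeneous). Models heterogeneous proliferative capacity
#'   of activated lineages; inherited by daughters.
#' @param founder_div_dist Optional tibble (`divisions`, `weight`) giving the
#'   distribution of the founder division allowance; overrides
#'   `founder_divisions`. `NULL` (default) uses `founder_divisions` plus or
#'   minus one.
#' @param recycle_divisions_base Base number of dark-zone divisions granted on
#'   recycling; one extra division is granted per affinity quartile above the
#'   population median, capped at `recycle_divisions_cap`.
#' @param recycle_divisions_cap Cap on divisions granted at recycling.
#' @param d_min,d_max Founder distance band from the shape-space optimum.
#' @param mbc_fraction Fraction of low-affinity output cells recorded as
#'   memory B cells rather than plasmablasts.
#' @param cmyc_l0 cMyc reporter level set at selection (arbitrary MFI-like
#'   units).
#' @param cmyc_halflife Half-life (hours) of the cMyc level decay in the
#'   absence of further stimulation.
#' @param m_phase_level_factor Reporting-only multiplier applied to the cMyc
#'   level of mitotic (pH3+) cells.
#' @param sample_every Census cadence in hours.
#' @param pulses Optional tibble of label pulses with columns
#'   `label` (`"EdU"` or `"BrdU"`), `start`, `end` (hours).
#' @param affinity An [affinity_model()].
#' @return An object of class `gc_config` (a named list with a `free`
#'   attribute naming the free parameters).
#' @export
gc_config <- function(founders = 100L, sim_days = 21, dt = 0.1,
                      t_g1 = 2, t_s = 4, t_g2 = 1.5, t_m = 0.5,
                      phase_jitter = 0.1,
                      p_recycle = 0.9, p_output = 0.1,
                      selection_threshold = 10, n_contacts_required = 3L,
                      contact_gain = 1, cc_lifetime = 10,
                      tfh_capacity = 4L,
                      lz_div_high = 0.12, lz_div_low = 0.04,
                      p_mut = 0.2,
                      founder_divisions = 4L,
                      founder_delay_max = 0,
                      founder_div_dist = NULL,
                      cycle_speed_range = c(1, 1),
                      recycle_divisions_base = 4L,
                      recycle_divisions_cap = 6L,
                      d_min = 3, d_max = 5,
                      mbc_fraction = 0.5,
                      cmyc_l0 = 100, cmyc_halflife = 12,
                      m_phase_level_factor = 0.3,
                      sample_every = 6,
                      pulses = NULL,
                      affinity = affinity_model()) {
  cfg <- list(
    founders = as.integer(founders), sim_days = sim_days, dt = dt,
    t_g1 = t_g1, t_s = t_s, t_g2 = t_g2, t_m = t_m,
    phase_jitter = phase_jitter,
    p_recycle = p_recycle, p_output = p_output,
    selection_threshold = selection_threshold,
    n_contacts_required = as.integer(n_contacts_required),
    contact_gain = contact_gain, cc_lifetime = cc_lifetime,
    tfh_capacity = as.integer(tfh_capacity),
    lz_div_high = lz_div_high, lz_div_low = lz_div_low,
    p_mut = p_mut,
    founder_divisions = as.integer(founder_divisions),
    founder_delay_max = founder_delay_max,
    founder_div_dist = if (is.null(founder_div_dist)) NULL else
      tibble::as_tibble(founder_div_dist),
    cycle_speed_range = cycle_speed_range,
    recycle_divisions_base = as.integer(recycle_divisions_base),
    recycle_divisions_cap = as.integer(recycle_divisions_cap),
    d_min = d_min, d_max = d_max,
    mbc_fraction = mbc_fraction,
    cmyc_l0 = cmyc_l0, cmyc_halflife = cmyc_halflife,
    m_phase_level_factor = m_phase_level_factor,
    sample_every = sample_every,
    pulses = if (is.null(pulses)) NULL else tibble::as_tibble(pulses),
    affinity = affinity
  )
  structure(validate_config(cfg), class = "gc_config",
            free = c("tfh_capacity", "lz_div_high", "lz_div_low"))
}

validate_config <- function(cfg) {
  durs <- c(cfg$t_g1, cfg$t_s, cfg$t_g2, cfg$t_m)
  if (any(durs <= 0)) stop("phase durations must be positive", call. = FALSE)
  if (abs(cfg$p_recycle + cfg$p_output - 1) > 1e-12)
    stop("p_recycle + p_output must equal 1", call. = FALSE)
  if (cfg$dt <= 0 || cfg$dt > min(durs) * (1 - cfg$phase_jitter) *
        min(cfg$cycle_speed_range))
    stop("dt must be positive and no larger than the shortest (jittered, ",
         "speed-scaled) phase duration", call. = FALSE)
  if (cfg$phase_jitter < 0 || cfg$phase_jitter >= 1)
    stop("phase_jitter must be in [0, 1)", call. = FALSE)
  if (cfg$cc_lifetime <= 0) stop("cc_lifetime must be positive",
                                 call. = FALSE)
  if (!is.null(cfg$pulses)) {
    stopifnot(all(c("label", "start", "end") %in% names(cfg$pulses)),
              all(cfg$pulses$label %in% c("EdU", "BrdU")),
              all(cfg$pulses$start < cfg$pulses$end))
  }
  if (length(cfg$cycle_speed_range) != 2L ||
      any(cfg$cycle_speed_range <= 0) ||
      cfg$cycle_speed_range[1L] > cfg$cycle_speed_range[2L])
    stop("cycle_speed_range must be two positive nondecreasing numbers",
         call. = FALSE)
  if (!is.null(cfg$founder_div_dist)) {
    stopifnot(all(c("divisions", "weight") %in% names(cfg$founder_div_dist)),
              all(cfg$founder_div_dist$divisions >= 1),
              all(cfg$founder_div_dist$weight > 0))
  }
  if (!inherits(cfg$affinity, "affinity_model"))
    stop("`affinity` must be an affinity_model", call. = FALSE)
  cfg
}

#' @export
print.gc_config <- function(x, ...) {
  cat("<gc_config> ", x$founders, " founders, ", x$sim_days, " days, dt = ",
      x$dt, " h\n", sep = "")
  cat("  cycle G1/S/G2/M = ", x$t_g1, "/", x$t_s, "/", x$t_g2, "/", x$t_m,
      " h (jitter ±", 100 * x$phase_jitter, "%)\n", sep = "")
  cat("  fate split recycle:output = ", 100 * x$p_recycle, "%:",
      100 * x$p_output, "% (fixed)\n", sep = "")
  cat("  selection: threshold ", x$selection_threshold, ", >= ",
      x$n_contacts_required, " contacts, TFH capacity ", x$tfh_capacity,
      "/step, CC lifetime ", x$cc_lifetime, " h\n", sep = "")
  cat("  LZ division /h: high ", x$lz_div_high, ", low ", x$lz_div_low,
      "\n", sep = "")
  cat("  free parameters: ", paste(attr(x, "free"), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Modify a configuration
#'
#' Returns a revalidated copy with the named fields replaced.
#' @param config A `gc_config`.
#' @param ... Named fields to replace.
#' @export
update_config <- function(config, ...) {
  dots <- list(...)
  unknown <- setdiff(names(dots), names(config))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(dots)) {
    config[[nm]] <- if (is.integer(config[[nm]])) as.integer(dots[[nm]])
    else dots[[nm]]
  }
  structure(validate_config(unclass(config)), class = "gc_config",
            free = attr(config, "free"))
}

#' Apply a parameter point to a config and topology
#'
#' Names in `point` are matched first against topology dwell parameters, then
#' against configuration fields; unknown names raise an error. Used by the
#' grid-search fitter.
#'
#' @param config A `gc_config`.
#' @param topology A `gc_topology`.
#' @param point Named list or one-row data frame.
#' @return List with elements `config` and `topology`.
#' @export
apply_point <- function(config, topology, point) {
  point <- as.list(point)
  in_topo <- names(point) %in% topology$params$name
  if (any(in_topo))
    topology <- set_topology_params(topology, point[in_topo])
  rest <- point[!in_topo]
  if (length(rest))
    config <- do.call(update_config, c(list(config), rest))
  list(config = config, topology = topology)
}

#' Write / read a configuration as YAML
#'
#' The affinity model and pulse table are serialized inline; reading rebuilds
#' and revalidates the full object, so a round trip is exact.
#'
#' @param config A `gc_config`.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  obj <- unclass(config)
  obj$affinity <- unclass(obj$affinity)
  if (!is.null(obj$pulses)) obj$pulses <- as.list(obj$pulses)
  obj$.free <- attr(config, "free")
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$.free <- NULL
  obj$affinity <- do.call(affinity_model, obj$affinity)
  if (!is.null(obj$pulses)) obj$pulses <- tibble::as_tibble(obj$pulses)
  do.call(gc_config, obj)
}
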