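# Agent-based germinal-center engine.
#
# The population lives in an environment of parallel atomic vectors (one slot
# per agent) for speed; the module surface converts to tibbles. Zones, phases
# and subpopulations are integer-coded:
#   zone: 1 = DZ, 2 = LZ
#   program: 1 = CB (centroblast), 2 = CC (centrocyte), 3 = selected
#   phase: 0 = G0, 1 = G1, 2 = S, 3 = G2, 4 = M
#   subpop: see SUBPOPS (0 = NONE ... 5 = DZ_CMYC)

ZONE_DZ <- 1L; ZONE_LZ <- 2L
PROG_CB <- 1L; PROG_CC <- 2L; PROG_SEL <- 3L
PHASES <- c("G0", "G1", "S", "G2", "M")

jitter_dur <- function(n, base, jit) {
  if (jit <= 0) rep(base, n) else base * (1 + stats::runif(n, -jit, jit))
}

# per-agent fields besides id and the position matrix
FIELDS <- c("zone", "program", "phase", "ela", "dur", "antigen", "tc",
            "ncon", "sub", "sub_t", "late_t", "level", "edu", "brdu",
            "ctv", "divrem", "born", "sel_t", "lz_t", "aff", "act_t",
            "speed")

#' Seed a germinal center
#'
#' Creates the initial state: `founders` centroblasts in the dark zone, in G1
#' at a random point of the phase (desynchronized), at shape-space positions
#' drawn in the founder distance band (all founders start below maximal
#' affinity), with `founder_divisions` divisions remaining and CellTrace
#' generation 0.
#'
#' @param config A [gc_config()].
#' @param seed Optional integer seed set before drawing the founders.
#' @return A `gc_state` object (environment).
#' @export
seed_gc <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$founders
  if (n < 1L) stop("cannot seed an empty GC: founders must be >= 1",
                   call. = FALSE)
  st <- new.env(parent = emptyenv())
  st$clock <- 0
  st$n <- n
  st$next_id <- n + 1L
  st$id <- seq_len(n)
  st$zone <- rep(ZONE_DZ, n)
  st$program <- rep(PROG_CB, n)
  sr <- config$cycle_speed_range
  st$speed <- if (sr[1L] == sr[2L]) rep(sr[1L], n) else
    stats::runif(n, sr[1L], sr[2L])
  delay <- config$founder_delay_max
  if (delay > 0) {
    # adoptive-transfer-like scenario: founders activate asynchronously
    st$phase <- rep(0L, n)
    st$act_t <- stats::runif(n) * delay
    st$dur <- jitter_dur(n, config$t_g1, config$phase_jitter) * st$speed
    st$ela <- rep(0, n)
  } else {
    st$phase <- rep(1L, n)
    st$act_t <- rep(0, n)
    st$dur <- jitter_dur(n, config$t_g1, config$phase_jitter) * st$speed
    st$ela <- stats::runif(n) * st$dur
  }
  st$pos <- founder_positions(n, config$affinity,
                              config$d_min, config$d_max)
  st$aff <- affinity(st$pos, config$affinity)
  st$antigen <- rep(0, n)
  st$tc <- rep(0, n)
  st$ncon <- rep(0L, n)
  st$sub <- rep(0L, n)
  st$sub_t <- rep(NA_real_, n)
  st$late_t <- rep(NA_real_, n)
  st$level <- rep(0, n)
  st$edu <- rep(FALSE, n)
  st$brdu <- rep(FALSE, n)
  st$ctv <- rep(0L, n)
  # Spread the founder division allowance so the first light-zone arrivals
  # are staggered rather than one synchronized wave: either the explicit
  # distribution of the scenario, or the default plus/minus one division.
  st$divrem <- if (!is.null(config$founder_div_dist)) {
    d <- config$founder_div_dist
    as.integer(d$divisions[sample.int(nrow(d), n, replace = TRUE,
                                      prob = d$weight / sum(d$weight))])
  } else {
    pmax(1L, config$founder_divisions +
           sample(c(-1L, 0L, 1L), n, replace = TRUE))
  }
  st$born <- rep(0, n)
  st$sel_t <- rep(NA_real_, n)
  st$lz_t <- rep(NA_real_, n)
  # accumulators
  st$n_dead <- 0L
  st$out_time <- numeric(); st$out_kind <- character()
  st$out_aff <- numeric(); st$out_ctv <- integer()
  st$n_recycle <- 0L; st$n_output <- 0L
  st$births <- 0L; st$deaths <- 0L
  st$cum_entries <- stats::setNames(integer(5L), names(SUBPOPS)[-1L])
  st$ev_sel <- list(); st$ev_rec <- list()
  class(st) <- "gc_state"
  st
}

#' @export
print.gc_state <- function(x, ...) {
  cat("<gc_state> t = ", x$clock, " h, ", n_agents(x), " agents, ",
      sum(x$sub > 0L), " cMyc+, ", length(x$out_kind), " outputs\n", sep = "")
  invisible(x)
}

n_agents <- function(state) state$n - state$n_dead

# Dead/exited agents are zeroed in place (program 0) so every selector skips
# them; storage is reclaimed here once they accumulate. Vectors are
# preallocated with capacity doubling; slots beyond st$n are inert zeros.
compact_state <- function(st) {
  if (st$n_dead > 0L || st$n < length(st$id)) {
    alive <- which(st$program[seq_len(st$n)] > 0L)
    for (f in c("id", FIELDS)) st[[f]] <- st[[f]][alive]
    st$pos <- st$pos[alive, , drop = FALSE]
    st$n <- length(alive)
    st$n_dead <- 0L
  }
  invisible(st)
}

#' Advance the simulation by one time step
#'
#' Applies, in fixed order: cell-cycle progression and division (centroblasts
#' in the dark zone; cMyc+ light-zone cells start cycles with
#' affinity-dependent probability), hypermutation at dark-zone division,
#' DZ-to-LZ transit when divisions are exhausted, light-zone antigen capture
#' (success probability = affinity per attempt), rationed TFH contacts
#' (highest presented antigen first), positive selection above the signal
#' threshold, the subpopulation state machine (fate decisions before timers),
#' apoptosis of unselected centrocytes at the end of their lifetime, label
#' pulses, and cMyc level decay. The clock advances by `config$dt`.
#'
#' @param state A `gc_state` (modified in place and returned).
#' @param config A [gc_config()].
#' @param topology A [gc_topology()] or the result of its internal
#'   compilation.
#' @return The state, invisibly.
#' @export
gc_step <- function(state, config, topology) {
  st <- state
  if (inherits(topology, "gc_topology")) topology <- compile_topology(topology)
  dt <- config$dt
  clock <- st$clock
  if (n_agents(st) == 0L) { st$clock <- clock + dt; return(invisible(st)) }
  jit <- config$phase_jitter
  base_dur <- c(config$t_g1, config$t_s, config$t_g2, config$t_m)
  thr <- config$affinity$high_low_threshold

  ## Detach the agent vectors into locals so indexed assignments update in
  ## place (environment-bound vectors would be copied on every `st$x[i] <-`),
  ## and write them back once at the end of the step.
  id <- st$id; zone <- st$zone; program <- st$program; phase <- st$phase
  ela <- st$ela; dur <- st$dur; antigen <- st$antigen; tc <- st$tc
  ncon <- st$ncon; sub <- st$sub; sub_t <- st$sub_t; late_t <- st$late_t
  level <- st$level; edu <- st$edu; brdu <- st$brdu; ctv <- st$ctv
  divrem <- st$divrem; born <- st$born; sel_t <- st$sel_t; lz_t <- st$lz_t
  aff <- st$aff; act_t <- st$act_t; speed <- st$speed; pos <- st$pos
  n <- st$n
  rm(list = c("id", FIELDS, "pos", "n"), envir = st)

  ## (0) delayed founder activation (only used by transfer-like scenarios)
  if (config$founder_delay_max > 0) {
    dorm <- which(zone == ZONE_DZ & program == PROG_CB & phase == 0L &
                    divrem > 0L & act_t <= clock)
    if (length(dorm)) {
      phase[dorm] <- 1L
      ela[dorm] <- 0
      dur[dorm] <- jitter_dur(length(dorm), config$t_g1, jit) * speed[dorm]
    }
  }

  ## index of cMyc+ agents, reused by (1a), (7) and the level decay
  pos_idx <- which(sub > 0L)

  ## (1a) cMyc+ LZ cells in G0 start a division cycle (affinity-dependent)
  lz_g0 <- pos_idx[zone[pos_idx] == ZONE_LZ & phase[pos_idx] == 0L]
  if (length(lz_g0)) {
    p <- ifelse(aff[lz_g0] >= thr, config$lz_div_high,
                config$lz_div_low) * dt
    go <- lz_g0[stats::runif(length(lz_g0)) < p]
    if (length(go)) {
      phase[go] <- 1L
      ela[go] <- 0
      dur[go] <- jitter_dur(length(go), config$t_g1, jit) * speed[go]
    }
  }

  ## (1b) phase progression and (2) division with hypermutation
  cyc <- which(phase > 0L)
  if (length(cyc)) {
    ela[cyc] <- ela[cyc] + dt
    done <- cyc[ela[cyc] >= dur[cyc]]
    if (length(done)) {
      adv <- done[phase[done] < 4L]
      if (length(adv)) {
        phase[adv] <- phase[adv] + 1L
        ela[adv] <- 0
        dur[adv] <- base_dur[phase[adv]] * speed[adv] *
          (if (jit > 0) 1 + stats::runif(length(adv), -jit, jit) else 1)
      }
      mit <- done[phase[done] == 4L]
      if (length(mit)) {
        ## division at the end of M; the mother slot becomes one daughter
        dzm <- mit[zone[mit] == ZONE_DZ]
        lzm <- mit[zone[mit] == ZONE_LZ]
        ctv[mit] <- ctv[mit] + 1L
        if (length(dzm)) {
          divrem[dzm] <- divrem[dzm] - 1L
          more <- dzm[divrem[dzm] > 0L]
          rest <- dzm[divrem[dzm] <= 0L]
          if (length(more)) {
            phase[more] <- 1L
            ela[more] <- 0
            dur[more] <- jitter_dur(length(more), config$t_g1, jit) *
              speed[more]
          }
          if (length(rest)) phase[rest] <- 0L
        }
        if (length(lzm)) phase[lzm] <- 0L # back to G0 in the LZ
        born[mit] <- clock
        m <- length(mit)
        if (n + m > length(id)) { # grow capacity (doubling); slots are inert
          pad <- max(length(id), n + m - length(id))
          id <- c(id, integer(pad)); zone <- c(zone, integer(pad))
          program <- c(program, integer(pad)); phase <- c(phase, integer(pad))
          ela <- c(ela, numeric(pad)); dur <- c(dur, numeric(pad))
          antigen <- c(antigen, numeric(pad)); tc <- c(tc, numeric(pad))
          ncon <- c(ncon, integer(pad)); sub <- c(sub, integer(pad))
          sub_t <- c(sub_t, numeric(pad)); late_t <- c(late_t, numeric(pad))
          level <- c(level, numeric(pad)); edu <- c(edu, logical(pad))
          brdu <- c(brdu, logical(pad)); ctv <- c(ctv, integer(pad))
          divrem <- c(divrem, integer(pad)); born <- c(born, numeric(pad))
          sel_t <- c(sel_t, numeric(pad)); lz_t <- c(lz_t, numeric(pad))
          aff <- c(aff, numeric(pad)); act_t <- c(act_t, numeric(pad))
          speed <- c(speed, numeric(pad))
          pos <- rbind(pos, matrix(0L, nrow = pad, ncol = ncol(pos)))
        }
        slots <- n + seq_len(m)
        id[slots] <- st$next_id + seq_len(m) - 1L
        st$next_id <- st$next_id + m
        zone[slots] <- zone[mit]; program[slots] <- program[mit]
        phase[slots] <- phase[mit]; ela[slots] <- ela[mit]
        dur[slots] <- dur[mit]; antigen[slots] <- antigen[mit]
        tc[slots] <- tc[mit]; ncon[slots] <- ncon[mit]
        sub[slots] <- sub[mit]; sub_t[slots] <- sub_t[mit]
        late_t[slots] <- late_t[mit]; level[slots] <- level[mit]
        edu[slots] <- edu[mit]; brdu[slots] <- brdu[mit]
        ctv[slots] <- ctv[mit]; divrem[slots] <- divrem[mit]
        born[slots] <- born[mit]; sel_t[slots] <- sel_t[mit]
        lz_t[slots] <- lz_t[mit]; aff[slots] <- aff[mit]
        act_t[slots] <- act_t[mit]; speed[slots] <- speed[mit]
        pos[slots, ] <- pos[mit, , drop = FALSE]
        n <- n + m
        st$births <- st$births + m
        # daughters born into a cMyc+ subpop count as entries (keeps the
        # cumulative entry flow conserved under division within a subpop)
        dsub <- sub[mit]
        if (any(dsub > 0L))
          st$cum_entries <- st$cum_entries +
            tabulate(dsub[dsub > 0L], nbins = 5L)
        # somatic hypermutation in the dark zone only (both daughters)
        if (length(dzm) && config$p_mut > 0) {
          dz_all <- c(dzm, slots[match(dzm, mit)])
          pos[dz_all, ] <- mutate_matrix(pos[dz_all, , drop = FALSE],
                                         config$p_mut, config$affinity)
          aff[dz_all] <- affinity(pos[dz_all, , drop = FALSE],
                                  config$affinity)
        }
      }
    }
  }

  ## (3) DZ -> LZ transit when divisions are exhausted
  tr <- which(zone == ZONE_DZ & program == PROG_CB &
                divrem <= 0L & phase == 0L)
  if (length(tr)) {
    zone[tr] <- ZONE_LZ
    program[tr] <- PROG_CC
    antigen[tr] <- 0; tc[tr] <- 0; ncon[tr] <- 0L
    lz_t[tr] <- clock
  }

  ## (4) antigen capture by centrocytes: one attempt/step, P(success)=affinity
  cc <- which(program == PROG_CC)
  if (length(cc)) {
    hit <- cc[stats::runif(length(cc)) < aff[cc]]
    antigen[hit] <- antigen[hit] + 1
  }

  ## (5) rationed TFH contacts, highest presented antigen first, random ties
  cand <- cc[antigen[cc] > 0]
  take <- integer()
  if (length(cand)) {
    cap <- config$tfh_capacity
    take <- if (length(cand) > cap) {
      # top-`cap` by presented antigen; the uniform jitter (< 1 unit) breaks
      # integer ties at random without a full sort
      key <- antigen[cand] + stats::runif(length(cand))
      kth <- length(cand) - cap + 1L
      thr_key <- sort(key, partial = kth)[kth]
      utils::head(cand[key >= thr_key], cap)
    } else cand
    tc[take] <- tc[take] + config$contact_gain * antigen[take]
    ncon[take] <- ncon[take] + 1L
  }

  ## (6) positive selection (tc only grows at a contact, so threshold
  ## crossings happen exactly among this step's contacted cells)
  sel <- take[tc[take] >= config$selection_threshold &
                ncon[take] >= config$n_contacts_required]
  if (length(sel)) {
    program[sel] <- PROG_SEL
    sel_t[sel] <- clock
    level[sel] <- config$cmyc_l0
    sub[sel] <- topology$sel_target
    sub_t[sel] <- clock
    st$cum_entries[[topology$sel_target]] <-
      st$cum_entries[[topology$sel_target]] + length(sel)
    st$ev_sel[[length(st$ev_sel) + 1L]] <-
      cbind(time = rep(clock, length(sel)), affinity = aff[sel])
  }

  ## (7) subpopulation state machine: fate decisions first, then timers/exits
  exited <- integer()
  dz_in <- integer()
  for (s in topology$order) {
    r <- topology$rules[[s]]
    due <- pos_idx[sub[pos_idx] == s & (clock - sub_t[pos_idx]) >= r$dwell]
    if (!length(due)) next
    if (r$type == "fate") {
      out_i <- due[stats::runif(length(due)) < config$p_output]
      rec_i <- setdiff(due, out_i)
      st$n_output <- st$n_output + length(out_i)
      st$n_recycle <- st$n_recycle + length(rec_i)
      moved <- list(list(out_i, r$out_to), list(rec_i, r$rec_to))
    } else if (r$type == "timer") {
      moved <- list(list(due, r$to))
    } else { # gc_exit: leaves the GC as an output cell
      low <- aff[due] < thr
      mbc <- low & stats::runif(length(due)) < config$mbc_fraction
      st$out_time <- c(st$out_time, rep(clock, length(due)))
      st$out_kind <- c(st$out_kind, ifelse(mbc, "MBC", "PB"))
      st$out_aff <- c(st$out_aff, aff[due])
      st$out_ctv <- c(st$out_ctv, ctv[due])
      exited <- c(exited, due)
      next
    }
    for (mv in moved) {
      idx <- mv[[1L]]; to <- mv[[2L]]
      if (!length(idx)) next
      sub[idx] <- to
      sub_t[idx] <- clock
      if (to > 0L)
        st$cum_entries[[to]] <- st$cum_entries[[to]] + length(idx)
      if (to == 5L) dz_in <- c(dz_in, idx)
      if (to == 0L) level[idx] <- 0
    }
  }

  ## dark-zone re-entry of recycled cells (transition into DZ_CMYC):
  ## CB differentiation with an affinity-graded division allowance
  if (length(dz_in)) {
    qs <- stats::quantile(aff[program > 0L], c(0.5, 0.75), names = FALSE)
    zone[dz_in] <- ZONE_DZ
    program[dz_in] <- PROG_CB
    divrem[dz_in] <- pmin(as.integer(
      config$recycle_divisions_base +
        (aff[dz_in] >= qs[1L]) + (aff[dz_in] >= qs[2L])),
      config$recycle_divisions_cap)
    antigen[dz_in] <- 0; tc[dz_in] <- 0; ncon[dz_in] <- 0L
    g0 <- dz_in[phase[dz_in] == 0L]
    if (length(g0)) {
      phase[g0] <- 1L
      ela[g0] <- 0
      dur[g0] <- jitter_dur(length(g0), config$t_g1, jit) * speed[g0]
    }
    st$ev_rec[[length(st$ev_rec) + 1L]] <-
      cbind(time = rep(clock, length(dz_in)), affinity = aff[dz_in])
  }

  ## (8) apoptosis of unselected centrocytes; cMyc+ cells are protected
  ## from this rule regardless of program
  die <- cc[program[cc] == PROG_CC & sub[cc] == 0L &
              (clock - lz_t[cc]) >= config$cc_lifetime]
  st$deaths <- st$deaths + length(die)

  gone <- c(die, exited)
  if (length(gone)) { # zero in place; storage reclaimed by compact_state()
    program[gone] <- 0L
    zone[gone] <- 0L
    sub[gone] <- 0L
    phase[gone] <- 0L
    st$n_dead <- st$n_dead + length(gone)
  }

  ## label pulses: any agent in S during an active window acquires the label
  if (!is.null(config$pulses)) {
    for (i in seq_len(nrow(config$pulses))) {
      p <- config$pulses[i, ]
      if (clock >= p$start - 1e-9 && clock < p$end - 1e-9) {
        in_s <- phase == 2L
        if (p$label == "EdU") edu <- edu | in_s
        else brdu <- brdu | in_s
      }
    }
  }

  ## cMyc level decay (cells that lost cMyc or died this step dropped out)
  pos_idx <- pos_idx[sub[pos_idx] > 0L]
  if (length(pos_idx))
    level[pos_idx] <- level[pos_idx] * 2^(-dt / config$cmyc_halflife)

  ## write the agent vectors back
  st$id <- id; st$zone <- zone; st$program <- program; st$phase <- phase
  st$ela <- ela; st$dur <- dur; st$antigen <- antigen; st$tc <- tc
  st$ncon <- ncon; st$sub <- sub; st$sub_t <- sub_t; st$late_t <- late_t
  st$level <- level; st$edu <- edu; st$brdu <- brdu; st$ctv <- ctv
  st$divrem <- divrem; st$born <- born; st$sel_t <- sel_t; st$lz_t <- lz_t
  st$aff <- aff; st$act_t <- act_t; st$speed <- speed; st$pos <- pos
  st$n <- n
  st$clock <- clock + dt
  invisible(st)
}

#' Census of a germinal-center state
#'
#' Counts the whole GC, the cMyc+ compartment, every cMyc+ subpopulation and
#' the cumulative output cells.
#'
#' @param state A `gc_state`.
#' @return A tibble with columns `population` and `count`. Subpopulation
#'   counts sum to the `cmyc` count; `gc` counts all live agents.
#' @export
gc_census <- function(state) {
  sub <- state$sub
  tibble::tibble(
    population = c("gc", "cmyc", "early", "prepb", "late_int", "late_lo",
                   "dz", "outputs"),
    count = c(n_agents(state), sum(sub > 0L),
              sum(sub == 1L), sum(sub == 2L), sum(sub == 3L),
              sum(sub == 4L), sum(sub == 5L),
              length(state$out_kind))
  )
}

#' Extract the agent population as a tibble
#'
#' One row per live agent with derived observables: DNA content (2n in G0/G1,
#' linear 2n to 4n across S, 4n in G2/M), the pH3 mitosis flag (true exactly
#' in M), affinity and the high/low gate, and the reported cMyc level (the
#' raw level multiplied by `m_phase_level_factor` while pH3+, mirroring the
#' mitotic drop of the reporter).
#'
#' @param state A `gc_state`.
#' @param config A [gc_config()] (for the DNA-content and reporting rules).
#' @return A tibble.
#' @export
gc_cells <- function(state, config) {
  st <- compact_state(state)
  n <- n_agents(st)
  dna <- rep(2, n)
  dna[st$phase == 2L] <- 2 + 2 * pmin(st$ela[st$phase == 2L] /
                                        st$dur[st$phase == 2L], 1)
  dna[st$phase >= 3L] <- 4
  ph3 <- st$phase == 4L
  tibble::tibble(
    id = st$id,
    zone = c("DZ", "LZ")[st$zone],
    program = c("CB", "CC", "selected")[st$program],
    phase = PHASES[st$phase + 1L],
    phase_elapsed = st$ela,
    phase_duration = st$dur,
    dna_content = dna,
    ph3 = ph3,
    subpop = subpop_label(st$sub),
    sub_entered = st$sub_t,
    cmyc_level = st$level,
    cmyc_reported = st$level * ifelse(ph3, config$m_phase_level_factor, 1),
    edu = st$edu,
    brdu = st$brdu,
    ctv_generation = st$ctv,
    divisions_remaining = st$divrem,
    antigen = st$antigen,
    tc_signal = st$tc,
    affinity = st$aff,
    affinity_class = ifelse(st$aff >= config$affinity$high_low_threshold,
                            "high", "low"),
    born = st$born,
    selected_at = st$sel_t
  )
}

#' Run the germinal-center simulation
#'
#' Runs `replicates` independent simulations of `days` simulated days,
#' sampling a census every `sample_every` hours (the `t = 0` census is always
#' included). Replicate `r` uses seed `seed + 1000 * (r - 1)`, so a fixed
#' `seed` reproduces the whole set bit for bit.
#'
#' @param config A [gc_config()].
#' @param topology A [gc_topology()]; default [model_zero()].
#' @param seed Integer base seed.
#' @param replicates Number of independent replicates.
#' @param days Simulated days (default `config$sim_days`).
#' @param sample_every Census cadence in hours (default
#'   `config$sample_every`).
#' @param keep_state If `TRUE`, attach the final `gc_state` of each replicate
#'   (as a [gc_cells()] tibble) in `attr(, "cells")`.
#' @return A `gc_timecourse` tibble with columns `replicate`, `time_h`,
#'   `population`, `count`, carrying the config, topology name, seed, per
#'   replicate event summaries (`attr(, "events")`) and output-cell tables
#'   (`attr(, "outputs")`).
#' @examples
#' tc <- simulate_gc(gc_config(founders = 30, sim_days = 2), seed = 1)
#' dplyr::filter(tc, time_h == 48)
#' @export
simulate_gc <- function(config, topology = model_zero(), seed = 1L,
                        replicates = 1L, days = config$sim_days,
                        sample_every = config$sample_every,
                        keep_state = FALSE) {
  comp <- compile_topology(topology)
  steps <- round(days * 24 / config$dt)
  stride <- max(1L, round(sample_every / config$dt))
  res <- vector("list", replicates)
  events <- vector("list", replicates)
  outputs <- vector("list", replicates)
  cells <- if (keep_state) vector("list", replicates) else NULL
  for (r in seq_len(replicates)) {
    st <- seed_gc(config, seed = seed + 1000L * (r - 1L))
    samples <- list(dplyr::mutate(gc_census(st), time_h = 0))
    for (k in seq_len(steps)) {
      gc_step(st, config, comp)
      if (st$n_dead > 256L && st$n_dead * 4L > st$n)
        compact_state(st)
      if (k %% stride == 0L)
        samples[[length(samples) + 1L]] <-
          dplyr::mutate(gc_census(st), time_h = round(k * config$dt, 6))
    }
    res[[r]] <- dplyr::bind_rows(samples) |>
      dplyr::mutate(replicate = r) |>
      dplyr::select("replicate", "time_h", "population", "count")
    events[[r]] <- list(
      n_recycle = st$n_recycle, n_output = st$n_output,
      births = st$births, deaths = st$deaths,
      cum_entries = st$cum_entries,
      selections = event_tibble(st$ev_sel),
      dz_entries = event_tibble(st$ev_rec)
    )
    outputs[[r]] <- tibble::tibble(
      replicate = r, time_h = st$out_time, kind = st$out_kind,
      affinity = st$out_aff, ctv_generation = st$out_ctv)
    if (keep_state) cells[[r]] <- gc_cells(st, config)
  }
  out <- dplyr::bind_rows(res)
  class(out) <- c("gc_timecourse", class(out))
  attr(out, "config") <- config
  attr(out, "topology") <- topology$name
  attr(out, "seed") <- seed
  attr(out, "events") <- events
  attr(out, "outputs") <- dplyr::bind_rows(outputs)
  if (keep_state) attr(out, "cells") <- cells
  out
}

event_tibble <- function(lst) {
  if (!length(lst))
    return(tibble::tibble(time = numeric(), affinity = numeric()))
  m <- do.call(rbind, lst)
  tibble::tibble(time = m[, "time"], affinity = m[, "affinity"])
}

#' Aggregate replicate time courses
#'
#' @param tc A `gc_timecourse` (long tibble with `replicate`, `time_h`,
#'   `population`, `count`).
#' @return Tibble with per-(time, population) `mean`, `sd` and `n` over
#'   replicates.
#' @export
aggregate_timecourse <- function(tc) {
  dplyr::summarise(
    dplyr::group_by(tc, .data$time_h, .data$population),
    mean = mean(.data$count), sd = stats::sd(.data$count),
    n = dplyr::n(), .groups = "drop")
}
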