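# Steady-state cycling population: the testbed for the dual-pulse
# instruments, decoupled from selection and zone dynamics.

#' Simulate a steady-state cycling population under label pulses
#'
#' Cells cycle continuously through G1, S, G2 and M with the phase durations
#' of `config` (jittered per cell per phase) and divide at the end of M; both
#' daughters keep cycling and inherit labels, and the CellTrace generation
#' counter increments by one per division. The initial population is placed
#' uniformly at random along the cycle, approximating the steady-state age
#' structure. Label pulses are applied exactly as in the full GC simulator:
#' any cell in S during an active window acquires the label, permanently.
#'
#' While running, the median DNA content of the EdU-negative BrdU-positive
#' (early-S) cohort is recorded at every step, which is the readout used to
#' time the 2n-to-4n doubling of cells that entered S during the second
#' pulse.
#'
#' @param n Initial number of cells.
#' @param hours Simulated hours.
#' @param config A [gc_config()] supplying `t_g1`, `t_s`, `t_g2`, `t_m`,
#'   `phase_jitter` and `dt`.
#' @param pulses Pulse tibble as in [gc_config()]; default the standard
#'   1 h EdU + 1 h BrdU protocol.
#' @param seed Optional integer seed.
#' @return An object of class `gc_cycling`: a list with `cells` (tibble of
#'   the final population with `phase`, `phase_elapsed`, `phase_duration`,
#'   `dna_content`, `edu`, `brdu`, `ctv_generation`) and `track` (tibble
#'   `time_h`, `n_earlyS`, `median_dna_earlyS`).
#' @examples
#' x <- simulate_cycling(500, hours = 8, seed = 1)
#' time_to_tetraploid(x)
#' @export
simulate_cycling <- function(n = 2000L, hours = 10,
                             config = gc_config(),
                             pulses = dual_pulse_protocol(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1)
  dt <- config$dt
  jit <- config$phase_jitter
  base <- c(config$t_g1, config$t_s, config$t_g2, config$t_m)
  total <- sum(base)
  # uniform position along the cycle
  u <- stats::runif(n) * total
  cum <- cumsum(base)
  phase <- findInterval(u, c(0, cum[-4L])) # 1..4
  ela <- u - c(0, cum[-4L])[phase]
  st <- list2env(list(
    phase = as.integer(phase), ela = ela,
    dur = base[phase] * (if (jit > 0) 1 + stats::runif(n, -jit, jit) else 1),
    edu = rep(FALSE, n), brdu = rep(FALSE, n), ctv = rep(0L, n)
  ), parent = emptyenv())
  # cells started mid-phase keep ela < dur even with downward jitter
  st$dur <- pmax(st$dur, st$ela + dt / 2)

  steps <- round(hours / dt)
  track_t <- numeric(steps); track_n <- integer(steps)
  track_med <- numeric(steps)
  clock <- 0
  for (k in seq_len(steps)) {
    st$ela <- st$ela + dt
    done <- which(st$ela >= st$dur)
    if (length(done)) {
      adv <- done[st$phase[done] < 4L]
      if (length(adv)) {
        st$phase[adv] <- st$phase[adv] + 1L
        st$ela[adv] <- 0
        st$dur[adv] <- base[st$phase[adv]] *
          (if (jit > 0) 1 + stats::runif(length(adv), -jit, jit) else 1)
      }
      mit <- done[st$phase[done] == 4L]
      if (length(mit)) {
        st$phase[mit] <- 1L
        st$ela[mit] <- 0
        st$dur[mit] <- base[1L] *
          (if (jit > 0) 1 + stats::runif(length(mit), -jit, jit) else 1)
        st$ctv[mit] <- st$ctv[mit] + 1L
        for (f in c("phase", "ela", "dur", "edu", "brdu", "ctv"))
          st[[f]] <- c(st[[f]], st[[f]][mit])
      }
    }
    if (!is.null(pulses)) {
      for (i in seq_len(nrow(pulses))) {
        p <- pulses[i, ]
        if (clock >= p$start - 1e-9 && clock < p$end - 1e-9) {
          in_s <- st$phase == 2L
          if (p$label == "EdU") st$edu <- st$edu | in_s
          else st$brdu <- st$brdu | in_s
        }
      }
    }
    clock <- clock + dt
    cohort <- !st$edu & st$brdu
    track_t[k] <- clock
    track_n[k] <- sum(cohort)
    track_med[k] <- if (any(cohort))
      stats::median(cycling_dna(st, cohort)) else NA_real_
  }
  cells <- tibble::tibble(
    phase = PHASES[st$phase + 1L],
    phase_elapsed = st$ela,
    phase_duration = st$dur,
    edu = st$edu, brdu = st$brdu,
    ctv_generation = st$ctv
  )
  cells$dna_content <- dna_content(cells)
  structure(list(
    cells = cells,
    track = tibble::tibble(time_h = track_t, n_earlyS = track_n,
                           median_dna_earlyS = track_med),
    pulses = pulses, config = config
  ), class = "gc_cycling")
}

cycling_dna <- function(st, which_cells) {
  ph <- st$phase[which_cells]
  out <- rep(2, length(ph))
  s <- ph == 2L
  out[s] <- 2 + 2 * pmin(st$ela[which_cells][s] / st$dur[which_cells][s], 1)
  out[ph >= 3L] <- 4
  out
}

#' @export
print.gc_cycling <- function(x, ...) {
  cat("<gc_cycling> ", nrow(x$cells), " cells after ",
      max(x$track$time_h), " h\n", sep = "")
  invisible(x)
}

#' Time for the early-S cohort to reach tetraploid DNA content
#'
#' Hours from the end of the second (BrdU) pulse window until the median DNA
#' content of the EdU-negative BrdU-positive cohort first reaches 4n. The
#' reference point is the first observation after labeling is complete,
#' matching how the doubling time is read off a pulse-chase time course.
#'
#' @param x A `gc_cycling` result whose pulses include a BrdU window.
#' @param target Median DNA content defining "tetraploid" (default 4, i.e.
#'   the full 4n level).
#' @return Hours (length 1); `NA` if the cohort never reaches the target.
#' @export
time_to_tetraploid <- function(x, target = 4) {
  stopifnot(inherits(x, "gc_cycling"))
  ref <- max(x$pulses$end[x$pulses$label == "BrdU"])
  tr <- x$track[x$track$time_h >= ref, ]
  hit <- which(!is.na(tr$median_dna_earlyS) &
                 tr$median_dna_earlyS >= target - 1e-9)
  if (!length(hit)) return(NA_real_)
  tr$time_h[hit[1L]] - ref
}
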