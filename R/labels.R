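# In-silico cytometry instruments: EdU/BrdU dual labeling, DNA content,
# CellTrace (CTV) division compartments, and the derived estimators.

#' The standard dual-pulse protocol
#'
#' EdU for one hour, then BrdU for one further hour. Start times are hours
#' from the start of the experiment.
#'
#' @param start Start of the EdU window (hours).
#' @param width Width of each label window (hours).
#' @return A tibble of pulses usable as the `pulses` field of [gc_config()].
#' @export
dual_pulse_protocol <- function(start = 0, width = 1) {
  starts <- c(start, start + width)
  tibble::tibble(label = c("EdU", "BrdU"),
                 start = starts,
                 end = starts + width)
}

#' Classify cells by EdU/BrdU dual labeling
#'
#' EdU-negative BrdU-positive cells were in early S phase during the second
#' window; double-positive cells were in mid/late S; EdU-positive
#' BrdU-negative cells had left S before the second window (post-S);
#' double-negative cells never touched S during either window.
#'
#' @param cells A tibble with logical columns `edu` and `brdu` (e.g. from
#'   [gc_cells()] or [simulate_cycling()]).
#' @return The tibble with an added `dual_label` column in
#'   `c("earlyS", "midlateS", "postS", "unlabeled")`.
#' @export
dual_label_classify <- function(cells) {
  dplyr::mutate(
    tibble::as_tibble(cells),
    dual_label = dplyr::case_when(
      !.data$edu & .data$brdu ~ "earlyS",
      .data$edu & .data$brdu ~ "midlateS",
      .data$edu & !.data$brdu ~ "postS",
      TRUE ~ "unlabeled"
    ))
}

#' Count dual-label classes
#'
#' @param cells A tibble with `edu` and `brdu` columns.
#' @param interval The interval between the two pulses in hours.
#' @return A one-row tibble with `n_earlyS`, `n_midlateS`, `n_postS`,
#'   `n_unlabeled` and `interval`.
#' @export
dual_label_counts <- function(cells, interval = 1) {
  stopifnot(interval > 0)
  cl <- dual_label_classify(cells)$dual_label
  tibble::tibble(
    n_earlyS = sum(cl == "earlyS"),
    n_midlateS = sum(cl == "midlateS"),
    n_postS = sum(cl == "postS"),
    n_unlabeled = sum(cl == "unlabeled"),
    interval = interval
  )
}

#' S-phase duration from dual-label counts
#'
#' The ratio of mid/late-S (double-positive) to post-S (EdU+BrdU-) cells,
#' multiplied by the pulse interval, estimates the S-phase duration. With no
#' post-S cells the estimate is undefined and `NA` is returned with a
#' warning (mirroring the "U.D." convention of sparse gates).
#'
#' @param counts A row from [dual_label_counts()] (or any list with
#'   `n_midlateS`, `n_postS`, `interval`).
#' @return Estimated S-phase duration in hours.
#' @export
s_phase_duration <- function(counts) {
  if (counts$n_postS == 0) {
    warning("no post-S cells: S-phase duration undefined (U.D.)",
            call. = FALSE)
    return(NA_real_)
  }
  counts$n_midlateS / counts$n_postS * counts$interval
}

#' DNA content of cells
#'
#' 2n in G0/G1, rising linearly from 2n to 4n across S, and 4n in G2/M.
#'
#' @param cells A tibble with columns `phase` (`"G0"`, `"G1"`, `"S"`, `"G2"`,
#'   `"M"`), `phase_elapsed` and `phase_duration` (hours).
#' @return Numeric vector in `[2, 4]`, one per row.
#' @export
dna_content <- function(cells) {
  out <- rep(2, nrow(cells))
  s <- cells$phase == "S"
  out[s] <- 2 + 2 * pmin(cells$phase_elapsed[s] / cells$phase_duration[s], 1)
  out[cells$phase %in% c("G2", "M")] <- 4
  out
}

#' Diploid fraction of post-S cells
#'
#' Among EdU+BrdU- (post-S) cells, the percentage whose DNA content is below
#' the 2n/4n gate boundary, i.e. cells that completed cytokinesis and
#' returned to G1 since leaving S. The gate boundary at content 3.0 is a
#' package convention (real gates are drawn on a dye histogram).
#'
#' @param cells A tibble with `edu`, `brdu` and `dna_content` columns.
#' @param gate 2n/4n boundary on the DNA-content scale.
#' @return Percentage in `[0, 100]`; `NA` with a warning if there are no
#'   post-S cells.
#' @export
post_s_diploid_fraction <- function(cells, gate = 3) {
  post <- cells$edu & !cells$brdu
  if (!any(post)) {
    warning("no post-S cells: diploid fraction undefined", call. = FALSE)
    return(NA_real_)
  }
  100 * mean(cells$dna_content[post] < gate)
}

#' Subpopulation composition of CTV division compartments
#'
#' Mirrors division-tracking cytometry: cMyc+ cells are binned by divisions
#' since staining into `div4`, `div5`, `div6` and `div7+`, and within each
#' compartment the percentage contributed by every cMyc+ subpopulation is
#' reported. Percentages within a compartment sum to 100; empty compartments
#' are omitted.
#'
#' @param cells A tibble with `subpop` and `ctv_generation` columns (e.g.
#'   from [gc_cells()]).
#' @param min_div First tracked division compartment.
#' @param max_div Last single-division compartment; later generations are
#'   pooled as `"div<max_div + 1>+"`.
#' @return A tibble `compartment`, `subpop`, `n`, `percent`.
#' @export
ctv_composition <- function(cells, min_div = 4L, max_div = 6L) {
  pos <- dplyr::filter(tibble::as_tibble(cells),
                       .data$subpop != "NONE",
                       .data$ctv_generation >= min_div)
  if (!nrow(pos))
    return(tibble::tibble(compartment = character(), subpop = character(),
                          n = integer(), percent = numeric()))
  pos <- dplyr::mutate(pos, compartment = ifelse(
    .data$ctv_generation > max_div, paste0("div", max_div + 1L, "+"),
    paste0("div", .data$ctv_generation)))
  pos |>
    dplyr::count(.data$compartment, .data$subpop, name = "n") |>
    dplyr::group_by(.data$compartment) |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$compartment, .data$subpop)
}

#' Per-boundary transit of subpopulation shares across divisions
#'
#' For each subpopulation, the ratio and difference of its compartment share
#' between consecutive division compartments; a ratio near 0.5 means the
#' share halves per division round.
#'
#' @param composition A tibble `compartment`, `subpop`, `percent` (from
#'   [ctv_composition()] or a reference table).
#' @return A tibble `subpop`, `boundary`, `from_percent`, `to_percent`,
#'   `ratio`, `difference`. Ratios with a zero denominator are `NA`.
#' @export
transit_fractions <- function(composition) {
  comp <- dplyr::filter(tibble::as_tibble(composition),
                        !is.na(.data$percent))
  comps <- sort(unique(comp$compartment))
  if (length(comps) < 2L)
    stop("need at least two consecutive division compartments",
         call. = FALSE)
  comp |>
    dplyr::arrange(.data$subpop, .data$compartment) |>
    dplyr::group_by(.data$subpop) |>
    dplyr::reframe(
      boundary = paste0(utils::head(.data$compartment, -1L), "->",
                        utils::tail(.data$compartment, -1L)),
      from_percent = utils::head(.data$percent, -1L),
      to_percent = utils::tail(.data$percent, -1L),
      ratio = ifelse(from_percent == 0, NA_real_,
                     to_percent / from_percent),
      difference = to_percent - from_percent
    )
}
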