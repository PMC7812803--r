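# Model-selection harness: normalization, RSS, AICc, grid-search fitting of
# free timing parameters, and ranking of candidate topologies.

value_column <- function(tc) {
  for (cand in c("value", "count", "mean"))
    if (cand %in% names(tc)) return(cand)
  stop("time course needs a `value`, `count` or `mean` column",
       call. = FALSE)
}

#' Normalize a time course by a shared reference maximum
#'
#' All populations of one run or dataset are divided by a single reference:
#' the maximum of the simulated total-GC curve of the candidate under
#' evaluation. Ratios between populations at each time are therefore
#' preserved, and two datasets normalized by the same divisor remain
#' comparable.
#'
#' @param tc A tibble with `time_h`, `population` and a `value`/`count`/
#'   `mean` column.
#' @param reference_max Positive scalar divisor.
#' @return The tibble with a `value` column holding the normalized values.
#' @export
normalize_timecourse <- function(tc, reference_max) {
  if (!is.numeric(reference_max) || length(reference_max) != 1L ||
      !is.finite(reference_max) || reference_max <= 0)
    stop("`reference_max` must be a single positive number", call. = FALSE)
  col <- value_column(tc)
  dplyr::mutate(tibble::as_tibble(tc), value = .data[[col]] / reference_max)
}

# collapse a per-replicate long table to a mean curve (time_h, population,
# value); pass-through if already a single curve
mean_curve <- function(tc) {
  col <- value_column(tc)
  tc <- tibble::as_tibble(tc)
  if ("replicate" %in% names(tc) && length(unique(tc$replicate)) > 1L) {
    dplyr::summarise(dplyr::group_by(tc, .data$time_h, .data$population),
                     value = mean(.data[[col]]), .groups = "drop")
  } else {
    dplyr::transmute(tc, time_h = .data$time_h,
                     population = .data$population,
                     value = .data[[col]])
  }
}

#' Residual sum of squares between simulated and observed time courses
#'
#' Sums, over populations and observed time points, the squared difference
#' between the (linearly interpolated) simulated curve and the data. Both
#' inputs are expected on the same (normalized) scale. Every population in
#' `data` must be present in `sim`; simulated values outside the simulated
#' time range are clamped to the nearest endpoint.
#'
#' @param sim,data Tibbles with `time_h`, `population` and a value column.
#' @return A single nonnegative number.
#' @export
timecourse_rss <- function(sim, data) {
  sim <- mean_curve(sim)
  data <- mean_curve(data)
  missing <- setdiff(unique(data$population), unique(sim$population))
  if (length(missing))
    stop("population(s) missing from the simulation: ",
         paste(missing, collapse = ", "), call. = FALSE)
  total <- 0
  for (p in unique(data$population)) {
    s <- sim[sim$population == p, ]
    d <- data[data$population == p, ]
    shat <- if (nrow(s) == 1L) rep(s$value, nrow(d)) else
      stats::approx(s$time_h, s$value, xout = d$time_h, rule = 2)$y
    total <- total + sum((shat - d$value)^2)
  }
  total
}

#' Corrected Akaike information criterion for least-squares fits
#'
#' `n * log(rss / n) + 2k + 2k(k + 1) / (n - k - 1)`, the standard AICc for
#' a model with `k` free parameters fitted to `n` points by least squares.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Number of fitted data points.
#' @param k Number of free parameters.
#' @return A single number; `NA` with a warning when `n <= k + 1` (the
#'   correction is undefined).
#' @export
aicc <- function(rss, n, k) {
  if (n <= k + 1) {
    warning("AICc undefined: need n > k + 1", call. = FALSE)
    return(NA_real_)
  }
  if (!is.finite(rss) || rss <= 0)
    stop("`rss` must be positive and finite", call. = FALSE)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Grid-search fit of a topology's free parameters
#'
#' For every row of `grid`, the candidate topology/configuration is
#' simulated `replicates` times, replicate censuses are averaged, both the
#' simulation and the data are normalized by the candidate's own simulated
#' GC maximum, and the RSS against the data is recorded. The returned fit
#' holds the argmin point and its AICc. All grid points share the same
#' replicate seeds (common random numbers), so the fit is deterministic
#' given `seed`.
#'
#' Grid column names are matched against topology dwell parameters first,
#' then configuration fields. A simulation failure at a grid point is
#' recorded as a failed point (RSS `NA`), excluded from the argmin, and
#' reported as a warning.
#'
#' @param data Observed time course: tibble with `time_h`, `population` and
#'   a value column (per-replicate tables are averaged first).
#' @param topology A [gc_topology()] candidate.
#' @param grid Data frame of candidate parameter points (one per row).
#' @param config A [gc_config()].
#' @param replicates Simulations per grid point.
#' @param seed Integer base seed.
#' @param days Simulated days per run; defaults to covering the data.
#' @param populations Populations entering the RSS; default: all populations
#'   present in the data.
#' @return An object of class `gc_fit`.
#' @export
fit_topology <- function(data, topology, grid, config,
                         replicates = 20L, seed = 1L, days = NULL,
                         populations = NULL) {
  grid <- tibble::as_tibble(grid)
  if (!nrow(grid)) stop("`grid` must contain at least one point",
                        call. = FALSE)
  data <- mean_curve(data)
  if (!is.null(populations))
    data <- dplyr::filter(data, .data$population %in% populations)
  if (is.null(days)) days <- ceiling(max(data$time_h) / 24)
  rss_vec <- rep(NA_real_, nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    rss_vec[gi] <- tryCatch({
      ap <- apply_point(config, topology, grid[gi, ])
      tc <- simulate_gc(ap$config, ap$topology, seed = seed,
                        replicates = replicates, days = days)
      sim <- mean_curve(tc)
      ref <- max(sim$value[sim$population == "gc"])
      timecourse_rss(normalize_timecourse(sim, ref),
                     normalize_timecourse(data, ref))
    }, error = function(e) {
      warning("grid point ", gi, " failed and was excluded: ",
              conditionMessage(e), call. = FALSE)
      NA_real_
    })
  }
  if (all(is.na(rss_vec)))
    stop("all grid points failed", call. = FALSE)
  best <- which.min(rss_vec)
  n <- nrow(data)
  k <- ncol(grid)
  structure(list(
    topology = topology$name,
    params = as.list(grid[best, ]),
    rss = rss_vec[best],
    n = n, k = k,
    aicc = aicc(rss_vec[best], n, k),
    grid_results = dplyr::mutate(grid, rss = rss_vec),
    replicates = replicates, seed = seed, days = days
  ), class = "gc_fit")
}

#' @export
print.gc_fit <- function(x, ...) {
  cat("<gc_fit> ", x$topology, ": RSS = ", signif(x$rss, 5),
      ", AICc = ", signif(x$aicc, 6), " (n = ", x$n, ", k = ", x$k, ")\n",
      sep = "")
  cat("  at ", paste(names(x$params), unlist(x$params), sep = " = ",
                     collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the grid of a fit
#'
#' @param x A `gc_fit`.
#' @param ... Unused.
#' @return The grid with one row per evaluated point and its RSS.
#' @method tidy gc_fit
#' @export
tidy.gc_fit <- function(x, ...) x$grid_results

#' One-row summary of a fit
#'
#' @param x A `gc_fit`.
#' @param ... Unused.
#' @method glance gc_fit
#' @export
glance.gc_fit <- function(x, ...) {
  tibble::tibble(topology = x$topology, rss = x$rss, k = x$k, n = x$n,
                 aicc = x$aicc, replicates = x$replicates)
}

#' Rank fitted candidate topologies
#'
#' Ascending AICc; ties are broken by lower RSS, then by topology name.
#'
#' @param fits A list of `gc_fit` objects (at least two).
#' @return A tibble `topology`, `rss`, `k`, `n`, `aicc`, `rank` (rank 1 =
#'   lowest AICc).
#' @export
rank_models <- function(fits) {
  if (length(fits) < 2L) stop("need at least two fits to rank",
                              call. = FALSE)
  tab <- dplyr::bind_rows(lapply(fits, glance))
  tab <- dplyr::arrange(tab, .data$aicc, .data$rss, .data$topology)
  dplyr::mutate(tab, rank = dplyr::row_number())
}
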