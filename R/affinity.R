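#' Shape-space affinity model
#'
#' The B-cell receptor (BCR) of every agent is a point on a small integer
#' lattice ("shape space"); antigen affinity is a Gaussian kernel of the
#' Euclidean distance to an optimal point. The model also carries the
#' association constant of the full-affinity reference BCR and the fold drop
#' of the mutant antigen used for high/low-affinity gating, so that a gate
#' expressed as a fraction of maximal affinity can be re-expressed on the
#' Ka scale.
#'
#' @param dimension Number of lattice dimensions (default 4).
#' @param extent Lattice side length `L`; coordinates live in `0:(L - 1)`.
#' @param gamma Kernel width in lattice units; affinity is
#'   `exp(-d^2 / gamma^2)` for distance `d` to the optimum.
#' @param optimum Integer vector of length `dimension`, the lattice position
#'   of maximal affinity. Default: lattice center.
#' @param k_high Association constant (1/M) of the full-affinity reference
#'   BCR-antigen pair.
#' @param fold_drop Fold reduction in affinity of the low-affinity (mutant)
#'   antigen relative to the reference.
#' @param high_low_threshold Fraction of maximal affinity at or above which a
#'   cell is gated "high" affinity (closed boundary: exactly at the threshold
#'   is high).
#' @return An object of class `affinity_model`.
#' @examples
#' m <- affinity_model()
#' affinity(tibble::tibble(x1 = 20, x2 = 20, x3 = 20, x4 = 22), m)
#' @export
affinity_model <- function(dimension = 4L, extent = 40L, gamma = 2.8,
                           optimum = NULL,
                           k_high = 2e10, fold_drop = 13000,
                           high_low_threshold = 0.5) {
  stopifnot(dimension >= 1, extent >= 2, gamma > 0, fold_drop > 1,
            high_low_threshold > 0, high_low_threshold <= 1)
  if (is.null(optimum)) optimum <- rep(as.integer(extent %/% 2), dimension)
  optimum <- as.integer(optimum)
  if (length(optimum) != dimension)
    stop("`optimum` must have length `dimension` (", dimension, ")",
         call. = FALSE)
  if (any(optimum < 0L | optimum > extent - 1L))
    stop("`optimum` must lie on the lattice [0, extent - 1]", call. = FALSE)
  structure(
    list(dimension = as.integer(dimension), extent = as.integer(extent),
         gamma = gamma, optimum = optimum, k_high = k_high,
         fold_drop = fold_drop, high_low_threshold = high_low_threshold),
    class = "affinity_model"
  )
}

#' @export
print.affinity_model <- function(x, ...) {
  cat("<affinity_model> ", x$dimension, "-D lattice, extent ", x$extent,
      ", gamma = ", x$gamma, "\n", sep = "")
  cat("  reference Ka = ", format(x$k_high, scientific = TRUE),
      " 1/M; low-antigen fold drop = ", x$fold_drop,
      " (effective low Ka = ",
      format(x$k_high / x$fold_drop, scientific = TRUE, digits = 3), " 1/M)\n",
      sep = "")
  cat("  high/low gate at ", x$high_low_threshold, " of maximal affinity\n",
      sep = "")
  invisible(x)
}

#' Effective association constant of the low-affinity scenario
#'
#' `k_high / fold_drop`: the Ka with which the reference BCR binds the mutant
#' antigen used for affinity gating.
#' @param model An [affinity_model()].
#' @return A single number (1/M).
#' @export
k_low <- function(model) {
  stopifnot(inherits(model, "affinity_model"))
  model$k_high / model$fold_drop
}

# Coerce positions given as tibble/data.frame/matrix/vector to an integer
# matrix with one row per cell, checking dimension and lattice bounds.
position_matrix <- function(pos, model) {
  if (is.data.frame(pos)) pos <- as.matrix(pos)
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = 1L)
  storage.mode(pos) <- "integer"
  if (ncol(pos) != model$dimension)
    stop("position dimension (", ncol(pos), ") does not match the model (",
         model$dimension, ")", call. = FALSE)
  if (any(pos < 0L | pos > model$extent - 1L, na.rm = TRUE))
    stop("positions must lie on the lattice [0, extent - 1]", call. = FALSE)
  pos
}

#' Affinity of shape-space positions
#'
#' @param positions A data frame, matrix, or single vector of integer lattice
#'   coordinates (one row per cell, `dimension` columns).
#' @param model An [affinity_model()].
#' @return Numeric vector of affinities in `[0, 1]`, one per row; 1 exactly at
#'   the optimum and strictly decreasing with distance.
#' @export
affinity <- function(positions, model) {
  pos <- position_matrix(positions, model)
  d2 <- rowSums((sweep(pos, 2L, model$optimum))^2)
  exp(-d2 / model$gamma^2)
}

#' Classify positions into high and low affinity gates
#'
#' A cell is "high" iff its affinity is at or above
#' `model$high_low_threshold` (closed boundary).
#'
#' @inheritParams affinity
#' @return Character vector, `"high"` or `"low"` per row.
#' @export
classify_affinity <- function(positions, model) {
  ifelse(affinity(positions, model) >= model$high_low_threshold,
         "high", "low")
}

#' Somatic hypermutation step on the lattice
#'
#' With probability `p_mut` per row, one uniformly chosen coordinate moves by
#' plus or minus one lattice unit, clamped to the lattice boundary (so a
#' boundary cell may mutate "in place"). At most one coordinate changes.
#'
#' @inheritParams affinity
#' @param p_mut Per-cell mutation probability in `[0, 1]`.
#' @return A tibble of mutated coordinates with the input column names (or
#'   `x1...xD` if the input was unnamed).
#' @export
mutate_positions <- function(positions, p_mut, model) {
  stopifnot(p_mut >= 0, p_mut <= 1)
  pos <- position_matrix(positions, model)
  nm <- colnames(pos)
  pos <- mutate_matrix(pos, p_mut, model)
  colnames(pos) <- if (is.null(nm)) paste0("x", seq_len(ncol(pos))) else nm
  tibble::as_tibble(pos)
}

# In-place matrix version used by the simulator hot path.
mutate_matrix <- function(pos, p_mut, model) {
  n <- nrow(pos)
  if (n == 0L || p_mut <= 0) return(pos)
  hit <- stats::runif(n) < p_mut
  if (!any(hit)) return(pos)
  idx <- which(hit)
  coord <- sample.int(ncol(pos), length(idx), replace = TRUE)
  step <- sample(c(-1L, 1L), length(idx), replace = TRUE)
  flat <- idx + (coord - 1L) * n
  pos[flat] <- pmin(pmax(pos[flat] + step, 0L), model$extent - 1L)
  pos
}

#' Random founder positions at a given distance band from the optimum
#'
#' Founders are drawn uniformly from lattice points whose Euclidean distance
#' to the optimum lies in `[d_min, d_max]`, i.e. all founders start below
#' maximal affinity (rejection sampling near the optimum).
#'
#' @param n Number of positions.
#' @param model An [affinity_model()].
#' @param d_min,d_max Distance band (lattice units).
#' @return Integer matrix `n x dimension`.
#' @export
founder_positions <- function(n, model, d_min = 3, d_max = 5) {
  stopifnot(n >= 1, d_min >= 1, d_max >= d_min)
  out <- matrix(NA_integer_, nrow = n, ncol = model$dimension)
  filled <- 0L
  while (filled < n) {
    m <- max(2L * (n - filled), 16L)
    # propose within a cube of half-width d_max around the optimum
    prop <- sapply(seq_len(model$dimension), function(j) {
      v <- model$optimum[j] +
        sample.int(2L * ceiling(d_max) + 1L, m, replace = TRUE) -
        (ceiling(d_max) + 1L)
      pmin(pmax(v, 0L), model$extent - 1L)
    })
    d <- sqrt(rowSums(sweep(prop, 2L, model$optimum)^2))
    ok <- which(d >= d_min & d <= d_max)
    take <- utils::head(ok, n - filled)
    if (length(take)) {
      out[filled + seq_along(take), ] <- prop[take, , drop = FALSE]
      filled <- filled + length(take)
    }
  }
  colnames(out) <- paste0("x", seq_len(model$dimension))
  out
}
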