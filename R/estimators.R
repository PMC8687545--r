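#' Time-averaged MSD with overlapping windows
#'
#' For positions `x_0, ..., x_N` at evenly spaced events and lag `k`,
#' \deqn{\mathrm{TAMSD}_1(k) = \frac{1}{N-k+1}\sum_{i=0}^{N-k}
#'   \|x_{i+k} - x_i\|^2.}
#' Well averaged for small `k`, but successive overlapping displacements
#' are not independent.
#'
#' @param positions `(N + 1) x 2` matrix of ordered planar positions, or a
#'   `centroid_trajectory`.
#' @param k Event lag, `1 <= k <= N` (default 1).
#' @return Non-negative scalar.
#' @export
tamsd_overlapping <- function(positions, k = 1L) {
  x <- trajectory_positions(positions)
  N <- nrow(x) - 1L
  if (k < 1L || k > N) stop("lag 'k' must lie in [1, N]", call. = FALSE)
  d <- x[(1L + k):(N + 1L), , drop = FALSE] - x[1L:(N - k + 1L), , drop = FALSE]
  mean(rowSums(d^2))
}

#' Time-averaged MSD with disjoint windows
#'
#' \deqn{\mathrm{TAMSD}_2(k) = \frac{1}{\lfloor N/k\rfloor}
#'   \sum_{i=0}^{\lfloor N/k\rfloor - 1}\|x_{(i+1)k} - x_{ik}\|^2.}
#' Displacements are non-overlapping, hence uncorrelated windows; equal to
#' [tamsd_overlapping()] at `k = 1`.  This is the estimator used when a
#' simulated trajectory is compared against the analytic MSD.
#'
#' @inheritParams tamsd_overlapping
#' @return Non-negative scalar.
#' @export
tamsd_disjoint <- function(positions, k = 1L) {
  x <- trajectory_positions(positions)
  N <- nrow(x) - 1L
  if (k < 1L) stop("lag 'k' must be >= 1", call. = FALSE)
  m <- N %/% k
  if (m == 0L) stop("trajectory too short for lag 'k'", call. = FALSE)
  idx <- seq(0L, m) * k + 1L
  d <- x[idx[-1L], , drop = FALSE] - x[idx[-(m + 1L)], , drop = FALSE]
  mean(rowSums(d^2))
}

#' Ensemble-averaged MSD
#'
#' Over `P` realisations, `EAMSD(tau) = (1/P) sum_j ||x^j(tau) - x^j(0)||^2`.
#'
#' @param trajectories List of position matrices or `centroid_trajectory`
#'   objects, each with more than `tau` recorded events.
#' @param tau Integer event lag.
#' @return Non-negative scalar.
#' @export
eamsd <- function(trajectories, tau = 1L) {
  if (length(trajectories) == 0L) stop("empty ensemble", call. = FALSE)
  d2 <- vapply(trajectories, function(tr) {
    x <- trajectory_positions(tr)
    if (nrow(x) <= tau) stop("trajectory shorter than 'tau'", call. = FALSE)
    sum((x[tau + 1L, ] - x[1L, ])^2)
  }, numeric(1))
  mean(d2)
}

#' Mean per-event displacement of a trajectory
#'
#' `(1/N) sum_i (x_{i+1} - x_i) = (x_N - x_0) / N`; the empirical
#' counterpart of [mean_jump()].
#'
#' @inheritParams tamsd_overlapping
#' @return Length-2 numeric vector.
#' @export
mean_step_displacement <- function(positions) {
  x <- trajectory_positions(positions)
  N <- nrow(x) - 1L
  if (N < 1L) stop("need at least one displacement", call. = FALSE)
  (x[N + 1L, ] - x[1L, ]) / N
}
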