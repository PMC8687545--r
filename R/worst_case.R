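#' Worst-case centroid displacement of a detach event
#'
#' If every attached FA sits at the extremal position `eta_max (n - 1)`
#' except one at the origin, detaching the origin site from a state of `k`
#' attachments moves the centroid by `eta_max (n - 1) / k`.  At `k = n`
#' this is the global worst case `eta_max (n - 1) / n`.
#'
#' @param n Total number of FAs.
#' @param k Attachment count before the detachment, `2 <= k <= n`
#'   (vectorised).  A `k = 1` detachment freezes the centroid and is
#'   excluded.
#' @param eta_max Maximal outreach length.
#' @return Displacement bound(s).
#' @export
max_detach_displacement <- function(n, k, eta_max) {
  stopifnot(n >= 2, all(k >= 2 & k <= n), eta_max >= 0)
  eta_max * (n - 1) / k
}

#' Worst-case FA placement recurrence
#'
#' In the one-dimensional worst case every new FA attaches at the maximal
#' outreach from the mean of its predecessors, giving the linear recurrence
#' \deqn{x_t = \frac{x_{t-1} + \dots + x_{t-n+2}}{n-1} + \eta_{max}}
#' (the window holds `n - 2` previous positions; the pinned site `x_1 = 0`
#' is absorbed into the divisor).  The recurrence converges to the fixed
#' point `x* = eta_max (n - 1)` from any start.
#'
#' @param n Total number of FAs, `n >= 3` (the window is empty below that).
#' @param eta_max Maximal outreach length.
#' @param x_init Initial window values, recycled to length `n - 2`
#'   (default 0).
#' @param steps Number of iterates to produce.
#' @return Numeric vector of the `steps` successive positions `x_t`.
#' @examples
#' recurrence_trajectory(3, 1, steps = 5)   # 1, 1.5, 1.75, 1.875, 1.9375
#' @export
recurrence_trajectory <- function(n, eta_max, x_init = 0, steps = 100L) {
  stopifnot(steps >= 1)
  if (n < 3) stop("the recurrence needs n >= 3", call. = FALSE)
  w <- rep_len(as.numeric(x_init), n - 2L)
  out <- numeric(steps)
  for (t in seq_len(steps)) {
    xt <- sum(w) / (n - 1) + eta_max
    out[t] <- xt
    if (n > 3L) w <- c(xt, w[seq_len(n - 3L)]) else w <- xt
  }
  out
}

#' Fixed point of the worst-case recurrence
#'
#' `x* = eta_max (n - 1)`: the attracting steady state of
#' [recurrence_trajectory()].
#'
#' @param n Total number of FAs (>= 2).
#' @param eta_max Maximal outreach length.
#' @return The fixed point.
#' @export
recurrence_fixed_point <- function(n, eta_max) {
  stopifnot(n >= 2, eta_max >= 0)
  eta_max * (n - 1)
}

#' Characteristic roots of the worst-case recurrence
#'
#' Roots of `(n - 1) lambda^(n-2) = lambda^(n-3) + ... + lambda + 1`.
#' Exactly one root is real and positive (Descartes' rule), and every root
#' lies strictly inside the unit circle, which is what makes the fixed
#' point attracting.
#'
#' @param n Total number of FAs, `n >= 3`.
#' @return A list with `roots` (complex vector) and `zeta` (the unique
#'   positive real root, in `(0, 1)`).
#' @examples
#' characteristic_roots(3)$zeta   # 0.5
#' @export
characteristic_roots <- function(n) {
  if (n < 3) stop("the recurrence needs n >= 3", call. = FALSE)
  # ascending coefficients of (n-1) x^(n-2) - x^(n-3) - ... - x - 1
  coefs <- c(rep(-1, n - 2L), n - 1)
  roots <- polyroot(coefs)
  pos <- which(abs(Im(roots)) < 1e-8 & Re(roots) > 0)
  if (length(pos) != 1L)
    stop("expected exactly one positive real root", call. = FALSE)
  list(roots = roots, zeta = Re(roots[pos]))
}

#' Limiting worst-case displacement
#'
#' As the recurrence approaches its fixed point, a detachment of the pinned
#' site from the fully attached state displaces the centroid by
#' `eta_max (n - 1) / n` -- the supremum of `||c^{j+1} - c^j||`, attained
#' in the limit.
#'
#' @inheritParams recurrence_fixed_point
#' @return The limiting displacement.
#' @export
limiting_displacement <- function(n, eta_max) {
  stopifnot(n >= 2, eta_max >= 0)
  eta_max * (n - 1) / n
}

#' Upper bound on the MSD at one event lag
#'
#' Partitions the event space into attach events (exact contributions, as
#' in [amsd()]), detach events from a provably sequential configuration
#' (sequential displacement algebra weighted by
#' [sequential_path_probability()], as in [lower_bound_msd()]), and detach
#' events from any other configuration, which are charged the worst-case
#' displacement `eta_max (n - 1) / k` with the leftover probability
#' `max(0, k pi_k p_k - P_k^d)`:
#' \deqn{\mathrm{UB} = \mathrm{LB} + \sum_{k=2}^{n}
#'   \max(0,\, k\pi_k p_k - P_k^d)\Big(\frac{\eta_{max}(n-1)}{k}\Big)^2.}
#' Coarse by construction (the worst case is a rare event carried with a
#' large probability), but a genuine bound: `LB <= AMSD <= UB`.
#'
#' @inheritParams mean_jump
#' @return Non-negative scalar.
#' @examples
#' upper_bound_msd(2, 1, outreach_distribution())   # 175/12
#' @export
upper_bound_msd <- function(n, r, dist, weights = NULL) {
  check_nr(n, r)
  check_equal_weights(weights)
  ub <- lower_bound_msd(n, r, dist)
  if (n >= 2L) {
    k <- 2:n
    pik <- stationary_distribution(n, r)[k + 1L]
    pk <- switch_probability(n, r, k)
    pseq <- sequential_path_probability(n, r, k)
    nonseq <- pmax(0, k * pik * pk - pseq)
    ub <- ub + sum(nonseq * max_detach_displacement(n, k,
                                                    outreach_max_length(dist))^2)
  }
  ub
}
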