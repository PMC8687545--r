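#' Per-FA switching probability
#'
#' With `k` of `n` FAs attached, each attached FA changes status at the next
#' event with probability `p_k = 1 / (k + (n - k) r)` and each detached FA
#' with probability `r p_k`.  The total over all FAs,
#' `k p_k + (n - k) r p_k`, is exactly 1: some FA switches at every event.
#'
#' @param n Total number of FAs.
#' @param r Propensity ratio (> 0).
#' @param k Number of attached FAs, `0 <= k <= n` (vectorised).
#' @return `p_k`, the probability that a *given* attached FA detaches
#'   (equivalently `r p_k` is that a given detached FA attaches).
#' @examples
#' switch_probability(5, 1, 0:5)   # all 0.2
#' @export
switch_probability <- function(n, r, k) {
  check_nr(n, r)
  if (any(k < 0 | k > n)) stop("'k' must lie in [0, n]", call. = FALSE)
  1 / (k + (n - k) * r)
}

#' Probability that the next event is an attachment
#'
#' `(n - k) r p_k`; the complement `k p_k` is the detach probability.
#' Equals 1 at `k = 0` (an attachment is forced) and 0 at `k = n`.
#'
#' @inheritParams switch_probability
#' @return Attachment probability in `[0, 1]` (vectorised over `k`).
#' @export
attach_probability <- function(n, r, k) {
  (n - k) * r * switch_probability(n, r, k)
}

#' Stationary distribution of the attachment count
#'
#' The attachment count is a birth--death chain on `{0, ..., n}` with birth
#' probability `(n - k) r p_k` and death probability `k p_k`.  Its globally
#' attracting stationary distribution is
#' \deqn{\pi_0 = \frac{1}{2(1+r)^{n-1}}, \qquad
#'       \pi_k = \frac{r^{k-1}\binom{n-1}{k-1}[k + (n-k)r]}{2(1+r)^{n-1}k},
#'       \ 1 \le k \le n.}
#'
#' @inheritParams switch_probability
#' @return Numeric vector `c(pi_0, ..., pi_n)` summing to 1.
#' @examples
#' stationary_distribution(5, 1)   # c(1, 5, 10, 10, 5, 1) / 32
#' @export
stationary_distribution <- function(n, r) {
  check_nr(n, r)
  k <- seq_len(n)
  pk <- r^(k - 1) * choose(n - 1, k - 1) * (k + (n - k) * r) /
    (2 * (1 + r)^(n - 1) * k)
  c(1 / (2 * (1 + r)^(n - 1)), pk)
}

#' Mean centroid displacement per binding event
#'
#' Closed-form first moment of the one-event centroid jump under the
#' stationary-compatible initial distribution:
#' \deqn{E[c^{j+1}-c^j] = \Big(1 + \sum_{k=1}^{n}
#'   \big(r^{k-1}(1-r)\tbinom{n-1}{k-1} + r^k\tbinom{n}{k}\big)
#'   \frac{r(n-k)}{(k+r(n-k))(k+1)}\Big)\frac{E_\nu[\eta]}{2(1+r)^{n-1}}.}
#' Only attach events move the mean: detach displacements from a symmetric
#' creation story average out except through the attach-biased terms.
#'
#' @inheritParams switch_probability
#' @param dist An [outreach_distribution()].
#' @param weights Optional spring weights; anything unequal is rejected
#'   because the formula assumes the unweighted mean.
#' @return Length-2 numeric vector, `E[c^{j+1} - c^j]`.
#' @examples
#' mean_jump(2, 1, outreach_distribution())   # (3/8) * c(15/pi, 0)
#' @export
mean_jump <- function(n, r, dist, weights = NULL) {
  check_nr(n, r)
  check_equal_weights(weights)
  k <- seq_len(n)
  s <- sum((r^(k - 1) * (1 - r) * choose(n - 1, k - 1) +
              r^k * choose(n, k)) *
             (r * (n - k)) / ((k + r * (n - k)) * (k + 1)))
  (1 + s) / (2 * (1 + r)^(n - 1)) * outreach_mean_vector(dist)
}

#' Centroid displacement of an attach event
#'
#' Going from `k - 1` to `k` attached FAs with outreach `eta`, the centroid
#' moves by `eta / k` (the new site enters the mean of `k` points).
#'
#' @param k Attachment count after the event, `1 <= k <= n`.
#' @param eta Outreach vector (length-2) or matrix of outreach vectors.
#' @return Displacement(s), same shape as `eta`.
#' @export
attach_displacement <- function(k, eta) {
  stopifnot(k >= 1)
  eta / k
}

#' Expected squared displacement of an attach event
#'
#' `E[||c^{j+1} - c^j||^2] = E[||eta||^2] / k^2` for the event that brings
#' the attachment count up to `k`.
#'
#' @param k Attachment count after the event (vectorised).
#' @param dist An [outreach_distribution()].
#' @return Non-negative scalar (or vector over `k`).
#' @export
attach_expectation <- function(k, dist) {
  stopifnot(all(k >= 1))
  outreach_mean_square(dist) / k^2
}

#' Summed expected squared displacement over the detach possibilities
#'
#' For a sequential configuration of `k >= 2` attached FAs there are `k`
#' detach possibilities (see [detach_possibilities()]).  Summing
#' `E[||c^{j+1} - c^j||^2]` over all of them, with outreach cross terms
#' dropped, gives
#' \deqn{\frac{1}{(k-1)^2}\sum_{i=1}^{k-1}\frac{i\,E_\nu[\|\eta\|^2]}{i+1}.}
#' This is the *sum* over the `k` possibilities, each of which carries the
#' per-FA probability `p_k` in the AMSD assembly, not their average.  The
#' dropped cross terms vanish exactly for an isotropic (mean-zero) angle
#' law; for a biased law the expression is the same deliberate
#' approximation that underlies the AMSD.
#'
#' @param k Attachment count before the detach event, `k >= 2` (vectorised).
#' @param dist An [outreach_distribution()].
#' @return Non-negative scalar (or vector over `k`).
#' @examples
#' detach_sum_expectation(2, outreach_distribution())   # (100/3) / 2
#' @export
detach_sum_expectation <- function(k, dist) {
  stopifnot(all(k >= 2))
  E2 <- outreach_mean_square(dist)
  vapply(k, function(kk) {
    i <- seq_len(kk - 1)
    sum(i / (i + 1)) * E2 / (kk - 1)^2
  }, numeric(1))
}

#' Approximate MSD at one event lag (AMSD)
#'
#' The closed-form estimate of `E[||c^{j+1} - c^j||^2]` obtained by using
#' the exact attach displacements for every state and the
#' sequential-configuration detach displacements with full state-space
#' probabilities:
#' \deqn{\mathrm{AMSD}(1) = \frac{E_\nu[\|\eta\|^2]}{2(1+r)^{n-1}}
#'   \Big(1 + \sum_{k=1}^{n-1}\binom{n-1}{k} r^k\Big[\frac{1}{(k+1)^2}
#'   + \frac{1}{(k+1)k^2}\sum_{i=1}^{k}\frac{i}{i+1}\Big]\Big).}
#' For `n = 2` this is exact and equals [exact_msd_small_n()].
#'
#' @inheritParams mean_jump
#' @return Non-negative scalar.
#' @examples
#' amsd(2, 1, outreach_distribution())   # 12.5
#' @export
amsd <- function(n, r, dist, weights = NULL) {
  check_nr(n, r)
  check_equal_weights(weights)
  E2 <- outreach_mean_square(dist)
  if (n == 1L) return(E2 / 2)
  k <- seq_len(n - 1)
  inner <- vapply(k, function(kk) sum(seq_len(kk) / (seq_len(kk) + 1)),
                  numeric(1))
  s <- sum(choose(n - 1, k) * r^k *
             (1 / (k + 1)^2 + inner / ((k + 1) * k^2)))
  E2 / (2 * (1 + r)^(n - 1)) * (1 + s)
}

#' Exact MSD at one event lag for one or two focal adhesions
#'
#' For `n = 1` the only displacement is the outreach after full detachment,
#' giving `E[||eta||^2] / 2`.  For `n = 2` every configuration is
#' sequential, so direct enumeration of all transitions yields
#' `E[||eta||^2] (1 + r/2) / (2(1+r))`.
#'
#' @param n 1 or 2.
#' @inheritParams mean_jump
#' @return Non-negative scalar.
#' @export
exact_msd_small_n <- function(n, r, dist) {
  check_nr(n, r)
  E2 <- outreach_mean_square(dist)
  if (n == 1L) E2 / 2
  else if (n == 2L) E2 * (1 + r / 2) / (2 * (1 + r))
  else stop("exact enumeration is available only for n = 1 or 2", call. = FALSE)
}

#' Probability of a coinciding sequential history followed by a detachment
#'
#' The probability of reaching `k` attachments by a history identical to a
#' sequential creation story (attach, attach, ..., never detach) and then
#' detaching one FA:
#' \deqn{P_k^d(r) = \pi_0\, k\, r^k\, p_0 p_1 \cdots p_k\, \frac{n!}{(n-k)!}.}
#' As `r -> 0`, `P_1^d -> 1/2` and `P_k^d -> 0` for `k >= 2`; as
#' `r -> Inf` all `P_k^d -> 0`.
#'
#' @inheritParams switch_probability
#' @param k Attachment count reached, `1 <= k <= n` (vectorised).
#' @return Probability (or vector over `k`).
#' @examples
#' sequential_path_probability(5, 1, 1)   # 1/160
#' @export
sequential_path_probability <- function(n, r, k) {
  check_nr(n, r)
  if (any(k < 1 | k > n)) stop("'k' must lie in [1, n]", call. = FALSE)
  pi0 <- 1 / (2 * (1 + r)^(n - 1))
  vapply(k, function(kk) {
    p <- switch_probability(n, r, 0:kk)
    pi0 * kk * r^kk * prod(p) * prod(seq.int(n - kk + 1, n))
  }, numeric(1))
}

#' Lower bound on the MSD at one event lag
#'
#' Keeps the exact attach contributions of the AMSD but credits detach
#' events only when the configuration provably is sequential -- i.e. with
#' the coinciding-history probability [sequential_path_probability()] in
#' place of the full state probability, and zero for everything unknown:
#' \deqn{\mathrm{LB} = [\text{attach part of AMSD}] +
#'   \sum_{k=2}^{n} \frac{P_k^d(r)}{k}\,
#'   \Big[\text{detach sum expectation}\Big]_k.}
#' `LB <= AMSD` term by term.
#'
#' @inheritParams mean_jump
#' @return Non-negative scalar.
#' @examples
#' lower_bound_msd(2, 1, outreach_distribution())   # 275/24
#' @export
lower_bound_msd <- function(n, r, dist, weights = NULL) {
  check_nr(n, r)
  check_equal_weights(weights)
  lb <- amsd_attach_part(n, r, dist)
  if (n >= 2L) {
    k <- 2:n
    lb <- lb + sum(sequential_path_probability(n, r, k) / k *
                     detach_sum_expectation(k, dist))
  }
  lb
}

# attach-event contribution shared by AMSD, LB and UB:
# pi_k * r p_k * (n - k) possibilities * E||eta||^2 / (k+1)^2, k = 0..n-1
amsd_attach_part <- function(n, r, dist) {
  E2 <- outreach_mean_square(dist)
  if (n == 1L) return(E2 / 2)
  k <- seq_len(n - 1)
  E2 / (2 * (1 + r)^(n - 1)) *
    (1 + sum(choose(n - 1, k) * r^k / (k + 1)^2))
}

#' Quadratic MSD approximation as a function of the event lag
#'
#' Treating the centroid process like a space- and time-homogeneous walk,
#' \deqn{\mathrm{MSD}(\tau) \approx \tau\,(\mathrm{AMSD}(1) - \|m\|^2)
#'   + \tau^2 \|m\|^2, \qquad m = E[c^1 - c^0],}
#' linear in `tau` for an isotropic outreach and quadratic when the
#' outreach is biased.  At `tau = 1` it reduces to [amsd()] exactly.  The
#' per-event jumps are not independent, so for `tau > 1` this is an
#' approximation, not an identity.
#'
#' @inheritParams mean_jump
#' @param tau Positive integer event lag (vectorised).
#' @return MSD estimate(s), same length as `tau`.
#' @export
msd_of_tau <- function(n, r, dist, tau, weights = NULL) {
  stopifnot(all(tau >= 1))
  m2 <- sum(mean_jump(n, r, dist, weights)^2)
  a <- amsd(n, r, dist, weights)
  tau * (a - m2) + tau^2 * m2
}

check_nr <- function(n, r) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != as.integer(n))
    stop("'n' must be a positive integer", call. = FALSE)
  if (length(r) != 1L || !is.finite(r) || r <= 0)
    stop("'r' must be a positive real", call. = FALSE)
  invisible(TRUE)
}
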