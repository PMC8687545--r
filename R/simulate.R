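#' Initialisation policy for the simulator
#'
#' The default (`circle_all_attached`) places the `n` FAs equally spaced on
#' a circle around the origin at a single random radius drawn uniformly
#' from `radius`, with every FA attached; the centroid then starts at the
#' origin.  `steady_state_count` uses the same circle but attaches only the
#' first `k` sites, with `k` drawn from the stationary attachment
#' distribution, for runs that want to skip most of the burn-in.
#'
#' @param mode `"circle_all_attached"` or `"steady_state_count"`.
#' @param radius Range of the uniform circle-radius law (default `[0, 10]`).
#' @return An object of class `init_policy`.
#' @export
init_policy <- function(mode = c("circle_all_attached", "steady_state_count"),
                        radius = c(0, 10)) {
  mode <- match.arg(mode)
  radius <- as.numeric(radius)
  stopifnot(length(radius) == 2L, radius[1] >= 0, radius[2] >= radius[1])
  structure(list(mode = mode, radius = radius), class = "init_policy")
}

# draws: 1 uniform (radius), plus 1 uniform (count) for steady_state_count
init_state <- function(params, init) {
  n <- params$n
  rad <- stats::runif(1, init$radius[1], init$radius[2])
  ang <- 2 * pi * (seq_len(n) - 1) / n
  v <- cbind(rad * cos(ang), rad * sin(ang), deparse.level = 0)
  if (n == 1L) v <- matrix(c(rad, 0), 1L, 2L)
  psi <- rep(1L, n)
  if (init$mode == "steady_state_count") {
    pi_k <- stationary_distribution(n, params$r)
    k0 <- findInterval(stats::runif(1), cumsum(pi_k)) # 0..n
    psi <- as.integer(seq_len(n) <= k0)
  }
  if (any(psi == 1L)) {
    cell_state(psi, v, weights = params$weights)
  } else {
    cell_state(psi, v, weights = params$weights, centroid = c(0, 0))
  }
}

#' Advance the centroid jump process by one binding event
#'
#' Implements one event of the discrete centroid model with a fixed,
#' documented draw order from the session RNG: (1) a standard uniform `u`
#' decides the event type -- attachment if `u < (n - k) r p` with
#' `p = 1/(k + (n - k) r)`, else detachment; (2) a uniform selects the FA
#' (uniformly among the detached FAs for an attach, among the attached for
#' a detach, by index order); for an attach event (3) the outreach length
#' and (4) angle are drawn and the FA is placed at that outreach from the
#' current centroid.  The centroid is then recomputed as the weighted mean
#' of the attached positions; if every FA is detached it does not move.
#'
#' @param state A [cell_state()].
#' @param params A [model_params()] (its `seed` field is ignored here; seed
#'   the session RNG yourself for reproducible stepping).
#' @param dist An [outreach_distribution()].
#' @return A list with the new `state` and a one-row `record` data frame
#'   (`event`, `kind`, `fa`, `attached`, `cx`, `cy`); the `event` counter
#'   is left `NA` for the caller to fill.
#' @export
step_event <- function(state, params, dist) {
  stopifnot(inherits(state, "cell_state"))
  n <- params$n
  k <- sum(state$psi)
  u <- stats::runif(1)
  if (u < attach_probability(n, params$r, k)) {
    cand <- which(state$psi == 0L)
    fa <- cand[pick_index(length(cand))]
    eta <- sample_outreach(dist, 1L)[1L, ]
    state$v[fa, ] <- state$centroid + eta
    state$psi[fa] <- 1L
    kind <- "attach"
  } else {
    cand <- which(state$psi == 1L)
    fa <- cand[pick_index(length(cand))]
    state$psi[fa] <- 0L
    kind <- "detach"
  }
  if (any(state$psi == 1L))
    state$centroid <- solve_centroid(state$v, state$psi, state$weights)
  list(state = state,
       record = data.frame(event = NA_integer_, kind = kind, fa = fa,
                           attached = sum(state$psi),
                           cx = state$centroid[1], cy = state$centroid[2]))
}

# uniform index in 1..m from a single draw, matching the C++ core
pick_index <- function(m) {
  min(m, floor(stats::runif(1) * m) + 1L)
}

#' Simulate the centroid jump process
#'
#' Runs the event-driven simulation: initialise per `init`, run `burn_in`
#' unrecorded events to wash out the initial condition, then record
#' `events` binding events.  Each event follows the draw order documented
#' in [step_event()]; the whole trajectory is a deterministic function of
#' `params$seed`.  The event loop is implemented in C++ and reproduces
#' repeated [step_event()] calls bitwise.
#'
#' @param params A [model_params()].
#' @param dist An [outreach_distribution()].
#' @param init An [init_policy()].
#' @return An object of class `centroid_trajectory`: a list with
#'   `records` (data frame `event`, `kind`, `fa`, `attached`, `cx`, `cy`),
#'   `x0` (centroid position at event 0, i.e. after burn-in),
#'   `final_state`, and the `params`, `dist`, `init` metadata.
#' @examples
#' traj <- simulate_centroid(model_params(5, 1, events = 100, seed = 1))
#' head(traj$records)
#' @export
simulate_centroid <- function(params, dist = outreach_distribution(),
                              init = init_policy()) {
  stopifnot(inherits(params, "model_params"),
            inherits(dist, "outreach_distribution"),
            inherits(init, "init_policy"))
  if (!is.null(params$seed)) set.seed(params$seed)
  st <- init_state(params, init)
  res <- sim_core(params$n, params$r, params$events, params$burn_in,
                  st$psi, st$v, st$centroid, st$weights,
                  dist$length$lo, dist$length$hi,
                  dist$angle_deg$lo, dist$angle_deg$hi)
  records <- data.frame(
    event = seq_len(params$events),
    kind = c("detach", "attach")[res$kind + 1L],
    fa = res$fa, attached = res$attached, cx = res$cx, cy = res$cy)
  final <- cell_state(res$psi, res$v, weights = params$weights,
                      centroid = res$centroid)
  structure(list(records = records, x0 = res$x0, final_state = final,
                 params = params, dist = dist, init = init),
            class = "centroid_trajectory")
}

#' @export
print.centroid_trajectory <- function(x, ...) {
  cat(sprintf(
    "Centroid trajectory: n = %d, r = %g, %d recorded events (burn-in %d)\n",
    x$params$n, x$params$r, nrow(x$records), x$params$burn_in))
  invisible(x)
}

#' Event-indexed centroid positions of a trajectory
#'
#' Returns the `(events + 1) x 2` matrix of centroid positions
#' `x_0, ..., x_N`, where `x_0` is the position at the end of the burn-in
#' and row `j + 1` the position after recorded event `j`.
#'
#' @param traj A `centroid_trajectory` (or a bare numeric matrix, returned
#'   unchanged).
#' @return Numeric matrix with two columns.
#' @export
trajectory_positions <- function(traj) {
  if (is.matrix(traj)) {
    stopifnot(ncol(traj) == 2L)
    return(traj)
  }
  stopifnot(inherits(traj, "centroid_trajectory"))
  rbind(traj$x0, cbind(traj$records$cx, traj$records$cy), deparse.level = 0)
}
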