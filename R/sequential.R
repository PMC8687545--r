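#' Sequential configuration of attached focal adhesions
#'
#' A configuration of `k` attached FAs is *sequential* if it can be reached
#' by attaching FAs one at a time, each at an outreach from the centroid of
#' the previously attached ones (its "creation story").  FA 1 sits at the
#' first centroid, so only the outreaches `eta_2, ..., eta_k` parameterise
#' the configuration.  Sequential configurations keep the FAs close
#' together and make the detach displacement computable in closed form.
#'
#' @param etas `(k - 1) x 2` numeric matrix whose rows are the
#'   creation-story outreaches `eta_2, ..., eta_k`; a `0 x 2` matrix (or
#'   `NULL`) gives the single-FA configuration `k = 1`.
#' @return An object of class `sequential_config` with fields `k` and `etas`.
#' @export
sequential_config <- function(etas = NULL) {
  if (is.null(etas)) etas <- matrix(numeric(0), 0L, 2L)
  etas <- as.matrix(etas)
  if (length(etas) == 2L && nrow(etas) == 2L) etas <- t(etas)
  stopifnot(ncol(etas) == 2L, all(is.finite(etas)))
  structure(list(k = nrow(etas) + 1L, etas = etas),
            class = "sequential_config")
}

as_sequential_config <- function(x) {
  if (inherits(x, "sequential_config")) x else sequential_config(x)
}

#' Build the cell state of a sequential configuration
#'
#' Starting from `v_1 = c_1 = 0`, each subsequent FA attaches at
#' `v_m = c_{m-1} + eta_m` and the centroid updates to
#' `c_m = c_{m-1} + eta_m / m`.  The returned state satisfies the
#' force-balance invariant by construction.
#'
#' @param config A [sequential_config()] or an outreach matrix accepted by it.
#' @return A [cell_state()] with all `k` FAs attached, positions in
#'   creation-story order, relative to `v_1 = 0`.
#' @export
build_sequential_state <- function(config) {
  config <- as_sequential_config(config)
  k <- config$k
  v <- matrix(0, k, 2L)
  cen <- c(0, 0)
  if (k >= 2L) {
    for (m in 2:k) {
      v[m, ] <- cen + config$etas[m - 1L, ]
      cen <- cen + config$etas[m - 1L, ] / m
    }
  }
  cell_state(psi = rep(1L, k), v = v)
}

#' Centroid displacements of the possible detach events
#'
#' For a sequential configuration with `k >= 2` attached FAs there are `k`
#' possible detachments.  In creation-story order, possibility
#' `l = 0, ..., k - 2` (FA `l + 1` detaching) displaces the centroid by
#' \deqn{\frac{1}{k-1}\Big[\sum_{i=0}^{k-(l+2)}\frac{\eta_{k-i}}{k-i}
#'   - \frac{l\,\eta_{l+1}}{l+1}\Big],}
#' and the last possibility (FA `k` detaching) by `-eta_k / k`.  Each entry
#' equals `(c_k - v_d) / (k - 1)` for the detaching site `d`, i.e. what one
#' gets by removing the site and re-averaging.
#'
#' @param config A [sequential_config()] (or outreach matrix) with `k >= 2`.
#' @return A `k x 2` matrix; row `d` is the centroid displacement when
#'   creation-story FA `d` detaches.
#' @examples
#' detach_possibilities(rbind(c(1, 0)))   # rbind(c(.5, 0), c(-.5, 0))
#' @export
detach_possibilities <- function(config) {
  config <- as_sequential_config(config)
  k <- config$k
  if (k < 2L) stop("detach displacements need k >= 2 attached FAs", call. = FALSE)
  eta <- function(m) config$etas[m - 1L, ]   # eta_m, m = 2..k
  out <- matrix(0, k, 2L)
  for (l in 0:(k - 2L)) {
    acc <- c(0, 0)
    for (i in 0:(k - (l + 2L))) acc <- acc + eta(k - i) / (k - i)
    if (l > 0L) acc <- acc - l * eta(l + 1L) / (l + 1L)
    out[l + 1L, ] <- acc / (k - 1L)
  }
  out[k, ] <- -eta(k) / k
  out
}
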