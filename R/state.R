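#' Cell state: attachment vector, FA positions, centroid
#'
#' A cell state consists of a binary attachment vector `psi` (1 = attached),
#' the planar positions `v` of all `n` focal adhesions, positive spring
#' weights `alpha`, and the centroid `c`.  Whenever at least one FA is
#' attached the centroid satisfies the force balance
#' `sum_i alpha_i psi_i (v_i - c) = 0`, i.e. it is the weighted mean of the
#' attached positions.  Detached FAs keep their last position until they
#' reattach.
#'
#' @param psi Integer/logical vector of length `n`; 1 or `TRUE` = attached.
#' @param v `n x 2` numeric matrix of FA positions.
#' @param weights Positive spring constants, recycled to length `n`;
#'   default all 1.
#' @param centroid Centroid position.  Required when no FA is attached
#'   (the force balance then leaves it free); otherwise computed from the
#'   attached positions and must not be supplied inconsistently.
#' @return An object of class `cell_state` with fields `psi`, `v`,
#'   `weights`, `centroid`.
#' @examples
#' st <- cell_state(psi = c(1, 1), v = rbind(c(0, 0), c(2, 0)))
#' st$centroid   # c(1, 0)
#' @export
cell_state <- function(psi, v, weights = 1, centroid = NULL) {
  psi <- as.integer(psi)
  v <- as.matrix(v)
  n <- length(psi)
  stopifnot(n >= 1L, all(psi %in% c(0L, 1L)),
            nrow(v) == n, ncol(v) == 2L, all(is.finite(v)))
  weights <- rep_len(as.numeric(weights), n)
  if (any(weights <= 0)) stop("spring weights must be positive", call. = FALSE)
  if (any(psi == 1L)) {
    centroid <- solve_centroid(v, psi = psi, weights = weights)
  } else if (is.null(centroid)) {
    stop("a centroid must be supplied when no FA is attached", call. = FALSE)
  }
  structure(list(psi = psi, v = v, weights = weights,
                 centroid = as.numeric(centroid)),
            class = "cell_state")
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("Cell state: %d/%d FAs attached, centroid (%.4g, %.4g)\n",
              sum(x$psi), length(x$psi), x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Centroid of the attached focal adhesions
#'
#' Solves the force balance `0 = sum_i alpha_i (c - v_i) psi_i` for the
#' centroid: the weighted mean of the attached positions.
#'
#' @param v `n x 2` matrix of FA positions (or only the attached ones).
#' @param psi Optional attachment indicator; if omitted all rows of `v`
#'   count as attached.
#' @param weights Positive weights, recycled to `nrow(v)`.
#' @return Length-2 centroid position.  Signals an error of class
#'   `centroidMSD_no_attachment` when no FA is attached, so that callers
#'   can keep the previous centroid.
#' @examples
#' solve_centroid(rbind(c(0, 0), c(2, 0)))                      # c(1, 0)
#' solve_centroid(rbind(c(0, 0), c(1, 0)), weights = c(1, 3))   # c(0.75, 0)
#' @export
solve_centroid <- function(v, psi = NULL, weights = 1) {
  v <- as.matrix(v)
  stopifnot(ncol(v) == 2L)
  n <- nrow(v)
  if (is.null(psi)) psi <- rep(1L, n)
  weights <- rep_len(as.numeric(weights), n)
  att <- which(psi == 1L | psi == TRUE)
  if (length(att) == 0L) {
    cond <- structure(
      class = c("centroidMSD_no_attachment", "error", "condition"),
      list(message = "no attached FA: centroid is undetermined",
           call = sys.call(-1)))
    stop(cond)
  }
  w <- weights[att]
  colSums(v[att, , drop = FALSE] * w) / sum(w)
}

#' Model parameters for the centroid jump process
#'
#' @param n Total number of focal adhesions (>= 1).
#' @param r Attach/detach propensity ratio (> 0): a detached FA switches with
#'   propensity `r` times that of an attached one, so per event the attach
#'   probability is `(n - k) r p` and the detach probability `k p` with
#'   `p = 1 / (k + (n - k) r)`.
#' @param events Number of recorded binding events (>= 0).
#' @param burn_in Unrecorded events run first to wash out the initial
#'   condition (default 10000, enough to reach the stationary attachment
#'   distribution for `n <= 10` over a wide range of `r`).
#' @param seed Optional integer seed; when non-`NULL`, [simulate_centroid()]
#'   seeds the session RNG with it so runs are bit-reproducible.
#' @param weights Spring constants, recycled to length `n`.
#' @return An object of class `model_params`.
#' @export
model_params <- function(n, r, events, burn_in = 10000L, seed = NULL,
                         weights = 1) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("'n' must be a positive integer", call. = FALSE)
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("'r' must be a positive real", call. = FALSE)
  events <- as.integer(events)
  burn_in <- as.integer(burn_in)
  if (is.na(events) || events < 0L) stop("'events' must be >= 0", call. = FALSE)
  if (is.na(burn_in) || burn_in < 0L) stop("'burn_in' must be >= 0", call. = FALSE)
  weights <- rep_len(as.numeric(weights), n)
  if (any(weights <= 0)) stop("spring weights must be positive", call. = FALSE)
  structure(list(n = n, r = r, events = events, burn_in = burn_in,
                 seed = if (!is.null(seed)) as.integer(seed), weights = weights),
            class = "model_params")
}

# analytic formulas assume the unweighted mean; reject anything else
check_equal_weights <- function(weights) {
  if (!is.null(weights) && length(weights) > 1L &&
      diff(range(weights)) > 0)
    stop("analytic MSD formulas require equal spring weights", call. = FALSE)
  invisible(TRUE)
}
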