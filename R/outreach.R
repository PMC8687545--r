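#' Outreach distribution of a newly attaching focal adhesion
#'
#' The outreach is the random planar vector from the current cell centroid to
#' the point where a detached focal adhesion (FA) reattaches.  It is specified
#' in polar form: a length law on `[0, L_max]` and an angle law on an angular
#' interval, with the angle measured counter-clockwise from the positive
#' x-axis in degrees.  Supported laws are `uniform` (a two-element range) and
#' `degenerate` (a single value); these are the laws for which all moments
#' used by the MSD theory have closed forms.
#'
#' The defaults -- length uniform on `[0, 10]`, angle uniform on
#' `[-30, 30]` degrees -- give a forward-biased outreach with
#' `E[eta] = (15/pi, 0)` and `E[||eta||^2] = 100/3`.
#'
#' @param length Either a length-2 numeric range `c(lo, hi)` for a uniform
#'   length law, or a single value for a degenerate (point-mass) law.
#'   Lengths must be non-negative and the maximum must be finite and positive.
#' @param angle_deg Angle law in degrees, same convention: range for uniform,
#'   single value for degenerate.
#' @return An object of class `outreach_distribution`.
#' @examples
#' nu <- outreach_distribution()                      # the default law
#' outreach_mean_vector(nu)                           # (15/pi, 0)
#' outreach_mean_square(nu)                           # 100/3
#' outreach_distribution(length = 5, angle_deg = 90)  # point mass at (0, 5)
#' @export
outreach_distribution <- function(length = c(0, 10), angle_deg = c(-30, 30)) {
  len <- as_law(length, "length")
  ang <- as_law(angle_deg, "angle_deg")
  if (len$lo < 0)
    stop("outreach lengths must be non-negative", call. = FALSE)
  if (!is.finite(len$hi) || len$hi <= 0)
    stop("maximum outreach length must be finite and positive", call. = FALSE)
  structure(list(length = len, angle_deg = ang),
            class = "outreach_distribution")
}

# normalise a user-supplied law description to list(law, lo, hi)
as_law <- function(x, what) {
  if (is.list(x) && !is.null(x$law)) {
    law <- match.arg(x$law, c("uniform", "degenerate"))
    if (law == "degenerate") x <- x$at else x <- c(x$lo, x$hi)
  }
  x <- as.numeric(x)
  if (length(x) == 1L) x <- c(x, x)
  if (length(x) != 2L || any(!is.finite(x)) || x[2] < x[1])
    stop("'", what, "' must be a single value or an increasing range c(lo, hi)",
         call. = FALSE)
  list(law = if (x[1] == x[2]) "degenerate" else "uniform",
       lo = x[1], hi = x[2])
}

#' @export
print.outreach_distribution <- function(x, ...) {
  fmt <- function(l) {
    if (l$law == "degenerate") sprintf("degenerate at %g", l$lo)
    else sprintf("uniform on [%g, %g]", l$lo, l$hi)
  }
  cat("Outreach distribution nu:\n",
      "  length   : ", fmt(x$length), "\n",
      "  angle    : ", fmt(x$angle_deg), " degrees\n", sep = "")
  invisible(x)
}

#' Maximal outreach length
#'
#' Upper end of the support of the outreach length law; the `eta_max` that
#' drives the worst-case displacement bound.
#'
#' @param dist An [outreach_distribution()].
#' @return A positive scalar.
#' @export
outreach_max_length <- function(dist) {
  stopifnot(inherits(dist, "outreach_distribution"))
  dist$length$hi
}

#' Sample outreach vectors
#'
#' Draws i.i.d. outreach vectors `(L cos(theta), L sin(theta))` from the
#' distribution `nu`, using the session RNG.  The draw order is fixed and
#' documented: for each sample the length is drawn first, then the angle.
#' Degenerate laws still consume a uniform draw so that the RNG stream does
#' not depend on the law type.
#'
#' @param dist An [outreach_distribution()].
#' @param n Number of samples.
#' @return An `n x 2` numeric matrix of planar vectors.
#' @export
sample_outreach <- function(dist, n = 1L) {
  stopifnot(inherits(dist, "outreach_distribution"), n >= 0)
  if (n == 0L) return(matrix(numeric(0), 0L, 2L))
  u <- stats::runif(2L * n)
  len <- dist$length
  ang <- dist$angle_deg
  L <- len$lo + (len$hi - len$lo) * u[seq(1L, 2L * n, by = 2L)]
  th <- (ang$lo + (ang$hi - ang$lo) * u[seq(2L, 2L * n, by = 2L)]) * (pi / 180)
  cbind(L * cos(th), L * sin(th), deparse.level = 0)
}

#' First moment of the outreach distribution
#'
#' Closed-form `E[eta] = E[L] * (E[cos theta], E[sin theta])`, using
#' `E[cos theta] = (sin b - sin a) / (b - a)` for an angle uniform on
#' `[a, b]` radians (and the analogous sine term).
#'
#' @param dist An [outreach_distribution()].
#' @return A length-2 numeric vector.
#' @examples
#' outreach_mean_vector(outreach_distribution())          # c(15/pi, 0)
#' outreach_mean_vector(outreach_distribution(angle_deg = c(0, 360)))  # c(0,0)
#' @export
outreach_mean_vector <- function(dist) {
  stopifnot(inherits(dist, "outreach_distribution"))
  EL <- law_mean(dist$length)
  a <- dist$angle_deg$lo * pi / 180
  b <- dist$angle_deg$hi * pi / 180
  if (a == b) {
    ec <- cos(a); es <- sin(a)
  } else {
    ec <- (sin(b) - sin(a)) / (b - a)
    es <- (cos(a) - cos(b)) / (b - a)
  }
  EL * c(ec, es)
}

#' Second moment of the outreach length
#'
#' `E[||eta||^2] = E[L^2]`, independent of the angle law.  For a length
#' uniform on `[0, L_max]` this is `L_max^2 / 3`.
#'
#' @param dist An [outreach_distribution()].
#' @return A non-negative scalar.
#' @export
outreach_mean_square <- function(dist) {
  stopifnot(inherits(dist, "outreach_distribution"))
  l <- dist$length
  if (l$law == "degenerate") l$lo^2 else (l$lo^2 + l$lo * l$hi + l$hi^2) / 3
}

law_mean <- function(l) if (l$law == "degenerate") l$lo else (l$lo + l$hi) / 2
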