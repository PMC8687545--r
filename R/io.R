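#' Write a trajectory to CSV
#'
#' Writes the recorded events as CSV with header
#' `event,kind,fa,attached,cx,cy`, positions serialised with 17 significant
#' digits so the round trip is lossless, and a JSON metadata sidecar
#' (`<path>.json`) holding the parameters, outreach distribution, seed and
#' the event-0 position.
#'
#' @param traj A `centroid_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "centroid_trajectory"))
  rec <- traj$records
  out <- data.frame(event = rec$event, kind = rec$kind, fa = rec$fa,
                    attached = rec$attached,
                    cx = sprintf("%.17g", rec$cx),
                    cy = sprintf("%.17g", rec$cy))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  meta <- list(
    params = list(n = traj$params$n, r = traj$params$r,
                  events = traj$params$events, burn_in = traj$params$burn_in,
                  seed = traj$params$seed, weights = traj$params$weights),
    outreach = list(length = list(law = traj$dist$length$law,
                                  lo = traj$dist$length$lo,
                                  hi = traj$dist$length$hi),
                    angle_deg = list(law = traj$dist$angle_deg$law,
                                     lo = traj$dist$angle_deg$lo,
                                     hi = traj$dist$angle_deg$hi)),
    init = list(mode = traj$init$mode, radius = traj$init$radius),
    x0 = traj$x0)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(path)
}

#' Read a trajectory CSV
#'
#' Reads a CSV written by [write_trajectory()] (metadata sidecar optional)
#' and validates it: exact header, strictly increasing event index, and an
#' attachment count that changes by exactly one per event (attach events
#' increment it, detach events decrement it).
#'
#' @param path CSV path.
#' @return A list with `positions` (the `(N + 1) x 2` matrix, the event-0
#'   row taken from the sidecar or, failing that, `NA`-free only from
#'   event 1 on), `records`, and `meta` (`NULL` when no sidecar exists).
#' @export
read_trajectory <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  expected <- c("event", "kind", "fa", "attached", "cx", "cy")
  if (!identical(header, expected))
    stop("malformed trajectory header: expected ",
         paste(expected, collapse = ","), call. = FALSE)
  rec <- utils::read.csv(path, colClasses = c(
    event = "integer", kind = "character", fa = "integer",
    attached = "integer", cx = "numeric", cy = "numeric"))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
  if (nrow(rec) > 0L) {
    if (any(diff(rec$event) <= 0L))
      stop("event index must be strictly increasing", call. = FALSE)
    dk <- diff(rec$attached)
    if (any(abs(dk) != 1L))
      stop("attachment count must change by exactly 1 per event",
           call. = FALSE)
    step <- ifelse(rec$kind == "attach", 1L, -1L)
    if (any(dk != step[-1L]))
      stop("event kind inconsistent with attachment count", call. = FALSE)
  }
  x0 <- if (!is.null(meta$x0)) as.numeric(meta$x0)
  pos <- cbind(rec$cx, rec$cy, deparse.level = 0)
  if (!is.null(x0)) pos <- rbind(x0, pos, deparse.level = 0)
  list(positions = pos, records = rec, meta = meta)
}
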