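#' Treatment arc geometry
#'
#' Describes one arc: the isocenter in support coordinates, the couch angle,
#' and the gantry interval. The gantry is traversed strictly increasing
#' modulo 360 from `gantry_start_deg` to `gantry_end_deg` (an arc written
#' 350 -> 10 passes through 0, never "the short way round"), matching how
#' clinical arc ranges are written. Equal start and end denote a
#' single-angle query.
#'
#' @param isocenter Length-3 numeric, isocenter in support coordinates, mm.
#' @param couch_deg Couch angle, degrees.
#' @param gantry_start_deg,gantry_end_deg Arc limits, degrees.
#' @param step_deg Sampling interval along the gantry, degrees (> 0,
#'   default 1).
#' @param collimator_deg Collimator angle, degrees (default 0; cannot affect
#'   clearances for a circular cone).
#' @return An `arc_spec` object.
#' @export
arc_spec <- function(isocenter = c(0, 0, 0), couch_deg = 0,
                     gantry_start_deg = 0, gantry_end_deg = 0,
                     step_deg = 1, collimator_deg = 0) {
  stopifnot(length(isocenter) == 3L, all(is.finite(isocenter)),
            is.finite(couch_deg), is.finite(gantry_start_deg),
            is.finite(gantry_end_deg), is.finite(step_deg), step_deg > 0)
  structure(list(isocenter = as.numeric(isocenter),
                 couch_deg = couch_deg %% 360,
                 gantry_start_deg = gantry_start_deg %% 360,
                 gantry_end_deg = gantry_end_deg %% 360,
                 step_deg = as.numeric(step_deg),
                 collimator_deg = collimator_deg %% 360),
            class = "arc_spec")
}

#' Gantry angles sampled along an arc
#'
#' Returns the sampled gantry angles in traversal order: `start`,
#' `start + step`, ... (modulo 360), plus the exact end angle when it does
#' not fall on the step grid. A zero-span arc yields the single start angle.
#'
#' @param arc An [arc_spec()].
#' @param step_deg Override of the arc's step, degrees.
#' @return Numeric vector of gantry angles in [0, 360), traversal order.
#' @export
arc_angles <- function(arc, step_deg = arc$step_deg) {
  stopifnot(inherits(arc, "arc_spec"), step_deg > 0)
  span <- (arc$gantry_end_deg - arc$gantry_start_deg) %% 360
  if (span == 0)
    return(arc$gantry_start_deg)
  k <- floor(span / step_deg + 1e-9)
  offs <- (0:k) * step_deg
  if (k * step_deg < span - 1e-9)
    offs <- c(offs, span)
  (arc$gantry_start_deg + offs) %% 360
}

#' @export
print.arc_spec <- function(x, ...) {
  cat(sprintf(
    "<arc_spec> iso (%.1f, %.1f, %.1f) mm, couch %.1f deg, gantry %.1f -> %.1f deg (step %g)\n",
    x$isocenter[1], x$isocenter[2], x$isocenter[3],
    x$couch_deg, x$gantry_start_deg, x$gantry_end_deg, x$step_deg))
  invisible(x)
}
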