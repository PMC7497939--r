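#' Select candidate collision points in the BEV projection
#'
#' A contour point can only limit the cone's clearance if it lies inside
#' the cone's radial footprint, padded by the detection margin: candidates
#' satisfy `sqrt(x^2 + y^2) <= R + detection_margin` (closed inequality) in
#' collimator coordinates.
#'
#' @param points A `point_cloud` in the `collimator` frame.
#' @param cone A [cone_spec()].
#' @param detection_margin_mm Radial padding, mm.
#' @return Integer indices of candidate points (possibly empty).
#' @export
radial_candidates <- function(points, cone, detection_margin_mm = 5) {
  assert_frame(points, "collimator", "points")
  stopifnot(inherits(cone, "cone_spec"), detection_margin_mm >= 0)
  r <- sqrt(points$xyz[, 1]^2 + points$xyz[, 2]^2)
  unname(which(r <= cone$radius_mm + detection_margin_mm))
}

#' Signed clearance from a point to the cone solid
#'
#' For a BEV point with radial distance `r = sqrt(x^2 + y^2)` and depth `z`
#' (positive toward the source), with cone radius `R`, face distance `D`
#' and body length `L`:
#' \itemize{
#'   \item `z <= D`, `r <= R`: clearance is the face gap `D - z`;
#'   \item `z <= D`, `r > R`: clearance is the distance to the face edge
#'     circle, `sqrt((r - R)^2 + (D - z)^2)`;
#'   \item `z > D` (and, for finite `L`, `z <= D + L`): the point is beside
#'     or inside the cone body -- a collision; the returned value is the
#'     negative penetration depth `-(z - D)`;
#'   \item `z > D + L` (finite `L` only): distance to the cylinder's top
#'     rim/face.
#' }
#' The negative branch deliberately flags every candidate point beyond the
#' face plane, including those in the detection annulus `R < r <= R + m`:
#' a point that close to the cone body at a depth beyond the face is
#' treated as a collision (conservative).
#'
#' Callers are expected to pass points that already passed
#' [radial_candidates()]; the function itself accepts any point.
#'
#' @param p Length-3 numeric (one BEV point), an n x 3 matrix, or a
#'   `point_cloud` in the `collimator` frame.
#' @param cone A [cone_spec()].
#' @return Numeric vector of signed clearances, mm (negative = collision).
#' @examples
#' bl <- cone_preset("brainlab_truebeam")
#' point_to_cone_clearance(c(0, 0, 216), bl)        # 50 mm face gap
#' point_to_cone_clearance(c(36.75, 0, 262), bl)    # 5 mm to the face edge
#' point_to_cone_clearance(c(0, 0, 270), bl)        # -4 mm: collision
#' @export
point_to_cone_clearance <- function(p, cone) {
  stopifnot(inherits(cone, "cone_spec"))
  if (inherits(p, "point_cloud")) {
    assert_frame(p, "collimator", "p")
    p <- p$xyz
  } else if (is.null(dim(p))) {
    stopifnot(length(p) == 3L)
    p <- matrix(as.numeric(p), nrow = 1L)
  }
  r <- unname(sqrt(p[, 1]^2 + p[, 2]^2))
  z <- unname(p[, 3])
  R <- cone$radius_mm
  D <- cone$face_distance_mm
  L <- cone$length_mm
  out <- numeric(length(z))
  beyond_tip <- is.finite(L) & z > D + L
  body <- !beyond_tip & z > D
  face <- z <= D & r <= R
  edge <- z <= D & r > R
  out[face] <- D - z[face]
  out[edge] <- sqrt((r[edge] - R)^2 + (D - z[edge])^2)
  out[body] <- -(z[body] - D)
  if (any(beyond_tip)) {
    dz <- z[beyond_tip] - (D + L)
    dr <- pmax(r[beyond_tip] - R, 0)
    out[beyond_tip] <- sqrt(dr^2 + dz^2)
  }
  out
}

# internal: one clearance sample at a fixed gantry angle, given the contour
# already positioned in the support frame
clearance_sample <- function(contour, arc, gantry_deg, cone, marg) {
  ang <- angle_set(arc$couch_deg, gantry_deg, arc$collimator_deg)
  bev <- bev_transform(contour, arc$isocenter, ang)
  idx <- radial_candidates(bev, cone, marg$detection_margin_mm)
  if (length(idx) == 0L) {
    return(data.frame(gantry_deg = gantry_deg, clearance_mm = Inf,
                      collision = FALSE, nearest_point_index = NA_integer_))
  }
  cl <- point_to_cone_clearance(bev$xyz[idx, , drop = FALSE], cone)
  j <- which.min(cl)  # first minimum in cloud order: deterministic ties
  data.frame(gantry_deg = gantry_deg, clearance_mm = cl[j],
             collision = cl[j] < 0, nearest_point_index = idx[j])
}

#' Clearance at a single couch/gantry combination
#'
#' Transforms the contour into the BEV frame at the arc's couch angle and
#' the requested gantry angle, selects candidate points, and returns the
#' minimum signed cone clearance over them. When no contour point lies
#' inside the padded radial footprint the clearance is `Inf` (the contour
#' cannot limit this angle) and no collision is flagged.
#'
#' @param contour A non-empty `point_cloud` in the `support` frame.
#' @param arc An [arc_spec()] carrying isocenter and couch angle.
#' @param cone A [cone_spec()].
#' @param margins A [margins()] object.
#' @param gantry_deg Gantry angle to evaluate; defaults to the arc's start
#'   angle.
#' @return One-row data frame with `gantry_deg`, `clearance_mm`,
#'   `collision`, `nearest_point_index`.
#' @export
clearance_at <- function(contour, arc, cone, margins = coneclear::margins(),
                         gantry_deg = arc$gantry_start_deg) {
  assert_frame(contour, "support", "contour")
  if (n_points(contour) == 0L) stop("empty contour")
  stopifnot(inherits(arc, "arc_spec"), inherits(cone, "cone_spec"),
            inherits(margins, "margins"), is.finite(gantry_deg))
  clearance_sample(contour, arc, gantry_deg %% 360, cone, margins)
}

#' Scan an arc at fixed gantry steps
#'
#' Evaluates [clearance_at()] at every step (default 1 degree) from the arc
#' start to the arc end, traversing strictly increasing modulo 360, with
#' the exact end angle appended when it is off the step grid. Records the
#' minimum clearance and the first gantry angle attaining it.
#'
#' @inheritParams clearance_at
#' @return An `arc_clearance` object: list with `samples` (data frame, one
#'   row per angle in traversal order), `min_clearance_mm`,
#'   `gantry_at_min_deg`, `any_collision`, plus the `arc`, `cone` and
#'   `margins` used.
#' @export
scan_arc <- function(contour, arc, cone, margins = coneclear::margins()) {
  assert_frame(contour, "support", "contour")
  if (n_points(contour) == 0L) stop("empty contour")
  stopifnot(inherits(arc, "arc_spec"), inherits(cone, "cone_spec"),
            inherits(margins, "margins"))
  gantry <- arc_angles(arc)
  rows <- lapply(gantry, function(g)
    clearance_sample(contour, arc, g, cone, margins))
  samples <- do.call(rbind, rows)
  rownames(samples) <- NULL
  i_min <- which.min(samples$clearance_mm)  # first occurrence on ties
  structure(list(samples = samples,
                 min_clearance_mm = samples$clearance_mm[i_min],
                 gantry_at_min_deg = samples$gantry_deg[i_min],
                 any_collision = any(samples$collision),
                 arc = arc, cone = cone, margins = margins),
            class = "arc_clearance")
}

#' @export
print.arc_clearance <- function(x, ...) {
  cat(sprintf("<arc_clearance> couch %.1f deg, %d gantry samples\n",
              x$arc$couch_deg, nrow(x$samples)))
  cat(sprintf("  min clearance %.2f mm at gantry %.1f deg%s\n",
              x$min_clearance_mm, x$gantry_at_min_deg,
              if (x$any_collision) "  [COLLISION]" else ""))
  invisible(x)
}

#' Collision-free gantry sub-arcs
#'
#' Extracts the maximal contiguous runs of sampled gantry angles whose
#' clearance is at least the safety margin. Intervals are reported as
#' `[gantry_lo, gantry_hi]` in traversal order (an interval may wrap
#' through 0 for wrapping arcs); the longest run is flagged.
#'
#' @param result An `arc_clearance` from [scan_arc()].
#' @param safety_margin_mm Minimum accepted clearance, mm; defaults to the
#'   safety margin the scan was run with.
#' @return A `collision_free_report`: list with `intervals` (data frame
#'   `gantry_lo`, `gantry_hi`, `n_samples`, `longest`), and
#'   `safety_margin_mm`. Zero-row `intervals` means no angle is safe.
#' @export
collision_free_ranges <- function(result,
                                  safety_margin_mm = result$margins$safety_margin_mm) {
  stopifnot(inherits(result, "arc_clearance"),
            is.finite(safety_margin_mm), safety_margin_mm >= 0,
            nrow(result$samples) > 0L)
  ok <- result$samples$clearance_mm >= safety_margin_mm
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  if (!any(keep)) {
    intervals <- data.frame(gantry_lo = numeric(0), gantry_hi = numeric(0),
                            n_samples = integer(0), longest = logical(0))
  } else {
    starts <- starts[keep]; ends <- ends[keep]
    intervals <- data.frame(
      gantry_lo = result$samples$gantry_deg[starts],
      gantry_hi = result$samples$gantry_deg[ends],
      n_samples = ends - starts + 1L)
    intervals$longest <- seq_len(nrow(intervals)) ==
      which.max(intervals$n_samples)
  }
  structure(list(intervals = intervals,
                 safety_margin_mm = as.numeric(safety_margin_mm)),
            class = "collision_free_report")
}

#' @export
print.collision_free_report <- function(x, ...) {
  cat(sprintf("<collision_free_report> safety margin %.1f mm: %d interval(s)\n",
              x$safety_margin_mm, nrow(x$intervals)))
  if (nrow(x$intervals) > 0)
    for (i in seq_len(nrow(x$intervals)))
      cat(sprintf("  gantry %.1f -> %.1f deg (%d samples)%s\n",
                  x$intervals$gantry_lo[i], x$intervals$gantry_hi[i],
                  x$intervals$n_samples[i],
                  if (x$intervals$longest[i]) "  [longest]" else ""))
  invisible(x)
}

#' Clearance map over couch and gantry angle grids
#'
#' Evaluates the signed clearance at every combination of the supplied
#' couch and gantry angles, producing the 2D map used to pick collision-free
#' non-coplanar geometries at a glance.
#'
#' @param contour A non-empty `point_cloud` in the `support` frame.
#' @param iso Length-3 numeric isocenter, support frame, mm.
#' @param couch_angles,gantry_angles Numeric vectors of angles, degrees.
#' @param cone A [cone_spec()].
#' @param margins A [margins()] object.
#' @return Numeric matrix `length(couch_angles)` x `length(gantry_angles)`
#'   of signed clearances in mm, dimnames set to the angles.
#' @export
collision_map <- function(contour, iso, couch_angles, gantry_angles, cone,
                          margins = coneclear::margins()) {
  assert_frame(contour, "support", "contour")
  if (n_points(contour) == 0L) stop("empty contour")
  stopifnot(length(couch_angles) >= 1L, length(gantry_angles) >= 1L)
  m <- matrix(NA_real_, length(couch_angles), length(gantry_angles),
              dimnames = list(couch = format(couch_angles),
                              gantry = format(gantry_angles)))
  for (i in seq_along(couch_angles)) {
    arc <- arc_spec(isocenter = iso, couch_deg = couch_angles[i])
    for (j in seq_along(gantry_angles))
      m[i, j] <- clearance_sample(contour, arc, gantry_angles[j] %% 360,
                                  cone, margins)$clearance_mm
  }
  m
}

#' Naive full-scan clearance reference
#'
#' Reference implementation of the arc scan: the same transformation chain
#' and the same piecewise point-to-cone formula, but evaluated point by
#' point in explicit loops at a fine angular step, with no vectorization
#' shortcuts. Intended for verification; it must agree exactly with
#' [scan_arc()] on shared grid angles.
#'
#' @inheritParams scan_arc
#' @param fine_step_deg Angular step, degrees (default 0.1).
#' @return An `arc_clearance` object (samples at the fine step).
#' @export
brute_force_clearance <- function(contour, arc, cone,
                                  margins = coneclear::margins(),
                                  fine_step_deg = 0.1) {
  assert_frame(contour, "support", "contour")
  if (n_points(contour) == 0L) stop("empty contour")
  gantry <- arc_angles(arc, step_deg = fine_step_deg)
  R <- cone$radius_mm
  D <- cone$face_distance_mm
  L <- cone$length_mm
  rmax <- R + margins$detection_margin_mm
  iso <- arc$isocenter
  n <- n_points(contour)
  cl_out <- numeric(length(gantry))
  col_out <- logical(length(gantry))
  idx_out <- integer(length(gantry))
  for (a in seq_along(gantry)) {
    m <- bev_matrix(angle_set(arc$couch_deg, gantry[a], arc$collimator_deg))
    best <- Inf
    best_i <- NA_integer_
    for (i in seq_len(n)) {
      dx <- contour$xyz[i, 1] - iso[1]
      dy <- contour$xyz[i, 2] - iso[2]
      dz <- contour$xyz[i, 3] - iso[3]
      vx <- dx * m[1, 1] + dy * m[1, 2] + dz * m[1, 3]
      vy <- dx * m[2, 1] + dy * m[2, 2] + dz * m[2, 3]
      r <- sqrt(vx^2 + vy^2)
      if (r > rmax) next
      z <- dx * m[3, 1] + dy * m[3, 2] + dz * m[3, 3]
      if (is.finite(L) && z > D + L) {
        d <- sqrt(max(r - R, 0)^2 + (z - (D + L))^2)
      } else if (z > D) {
        d <- -(z - D)
      } else if (r <= R) {
        d <- D - z
      } else {
        d <- sqrt((r - R)^2 + (D - z)^2)
      }
      if (d < best) {
        best <- d
        best_i <- i
      }
    }
    cl_out[a] <- best
    col_out[a] <- is.finite(best) && best < 0
    idx_out[a] <- best_i
  }
  samples <- data.frame(gantry_deg = gantry, clearance_mm = cl_out,
                        collision = col_out, nearest_point_index = idx_out)
  i_min <- which.min(samples$clearance_mm)
  structure(list(samples = samples,
                 min_clearance_mm = samples$clearance_mm[i_min],
                 gantry_at_min_deg = samples$gantry_deg[i_min],
                 any_collision = any(samples$collision),
                 arc = arc, cone = cone, margins = margins),
            class = "arc_clearance")
}
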