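#' Coordinate frames used throughout the package
#'
#' Every point cloud is tagged with the frame its coordinates live in:
#' \describe{
#'   \item{dicom_patient}{DICOM LPS patient coordinates as stored in an
#'     RT structure set (mm).}
#'   \item{support}{Patient-support coordinates: X(+: patient left),
#'     Y(+: posterior), Z(+: superior), origin at the treatment isocenter
#'     reference (mm).}
#'   \item{collimator}{Beam's-eye-view (collimator) coordinates: the cone
#'     axis is +z, pointing from the isocenter toward the radiation source
#'     (mm).}
#' }
#' Operations refuse to mix frames; this catches the classic bug of feeding
#' untransformed contours to the clearance engine.
#'
#' @format Character vector of the three frame tags.
#' @export
FRAMES <- c("dicom_patient", "support", "collimator")

#' Construct a point cloud tagged with a coordinate frame
#'
#' @param xyz Numeric matrix with three columns (x, y, z) in millimetres, or
#'   a length-3 vector for a single point.
#' @param frame One of [FRAMES].
#' @return An object of class `point_cloud`: a list with elements `xyz`
#'   (n x 3 numeric matrix) and `frame`.
#' @examples
#' pc <- point_cloud(rbind(c(0, 50, 0), c(10, 50, 0)), "support")
#' n_points(pc)
#' @export
point_cloud <- function(xyz, frame) {
  if (is.null(dim(xyz))) {
    stopifnot(length(xyz) == 3L)
    xyz <- matrix(as.numeric(xyz), nrow = 1L)
  }
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L)
    stop("point cloud must have 3 columns (x, y, z in mm)")
  if (!all(is.finite(xyz)))
    stop("point cloud contains non-finite coordinates")
  frame <- match.arg(frame, FRAMES)
  colnames(xyz) <- c("x", "y", "z")
  structure(list(xyz = xyz, frame = frame), class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points in frame '%s'\n", nrow(x$xyz), x$frame))
  rng <- apply(x$xyz, 2, range)
  cat(sprintf("  x: [%.2f, %.2f]  y: [%.2f, %.2f]  z: [%.2f, %.2f] mm\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud A `point_cloud`.
#' @return Integer point count.
#' @export
n_points <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  nrow(cloud$xyz)
}

# internal: stop unless the cloud is in the expected frame
assert_frame <- function(cloud, frame, what = deparse(substitute(cloud))) {
  if (!inherits(cloud, "point_cloud"))
    stop(sprintf("'%s' must be a point_cloud", what))
  if (cloud$frame != frame)
    stop(sprintf("'%s' is in frame '%s' but frame '%s' is required",
                 what, cloud$frame, frame))
  invisible(cloud)
}

#' Translate a point cloud so that a known origin offset is removed
#'
#' Rigidly translates every point by `-offset`. This supports image sets
#' whose stereotactic origin is known externally (e.g. from an image
#' registration against a couch-extension template): contours exported in
#' scanner coordinates are shifted so that the stereotactic origin becomes
#' the coordinate origin.
#'
#' @param cloud A `point_cloud` (any frame).
#' @param offset Length-3 numeric, mm: the current coordinates of the point
#'   that should become the origin.
#' @return A `point_cloud` in the same frame.
#' @export
translate_to_origin <- function(cloud, offset) {
  stopifnot(inherits(cloud, "point_cloud"), length(offset) == 3L,
            all(is.finite(offset)))
  out <- cloud
  out$xyz <- sweep(cloud$xyz, 2L, as.numeric(offset), "-")
  colnames(out$xyz) <- c("x", "y", "z")
  out
}
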