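#' Rotation matrix about the y axis
#'
#' Elementary rotation used for the patient-support (couch) angle. The
#' entries follow the convention used for isocentric machine geometry:
#' \deqn{R_y(\theta) = \begin{pmatrix} \cos\theta & 0 & \sin\theta \\
#'   0 & 1 & 0 \\ -\sin\theta & 0 & \cos\theta \end{pmatrix}}
#'
#' @param theta_deg Angle in degrees.
#' @return 3x3 orthonormal matrix, determinant +1.
#' @export
rotation_y <- function(theta_deg) {
  stopifnot(is.finite(theta_deg))
  t <- theta_deg * pi / 180
  ct <- cos(t); st <- sin(t)
  rbind(c(ct, 0, st),
        c(0, 1, 0),
        c(-st, 0, ct))
}

#' Rotation matrix about the z axis
#'
#' Elementary rotation used for the gantry (and, trivially, collimator)
#' angle:
#' \deqn{R_z(\theta) = \begin{pmatrix} \cos\theta & \sin\theta & 0 \\
#'   -\sin\theta & \cos\theta & 0 \\ 0 & 0 & 1 \end{pmatrix}}
#'
#' @inheritParams rotation_y
#' @return 3x3 orthonormal matrix, determinant +1.
#' @export
rotation_z <- function(theta_deg) {
  stopifnot(is.finite(theta_deg))
  t <- theta_deg * pi / 180
  ct <- cos(t); st <- sin(t)
  rbind(c(ct, st, 0),
        c(-st, ct, 0),
        c(0, 0, 1))
}

#' Axis-convention exchange into the collimator frame
#'
#' Constant matrix swapping the gantry-frame axes into the beam's-eye-view
#' convention, mapping (x, y, z) to (x, z, -y). After this swap the +z axis
#' points from the isocenter toward the radiation source along the beam.
#'
#' @return 3x3 orthonormal matrix, determinant +1.
#' @export
convention_swap <- function() {
  rbind(c(1, 0, 0),
        c(0, 0, 1),
        c(0, -1, 0))
}

#' Couch/gantry/collimator angle triple
#'
#' Angles are normalized to [0, 360). The collimator angle defaults to zero:
#' a circular cone is rotationally symmetric about the beam axis, so
#' collimator rotation cannot change any clearance (a property the test
#' suite asserts); it is accepted for completeness.
#'
#' @param couch_deg Patient-support rotation about the vertical axis, degrees.
#' @param gantry_deg Gantry rotation, degrees.
#' @param collimator_deg Collimator rotation, degrees (default 0).
#' @return An `angle_set` object.
#' @export
angle_set <- function(couch_deg = 0, gantry_deg = 0, collimator_deg = 0) {
  stopifnot(is.finite(couch_deg), is.finite(gantry_deg),
            is.finite(collimator_deg))
  structure(list(couch_deg = couch_deg %% 360,
                 gantry_deg = gantry_deg %% 360,
                 collimator_deg = collimator_deg %% 360),
            class = "angle_set")
}

# internal: the full support -> collimator rotation for an angle_set.
# Collimator rotation is applied after the convention swap so that it spins
# about the beam axis (the collimator z), where it provably preserves the
# radial and depth coordinates the clearance depends on.
bev_matrix <- function(angles) {
  m <- convention_swap() %*% rotation_z(angles$gantry_deg) %*%
    rotation_y(angles$couch_deg)
  if (angles$collimator_deg != 0)
    m <- rotation_z(angles$collimator_deg) %*% m
  m
}

#' Transform support-frame points into the beam's-eye-view frame
#'
#' Applies the rigid chain
#' `R_z(collimator) . swap . R_z(gantry) . R_y(couch) . (v - iso)`,
#' taking hardware contour points from patient-support coordinates into the
#' collimator (BEV) frame in which the cone axis is +z toward the source.
#' No perspective projection is applied: the BEV x, y values stay metric so
#' that Euclidean distances to the cone are meaningful.
#'
#' @param points A `point_cloud` in the `support` frame.
#' @param iso Length-3 numeric or `point_cloud` of one point: isocenter in
#'   support coordinates, mm.
#' @param angles An [angle_set()].
#' @return A `point_cloud` in the `collimator` frame.
#' @examples
#' pc <- point_cloud(c(0, -100, 0), "support")  # 100 mm anterior
#' bev_transform(pc, c(0, 0, 0), angle_set(0, 0))$xyz  # -> (0, 0, 100)
#' @export
bev_transform <- function(points, iso, angles) {
  assert_frame(points, "support", "points")
  if (inherits(iso, "point_cloud")) {
    assert_frame(iso, "support", "iso")
    stopifnot(nrow(iso$xyz) == 1L)
    iso <- drop(iso$xyz)
  }
  stopifnot(length(iso) == 3L, all(is.finite(iso)))
  if (!inherits(angles, "angle_set"))
    stop("'angles' must be an angle_set")
  m <- bev_matrix(angles)
  centered <- sweep(points$xyz, 2L, as.numeric(iso), "-")
  # explicit column arithmetic: bit-reproducible across BLAS builds and
  # identical to the scalar per-point reference path
  out <- cbind(
    centered[, 1] * m[1, 1] + centered[, 2] * m[1, 2] + centered[, 3] * m[1, 3],
    centered[, 1] * m[2, 1] + centered[, 2] * m[2, 2] + centered[, 3] * m[2, 3],
    centered[, 1] * m[3, 1] + centered[, 2] * m[3, 2] + centered[, 3] * m[3, 3])
  colnames(out) <- c("x", "y", "z")
  structure(list(xyz = out, frame = "collimator"), class = "point_cloud")
}

#' Map DICOM patient coordinates onto the support frame
#'
#' For a head-first-supine (HFS) patient the DICOM LPS axes coincide with
#' the support convention X(+: left), Y(+: posterior), Z(+: superior), so
#' the mapping is the identity on coordinates and only the frame tag
#' changes. Other orientations are rejected: all cranial SRS setups this
#' package targets are HFS.
#'
#' @param points A `point_cloud` in the `dicom_patient` frame.
#' @param orientation Patient orientation; only `"HFS"` (alias
#'   `"head-first-supine"`) is supported.
#' @return A `point_cloud` in the `support` frame.
#' @export
support_from_dicom <- function(points, orientation = "HFS") {
  assert_frame(points, "dicom_patient", "points")
  if (!orientation %in% c("HFS", "head-first-supine"))
    stop(sprintf("unsupported patient orientation '%s': only head-first-supine (HFS) is implemented",
                 orientation))
  structure(list(xyz = points$xyz, frame = "support"), class = "point_cloud")
}
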