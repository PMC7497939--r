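#' Synthetic couch-top slab specification
#'
#' A horizontal plane of grid points emulating the top surface of a couch
#' extension: only the surface nearest the cone matters for the minimum
#' clearance, so the slab body is not modeled.
#'
#' @param top_depth_mm Vertical offset of the slab top below the isocenter
#'   (+y in the support frame), mm (> 0).
#' @param width_mm Extent along support x, mm (> 0).
#' @param length_mm Extent along support z, mm (> 0).
#' @param grid_spacing_mm Grid pitch, mm (> 0).
#' @return A `slab_spec` object.
#' @export
slab_spec <- function(top_depth_mm, width_mm = 300, length_mm = 300,
                      grid_spacing_mm = 1) {
  stopifnot(top_depth_mm > 0, width_mm > 0, length_mm > 0,
            grid_spacing_mm > 0)
  structure(list(top_depth_mm = as.numeric(top_depth_mm),
                 width_mm = as.numeric(width_mm),
                 length_mm = as.numeric(length_mm),
                 grid_spacing_mm = as.numeric(grid_spacing_mm)),
            class = "slab_spec")
}

#' Synthetic box specification
#'
#' A rectangular box of grid points on all six faces, emulating a
#' positioning-array-like obstacle that can be placed to collide with the
#' cone at known angles.
#'
#' @param center Length-3 numeric, box center in support coordinates, mm.
#' @param dims Length-3 numeric, full edge lengths (dx, dy, dz), mm (> 0).
#' @param grid_spacing_mm Grid pitch on each face, mm (> 0).
#' @return A `box_spec` object.
#' @export
box_spec <- function(center, dims, grid_spacing_mm = 2) {
  stopifnot(length(center) == 3L, all(is.finite(center)),
            length(dims) == 3L, all(dims > 0), grid_spacing_mm > 0)
  structure(list(center = as.numeric(center), dims = as.numeric(dims),
                 grid_spacing_mm = as.numeric(grid_spacing_mm)),
            class = "box_spec")
}

# grid covering [-h, h] at the given pitch, always containing both ends
grid_axis <- function(h, spacing) {
  g <- seq(-h, h, by = spacing)
  if (g[length(g)] < h - 1e-9) g <- c(g, h)
  g
}

#' Build the slab fixture point cloud
#'
#' Regular grid on the plane y = `top_depth_mm`, centered under the
#' isocenter. Deterministic: identical spec gives an identical cloud.
#'
#' @param spec A [slab_spec()].
#' @return A `point_cloud` in the `support` frame.
#' @examples
#' slab <- make_slab(slab_spec(50, 100, 100, 10))
#' n_points(slab)  # 11 x 11
#' @export
make_slab <- function(spec) {
  stopifnot(inherits(spec, "slab_spec"))
  gx <- grid_axis(spec$width_mm / 2, spec$grid_spacing_mm)
  gz <- grid_axis(spec$length_mm / 2, spec$grid_spacing_mm)
  g <- expand.grid(x = gx, z = gz, KEEP.OUT.ATTRS = FALSE)
  point_cloud(cbind(g$x, spec$top_depth_mm, g$z), "support")
}

#' Build the box fixture point cloud
#'
#' Grid points on all six faces of the box (deduplicated edges are kept;
#' duplicates at edges are harmless for a minimum distance).
#'
#' @param spec A [box_spec()].
#' @return A `point_cloud` in the `support` frame.
#' @export
make_box <- function(spec) {
  stopifnot(inherits(spec, "box_spec"))
  h <- spec$dims / 2
  gx <- grid_axis(h[1], spec$grid_spacing_mm)
  gy <- grid_axis(h[2], spec$grid_spacing_mm)
  gz <- grid_axis(h[3], spec$grid_spacing_mm)
  faces <- list()
  gxy <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
  faces[[1]] <- cbind(gxy$x, gxy$y, -h[3])
  faces[[2]] <- cbind(gxy$x, gxy$y, h[3])
  gxz <- expand.grid(x = gx, z = gz, KEEP.OUT.ATTRS = FALSE)
  faces[[3]] <- cbind(gxz$x, -h[2], gxz$z)
  faces[[4]] <- cbind(gxz$x, h[2], gxz$z)
  gyz <- expand.grid(y = gy, z = gz, KEEP.OUT.ATTRS = FALSE)
  faces[[5]] <- cbind(-h[1], gyz$y, gyz$z)
  faces[[6]] <- cbind(h[1], gyz$y, gyz$z)
  xyz <- do.call(rbind, faces)
  xyz <- unique(xyz)
  xyz <- sweep(xyz, 2L, spec$center, "+")
  point_cloud(xyz, "support")
}

#' Closed-form slab clearance oracle
#'
#' Minimum of the engine's piecewise point-to-cone clearance over an
#' infinite plane `y = top_depth_mm` (support frame, couch 0, isocenter at
#' the origin), restricted to the candidate region
#' `r <= R + detection_margin`. The minimization reduces to one dimension:
#' the BEV depth of a plane point depends only on its BEV x, and shrinking
#' |BEV y| toward 0 never increases any branch of the formula, so the
#' minimum lies on the BEV y = 0 line, where each branch is linear or
#' quadratic in BEV x and minimized in closed form.
#'
#' Valid for gantry angles strictly between 90 and 270 degrees (beam axis
#' pointing into the lower half-space); outside that range the infinite
#' plane either never enters the detection cylinder or trivially collides,
#' and the formula refuses.
#'
#' @param top_depth_mm Plane depth below the isocenter, mm (> 0).
#' @param gantry_deg Gantry angle, degrees, in (90, 270).
#' @param cone A [cone_spec()] (semi-infinite body).
#' @param detection_margin_mm Radial padding used by the engine, mm.
#' @return Signed clearance, mm (negative = collision penetration depth).
#' @export
analytic_slab_clearance <- function(top_depth_mm, gantry_deg, cone,
                                    detection_margin_mm = 5) {
  stopifnot(top_depth_mm > 0, inherits(cone, "cone_spec"),
            detection_margin_mm >= 0)
  if (!is.finite(cone$length_mm))
    L_ok <- TRUE
  else
    stop("analytic slab clearance assumes a semi-infinite cone body")
  g <- (gantry_deg %% 360) * pi / 180
  cg <- cos(g); sg <- sin(g)
  if (cg >= -1e-9)
    stop("analytic slab clearance is valid only for gantry angles strictly between 90 and 270 degrees")
  d <- top_depth_mm
  R <- cone$radius_mm
  D <- cone$face_distance_mm
  Rm <- R + detection_margin_mm
  # plane point at BEV y = 0 with BEV x = X has depth Z(X) = (sg*X - d)/cg
  Zfun <- function(X) (sg * X - d) / cg
  z_ends <- Zfun(c(-Rm, Rm))
  if (max(z_ends) > D)          # linear in X: max at an interval end
    return(-(max(z_ends) - D))  # deepest candidate penetration
  # face region |X| <= R: clearance D - Z, linear -> endpoint minimum
  best <- D - max(Zfun(c(-R, R)))
  # annulus regions R < |X| <= Rm: sqrt((W - R)^2 + (b - k W)^2), W = |X|
  b <- D + d / cg
  for (sgn in c(-1, 1)) {
    k <- sgn * sg / cg          # D - Z(sgn * W) = b - k W
    Wstar <- (R + k * b) / (1 + k^2)
    Wstar <- min(max(Wstar, R), Rm)
    best <- min(best, sqrt((Wstar - R)^2 + (b - k * Wstar)^2))
  }
  best
}

#' Write point clouds as a minimal DICOM RT structure set
#'
#' Emits a standards-conformant explicit-VR little-endian RT-STRUCT whose
#' ROI contours are the clouds' points grouped into planar polylines by
#' z level (points within a level ordered counter-clockwise around their
#' centroid). Deterministic: identical inputs give byte-identical files.
#' Levels with fewer than 3 points are dropped (a DICOM planar contour
#' needs at least 3 vertices).
#'
#' @param clouds A `point_cloud` or list of them, in the `support` or
#'   `dicom_patient` frame (coordinates are written as-is; the HFS mapping
#'   is the identity).
#' @param roi_names Character vector of ROI names, one per cloud.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_synthetic_rtstruct <- function(clouds, roi_names, path) {
  if (inherits(clouds, "point_cloud")) clouds <- list(clouds)
  stopifnot(length(clouds) >= 1L, length(roi_names) == length(clouds),
            is.character(roi_names))
  uid_root <- "2.25.430712986523401"
  fmt_ds <- function(x) {
    s <- sprintf("%.6f", x)
    if (any(nchar(s) > 16L)) stop("coordinate too large for DICOM DS")
    s
  }
  roi_def_items <- list()
  roi_contour_items <- list()
  for (i in seq_along(clouds)) {
    cl <- clouds[[i]]
    stopifnot(inherits(cl, "point_cloud"))
    xyz <- cl$xyz
    levels <- split(seq_len(nrow(xyz)), xyz[, 3])
    contour_items <- list()
    for (lv in levels) {
      if (length(lv) < 3L) next
      pts <- xyz[lv, , drop = FALSE]
      ctr <- colMeans(pts)
      ord <- order(atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1]),
                   pts[, 1], pts[, 2])
      pts <- pts[ord, , drop = FALSE]
      if (nrow(pts) > 5000L)
        stop("contour level too dense for a single DICOM contour item; increase grid spacing")
      data_str <- paste(fmt_ds(as.vector(t(pts))), collapse = "\\")
      contour_items[[length(contour_items) + 1L]] <- c(
        dcm_element(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        dcm_element(0x3006, 0x0046, "IS", as.character(nrow(pts))),
        dcm_element(0x3006, 0x0050, "DS", data_str))
    }
    if (length(contour_items) == 0L)
      stop(sprintf("cloud %d has no z level with >= 3 points", i))
    roi_def_items[[i]] <- c(
      dcm_element(0x3006, 0x0022, "IS", as.character(i)),
      dcm_element(0x3006, 0x0024, "UI", paste0(uid_root, ".3")),
      dcm_element(0x3006, 0x0026, "LO", roi_names[i]),
      dcm_element(0x3006, 0x0036, "CS", "MANUAL"))
    roi_contour_items[[i]] <- c(
      dcm_sequence(0x3006, 0x0040, contour_items),
      dcm_element(0x3006, 0x0084, "IS", as.character(i)))
  }
  dataset <- c(
    dcm_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.481.3"),
    dcm_element(0x0008, 0x0018, "UI", paste0(uid_root, ".2")),
    dcm_element(0x0008, 0x0020, "DA", "20200101"),
    dcm_element(0x0008, 0x0030, "TM", "000000"),
    dcm_element(0x0008, 0x0060, "CS", "RTSTRUCT"),
    dcm_element(0x0010, 0x0010, "PN", "SYNTHETIC^FIXTURE"),
    dcm_element(0x0010, 0x0020, "LO", "coneclear-fixture"),
    dcm_element(0x0020, 0x000D, "UI", paste0(uid_root, ".0")),
    dcm_element(0x0020, 0x000E, "UI", paste0(uid_root, ".1")),
    dcm_element(0x3006, 0x0002, "SH", "coneclear"),
    dcm_sequence(0x3006, 0x0020, roi_def_items),
    dcm_sequence(0x3006, 0x0039, roi_contour_items))
  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.481.3"),
    dcm_element(0x0002, 0x0003, "UI", paste0(uid_root, ".2")),
    dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    dcm_element(0x0002, 0x0012, "UI", paste0(uid_root, ".9")))
  meta <- c(dcm_element(0x0002, 0x0000, "UL", dcm_uint32(length(meta_body))),
            meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0), 128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset), con)
  invisible(path)
}
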