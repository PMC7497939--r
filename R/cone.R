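#' Stereotactic cone geometry
#'
#' The cone is modeled as the solid that matters for clearance: a cylinder
#' of radius `radius_mm` about the beam axis whose distal face sits at BEV
#' z = `face_distance_mm` from the isocenter and which extends toward the
#' source. `length_mm` bounds that extent; the default `Inf` (semi-infinite)
#' is the conservative choice, since the gantry head behind the cone is at
#' least as wide as the cone itself.
#'
#' @param radius_mm Outer radius of the cone housing, mm (> 0).
#' @param face_distance_mm Perpendicular distance from the distal cone face
#'   to the isocenter, mm (> 0).
#' @param length_mm Extent of the modeled cylinder from the face toward the
#'   source, mm (> 0 or `Inf`).
#' @param name Optional preset label.
#' @return A `cone_spec` object.
#' @seealso [cone_preset()] for the measured machine presets.
#' @export
cone_spec <- function(radius_mm, face_distance_mm, length_mm = Inf,
                      name = "custom") {
  stopifnot(is.finite(radius_mm), radius_mm > 0,
            is.finite(face_distance_mm), face_distance_mm > 0,
            length_mm > 0)
  structure(list(radius_mm = as.numeric(radius_mm),
                 face_distance_mm = as.numeric(face_distance_mm),
                 length_mm = as.numeric(length_mm),
                 name = name),
            class = "cone_spec")
}

#' Measured cone presets
#'
#' Measured geometries of the two supported cone/linac combinations:
#' \describe{
#'   \item{brainlab_truebeam}{BrainLAB SRS cones on a TrueBeam STx:
#'     outer diameter 67.5 mm (radius 33.75 mm), cone face 26.6 cm
#'     (266 mm) from the isocenter.}
#'   \item{icvi_novalis}{Varian Integrated Conical Collimator Verification &
#'     Interlock cones on a Novalis Tx: outer diameter 74.0 mm (radius
#'     37.0 mm), cone face 25.6 cm (256 mm) from the isocenter.}
#' }
#'
#' @param name Preset name.
#' @return A `cone_spec`.
#' @examples
#' cone_preset("brainlab_truebeam")
#' @export
cone_preset <- function(name = c("brainlab_truebeam", "icvi_novalis")) {
  name <- match.arg(name)
  switch(name,
         brainlab_truebeam = cone_spec(67.5 / 2, 266, name = name),
         icvi_novalis = cone_spec(74.0 / 2, 256, name = name))
}

#' @export
print.cone_spec <- function(x, ...) {
  cat(sprintf("<cone_spec> %s: R = %.2f mm, face at %.1f mm from isocenter, body length %s\n",
              x$name, x$radius_mm, x$face_distance_mm,
              if (is.finite(x$length_mm)) sprintf("%.1f mm", x$length_mm) else "unbounded"))
  invisible(x)
}

#' Detection and safety margins
#'
#' `detection_margin_mm` pads the cone radius when selecting candidate
#' contour points in the BEV projection; `safety_margin_mm` is the minimum
#' clearance required to call a gantry angle collision-free. Both default
#' to 5 mm; clinical use on systems with residual 6D setup corrections
#' warrants 10 mm or more, since setup rotations of ~2 degrees move a
#' 15 cm-distant device edge by ~5 mm.
#'
#' @param detection_margin_mm Radial padding, mm (>= 0).
#' @param safety_margin_mm Minimum accepted clearance, mm (>= 0).
#' @return A `margins` object.
#' @export
margins <- function(detection_margin_mm = 5, safety_margin_mm = 5) {
  stopifnot(is.finite(detection_margin_mm), detection_margin_mm >= 0,
            is.finite(safety_margin_mm), safety_margin_mm >= 0)
  structure(list(detection_margin_mm = as.numeric(detection_margin_mm),
                 safety_margin_mm = as.numeric(safety_margin_mm)),
            class = "margins")
}
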