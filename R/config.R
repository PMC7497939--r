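#' Assemble a run configuration
#'
#' The configuration binds one geometry source (an RT-STRUCT file with ROI
#' names, or a synthetic fixture spec), a cone (machine preset or explicit
#' geometry), margins, and one or more arcs. Isocenters are given in cm
#' (the convention treatment plans print) and converted to mm internally.
#'
#' @param structure_file Optional path to an RT-STRUCT file.
#' @param roi Optional character vector of ROI names to load from it.
#' @param fixture Optional `slab_spec`/`box_spec` (or list of them) used
#'   instead of a file. Exactly one of `structure_file`/`fixture` must be
#'   given.
#' @param machine Machine preset name for [cone_preset()], or `NULL` when
#'   `cone` is given.
#' @param cone Optional explicit [cone_spec()].
#' @param margins A [margins()] object.
#' @param arcs List of arc descriptions; each a list with `isocenter_cm`
#'   (length 3), `couch_deg`, `gantry_start`, `gantry_end`, optional `step`.
#' @param out Optional output path stem for reports.
#' @param format Report format, `"json"` or `"csv"`.
#' @param origin_offset_mm Optional length-3 offset subtracted from file
#'   contours (stereotactic origin of a non-localized image set), mm.
#' @param resample_mm Contour densification spacing for file input, mm.
#' @return A `run_config` object.
#' @export
run_config <- function(structure_file = NULL, roi = NULL, fixture = NULL,
                       machine = NULL, cone = NULL,
                       margins = coneclear::margins(), arcs,
                       out = NULL, format = c("json", "csv"),
                       origin_offset_mm = NULL, resample_mm = 1.0) {
  format <- match.arg(format)
  if (is.null(structure_file) == is.null(fixture))
    stop("exactly one geometry source (structure_file or fixture) is required")
  if (is.null(cone)) {
    if (is.null(machine)) stop("either a machine preset or an explicit cone is required")
    cone <- cone_preset(machine)
  }
  stopifnot(inherits(cone, "cone_spec"), inherits(margins, "margins"))
  if (inherits(fixture, c("slab_spec", "box_spec"))) fixture <- list(fixture)
  if (length(arcs) == 0L) stop("at least one arc is required")
  arcs <- lapply(arcs, function(a) {
    if (inherits(a, "arc_spec")) return(a)
    arc_spec(isocenter = as.numeric(a$isocenter_cm) * 10,
             couch_deg = a$couch_deg %||% 0,
             gantry_start_deg = a$gantry_start,
             gantry_end_deg = a$gantry_end,
             step_deg = a$step %||% 1)
  })
  structure(list(structure_file = structure_file, roi = roi,
                 fixture = fixture, cone = cone, margins = margins,
                 arcs = arcs, out = out, format = format,
                 origin_offset_mm = origin_offset_mm,
                 resample_mm = resample_mm),
            class = "run_config")
}

#' Read a run configuration from a YAML or JSON file
#'
#' Accepted keys mirror [run_config()]: `geometry` (with `structure_file`
#' + `roi`, or `fixture` with `type: slab|box` and its spec fields),
#' `machine` or `cone` (`radius_mm`, `face_distance_mm`), `margins`
#' (`detection_mm`, `safety_mm`), `arcs` (list with `isocenter_cm`,
#' `couch_deg`, `gantry_start`, `gantry_end`, `step`), `output` (`path`,
#' `format`).
#'
#' @param path Config file path (`.yaml`/`.yml`/`.json`).
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else
    yaml::read_yaml(path)
  geo <- cfg$geometry %||% list()
  fixture <- NULL
  if (!is.null(geo$fixture)) {
    fx <- geo$fixture
    fixture <- switch(fx$type %||% stop("fixture needs a 'type'"),
      slab = slab_spec(fx$top_depth_mm, fx$width_mm %||% 300,
                       fx$length_mm %||% 300, fx$grid_spacing_mm %||% 1),
      box = box_spec(as.numeric(fx$center_mm), as.numeric(fx$dims_mm),
                     fx$grid_spacing_mm %||% 2),
      stop(sprintf("unknown fixture type '%s'", fx$type)))
  }
  cone <- NULL
  if (!is.null(cfg$cone))
    cone <- cone_spec(cfg$cone$radius_mm, cfg$cone$face_distance_mm)
  mg <- cfg$margins %||% list()
  run_config(
    structure_file = geo$structure_file,
    roi = if (!is.null(geo$roi)) as.character(unlist(geo$roi)),
    fixture = fixture,
    machine = cfg$machine,
    cone = cone,
    margins = margins(mg$detection_mm %||% 5, mg$safety_mm %||% 5),
    arcs = cfg$arcs %||% stop("config needs an 'arcs' list"),
    out = cfg$output$path,
    format = cfg$output$format %||% "json",
    origin_offset_mm = if (!is.null(geo$origin_offset_mm))
      as.numeric(geo$origin_offset_mm),
    resample_mm = geo$resample_mm %||% 1.0)
}

# internal: materialize the configured geometry as one support-frame cloud
config_geometry <- function(config) {
  if (!is.null(config$structure_file)) {
    rois <- read_rtstruct(config$structure_file, config$roi)
    clouds <- lapply(rois, resample_contours,
                     max_spacing_mm = config$resample_mm)
    xyz <- do.call(rbind, lapply(clouds, function(c) c$xyz))
    cloud <- point_cloud(xyz, "dicom_patient")
    if (!is.null(config$origin_offset_mm))
      cloud <- translate_to_origin(cloud, config$origin_offset_mm)
    support_from_dicom(cloud)
  } else {
    clouds <- lapply(config$fixture, function(f)
      if (inherits(f, "slab_spec")) make_slab(f) else make_box(f))
    point_cloud(do.call(rbind, lapply(clouds, function(c) c$xyz)), "support")
  }
}
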