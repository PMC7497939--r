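#' A named ROI and its planar contours
#'
#' @param roi_name ROI label as stored in the structure set.
#' @param slices List of closed planar polylines; each is an n x 3 numeric
#'   matrix of vertices in DICOM patient coordinates, mm, n >= 3.
#' @param source Identifier of the originating file (informational).
#' @return A `roi_contour_set` object.
#' @export
roi_contour_set <- function(roi_name, slices, source = NA_character_) {
  stopifnot(is.character(roi_name), length(slices) >= 1L)
  slices <- lapply(slices, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    if (ncol(s) != 3L || nrow(s) < 3L)
      stop("each contour slice needs >= 3 vertices with 3 coordinates")
    if (!all(is.finite(s))) stop("non-finite contour vertex")
    colnames(s) <- c("x", "y", "z")
    s
  })
  structure(list(roi_name = roi_name, slices = slices, source = source),
            class = "roi_contour_set")
}

#' @export
print.roi_contour_set <- function(x, ...) {
  cat(sprintf("<roi_contour_set> '%s': %d slices, %d vertices\n",
              x$roi_name, length(x$slices),
              sum(vapply(x$slices, nrow, 0L))))
  invisible(x)
}

#' Read hardware contours from a DICOM RT structure set
#'
#' Extracts the named ROIs' contour polylines verbatim (mm, DICOM patient
#' coordinates); no geometric processing is applied. Supports explicit and
#' implicit VR little-endian transfer syntaxes.
#'
#' @param path Path to an RT-STRUCT file.
#' @param roi_names Optional character vector; only ROIs whose name matches
#'   (case-insensitively) are returned. `NULL` returns all ROIs in file
#'   order.
#' @return List of [roi_contour_set()] objects.
#' @export
read_rtstruct <- function(path, roi_names = NULL) {
  f <- dcm_read_file(path)
  modality <- dcm_string(f$data, "00080060")
  if (!identical(modality, "RTSTRUCT"))
    stop(sprintf("not an RT structure set (modality '%s'): %s",
                 modality %||% "missing", path))
  roi_defs <- f$data[["30060020"]]
  roi_contours <- f$data[["30060039"]]
  if (is.null(roi_defs) || is.null(roi_contours))
    stop(sprintf("structure set has no ROI sequences: %s", path))
  names_by_number <- list()
  order_by_number <- list()
  for (i in seq_along(roi_defs)) {
    num <- as.character(dcm_numbers(roi_defs[[i]], "30060022"))
    names_by_number[[num]] <- dcm_string(roi_defs[[i]], "30060026")
    order_by_number[[num]] <- i
  }
  out <- list()
  for (rc in roi_contours) {
    num <- as.character(dcm_numbers(rc, "30060084"))
    nm <- names_by_number[[num]] %||% sprintf("ROI-%s", num)
    slices <- lapply(rc[["30060040"]] %||% list(), function(cs) {
      pts <- dcm_numbers(cs, "30060050")
      matrix(pts, ncol = 3L, byrow = TRUE)
    })
    slices <- Filter(function(s) nrow(s) >= 3L, slices)
    if (length(slices) == 0L) next
    out[[length(out) + 1L]] <- roi_contour_set(nm, slices, source = path)
  }
  if (!is.null(roi_names)) {
    want <- tolower(roi_names)
    have <- tolower(vapply(out, function(r) r$roi_name, ""))
    missing <- setdiff(want, have)
    if (length(missing) > 0L)
      stop(sprintf("ROI not found in %s: %s", path,
                   paste(missing, collapse = ", ")))
    out <- out[have %in% want]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flatten ROI contours into a point cloud, densified to a maximum spacing
#'
#' TPS exports vary widely in vertex density; clearance is computed against
#' points, so sparse polylines could miss the true nearest surface point by
#' up to half a segment length. Each closed-polyline segment longer than
#' `max_spacing_mm` is subdivided by linear interpolation (original
#' vertices retained), bounding that error by `max_spacing_mm / 2` along
#' the contour.
#'
#' @param roi A [roi_contour_set()].
#' @param max_spacing_mm Maximum allowed distance between consecutive
#'   points along each polyline, mm. `Inf` keeps original vertices only.
#' @return A `point_cloud` in the `dicom_patient` frame.
#' @export
resample_contours <- function(roi, max_spacing_mm = 1.0) {
  stopifnot(inherits(roi, "roi_contour_set"), max_spacing_mm > 0)
  pieces <- lapply(roi$slices, function(s) {
    n <- nrow(s)
    nxt <- s[c(2:n, 1L), , drop = FALSE]  # closed: wrap last -> first
    seg <- nxt - s
    len <- sqrt(rowSums(seg^2))
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      k <- if (is.finite(max_spacing_mm)) ceiling(len[i] / max_spacing_mm) else 1L
      k <- max(k, 1L)
      # k points starting at the vertex, excluding the next vertex
      t <- (seq_len(k) - 1L) / k
      rows[[i]] <- cbind(s[i, 1] + t * seg[i, 1],
                         s[i, 2] + t * seg[i, 2],
                         s[i, 3] + t * seg[i, 3])
    }
    do.call(rbind, rows)
  })
  point_cloud(do.call(rbind, pieces), "dicom_patient")
}

#' Write an arc clearance report
#'
#' JSON reports carry the sampled clearances plus a summary block (minimum
#' clearance and its gantry angle, collision flag, collision-free
#' intervals). CSV reports carry one row per sampled gantry angle with
#' `couch_deg`, `gantry_deg`, `clearance_mm`, `collision`. Clearances are
#' rounded to 0.01 mm at serialization only; `Inf` (no candidate points)
#' serializes as the JSON string `"Inf"` / CSV `Inf` and reads back as
#' `Inf`.
#'
#' @param result An `arc_clearance` from [scan_arc()].
#' @param ranges Optional `collision_free_report`; computed from `result`
#'   with its safety margin when omitted.
#' @param path Output file path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("json", "csv"),
                         ranges = NULL) {
  stopifnot(inherits(result, "arc_clearance"))
  format <- match.arg(format)
  if (is.null(ranges)) ranges <- collision_free_ranges(result)
  stopifnot(inherits(ranges, "collision_free_report"))
  samples <- result$samples
  samples$clearance_mm <- round(samples$clearance_mm, 2)
  samples$couch_deg <- result$arc$couch_deg
  samples <- samples[, c("couch_deg", "gantry_deg", "clearance_mm",
                         "collision")]
  if (format == "csv") {
    utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  intervals <- ranges$intervals
  # jsonlite drops non-finite values from data-frame rows; the no-candidate
  # sentinel is mapped to JSON null and restored to Inf by read_report()
  samples$clearance_mm[!is.finite(samples$clearance_mm)] <- NA
  min_cl <- round(result$min_clearance_mm, 2)
  if (!is.finite(min_cl)) min_cl <- NA
  obj <- list(
    couch_deg = result$arc$couch_deg,
    arc = list(gantry_start_deg = result$arc$gantry_start_deg,
               gantry_end_deg = result$arc$gantry_end_deg,
               step_deg = result$arc$step_deg,
               isocenter_mm = result$arc$isocenter),
    cone = list(name = result$cone$name,
                radius_mm = result$cone$radius_mm,
                face_distance_mm = result$cone$face_distance_mm),
    margins = list(detection_margin_mm = result$margins$detection_margin_mm,
                   safety_margin_mm = ranges$safety_margin_mm),
    samples = samples,
    summary = list(min_clearance_mm = min_cl,
                   gantry_at_min_deg = result$gantry_at_min_deg,
                   any_collision = result$any_collision,
                   collision_free_intervals = if (nrow(intervals) == 0)
                     list()
                   else
                     intervals[, c("gantry_lo", "gantry_hi")])
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Read back a JSON clearance report
#'
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return Nested list mirroring the JSON structure; `"Inf"` strings are
#'   restored to numeric `Inf` in the samples.
#' @export
read_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!is.null(obj$samples) && nrow(obj$samples) > 0) {
    if (is.null(obj$samples$clearance_mm))
      obj$samples$clearance_mm <- NA_real_
    cl <- as.numeric(obj$samples$clearance_mm)
    cl[is.na(cl)] <- Inf
    obj$samples$clearance_mm <- cl
  }
  if (is.null(obj$summary$min_clearance_mm))
    obj$summary$min_clearance_mm <- Inf
  obj$summary$min_clearance_mm <- as.numeric(obj$summary$min_clearance_mm)
  if (length(obj$summary$collision_free_intervals) == 0)
    obj$summary$collision_free_intervals <-
      data.frame(gantry_lo = numeric(0), gantry_hi = numeric(0))
  obj
}
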