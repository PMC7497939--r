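sorted_xyz <- function(m) m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]

test_that("synthetic RT-STRUCT files round-trip point sets losslessly", {
  slab <- make_slab(slab_spec(50, 100, 100, 10))
  box <- make_box(box_spec(c(10, 80, 0), c(40, 40, 40), 10))
  path <- tempfile(fileext = ".dcm")
  write_synthetic_rtstruct(list(slab, box), c("CouchTop", "Array"), path)
  rois <- read_rtstruct(path)
  expect_length(rois, 2)
  expect_equal(vapply(rois, function(r) r$roi_name, ""),
               c("CouchTop", "Array"))
  for (pair in list(list(rois[[1]], slab), list(rois[[2]], box))) {
    got <- sorted_xyz(do.call(rbind, pair[[1]]$slices))
    want <- sorted_xyz(pair[[2]]$xyz)
    expect_equal(dim(got), dim(want))
    expect_lt(max(abs(got - want)), 1e-6)
  }
})

test_that("ROI filtering is case-insensitive and missing ROIs raise errors", {
  path <- tempfile(fileext = ".dcm")
  write_synthetic_rtstruct(list(make_slab(slab_spec(40, 60, 60, 10))),
                           "CouchTop", path)
  expect_length(read_rtstruct(path, "couchtop"), 1)
  expect_error(read_rtstruct(path, "FRPA"), "ROI not found")
  expect_error(read_rtstruct(tempfile(fileext = ".dcm")), "not found")
})

test_that("non-RTSTRUCT DICOM and non-DICOM files are rejected distinctly", {
  junk <- tempfile()
  writeBin(as.raw(1:200), junk)
  expect_error(read_rtstruct(junk), "not a DICOM")
  # minimal valid DICOM of a different modality, built from the codec
  ct <- tempfile(fileext = ".dcm")
  meta_body <- c(coneclear:::dcm_element(0x0002, 0x0010, "UI",
                                         "1.2.840.10008.1.2.1"))
  meta <- c(coneclear:::dcm_element(0x0002, 0x0000, "UL",
                                    coneclear:::dcm_uint32(length(meta_body))),
            meta_body)
  con <- file(ct, "wb")
  writeBin(rep(as.raw(0), 128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, coneclear:::dcm_element(0x0008, 0x0060, "CS", "CT")), con)
  close(con)
  expect_error(read_rtstruct(ct), "modality")
})

test_that("the writer emits files an independent DICOM implementation accepts", {
  path <- tempfile(fileext = ".dcm")
  slab <- make_slab(slab_spec(50, 100, 100, 10))
  write_synthetic_rtstruct(list(slab), "COUCH", path)
  script <- paste(
    "import sys, pydicom",
    "ds = pydicom.dcmread(sys.argv[1])",
    "print(ds.Modality)",
    "print(ds.StructureSetROISequence[0].ROIName)",
    "cs = ds.ROIContourSequence[0].ContourSequence",
    "print(sum(int(c.NumberOfContourPoints) for c in cs))",
    "print(min(float(v) for c in cs for v in c.ContourData[1::3]))",
    sep = "\n")
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script), shQuote(path)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0,
              label = paste("pydicom read failed:", paste(out, collapse = " ")))
  expect_equal(out[1], "RTSTRUCT")
  expect_equal(out[2], "COUCH")
  expect_equal(as.integer(out[3]), n_points(slab))
  expect_equal(as.numeric(out[4]), 50)
})

test_that("implicit VR little-endian structure sets are readable", {
  path <- tempfile(fileext = ".dcm")
  implicit <- tempfile(fileext = ".dcm")
  slab <- make_slab(slab_spec(50, 80, 80, 10))
  write_synthetic_rtstruct(list(slab), "COUCH", path)
  script <- paste(
    "import sys, pydicom",
    "ds = pydicom.dcmread(sys.argv[1])",
    "ds.file_meta.TransferSyntaxUID = pydicom.uid.ImplicitVRLittleEndian",
    "ds.save_as(sys.argv[2], enforce_file_format=True)",
    sep = "\n")
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script), shQuote(path),
                        shQuote(implicit)), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0,
              label = paste("pydicom rewrite failed:",
                            paste(out, collapse = " ")))
  rois <- read_rtstruct(implicit)
  expect_equal(sorted_xyz(do.call(rbind, rois[[1]]$slices)),
               sorted_xyz(slab$xyz), ignore_attr = TRUE)
})

test_that("contour resampling subdivides long segments and keeps vertices", {
  sq <- roi_contour_set("SQ", list(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10), 5)))
  dense <- resample_contours(sq, 1)
  expect_equal(n_points(dense), 40)  # 4 sides x 10 subdivisions
  expect_equal(dense$frame, "dicom_patient")
  # original vertices retained
  for (v in seq_len(4))
    expect_true(any(colSums(abs(t(dense$xyz) - sq$slices[[1]][v, ])) < 1e-12))
  # spacing larger than every segment: vertices only
  coarse <- resample_contours(sq, 50)
  expect_equal(n_points(coarse), 4)
})

test_that("resampling bounds the point-set error by half the spacing", {
  set.seed(81)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    ang <- sort(runif(n, 0, 2 * pi))
    poly <- cbind(30 * cos(ang) + rnorm(n), 30 * sin(ang) + rnorm(n), 0)
    roi <- roi_contour_set("P", list(poly))
    spacing <- runif(1, 0.5, 3)
    cloud <- resample_contours(roi, spacing)
    q <- c(runif(2, -40, 40), runif(1, -5, 5))
    d_points <- sqrt(min(colSums((t(cloud$xyz) - q)^2)))
    d_poly <- point_polyline_dist(q, poly)
    expect_lte(d_points, d_poly + spacing / 2 + 1e-9)
    expect_gte(d_points, d_poly - 1e-9)
  }
})

test_that("translate_to_origin shifts rigidly and inverts exactly", {
  cloud <- make_box(box_spec(c(5, 60, -5), c(20, 20, 20), 10))
  off <- c(12, -7, 3)
  moved <- translate_to_origin(cloud, off)
  expect_equal(moved$xyz, sweep(cloud$xyz, 2, off, "-"), ignore_attr = TRUE)
  back <- translate_to_origin(moved, -off)
  expect_equal(back$xyz, cloud$xyz, tolerance = 1e-12)
  expect_equal(translate_to_origin(cloud, c(0, 0, 0))$xyz, cloud$xyz)
})

test_that("reports round-trip in JSON and carry the right CSV shape", {
  slab <- make_slab(slab_spec(50, 200, 200, 2))
  res <- scan_arc(slab, arc_spec(c(0, 0, 0), 0, 175, 185), bl <- cone_preset("brainlab_truebeam"))
  rng <- collision_free_ranges(res, 5)
  jp <- tempfile(fileext = ".json")
  write_report(res, jp, "json", ranges = rng)
  back <- read_report(jp)
  expect_equal(back$samples$clearance_mm, round(res$samples$clearance_mm, 2))
  expect_equal(back$samples$gantry_deg, res$samples$gantry_deg)
  expect_equal(back$summary$min_clearance_mm, round(res$min_clearance_mm, 2))
  expect_equal(back$summary$gantry_at_min_deg, res$gantry_at_min_deg)
  expect_equal(back$cone$radius_mm, 33.75)

  cp <- tempfile(fileext = ".csv")
  write_report(res, cp, "csv")
  expect_length(readLines(cp), nrow(res$samples) + 1)
  csv <- utils::read.csv(cp)
  expect_named(csv, c("couch_deg", "gantry_deg", "clearance_mm", "collision"))

  # empty interval list serializes as [], not null, and reads back empty
  far <- point_cloud(c(400, 400, 0), "support")
  res2 <- scan_arc(far, arc_spec(c(0, 0, 0), 0, 10, 12), bl)
  res2$samples$clearance_mm <- -1  # force nothing safe
  res2$min_clearance_mm <- -1
  jp2 <- tempfile(fileext = ".json")
  write_report(res2, jp2, "json", ranges = collision_free_ranges(res2, 5))
  expect_match(paste(readLines(jp2), collapse = ""),
               "\"collision_free_intervals\":\\[\\]")
  expect_equal(nrow(read_report(jp2)$summary$collision_free_intervals), 0)
})

test_that("infinite clearances survive serialization", {
  far <- point_cloud(c(400, 400, 0), "support")
  res <- scan_arc(far, arc_spec(c(0, 0, 0), 0, 10, 12),
                  cone_preset("brainlab_truebeam"))
  jp <- tempfile(fileext = ".json")
  write_report(res, jp, "json")
  back <- read_report(jp)
  expect_true(all(is.infinite(back$samples$clearance_mm)))
})
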