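bl <- cone_preset("brainlab_truebeam")

test_that("arc sampling counts, wrap-around and off-grid endpoints", {
  expect_length(arc_angles(arc_spec(c(0, 0, 0), 0, 160, 200)), 41)
  expect_length(arc_angles(arc_spec(c(0, 0, 0), 0, 200, 340)), 141)
  wrap <- arc_angles(arc_spec(c(0, 0, 0), 0, 350, 10))
  expect_equal(wrap, c(350:359, 0:10))
  # exact non-integer end appended after the 1-degree grid
  off <- arc_angles(arc_spec(c(0, 0, 0), 0, 160, 200.5))
  expect_length(off, 42)
  expect_equal(utils::tail(off, 2), c(200, 200.5))
  # single-angle query
  expect_equal(arc_angles(arc_spec(c(0, 0, 0), 0, 42, 42)), 42)
})

test_that("scan_arc records min, argmin and ties break to first traversal", {
  slab <- make_slab(slab_spec(50, 300, 300, 1))
  res <- scan_arc(slab, arc_spec(c(0, 0, 0), 0, 160, 200), bl)
  expect_equal(nrow(res$samples), 41)
  expect_equal(res$min_clearance_mm, min(res$samples$clearance_mm))
  expect_equal(res$samples$clearance_mm[res$samples$gantry_deg == 180],
               216.0, tolerance = 1e-9)
  # symmetric geometry: the arc minimum sits at the arc ends, where the
  # detection annulus admits the closest points (closed-form oracle value)
  expect_equal(res$gantry_at_min_deg, 160)
  expect_equal(res$min_clearance_mm,
               analytic_slab_clearance(50, 160, bl), tolerance = 0.5)

  # exact tie everywhere (single point at the isocenter): first angle wins
  pt <- point_cloud(c(0, 0, 0), "support")
  tie <- scan_arc(pt, arc_spec(c(0, 0, 0), 0, 170, 190), bl)
  expect_equal(tie$gantry_at_min_deg, 170)
  expect_true(all(tie$samples$clearance_mm == bl$face_distance_mm))
})

test_that("collision-free ranges are maximal runs at or above the margin", {
  # synthetic result exercising the run rule directly
  samples <- data.frame(gantry_deg = 178:183,
                        clearance_mm = c(10, 6, 4, 3, 6, 10),
                        collision = FALSE, nearest_point_index = 1L)
  res <- structure(list(samples = samples, min_clearance_mm = 3,
                        gantry_at_min_deg = 181, any_collision = FALSE,
                        arc = arc_spec(c(0, 0, 0), 0, 178, 183),
                        cone = bl, margins = margins()),
                   class = "arc_clearance")
  rng <- collision_free_ranges(res, 5)
  expect_equal(rng$intervals$gantry_lo, c(178, 182))
  expect_equal(rng$intervals$gantry_hi, c(179, 183))
  expect_equal(rng$intervals$n_samples, c(2L, 2L))

  all_ok <- collision_free_ranges(res, 3)
  expect_equal(all_ok$intervals$gantry_lo, 178)
  expect_equal(all_ok$intervals$gantry_hi, 183)
  none <- collision_free_ranges(res, 11)
  expect_equal(nrow(none$intervals), 0L)
})

test_that("safety margins nest: stricter margins give subset intervals", {
  set.seed(51)
  in_interval <- function(samples, intervals, i)
    any(vapply(seq_len(nrow(intervals)), function(k) {
      lo <- which(samples$gantry_deg == intervals$gantry_lo[k])[1]
      hi <- which(samples$gantry_deg == intervals$gantry_hi[k])[1]
      i >= lo && i <= hi
    }, TRUE))
  for (rep in 1:20) {
    g <- random_geometry()
    res <- scan_arc(g$contour, g$arc, bl)
    r5 <- collision_free_ranges(res, 5)
    r10 <- collision_free_ranges(res, 10)
    for (i in seq_len(nrow(res$samples))) {
      if (in_interval(res$samples, r10$intervals, i))
        expect_true(in_interval(res$samples, r5$intervals, i))
      # no interval contains a collision sample
      if (res$samples$collision[i])
        expect_false(in_interval(res$samples, r5$intervals, i))
    }
  }
})

test_that("collision map is consistent with single-angle queries and symmetry", {
  slab <- make_slab(slab_spec(60, 300, 300, 2))
  iso <- c(0, 0, 0)
  m <- collision_map(slab, iso, c(0, 10), c(170, 180, 190), bl)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(m[1, 2],
               clearance_at(slab, arc_spec(iso, 0, 180, 180), bl)$clearance_mm)
  expect_equal(m[2, 3],
               clearance_at(slab, arc_spec(iso, 10, 190, 190), bl)$clearance_mm)
  # slab is symmetric in x: clearance(couch 0, g) = clearance(couch 0, 360-g)
  gs <- c(150, 160, 170, 185, 200)
  m2 <- collision_map(slab, iso, 0, gs, bl)
  m2r <- collision_map(slab, iso, 0, 360 - gs, bl)
  expect_equal(drop(m2), drop(m2r), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(collision_map(slab, iso, numeric(0), 180, bl))
})

test_that("rigid-motion consistency: rotating the contour equals adding couch angle", {
  set.seed(61)
  box <- make_box(box_spec(c(15, 90, -10), c(50, 40, 60), 5))
  iso <- c(5, -2, 7)
  for (delta in c(30, 125)) {
    direct <- clearance_at(box, arc_spec(iso, delta, 165, 165), bl)
    rot <- box
    rot$xyz <- sweep(sweep(box$xyz, 2, iso, "-") %*% t(rotation_y(delta)),
                     2, iso, "+")
    pre <- clearance_at(rot, arc_spec(iso, 0, 165, 165), bl)
    expect_equal(direct$clearance_mm, pre$clearance_mm, tolerance = 1e-9)
  }
})

test_that("brute-force reference agrees with the vectorized scan", {
  set.seed(71)
  box <- make_box(box_spec(c(10, 85, 5), c(60, 50, 70), 5))
  arc <- arc_spec(c(0, 0, 0), 20, 168, 192)
  s <- scan_arc(box, arc, bl)
  b <- brute_force_clearance(box, arc, bl, fine_step_deg = 1)
  expect_identical(s$samples$clearance_mm, b$samples$clearance_mm)
  expect_identical(s$samples$nearest_point_index,
                   b$samples$nearest_point_index)
  fine <- brute_force_clearance(box, arc, bl, fine_step_deg = 0.5)
  expect_lte(abs(fine$gantry_at_min_deg - s$gantry_at_min_deg),
             arc$step_deg)
})
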