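# Independently hand-expanded symbolic product of the three transform
# factors: swap . Rz(gantry) . Ry(couch). Each entry written out from the
# printed matrices by hand, kept free of the package's composition code.
oracle_bev_matrix <- function(couch_deg, gantry_deg) {
  cS <- cos(couch_deg * pi / 180); sS <- sin(couch_deg * pi / 180)
  cG <- cos(gantry_deg * pi / 180); sG <- sin(gantry_deg * pi / 180)
  rbind(c(cG * cS,  sG, cG * sS),
        c(-sS,      0,  cS),
        c(sG * cS, -cG, sG * sS))
}

oracle_bev_point <- function(p, iso, couch_deg, gantry_deg) {
  drop(oracle_bev_matrix(couch_deg, gantry_deg) %*% (p - iso))
}

# random support-frame cloud in the posterior hemisphere where hardware sits
random_support_cloud <- function(n = 100) {
  point_cloud(cbind(runif(n, -120, 120),
                    runif(n, 30, 150),
                    runif(n, -120, 120)), "support")
}

# deterministic family of randomized test geometries: a posterior box or
# slab plus an arc through the lower hemisphere
random_geometry <- function() {
  if (runif(1) < 0.5) {
    contour <- make_box(box_spec(
      center = c(runif(1, -30, 30), runif(1, 60, 140), runif(1, -30, 30)),
      dims = runif(3, 30, 90), grid_spacing_mm = 6))
  } else {
    contour <- make_slab(slab_spec(
      top_depth_mm = runif(1, 40, 120), width_mm = 200, length_mm = 200,
      grid_spacing_mm = 8))
  }
  start <- runif(1, 140, 200)
  arc <- arc_spec(isocenter = runif(3, -10, 10),
                  couch_deg = runif(1, 0, 360),
                  gantry_start_deg = start,
                  gantry_end_deg = start + 12)
  list(contour = contour, arc = arc)
}

# minimum distance from a point to a closed polyline (segment-wise oracle)
point_polyline_dist <- function(q, poly) {
  n <- nrow(poly)
  d <- Inf
  for (i in seq_len(n)) {
    a <- poly[i, ]
    b <- poly[if (i == n) 1L else i + 1L, ]
    ab <- b - a
    t <- sum((q - a) * ab) / sum(ab * ab)
    t <- min(max(t, 0), 1)
    d <- min(d, sqrt(sum((q - (a + t * ab))^2)))
  }
  d
}
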