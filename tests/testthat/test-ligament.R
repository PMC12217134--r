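test_that("principal-axis alignment recovers an oblique cylinder axis", {
  ph <- make_ligament_phantom(length = 2,
                              radius_profile = list(type = "constant",
                                                    r0 = 0.3),
                              axis_direction = c(1, 1, 1) / sqrt(3))
  al <- align_longitudinal(mesh_to_pointcloud(ph$mesh))
  ext <- apply(al$cloud$points, 2, function(w) diff(range(w)))
  expect_equal(ext[3], 2.0, tolerance = 0.02)
  expect_equal(ext[1], 0.6, tolerance = 0.04)
  expect_equal(ext[2], 0.6, tolerance = 0.04)
  rot <- al$frame$rotation
  expect_equal(crossprod(rot), diag(3), tolerance = 1e-10)
  expect_equal(det(rot), 1, tolerance = 1e-10)
})

test_that("a z-aligned cylinder keeps its axis and a sphere is degenerate", {
  ph <- make_ligament_phantom(length = 2,
                              radius_profile = list(type = "constant",
                                                    r0 = 0.3),
                              axis_direction = c(0, 0, 1))
  al <- align_longitudinal(mesh_to_pointcloud(ph$mesh))
  # longitudinal axis maps onto +/- z
  expect_equal(abs(al$frame$rotation[3, 3]), 1, tolerance = 1e-8)
  set.seed(11)
  u <- matrix(stats::rnorm(3000), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  expect_error(align_longitudinal(point_cloud(u)), "degenerate")
})

test_that("slice profiles recover analytic cross-sections", {
  ph <- make_ligament_phantom(length = 2,
                              radius_profile = list(type = "constant",
                                                    r0 = 0.3))
  al <- align_longitudinal(mesh_to_pointcloud(ph$mesh))
  prof <- slice_profile(al$cloud, morphometry_config("rat"))
  expect_equal(nrow(prof$sections), 20L)
  expect_true(all(abs(prof$sections$area - pi * 0.09) / (pi * 0.09) < 0.02))
  # one giant slab spans the whole ligament
  prof1 <- slice_profile(al$cloud, morphometry_config("rat", increment = 10))
  expect_equal(nrow(prof1$sections), 1L)
  expect_equal(prof1$sections$area[1], pi * 0.09, tolerance = 0.02 * pi * 0.09)
})

test_that("a cone profile gives strictly decreasing section areas", {
  ph <- make_ligament_phantom(length = 2,
                              radius_profile = list(type = "linear",
                                                    r0 = 0.4, r1 = 0.1))
  al <- align_longitudinal(mesh_to_pointcloud(ph$mesh))
  prof <- slice_profile(al$cloud, morphometry_config("rat"))
  areas <- prof$sections$area
  zc <- (prof$sections$z_lo + prof$sections$z_hi) / 2
  # radius shrinks along +z after skewness-fixed alignment; tolerate 2% noise
  if (areas[1] < areas[length(areas)]) areas <- rev(areas)
  expect_true(all(diff(areas) < 0.02 * areas[-length(areas)]))
  # oracle: analytic pi r(z)^2 at slab centers
  r_at <- 0.4 + (0.1 - 0.4) * (sort(zc) - min(zc) + 0.05) / 2
  expect_equal(sort(areas, decreasing = TRUE),
               sort(pi * r_at^2, decreasing = TRUE), tolerance = 0.05)
})

test_that("midsubstance selection follows the window arithmetic", {
  const <- structure(list(
    increment = 0.1, method = "hull", fraction = 0.5,
    sections = data.frame(z_lo = seq(0, 1.9, 0.1), z_hi = seq(0.1, 2, 0.1),
                          area = rep(0.30, 20), n_points = 50)),
    class = "csa_profile")
  expect_equal(midsubstance_csa(const, 0.5)$csa, 0.30)
  flared <- structure(list(
    increment = 1, method = "hull", fraction = 0.5,
    sections = data.frame(z_lo = 0:7, z_hi = 1:8,
                          area = c(1, 0.5, 0.3, 0.3, 0.3, 0.3, 0.5, 1),
                          n_points = 50)),
    class = "csa_profile")
  ms <- midsubstance_csa(flared, 0.5)
  expect_equal(ms$indices, 3:6)
  expect_equal(ms$csa, 0.30)
  expect_equal(midsubstance_csa(flared, 1.0)$csa, mean(flared$sections$area))
})

test_that("normalized CSA reproduces the printed cross-species arithmetic", {
  expect_equal(round_half_away(normalize_csa(0.26, 33.35), 2), 0.78)
  expect_equal(round_half_away(normalize_csa(0.054, 5.67), 2), 0.95)
  x <- c(0.1, 0.26, 0.4)
  expect_equal(normalize_csa(x, 2 * 33.35), normalize_csa(x, 33.35) / 2)
  expect_error(normalize_csa(0.3, 0), "positive")
})

test_that("midsubstance CSA is invariant to rigid rotation of the input", {
  ph <- make_ligament_phantom(length = 2,
                              radius_profile = list(type = "constant",
                                                    r0 = 0.3))
  base <- slice_profile(align_longitudinal(mesh_to_pointcloud(ph$mesh))$cloud,
                        morphometry_config("rat"))$midsubstance_csa
  set.seed(42)
  for (i in 1:20) {
    rot <- rodentmorph:::random_rotation()
    shift <- stats::rnorm(3, sd = 5)
    v <- sweep(ph$mesh$vertices %*% t(rot), 2, shift, "+")
    m <- triangle_mesh(v, ph$mesh$faces)
    csa <- slice_profile(align_longitudinal(mesh_to_pointcloud(m))$cloud,
                         morphometry_config("rat"))$midsubstance_csa
    expect_lt(abs(csa - base) / base, 0.01)
  }
})

test_that("hull and plane-intersection methods agree on convex sections", {
  ph <- make_ligament_phantom(length = 2,
                              radius_profile = list(type = "constant",
                                                    r0 = 0.3))
  al <- align_longitudinal(mesh_to_pointcloud(ph$mesh))
  amesh <- apply_alignment(ph$mesh, al$frame)
  hull <- slice_profile(al$cloud, morphometry_config("rat"))
  plane <- slice_profile(al$cloud,
                         morphometry_config("rat",
                                            csa_method = "plane_intersection"),
                         mesh = amesh)
  rel <- abs(hull$sections$area - plane$sections$area) / plane$sections$area
  expect_true(all(rel < 0.01))
})

test_that("hull over-estimates a crescent (non-convex) cross-section", {
  ph <- make_ligament_phantom(
    length = 2, radius_profile = list(type = "constant", r0 = 1),
    cross_section = list(type = "crescent", r_outer = 0.3, r_inner = 0.15,
                         offset = 0.25))
  al <- align_longitudinal(mesh_to_pointcloud(ph$mesh))
  amesh <- apply_alignment(ph$mesh, al$frame)
  hull <- slice_profile(al$cloud, morphometry_config("rat"))
  plane <- slice_profile(al$cloud,
                         morphometry_config("rat",
                                            csa_method = "plane_intersection"),
                         mesh = amesh)
  mid <- 5:15
  expect_true(all(hull$sections$area[mid] >= plane$sections$area[mid]))
  expect_gt(mean(hull$sections$area[mid]), 1.02 * mean(plane$sections$area[mid]))
})

test_that("tube CSA is recovered within 2% across rat and mouse scales", {
  for (r0 in c(0.1, 0.2, 0.3)) {
    ph <- make_ligament_phantom(length = 1.5,
                                radius_profile = list(type = "constant",
                                                      r0 = r0),
                                vertex_density = 4000)
    prof <- slice_profile(
      align_longitudinal(mesh_to_pointcloud(ph$mesh))$cloud,
      morphometry_config("mouse"))  # 0.05 mm increments
    expect_gte(min(prof$sections$n_points), 100)
    expect_lt(abs(prof$midsubstance_csa - pi * r0^2) / (pi * r0^2), 0.02)
  }
})

test_that("flared insertions are excluded from the midsubstance", {
  base <- make_ligament_phantom(length = 2,
                                radius_profile = list(type = "constant",
                                                      r0 = 0.3))
  flare <- make_ligament_phantom(
    length = 2, radius_profile = list(type = "flared", r_mid = 0.3,
                                      r_end = 0.45, flare_fraction = 0.2))
  get_ms <- function(ph) {
    slice_profile(align_longitudinal(mesh_to_pointcloud(ph$mesh))$cloud,
                  morphometry_config("rat"))$midsubstance_csa
  }
  expect_lt(abs(get_ms(flare) - get_ms(base)) / get_ms(base), 0.01)
})
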