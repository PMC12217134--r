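test_that("anatomic orientation applies and inverts exactly", {
  mp <- make_meniscus_phantom()
  fr_id <- anatomic_frame(diag(3), "lateral")
  cl <- orient_meniscus(mp$mesh, fr_id)
  expect_equal(cl$points, unname(mp$mesh$vertices))
  expect_identical(attr(cl, "side"), "lateral")
  rot <- rotation_about_axis(c(0, 0, 1), pi / 2)
  cl90 <- orient_meniscus(mp$mesh, anatomic_frame(rot, "lateral"))
  ext0 <- apply(cl$points, 2, function(w) diff(range(w)))
  ext90 <- apply(cl90$points, 2, function(w) diff(range(w)))
  expect_equal(ext90[c(2, 1, 3)], ext0, tolerance = 1e-9)
  back <- cl90$points %*% rot  # inverse rotation
  expect_lt(max(abs(back - cl$points)), 1e-9)
  expect_error(anatomic_frame(matrix(1:9, 3), "medial"), "orthonormal")
})

test_that("region slabs land on the apex and the two free ends", {
  mp <- make_meniscus_phantom(ring_radius = 2, sweep_degrees = 180,
                              section_width = 1, section_height = 0.8)
  cl <- orient_meniscus(mp$mesh, anatomic_frame(diag(3), "lateral"))
  cen <- select_region_slices(cl, "central", 0.1)
  expect_identical(attr(cen, "plane"), "coronal")
  # coronal slabs centered at the apex y (apex at (R+a, 0, 0))
  expect_lt(abs(mean(attr(cen, "centers")) - mp$manifest$apex[2]), 0.15)
  ant <- select_region_slices(cl, "anterior_horn", 0.1)
  pos <- select_region_slices(cl, "posterior_horn", 0.1)
  expect_identical(attr(ant, "plane"), "sagittal")
  # sagittal slabs near the free-end x (ends at x = 0); within the slab span
  expect_lt(abs(mean(attr(ant, "centers")) - mp$manifest$horn_ends[1, 1]), 0.6)
  expect_lt(abs(mean(attr(pos, "centers")) - mp$manifest$horn_ends[2, 1]), 0.6)
  # symmetric phantom: horn slabs mirror about the x axis within a voxel
  expect_lt(abs(mean(attr(ant, "centers")) - mean(attr(pos, "centers"))), 0.1)
  expect_error(select_region_slices(cl, "central", 10), "too large")
})

test_that("station spans measure rectangles, ellipses and wedges", {
  set.seed(2)
  rect <- cbind(stats::runif(5000, 0, 1), stats::runif(5000, 0, 0.4))
  mr <- measure_slice(rect, 10)
  expect_equal(mr$slice_width, 1.0, tolerance = 0.01)
  expect_equal(mr$slice_height, 0.4, tolerance = 0.01)
  expect_true(all(abs(mr$station_heights - 0.4) < 0.02))
  expect_true(all(abs(mr$station_widths - 1.0) < 0.02))
  ell <- make_ellipse_points(0.5, 0.2, n = 8000)
  me <- measure_slice(ell, 10)
  expect_equal(me$slice_width, 1.0, tolerance = 0.03)
  expect_equal(me$slice_height, 0.4, tolerance = 0.03)
  # triangular wedge: non-constant spans, so mean < max aggregation
  wedge <- cbind(stats::runif(5000), stats::runif(5000))
  wedge <- wedge[wedge[, 2] < wedge[, 1], ]
  expect_lt(measure_slice(wedge, 10, mode = "mean")$slice_height,
            measure_slice(wedge, 10, mode = "max")$slice_height)
})

test_that("regional summaries are slice means", {
  mk <- function(w, h) {
    structure(list(station_widths = rep(w, 10), station_heights = rep(h, 10),
                   slice_width = w, slice_height = h, n_stations = 10,
                   mode = "max"),
              class = "meniscus_slice_measure")
  }
  reg <- summarize_region(list(mk(1.0, 0.5), mk(1.2, 0.5), mk(1.1, 0.5)),
                          "central")
  expect_equal(reg$width, 1.1)
  expect_equal(reg$height, 0.5)
  same <- summarize_region(list(mk(1, 2), mk(1, 2), mk(1, 2)), "central")
  expect_equal(same$width, 1)
  expect_error(summarize_region(list(mk(1, 1), mk(1, 1)), "central"),
               "exactly 3")
})

test_that("torus-wedge phantom recovers central and horn dimensions", {
  mp <- make_meniscus_phantom(ring_radius = 2, sweep_degrees = 180,
                              section_width = 1.0, section_height = 0.8,
                              horn_scale = 1.2)
  reg <- meniscus_regions(mp$mesh, anatomic_frame(diag(3), "lateral"),
                          slice_thickness = 0.1)
  cen <- reg[reg$region == "central", ]
  expect_equal(cen$width_mm, 1.0, tolerance = 0.03)
  expect_equal(cen$height_mm, 0.8, tolerance = 0.03)
  horns <- reg[reg$region != "central", ]
  expect_true(all(abs(horns$width_mm - 1.2) / 1.2 < 0.05))
  # horns wider than the central region, as in the regional-width pattern
  expect_true(all(horns$width_mm > cen$width_mm))
  expect_true(all(abs(horns$width_mm / cen$width_mm - 1.2) < 0.06))
})

test_that("constant-section phantom gives equal regions on both sides", {
  for (side in c("lateral", "medial")) {
    mp <- make_meniscus_phantom(ring_radius = 2, section_width = 1.0,
                                section_height = 0.8, horn_scale = 1.0,
                                side = side)
    reg <- meniscus_regions(mp$mesh, anatomic_frame(diag(3), side),
                            slice_thickness = 0.1)
    expect_lt(diff(range(reg$width_mm)) / mean(reg$width_mm), 0.05)
    expect_lt(diff(range(reg$height_mm)) / mean(reg$height_mm), 0.05)
  }
})

test_that("regional values ignore point order and rigid translation", {
  mp <- make_meniscus_phantom(horn_scale = 1.2)
  fr <- anatomic_frame(diag(3), "lateral")
  base <- meniscus_regions(mp$mesh, fr, 0.1)
  set.seed(9)
  perm <- sample(nrow(mp$mesh$vertices))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  shuf <- triangle_mesh(mp$mesh$vertices[perm, ],
                        matrix(inv[mp$mesh$faces], ncol = 3),
                        name = mp$mesh$name)
  moved <- triangle_mesh(sweep(mp$mesh$vertices, 2, c(5, -3, 2), "+"),
                         mp$mesh$faces, name = mp$mesh$name)
  expect_equal(meniscus_regions(shuf, fr, 0.1)$width_mm, base$width_mm,
               tolerance = 1e-12)
  expect_equal(meniscus_regions(moved, fr, 0.1)$width_mm, base$width_mm,
               tolerance = 1e-9)
})
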