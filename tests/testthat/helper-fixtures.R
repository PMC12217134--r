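# shared fixtures built in code

# axis-aligned unit cube as 12 consistently wound triangles
make_cube_mesh <- function(side = 1) {
  v <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
  dimnames(v) <- NULL
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  triangle_mesh(v, f)
}

# voxelized solid sphere mask (center-in occupancy)
make_sphere_mask <- function(radius, voxel_size) {
  n <- as.integer(ceiling(2 * (radius + voxel_size) / voxel_size))
  cx <- (seq_len(n) - 0.5) * voxel_size - n * voxel_size / 2
  g <- expand.grid(x = cx, y = cx, z = cx)
  label_volume(array(as.integer(g$x^2 + g$y^2 + g$z^2 <= radius^2),
                     dim = c(n, n, n)), voxel_size)
}

# dense boundary+interior point sample of an axis-aligned ellipse (2D)
make_ellipse_points <- function(a, b, n = 4000, seed = 1) {
  set.seed(seed)
  th <- stats::runif(n, 0, 2 * pi)
  rr <- sqrt(stats::runif(n))
  cbind(a * rr * cos(th), b * rr * sin(th))
}

# write a complete phantom specimen (4 tube ligaments, 2 menisci, footprint)
# into dir and return the run config list
make_phantom_specimen <- function(dir, species = "rat", seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  radii <- c(ACL = 0.28, PCL = 0.33, MCL = 0.23, LCL = 0.27)
  ligs <- lapply(names(radii), function(nm) {
    ph <- make_ligament_phantom(
      length = 2, radius_profile = list(type = "constant", r0 = radii[[nm]]),
      vertex_density = 1200, axis_direction = c(0.2, 0.3, 0.93), seed = seed)
    p <- file.path(dir, paste0(nm, ".stl"))
    write_stl(ph$mesh, p, "binary")
    list(name = nm, path = p)
  })
  mens <- lapply(c("medial", "lateral"), function(sd1) {
    mp <- make_meniscus_phantom(ring_radius = 2, section_width = 1,
                                section_height = 0.8, horn_scale = 1.2,
                                side = sd1, seed = seed)
    p <- file.path(dir, paste0(sd1, "_meniscus.stl"))
    write_stl(mp$mesh, p, "binary")
    list(name = paste0(sd1, "_meniscus"), path = p, side = sd1, frame = NULL)
  })
  fp <- make_footprint_mask(list(type = "ellipse", a = 3.5, b = 3),
                            voxel_size = 0.1, seed = seed)
  fpath <- file.path(dir, "footprint.nii.gz")
  write_label_volume(fp$vol, fpath)
  list(specimen = basename(dir), species = species, ligaments = ligs,
       menisci = mens, footprint = fpath, seed = seed)
}

# independent Kruskal-Wallis H for the enumeration oracle (no package code)
oracle_kw_h <- function(values, g) {
  r <- rank(values)
  n <- length(values)
  agg <- tapply(r, g, sum)
  ns <- tapply(r, g, length)
  h <- 12 / (n * (n + 1)) * sum(agg^2 / ns) - 3 * (n + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / corr
}
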