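# Synthetic phantoms with analytic ground truth. Generators are pure
# functions of their arguments plus `seed`; surfaces are parametric lattices
# triangulated with end caps, watertight by construction.

# orthonormal basis (e1, e2) perpendicular to a unit axis u
perp_basis <- function(u) {
  u <- u / sqrt(sum(u^2))
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(u = u, e1 = e1, e2 = e2)
}

# triangulate a closed-ring lattice (nz rings of ntheta points, ring i
# vertices at rows (i-1)*ntheta + 1:ntheta) with fan caps to two apex rows
lattice_faces <- function(nz, ntheta, cap_lo, cap_hi) {
  f <- vector("list", nz - 1 + 2)
  for (i in seq_len(nz - 1)) {
    a <- (i - 1) * ntheta + seq_len(ntheta)
    b <- a + ntheta
    an <- c(a[-1], a[1])
    bn <- c(b[-1], b[1])
    f[[i]] <- rbind(cbind(a, an, bn), cbind(a, bn, b))
  }
  a <- seq_len(ntheta)
  an <- c(a[-1], a[1])
  f[[nz]] <- cbind(an, a, cap_lo)  # bottom cap
  a <- (nz - 1) * ntheta + seq_len(ntheta)
  an <- c(a[-1], a[1])
  f[[nz + 1]] <- cbind(a, an, cap_hi)  # top cap
  do.call(rbind, unname(f))
}

# crescent cross-section boundary: outer disc of radius r_outer minus an
# inner disc of radius r_inner centered at (offset, 0); returns a closed
# polygon (n points) and its analytic area
crescent_section <- function(r_outer, r_inner, offset, n = 96L) {
  d <- offset
  if (d + r_inner <= r_outer || d >= r_outer + r_inner) {
    stop("crescent requires the inner circle to cross the outer boundary")
  }
  # circle intersection points
  x0 <- (d^2 - r_inner^2 + r_outer^2) / (2 * d)
  y0 <- sqrt(max(0, r_outer^2 - x0^2))
  a_out <- atan2(y0, x0)            # outer-circle intersection angle
  a_in <- atan2(y0, x0 - d)         # inner-circle angle (about its center)
  n1 <- max(8L, as.integer(round(n * (2 * pi - 2 * a_out) / (2 * pi))))
  n2 <- max(8L, n - n1)
  th1 <- seq(a_out, 2 * pi - a_out, length.out = n1)
  outer <- cbind(r_outer * cos(th1), r_outer * sin(th1))
  th2 <- seq(-a_in, a_in, length.out = n2)  # traversed back along inner arc
  inner <- cbind(d + r_inner * cos(rev(th2)), r_inner * sin(rev(th2)))
  poly <- rbind(outer, inner[-1, , drop = FALSE])
  poly <- poly[!duplicated(round(poly, 12)), , drop = FALSE]
  # lens (overlap) area of the two discs
  lens <- r_outer^2 * acos(x0 / r_outer) - x0 * y0 +
    r_inner^2 * acos((d - x0) / r_inner) - (d - x0) * y0
  list(poly = poly, area = pi * r_outer^2 - lens)
}

radius_profile_fun <- function(rp, length) {
  type <- rp$type
  if (is.null(type)) stop("radius_profile needs a 'type'")
  switch(type,
    constant = {
      if (rp$r0 <= 0) stop("radius must be positive")
      function(z) rep(rp$r0, length(z))
    },
    linear = {
      if (rp$r0 <= 0 || rp$r1 <= 0) stop("radii must be positive")
      function(z) rp$r0 + (rp$r1 - rp$r0) * z / length
    },
    flared = {
      if (rp$r_mid <= 0 || rp$r_end <= 0) stop("radii must be positive")
      ff <- rp$flare_fraction
      if (ff <= 0 || ff >= 0.5) stop("flare_fraction must be in (0, 0.5)")
      function(z) {
        u <- z / length
        ramp <- pmax(0, pmin(1, pmax(ff - u, u - (1 - ff)) / ff))
        rp$r_mid + (rp$r_end - rp$r_mid) * ramp
      }
    },
    stop("unknown radius_profile type: ", type))
}

#' Generate a tube-like ligament phantom
#'
#' A watertight tube along `axis_direction` whose cross-section (circle,
#' ellipse, or crescent) is scaled along the length by a radius profile.
#' For a circular section the profile value is the radius in mm; for ellipse
#' and crescent sections the stated dimensions are taken at profile value 1
#' and the profile acts as a dimensionless scale. The manifest carries the
#' analytic CSA at every ring z and the analytic midsubstance CSA (mean of
#' the analytic CSA over the middle `midsubstance_fraction` of the length).
#'
#' @param length tube length in mm.
#' @param radius_profile list: `list(type = "constant", r0 = )`,
#'   `list(type = "linear", r0 = , r1 = )`, or `list(type = "flared",
#'   r_mid = , r_end = , flare_fraction = )`.
#' @param cross_section list: `list(type = "circle")`,
#'   `list(type = "ellipse", a = , b = )`, or `list(type = "crescent",
#'   r_outer = , r_inner = , offset = )`.
#' @param axis_direction 3-vector (normalized internally).
#' @param vertex_density target surface density in points per mm^2.
#' @param jitter_sd optional Gaussian vertex jitter in mm (stress testing).
#' @param seed RNG seed (used only by `jitter_sd`; geometry is
#'   deterministic).
#' @param midsubstance_fraction fraction used for the manifest's analytic
#'   midsubstance value (default 0.5).
#' @return A list with `mesh` (a [triangle_mesh()]) and `manifest` (analytic
#'   ground truth and the generating parameters).
#' @export
make_ligament_phantom <- function(length = 2,
                                  radius_profile = list(type = "constant",
                                                        r0 = 0.3),
                                  cross_section = list(type = "circle"),
                                  axis_direction = c(0, 0, 1),
                                  vertex_density = 2000,
                                  jitter_sd = 0, seed = 1L,
                                  midsubstance_fraction = 0.5) {
  if (length <= 0) stop("length must be positive")
  rfun <- radius_profile_fun(radius_profile, length)
  cs_type <- cross_section$type
  if (cs_type == "circle") {
    base <- NULL
    unit_area <- pi
    ref_r <- max(rfun(seq(0, length, length.out = 101)))
  } else if (cs_type == "ellipse") {
    if (cross_section$a <= 0 || cross_section$b <= 0) {
      stop("ellipse semi-axes must be positive")
    }
    unit_area <- pi * cross_section$a * cross_section$b
    ref_r <- max(cross_section$a, cross_section$b)
  } else if (cs_type == "crescent") {
    cres <- crescent_section(cross_section$r_outer, cross_section$r_inner,
                             cross_section$offset)
    unit_area <- cres$area
    ref_r <- cross_section$r_outer
  } else stop("unknown cross_section type: ", cs_type)
  h <- 1 / sqrt(vertex_density)
  circ <- 2 * pi * ref_r
  ntheta <- max(48L, as.integer(ceiling(circ / h)))
  nz <- max(20L, as.integer(ceiling(length / h)) + 1L)
  zs <- seq(0, length, length.out = nz)
  scale <- rfun(zs)
  if (cs_type == "circle") {
    th <- seq(0, 2 * pi, length.out = ntheta + 1L)[-(ntheta + 1L)]
    sec <- cbind(cos(th), sin(th))
  } else if (cs_type == "ellipse") {
    th <- seq(0, 2 * pi, length.out = ntheta + 1L)[-(ntheta + 1L)]
    sec <- cbind(cross_section$a * cos(th), cross_section$b * sin(th))
  } else {
    sec <- crescent_section(cross_section$r_outer, cross_section$r_inner,
                            cross_section$offset, n = ntheta)$poly
    ntheta <- nrow(sec)
  }
  bs <- perp_basis(axis_direction)
  verts <- matrix(0, nz * ntheta + 2L, 3L)
  for (i in seq_len(nz)) {
    xy <- sec * scale[i]
    rows <- (i - 1L) * ntheta + seq_len(ntheta)
    zc <- zs[i] - length / 2
    verts[rows, ] <- outer(xy[, 1], bs$e1) + outer(xy[, 2], bs$e2) +
      matrix(zc * bs$u, ntheta, 3L, byrow = TRUE)
  }
  cap_lo <- nz * ntheta + 1L
  cap_hi <- nz * ntheta + 2L
  verts[cap_lo, ] <- (0 - length / 2) * bs$u
  verts[cap_hi, ] <- (length - length / 2) * bs$u
  if (jitter_sd > 0) {
    set.seed(seed)
    verts <- verts + matrix(stats::rnorm(length(verts), sd = jitter_sd),
                            ncol = 3L)
  }
  faces <- lattice_faces(nz, ntheta, cap_lo, cap_hi)
  mesh <- triangle_mesh(verts, faces, name = "other")
  csa <- unit_area * if (cs_type == "circle") scale^2 else scale^2
  zfine <- seq(0, length, length.out = 2001L)
  afine <- unit_area * rfun(zfine)^2
  f <- midsubstance_fraction
  win <- zfine >= (1 - f) / 2 * length & zfine <= (1 + f) / 2 * length
  manifest <- list(
    kind = "ligament_phantom",
    parameters = list(length = length, radius_profile = radius_profile,
                      cross_section = cross_section,
                      axis_direction = axis_direction,
                      vertex_density = vertex_density, jitter_sd = jitter_sd,
                      seed = seed),
    csa_by_z = data.frame(z = zs, area = csa),
    midsubstance_csa = mean(afine[win]),
    midsubstance_fraction = f)
  list(mesh = mesh, manifest = manifest)
}

#' Generate a C-shaped meniscus phantom
#'
#' An elliptical cross-section (width `section_width` = 2a radially, height
#' `section_height` = 2b proximo-distally) swept along a circular arc of
#' radius `ring_radius` spanning `sweep_degrees`, with the circumferential
#' apex on the +x (lateral) side and the two free ends (horns) toward +y
#' (anterior) and -y (posterior). The outer fifth of the arc at each end is
#' scaled by `horn_scale`. For `side = "medial"` the phantom is mirrored in
#' x.
#'
#' @param ring_radius arc radius in mm (must exceed a).
#' @param sweep_degrees arc span in degrees, in (90, 360).
#' @param section_width full radial width 2a in mm.
#' @param section_height full height 2b in mm.
#' @param horn_scale multiplier applied to the end fifths of the arc.
#' @param side `"lateral"` (apex at +x, default) or `"medial"` (mirrored).
#' @param n_phi,n_psi lattice resolution along the arc and around the
#'   section.
#' @param seed recorded for provenance; the geometry is deterministic.
#' @return A list with `mesh` and `manifest` (regional analytic
#'   widths/heights, apex and horn coordinates).
#' @export
make_meniscus_phantom <- function(ring_radius = 2, sweep_degrees = 180,
                                  section_width = 1.0, section_height = 0.8,
                                  horn_scale = 1.0,
                                  side = c("lateral", "medial"),
                                  n_phi = 181L, n_psi = 64L, seed = 1L) {
  side <- match.arg(side)
  a <- section_width / 2
  b <- section_height / 2
  if (ring_radius <= a) stop("ring_radius must exceed the section half-width")
  if (sweep_degrees <= 90 || sweep_degrees >= 360) {
    stop("sweep_degrees must lie in (90, 360)")
  }
  if (horn_scale <= 0) stop("horn_scale must be positive")
  half <- sweep_degrees / 2 * pi / 180
  phis <- seq(-half, half, length.out = n_phi)
  # end fifths of the arc carry the horn scale
  s <- ifelse(abs(phis) >= (1 - 2 / 5) * half, horn_scale, 1)
  psi <- seq(0, 2 * pi, length.out = n_psi + 1L)[-(n_psi + 1L)]
  verts <- matrix(0, n_phi * n_psi + 2L, 3L)
  for (i in seq_len(n_phi)) {
    rad <- ring_radius + a * s[i] * cos(psi)
    rows <- (i - 1L) * n_psi + seq_len(n_psi)
    verts[rows, ] <- cbind(rad * cos(phis[i]), rad * sin(phis[i]),
                           b * s[i] * sin(psi))
  }
  cap_lo <- n_phi * n_psi + 1L
  cap_hi <- n_phi * n_psi + 2L
  verts[cap_lo, ] <- c(ring_radius * cos(phis[1]),
                       ring_radius * sin(phis[1]), 0)
  verts[cap_hi, ] <- c(ring_radius * cos(phis[n_phi]),
                       ring_radius * sin(phis[n_phi]), 0)
  if (side == "medial") verts[, 1] <- -verts[, 1]
  faces <- lattice_faces(n_phi, n_psi, cap_lo, cap_hi)
  nm <- if (side == "medial") "medial_meniscus" else "lateral_meniscus"
  mesh <- triangle_mesh(verts, faces, name = nm)
  sgn <- if (side == "medial") -1 else 1
  manifest <- list(
    kind = "meniscus_phantom",
    parameters = list(ring_radius = ring_radius,
                      sweep_degrees = sweep_degrees,
                      section_width = section_width,
                      section_height = section_height,
                      horn_scale = horn_scale, side = side, seed = seed),
    central = list(width = section_width, height = section_height),
    anterior_horn = list(width = section_width * horn_scale,
                         height = section_height * horn_scale),
    posterior_horn = list(width = section_width * horn_scale,
                          height = section_height * horn_scale),
    apex = c(sgn * (ring_radius + a), 0, 0),
    horn_ends = rbind(
      anterior = c(sgn * ring_radius * cos(half), ring_radius * sin(half), 0),
      posterior = c(sgn * ring_radius * cos(half), -ring_radius * sin(half),
                    0)))
  list(mesh = mesh, manifest = manifest)
}

#' Generate a single-axial-slice footprint mask
#'
#' Voxel centers are tested against an analytic ellipse or a seeded smooth
#' blob (radius modulated by a few random harmonics); the mask occupies one
#' axial slice, as in the tibial plateau footprint segmentation.
#'
#' @param shape `list(type = "ellipse", a = , b = )` (semi-axes in mm) or
#'   `list(type = "blob", r = , amplitude = )`.
#' @param voxel_size voxel edge in mm.
#' @param seed RNG seed (blob harmonics only).
#' @return A list with `vol` (a [label_volume()], axial axis 3) and
#'   `manifest` (`n_voxels`, exact `area_mm2`, and for the ellipse the
#'   analytic `analytic_area`).
#' @export
make_footprint_mask <- function(shape = list(type = "ellipse", a = 3, b = 2),
                                voxel_size = 0.05, seed = 1L) {
  if (voxel_size <= 0) stop("voxel_size must be positive")
  if (shape$type == "ellipse") {
    a <- shape$a; b <- shape$b
    rmax <- max(a, b)
    inside_fun <- function(x, y) (x / a)^2 + (y / b)^2 <= 1
    analytic <- pi * a * b
  } else if (shape$type == "blob") {
    set.seed(seed)
    r0 <- shape$r
    amp <- if (is.null(shape$amplitude)) 0.15 else shape$amplitude
    kmax <- 5L
    amps <- stats::runif(kmax, 0, amp) * r0
    phases <- stats::runif(kmax, 0, 2 * pi)
    rmax <- r0 * (1 + amp * kmax)
    inside_fun <- function(x, y) {
      th <- atan2(y, x)
      rr <- r0 + Reduce(`+`, lapply(seq_len(kmax), function(k) {
        amps[k] * cos(k * th + phases[k])
      }))
      x^2 + y^2 <= rr^2
    }
    analytic <- NA_real_
  } else stop("unknown footprint shape: ", shape$type)
  n <- as.integer(ceiling(2 * (rmax + voxel_size) / voxel_size))
  cx <- (seq_len(n) - 0.5) * voxel_size - (n * voxel_size) / 2
  g <- expand.grid(x = cx, y = cx)
  occ <- inside_fun(g$x, g$y)
  mask <- array(0L, dim = c(n, n, 1L))
  mask[, , 1] <- matrix(as.integer(occ), n, n)
  vol <- label_volume(mask, voxel_size,
                      axis_labels = c("sagittal", "coronal", "axial"))
  manifest <- list(kind = "footprint_mask",
                   parameters = c(shape, voxel_size = voxel_size,
                                  seed = seed),
                   n_voxels = sum(mask), area_mm2 = sum(mask) * voxel_size^2,
                   analytic_area = analytic)
  list(vol = vol, manifest = manifest)
}

#' Simulate paired rater/method measurements
#'
#' Subjects are drawn from Normal(mu, subject_sd^2); each of the two raters
#' adds its own bias and Normal(0, error_sd^2) noise. The manifest records
#' the analytic two-way absolute-agreement single-score ICC target
#' `subject_sd^2 / (subject_sd^2 + rater_bias^2 / 2 + error_sd^2)` and the
#' Bland-Altman bias convention `d = rater1 - rater2` (so a positive
#' `rater_bias` added to rater 2 yields bias `-rater_bias`).
#'
#' @param n number of subjects (>= 3).
#' @param subject_sd between-subject SD.
#' @param rater_bias systematic offset added to rater 2.
#' @param error_sd within-rater measurement SD.
#' @param mu grand mean (default 10).
#' @param seed RNG seed.
#' @return A list with `table` (data frame: subject, rater1, rater2) and
#'   `manifest`.
#' @export
make_agreement_pairs <- function(n = 10L, subject_sd = 2, rater_bias = 0,
                                 error_sd = 1, mu = 10, seed = 1L) {
  if (n < 3L) stop("need n >= 3 subjects")
  if (subject_sd < 0 || error_sd < 0) stop("SDs must be >= 0")
  set.seed(seed)
  subj <- mu + stats::rnorm(n, sd = subject_sd)
  r1 <- subj + stats::rnorm(n, sd = error_sd)
  r2 <- subj + rater_bias + stats::rnorm(n, sd = error_sd)
  icc_target <- if (subject_sd == 0 && error_sd == 0 && rater_bias == 0) 1 else
    subject_sd^2 / (subject_sd^2 + rater_bias^2 / 2 + error_sd^2)
  list(table = data.frame(subject = seq_len(n), rater1 = r1, rater2 = r2),
       manifest = list(kind = "agreement_pairs",
                       parameters = list(n = n, subject_sd = subject_sd,
                                         rater_bias = rater_bias,
                                         error_sd = error_sd, mu = mu,
                                         seed = seed),
                       icc_target = icc_target,
                       ba_bias = -rater_bias))
}

#' Simulate a tidy morphometry cohort table
#'
#' Draws per-specimen values around supplied group means (e.g. the printed
#' per-tissue CSA means and SDs), producing a tidy table consumable by the
#' statistics stage.
#'
#' @param effects data frame of factor columns plus a `mean` column and
#'   optionally an `sd` column (overrides `noise_sd` per group).
#' @param noise_sd common within-group SD when `effects$sd` is absent.
#' @param n_per_group specimens per group (>= 2).
#' @param seed RNG seed.
#' @return A list with `table` (tidy data frame: `specimen`, the factor
#'   columns, `value`) and `manifest` (true means/SDs).
#' @export
make_cohort_table <- function(effects, noise_sd = 0, n_per_group = 10L,
                              seed = 1L) {
  if (n_per_group < 2L) stop("n_per_group must be >= 2")
  if (!is.data.frame(effects) || !"mean" %in% names(effects)) {
    stop("effects must be a data frame with a 'mean' column")
  }
  set.seed(seed)
  sds <- if ("sd" %in% names(effects)) effects$sd else
    rep(noise_sd, nrow(effects))
  fac_cols <- setdiff(names(effects), c("mean", "sd"))
  rows <- lapply(seq_len(nrow(effects)), function(i) {
    vals <- effects$mean[i] + stats::rnorm(n_per_group, sd = sds[i])
    cbind(data.frame(specimen = seq_len(n_per_group)),
          effects[rep(i, n_per_group), fac_cols, drop = FALSE],
          data.frame(value = vals, row.names = NULL))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab,
       manifest = list(kind = "cohort_table",
                       parameters = list(noise_sd = noise_sd,
                                         n_per_group = n_per_group,
                                         seed = seed),
                       true_means = effects))
}
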