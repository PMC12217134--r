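#' Morphometry configuration
#'
#' Species presets fix the slicing increment used for CSA profiles: 0.1 mm for
#' rat and 0.05 mm for mouse, matching the source voxel sizes.
#'
#' @param species `"rat"` or `"mouse"`.
#' @param increment slab thickness Delta-z in mm; defaults to the species
#'   preset.
#' @param midsubstance_fraction fraction of the ligament length (centered)
#'   averaged into the midsubstance CSA; default 0.50.
#' @param csa_method `"hull"` (2D convex hull of the flattened slab points,
#'   default) or `"plane_intersection"` (polygon area of the mesh/mid-plane
#'   section, used as a geometric cross-check).
#' @param alpha significance level carried into the statistics stage.
#' @return A list of class `morphometry_config`.
#' @export
morphometry_config <- function(species = c("rat", "mouse"), increment = NULL,
                               midsubstance_fraction = 0.5,
                               csa_method = c("hull", "plane_intersection"),
                               alpha = 0.05) {
  species <- match.arg(species)
  csa_method <- match.arg(csa_method)
  if (is.null(increment)) increment <- if (species == "rat") 0.1 else 0.05
  if (increment <= 0) stop("increment must be positive")
  if (midsubstance_fraction <= 0 || midsubstance_fraction > 1) {
    stop("midsubstance_fraction must be in (0, 1]")
  }
  structure(list(species = species, increment = increment,
                 midsubstance_fraction = midsubstance_fraction,
                 csa_method = csa_method, alpha = alpha),
            class = "morphometry_config")
}

#' Align a ligament point cloud to its longitudinal axis
#'
#' The longitudinal axis is the first principal component of the centered
#' cloud and is mapped onto +z; the second and third components become x and
#' y. The z sign is chosen so the skewness of the aligned z coordinates is
#' nonnegative, making the frame deterministic; x is fixed by orienting the
#' second component's largest-magnitude entry positive and y completes a
#' right-handed frame.
#'
#' @param cloud a [point_cloud()].
#' @param min_extent_ratio minimum ratio of first to second principal extent
#'   below which the axis is considered degenerate (default 1.2).
#' @return A list with `cloud` (the aligned [point_cloud()]) and `frame` (a
#'   list with the 3x3 `rotation` applied after subtracting `centroid`).
#' @export
align_longitudinal <- function(cloud, min_extent_ratio = 1.2) {
  stopifnot(inherits(cloud, "point_cloud"))
  p <- cloud$points
  if (nrow(p) < 4L) stop("need at least 4 points for axis alignment")
  centroid <- colMeans(p)
  pc <- sweep(p, 2, centroid)
  sv <- svd(pc, nu = 0)
  ax <- sv$v  # columns: principal directions
  proj <- pc %*% ax
  extents <- apply(proj, 2, function(w) diff(range(w)))
  if (extents[2] == 0 || extents[1] / extents[2] < min_extent_ratio) {
    stop("degenerate longitudinal axis: extent ratio ",
         signif(extents[1] / max(extents[2], .Machine$double.eps), 4),
         " < ", min_extent_ratio)
  }
  zdir <- ax[, 1]
  zc <- as.vector(pc %*% zdir)
  if (mean((zc - mean(zc))^3) < 0) zdir <- -zdir
  xdir <- ax[, 2]
  if (xdir[which.max(abs(xdir))] < 0) xdir <- -xdir
  ydir <- c(zdir[2] * xdir[3] - zdir[3] * xdir[2],
            zdir[3] * xdir[1] - zdir[1] * xdir[3],
            zdir[1] * xdir[2] - zdir[2] * xdir[1])
  rot <- rbind(xdir, ydir, zdir)
  dimnames(rot) <- NULL
  aligned <- pc %*% t(rot)
  frame <- list(rotation = rot, centroid = centroid)
  list(cloud = point_cloud(aligned, source = cloud$source), frame = frame)
}

#' Apply an alignment frame to a point cloud or mesh
#'
#' @param x a [point_cloud()] or [triangle_mesh()].
#' @param frame an alignment frame from [align_longitudinal()].
#' @return Object of the same class expressed in the aligned coordinates.
#' @export
apply_alignment <- function(x, frame) {
  rot <- frame$rotation
  if (inherits(x, "point_cloud")) {
    point_cloud(sweep(x$points, 2, frame$centroid) %*% t(rot),
                source = x$source)
  } else if (inherits(x, "triangle_mesh")) {
    triangle_mesh(sweep(x$vertices, 2, frame$centroid) %*% t(rot),
                  x$faces, name = x$name)
  } else stop("x must be a point_cloud or triangle_mesh")
}

# area of the 2D convex hull of a point set (shoelace on the hull polygon)
hull_area <- function(xy) {
  xy <- unique(xy)
  if (nrow(xy) < 3L) return(0)
  h <- grDevices::chull(xy[, 1], xy[, 2])
  if (length(h) < 3L) return(0)
  x <- xy[h, 1]; y <- xy[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# total enclosed area of the polygon loops where a watertight mesh meets the
# plane z = zc; holes (nested loops) are subtracted by containment parity.
mesh_plane_section_area <- function(mesh, zc) {
  v <- mesh$vertices
  f <- mesh$faces
  if (any(abs(v[, 3] - zc) < 1e-12)) zc <- zc + 1e-9
  above <- v[, 3] > zc
  s <- above[f[, 1]] + above[f[, 2]] + above[f[, 3]]
  cross_tri <- which(s == 1L | s == 2L)
  if (length(cross_tri) == 0L) return(0)
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  seg_a <- character(length(cross_tri))
  seg_b <- character(length(cross_tri))
  pts <- new.env(parent = emptyenv())
  for (q in seq_along(cross_tri)) {
    tr <- f[cross_tri[q], ]
    eds <- rbind(tr[c(1, 2)], tr[c(2, 3)], tr[c(3, 1)])
    hit <- which(above[eds[, 1]] != above[eds[, 2]])
    keys <- character(2)
    for (w in 1:2) {
      a <- eds[hit[w], 1]; b <- eds[hit[w], 2]
      key <- edge_key(a, b)
      if (is.null(pts[[key]])) {
        tt <- (zc - v[a, 3]) / (v[b, 3] - v[a, 3])
        pts[[key]] <- v[a, 1:2] + tt * (v[b, 1:2] - v[a, 1:2])
      }
      keys[w] <- key
    }
    seg_a[q] <- keys[1]; seg_b[q] <- keys[2]
  }
  # chain segments into loops: each crossed edge touches exactly two
  # crossing triangles on a watertight mesh
  nbr <- new.env(parent = emptyenv())
  for (q in seq_along(seg_a)) {
    nbr[[seg_a[q]]] <- c(nbr[[seg_a[q]]], seg_b[q])
    nbr[[seg_b[q]]] <- c(nbr[[seg_b[q]]], seg_a[q])
  }
  visited <- new.env(parent = emptyenv())
  loops <- list()
  for (start in ls(nbr)) {
    if (!is.null(visited[[start]])) next
    loop <- character(0)
    cur <- start
    prev <- ""
    repeat {
      visited[[cur]] <- TRUE
      loop <- c(loop, cur)
      cand <- nbr[[cur]]
      cand <- cand[cand != prev]
      unv <- cand[vapply(cand, function(k) is.null(visited[[k]]),
                         logical(1))]
      if (length(unv) == 0L) break
      prev <- cur
      cur <- unv[1]
    }
    if (length(loop) >= 3L) loops[[length(loops) + 1L]] <- loop
  }
  if (length(loops) == 0L) return(0)
  polys <- lapply(loops, function(lp) {
    do.call(rbind, lapply(lp, function(k) pts[[k]]))
  })
  areas <- vapply(polys, function(pl) {
    x <- pl[, 1]; y <- pl[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }, numeric(1))
  if (length(polys) == 1L) return(areas)
  # nesting depth by even-odd containment of each loop's first vertex
  depth <- vapply(seq_along(polys), function(i) {
    pt <- polys[[i]][1, ]
    sum(vapply(seq_along(polys), function(j) {
      if (j == i) return(FALSE)
      point_in_polygon(pt, polys[[j]])
    }, logical(1)))
  }, numeric(1))
  sum(areas * ifelse(depth %% 2 == 0, 1, -1))
}

point_in_polygon <- function(pt, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((poly[i, 2] > pt[2]) != (poly[j, 2] > pt[2])) {
      xint <- poly[j, 1] + (pt[2] - poly[j, 2]) / (poly[i, 2] - poly[j, 2]) *
        (poly[i, 1] - poly[j, 1])
      if (pt[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Slice an aligned ligament into a cross-sectional-area profile
#'
#' The aligned cloud is cut into half-open slabs `[z_lo, z_lo + increment)`
#' starting at the minimum z. Each slab's points are flattened onto the x-y
#' plane (orthographic projection along z, no obliquity correction) and the
#' slab CSA computed either as the area of the 2D convex hull of those points
#' (default) or as the enclosed polygon area where the source mesh intersects
#' the slab's mid-plane. A trailing partial slab is kept only if it holds at
#' least 3 points; interior slabs with fewer than 3 non-collinear points get
#' area 0 with a warning.
#'
#' @param cloud an aligned [point_cloud()] (see [align_longitudinal()]).
#' @param cfg a [morphometry_config()].
#' @param mesh the aligned [triangle_mesh()]; required for
#'   `csa_method = "plane_intersection"`.
#' @return An object of class `csa_profile` with the per-slab table
#'   (`sections`), the increment, the method, and the midsubstance CSA.
#' @export
slice_profile <- function(cloud, cfg = morphometry_config(), mesh = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  p <- cloud$points
  dz <- cfg$increment
  zmin <- min(p[, 3])
  zmax <- max(p[, 3])
  nbin <- max(1L, as.integer(ceiling((zmax - zmin) / dz - 1e-9)))
  bin <- pmin(nbin, floor((p[, 3] - zmin) / dz) + 1L)
  counts <- tabulate(bin, nbins = nbin)
  # trailing partial slab dropped if nearly empty
  z_hi_last <- zmin + nbin * dz
  if (nbin > 1L && z_hi_last > zmax + 1e-12 && counts[nbin] < 3L) {
    keep_bins <- seq_len(nbin - 1L)
  } else keep_bins <- seq_len(nbin)
  areas <- numeric(length(keep_bins))
  npts <- integer(length(keep_bins))
  for (i in seq_along(keep_bins)) {
    b <- keep_bins[i]
    sel <- bin == b
    npts[i] <- sum(sel)
    if (cfg$csa_method == "hull") {
      if (npts[i] < 3L) {
        warning("slab ", b, " has fewer than 3 points; area set to 0")
        areas[i] <- 0
      } else {
        areas[i] <- hull_area(p[sel, 1:2, drop = FALSE])
      }
    } else {
      if (is.null(mesh)) {
        stop("csa_method = 'plane_intersection' requires the aligned mesh")
      }
      zc <- zmin + (b - 0.5) * dz
      areas[i] <- mesh_plane_section_area(mesh, zc)
    }
  }
  sections <- data.frame(
    z_lo = zmin + (keep_bins - 1L) * dz,
    z_hi = pmin(zmin + keep_bins * dz, zmax),  # last slab may be shorter
    area = areas, n_points = npts)
  prof <- structure(list(increment = dz, sections = sections,
                         method = cfg$csa_method,
                         fraction = cfg$midsubstance_fraction,
                         midsubstance_csa = NA_real_,
                         source = cloud$source),
                    class = "csa_profile")
  ms <- midsubstance_csa(prof, cfg$midsubstance_fraction)
  prof$midsubstance_csa <- ms$csa
  prof$midsubstance_sections <- ms$indices
  prof
}

#' Midsubstance cross-sectional area
#'
#' Unweighted mean of the slab CSAs whose slab center lies in the central
#' `fraction` of the ligament's z-extent; the flared insertion regions at
#' both ends are excluded.
#'
#' @param profile a `csa_profile` from [slice_profile()].
#' @param fraction centered fraction of the length to keep (default 0.5).
#' @return A list with `csa` (mm^2) and `indices` of the included sections.
#' @export
midsubstance_csa <- function(profile, fraction = 0.5) {
  stopifnot(inherits(profile, "csa_profile"))
  sec <- profile$sections
  if (nrow(sec) < 1L) stop("profile has no sections")
  zmin <- min(sec$z_lo)
  L <- max(sec$z_hi) - zmin
  lo <- zmin + (1 - fraction) / 2 * L
  hi <- zmin + (1 + fraction) / 2 * L
  centers <- (sec$z_lo + sec$z_hi) / 2
  idx <- which(centers >= lo - 1e-12 & centers <= hi + 1e-12)
  if (length(idx) == 0L) {
    stop("no section center falls inside the midsubstance window; ",
         "increment too coarse for this fraction")
  }
  list(csa = mean(sec$area[idx]), indices = idx)
}

#' Normalize a ligament CSA to bone size
#'
#' Expresses a ligament CSA as a percentage of the tibial plateau footprint
#' area, enabling scaled cross-species comparison.
#'
#' @param csa ligament CSA in mm^2.
#' @param footprint tibial plateau footprint area in mm^2 (> 0).
#' @return Normalized CSA in percent (100 * csa / footprint).
#' @export
normalize_csa <- function(csa, footprint) {
  if (!is.numeric(footprint) || any(footprint <= 0)) {
    stop("footprint area must be positive")
  }
  100 * csa / footprint
}

#' @export
print.csa_profile <- function(x, ...) {
  cat(sprintf("csa_profile '%s' (%s method): %d sections at dz = %g mm\n",
              x$source, x$method, nrow(x$sections), x$increment))
  cat(sprintf("  midsubstance CSA (middle %.0f%%): %.4f mm^2 over %d sections\n",
              100 * x$fraction, x$midsubstance_csa,
              length(x$midsubstance_sections)))
  invisible(x)
}

#' @export
plot.csa_profile <- function(x, ...) {
  sec <- x$sections
  zc <- (sec$z_lo + sec$z_hi) / 2
  graphics::plot(zc, sec$area, type = "b", xlab = "z (mm)",
                 ylab = expression(CSA ~ (mm^2)),
                 main = sprintf("CSA profile: %s", x$source), ...)
  inc <- x$midsubstance_sections
  graphics::points(zc[inc], sec$area[inc], pch = 16)
  graphics::abline(h = x$midsubstance_csa, lty = 2)
  invisible(x)
}
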