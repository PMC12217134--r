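#' Anatomic coordinate frame
#'
#' Rotation from the scanner/export coordinates to anatomic axes:
#' x = medial-lateral (positive toward lateral), y = posterior-anterior
#' (positive toward anterior), z = distal-proximal. The frame is supplied by
#' the user (e.g. from a saved registration); it is not derived from the
#' data.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param side `"medial"` or `"lateral"`; decides which x-extremum is the
#'   circumferential apex of the meniscus.
#' @return A list of class `anatomic_frame`.
#' @export
anatomic_frame <- function(rotation = diag(3), side = c("medial", "lateral")) {
  side <- match.arg(side)
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    stop("rotation must be orthonormal")
  }
  if (det(rotation) < 0) stop("rotation must be proper (determinant +1)")
  structure(list(rotation = rotation, side = side), class = "anatomic_frame")
}

#' Express a meniscus mesh in anatomic coordinates
#'
#' @param mesh a [triangle_mesh()].
#' @param frame an [anatomic_frame()].
#' @return A [point_cloud()] of the mesh vertices in anatomic axes, with the
#'   side label attached as attribute `"side"`.
#' @export
orient_meniscus <- function(mesh, frame) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(frame, "anatomic_frame"))
  pts <- mesh$vertices %*% t(frame$rotation)
  cl <- point_cloud(pts, source = mesh$name)
  attr(cl, "side") <- frame$side
  cl
}

#' Select the three measurement slabs for a meniscal region
#'
#' Central region: three contiguous coronal slabs (stacked along the
#' anterior-posterior axis) centered on the circumferential apex, i.e. the
#' point at the extreme medial-lateral coordinate toward the tissue side
#' (lateral-most for a lateral meniscus, medial-most for a medial one).
#' Anterior/posterior horn: three contiguous sagittal slabs (stacked along
#' the medial-lateral axis) centered at the mid-x of the horn's free-end
#' lobe; horn points are those beyond the cloud centroid toward
#' anterior/posterior, and the lobe is the part of the horn within a small
#' band of its extreme y.
#'
#' @param cloud an oriented [point_cloud()] from [orient_meniscus()].
#' @param region `"central"`, `"anterior_horn"`, or `"posterior_horn"`.
#' @param slice_thickness slab thickness in mm; default should match the
#'   source voxel size (0.1 rat, 0.05 mouse).
#' @param side overrides the side attached to `cloud`.
#' @return A list of three point matrices (columns x, y, z) with attributes
#'   `plane` (`"coronal"` or `"sagittal"`) and `centers` (slab center
#'   coordinates along the stacking axis).
#' @export
select_region_slices <- function(cloud, region = c("central", "anterior_horn",
                                                   "posterior_horn"),
                                 slice_thickness = 0.1, side = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  region <- match.arg(region)
  if (slice_thickness <= 0) stop("slice_thickness must be positive")
  if (is.null(side)) side <- attr(cloud, "side")
  if (is.null(side)) stop("side not given and not attached to the cloud")
  side <- match.arg(side, c("medial", "lateral"))
  p <- cloud$points
  centroid <- colMeans(p)
  t <- slice_thickness
  if (region == "central") {
    span <- diff(range(p[, 2]))
    if (3 * t > span) {
      stop("slice_thickness too large: 3 slabs of ", t,
           " mm exceed the anterior-posterior span (", signif(span, 4), " mm)")
    }
    sgn <- if (side == "lateral") 1 else -1
    apex <- which.max(sgn * p[, 1])
    y0 <- p[apex, 2]
    edges <- y0 + c(-1.5, -0.5, 0.5, 1.5) * t
    slabs <- lapply(1:3, function(i) {
      p[p[, 2] >= edges[i] & p[, 2] < edges[i + 1], , drop = FALSE]
    })
    centers <- y0 + c(-1, 0, 1) * t
    plane <- "coronal"
  } else {
    span <- diff(range(p[, 1]))
    if (3 * t > span) {
      stop("slice_thickness too large: 3 slabs of ", t,
           " mm exceed the medial-lateral span (", signif(span, 4), " mm)")
    }
    sgn <- if (region == "anterior_horn") 1 else -1
    horn <- p[sgn * (p[, 2] - centroid[2]) > 0, , drop = FALSE]
    if (nrow(horn) < 3L) stop("no ", region, " lobe found beyond the centroid")
    y_ext <- max(sgn * horn[, 2])
    depth <- max(1.5 * t, 0.05 * (y_ext - sgn * centroid[2]))
    lobe <- horn[sgn * horn[, 2] >= y_ext - depth, , drop = FALSE]
    x0 <- (min(lobe[, 1]) + max(lobe[, 1])) / 2
    edges <- x0 + c(-1.5, -0.5, 0.5, 1.5) * t
    slabs <- lapply(1:3, function(i) {
      horn[horn[, 1] >= edges[i] & horn[, 1] < edges[i + 1], , drop = FALSE]
    })
    centers <- x0 + c(-1, 0, 1) * t
    plane <- "sagittal"
  }
  few <- vapply(slabs, nrow, integer(1)) < 3L
  if (any(few)) {
    stop("slab(s) ", paste(which(few), collapse = ", "), " in region '",
         region, "' hold fewer than 3 points; resolution too coarse")
  }
  attr(slabs, "plane") <- plane
  attr(slabs, "centers") <- centers
  slabs
}

# flatten a 3D slab onto its measurement plane: coronal -> (x, z),
# sagittal -> (y, z); horizontal first, vertical (proximal-distal) second
flatten_slab <- function(slab, plane) {
  if (plane == "coronal") slab[, c(1, 3), drop = FALSE]
  else slab[, c(2, 3), drop = FALSE]
}

#' Measure widths and heights across a flattened meniscal slice
#'
#' Ten (by default) equally spaced stations are laid across the slice in
#' each direction: heights are the vertical spans of the points falling in
#' each of `n_stations` equal horizontal bins, and widths the horizontal
#' spans in equal vertical bins. The per-slice width/height is the `mode`
#' aggregation (max by default) over the stations.
#'
#' @param points2d matrix with columns (horizontal, vertical) in mm.
#' @param n_stations number of stations per direction (default 10).
#' @param mode `"max"` (default) or `"mean"` aggregation over stations.
#' @return An object of class `meniscus_slice_measure` with station vectors
#'   and the aggregated `slice_width` / `slice_height`.
#' @export
measure_slice <- function(points2d, n_stations = 10L, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  points2d <- as.matrix(points2d)
  if (nrow(points2d) < 3L) stop("need at least 3 points in a slice")
  if (n_stations < 1L) stop("n_stations must be >= 1")
  span_fun <- function(vals, bins, positions) {
    out <- numeric(n_stations)
    for (i in seq_len(n_stations)) {
      sel <- bins == i
      if (!any(sel)) {
        warning("empty station bin ", i, "; span recorded as 0")
        out[i] <- 0
      } else {
        out[i] <- diff(range(vals[sel]))
      }
    }
    out
  }
  h <- points2d[, 1]; v <- points2d[, 2]
  hbin <- pmin(n_stations,
               floor((h - min(h)) / (diff(range(h)) + 1e-12) * n_stations) + 1L)
  vbin <- pmin(n_stations,
               floor((v - min(v)) / (diff(range(v)) + 1e-12) * n_stations) + 1L)
  station_heights <- span_fun(v, hbin)
  station_widths <- span_fun(h, vbin)
  agg <- if (mode == "max") max else mean
  structure(list(station_widths = station_widths,
                 station_heights = station_heights,
                 slice_width = agg(station_widths),
                 slice_height = agg(station_heights),
                 n_stations = n_stations, mode = mode),
            class = "meniscus_slice_measure")
}

#' Aggregate three slice measures into a regional width and height
#'
#' The regional value is the arithmetic mean over the three slices of the
#' per-slice value; the per-slice value is the `mode` aggregation over
#' stations (max per the figure-caption convention, mean per the methods
#' text; both are provided).
#'
#' @param slices list of exactly 3 [measure_slice()] results.
#' @param region region label.
#' @param mode `"max"` or `"mean"`; re-aggregates the stored stations.
#' @return An object of class `meniscus_region_measure` with `width` and
#'   `height` in mm.
#' @export
summarize_region <- function(slices, region = c("central", "anterior_horn",
                                                "posterior_horn"),
                             mode = c("max", "mean")) {
  region <- match.arg(region)
  mode <- match.arg(mode)
  if (length(slices) != 3L ||
      !all(vapply(slices, inherits, logical(1), "meniscus_slice_measure"))) {
    stop("need exactly 3 meniscus_slice_measure objects")
  }
  agg <- if (mode == "max") max else mean
  w <- vapply(slices, function(s) agg(s$station_widths), numeric(1))
  h <- vapply(slices, function(s) agg(s$station_heights), numeric(1))
  structure(list(region = region, slice_measures = slices,
                 width = mean(w), height = mean(h), mode = mode),
            class = "meniscus_region_measure")
}

#' @export
print.meniscus_region_measure <- function(x, ...) {
  cat(sprintf("meniscus region '%s' (%s over stations): width %.3f mm, height %.3f mm\n",
              x$region, x$mode, x$width, x$height))
  invisible(x)
}

#' Regional meniscal morphometry from an oriented mesh
#'
#' Convenience wrapper: orients the mesh, selects the three slabs per region,
#' measures each flattened slab at `n_stations` stations, and aggregates.
#'
#' @param mesh a [triangle_mesh()].
#' @param frame an [anatomic_frame()].
#' @param slice_thickness slab thickness in mm (default the rat voxel 0.1).
#' @param n_stations stations per slice (default 10).
#' @param mode `"max"` (default) or `"mean"` station aggregation.
#' @return A data frame with one row per region: `region`, `width_mm`,
#'   `height_mm`, `mode`.
#' @export
meniscus_regions <- function(mesh, frame, slice_thickness = 0.1,
                             n_stations = 10L, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  cloud <- orient_meniscus(mesh, frame)
  regions <- c("anterior_horn", "central", "posterior_horn")
  rows <- lapply(regions, function(rg) {
    slabs <- select_region_slices(cloud, rg, slice_thickness)
    plane <- attr(slabs, "plane")
    sm <- lapply(slabs, function(s) {
      measure_slice(flatten_slab(s, plane), n_stations, mode)
    })
    reg <- summarize_region(sm, rg, mode)
    data.frame(region = rg, width_mm = reg$width, height_mm = reg$height,
               mode = mode)
  })
  do.call(rbind, rows)
}
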