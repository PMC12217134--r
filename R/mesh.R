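#' Triangle surface mesh
#'
#' Lightweight container for a triangulated tissue surface in millimetres,
#' the unit of all geometry in this package (STL carries no unit metadata;
#' segmentations of rodent knees are exported in mm).
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param name tissue label; one of `"ACL"`, `"PCL"`, `"MCL"`, `"LCL"`,
#'   `"medial_meniscus"`, `"lateral_meniscus"`, `"tibia"`, `"other"`.
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `name`.
#' @export
triangle_mesh <- function(vertices, faces, name = "other") {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(vertices) <- "double"
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  name <- match.arg(name, c("ACL", "PCL", "MCL", "LCL", "medial_meniscus",
                            "lateral_meniscus", "tibia", "other"))
  structure(list(vertices = vertices, faces = faces, name = name),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("triangle_mesh '%s': %d vertices, %d faces\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox (mm): x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Surface point cloud
#'
#' @param points numeric matrix, n x 3, in mm.
#' @param source name of the originating mesh/tissue.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, source = "other") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) == 0L) stop("point cloud must be nonempty")
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  if (!all(is.finite(points))) stop("point coordinates must be finite")
  structure(list(points = points, source = source), class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud from '%s': %d points\n", x$source, nrow(x$points)))
  invisible(x)
}

#' Convert a mesh to its surface point cloud
#'
#' Ligament morphometry operates on the surface point cloud of the
#' segmentation mesh; points are the unique mesh vertices, with no resampling.
#'
#' @param mesh a [triangle_mesh()].
#' @return A [point_cloud()] whose points are the mesh vertices.
#' @export
mesh_to_pointcloud <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  point_cloud(unique(mesh$vertices), source = mesh$name)
}

# deduplicate vertices by exact coordinate match; faces re-indexed.
# Exact (not tolerance-based) so write/read round-trips stay bit-stable.
dedup_mesh <- function(vertices, faces, name = "other") {
  key <- paste(vertices[, 1], vertices[, 2], vertices[, 3], sep = "|")
  first <- !duplicated(key)
  newidx <- match(key, key[first])  # new index of each original vertex row
  faces2 <- matrix(newidx[faces], ncol = 3L)
  triangle_mesh(vertices[first, , drop = FALSE], faces2, name = name)
}

#' Read an STL surface file
#'
#' Reads binary or ASCII STL (dialect auto-detected). Coordinates are taken
#' as millimetres. Vertices repeated across facets are merged by exact
#' coordinate match and faces re-indexed.
#'
#' @param path path to an `.stl` file.
#' @param name tissue label attached to the mesh (see [triangle_mesh()]).
#' @return A [triangle_mesh()].
#' @export
read_stl <- function(path, name = "other") {
  if (!file.exists(path)) stop("STL file not found: ", path)
  size <- file.info(path)$size
  if (is.na(size) || size < 15) stop("not a valid STL file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = min(size, 84))
  is_binary <- FALSE
  if (size >= 84) {
    ntri <- readBin(head[81:84], "integer", size = 4, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && size == 84 + 50 * as.numeric(ntri)) {
      is_binary <- TRUE
    }
  }
  if (is_binary) {
    ntri <- readBin(head[81:84], "integer", size = 4, endian = "little")
    if (ntri == 0L) stop("empty STL mesh (zero triangles): ", path)
    rec <- readBin(con, "raw", n = 50 * ntri)
    if (length(rec) < 50 * ntri) stop("truncated binary STL: ", path)
    idx <- rep(seq(0L, ntri - 1L) * 50L, each = 48L) + rep(1:48, ntri)
    vals <- readBin(rec[idx], "double", n = 12L * ntri, size = 4,
                    endian = "little")
    m <- matrix(vals, ncol = 12L, byrow = TRUE) # normal + 3 vertices per row
    verts <- rbind(m[, 4:6, drop = FALSE], m[, 7:9, drop = FALSE],
                   m[, 10:12, drop = FALSE])
    ord <- as.vector(t(matrix(seq_len(3L * ntri), ncol = 3L)))
    verts <- verts[ord, , drop = FALSE]
    faces <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3L != 0L) {
      stop("unreadable or truncated ASCII STL: ", path)
    }
    parts <- strsplit(trimws(vl), "\\s+")
    verts <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(verts))) stop("non-numeric vertex in ASCII STL: ", path)
    faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  }
  dedup_mesh(verts, faces, name = name)
}

#' Write an STL surface file
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param dialect `"binary"` (default) or `"ascii"`.
#' @return Invisibly, `path`.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  dialect <- match.arg(dialect)
  v <- mesh$vertices
  f <- mesh$faces
  # per-facet normals from winding (consumers largely ignore them)
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  if (dialect == "binary") {
    con <- tryCatch(file(path, "wb"), error = function(e)
      stop("cannot open for writing: ", path))
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", "rodentmorph binary STL"))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    tri <- cbind(nrm, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                 v[f[, 3], , drop = FALSE])
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(tri[i, ]), con, size = 4, endian = "little")
      writeBin(as.integer(0L), con, size = 2, endian = "little")
    }
  } else {
    fmt <- function(x) sprintf("%.9g", x)
    lines <- character(0)
    out <- vector("list", nrow(f))
    for (i in seq_len(nrow(f))) {
      out[[i]] <- c(
        sprintf("  facet normal %s %s %s", fmt(nrm[i, 1]), fmt(nrm[i, 2]),
                fmt(nrm[i, 3])),
        "    outer loop",
        sprintf("      vertex %s %s %s", fmt(v[f[i, 1], 1]),
                fmt(v[f[i, 1], 2]), fmt(v[f[i, 1], 3])),
        sprintf("      vertex %s %s %s", fmt(v[f[i, 2], 1]),
                fmt(v[f[i, 2], 2]), fmt(v[f[i, 2], 3])),
        sprintf("      vertex %s %s %s", fmt(v[f[i, 3], 1]),
                fmt(v[f[i, 3], 2]), fmt(v[f[i, 3], 3])),
        "    endloop",
        "  endfacet")
    }
    lines <- c(sprintf("solid %s", mesh$name), unlist(out),
               sprintf("endsolid %s", mesh$name))
    tryCatch(writeLines(lines, path), error = function(e)
      stop("cannot open for writing: ", path))
  }
  invisible(path)
}

#' Enclosed volume of a watertight mesh
#'
#' Divergence-theorem volume: sum of signed tetrahedra spanned by each facet
#' and the origin. The absolute value is returned so facet orientation does
#' not matter for closed surfaces.
#'
#' @param mesh a [triangle_mesh()].
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  s <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
       a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
       a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  abs(sum(s)) / 6
}

#' Surface area of a mesh
#'
#' @param mesh a [triangle_mesh()].
#' @return Total facet area in mm^2.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

# apply a rigid transform (rotation then translation) to a mesh
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  triangle_mesh(v, mesh$faces, name = mesh$name)
}
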