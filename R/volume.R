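#' Binary label volume
#'
#' A 3D binary segmentation mask with isotropic voxels, as produced by manual
#' segmentation of high-field MRI (0.1 mm voxels for rat, 0.05 mm for mouse).
#' Voxel centers are at `(index - 0.5) * voxel_size` along each axis.
#'
#' @param mask 3D array of 0/1 occupancy.
#' @param voxel_size isotropic voxel edge length in mm.
#' @param axis_labels character vector of length 3 mapping array axes to
#'   anatomical planes; a permutation of `"sagittal"`, `"coronal"`, `"axial"`.
#'   The plane label names the slicing plane whose slices are stacked along
#'   that axis (so the `"axial"` axis is the proximal-distal direction).
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(mask, voxel_size,
                         axis_labels = c("sagittal", "coronal", "axial")) {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  if (!all(mask %in% c(0, 1))) stop("mask must contain only 0/1")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0) {
    stop("voxel_size must be a single positive number (mm)")
  }
  if (!setequal(axis_labels, c("sagittal", "coronal", "axial")) ||
      length(axis_labels) != 3L) {
    stop("axis_labels must be a permutation of sagittal/coronal/axial")
  }
  storage.mode(mask) <- "integer"
  structure(list(mask = mask, voxel_size = voxel_size,
                 axis_labels = axis_labels),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("label_volume: %d x %d x %d voxels at %g mm, %d occupied\n",
              d[1], d[2], d[3], x$voxel_size, sum(x$mask)))
  cat(sprintf("  axes: %s\n", paste(x$axis_labels, collapse = " / ")))
  invisible(x)
}

#' Read a label volume (NIfTI, NRRD, or raw + JSON sidecar)
#'
#' NIfTI (`.nii`/`.nii.gz`) is read through RNifti; voxel size comes from the
#' header and must be isotropic. A minimal NRRD reader supports `encoding:
#' ascii` and `encoding: raw` with a `spacings:` field. As a documented
#' fallback, a whitespace-separated text file of 0/1 values plus a JSON
#' sidecar (`<file>.json` with `dim`, `voxel_size`, optionally `axis_labels`)
#' is accepted. Values are binarized at 0.5.
#'
#' @param path input file.
#' @param axis_labels axis-to-plane mapping; required when the container
#'   carries no orientation metadata (all supported containers here), default
#'   sagittal/coronal/axial for axes 1/2/3.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path,
                              axis_labels = c("sagittal", "coronal", "axial")) {
  if (!file.exists(path)) stop("label volume not found: ", path)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    vs <- RNifti::pixdim(img)
    if (length(vs) < 3L) stop("NIfTI volume must be 3D: ", path)
    vs <- vs[1:3]
    if (diff(range(vs)) > 1e-6 * max(vs)) {
      stop("anisotropic voxels not supported (pixdim ",
           paste(signif(vs, 6), collapse = " x "), ")")
    }
    arr <- as.array(img)
    if (length(dim(arr)) > 3L) arr <- arr[, , , 1]
    label_volume((arr > 0.5) * 1L, vs[1], axis_labels)
  } else if (grepl("\\.nrrd$", lower)) {
    read_nrrd_label(path, axis_labels)
  } else {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      stop("unsupported label volume format (need .nii/.nii.gz/.nrrd or a ",
           path, ".json sidecar)")
    }
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    vals <- scan(path, what = numeric(), quiet = TRUE)
    d <- as.integer(meta$dim)
    if (length(vals) != prod(d)) stop("raw volume size does not match sidecar dim")
    al <- if (!is.null(meta$axis_labels)) meta$axis_labels else axis_labels
    label_volume(array((vals > 0.5) * 1L, dim = d), meta$voxel_size, al)
  }
}

read_nrrd_label <- function(path, axis_labels) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("truncated NRRD header: ", path)
    if (ln == "") break
    if (grepl("^#", ln)) next
    kv <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3L) fields[[trimws(tolower(kv[2]))]] <- trimws(kv[3])
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD supported")
  enc <- tolower(fields$encoding)
  vs <- NA_real_
  if (!is.null(fields$spacings)) {
    sp <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
    if (diff(range(sp)) > 1e-6 * max(sp)) stop("anisotropic NRRD not supported")
    vs <- sp[1]
  } else stop("NRRD must carry a 'spacings' field")
  n <- prod(sizes)
  if (enc == "ascii" || enc == "text" || enc == "txt") {
    vals <- scan(con, what = numeric(), n = n, quiet = TRUE)
  } else if (enc == "raw") {
    type <- tolower(fields$type)
    rd <- switch(type,
      "uchar" = , "uint8" = , "unsigned char" =
        as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE)),
      "short" = , "int16" =
        as.numeric(readBin(con, "integer", n = n, size = 2,
                           endian = "little")),
      "int" = , "int32" =
        as.numeric(readBin(con, "integer", n = n, size = 4,
                           endian = "little")),
      "float" = readBin(con, "double", n = n, size = 4, endian = "little"),
      "double" = readBin(con, "double", n = n, size = 8, endian = "little"),
      stop("unsupported NRRD type: ", type))
    vals <- rd
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(vals) != n) stop("truncated NRRD data: ", path)
  label_volume(array((vals > 0.5) * 1L, dim = sizes), vs, axis_labels)
}

#' Write a label volume
#'
#' Format chosen by extension: `.nii`/`.nii.gz` (NIfTI via RNifti), `.nrrd`
#' (ASCII-encoded NRRD), anything else as whitespace text plus a JSON sidecar.
#'
#' @param vol a [label_volume()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    m <- vol$mask
    # NIfTI writers drop trailing singleton dimensions; pad any size-1 axis
    # with an empty slice so the volume stays 3D (content unchanged)
    d <- dim(m)
    if (any(d == 1L)) {
      d2 <- pmax(d, 2L)
      m2 <- array(0L, d2)
      m2[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- m
      m <- m2
    }
    img <- RNifti::asNifti(m)
    img <- RNifti::`pixdim<-`(img, rep(vol$voxel_size, 3))
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.nrrd$", lower)) {
    d <- dim(vol$mask)
    hdr <- c("NRRD0004",
             "type: uchar",
             "dimension: 3",
             sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
             sprintf("spacings: %g %g %g", vol$voxel_size, vol$voxel_size,
                     vol$voxel_size),
             "encoding: ascii",
             "")
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(paste(as.vector(vol$mask), collapse = " "), con)
  } else {
    writeLines(paste(as.vector(vol$mask), collapse = " "), path)
    jsonlite::write_json(
      list(dim = dim(vol$mask), voxel_size = vol$voxel_size,
           axis_labels = vol$axis_labels),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# separable Gaussian smoothing of a 3D array; sigma in voxels, zero-padded
# boundary (callers pad the mask so the surface never touches the border).
gaussian_smooth3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  conv_axis <- function(a, axis) {
    d <- dim(a)
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    b <- aperm(a, perm)
    db <- dim(b)
    m <- matrix(b, nrow = db[1])
    n1 <- db[1]
    kmat <- matrix(0, n1, n1)
    for (off in seq(-r, r)) {
      idx <- seq_len(n1)
      j <- idx + off
      ok <- j >= 1 & j <= n1
      kmat[cbind(idx[ok], j[ok])] <- kmat[cbind(idx[ok], j[ok])] + k[off + r + 1]
    }
    out <- kmat %*% m
    dim(out) <- db
    aperm(out, order(perm))
  }
  a <- conv_axis(a, 1)
  a <- conv_axis(a, 2)
  conv_axis(a, 3)
}

# marching-tetrahedra case table: for the 14 mixed sign patterns, triangles
# as rows of 6 tet-corner indices (three (a,b) edge pairs to interpolate).
mt_case_table <- local({
  single <- function(i) {
    o <- setdiff(1:4, i)
    matrix(c(i, o[1], i, o[2], i, o[3]), nrow = 1)
  }
  double <- function(i, j) {
    o <- setdiff(1:4, c(i, j))
    q1 <- c(i, o[1]); q2 <- c(i, o[2]); q3 <- c(j, o[2]); q4 <- c(j, o[1])
    rbind(c(q1, q2, q3), c(q1, q3, q4))
  }
  tab <- vector("list", 15)
  for (case in 1:14) {
    ins <- which(bitwAnd(case, c(1L, 2L, 4L, 8L)) > 0L)
    tab[[case]] <- if (length(ins) == 1L) single(ins)
      else if (length(ins) == 3L) single(setdiff(1:4, ins))
      else double(ins[1], ins[2])
  }
  tab
})

# cube corner offsets (x, y, z) and the 6-tetrahedra decomposition along
# the v1-v7 diagonal
mt_corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                    c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
mt_tets <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                 c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))

# iso-surface of a scalar field sampled on a regular grid (marching
# tetrahedra at the given level). coords(i) = origin + (i-1)*spacing.
marching_tetrahedra <- function(field, level, spacing, origin = c(0, 0, 0)) {
  d <- dim(field)
  ins <- field > level
  sub <- function(a, dx, dy, dz) {
    a[(1 + dx):(d[1] - 1 + dx), (1 + dy):(d[2] - 1 + dy),
      (1 + dz):(d[3] - 1 + dz)]
  }
  s <- sub(ins, 0, 0, 0) + sub(ins, 1, 0, 0) + sub(ins, 1, 1, 0) +
       sub(ins, 0, 1, 0) + sub(ins, 0, 0, 1) + sub(ins, 1, 0, 1) +
       sub(ins, 1, 1, 1) + sub(ins, 0, 1, 1)
  act <- which(s > 0 & s < 8, arr.ind = TRUE)
  if (nrow(act) == 0L) stop("field never crosses the iso level")
  # linear index of each cube's 8 corners
  lin <- function(i, j, k) i + (j - 1) * d[1] + (k - 1) * d[1] * d[2]
  cidx <- sapply(1:8, function(c8) {
    lin(act[, 1] + mt_corners[c8, 1], act[, 2] + mt_corners[c8, 2],
        act[, 3] + mt_corners[c8, 3])
  })
  if (is.null(dim(cidx))) cidx <- matrix(cidx, nrow = 1)
  fvals <- matrix(field[cidx], nrow = nrow(act))
  # corner coordinates
  cx <- (act[, 1] - 1); cy <- (act[, 2] - 1); cz <- (act[, 3] - 1)
  tri_list <- vector("list", 6 * 14)
  slot <- 0L
  for (t6 in 1:6) {
    tc <- mt_tets[t6, ]
    f4 <- fvals[, tc, drop = FALSE]
    b <- (f4[, 1] > level) + 2L * (f4[, 2] > level) + 4L * (f4[, 3] > level) +
         8L * (f4[, 4] > level)
    for (case in 1:14) {
      rows <- which(b == case)
      if (length(rows) == 0L) next
      tris <- mt_case_table[[case]]
      for (ti in seq_len(nrow(tris))) {
        e <- tris[ti, ]
        pts <- lapply(c(1, 3, 5), function(q) {
          a <- e[q]; bb <- e[q + 1]
          fa <- f4[rows, a]; fb <- f4[rows, bb]
          ca <- tc[a]; cb <- tc[bb]
          pa <- cbind(cx[rows] + mt_corners[ca, 1],
                      cy[rows] + mt_corners[ca, 2],
                      cz[rows] + mt_corners[ca, 3])
          pb <- cbind(cx[rows] + mt_corners[cb, 1],
                      cy[rows] + mt_corners[cb, 2],
                      cz[rows] + mt_corners[cb, 3])
          # interpolate from the lower global node so shared edges produce
          # bit-identical points in every tetrahedron (exact vertex merge)
          swap <- cidx[rows, ca] > cidx[rows, cb]
          if (any(swap)) {
            tmp <- fa[swap]; fa[swap] <- fb[swap]; fb[swap] <- tmp
            tmp <- pa[swap, , drop = FALSE]
            pa[swap, ] <- pb[swap, , drop = FALSE]
            pb[swap, ] <- tmp
          }
          tt <- (level - fa) / (fb - fa)
          pa + tt * (pb - pa)
        })
        # orient windings so normals point toward the outside corners
        ins_tet <- which(bitwAnd(case, c(1L, 2L, 4L, 8L)) > 0L)
        out_tet <- setdiff(1:4, ins_tet)
        dirv <- colMeans(mt_corners[tc[out_tet], , drop = FALSE]) -
                colMeans(mt_corners[tc[ins_tet], , drop = FALSE])
        e1m <- pts[[2]] - pts[[1]]
        e2m <- pts[[3]] - pts[[1]]
        nrm <- cbind(e1m[, 2] * e2m[, 3] - e1m[, 3] * e2m[, 2],
                     e1m[, 3] * e2m[, 1] - e1m[, 1] * e2m[, 3],
                     e1m[, 1] * e2m[, 2] - e1m[, 2] * e2m[, 1])
        flip <- as.vector(nrm %*% dirv) < 0
        p2 <- pts[[2]]; p3 <- pts[[3]]
        if (any(flip)) {
          tmp <- p2[flip, , drop = FALSE]
          p2[flip, ] <- p3[flip, , drop = FALSE]
          p3[flip, ] <- tmp
        }
        slot <- slot + 1L
        tri_list[[slot]] <- cbind(pts[[1]], p2, p3)
      }
    }
  }
  tri <- do.call(rbind, tri_list[seq_len(slot)])
  nt <- nrow(tri)
  verts <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
                 tri[, 7:9, drop = FALSE])
  ord <- as.vector(t(matrix(seq_len(3L * nt), ncol = 3L)))
  verts <- verts[ord, , drop = FALSE]
  # drop degenerate (zero-area) triangles produced when an interpolated point
  # lands exactly on a tet vertex shared by two edges
  faces <- matrix(seq_len(3L * nt), ncol = 3L, byrow = TRUE)
  verts <- sweep(verts * spacing, 2, origin, "+")
  m <- dedup_mesh(verts, faces)
  keep <- m$faces[, 1] != m$faces[, 2] & m$faces[, 2] != m$faces[, 3] &
          m$faces[, 1] != m$faces[, 3]
  triangle_mesh(m$vertices, m$faces[keep, , drop = FALSE])
}

#' Generate a surface mesh from a binary label volume
#'
#' The mask is smoothed with an isotropic Gaussian filter (`sigma` in voxel
#' units) and the 0.5 iso-surface extracted on the grid of voxel centers,
#' with coordinates scaled to mm by the voxel size. At `sigma = 0` the exact
#' voxel-boundary surface is returned instead (no interpolation), so the mesh
#' of a single voxel is a cube of side `voxel_size` and the enclosed volume
#' always equals `n_voxels * voxel_size^3` exactly.
#'
#' @param vol a [label_volume()].
#' @param sigma Gaussian smoothing width in voxels (default 1.0, matching the
#'   smoothing applied to segmentation masks before surface export).
#' @param name tissue label for the resulting mesh.
#' @return A watertight [triangle_mesh()].
#' @export
mesh_from_volume <- function(vol, sigma = 1.0, name = "other") {
  stopifnot(inherits(vol, "label_volume"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (sum(vol$mask) == 0L) stop("empty label volume")
  vs <- vol$voxel_size
  if (sigma == 0) {
    m <- cuberille_surface(vol$mask, vs)
    return(triangle_mesh(m$vertices, m$faces, name = name))
  }
  pad <- max(2L, as.integer(ceiling(3 * sigma)) + 1L)
  d <- dim(vol$mask)
  field <- array(0, dim = d + 2L * pad)
  field[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]),
        (pad + 1):(pad + d[3])] <- vol$mask
  field <- gaussian_smooth3(field, sigma)
  # grid node i sits at voxel center ((i - pad) - 0.5) * vs
  m <- marching_tetrahedra(field, 0.5, spacing = vs,
                           origin = rep((0.5 - pad) * vs, 3))
  triangle_mesh(m$vertices, m$faces, name = name)
}

# exact boundary surface of a voxel set: two triangles per exposed face
cuberille_surface <- function(mask, vs) {
  d <- dim(mask)
  occ <- array(FALSE, d + 2L)
  occ[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask > 0
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  quads <- vector("list", 6)
  for (s in 1:6) {
    sh <- shifts[s, ]
    inner <- occ[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
    nb <- occ[(2:(d[1] + 1)) + sh[1], (2:(d[2] + 1)) + sh[2],
              (2:(d[3] + 1)) + sh[3], drop = FALSE]
    idx <- which(inner & !nb, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    # voxel (i,j,k) spans [(i-1)vs, i vs] per axis; exposed face on side sh
    lo <- (idx - 1) * vs
    hi <- idx * vs
    ax <- which(sh != 0)
    faceplane <- if (sh[ax] > 0) hi[, ax] else lo[, ax]
    oth <- setdiff(1:3, ax)
    c1 <- matrix(0, nrow(idx), 3); c2 <- c1; c3 <- c1; c4 <- c1
    c1[, ax] <- faceplane; c2[, ax] <- faceplane
    c3[, ax] <- faceplane; c4[, ax] <- faceplane
    c1[, oth[1]] <- lo[, oth[1]]; c1[, oth[2]] <- lo[, oth[2]]
    c2[, oth[1]] <- hi[, oth[1]]; c2[, oth[2]] <- lo[, oth[2]]
    c3[, oth[1]] <- hi[, oth[1]]; c3[, oth[2]] <- hi[, oth[2]]
    c4[, oth[1]] <- lo[, oth[1]]; c4[, oth[2]] <- hi[, oth[2]]
    # orient windings outward: cross(e_oth1, e_oth2) = eps * e_ax
    eps <- if (ax == 2L) -1 else 1
    if (eps * sh[ax] > 0) {
      quads[[s]] <- rbind(cbind(c1, c2, c3), cbind(c1, c3, c4))
    } else {
      quads[[s]] <- rbind(cbind(c1, c4, c3), cbind(c1, c3, c2))
    }
  }
  tri <- do.call(rbind, quads)
  nt <- nrow(tri)
  verts <- rbind(tri[, 1:3], tri[, 4:6], tri[, 7:9])
  ord <- as.vector(t(matrix(seq_len(3L * nt), ncol = 3L)))
  dedup_mesh(verts[ord, , drop = FALSE],
             matrix(seq_len(3L * nt), ncol = 3L, byrow = TRUE))
}

#' Voxelize a watertight mesh into a binary label volume
#'
#' A voxel is occupied iff its center lies inside the mesh (parity of surface
#' crossings along the z column). The bounding grid is padded by one voxel on
#' every side.
#'
#' @param mesh a watertight [triangle_mesh()].
#' @param voxel_size isotropic voxel edge in mm.
#' @param axis_labels passed to [label_volume()].
#' @return A [label_volume()].
#' @export
voxelize <- function(mesh, voxel_size,
                     axis_labels = c("sagittal", "coronal", "axial")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (voxel_size <= 0) stop("voxel_size must be positive")
  if (!is_watertight(mesh)) {
    stop("mesh is not watertight; voxelization needs a closed surface")
  }
  v <- mesh$vertices
  f <- mesh$faces
  bbmin <- apply(v, 2, min)
  bbmax <- apply(v, 2, max)
  org <- bbmin - voxel_size
  dims <- pmax(1L, as.integer(ceiling((bbmax - org) / voxel_size)) + 1L)
  ctr <- function(i) org + (i - 0.5) * voxel_size  # vectorized per axis below
  xs <- org[1] + (seq_len(dims[1]) - 0.5) * voxel_size
  ys <- org[2] + (seq_len(dims[2]) - 0.5) * voxel_size
  zs <- org[3] + (seq_len(dims[3]) - 0.5) * voxel_size
  # collect z-crossings per (x, y) column
  crossings <- new.env(parent = emptyenv())
  nx <- dims[1]
  for (tr in seq_len(nrow(f))) {
    p1 <- v[f[tr, 1], ]; p2 <- v[f[tr, 2], ]; p3 <- v[f[tr, 3], ]
    det <- (p2[1] - p1[1]) * (p3[2] - p1[2]) -
           (p3[1] - p1[1]) * (p2[2] - p1[2])
    if (abs(det) < 1e-14) next  # vertical facet: no column pierces it
    ix <- which(xs >= min(p1[1], p2[1], p3[1]) - 1e-12 &
                xs <= max(p1[1], p2[1], p3[1]) + 1e-12)
    iy <- which(ys >= min(p1[2], p2[2], p3[2]) - 1e-12 &
                ys <= max(p1[2], p2[2], p3[2]) + 1e-12)
    if (length(ix) == 0L || length(iy) == 0L) next
    gx <- rep(xs[ix], times = length(iy))
    gy <- rep(ys[iy], each = length(ix))
    l1 <- ((p2[1] - gx) * (p3[2] - gy) - (p3[1] - gx) * (p2[2] - gy)) / det
    l2 <- ((p3[1] - gx) * (p1[2] - gy) - (p1[1] - gx) * (p3[2] - gy)) / det
    l3 <- 1 - l1 - l2
    inside <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    if (!any(inside)) next
    zc <- l1[inside] * p1[3] + l2[inside] * p2[3] + l3[inside] * p3[3]
    cols <- (rep(ix, times = length(iy)) +
             (rep(iy, each = length(ix)) - 1L) * nx)[inside]
    for (q in seq_along(cols)) {
      key <- as.character(cols[q])
      crossings[[key]] <- c(crossings[[key]], zc[q])
    }
  }
  mask <- array(0L, dim = dims)
  tol <- 1e-9 * max(voxel_size, max(abs(v)))
  for (key in ls(crossings)) {
    zv <- sort(crossings[[key]])
    if (length(zv) > 1L) zv <- zv[c(TRUE, diff(zv) > tol)]  # shared edges
    if (length(zv) %% 2L == 1L) zv <- zv[-length(zv)]  # grazing contact
    if (length(zv) == 0L) next
    col <- as.integer(key)
    parity <- findInterval(zs, zv) %% 2L
    occz <- which(parity == 1L)
    if (length(occz)) {
      ix <- ((col - 1L) %% nx) + 1L
      iy <- ((col - 1L) %/% nx) + 1L
      mask[ix, iy, occz] <- 1L
    }
  }
  label_volume(mask, voxel_size, axis_labels)
}

#' Test whether a mesh is watertight
#'
#' Every undirected edge must be shared by exactly two faces.
#'
#' @param mesh a [triangle_mesh()].
#' @return Logical.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}
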