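# Triangulated surface meshes: construction, queries and ASCII file I/O.
# A mesh is list(vertices = n x 3 numeric, faces = m x 3 integer, 1-based),
# faces oriented counter-clockwise seen from outside (outward normals).

#' Triangulated unit icosphere
#'
#' Subdivides an icosahedron `level` times (each subdivision splits every
#' triangle into 4) and projects vertices onto the sphere. The result has
#' `10 * 4^level + 2` vertices and `20 * 4^level` faces, outward-oriented.
#'
#' @param level subdivision level (>= 0).
#' @param radius sphere radius (default 1).
#' @return a mesh `list(vertices, faces)`.
#' @export
icosphere <- function(level = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    mid <- new.env(parent = emptyenv())
    nv <- nrow(v)
    vlist <- vector("list", 0)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- mid[[key]]
      if (!is.null(idx)) return(idx)
      p <- (v[a, ] + v[b, ]); p <- p / sqrt(sum(p^2))
      vlist[[length(vlist) + 1L]] <<- p
      idx <- nv + length(vlist)
      mid[[key]] <- idx
      idx
    }
    nf <- matrix(0L, 4L * nrow(f), 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf[4L * i - 3L, ] <- c(a, ab, ca)
      nf[4L * i - 2L, ] <- c(b, bc, ab)
      nf[4L * i - 1L, ] <- c(c_, ca, bc)
      nf[4L * i, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, vlist))
    v <- v / sqrt(rowSums(v^2))
    f <- nf
  }
  list(vertices = v * radius, faces = f)
}

#' Nested concentric-sphere head model
#'
#' Builds a synthetic macaque-scale head model from nested icospheres
#' (innermost first; default radii 30/35/38 mm for brain/skull/scalp) with
#' the standard compartment conductivities.
#'
#' @param radii increasing surface radii, mm (default `c(30, 35, 38)`).
#' @param level icosphere subdivision level (default 3: 642 vertices and
#'   1280 faces per surface).
#' @param conductivities region conductivities, S/m: inside surface 1, ...,
#'   outside the outermost surface. Default brain 0.33, skull 0.0063,
#'   scalp 0.43, air 0.
#' @return a \linkS4class{HeadModel}.
#' @export
buildNestedSpheres <- function(radii = c(30, 35, 38), level = 3,
                               conductivities = c(0.33, 0.0063, 0.43, 0)) {
  if (any(diff(radii) <= 0)) stop("radii must be strictly increasing")
  if (length(conductivities) != length(radii) + 1L)
    stop("one conductivity per region (length(radii) + 1) is required")
  base <- icosphere(level, 1)
  surfs <- lapply(radii, function(r) list(vertices = base$vertices * r,
                                          faces = base$faces))
  new("HeadModel", surfaces = surfs, conductivities = conductivities)
}

#' Is a mesh a closed 2-manifold surface?
#'
#' Checks that every edge is shared by exactly two faces with consistent
#' orientation.
#'
#' @param mesh a mesh `list(vertices, faces)`.
#' @return logical.
#' @export
meshIsClosed <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])   # directed edges
  key <- paste(he[, 1], he[, 2])
  rkey <- paste(he[, 2], he[, 1])
  !anyDuplicated(key) && all(key %in% rkey)
}

#' Signed volume enclosed by a mesh (positive for outward orientation)
#' @param mesh a mesh `list(vertices, faces)`.
#' @return numeric volume.
#' @export
meshVolume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Flip face orientation if the mesh is not outward-oriented
#' @param mesh a mesh
#' @return the mesh, outward-oriented
#' @export
ensureOutward <- function(mesh) {
  if (meshVolume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

#' Test whether points lie inside a closed mesh (winding number)
#' @param pts n x 3 matrix of query points
#' @param mesh a closed, outward-oriented mesh
#' @return logical vector
#' @export
pointsInMesh <- function(pts, mesh) {
  pts <- matrix(pts, ncol = 3L)
  omega <- rowSums(.solidAngleMatrix(pts, mesh$vertices, mesh$faces))
  omega > 2 * pi
}

#' Face centroids, areas and outward normals
#' @noRd
faceGeometry <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sqrt(rowSums(cr^2)) / 2
  list(centroids = (a + b + c_) / 3, areas = area,
       normals = cr / pmax(2 * area, .Machine$double.eps))
}

#' First intersection of rays from a common origin with a mesh
#' (Moller-Trumbore, vectorized over faces). Returns n x 3 points; NA rows
#' where a ray misses.
#' @noRd
rayMeshIntersect <- function(mesh, origin, directions) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  out <- matrix(NA_real_, nrow(directions), 3L)
  for (i in seq_len(nrow(directions))) {
    d <- directions[i, ]
    pv <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
                d[3] * e2[, 1] - d[1] * e2[, 3],
                d[1] * e2[, 2] - d[2] * e2[, 1])
    det <- rowSums(e1 * pv)
    ok <- abs(det) > 1e-12
    tv <- sweep(a, 2L, origin, "-") * -1
    u <- rowSums(tv * pv) / det
    qv <- cbind(tv[, 2] * e1[, 3] - tv[, 3] * e1[, 2],
                tv[, 3] * e1[, 1] - tv[, 1] * e1[, 3],
                tv[, 1] * e1[, 2] - tv[, 2] * e1[, 1])
    vv <- (qv %*% d) / det
    tt <- rowSums(qv * e2) / det
    hit <- ok & u >= -1e-9 & vv >= -1e-9 & (u + vv) <= 1 + 1e-9 & tt > 1e-9
    if (any(hit)) {
      tbest <- min(tt[hit])
      out[i, ] <- origin + tbest * d
    }
  }
  out
}

#' Merge duplicate vertices (within a tolerance) and reindex faces
#' @param mesh a mesh
#' @param tol absolute coordinate tolerance for identifying vertices
#' @return a mesh with unique vertices
#' @export
mergeVertices <- function(mesh, tol = 1e-9) {
  key <- apply(round(mesh$vertices / tol) * tol, 1L, paste, collapse = "|")
  first <- !duplicated(key)
  map <- match(key, key[first])   # original index -> merged index
  list(vertices = mesh$vertices[first, , drop = FALSE],
       faces = matrix(map[mesh$faces], ncol = 3L))
}

#' Canonical form of a mesh for cross-format comparison
#'
#' Merges duplicate vertices, sorts vertices lexicographically, remaps faces,
#' rotates each face so its smallest vertex index comes first (preserving
#' orientation) and sorts faces lexicographically.
#'
#' @param mesh a mesh
#' @param tol vertex merge tolerance
#' @return a canonicalized mesh
#' @export
canonicalMesh <- function(mesh, tol = 1e-9) {
  m <- mergeVertices(mesh, tol)
  ord <- order(m$vertices[, 1], m$vertices[, 2], m$vertices[, 3])
  rank <- match(seq_len(nrow(m$vertices)), ord)
  v <- m$vertices[ord, , drop = FALSE]
  f <- matrix(rank[m$faces], ncol = 3L)
  f <- t(apply(f, 1L, function(tri) {
    k <- which.min(tri)
    tri[((seq_len(3L) + k - 2L) %% 3L) + 1L]
  }))
  f <- f[order(f[, 1], f[, 2], f[, 3]), , drop = FALSE]
  list(vertices = v, faces = f)
}

#' Read a triangulated surface from an ASCII STL, OFF or PLY file
#'
#' The format is chosen from the file extension. STL triangle soups are
#' merged into an indexed mesh.
#'
#' @param path file path ending in `.stl`, `.off` or `.ply`.
#' @return a mesh `list(vertices, faces)`.
#' @export
readMesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  mesh <- switch(ext,
    stl = {
      vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
      if (!length(vl)) stop("malformed STL: no vertex records")
      v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
        as.numeric(p[2:4])))
      if (nrow(v) %% 3L != 0L) stop("malformed STL: vertex count not divisible by 3")
      mergeVertices(list(vertices = v,
                         faces = matrix(seq_len(nrow(v)), ncol = 3L, byrow = TRUE)))
    },
    off = {
      lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
      if (toupper(trimws(lines[1])) != "OFF") stop("malformed OFF header")
      counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
      nv <- counts[1]; nf <- counts[2]
      v <- do.call(rbind, lapply(strsplit(trimws(lines[3:(2 + nv)]), "\\s+"),
                                 function(p) as.numeric(p[1:3])))
      f <- do.call(rbind, lapply(strsplit(trimws(lines[(3 + nv):(2 + nv + nf)]), "\\s+"),
                                 function(p) {
        p <- as.integer(p)
        if (p[1] != 3L) stop("only triangulated OFF faces are supported")
        p[2:4] + 1L
      }))
      list(vertices = v, faces = f)
    },
    ply = {
      endHdr <- grep("^end_header", lines)[1]
      if (is.na(endHdr)) stop("malformed PLY header")
      hdr <- lines[1:endHdr]
      if (!any(grepl("^format ascii", hdr))) stop("only ASCII PLY is supported")
      nv <- as.integer(sub("^element vertex\\s+", "", grep("^element vertex", hdr, value = TRUE)))
      nf <- as.integer(sub("^element face\\s+", "", grep("^element face", hdr, value = TRUE)))
      body <- lines[(endHdr + 1L):length(lines)]
      v <- do.call(rbind, lapply(strsplit(trimws(body[1:nv]), "\\s+"),
                                 function(p) as.numeric(p[1:3])))
      f <- do.call(rbind, lapply(strsplit(trimws(body[(nv + 1L):(nv + nf)]), "\\s+"),
                                 function(p) {
        p <- as.integer(p)
        if (p[1] != 3L) stop("only triangulated PLY faces are supported")
        p[2:4] + 1L
      }))
      list(vertices = v, faces = f)
    },
    stop("unsupported mesh format: ", ext)
  )
  mesh
}

#' Write a triangulated surface to an ASCII STL, OFF or PLY file
#'
#' @param mesh a mesh `list(vertices, faces)`.
#' @param path output path ending in `.stl`, `.off` or `.ply`.
#' @return invisibly, the path.
#' @export
writeMesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces
  fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  if (ext == "stl") {
    g <- faceGeometry(mesh)
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(sprintf("  facet normal %s %s %s",
                           fmt(g$normals[i, 1]), fmt(g$normals[i, 2]), fmt(g$normals[i, 3])),
                   "    outer loop",
                   sprintf("      vertex %s %s %s",
                           fmt(v[f[i, ], 1]), fmt(v[f[i, ], 2]), fmt(v[f[i, ], 3])),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  } else if (ext == "off") {
    writeLines("OFF", con)
    writeLines(sprintf("%d %d 0", nrow(v), nrow(f)), con)
    writeLines(sprintf("%s %s %s", fmt(v[, 1]), fmt(v[, 2]), fmt(v[, 3])), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else if (ext == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%s %s %s", fmt(v[, 1]), fmt(v[, 2]), fmt(v[, 3])), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else stop("unsupported mesh format: ", ext)
  invisible(path)
}
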