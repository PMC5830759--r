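#' Triangle surface mesh
#'
#' Container for a triangle surface mesh. Vertices are in mm; triangles are
#' 1-based vertex index triples whose winding encodes outward-facing normals.
#'
#' @param vertices numeric matrix, one row per vertex, 3 columns (x, y, z in mm)
#' @param triangles integer matrix, one row per triangle, 3 columns of vertex
#'   indices (1-based)
#' @param validate check index ranges and basic shape invariants
#' @return an object of class `softsim_surface_mesh`
#' @export
surface_mesh <- function(vertices, triangles, validate = TRUE) {
  vertices <- as_coord_matrix(vertices, "vertices")
  triangles <- as_index_matrix(triangles, 3L, "triangles")
  if (validate) {
    if (nrow(triangles) > 0 && (min(triangles) < 1L || max(triangles) > nrow(vertices)))
      stop("invalid-argument: triangle vertex index out of range")
    if (any(triangles[, 1] == triangles[, 2] | triangles[, 1] == triangles[, 3] |
            triangles[, 2] == triangles[, 3]))
      stop("invalid-argument: degenerate triangle with repeated vertex index")
  }
  structure(list(vertices = vertices, triangles = triangles),
            class = c("softsim_surface_mesh", "softsim_mesh"))
}

#' Tetrahedral volume mesh
#'
#' @param vertices numeric matrix, one row per vertex (mm)
#' @param tets integer matrix, one row per tetrahedron, 4 columns of vertex
#'   indices (1-based), ordered so the signed volume is positive
#' @param validate check index ranges and positive orientation
#' @return an object of class `softsim_tet_mesh`
#' @export
tet_mesh <- function(vertices, tets, validate = TRUE) {
  vertices <- as_coord_matrix(vertices, "vertices")
  tets <- as_index_matrix(tets, 4L, "tets")
  if (validate && nrow(tets) > 0) {
    if (min(tets) < 1L || max(tets) > nrow(vertices))
      stop("invalid-argument: tet vertex index out of range")
    v <- tet_signed_volumes(vertices, tets)
    if (any(v <= 0))
      stop("invalid-argument: tetrahedron with non-positive signed volume")
  }
  structure(list(vertices = vertices, tets = tets),
            class = c("softsim_tet_mesh", "softsim_mesh"))
}

#' @export
print.softsim_surface_mesh <- function(x, ...) {
  cat(sprintf("surface mesh: %d vertices, %d triangles, %s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (is_closed_surface(x)) "closed" else "open"))
  invisible(x)
}

#' @export
print.softsim_tet_mesh <- function(x, ...) {
  cat(sprintf("tetrahedral mesh: %d vertices, %d tets, volume %.4g mm^3\n",
              nrow(x$vertices), nrow(x$tets), mesh_volume(x)))
  invisible(x)
}

as_coord_matrix <- function(v, what) {
  v <- as.matrix(v)
  storage.mode(v) <- "double"
  if (ncol(v) != 3) stop("invalid-argument: ", what, " must have 3 columns")
  if (any(!is.finite(v))) stop("invalid-argument: non-finite ", what)
  dimnames(v) <- NULL
  v
}

as_index_matrix <- function(m, k, what) {
  m <- as.matrix(m)
  if (length(m) == 0) m <- matrix(integer(0), 0, k)
  storage.mode(m) <- "integer"
  if (ncol(m) != k) stop("invalid-argument: ", what, " must have ", k, " columns")
  dimnames(m) <- NULL
  m
}

tet_signed_volumes <- function(vertices, tets) {
  p1 <- vertices[tets[, 1], , drop = FALSE]
  e2 <- vertices[tets[, 2], , drop = FALSE] - p1
  e3 <- vertices[tets[, 3], , drop = FALSE] - p1
  e4 <- vertices[tets[, 4], , drop = FALSE] - p1
  cx <- e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]
  cy <- e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3]
  cz <- e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1]
  (cx * e4[, 1] + cy * e4[, 2] + cz * e4[, 3]) / 6
}

# 5-tet decompositions of the unit cell, by local corner index
# (bit 1 = +x, bit 2 = +y, bit 4 = +z), alternated by cell parity so that
# shared faces carry matching diagonals
.tet5_even <- rbind(c(0, 1, 3, 5), c(0, 2, 3, 6), c(0, 4, 5, 6),
                    c(3, 5, 6, 7), c(0, 3, 6, 5))
.tet5_odd <- rbind(c(0, 1, 2, 4), c(3, 1, 2, 7), c(5, 1, 4, 7),
                   c(6, 2, 4, 7), c(1, 2, 4, 7))

#' Generate a rectangular beam as a conforming tetrahedral lattice
#'
#' Builds a regular grid of hexahedral cells over a box and splits each cell
#' into 5 tetrahedra, alternating the split parity between neighbouring cells
#' so that all interior faces are conforming. The summed tet volume equals the
#' exact box volume.
#'
#' @param lengths numeric length-3, box edge lengths (mm)
#' @param divisions integer length-3, cells per direction (>= 1)
#' @return a [tet_mesh()]
#' @export
generate_beam <- function(lengths, divisions) {
  lengths <- as.numeric(lengths)
  divisions <- as.integer(divisions)
  if (length(lengths) != 3 || length(divisions) != 3)
    stop("invalid-argument: lengths and divisions must have length 3")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("invalid-argument: lengths must be positive")
  if (any(is.na(divisions)) || any(divisions < 1))
    stop("invalid-argument: divisions must be positive integers")
  d <- divisions
  nx <- d[1] + 1L; ny <- d[2] + 1L; nz <- d[3] + 1L
  g <- expand.grid(i = 0:d[1], j = 0:d[2], k = 0:d[3])
  vertices <- cbind(g$i * lengths[1] / d[1],
                    g$j * lengths[2] / d[2],
                    g$k * lengths[3] / d[3])
  vid <- function(i, j, k) 1L + i + nx * (j + ny * k)
  tets <- matrix(0L, 5L * prod(d), 4L)
  row <- 0L
  for (k in 0:(d[3] - 1L)) for (j in 0:(d[2] - 1L)) for (i in 0:(d[1] - 1L)) {
    corners <- c(vid(i, j, k), vid(i + 1L, j, k), vid(i, j + 1L, k),
                 vid(i + 1L, j + 1L, k), vid(i, j, k + 1L), vid(i + 1L, j, k + 1L),
                 vid(i, j + 1L, k + 1L), vid(i + 1L, j + 1L, k + 1L))
    split <- if ((i + j + k) %% 2L == 0L) .tet5_even else .tet5_odd
    for (s in 1:5) {
      row <- row + 1L
      tets[row, ] <- corners[split[s, ] + 1L]
    }
  }
  # enforce positive orientation
  v <- tet_signed_volumes(vertices, tets)
  flip <- v < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  tet_mesh(vertices, tets)
}

#' Generate a cube lattice tetrahedral mesh
#'
#' Convenience wrapper around [generate_beam()] for the cube rheometry
#' scenarios: `divisions` cells per direction, each split into 5 tets.
#'
#' @param edge_length cube edge (mm)
#' @param divisions cells per direction (>= 1)
#' @return a [tet_mesh()] with `(divisions+1)^3` vertices and `5*divisions^3` tets
#' @export
generate_cube_lattice <- function(edge_length, divisions) {
  if (length(edge_length) != 1 || !is.finite(edge_length) || edge_length <= 0)
    stop("invalid-argument: edge_length must be a positive number")
  if (length(divisions) != 1 || is.na(divisions) || divisions < 1)
    stop("invalid-argument: divisions must be a positive integer")
  generate_beam(rep(edge_length, 3), rep(as.integer(divisions), 3))
}

#' Generate an icosphere surface mesh
#'
#' Starts from a regular icosahedron and applies `subdivisions` rounds of
#' 1-to-4 face splitting with midpoint projection onto the sphere. The result
#' is a closed, outward-oriented triangle mesh.
#'
#' @param radius sphere radius (mm)
#' @param subdivisions non-negative integer
#' @return a [surface_mesh()]
#' @export
generate_icosphere <- function(radius, subdivisions = 2L) {
  if (length(radius) != 1 || !is.finite(radius) || radius <= 0)
    stop("invalid-argument: radius must be a positive number")
  subdivisions <- as.integer(subdivisions)
  if (is.na(subdivisions) || subdivisions < 0)
    stop("invalid-argument: subdivisions must be a non-negative integer")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midpoint_cache <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- midpoint_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (verts[a, ] + verts[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      midpoint_cache[[key]] <- idx
      idx
    }
    newf <- matrix(0L, 4L * nrow(f), 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[4L * t - 3L, ] <- c(a, ab, ca)
      newf[4L * t - 2L, ] <- c(b, bc, ab)
      newf[4L * t - 1L, ] <- c(c, ca, bc)
      newf[4L * t, ] <- c(ab, bc, ca)
    }
    v <- verts
    f <- newf
  }
  surface_mesh(v * radius, f)
}

#' Is a surface mesh closed and consistently oriented?
#'
#' A mesh is closed when every undirected edge is shared by exactly two
#' triangles, and consistently oriented when each directed edge appears exactly
#' once.
#'
#' @param mesh a [surface_mesh()]
#' @return logical
#' @export
is_closed_surface <- function(mesh) {
  stopifnot(inherits(mesh, "softsim_surface_mesh"))
  tr <- mesh$triangles
  if (nrow(tr) == 0) return(FALSE)
  dir_edges <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  keys <- paste(dir_edges[, 1], dir_edges[, 2])
  if (anyDuplicated(keys)) return(FALSE)
  ukeys <- paste(pmin(dir_edges[, 1], dir_edges[, 2]),
                 pmax(dir_edges[, 1], dir_edges[, 2]))
  all(table(ukeys) == 2L)
}

#' Enclosed volume of a mesh
#'
#' For a tetrahedral mesh, the sum of signed tet volumes
#' `(1/6) ((p2-p1) x (p3-p1)) . (p4-p1)`. For a closed oriented surface mesh,
#' the divergence-theorem sum `(1/6) sum_t (pt1 x pt2) . pt3`, which is
#' translation invariant.
#'
#' @param mesh a [tet_mesh()] or closed [surface_mesh()]
#' @return enclosed volume (mm^3)
#' @export
mesh_volume <- function(mesh) {
  if (inherits(mesh, "softsim_tet_mesh"))
    return(sum(tet_signed_volumes(mesh$vertices, mesh$tets)))
  if (inherits(mesh, "softsim_surface_mesh")) {
    if (!is_closed_surface(mesh))
      stop("topology-error: surface mesh is not closed/oriented; volume undefined")
    return(enclosed_volume(mesh$vertices, mesh$triangles))
  }
  stop("invalid-argument: not a softsim mesh")
}

enclosed_volume <- function(vertices, triangles) {
  p1 <- vertices[triangles[, 1], , drop = FALSE]
  p2 <- vertices[triangles[, 2], , drop = FALSE]
  p3 <- vertices[triangles[, 3], , drop = FALSE]
  cx <- p1[, 2] * p2[, 3] - p1[, 3] * p2[, 2]
  cy <- p1[, 3] * p2[, 1] - p1[, 1] * p2[, 3]
  cz <- p1[, 1] * p2[, 2] - p1[, 2] * p2[, 1]
  sum(cx * p3[, 1] + cy * p3[, 2] + cz * p3[, 3]) / 6
}

#' Unique edges of a mesh
#'
#' Extracts the deduplicated undirected edge set (each pair appears once with
#' `i < j`), used to place one spring per mesh edge.
#'
#' @param mesh a surface or tetrahedral mesh
#' @return integer matrix with columns `i`, `j`
#' @export
mesh_edges <- function(mesh) {
  if (inherits(mesh, "softsim_tet_mesh")) {
    el <- mesh$tets
    pairs <- rbind(el[, c(1, 2)], el[, c(1, 3)], el[, c(1, 4)],
                   el[, c(2, 3)], el[, c(2, 4)], el[, c(3, 4)])
  } else if (inherits(mesh, "softsim_surface_mesh")) {
    el <- mesh$triangles
    pairs <- rbind(el[, c(1, 2)], el[, c(2, 3)], el[, c(3, 1)])
  } else stop("invalid-argument: not a softsim mesh")
  e <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  e <- unique(e)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  colnames(e) <- c("i", "j")
  e
}

# every interior triangular face of a tet mesh must be shared by exactly 2 tets
tet_face_counts <- function(mesh) {
  tt <- mesh$tets
  faces <- rbind(tt[, c(1, 2, 3)], tt[, c(1, 2, 4)], tt[, c(1, 3, 4)], tt[, c(2, 3, 4)])
  sorted <- t(apply(faces, 1, sort))
  table(paste(sorted[, 1], sorted[, 2], sorted[, 3]))
}
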