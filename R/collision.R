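#' Collision primitive
#'
#' @param kind `"sphere"` (one node + radius) or `"triangle"` (three nodes)
#' @param nodes node index (sphere) or three node indices (triangle)
#' @param radius sphere radius (mm)
#' @return an object of class `softsim_primitive`
#' @export
collision_primitive <- function(kind = c("sphere", "triangle"), nodes, radius = NULL) {
  kind <- match.arg(kind)
  nodes <- as.integer(nodes)
  if (kind == "sphere") {
    stopifnot(length(nodes) == 1, !is.null(radius), radius > 0)
  } else {
    stopifnot(length(nodes) == 3, !anyDuplicated(nodes))
  }
  structure(list(kind = kind, nodes = nodes, radius = radius),
            class = "softsim_primitive")
}

#' Axis-aligned bounding box of a primitive
#'
#' Sphere: centre +/- (radius + margin). Triangle: componentwise vertex
#' extrema +/- margin.
#'
#' @param primitive a [collision_primitive()]
#' @param positions n x 3 node position matrix
#' @param margin inflation (mm)
#' @return list with `min` and `max` (length-3)
#' @export
compute_aabb <- function(primitive, positions, margin = 0) {
  if (primitive$kind == "sphere") {
    c0 <- positions[primitive$nodes, ]
    r <- primitive$radius + margin
    list(min = c0 - r, max = c0 + r)
  } else {
    p <- positions[primitive$nodes, , drop = FALSE]
    list(min = apply(p, 2, min) - margin, max = apply(p, 2, max) + margin)
  }
}

#' Spatial-hash bucket of an integer grid cell
#'
#' The three-prime XOR hash
#' `((i*73856093) xor (j*19349663) xor (k*83492791)) mod table_size`, mapped
#' to the non-negative range.
#'
#' @param i,j,k integer cell coordinates
#' @param table_size hash table size (>= 1)
#' @return bucket index in `[0, table_size)`
#' @export
hash_cell <- function(i, j, k, table_size) {
  stopifnot(table_size >= 1)
  cpp_hash_cell(as.integer(i), as.integer(j), as.integer(k), as.integer(table_size))
}

#' Broad-phase candidate pairs via spatial hashing
#'
#' Registers each primitive's AABB in every grid cell it overlaps, collects
#' same-bucket pairs once each, re-checks AABB overlap, and drops pairs that
#' share a node. The result equals brute-force all-pairs AABB intersection
#' (the hash only accelerates the search).
#'
#' @param primitives list of [collision_primitive()] objects
#' @param positions n x 3 node position matrix
#' @param cell_size grid cell edge (mm); default twice the mean sphere radius
#' @param table_size hash table size; default twice the primitive count
#' @param margin AABB inflation (mm)
#' @return two-column integer matrix of primitive index pairs (row `i < j`)
#' @export
broad_phase <- function(primitives, positions, cell_size = NULL,
                        table_size = NULL, margin = 0) {
  np <- length(primitives)
  if (np < 2) return(matrix(integer(0), 0, 2))
  radii <- vapply(primitives, function(p)
    if (p$kind == "sphere") p$radius else NA_real_, numeric(1))
  cell_size <- cell_size %||%
    (if (all(is.na(radii))) 1 else 2 * mean(radii, na.rm = TRUE))
  table_size <- as.integer(table_size %||% (2L * np))
  boxes <- lapply(primitives, compute_aabb, positions = positions, margin = margin)
  mn <- do.call(rbind, lapply(boxes, `[[`, "min"))
  mx <- do.call(rbind, lapply(boxes, `[[`, "max"))
  prim_nodes <- lapply(primitives, `[[`, "nodes")
  pairs <- cpp_broad_phase(mn, mx, prim_nodes, cell_size, table_size)
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

#' Sphere-sphere narrow phase
#'
#' Emits a unilateral distance contact (`rest = r1 + r2`, compliance 0) iff
#' the centres strictly penetrate (`|q - p| < r1 + r2`). Exactly touching
#' spheres generate no contact.
#'
#' @param q,p sphere centre node indices
#' @param positions n x 3 position matrix
#' @param r1,r2 radii (mm)
#' @return a [constraint()] or `NULL`
#' @export
narrow_sphere_sphere <- function(q, p, positions, r1, r2) {
  d <- positions[q, ] - positions[p, ]
  len <- sqrt(sum(d^2))
  rsum <- r1 + r2
  if (len < DEGEN_EPS) {
    warning("coincident sphere centres; pushing apart along +x")
    return(constraint("contact_sphere_sphere", nodes = c(q, p), rest = rsum))
  }
  if (len >= rsum) return(NULL)
  constraint("contact_sphere_sphere", nodes = c(q, p), rest = rsum)
}

#' Sphere-triangle narrow phase
#'
#' Emits a unilateral vertex-triangle contact (compliance 0) iff the signed
#' plane distance of the centre is below the radius and the centre's
#' projection falls inside the triangle face (barycentric test; edge and
#' vertex regions do not fire).
#'
#' @param q sphere centre node index
#' @param tri triangle node indices (length 3)
#' @param positions n x 3 position matrix
#' @param r sphere radius (mm)
#' @return a [constraint()] or `NULL`
#' @export
narrow_sphere_triangle <- function(q, tri, positions, r) {
  p1 <- positions[tri[1], ]; p2 <- positions[tri[2], ]; p3 <- positions[tri[3], ]
  ev <- eval_vertex_triangle(positions[q, ], p1, p2, p3, r)
  if (is.null(ev) || ev$C >= 0) return(NULL)
  e2 <- p2 - p1; e3 <- p3 - p1; u <- positions[q, ] - p1
  d22 <- sum(e2 * e2); d23 <- sum(e2 * e3); d33 <- sum(e3 * e3)
  det <- d22 * d33 - d23^2
  if (det <= 0) return(NULL)
  wb <- (d33 * sum(u * e2) - d23 * sum(u * e3)) / det
  wc <- (d22 * sum(u * e3) - d23 * sum(u * e2)) / det
  if (wb < 0 || wc < 0 || wb + wc > 1) return(NULL)
  constraint("contact_vertex_triangle", nodes = c(q, tri), rest = r)
}
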