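#' Build a simulation model from a mesh
#'
#' Derives the physics topology from a mesh: one spring per unique edge with
#' rest length equal to the initial edge length; per-tet volume constraints for
#' the `"entity"` preset (solid organs, tetrahedral meshes) or one global
#' closed-surface volume constraint for the `"cavity"` preset (hollow organs,
#' closed surface meshes); and, when enabled, one overstretch band constraint
#' per spring. Node masses are the total mass lumped uniformly.
#'
#' The `mode` switch supports three-way comparisons on the same mesh:
#' `"integrated"` (springs + dampers + constraints), `"pbd_only"` (edge
#' distance constraints instead of spring forces, no dampers) and `"msd_only"`
#' (springs + dampers, no volume/overstretch constraints).
#'
#' @param mesh a [tet_mesh()] (entity) or closed [surface_mesh()] (cavity)
#' @param material a [material_params()]
#' @param preset `"entity"` or `"cavity"`; defaults to the natural preset for
#'   the mesh type
#' @param mode `"integrated"`, `"pbd_only"` or `"msd_only"`
#' @param overstretch add a band limiter per spring
#' @param volume_constraints add the preset's volume constraints (per-tet or
#'   global surface). Disable for pure rheometry tests of the spring-damper
#'   behaviour, where position-level volume projection would mask the viscous
#'   time scales
#' @param total_mass total model mass (g); default `density * mesh_volume(mesh)`
#' @param density used when `total_mass` is `NULL` (g/mm^3, default 1e-3,
#'   i.e. 1 g/cm^3, typical of soft tissue)
#' @return an object of class `softsim_model`
#' @export
build_model <- function(mesh, material = material_params(),
                        preset = NULL,
                        mode = c("integrated", "pbd_only", "msd_only"),
                        overstretch = TRUE, volume_constraints = TRUE,
                        total_mass = NULL, density = 1e-3) {
  mode <- match.arg(mode)
  if (is.null(preset))
    preset <- if (inherits(mesh, "softsim_tet_mesh")) "entity" else "cavity"
  if (!preset %in% c("entity", "cavity"))
    stop("invalid-argument: unknown preset '", preset, "'")
  if (preset == "entity" && !inherits(mesh, "softsim_tet_mesh"))
    stop("invalid-argument: entity preset requires a tetrahedral mesh")
  if (preset == "cavity") {
    if (!inherits(mesh, "softsim_surface_mesh"))
      stop("invalid-argument: cavity preset requires a surface mesh")
    if (!is_closed_surface(mesh))
      stop("topology-error: cavity preset requires a closed oriented surface")
  }
  x <- mesh$vertices
  n <- nrow(x)
  vol <- mesh_volume(mesh)
  total_mass <- total_mass %||% (density * abs(vol))
  stopifnot(total_mass > 0)
  mass <- rep(total_mass / n, n)

  springs <- build_springs(mesh_edges(mesh), x, material)

  use_constraints <- mode != "msd_only"
  cons <- list(dist = matrix(numeric(0), 0, 4), over = matrix(numeric(0), 0, 4),
               tet = matrix(numeric(0), 0, 6), surf = NULL)
  if (mode == "pbd_only") {
    cons$dist <- cbind(springs$i, springs$j, springs$l0, material$alpha)
  }
  if (use_constraints && overstretch) {
    cons$over <- cbind(springs$i, springs$j, springs$l0, material$k_ratio)
  }
  if (use_constraints && volume_constraints) {
    if (preset == "entity") {
      V0 <- tet_signed_volumes(x, mesh$tets)
      cons$tet <- cbind(mesh$tets, V0, material$alpha)
    } else {
      cons$surf <- list(tris = mesh$triangles, V0 = vol, alpha = material$alpha)
    }
  }

  volume_spec <- if (preset == "entity")
    list(kind = "tet", idx = mesh$tets) else list(kind = "surface", idx = mesh$triangles)

  structure(list(
    mesh = mesh, preset = preset, mode = mode, material = material,
    x = x, x_rest = x, mass = mass, w = 1 / mass,
    springs = springs, constraints = cons, volume_spec = volume_spec,
    collision = list(sphere_nodes = integer(0), sphere_r = numeric(0),
                     tri = matrix(integer(0), 0, 3),
                     cell_size = NULL, table_size = NULL,
                     margin = 0, tri_margin = 0),
    n_mesh_nodes = n
  ), class = "softsim_model")
}

#' @export
print.softsim_model <- function(x, ...) {
  cons <- x$constraints
  cat(sprintf(
    "soft-body model (%s, %s): %d nodes, %d springs\n  constraints: %d distance, %d overstretch, %d tet-volume, %d surface-volume\n  collision: %d spheres, %d triangles\n",
    x$preset, x$mode, nrow(x$x), nrow(x$springs),
    nrow(cons$dist), nrow(cons$over), nrow(cons$tet),
    if (is.null(cons$surf)) 0L else 1L,
    length(x$collision$sphere_nodes), nrow(x$collision$tri)))
  invisible(x)
}

#' Attach collision spheres to model nodes
#'
#' @param model a [build_model()] result
#' @param nodes node indices carrying spheres (default: all mesh nodes)
#' @param radius sphere radius (mm), recycled over `nodes`
#' @return the updated model
#' @export
add_collision_spheres <- function(model, nodes = seq_len(model$n_mesh_nodes), radius) {
  stopifnot(inherits(model, "softsim_model"), all(radius > 0))
  model$collision$sphere_nodes <- c(model$collision$sphere_nodes, as.integer(nodes))
  model$collision$sphere_r <- c(model$collision$sphere_r,
                                rep_len(radius, length(nodes)))
  model
}

#' Add a fixed horizontal plane as collision geometry
#'
#' Appends four immovable nodes and two large collision triangles at height
#' `z`, oriented with the outward normal pointing up (+z), so falling bodies
#' rest on it.
#'
#' @param model a [build_model()] result
#' @param z plane height (mm)
#' @param size half-extent of the square plane (mm)
#' @param center x/y centre of the plane
#' @return the updated model
#' @export
add_static_plane <- function(model, z = 0, size = 200, center = c(0, 0)) {
  stopifnot(inherits(model, "softsim_model"))
  n0 <- nrow(model$x)
  corners <- rbind(c(center[1] - size, center[2] - size, z),
                   c(center[1] + size, center[2] - size, z),
                   c(center[1] + size, center[2] + size, z),
                   c(center[1] - size, center[2] + size, z))
  model$x <- rbind(model$x, corners)
  model$x_rest <- rbind(model$x_rest, corners)
  model$mass <- c(model$mass, rep(0, 4))
  model$w <- c(model$w, rep(0, 4))
  # counter-clockwise seen from +z -> normal up
  tris <- rbind(c(n0 + 1L, n0 + 2L, n0 + 3L), c(n0 + 1L, n0 + 3L, n0 + 4L))
  model$collision$tri <- rbind(model$collision$tri, tris)
  model
}

#' Node selectors on the rest geometry
#'
#' Convenience selectors for boundary conditions and probes, operating on the
#' model's rest positions: the bottom/top face (minimum/maximum z within a
#' tolerance) and the centre node of the top face (the rheometry test point;
#' exact for even division counts).
#'
#' @param model a [build_model()] result
#' @param tol coordinate tolerance (mm)
#' @return integer node indices
#' @export
nodes_bottom_face <- function(model, tol = 1e-6) {
  z <- model$x_rest[seq_len(model$n_mesh_nodes), 3]
  which(z < min(z) + tol)
}

#' @rdname nodes_bottom_face
#' @export
nodes_top_face <- function(model, tol = 1e-6) {
  z <- model$x_rest[seq_len(model$n_mesh_nodes), 3]
  which(z > max(z) - tol)
}

#' @rdname nodes_bottom_face
#' @export
node_top_center <- function(model, tol = 1e-6) {
  top <- nodes_top_face(model, tol)
  xy <- model$x_rest[top, 1:2, drop = FALSE]
  ctr <- colMeans(model$x_rest[seq_len(model$n_mesh_nodes), 1:2, drop = FALSE])
  d2 <- (xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2
  if (min(d2) > tol^2)
    warning("no exact centre node on the top face; using the nearest ",
            "(use even division counts for an exact test point)")
  top[which.min(d2)]
}
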