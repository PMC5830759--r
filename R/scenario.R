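#' Read a scenario configuration file
#'
#' YAML scenario files describe a full simulation: a `geometry` block (cube,
#' beam, icosphere, or a mesh file), a `material` block (k1, k2, b0, b1,
#' alpha, plus dl_c/dl_c_frac and k_ratio), a `model` block (preset, mode,
#' mass), a `solver` block (dt, iterations, gravity), a `boundary_conditions`
#' list (selectors `bottom_face`, `top_face`, `top_center` or explicit ids), a
#' `collision` block (node spheres, optional static plane) and a `probe`.
#'
#' @param path YAML file path
#' @return the parsed configuration list
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("parse-error: file not found: ", path)
  yaml::read_yaml(path)
}

scenario_geometry <- function(g) {
  kind <- g$kind %||% stop("invalid-argument: geometry block needs a 'kind'")
  switch(kind,
    cube = generate_cube_lattice(g$edge %||% 60, g$divisions %||% 6),
    beam = generate_beam(unlist(g$lengths %||% c(60, 20, 20)),
                         unlist(g$divisions %||% c(6, 2, 2))),
    icosphere = generate_icosphere(g$radius %||% 15, g$subdivisions %||% 2),
    surface_file = read_surface_mesh(g$path, require_closed = isTRUE(g$closed)),
    tet_file = read_tet_mesh(g$path),
    stop("invalid-argument: unknown geometry kind '", kind, "'"))
}

scenario_material <- function(m) {
  m <- m %||% list()
  material_params(
    k1 = m$k1 %||% 0.25, k2 = m$k2 %||% 10, dl_c = m$dl_c,
    dl_c_frac = m$dl_c_frac %||% 0.1, b0 = m$b0 %||% 2, b1 = m$b1 %||% 1000,
    k_ratio = m$k_ratio %||% 0.5, alpha = m$alpha %||% 0)
}

scenario_nodes <- function(sel, model) {
  if (is.character(sel)) {
    switch(sel,
      bottom_face = nodes_bottom_face(model),
      top_face = nodes_top_face(model),
      top_center = node_top_center(model),
      all = seq_len(model$n_mesh_nodes),
      stop("invalid-argument: unknown node selector '", sel, "'"))
  } else as.integer(unlist(sel))
}

#' Assemble and run a scenario
#'
#' Builds the model described by a configuration (see
#' [read_scenario_config()]) and runs it, optionally writing the probe and
#' diagnostic time series as CSV and the final node positions as an OBJ/TetGen
#' mesh into `out_dir`.
#'
#' @param config a configuration list or a path to a YAML file
#' @param out_dir optional output directory
#' @return the [run_simulation()] result
#' @export
run_scenario <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_scenario_config(config)
  mesh <- scenario_geometry(config$geometry)
  material <- scenario_material(config$material)
  mb <- config$model %||% list()
  model <- build_model(mesh, material,
                       preset = mb$preset,
                       mode = mb$mode %||% "integrated",
                       overstretch = mb$overstretch %||% TRUE,
                       total_mass = mb$total_mass,
                       density = mb$density %||% 1e-3)
  cl <- config$collision %||% list()
  if (!is.null(cl$sphere_radius))
    model <- add_collision_spheres(model,
                                   nodes = scenario_nodes(cl$sphere_nodes %||% "all", model),
                                   radius = cl$sphere_radius)
  if (!is.null(cl$plane))
    model <- add_static_plane(model, z = cl$plane$z %||% 0,
                              size = cl$plane$size %||% 200)
  if (!is.null(cl$cell_size)) model$collision$cell_size <- cl$cell_size
  if (!is.null(cl$table_size)) model$collision$table_size <- cl$table_size
  sv <- config$solver %||% list()
  sc <- solver_config(dt = sv$dt %||% 0.005, iterations = sv$iterations %||% 10,
                      gravity = unlist(sv$gravity %||% c(0, 0, 0)))
  bcs <- lapply(config$boundary_conditions %||% list(), function(bc)
    boundary_condition(bc$kind, scenario_nodes(bc$nodes, model),
                       unlist(bc$value %||% c(0, 0, 0)),
                       t0 = bc$t0 %||% 0, t1 = bc$t1 %||% Inf))
  probe <- if (!is.null(config$probe)) scenario_nodes(config$probe, model)[1]
  res <- run_simulation(model, sc, config$duration %||% 1, bcs, probe = probe,
                        stride = config$stride %||% 1L)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$series, file.path(out_dir, "series.csv"),
                     row.names = FALSE)
    final <- res$state$x[seq_len(model$n_mesh_nodes), , drop = FALSE]
    if (inherits(mesh, "softsim_surface_mesh")) {
      write_surface_mesh(surface_mesh(final, mesh$triangles),
                         file.path(out_dir, "final.obj"))
    } else {
      write_tet_mesh(tet_mesh(final, mesh$tets, validate = FALSE),
                     file.path(out_dir, "final"))
    }
  }
  res
}

#' Run a named experiment with optional CSV output
#'
#' Thin dispatcher used by the command-line interface: runs one of the
#' scripted experiments with its standard study conditions and writes its
#' series (and a small JSON-ish summary) under `out_dir`.
#'
#' @param name one of `"nonlinearity"`, `"creep"`, `"stress-relaxation"`,
#'   `"volume"`, `"stability"`
#' @param out_dir optional output directory
#' @param ... passed to the matching `run_*` function
#' @return the experiment object
#' @export
run_experiment <- function(name, out_dir = NULL, ...) {
  obj <- switch(name,
    nonlinearity = run_nonlinearity(...),
    creep = run_creep(...),
    `stress-relaxation` = run_stress_relaxation(...),
    volume = run_volume_tests(...),
    stability = run_stability(...),
    stop("invalid-argument: unknown experiment '", name, "'"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    series <- if (inherits(obj, "softsim_experiment")) obj$series else obj$series
    utils::write.csv(series, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  obj
}
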