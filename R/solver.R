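#' Solver configuration
#'
#' @param dt timestep (s)
#' @param iterations Gauss-Seidel projection sweeps per step
#' @param gravity acceleration vector (mm/s^2); use `c(0, 0, -9810)` for
#'   standard gravity in the package's mm/g/s unit convention
#' @param collision_margin AABB inflation for broad-phase culling (mm)
#' @return an object of class `softsim_solver_config`
#' @export
solver_config <- function(dt = 0.005, iterations = 10, gravity = c(0, 0, 0),
                          collision_margin = 0) {
  stopifnot(dt > 0, iterations >= 1, length(gravity) == 3)
  structure(list(dt = dt, iterations = as.integer(iterations),
                 gravity = as.numeric(gravity),
                 collision_margin = collision_margin),
            class = "softsim_solver_config")
}

#' Boundary condition
#'
#' `"fixed"` pins nodes (inverse mass 0) for the schedule window;
#' `"velocity"` drives nodes kinematically at a constant velocity vector;
#' `"force"` applies a constant external force vector per node. Windows are
#' half-open `[t0, t1)`.
#'
#' @param kind `"fixed"`, `"velocity"` or `"force"`
#' @param nodes node indices
#' @param value length-3 vector: ignored for `"fixed"`, velocity (mm/s) for
#'   `"velocity"`, force per node for `"force"`
#' @param t0,t1 schedule window (s)
#' @return an object of class `softsim_bc`
#' @export
boundary_condition <- function(kind = c("fixed", "velocity", "force"),
                               nodes, value = c(0, 0, 0), t0 = 0, t1 = Inf) {
  kind <- match.arg(kind)
  stopifnot(length(value) == 3, t1 > t0)
  structure(list(kind = kind, nodes = as.integer(nodes),
                 value = as.numeric(value), t0 = t0, t1 = t1),
            class = "softsim_bc")
}

#' Predicted (pre-projection) positions
#'
#' The position-level Verlet predictor
#' `x* = x + (x - x_prev) + w * f * dt^2` per node; fixed nodes (`w = 0`) stay
#' put. This is the reference form without damping; inside [run_simulation()]
#' the rest-referenced damper additionally attenuates the inertial term
#' semi-implicitly.
#'
#' @param system a [particle_system()]
#' @param forces n x 3 force array (spring + external)
#' @param dt timestep (s)
#' @return n x 3 matrix of predicted positions
#' @export
predict_positions <- function(system, forces, dt) {
  if (any(!is.finite(forces)))
    stop("solver-error: non-finite force at node ",
         which(!is.finite(rowSums(forces)))[1])
  system$x + (system$x - system$x_prev) + (system$w * forces) * dt^2
}

flatten_for_solver <- function(model, config, bcs, state, n_steps, stride,
                               t_start, probe) {
  n <- nrow(model$x)
  x <- state$x %||% model$x
  x_prev <- state$x_prev %||% x
  sys <- list(x = x, x_prev = x_prev, x_rest = model$x_rest,
              w = model$w, mass = model$mass)
  spr <- list(nodes = cbind(model$springs$i, model$springs$j) - 1L,
              l0 = model$springs$l0, dl_c = model$springs$dl_c,
              k1 = if (model$mode == "pbd_only") 0 else model$material$k1,
              k2 = if (model$mode == "pbd_only") 0 else model$material$k2,
              b0 = if (model$mode == "pbd_only") 0 else model$material$b0,
              b1 = if (model$mode == "pbd_only") 0 else model$material$b1)
  if (model$mode == "pbd_only") spr$nodes <- matrix(0L, 0, 2)
  cn <- model$constraints
  zero_index <- function(m, k) {
    m <- as.matrix(m)
    if (nrow(m)) m[, seq_len(k)] <- m[, seq_len(k)] - 1
    m
  }
  cons <- list(dist = zero_index(cn$dist, 2), over = zero_index(cn$over, 2),
               tet = zero_index(cn$tet, 4),
               has_surf = !is.null(cn$surf))
  if (cons$has_surf) {
    cons$surf_tris <- cn$surf$tris - 1L
    cons$surf_V0 <- cn$surf$V0
    cons$surf_alpha <- cn$surf$alpha
  }
  cl <- model$collision
  coll_on <- length(cl$sphere_nodes) > 0
  coll <- list(enabled = coll_on)
  if (coll_on) {
    mean_r <- mean(cl$sphere_r)
    coll <- list(
      enabled = TRUE,
      sphere_nodes = cl$sphere_nodes - 1L,
      sphere_r = cl$sphere_r,
      tri = cl$tri - 1L,
      cell_size = cl$cell_size %||% (2 * mean_r),
      table_size = as.integer(cl$table_size %||%
                                (2L * (length(cl$sphere_nodes) + nrow(cl$tri)))),
      margin = max(cl$margin, config$collision_margin),
      tri_margin = cl$tri_margin)
  }
  bcl <- lapply(bcs, function(bc) {
    stopifnot(inherits(bc, "softsim_bc"))
    list(kind = match(bc$kind, c("fixed", "velocity", "force")) - 1L,
         nodes = bc$nodes - 1L, value = bc$value,
         t0 = bc$t0, t1 = min(bc$t1, .Machine$double.xmax))
  })
  vs <- model$volume_spec
  cfg <- list(dt = config$dt, iterations = config$iterations,
              n_steps = as.integer(n_steps), stride = as.integer(stride),
              t_start = t_start, gravity = config$gravity,
              probe = if (is.null(probe)) -1L else as.integer(probe) - 1L,
              half_start = is.null(state$x),
              vol_kind = switch(vs$kind, none = 0L, tet = 1L, surface = 2L))
  if (cfg$vol_kind == 1L) cfg$vol_tets <- vs$idx - 1L
  if (cfg$vol_kind == 2L) cfg$vol_tris <- vs$idx - 1L
  list(sys = sys, spr = spr, cons = cons, coll = coll, bcl = bcl, cfg = cfg)
}

#' Run a simulation
#'
#' Advances the coupled mass-spring-damper + compliant-constraint system:
#' each step evaluates spring forces, predicts positions with the
#' damper-attenuated Verlet form, detects collisions on the predicted state,
#' resets all multipliers, runs the Gauss-Seidel projection loop and commits.
#' The loop is fully deterministic for a fixed configuration.
#'
#' @param model a [build_model()] result
#' @param config a [solver_config()]
#' @param duration simulated time (s); the number of steps is
#'   `round(duration / dt)`
#' @param bcs list of [boundary_condition()] objects
#' @param probe node index whose position, displacement and reaction force are
#'   sampled each recorded step (the reaction is `m a - f_internal`, the
#'   external force needed to hold the node on its trajectory)
#' @param stride record every `stride`-th step (0 = record nothing)
#' @param state optional `list(x, x_prev)` to continue from
#' @param t_start simulation clock at entry (s), used by BC schedules
#' @return an object of class `softsim_result`: `series` (data.frame of
#'   per-step diagnostics), final `state`, and the inputs' metadata
#' @export
run_simulation <- function(model, config = solver_config(), duration,
                           bcs = list(), probe = NULL, stride = 1L,
                           state = NULL, t_start = 0) {
  stopifnot(inherits(model, "softsim_model"),
            inherits(config, "softsim_solver_config"), duration >= 0)
  n_steps <- as.integer(round(duration / config$dt))
  args <- flatten_for_solver(model, config, bcs, state %||% list(),
                             n_steps, stride, t_start, probe)
  out <- cpp_run(args$sys, args$spr, args$cons, args$coll, args$bcl, args$cfg)
  if (out$degenerate_events > 0)
    warning(out$degenerate_events, " degenerate spring/constraint event(s) skipped")
  series <- as.data.frame(out$series)
  structure(list(series = series,
                 state = list(x = out$x, x_prev = out$x_prev),
                 model = model, config = config, t_end = t_start + n_steps * config$dt),
            class = "softsim_result")
}

#' @export
print.softsim_result <- function(x, ...) {
  cat(sprintf("simulation result: %d samples to t = %.4g s\n",
              nrow(x$series), x$t_end))
  invisible(x)
}

#' Advance a model one timestep
#'
#' Single-step convenience wrapper around the same compiled stepper as
#' [run_simulation()].
#'
#' @inheritParams run_simulation
#' @param t current simulation time (s)
#' @return list with `state` (`x`, `x_prev`) and `diagnostics` (one-row
#'   data.frame: residual `max_C`, contact count, kinetic energy, volume)
#' @export
step_simulation <- function(model, config = solver_config(), bcs = list(),
                            state = NULL, t = 0, probe = NULL) {
  res <- run_simulation(model, config, duration = config$dt, bcs = bcs,
                        probe = probe, stride = 1L, state = state, t_start = t)
  list(state = res$state, diagnostics = res$series)
}
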