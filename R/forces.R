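#' Material parameters for the viscoelastic mass-spring-damper model
#'
#' Bundles the control parameters of the force model and the compliant
#' constraints. The spring law is a third-degree polynomial
#' `k1*dl + k2*dl^3` for `|dl| <= dl_c` and continues linearly (C1) beyond the
#' crossover `dl_c`; the damper scales the baseline coefficient `b0` by
#' `b1 * ||x - x_rest||`, which is what produces creep and stress relaxation.
#'
#' @param k1 nonlinear spring stiffness (force/mm)
#' @param k2 cubic spring stiffness coefficient (force/mm^3)
#' @param dl_c absolute stiffness crossover displacement (mm), or `NULL` to use
#'   `dl_c_frac * l0` per spring
#' @param dl_c_frac fractional crossover used when `dl_c` is `NULL`
#' @param b0 baseline damping coefficient (force s/mm)
#' @param b1 viscoelastic damping coefficient (force s/mm^2)
#' @param k_ratio overstretch limit as a fraction of rest length
#' @param alpha constraint compliance (inverse stiffness) for bilateral
#'   constraints; 0 means rigid
#' @return an object of class `softsim_material`
#' @export
material_params <- function(k1 = 0.25, k2 = 10, dl_c = NULL, dl_c_frac = 0.1,
                            b0 = 2, b1 = 1000, k_ratio = 0.5, alpha = 0) {
  stopifnot(k1 >= 0, k2 >= 0, b0 >= 0, b1 >= 0, k_ratio > 0, alpha >= 0,
            is.null(dl_c) || dl_c > 0, dl_c_frac > 0)
  structure(list(k1 = k1, k2 = k2, dl_c = dl_c, dl_c_frac = dl_c_frac,
                 b0 = b0, b1 = b1, k_ratio = k_ratio, alpha = alpha),
            class = "softsim_material")
}

#' @export
print.softsim_material <- function(x, ...) {
  cat(sprintf(
    "material: k1 = %g, k2 = %g, dl_c = %s, b0 = %g, b1 = %g, k_ratio = %g, alpha = %g\n",
    x$k1, x$k2,
    if (is.null(x$dl_c)) sprintf("%g * l0", x$dl_c_frac) else format(x$dl_c),
    x$b0, x$b1, x$k_ratio, x$alpha))
  invisible(x)
}

#' Per-node particle state
#'
#' @param x current positions, n x 3 (mm)
#' @param x_prev previous-step positions (defaults to `x`, i.e. at rest)
#' @param w inverse masses (1/g); 0 marks a fixed node
#' @param x_rest rest positions used by the damper's displacement scaling
#' @param v velocities (mm/s), default zero; stored by shifting `x_prev`
#'   consistently with the position-level integrator requires `dt`, so `v` here
#'   is informational state for force evaluation
#' @return an object of class `softsim_particles`
#' @export
particle_system <- function(x, x_prev = x, w = rep(1, nrow(x)), x_rest = x,
                            v = matrix(0, nrow(x), 3)) {
  x <- as_coord_matrix(x, "x")
  x_prev <- as_coord_matrix(x_prev, "x_prev")
  x_rest <- as_coord_matrix(x_rest, "x_rest")
  v <- as_coord_matrix(v, "v")
  w <- as.numeric(w)
  n <- nrow(x)
  if (nrow(x_prev) != n || nrow(x_rest) != n || nrow(v) != n || length(w) != n)
    stop("invalid-argument: particle arrays must all have the same node count")
  if (any(w < 0) || any(!is.finite(w)))
    stop("invalid-argument: inverse masses must be finite and non-negative")
  structure(list(x = x, x_prev = x_prev, v = v, w = w, x_rest = x_rest),
            class = "softsim_particles")
}

#' Scalar nonlinear spring force
#'
#' Piecewise force law: `k1*dl + k2*dl^3` for `|dl| <= dl_c`, and
#' `(A + B(|dl| - dl_c)) * sign(dl)` with `A = k1*dl_c + k2*dl_c^3`,
#' `B = k1 + 3*k2*dl_c^2` beyond it. Odd in `dl` and C1 at the crossover.
#' Vectorized over `dl`.
#'
#' @param dl spring elongation(s) `||xi - xj|| - l0` (mm)
#' @param params a [material_params()]; its `dl_c` must be absolute unless
#'   `dl_c` is supplied here
#' @param dl_c optional absolute crossover override (mm)
#' @return force magnitude(s), same sign convention as `dl`
#' @export
spring_scalar <- function(dl, params = material_params(), dl_c = NULL) {
  dlc <- dl_c %||% params$dl_c
  if (is.null(dlc))
    stop("invalid-argument: an absolute dl_c is required (params$dl_c or dl_c)")
  k1 <- params$k1; k2 <- params$k2
  A <- k1 * dlc + k2 * dlc^3
  B <- k1 + 3 * k2 * dlc^2
  ifelse(abs(dl) <= dlc, k1 * dl + k2 * dl^3, sign(dl) * (A + B * (abs(dl) - dlc)))
}

#' Spring topology from a mesh or edge list
#'
#' One spring per unique edge with rest length equal to the initial edge
#' length; the crossover `dl_c` is resolved per spring (absolute, or fractional
#' from the material).
#'
#' @param edges integer matrix of node pairs (columns i, j)
#' @param x rest positions used for `l0`
#' @param params a [material_params()]
#' @return data.frame with columns `i`, `j`, `l0`, `dl_c`
#' @export
build_springs <- function(edges, x, params = material_params()) {
  l0 <- sqrt(rowSums((x[edges[, 1], , drop = FALSE] - x[edges[, 2], , drop = FALSE])^2))
  if (any(l0 <= 0)) stop("invalid-argument: zero-length spring in edge set")
  dlc <- if (is.null(params$dl_c)) params$dl_c_frac * l0 else rep(params$dl_c, length(l0))
  data.frame(i = edges[, 1], j = edges[, 2], l0 = l0, dl_c = dlc)
}

#' Per-node spring forces
#'
#' Accumulates a restoring, equal-and-opposite force pair per spring: the force
#' on `i` is `-spring_scalar(dl) * (xi - xj)/||xi - xj||`. The vector sum over
#' all nodes is exactly zero. Degenerate springs (length below 1e-9 mm)
#' contribute nothing and raise a warning.
#'
#' @param system a [particle_system()]
#' @param springs data.frame from [build_springs()]
#' @param params a [material_params()]
#' @return n x 3 force array
#' @export
spring_forces <- function(system, springs, params = material_params()) {
  x <- system$x
  d <- x[springs$i, , drop = FALSE] - x[springs$j, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  ok <- len >= 1e-9
  if (!all(ok)) warning(sum(!ok), " degenerate spring(s) skipped")
  f <- matrix(0, nrow(x), 3)
  if (!any(ok)) return(f)
  dl <- len[ok] - springs$l0[ok]
  fs <- spring_scalar(dl, params, dl_c = springs$dl_c[ok])
  fvec <- -d[ok, , drop = FALSE] * (fs / len[ok])
  for (c in 1:3) {
    f[, c] <- f[, c] +
      tapply_sum(fvec[, c], springs$i[ok], nrow(x)) -
      tapply_sum(fvec[, c], springs$j[ok], nrow(x))
  }
  f
}

tapply_sum <- function(values, index, n) {
  out <- numeric(n)
  agg <- rowsum(values, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Per-node damper forces
#'
#' The displacement-scaled velocity damper
#' `f_i = -(b0 + b1 * ||x_i - x_rest_i||) * v_i`: a direct drag on each point
#' mass whose coefficient grows with distance from the rest pose, which is the
#' mechanism behind the model's creep and stress-relaxation behaviour.
#'
#' @param system a [particle_system()]
#' @param params a [material_params()]
#' @return n x 3 force array opposing the velocities
#' @export
damper_forces <- function(system, params = material_params()) {
  disp <- sqrt(rowSums((system$x - system$x_rest)^2))
  -(params$b0 + params$b1 * disp) * system$v
}

`%||%` <- function(a, b) if (is.null(a)) b else a
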