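#' @name constraint-evaluation
#' @title Constraint functions and analytic gradients
#'
#' @description
#' Each `eval_*` function returns `list(C = <scalar>, grad = <k x 3 matrix>,
#' active = <logical>)` where the gradient rows follow the argument order of
#' the involved nodes. Gradients are exact analytic derivatives of `C`, so
#' they match central finite differences and, for translation-invariant
#' constraints, sum to the zero vector (which makes equal-mass projection
#' momentum-conserving). `active = FALSE` marks a unilateral constraint that
#' must not be projected in its current configuration. Degenerate
#' configurations return `NULL` with a warning.
NULL

DEGEN_EPS <- 1e-9

vcross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Distance constraint `C = |q - p| - rest`
#'
#' @param p,q node positions (length-3)
#' @param rest rest distance (mm)
#' @param unilateral if `TRUE` the constraint is only active under penetration
#'   (`C < 0`), the contact convention
#' @return see [constraint-evaluation]
#' @export
eval_distance <- function(p, q, rest, unilateral = FALSE) {
  d <- q - p
  len <- sqrt(sum(d^2))
  if (len < DEGEN_EPS) {
    warning("degenerate distance constraint skipped (coincident nodes)")
    return(NULL)
  }
  n <- d / len
  C <- len - rest
  list(C = C, grad = rbind(p = -n, q = n), active = !unilateral || C < 0)
}

#' Tetrahedral volume constraint
#'
#' `C = (1/6) ((p2-p1) x (p3-p1)) . (p4-p1) - V0`. The four gradients sum to
#' zero (the signed volume is translation invariant).
#'
#' @param p1,p2,p3,p4 tet vertex positions
#' @param V0 rest volume (mm^3)
#' @return see [constraint-evaluation]
#' @export
eval_tet_volume <- function(p1, p2, p3, p4, V0) {
  e2 <- p2 - p1; e3 <- p3 - p1; e4 <- p4 - p1
  C <- sum(vcross3(e2, e3) * e4) / 6 - V0
  g2 <- vcross3(e3, e4) / 6
  g3 <- vcross3(e4, e2) / 6
  g4 <- vcross3(e2, e3) / 6
  g1 <- -(g2 + g3 + g4)
  list(C = C, grad = rbind(p1 = g1, p2 = g2, p3 = g3, p4 = g4), active = TRUE)
}

#' Closed-surface volume constraint
#'
#' `C = (1/6) sum_t (pt1 x pt2) . pt3 - V0` over the triangles of a closed
#' oriented surface (divergence theorem; the 1/6 normalization makes `V0` a
#' true geometric volume). The gradient for a vertex accumulates the cross
#' products of its incident triangles' other two vertices; the total over all
#' vertices is zero.
#'
#' @param vertices n x 3 positions of all surface nodes
#' @param triangles m x 3 index matrix (1-based, outward orientation)
#' @param V0 rest enclosed volume (mm^3)
#' @return see [constraint-evaluation]; `grad` is n x 3
#' @export
eval_surface_volume <- function(vertices, triangles, V0) {
  n <- nrow(vertices)
  grad <- matrix(0, n, 3)
  V <- 0
  for (t in seq_len(nrow(triangles))) {
    a <- triangles[t, 1]; b <- triangles[t, 2]; cc <- triangles[t, 3]
    pa <- vertices[a, ]; pb <- vertices[b, ]; pc <- vertices[cc, ]
    V <- V + sum(vcross3(pa, pb) * pc) / 6
    grad[a, ] <- grad[a, ] + vcross3(pb, pc) / 6
    grad[b, ] <- grad[b, ] + vcross3(pc, pa) / 6
    grad[cc, ] <- grad[cc, ] + vcross3(pa, pb) / 6
  }
  list(C = V - V0, grad = grad, active = TRUE)
}

#' Overstretch/compression band constraint
#'
#' `C = (k_ratio*l0)^2 - (|p1-p2| - l0)^2`, a unilateral limiter that is
#' inactive while the elongation stays inside the band
#' `|dl| <= k_ratio * l0` and, once violated (`C < 0`), is projected rigidly
#' (compliance 0) to clamp the elongation back to the band edge. Both
#' overstretch and over-compression are limited.
#'
#' @param p1,p2 node positions
#' @param l0 rest length (mm)
#' @param k_ratio band half-width as a fraction of `l0`
#' @return see [constraint-evaluation]
#' @export
eval_overstretch <- function(p1, p2, l0, k_ratio) {
  stopifnot(l0 > 0)
  d <- p1 - p2
  len <- sqrt(sum(d^2))
  if (len < DEGEN_EPS) {
    warning("degenerate overstretch constraint skipped (coincident nodes)")
    return(NULL)
  }
  dl <- len - l0
  band <- k_ratio * l0
  C <- band^2 - dl^2
  g1 <- -2 * dl * d / len
  list(C = C, grad = rbind(p1 = g1, p2 = -g1), active = C < 0)
}

#' Vertex-triangle plane-distance constraint
#'
#' `C = (q - p1) . n - r` with `n` the unit normal of triangle
#' `(p1, p2, p3)`. Gradients are the exact analytic derivatives, including the
#' variation of the normal with the triangle vertices; they sum to zero.
#' Used unilaterally for contacts (active only when `C < 0`).
#'
#' @param q vertex (sphere centre) position
#' @param p1,p2,p3 triangle vertex positions
#' @param r offset radius (mm)
#' @param unilateral contact convention flag
#' @return see [constraint-evaluation]
#' @export
eval_vertex_triangle <- function(q, p1, p2, p3, r, unilateral = TRUE) {
  u <- q - p1; e2 <- p2 - p1; e3 <- p3 - p1
  m <- vcross3(e2, e3)
  M <- sqrt(sum(m^2))
  if (M < DEGEN_EPS) {
    warning("degenerate triangle skipped in vertex-triangle constraint")
    return(NULL)
  }
  nh <- m / M
  s <- sum(u * m)
  C <- s / M - r
  gq <- nh
  g2 <- (vcross3(e3, u) - (s / M) * vcross3(e3, nh)) / M
  g3 <- (vcross3(u, e2) - (s / M) * vcross3(nh, e2)) / M
  g1 <- -(gq + g2 + g3)
  list(C = C, grad = rbind(q = gq, p1 = g1, p2 = g2, p3 = g3),
       active = !unilateral || C < 0)
}

#' Tagged constraint object
#'
#' A light container pairing a constraint kind with its node ids, scalar rest
#' reference, compliance and accumulated multiplier, mirroring how the solver
#' stores constraints internally.
#'
#' @param kind one of `"distance"`, `"tet_volume"`, `"surface_volume"`,
#'   `"overstretch"`, `"contact_sphere_sphere"`, `"contact_vertex_triangle"`
#' @param nodes involved node indices, in the order the matching `eval_*`
#'   expects; for `surface_volume` supply the triangle index matrix via
#'   `triangles` instead
#' @param rest scalar reference (rest length, rest volume, or radius sum)
#' @param alpha compliance (0 = rigid)
#' @param triangles triangle matrix for `surface_volume`
#' @param k_ratio band fraction for `overstretch`
#' @return an object of class `softsim_constraint` with an accumulated
#'   multiplier `lam` initialised to 0
#' @export
constraint <- function(kind = c("distance", "tet_volume", "surface_volume",
                                "overstretch", "contact_sphere_sphere",
                                "contact_vertex_triangle"),
                       nodes = integer(0), rest = 0, alpha = 0,
                       triangles = NULL, k_ratio = NULL) {
  kind <- match.arg(kind)
  stopifnot(alpha >= 0, !anyDuplicated(nodes))
  unilateral <- kind %in% c("overstretch", "contact_sphere_sphere",
                            "contact_vertex_triangle")
  structure(list(kind = kind, nodes = as.integer(nodes), rest = rest,
                 alpha = alpha, lam = 0, unilateral = unilateral,
                 triangles = triangles, k_ratio = k_ratio),
            class = "softsim_constraint")
}

#' @export
print.softsim_constraint <- function(x, ...) {
  cat(constraint_dump_line(x), "\n")
  invisible(x)
}

#' One-line plain-text dump of a constraint (for debug snapshots)
#' @param con a [constraint()]
#' @return character scalar `kind | nodes | rest | alpha | lam`
#' @export
constraint_dump_line <- function(con) {
  nodes <- if (con$kind == "surface_volume")
    paste0("tris:", nrow(con$triangles)) else paste(con$nodes, collapse = ",")
  sprintf("%s | %s | %.9g | %.9g | %.9g", con$kind, nodes, con$rest, con$alpha, con$lam)
}

#' Evaluate a tagged constraint at given positions
#'
#' @param con a [constraint()]
#' @param x n x 3 position matrix
#' @return see [constraint-evaluation]; `grad` rows follow `con$nodes` (all
#'   nodes, for `surface_volume`)
#' @export
eval_constraint <- function(con, x) {
  nd <- con$nodes
  switch(con$kind,
    distance = eval_distance(x[nd[1], ], x[nd[2], ], con$rest),
    contact_sphere_sphere = eval_distance(x[nd[1], ], x[nd[2], ], con$rest,
                                          unilateral = TRUE),
    tet_volume = eval_tet_volume(x[nd[1], ], x[nd[2], ], x[nd[3], ], x[nd[4], ],
                                 con$rest),
    surface_volume = eval_surface_volume(x, con$triangles, con$rest),
    overstretch = eval_overstretch(x[nd[1], ], x[nd[2], ], con$rest, con$k_ratio),
    contact_vertex_triangle = eval_vertex_triangle(x[nd[1], ], x[nd[2], ],
                                                   x[nd[3], ], x[nd[4], ], con$rest))
}

#' Compliant (XPBD-style) projection of one constraint
#'
#' Applies the multiplier update
#' `dlam = -(C + at*lam) / (sum_k w_k |grad_k C|^2 + at)` with
#' `at = alpha/dt^2`, accumulates `lam`, and moves each involved node by
#' `w_k * grad_k C * dlam`. Fixed nodes (`w = 0`) never move. Unilateral
#' constraints are projected only while violated. With `alpha = 0` this
#' reduces to the classical position-based projection.
#'
#' @param con a [constraint()] (its `lam` carries across repeated calls within
#'   a timestep; reset it to 0 at the start of each step)
#' @param system a [particle_system()]
#' @param dt timestep (s) used to scale the compliance
#' @return list with the updated `system` and `con`
#' @export
project_constraint <- function(con, system, dt) {
  ev <- eval_constraint(con, system$x)
  if (is.null(ev) || !ev$active) return(list(system = system, con = con))
  idx <- if (con$kind == "surface_volume") seq_len(nrow(system$x)) else con$nodes
  w <- system$w[idx]
  at <- con$alpha / dt^2
  denom <- sum(w * rowSums(ev$grad^2)) + at
  if (denom <= 0) {
    warning("constraint projection skipped: all nodes fixed and compliance 0")
    return(list(system = system, con = con))
  }
  dlam <- -(ev$C + at * con$lam) / denom
  con$lam <- con$lam + dlam
  system$x[idx, ] <- system$x[idx, ] + (w * dlam) * ev$grad
  list(system = system, con = con)
}
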