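# Independent oracles used across the suite.

# central finite-difference gradient of a scalar constraint function over a
# k x 3 position block
fd_gradient <- function(Cfun, pts, h = 1e-6) {
  g <- matrix(0, nrow(pts), 3)
  for (i in seq_len(nrow(pts))) for (c in 1:3) {
    hp <- pts; hp[i, c] <- hp[i, c] + h
    hm <- pts; hm[i, c] <- hm[i, c] - h
    g[i, c] <- (Cfun(hp) - Cfun(hm)) / (2 * h)
  }
  g
}

# reference classical position-based dynamics step, written directly from the
# textbook scheme: Verlet predictor then Gauss-Seidel projection of distance
# constraints with Delta x = -C * w_k grad_k / sum(w |grad|^2), no
# multipliers, no compliance. Deliberately independent of the package's
# constraint code.
reference_pbd_step <- function(x, x_prev, w, dist, dt, iterations, forces = NULL) {
  n <- nrow(x)
  if (is.null(forces)) forces <- matrix(0, n, 3)
  xs <- x + (x - x_prev) + (w * forces) * dt^2
  xs[w == 0, ] <- x[w == 0, ]
  for (it in seq_len(iterations)) {
    for (k in seq_len(nrow(dist))) {
      i <- dist[k, 1]; j <- dist[k, 2]; rest <- dist[k, 3]
      d <- xs[i, ] - xs[j, ]
      len <- sqrt(sum(d^2))
      if (len < 1e-12) next
      C <- len - rest
      nh <- d / len
      denom <- w[i] + w[j]
      if (denom <= 0) next
      lam <- -C / denom
      xs[i, ] <- xs[i, ] + w[i] * lam * nh
      xs[j, ] <- xs[j, ] - w[j] * lam * nh
    }
  }
  list(x = xs, x_prev = x)
}

# build a minimal hand-rolled model around explicit arrays (bypassing mesh
# construction) so solver behaviour can be probed on tiny systems
bare_model <- function(x, springs = NULL, material = material_params(),
                       dist = NULL, mass = rep(1, nrow(x))) {
  x <- as.matrix(x)
  model <- structure(list(
    mesh = NULL, preset = "entity", mode = "integrated", material = material,
    x = x, x_rest = x, mass = mass, w = ifelse(mass > 0, 1 / mass, 0),
    springs = springs %||% data.frame(i = integer(0), j = integer(0),
                                      l0 = numeric(0), dl_c = numeric(0)),
    constraints = list(
      dist = dist %||% matrix(numeric(0), 0, 4),
      over = matrix(numeric(0), 0, 4),
      tet = matrix(numeric(0), 0, 6), surf = NULL),
    volume_spec = list(kind = "none"),
    collision = list(sphere_nodes = integer(0), sphere_r = numeric(0),
                     tri = matrix(integer(0), 0, 3), cell_size = NULL,
                     table_size = NULL, margin = 0, tri_margin = 0),
    n_mesh_nodes = nrow(x)), class = "softsim_model")
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random non-degenerate tetrahedron
random_tet <- function() {
  repeat {
    p <- matrix(stats::runif(12, -1, 1), 4, 3)
    v <- abs(det(rbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ])))
    if (v > 0.05) return(p)
  }
}
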