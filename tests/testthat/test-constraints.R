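test_that("distance constraint worked values", {
  ev <- eval_distance(c(0, 0, 0), c(3, 0, 0), rest = 2)
  expect_equal(ev$C, 1)
  expect_equal(ev$grad["q", ], c(1, 0, 0))
  expect_equal(ev$grad["p", ], c(-1, 0, 0))
  expect_equal(eval_distance(c(0, 0, 0), c(2, 0, 0), rest = 2)$C, 0)
  expect_equal(eval_distance(c(0, 0, 0), c(1.5, 0, 0), rest = 2)$C, -0.5)
  expect_warning(expect_null(eval_distance(c(0, 0, 0), c(0, 0, 0), 1)),
                 "degenerate")
})

test_that("tet volume constraint worked values and zero gradient sum", {
  unit <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  ev <- eval_tet_volume(unit[1, ], unit[2, ], unit[3, ], unit[4, ], V0 = 1 / 6)
  expect_equal(ev$C, 0)
  scaled <- unit * 2
  ev2 <- eval_tet_volume(scaled[1, ], scaled[2, ], scaled[3, ], scaled[4, ],
                         V0 = 1 / 6)
  expect_equal(ev2$C, 8 / 6 - 1 / 6)
  set.seed(7)
  for (rep in 1:5) {
    p <- random_tet()
    ev <- eval_tet_volume(p[1, ], p[2, ], p[3, ], p[4, ], V0 = 0.1)
    expect_lt(max(abs(colSums(ev$grad))), 1e-12)
  }
})

test_that("surface volume constraint: cube, scaling and translation invariance", {
  # unit cube as 12 outward triangles
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  cube_tris <- rbind(
    c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
    c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
    c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  ev <- eval_surface_volume(v, cube_tris, V0 = 1)
  expect_equal(ev$C, 0, tolerance = 1e-12)
  ico <- generate_icosphere(2, 1)
  evi <- eval_surface_volume(ico$vertices, ico$triangles,
                             V0 = mesh_volume(ico))
  expect_equal(evi$C, 0, tolerance = 1e-9)
  shifted <- sweep(ico$vertices, 2, c(5, 5, 5), "+")
  evs <- eval_surface_volume(shifted, ico$triangles, V0 = mesh_volume(ico))
  expect_equal(evs$C, 0, tolerance = 1e-9 * mesh_volume(ico))
  expect_lt(max(abs(colSums(evi$grad))), 1e-12)
})

test_that("overstretch constraint activates outside the band", {
  expect_false(eval_overstretch(c(0, 0, 0), c(1, 0, 0), l0 = 1,
                                k_ratio = 0.5)$active)
  ev <- eval_overstretch(c(0, 0, 0), c(2, 0, 0), l0 = 1, k_ratio = 0.5)
  expect_equal(ev$C, 0.25 - 1)
  expect_true(ev$active)
  # compression side is limited too
  evc <- eval_overstretch(c(0, 0, 0), c(0.2, 0, 0), l0 = 1, k_ratio = 0.5)
  expect_true(evc$active)
  expect_lt(evc$C, 0)
})

test_that("vertex-triangle constraint worked values", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  ev <- eval_vertex_triangle(c(0.2, 0.2, 0.5), tri[1, ], tri[2, ], tri[3, ], r = 1)
  expect_equal(ev$C, -0.5)
  expect_equal(ev$grad["q", ], c(0, 0, 1))
  expect_true(ev$active)
  ev0 <- eval_vertex_triangle(c(0.2, 0.2, 1), tri[1, ], tri[2, ], tri[3, ], r = 1)
  expect_equal(ev0$C, 0)
  ev2 <- eval_vertex_triangle(c(0.2, 0.2, 2), tri[1, ], tri[2, ], tri[3, ], r = 1)
  expect_equal(ev2$C, 1)
  expect_false(ev2$active) # no penetration, unilateral constraint inactive
})

test_that("analytic gradients match central differences for all types", {
  set.seed(11)
  tol <- 1e-5
  relcheck <- function(analytic, numeric) {
    expect_lt(max(abs(analytic - numeric)) / max(max(abs(numeric)), 1e-8), tol)
  }
  for (rep in 1:25) {
    # distance
    pq <- matrix(runif(6, -2, 2), 2, 3)
    if (sqrt(sum((pq[1, ] - pq[2, ])^2)) > 1e-3) {
      ev <- eval_distance(pq[1, ], pq[2, ], rest = runif(1, 0.1, 2))
      relcheck(ev$grad, fd_gradient(function(p)
        sqrt(sum((p[2, ] - p[1, ])^2)), pq))
    }
    # tet volume
    p <- random_tet()
    ev <- eval_tet_volume(p[1, ], p[2, ], p[3, ], p[4, ], V0 = 0)
    relcheck(ev$grad, fd_gradient(function(q)
      sum(softsim:::vcross3(q[2, ] - q[1, ], q[3, ] - q[1, ]) *
            (q[4, ] - q[1, ])) / 6, p))
    # overstretch (active branch)
    a <- matrix(runif(6, -2, 2), 2, 3)
    l0 <- 0.2
    if (sqrt(sum((a[1, ] - a[2, ])^2)) > 0.5) {
      ev <- eval_overstretch(a[1, ], a[2, ], l0 = l0, k_ratio = 0.5)
      relcheck(ev$grad, fd_gradient(function(q)
        (0.5 * l0)^2 - (sqrt(sum((q[1, ] - q[2, ])^2)) - l0)^2, a))
    }
    # vertex-triangle with varying normal
    vt <- matrix(runif(12, -1, 1), 4, 3)
    m <- softsim:::vcross3(vt[3, ] - vt[2, ], vt[4, ] - vt[2, ])
    if (sqrt(sum(m^2)) > 0.1) {
      ev <- eval_vertex_triangle(vt[1, ], vt[2, ], vt[3, ], vt[4, ], r = 0.3,
                                 unilateral = FALSE)
      relcheck(ev$grad, fd_gradient(function(q) {
        mm <- softsim:::vcross3(q[3, ] - q[2, ], q[4, ] - q[2, ])
        sum((q[1, ] - q[2, ]) * mm) / sqrt(sum(mm^2)) - 0.3
      }, vt))
    }
  }
  # surface volume on a perturbed icosahedron
  ico <- generate_icosphere(1, 0)
  for (rep in 1:4) {
    verts <- ico$vertices + matrix(rnorm(36, 0, 0.05), 12, 3)
    ev <- eval_surface_volume(verts, ico$triangles, V0 = 0)
    relcheck(ev$grad, fd_gradient(function(q)
      softsim:::enclosed_volume(q, ico$triangles), verts))
  }
})

test_that("compliant projection reduces to classical PBD at alpha = 0", {
  x <- rbind(c(0, 0, 0), c(2, 0, 0))
  sys <- particle_system(x)
  con <- constraint("distance", nodes = c(1L, 2L), rest = 1, alpha = 0)
  out <- project_constraint(con, sys, dt = 0.01)
  expect_equal(out$con$lam, -1 / 2)
  expect_equal(out$system$x[1, ], c(0.5, 0, 0))
  expect_equal(out$system$x[2, ], c(1.5, 0, 0))
  ev <- eval_constraint(out$con, out$system$x)
  expect_equal(ev$C, 0, tolerance = 1e-12)
})

test_that("projection respects inverse-mass weighting and fixed nodes", {
  x <- rbind(c(0, 0, 0), c(2, 0, 0))
  sys <- particle_system(x, w = c(0, 1))
  con <- constraint("distance", nodes = c(1L, 2L), rest = 1)
  out <- project_constraint(con, sys, dt = 0.01)
  expect_equal(out$system$x[1, ], c(0, 0, 0))       # fixed node never moves
  expect_equal(out$system$x[2, ], c(1, 0, 0))       # free node moves the full amount
})

test_that("infinite compliance leaves positions unchanged", {
  x <- rbind(c(0, 0, 0), c(2, 0, 0))
  sys <- particle_system(x)
  con <- constraint("distance", nodes = c(1L, 2L), rest = 1, alpha = 1e12)
  out <- project_constraint(con, sys, dt = 0.01)
  expect_equal(out$system$x, x, tolerance = 1e-9)
})

test_that("overstretch projection clamps to the band edge", {
  x <- rbind(c(0, 0, 0), c(2, 0, 0))
  sys <- particle_system(x)
  con <- constraint("overstretch", nodes = c(1L, 2L), rest = 1, k_ratio = 0.5)
  for (it in 1:20) {
    out <- project_constraint(con, sys, dt = 0.01)
    sys <- out$system; con <- out$con
  }
  expect_equal(sqrt(sum((sys$x[1, ] - sys$x[2, ])^2)), 1.5, tolerance = 1e-6)
})

test_that("repeated rigid projection drives |C| monotonically below 1e-6", {
  set.seed(3)
  p <- random_tet()
  sys <- particle_system(p)
  con <- constraint("tet_volume", nodes = 1:4,
                    rest = abs(det(rbind(p[2, ] - p[1, ], p[3, ] - p[1, ],
                                         p[4, ] - p[1, ])) / 6) * 2)
  prev <- Inf
  for (it in 1:30) {
    out <- project_constraint(con, sys, dt = 0.01)
    sys <- out$system; con <- out$con
    Cnow <- abs(eval_constraint(con, sys$x)$C)
    expect_lte(Cnow, prev + 1e-12)
    prev <- Cnow
  }
  expect_lt(prev, 1e-6)
})

test_that("XPBD decouples converged stretch from iteration count", {
  run_iters <- function(iters) {
    sys <- particle_system(rbind(c(0, 0, 0), c(2, 0, 0)))
    con <- constraint("distance", nodes = c(1L, 2L), rest = 1, alpha = 0.5)
    dt <- 0.1
    for (it in seq_len(iters)) {
      out <- project_constraint(con, sys, dt)
      sys <- out$system; con <- out$con
    }
    ev <- eval_constraint(con, sys$x)
    c(C = ev$C, lam = con$lam)
  }
  r5 <- run_iters(5)
  r50 <- run_iters(50)
  at <- 0.5 / 0.1^2
  expect_equal(r5[["C"]], -at * r5[["lam"]], tolerance = 1e-8)
  expect_equal(r50[["C"]], -at * r50[["lam"]], tolerance = 1e-10)
  expect_equal(r5[["C"]], r50[["C"]], tolerance = 1e-4)
})

test_that("equal-mass bilateral projection conserves momentum", {
  set.seed(5)
  for (rep in 1:5) {
    p <- random_tet()
    sys <- particle_system(p)
    con <- constraint("tet_volume", nodes = 1:4, rest = 0.2)
    out <- project_constraint(con, sys, dt = 0.01)
    dx <- out$system$x - p
    expect_lt(max(abs(colSums(dx))), 1e-9)
  }
})

test_that("constraint dump lines are stable plain text", {
  con <- constraint("distance", nodes = c(2L, 5L), rest = 1.5, alpha = 0.25)
  expect_match(constraint_dump_line(con), "^distance \\| 2,5 \\| 1.5 \\| 0.25 \\| 0$")
})
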