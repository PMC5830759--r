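test_that("AABBs for spheres and triangles, with margins", {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  sph <- collision_primitive("sphere", 1L, radius = 1)
  bb <- compute_aabb(sph, pos)
  expect_equal(bb$min, c(-1, -1, -1))
  expect_equal(bb$max, c(1, 1, 1))
  tri <- collision_primitive("triangle", 1:3)
  bt <- compute_aabb(tri, pos)
  expect_equal(bt$min, c(0, 0, 0))
  expect_equal(bt$max, c(1, 1, 0))
  bm <- compute_aabb(tri, pos, margin = 0.1)
  expect_equal(bm$min, c(-0.1, -0.1, -0.1))
  expect_equal(bm$max, c(1.1, 1.1, 0.1))
})

test_that("spatial hash matches the pinned three-prime form", {
  expect_equal(hash_cell(0, 0, 0, 17), 0)
  expect_equal(hash_cell(1, 0, 0, 10), 73856093 %% 10) # = 3
  expect_equal(hash_cell(0, 1, 0, 1000), 19349663 %% 1000)
  # identical cells always collide in the same bucket
  for (ts in c(7, 64, 1001))
    expect_equal(hash_cell(5, -3, 2, ts), hash_cell(5, -3, 2, ts))
  # non-negative range for negative coordinates
  expect_gte(hash_cell(-4, -7, -1, 13), 0)
})

test_that("broad phase finds overlapping spheres and skips distant ones", {
  pos <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(200, 0, 0))
  prims <- list(collision_primitive("sphere", 1L, radius = 1),
                collision_primitive("sphere", 2L, radius = 1),
                collision_primitive("sphere", 3L, radius = 1))
  pairs <- broad_phase(prims, pos)
  expect_equal(pairs, rbind(c(1L, 2L)), ignore_attr = TRUE)
})

test_that("broad phase equals the brute-force AABB oracle on random scenes", {
  set.seed(101)
  for (rep in 1:6) {
    n <- sample(20:100, 1)
    pos <- matrix(runif(3 * n, 0, 30), n, 3)
    prims <- lapply(seq_len(n), function(i)
      collision_primitive("sphere", i, radius = runif(1, 0.5, 3)))
    pairs <- broad_phase(prims, pos,
                         cell_size = runif(1, 1, 6),
                         table_size = sample(c(16, 101, 256), 1))
    boxes <- lapply(prims, compute_aabb, positions = pos)
    brute <- list()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (all(boxes[[i]]$min <= boxes[[j]]$max) &&
          all(boxes[[j]]$min <= boxes[[i]]$max))
        brute[[length(brute) + 1]] <- c(i, j)
    }
    brute <- if (length(brute)) do.call(rbind, brute) else matrix(integer(0), 0, 2)
    key <- function(m) sort(paste(m[, 1], m[, 2]))
    expect_identical(key(pairs), key(brute))
  }
})

test_that("sphere-sphere narrow phase uses strict penetration", {
  pos <- rbind(c(0, 0, 0), c(3, 0, 0))
  expect_null(narrow_sphere_sphere(1L, 2L, pos, 1, 1))   # 3 > 2
  pos2 <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  con <- narrow_sphere_sphere(1L, 2L, pos2, 1, 1)
  expect_s3_class(con, "softsim_constraint")
  expect_equal(eval_constraint(con, pos2)$C, -0.5)
  pos3 <- rbind(c(0, 0, 0), c(2, 0, 0))                  # exactly touching
  expect_null(narrow_sphere_sphere(1L, 2L, pos3, 1, 1))
})

test_that("sphere-triangle narrow phase requires face-interior projection", {
  pos <- rbind(c(0.2, 0.2, 0.5), c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  con <- narrow_sphere_triangle(1L, 2:4, pos, r = 1)
  expect_s3_class(con, "softsim_constraint")
  expect_equal(eval_constraint(con, pos)$C, -0.5)
  pos_high <- pos; pos_high[1, 3] <- 2
  expect_null(narrow_sphere_triangle(1L, 2:4, pos_high, r = 1))
  pos_out <- pos; pos_out[1, 1:2] <- c(2, 2) # projects outside the face
  expect_null(narrow_sphere_triangle(1L, 2:4, pos_out, r = 1))
})

test_that("separated primitives generate no position corrections in the solver", {
  x <- rbind(c(0, 0, 5), c(0, 0, 0), c(50, 0, 5), c(-50, 0, 5), c(0, 50, 5))
  model <- bare_model(x, material = material_params(b0 = 0, b1 = 0))
  model$collision$sphere_nodes <- 1:2
  model$collision$sphere_r <- c(1, 1)
  res <- run_simulation(model, solver_config(dt = 0.01, iterations = 5), 0.1)
  expect_equal(res$state$x, x, tolerance = 1e-12) # nothing moved
})

test_that("resting spheres do not interpenetrate after projection", {
  # two spheres dropped in line: one rests on a fixed one
  x <- rbind(c(0, 0, 0), c(0, 0, 2.5))
  model <- bare_model(x, material = material_params(b0 = 0.5, b1 = 0),
                      mass = c(0, 1))
  model$collision$sphere_nodes <- 1:2
  model$collision$sphere_r <- c(1, 1)
  res <- run_simulation(model, solver_config(dt = 0.005, iterations = 10,
                                             gravity = c(0, 0, -9810)), 0.5)
  gap <- res$state$x[2, 3] - res$state$x[1, 3]
  expect_gte(gap, 2 - 1e-3) # penetration below 1e-3 * radius
  expect_lt(gap, 2 + 1e-2)  # actually resting on the support
})
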