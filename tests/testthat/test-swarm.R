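test_that("velocity clamp limits every component symmetrically", {
  expect_equal(clamp_velocity(7, 5), 5)
  expect_equal(clamp_velocity(-7, 5), -5)
  expect_equal(clamp_velocity(c(3, -2), c(5, 5)), c(3, -2))
  V <- matrix(c(10, -10, 1, -1), 2, 2)
  expect_equal(clamp_velocity(V, c(2, 0.5)),
               matrix(c(2, -2, 0.5, -0.5), 2, 2))
})

test_that("the PSO velocity rule reproduces a hand-computed update", {
  # 1-D: w = 1, X = 0, V = 0, P = G = 1, c1 = c2 = 2.05, r = R = 0.5
  X <- matrix(0, 1, 1); V <- matrix(0, 1, 1); P <- matrix(1, 1, 1)
  v <- swarmdock:::pso_velocity(X, V, P, G = 1, w = 1, c1 = 2.05, c2 = 2.05,
                                r = matrix(0.5, 1, 1), R = matrix(0.5, 1, 1))
  expect_equal(v[1, 1], 2.05 * 0.5 * 1 + 2.05 * 0.5 * 1)
})

test_that("a particle at its own attractors does not move", {
  sp <- box_space(3)
  set.seed(1)
  st <- swarm_init(sp, 5, sphere)
  # collapse everything to a single point with zero velocity
  pt <- c(1, -2, 0.5)
  st$X <- matrix(pt, 5, 3, byrow = TRUE)
  st$P <- st$X
  st$G <- pt
  st$C <- pt
  st$fX <- st$fP <- rep(sphere(pt), 5)
  st$fG <- sphere(pt)
  st$V <- matrix(0, 5, 3)
  st2 <- pso_step(st, sphere, w = 1, c1 = 2.05, c2 = 2.05)
  expect_equal(st2$X, st$X)
  st3 <- rdpso_step(st, sphere, alpha = 0.5, beta = 1.45)
  expect_equal(st3$X, st$X)
})

test_that("the RDPSO velocity rule reproduces a hand-computed update", {
  # 1-D: X = 0, C = 1, p = 0.5, alpha = 0.5, phi = 1, beta = 1.45
  v <- swarmdock:::rdpso_velocity(X = matrix(0, 1, 1), C = 1,
                                  p = matrix(0.5, 1, 1), alpha = 0.5,
                                  beta = 1.45, phi = matrix(1, 1, 1))
  expect_equal(v[1, 1], 0.5 * 1 * 1 + 1.45 * 0.5)
})

test_that("local focus is the componentwise convex combination", {
  P <- c(0, 2, -1); G <- c(2, 2, 3)
  expect_equal(local_focus(P, G, gamma = 1), P)
  expect_equal(local_focus(P, G, gamma = 0), G)
  expect_equal(local_focus(0, 2, gamma = 0.5), 1)
  set.seed(5)
  p <- local_focus(P, G)
  expect_true(all(p >= pmin(P, G) & p <= pmax(P, G)))
})

test_that("mbest equals the mean of the personal bests after a step", {
  sp <- box_space(4)
  set.seed(2)
  st <- swarm_init(sp, 12, sphere)
  for (k in 1:5) st <- rdpso_step(st, sphere, alpha = 0.7, beta = 1.45)
  # brute-force recomputation of the mbest definition
  cm <- numeric(4)
  for (i in 1:12) cm <- cm + st$P[i, ]
  expect_equal(st$C, cm / 12)
  expect_equal(st$fG, min(st$fP))
})

test_that("swarm steps respect bounds, clamping and monotone gbest", {
  sp <- make_docking_space(c(0, 0, 0), 8, 3)
  set.seed(4)
  st <- swarm_init(sp, 15, sphere)
  vm <- vmax(sp)
  fg <- st$fG
  for (k in 1:30) {
    st <- if (k %% 2) rdpso_step(st, sphere, 0.8, 1.45)
          else pso_step(st, sphere, 0.7, 2.05, 2.05)
    expect_true(all(abs(st$V) <= matrix(vm, 15, sp$n, byrow = TRUE) + 1e-12))
    expect_true(all(st$X >= matrix(sp$lower, 15, sp$n, byrow = TRUE) - 1e-12))
    expect_true(all(st$X <= matrix(sp$upper, 15, sp$n, byrow = TRUE) + 1e-12))
    expect_lte(st$fG, fg)
    fg <- st$fG
  }
  expect_equal(st$evals, 15L * 31L)
})

test_that("identical seeds give bitwise-identical trajectories", {
  sp <- box_space(5)
  runner <- function() {
    set.seed(99)
    st <- swarm_init(sp, 10, sphere)
    for (k in 1:20) st <- rdpso_step(st, sphere, 0.8, 1.45)
    st
  }
  expect_identical(runner(), runner())
})

test_that("linear schedule hits its endpoints and midpoint", {
  expect_equal(linear_schedule(0.9, 0.3, 1, 100), 0.9)
  expect_equal(linear_schedule(0.9, 0.3, 100, 100), 0.3)
  expect_equal(linear_schedule(0.9, 0.3, 50.5, 100), 0.6)
  expect_equal(linear_schedule(0.9, 0.4, 1, 1), 0.9)
  expect_error(linear_schedule(0.9, 0.3, 0, 100), "n must")
  expect_error(linear_schedule(0.9, 0.3, 101, 100), "n must")
})

test_that("canonical RDPSO solves the 5-D sphere reliably", {
  sp <- box_space(5)
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    st <- swarm_init(sp, 20, sphere)
    n_max <- 500
    for (n in 1:n_max) {
      alpha <- linear_schedule(0.9, 0.3, n, n_max)
      st <- rdpso_step(st, sphere, alpha, 1.45)
      if (st$fG < 1e-3) break
    }
    if (st$fG < 1e-3) hits <- hits + 1
  }
  expect_gte(hits, 18)
})
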