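test_that("diversity matches hand values and a brute-force loop", {
  # all particles identical: zero spread
  X <- matrix(1, 5, 3)
  expect_equal(diversity(X, A = 2), 0)

  # two particles at the ends of a unit interval
  X2 <- matrix(c(0, 1), 2, 1)
  expect_equal(diversity(X2, A = 1), 0.5)

  set.seed(21)
  for (k in 1:20) {
    m <- sample(2:30, 1); n <- sample(1:10, 1)
    X <- matrix(rnorm(m * n), m, n)
    A <- runif(1, 0.5, 10)
    xbar <- colMeans(X)
    acc <- 0
    for (i in 1:m) acc <- acc + sqrt(sum((X[i, ] - xbar)^2))
    expect_equal(diversity(X, A), acc / (m * A))
  }
  expect_error(diversity(matrix(numeric(0), 0, 2), 1), "at least one")
})

test_that("the lower-bound schedule decays between its endpoints", {
  p <- pdc_params()
  expect_equal(lower_bound(100, 100, D1 = 1, p), 0.002)
  expect_equal(lower_bound(100, 100, D1 = 3, p), 0.006)
  expect_equal(lower_bound(50, 100, D1 = 1, p), 0.5 * (0.75 - 0.002) + 0.002)
  dl <- vapply(1:100, lower_bound, 0, n_max = 100, D1 = 1, params = p)
  expect_true(all(diff(dl) < 0))
  expect_error(lower_bound(0, 100, 1, p), "n must")
  expect_error(lower_bound(10, 100, -1, p), "D1")
})

test_that("divergence coefficients match the printed defaults and decay in Dr", {
  p <- pdc_params()
  c1 <- divergence_coeffs(1, 1, p)
  expect_equal(c1$alpha, 9)
  expect_equal(c1$beta, 3)
  c2 <- divergence_coeffs(0.5, 1, p)
  expect_equal(c2$alpha, 18)
  expect_equal(c2$beta, 3 / 0.5^0.7)
  expect_equal(divergence_coeffs(0.1, 1, p)$alpha, 90)
  # strictly decreasing in Dr
  drs <- seq(0.05, 2, by = 0.05)
  al <- vapply(drs, function(d) divergence_coeffs(d, 1, p)$alpha, 0)
  be <- vapply(drs, function(d) divergence_coeffs(d, 1, p)$beta, 0)
  expect_true(all(diff(al) < 0))
  expect_true(all(diff(be) < 0))
  # collapsed swarm is capped, not infinite
  c0 <- divergence_coeffs(0, 1, p)
  expect_true(is.finite(c0$alpha) && c0$alpha == 9 / 1e-6)
  expect_error(divergence_coeffs(0.5, 0, p), "D1")
})

test_that("parameter validation enforces the documented constraints", {
  expect_error(pdc_params(accr = 0.001), "accr")
  expect_error(pdc_params(dl1_factor = 0.96), "du_factor")
  expect_error(pdc_params(alpha0 = -1), "positive")
})

test_that("the phase machine transitions exactly at its bounds", {
  p <- pdc_params()
  n_max <- 1000L
  st <- pdc_init(D1 = 1)
  expect_equal(st$phase, "CONVERGE")

  # diversity just above the bound: stay converging, clock ticks
  dl <- lower_bound(10, n_max, 1, p)
  r <- pdc_update(st, dl + 1e-9, 10, n_max, p)
  expect_equal(r$phase, "CONVERGE")
  expect_equal(r$alpha_mode, "scheduled")
  expect_false(r$accelerate)

  # diversity just below the bound: flip to divergence with inflated
  # coefficients
  dl11 <- lower_bound(11, n_max, 1, p)
  r2 <- pdc_update(r$state, dl11 - 1e-9, 11, n_max, p)
  expect_equal(r2$phase, "DIVERGE")
  expect_equal(r2$alpha_mode, "divergence")
  expect_equal(r2$coeffs$alpha, p$alpha0 / (dl11 - 1e-9)^p$c1)

  # below the exit threshold: keep diverging
  r3 <- pdc_update(r2$state, 0.94, 12, n_max, p)
  expect_equal(r3$phase, "DIVERGE")

  # at/above 0.95 * D1: back to convergence with a reset clock
  r4 <- pdc_update(r3$state, 0.96, 13, n_max, p)
  expect_equal(r4$phase, "CONVERGE")
  expect_equal(r4$state$conv_clock, 0L)
})

test_that("acceleration fires once the convergence clock exceeds accr * n_max", {
  p <- pdc_params()
  n_max <- 1000L  # accr * n_max = 3 iterations
  st <- pdc_init(D1 = 1)
  flags <- logical(6)
  for (k in 1:6) {
    r <- pdc_update(st, 0.8, k, n_max, p)  # well above the bound
    st <- r$state
    flags[k] <- r$accelerate
  }
  # clock > 3 from the 4th converging iteration on, and stays raised
  expect_identical(flags, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
})

test_that("phases alternate with no self-transitions on scripted diversity", {
  p <- pdc_params()
  n_max <- 100L
  st <- pdc_init(D1 = 1)
  set.seed(31)
  dn_seq <- runif(n_max, 0, 1)
  phases <- character(n_max)
  for (k in seq_len(n_max)) {
    r <- pdc_update(st, dn_seq[k], k, n_max, p)
    st <- r$state
    phases[k] <- r$phase
  }
  runs <- rle(phases)$values
  expect_true(all(runs[-1] != runs[-length(runs)]))
})

test_that("accelerating the swarm contracts the personal bests", {
  sp <- box_space(6)
  set.seed(8)
  st <- swarm_init(sp, 20, sphere)
  st <- rdpso_step(st, sphere, 0.8, 1.45)

  # a particle whose pbest already equals gbest must not move
  ib <- which.min(st$fP)
  old_P <- st$P
  old_G <- st$G
  st2 <- accelerate_swarm(st, sphere)
  expect_equal(st2$P[ib, ], old_P[ib, ])

  # every pbest lies componentwise between its old value and gbest
  for (i in 1:20) {
    expect_true(all(st2$P[i, ] >= pmin(old_P[i, ], old_G) - 1e-12))
    expect_true(all(st2$P[i, ] <= pmax(old_P[i, ], old_G) + 1e-12))
  }
  expect_equal(st2$evals, st$evals + 20L)
  expect_lte(st2$fG, st$fG)

  # pbest-set diversity never increases under the contraction
  set.seed(17)
  for (k in 1:10) {
    st <- swarm_init(sp, 15, sphere)
    d_before <- diversity(st$P, sp$A)
    st3 <- accelerate_swarm(st, sphere)
    expect_lte(diversity(st3$P, sp$A), d_before + 1e-12)
  }
})

test_that("divergence coefficients re-inflate a collapsed swarm", {
  # a 10-D swarm collapsed to 1% of its initial diversity must recover
  # to at least 95% of it within 50 diverging iterations
  sp <- box_space(10)
  p <- pdc_params()
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    X1 <- random_positions(sp, 30)
    D1 <- diversity(X1, sp$A)
    st <- swarm_init(sp, 30, sphere)
    # collapse around one point at ~0.01 * D1 spread
    ctr <- st$X[1, ]
    st$X <- matrix(ctr, 30, 10, byrow = TRUE) +
      matrix(rnorm(300, sd = 0.01 * D1 * sp$A / sqrt(10)), 30, 10)
    st$X <- swarmdock:::repair_rows(sp, st$X)
    st$P <- st$X
    st$fX <- st$fP <- apply(st$X, 1, sphere)
    ib <- which.min(st$fP)
    st$G <- st$P[ib, ]; st$fG <- st$fP[ib]
    st$C <- colMeans(st$P)
    ok <- FALSE
    for (k in 1:50) {
      cf <- divergence_coeffs(diversity(st$X, sp$A), D1, p)
      st <- rdpso_step(st, sphere,
                       min(cf$alpha, 9e5), min(cf$beta, 3e5))
      if (diversity(st$X, sp$A) >= 0.95 * D1) { ok <- TRUE; break }
    }
    if (ok) hits <- hits + 1
  }
  expect_gte(hits, 18)
})
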