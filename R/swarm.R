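#' Swarm state and per-iteration update rules
#'
#' A swarm holds `M` particles in an `M x N` position matrix `X` with
#' velocities `V`, personal best positions `P` (fitness `fP`), the global
#' best `G` (fitness `fG`) and the mean best position `C` (the
#' componentwise mean of all personal bests). All algorithms here
#' minimize.
#'
#' @name swarm
NULL

#' Initialize a swarm
#'
#' Positions are drawn uniformly within the bounds, velocities start at
#' zero, and every particle is evaluated once, so `evals` starts at `M`.
#'
#' @param space a `search_space`.
#' @param m swarm size.
#' @param objective function mapping a position vector to a scalar.
#' @return an object of class `swarm_state`.
#' @export
swarm_init <- function(space, m, objective) {
  X <- random_positions(space, m)
  f <- apply(X, 1L, objective)
  ib <- which.min(f)
  structure(list(
    space = space,
    X = X, V = matrix(0, nrow = m, ncol = space$n),
    P = X, fX = f, fP = f,
    G = X[ib, ], fG = f[ib],
    C = colMeans(X),
    n = 0L, evals = length(f)
  ), class = "swarm_state")
}

#' @export
print.swarm_state <- function(x, ...) {
  cat(sprintf("swarm_state: M = %d, N = %d, iteration %d, gbest %.6g, evals %d\n",
              nrow(x$X), ncol(x$X), x$n, x$fG, x$evals))
  invisible(x)
}

#' Clamp velocities componentwise
#'
#' Each component is limited to `[-vmax[j], vmax[j]]`.
#'
#' @param v numeric vector or matrix (columns are dimensions).
#' @param vmax per-dimension non-negative limits.
#' @return clamped object of the same shape.
#' @export
clamp_velocity <- function(v, vmax) {
  if (is.matrix(v)) {
    if (ncol(v) != length(vmax)) stop("vmax length must match columns of v")
    lim <- matrix(vmax, nrow = nrow(v), ncol = ncol(v), byrow = TRUE)
  } else {
    if (length(v) != length(vmax)) stop("v and vmax must have equal length")
    lim <- vmax
  }
  pmin(pmax(v, -lim), lim)
}

## pbest/gbest bookkeeping shared by all update rules; ties keep the
## incumbent so trajectories are deterministic.
update_bests <- function(state) {
  imp <- state$fX < state$fP
  if (any(imp)) {
    state$P[imp, ] <- state$X[imp, , drop = FALSE]
    state$fP[imp] <- state$fX[imp]
  }
  ib <- which.min(state$fP)
  if (state$fP[ib] < state$fG) {
    state$G <- state$P[ib, ]
    state$fG <- state$fP[ib]
  }
  state$C <- colMeans(state$P)
  state
}

## pure velocity rules, exposed for direct verification with fixed draws
pso_velocity <- function(X, V, P, G, w, c1, c2, r, R) {
  Gm <- matrix(G, nrow = nrow(X), ncol = ncol(X), byrow = TRUE)
  w * V + c1 * r * (P - X) + c2 * R * (Gm - X)
}

rdpso_velocity <- function(X, C, p, alpha, beta, phi) {
  Cm <- matrix(C, nrow = nrow(X), ncol = ncol(X), byrow = TRUE)
  alpha * abs(Cm - X) * phi + beta * (p - X)
}

#' Canonical PSO iteration (inertia-weight variant)
#'
#' Velocity update `V <- w*V + c1*r*(P - X) + c2*R*(G - X)` with fresh
#' uniform draws `r, R ~ U(0,1)` per particle and dimension, followed by
#' the velocity clamp, the position move, repair, re-evaluation and
#' pbest/gbest/mbest bookkeeping. Consumes `M` objective evaluations.
#'
#' @param state a `swarm_state`.
#' @param objective the objective function.
#' @param w inertia weight.
#' @param c1,c2 positive acceleration coefficients.
#' @return the updated `swarm_state`.
#' @export
pso_step <- function(state, objective, w, c1, c2) {
  stopifnot(inherits(state, "swarm_state"), c1 > 0, c2 > 0)
  m <- nrow(state$X); n <- ncol(state$X)
  r <- matrix(runif(m * n), nrow = m, byrow = TRUE)
  R <- matrix(runif(m * n), nrow = m, byrow = TRUE)
  V <- pso_velocity(state$X, state$V, state$P, state$G, w, c1, c2, r, R)
  V <- clamp_velocity(V, vmax(state$space))
  X <- repair_rows(state$space, state$X + V)
  state$V <- V
  state$X <- X
  state$fX <- apply(X, 1L, objective)
  state$evals <- state$evals + m
  state$n <- state$n + 1L
  update_bests(state)
}

#' Local attractor of a particle
#'
#' Componentwise random convex combination `gamma*P + (1 - gamma)*G`
#' with a fresh `gamma ~ U(0,1)` per dimension; the point toward which
#' the drift velocity pulls.
#'
#' @param P personal best position vector.
#' @param G global best position vector.
#' @param gamma optional fixed draw(s) for verification; defaults to
#'   fresh uniforms.
#' @return the attractor vector.
#' @export
local_focus <- function(P, G, gamma = NULL) {
  if (length(P) != length(G)) stop("P and G must have equal length")
  if (is.null(gamma)) gamma <- runif(length(P))
  gamma * P + (1 - gamma) * G
}

#' Random drift PSO iteration
#'
#' The velocity is the sum of a random (thermal) component
#' `alpha * |C - X| * phi`, `phi ~ N(0,1)`, and a drift component
#' `beta * (p - X)` toward the particle's local attractor `p`; the
#' velocity clamp, move, repair and bookkeeping are as in [pso_step()].
#' Consumes `M` objective evaluations.
#'
#' @param state a `swarm_state`.
#' @param objective the objective function.
#' @param alpha positive thermal coefficient.
#' @param beta positive drift coefficient.
#' @return the updated `swarm_state`.
#' @export
rdpso_step <- function(state, objective, alpha, beta) {
  stopifnot(inherits(state, "swarm_state"), alpha > 0, beta > 0)
  m <- nrow(state$X); n <- ncol(state$X)
  gamma <- matrix(runif(m * n), nrow = m, byrow = TRUE)
  Gm <- matrix(state$G, nrow = m, ncol = n, byrow = TRUE)
  p <- gamma * state$P + (1 - gamma) * Gm
  phi <- matrix(rnorm(m * n), nrow = m, byrow = TRUE)
  V <- rdpso_velocity(state$X, state$C, p, alpha, beta, phi)
  V <- clamp_velocity(V, vmax(state$space))
  X <- repair_rows(state$space, state$X + V)
  state$V <- V
  state$X <- X
  state$fX <- apply(X, 1L, objective)
  state$evals <- state$evals + m
  state$n <- state$n + 1L
  update_bests(state)
}

#' Linear parameter schedule over iterations
#'
#' Interpolates linearly from `start` at `n = 1` to `end` at `n = n_max`;
#' used for the RDPSO thermal coefficient (0.9 to 0.3) and the PSO
#' inertia weight (0.9 to 0.4).
#'
#' @param start,end schedule endpoints.
#' @param n current iteration (1-based).
#' @param n_max final iteration.
#' @return the scheduled value.
#' @export
linear_schedule <- function(start, end, n, n_max) {
  if (n < 1 || n > n_max) stop("n must lie in [1, n_max]")
  if (n_max == 1) return(start)
  start + (end - start) * (n - 1) / (n_max - 1)
}
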