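#' Two-phased diversity control (2PDC)
#'
#' The controller measures swarm diversity every iteration and keeps it
#' between a linearly decaying lower bound and a fixed upper bound. While
#' the swarm converges normally it uses the canonical scheduled
#' coefficients; when diversity falls below the lower bound the swarm is
#' switched into a divergence phase with inflated coefficients until
#' diversity recovers to the upper bound; and when a convergence phase
#' fails to descend to the lower bound for long enough, an acceleration
#' mechanism pulls every personal best toward its local attractor.
#'
#' @name diversity_control
NULL

#' Parameters of the two-phased diversity controller
#'
#' @param dl1_factor lower-bound start, as a fraction of the initial
#'   diversity `D(X1)` (default 0.75).
#' @param dlnmax_factor lower-bound end fraction at the final iteration
#'   (default 0.002).
#' @param du_factor divergence exit threshold fraction (default 0.95).
#' @param alpha0,beta0 numerators of the divergence coefficients
#'   (defaults 9 and 3).
#' @param c1,c2 exponents shaping how fast the divergence coefficients
#'   grow as diversity shrinks (defaults 1 and 0.7).
#' @param accr acceleration clock fraction of the iteration horizon;
#'   no less than 0.003 (default 0.003).
#' @return an object of class `pdc_params`.
#' @export
pdc_params <- function(dl1_factor = 0.75, dlnmax_factor = 0.002,
                       du_factor = 0.95, alpha0 = 9, beta0 = 3,
                       c1 = 1, c2 = 0.7, accr = 0.003) {
  if (!(dlnmax_factor > 0 && dlnmax_factor < dl1_factor &&
        dl1_factor < du_factor && du_factor <= 1))
    stop("need 0 < dlnmax_factor < dl1_factor < du_factor <= 1")
  if (alpha0 <= 0 || beta0 <= 0) stop("alpha0 and beta0 must be positive")
  if (accr < 0.003) stop("accr must be no less than 0.003")
  structure(list(dl1_factor = dl1_factor, dlnmax_factor = dlnmax_factor,
                 du_factor = du_factor, alpha0 = alpha0, beta0 = beta0,
                 c1 = c1, c2 = c2, accr = accr),
            class = "pdc_params")
}

#' Swarm diversity: normalized mean distance from the centroid
#'
#' `D = (1/(M*A)) * sum_i ||X_i - Xbar||`, where `A` is the diagonal of
#' the search space and `Xbar` the componentwise mean position. All
#' genotype dimensions contribute with equal weight.
#'
#' @param positions an `M x N` matrix of particle positions.
#' @param A positive diagonal length of the search space.
#' @return the scalar diversity.
#' @export
diversity <- function(positions, A) {
  if (!is.matrix(positions) || nrow(positions) < 1L)
    stop("positions must be a matrix with at least one row")
  if (!is.numeric(A) || A <= 0) stop("A must be positive")
  xbar <- colMeans(positions)
  dev <- sweep(positions, 2L, xbar)
  sum(sqrt(rowSums(dev^2))) / (nrow(positions) * A)
}

#' Decaying lower bound of the diversity corridor
#'
#' `DL_n = (1 - n/n_max) * (DL_1 - DL_nmax) + DL_nmax`, with
#' `DL_1 = dl1_factor * D1` and `DL_nmax = dlnmax_factor * D1`. The
#' formula is used exactly as written, so the value at `n = 1` is
#' `(1 - 1/n_max) * (DL_1 - DL_nmax) + DL_nmax`, marginally below `DL_1`.
#'
#' @param n current iteration in `[1, n_max]`.
#' @param n_max iteration horizon.
#' @param D1 initial swarm diversity `D(X1)`, positive.
#' @param params a `pdc_params`.
#' @return the lower bound at iteration `n`.
#' @export
lower_bound <- function(n, n_max, D1, params = pdc_params()) {
  if (n < 1 || n > n_max) stop("n must lie in [1, n_max]")
  if (D1 <= 0) stop("D1 must be positive")
  dl1 <- params$dl1_factor * D1
  dlmax <- params$dlnmax_factor * D1
  (1 - n / n_max) * (dl1 - dlmax) + dlmax
}

#' Divergence-phase coefficients
#'
#' With diversity ratio `Dr = Dn / D1`, the inflated coefficients are
#' `alpha = alpha0 / Dr^c1` and `beta = beta0 / Dr^c2`; both grow without
#' bound as the swarm collapses. A fully collapsed swarm (`Dr = 0`) is
#' capped at `Dr = 1e-6` to keep the coefficients finite.
#'
#' @param Dn current diversity (>= 0).
#' @param D1 baseline diversity `D(X1)`, positive.
#' @param params a `pdc_params`.
#' @return list with elements `alpha` and `beta`.
#' @export
divergence_coeffs <- function(Dn, D1, params = pdc_params()) {
  if (D1 <= 0) stop("D1 must be positive")
  if (Dn < 0) stop("Dn must be non-negative")
  dr <- max(Dn / D1, 1e-6)
  list(alpha = params$alpha0 / dr^params$c1,
       beta = params$beta0 / dr^params$c2)
}

#' Initialize the controller state
#'
#' @param D1 diversity measured at the first iteration, positive.
#' @return an object of class `pdc_state` starting in the convergence
#'   phase with a zeroed acceleration clock.
#' @export
pdc_init <- function(D1) {
  if (D1 <= 0) stop("D1 must be positive")
  structure(list(phase = "CONVERGE", D1 = D1, conv_clock = 0L),
            class = "pdc_state")
}

#' One controller decision
#'
#' Runs the phase machine for the current iteration and selects the
#' coefficient mode:
#' \itemize{
#'   \item converging and `Dn < DL_n`: switch to the divergence phase;
#'   \item diverging and `Dn >= du_factor * D1`: switch back to
#'     convergence and reset the acceleration clock;
#'   \item while converging above the lower bound the clock ticks, and
#'     once it exceeds `accr * n_max` iterations the acceleration flag is
#'     raised (and stays raised while the condition persists).
#' }
#' In the convergence phase `alpha_mode = "scheduled"` (canonical
#' coefficients); in the divergence phase the inflated
#' [divergence_coeffs()] are returned.
#'
#' @param state a `pdc_state`.
#' @param Dn measured diversity at iteration `n`.
#' @param n,n_max iteration and horizon.
#' @param params a `pdc_params`.
#' @return list with `state` (updated), `phase`, `alpha_mode`
#'   (`"scheduled"` or `"divergence"`), `coeffs` (NULL or the inflated
#'   pair) and `accelerate` (logical).
#' @export
pdc_update <- function(state, Dn, n, n_max, params = pdc_params()) {
  stopifnot(inherits(state, "pdc_state"))
  accelerate <- FALSE
  if (state$phase == "CONVERGE") {
    dl <- lower_bound(n, n_max, state$D1, params)
    if (Dn < dl) {
      state$phase <- "DIVERGE"
    } else {
      state$conv_clock <- state$conv_clock + 1L
      if (state$conv_clock > params$accr * n_max) accelerate <- TRUE
    }
  } else {
    if (Dn >= params$du_factor * state$D1) {
      state$phase <- "CONVERGE"
      state$conv_clock <- 0L
    }
  }
  if (state$phase == "DIVERGE") {
    list(state = state, phase = state$phase, alpha_mode = "divergence",
         coeffs = divergence_coeffs(Dn, state$D1, params),
         accelerate = FALSE)
  } else {
    list(state = state, phase = state$phase, alpha_mode = "scheduled",
         coeffs = NULL, accelerate = accelerate)
  }
}

#' Accelerated convergence: contract the personal bests
#'
#' Every particle's personal best is replaced by its local attractor
#' (a random convex combination with the global best, fresh draw per
#' dimension), its fitness is re-evaluated (one evaluation per particle)
#' and the gbest/mbest bookkeeping refreshed. The global best itself
#' never worsens: some particle's pbest equals `G` and is a fixed point
#' of the contraction.
#'
#' @param state a `swarm_state`.
#' @param objective the objective function.
#' @return the updated `swarm_state` with `evals` advanced by `M`.
#' @export
accelerate_swarm <- function(state, objective) {
  stopifnot(inherits(state, "swarm_state"))
  m <- nrow(state$P); n <- ncol(state$P)
  gamma <- matrix(runif(m * n), nrow = m, byrow = TRUE)
  Gm <- matrix(state$G, nrow = m, ncol = n, byrow = TRUE)
  state$P <- gamma * state$P + (1 - gamma) * Gm
  state$fP <- apply(state$P, 1L, objective)
  state$evals <- state$evals + m
  ib <- which.min(state$fP)
  if (state$fP[ib] < state$fG) {
    state$G <- state$P[ib, ]
    state$fG <- state$fP[ib]
  }
  state$C <- colMeans(state$P)
  state
}

## degenerate-swarm escape: when diversity is exactly zero the random
## velocity |C - X|*phi vanishes everywhere, so inject a tiny uniform
## jitter (1e-6 of each range) before the next diverging step.
jitter_degenerate <- function(state) {
  rng <- state$space$upper - state$space$lower
  m <- nrow(state$X); n <- ncol(state$X)
  u <- matrix(runif(m * n, -1, 1), nrow = m, byrow = TRUE)
  state$X <- repair_rows(state$space,
                         state$X + u * matrix(rng * 1e-6, m, n, byrow = TRUE))
  state
}
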