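#' Run configuration for the swarm docking search
#'
#' Bundles the algorithm choice, swarm size, evaluation budget, seed and
#' the nested parameter sets. The production defaults mirror a full
#' docking run (swarm of 150 particles, 2.5e6 fitness evaluations); the
#' test suites use much smaller budgets. The iteration horizon used by
#' the lower-bound schedule is derived as `n_max = ceiling(budget / M)`,
#' so the schedule completes exactly when the budget would be exhausted
#' by swarm moves alone.
#'
#' @param algorithm one of `"DGLRDPSO"`, `"LRDPSO"`, `"LPSO"`.
#' @param M swarm size (default 150).
#' @param eval_budget total number of objective evaluations, counting the
#'   swarm updates, the acceleration re-evaluations and the local search
#'   (default 2.5e6).
#' @param seed integer RNG seed for the run.
#' @param pdc a [pdc_params()] set (DGLRDPSO only).
#' @param sw a [sw_params()] set, or `NULL` to disable local search.
#' @param alpha_schedule RDPSO thermal-coefficient schedule endpoints
#'   (default `c(0.9, 0.3)`).
#' @param beta RDPSO drift coefficient (default 1.45).
#' @param w_schedule LPSO inertia-weight schedule endpoints
#'   (default `c(0.9, 0.4)`).
#' @param c1,c2 LPSO acceleration coefficients (default 2.05 each).
#' @return an object of class `run_config`.
#' @export
run_config <- function(algorithm = c("DGLRDPSO", "LRDPSO", "LPSO"),
                       M = 150L, eval_budget = 2.5e6, seed = 1L,
                       pdc = pdc_params(), sw = sw_params(),
                       alpha_schedule = c(0.9, 0.3), beta = 1.45,
                       w_schedule = c(0.9, 0.4), c1 = 2.05, c2 = 2.05) {
  algorithm <- match.arg(algorithm)
  M <- as.integer(M)
  if (M < 1L) stop("M must be at least 1")
  if (eval_budget < M)
    stop("eval_budget must allow at least one full evaluation sweep (>= M)")
  structure(list(algorithm = algorithm, M = M, eval_budget = eval_budget,
                 seed = as.integer(seed), pdc = pdc, sw = sw,
                 alpha_schedule = alpha_schedule, beta = beta,
                 w_schedule = w_schedule, c1 = c1, c2 = c2),
            class = "run_config")
}

#' Run one optimization
#'
#' Orchestrates a full search: uniform random initialization inside the
#' bounds with zero velocities, then per iteration (1) measure swarm
#' diversity, (2) for DGLRDPSO let the 2PDC controller pick the phase and
#' coefficients, (3) one swarm update (RDPSO for DGLRDPSO/LRDPSO,
#' inertia-weight PSO for LPSO), (4) the acceleration contraction when
#' flagged, and (5) Solis-Wets local search on the currently best
#' particle with Lamarckian write-back (the improved point replaces the
#' particle's position, its personal best if better, and the global best
#' is refreshed). The run stops when the evaluation budget is consumed
#' or the iteration horizon is reached. LRDPSO is exactly DGLRDPSO with
#' the diversity controller disabled: both consume identical random
#' draws, so shared seeds give identical trajectories.
#'
#' @param objective function from a position vector to a scalar energy.
#' @param space a `search_space`.
#' @param config a [run_config()].
#' @return an object of class `run_record`: `trace` (data frame with
#'   `n`, `f_G`, `diversity`, `phase`, `alpha`, `beta`, `accel`,
#'   `evals`), `best` (list `x`, `f`), `evals_total`, `n_iter`, `seed`,
#'   `config`.
#' @export
run_search <- function(objective, space, config) {
  stopifnot(inherits(space, "search_space"), inherits(config, "run_config"))
  set.seed(config$seed)
  m <- config$M
  n_max <- as.integer(ceiling(config$eval_budget / m))
  use_pdc <- config$algorithm == "DGLRDPSO" && !is.null(config$pdc)
  is_pso <- config$algorithm == "LPSO"

  state <- swarm_init(space, m, objective)
  pdc_state <- NULL
  tr_n <- integer(0); tr_fg <- numeric(0); tr_div <- numeric(0)
  tr_phase <- character(0); tr_alpha <- numeric(0); tr_beta <- numeric(0)
  tr_accel <- logical(0); tr_evals <- integer(0)

  n <- 0L
  while (state$evals < config$eval_budget && n < n_max) {
    n <- n + 1L
    ## schedule clock: the coefficient and lower-bound schedules run on
    ## the fraction of the budget consumed, so they complete exactly at
    ## budget exhaustion even though the local search also draws on the
    ## budget (with no local search this reduces to the iteration index)
    n_sched <- min(n_max, max(n, ceiling(n_max * state$evals /
                                           config$eval_budget)))
    dn <- diversity(state$X, space$A)
    phase <- "CONVERGE"
    accel <- FALSE
    if (is_pso) {
      w <- linear_schedule(config$w_schedule[1], config$w_schedule[2],
                           n_sched, n_max)
      alpha <- w; beta <- NA_real_
      state <- pso_step(state, objective, w, config$c1, config$c2)
    } else {
      alpha <- linear_schedule(config$alpha_schedule[1],
                               config$alpha_schedule[2], n_sched, n_max)
      beta <- config$beta
      if (use_pdc) {
        if (is.null(pdc_state)) {
          if (dn <= 0) dn <- .Machine$double.eps  # degenerate first swarm
          pdc_state <- pdc_init(dn)
        }
        dec <- pdc_update(pdc_state, dn, n_sched, n_max, config$pdc)
        pdc_state <- dec$state
        phase <- dec$phase
        accel <- dec$accelerate
        if (dec$alpha_mode == "divergence") {
          alpha <- dec$coeffs$alpha
          beta <- dec$coeffs$beta
          if (dn == 0) state <- jitter_degenerate(state)
        }
      }
      state <- rdpso_step(state, objective, alpha, beta)
      if (accel) state <- accelerate_swarm(state, objective)
    }
    if (!is.null(config$sw) && state$evals < config$eval_budget) {
      ib <- which.min(state$fX)  # ties: which.min takes the lowest index
      res <- solis_wets(state$X[ib, ], objective, space, config$sw,
                        f0 = state$fX[ib])
      state$evals <- state$evals + res$evals_used
      state$X[ib, ] <- res$x
      state$fX[ib] <- res$f_x
      if (res$f_x < state$fP[ib]) {
        state$P[ib, ] <- res$x
        state$fP[ib] <- res$f_x
        if (res$f_x < state$fG) {
          state$G <- res$x
          state$fG <- res$f_x
        }
        state$C <- colMeans(state$P)
      }
    }
    tr_n <- c(tr_n, n); tr_fg <- c(tr_fg, state$fG); tr_div <- c(tr_div, dn)
    tr_phase <- c(tr_phase, phase); tr_alpha <- c(tr_alpha, alpha)
    tr_beta <- c(tr_beta, beta); tr_accel <- c(tr_accel, accel)
    tr_evals <- c(tr_evals, state$evals)
  }

  structure(list(
    trace = data.frame(n = tr_n, f_G = tr_fg, diversity = tr_div,
                       phase = tr_phase, alpha = tr_alpha, beta = tr_beta,
                       accel = tr_accel, evals = tr_evals,
                       stringsAsFactors = FALSE),
    best = list(x = state$G, f = state$fG),
    evals_total = state$evals, n_iter = n,
    seed = config$seed, config = config
  ), class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("run_record: %s, %d iterations, %d evaluations, best %.6g (seed %d)\n",
              x$config$algorithm, x$n_iter, x$evals_total, x$best$f, x$seed))
  invisible(x)
}

#' Write a run trace as a tab-separated file with a summary line
#'
#' @param record a `run_record`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_run_record <- function(record, path) {
  stopifnot(inherits(record, "run_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# algorithm=%s seed=%d evals=%d best=%.10g",
                     record$config$algorithm, record$seed,
                     record$evals_total, record$best$f), con)
  utils::write.table(record$trace, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
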