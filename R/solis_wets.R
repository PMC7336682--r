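#' Solis-Wets local search parameters
#'
#' @param max_iter iteration cap (default 300).
#' @param consec_limit consecutive successes (failures) before the step
#'   size is expanded (contracted); default 4.
#' @param rho0 initial step size in native genotype units -- Angstrom for
#'   translation, quaternion units, radians for torsions (default 1.0).
#' @param rho_min termination step size (default 0.01).
#' @param expansion step multiplier after a success run (default 2.0).
#' @param contraction step multiplier after a failure run (default 0.5).
#' @return an object of class `sw_params`.
#' @export
sw_params <- function(max_iter = 300L, consec_limit = 4L, rho0 = 1.0,
                      rho_min = 0.01, expansion = 2.0, contraction = 0.5) {
  if (rho_min >= rho0) stop("rho_min must be below rho0")
  if (expansion <= 1) stop("expansion must exceed 1")
  if (contraction <= 0 || contraction >= 1) stop("contraction must lie in (0, 1)")
  if (consec_limit < 1) stop("consec_limit must be at least 1")
  structure(list(max_iter = as.integer(max_iter),
                 consec_limit = as.integer(consec_limit),
                 rho0 = rho0, rho_min = rho_min,
                 expansion = expansion, contraction = contraction),
            class = "sw_params")
}

#' Solis-Wets stochastic local search
#'
#' Classical adaptive random search with a bias vector: each iteration
#' draws a deviate `delta` with components `N(bias[j], rho)` and tries
#' `x + delta`, then `x - delta` (both repaired into the space). A
#' success updates the bias (`0.2*bias + 0.4*delta` on the forward move,
#' `bias - 0.4*delta` on the reverse); a failure halves the bias. After
#' `consec_limit` consecutive successes the step size `rho` doubles,
#' after the same number of consecutive failures it halves, and the
#' search stops once `rho < rho_min` or `max_iter` iterations are done.
#' Only improving moves are ever accepted, so the returned fitness never
#' exceeds the input fitness.
#'
#' @param x0 start position (will be repaired).
#' @param f objective function.
#' @param space a `search_space`.
#' @param params a `sw_params`.
#' @param f0 optional known fitness of `x0`; when omitted it is computed
#'   (counting one evaluation).
#' @param trace if `TRUE`, the per-iteration step sizes and success flags
#'   are returned for inspection.
#' @return list with `x`, `f_x`, `evals_used`, and (if traced)
#'   `rho_trace` and `success_trace`.
#' @export
solis_wets <- function(x0, f, space, params = sw_params(), f0 = NULL,
                       trace = FALSE) {
  stopifnot(inherits(space, "search_space"), inherits(params, "sw_params"))
  x <- repair(space, x0)
  evals <- 0L
  if (is.null(f0)) {
    f0 <- f(x)
    evals <- evals + 1L
  }
  fx <- f0
  n <- space$n
  bias <- numeric(n)
  rho <- params$rho0
  succ_run <- 0L
  fail_run <- 0L
  rho_trace <- numeric(0)
  success_trace <- logical(0)
  for (it in seq_len(params$max_iter)) {
    if (rho < params$rho_min) break
    delta <- rnorm(n, mean = bias, sd = rho)
    x_fwd <- repair(space, x + delta)
    f_fwd <- f(x_fwd); evals <- evals + 1L
    if (f_fwd < fx) {
      x <- x_fwd; fx <- f_fwd
      bias <- 0.2 * bias + 0.4 * delta
      success <- TRUE
    } else {
      x_rev <- repair(space, x - delta)
      f_rev <- f(x_rev); evals <- evals + 1L
      if (f_rev < fx) {
        x <- x_rev; fx <- f_rev
        bias <- bias - 0.4 * delta
        success <- TRUE
      } else {
        bias <- 0.5 * bias
        success <- FALSE
      }
    }
    if (success) {
      succ_run <- succ_run + 1L
      fail_run <- 0L
      if (succ_run >= params$consec_limit) {
        rho <- params$expansion * rho
        succ_run <- 0L
      }
    } else {
      fail_run <- fail_run + 1L
      succ_run <- 0L
      if (fail_run >= params$consec_limit) {
        rho <- params$contraction * rho
        fail_run <- 0L
      }
    }
    if (trace) {
      rho_trace <- c(rho_trace, rho)
      success_trace <- c(success_trace, success)
    }
  }
  out <- list(x = x, f_x = fx, evals_used = evals)
  if (trace) {
    out$rho_trace <- rho_trace
    out$success_trace <- success_trace
  }
  out
}
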