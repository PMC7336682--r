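#' Box-bounded search spaces and the docking genotype
#'
#' A `search_space` describes the optimization domain as per-dimension
#' bounds, with optional periodic (angular) dimensions and an optional
#' quaternion block that is renormalized on repair. The docking genotype
#' flattens translation (3, Angstrom), orientation (4 quaternion
#' components, unitless) and torsion angles (radians) into one such
#' vector of length `7 + n_torsions`.
#'
#' @param lower,upper numeric vectors of per-dimension bounds,
#'   `lower[j] < upper[j]`.
#' @param periodic logical vector; periodic dimensions must span exactly
#'   `2*pi` and are wrapped (not clipped) on repair.
#' @param quat_block integer vector of 4 dimension indices forming a unit
#'   quaternion, or `NULL` for plain box domains.
#' @return an object of class `search_space` with fields `lower`, `upper`,
#'   `periodic`, `n` (dimensionality), `A` (diagonal length
#'   `sqrt(sum((upper - lower)^2))`) and `quat_block`.
#' @examples
#' sp <- make_search_space(rep(-5, 3), rep(5, 3))
#' sp$A
#' @export
make_search_space <- function(lower, upper, periodic = NULL, quat_block = NULL) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != length(upper) || length(lower) == 0L)
    stop("lower and upper must be non-empty vectors of equal length")
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("bounds must be finite")
  if (any(lower >= upper))
    stop("lower[j] < upper[j] required for all dimensions")
  n <- length(lower)
  if (is.null(periodic)) periodic <- rep(FALSE, n)
  if (length(periodic) != n) stop("periodic must match dimensionality")
  if (any(periodic)) {
    rng <- upper[periodic] - lower[periodic]
    if (any(abs(rng - 2 * pi) > 1e-9))
      stop("periodic dimensions must have range exactly 2*pi")
  }
  if (!is.null(quat_block)) {
    quat_block <- as.integer(quat_block)
    if (length(quat_block) != 4L || any(quat_block < 1L) || any(quat_block > n))
      stop("quat_block must index 4 dimensions")
  }
  structure(list(
    lower = lower, upper = upper, periodic = as.logical(periodic),
    n = n, A = sqrt(sum((upper - lower)^2)), quat_block = quat_block
  ), class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat(sprintf("search_space: %d dims (%d periodic%s), diagonal A = %.4g\n",
              x$n, sum(x$periodic),
              if (is.null(x$quat_block)) "" else ", quaternion block", x$A))
  invisible(x)
}

#' Construct the flexible-ligand docking search space
#'
#' The genotype has 3 translation dimensions bounded by a cubic search box,
#' 4 quaternion components each bounded in `[-1, 1]`, and one periodic
#' torsion dimension in `[-pi, pi)` per rotatable bond.
#'
#' @param box_center numeric length 3, box center (Angstrom).
#' @param box_edge positive edge length of the cubic box (Angstrom).
#' @param n_torsions number of rotatable bonds (>= 0).
#' @return a `search_space` of dimensionality `7 + n_torsions`.
#' @examples
#' make_docking_space(c(0, 0, 0), 22.5, 6)
#' @export
make_docking_space <- function(box_center, box_edge, n_torsions) {
  if (length(box_center) != 3L || any(!is.finite(box_center)))
    stop("box_center must be 3 finite numbers")
  if (!is.numeric(box_edge) || length(box_edge) != 1L || box_edge <= 0)
    stop("box_edge must be a single positive number")
  n_torsions <- as.integer(n_torsions)
  if (is.na(n_torsions) || n_torsions < 0L)
    stop("n_torsions must be a non-negative count")
  half <- box_edge / 2
  lower <- c(box_center - half, rep(-1, 4), rep(-pi, n_torsions))
  upper <- c(box_center + half, rep(1, 4), rep(pi, n_torsions))
  periodic <- c(rep(FALSE, 7), rep(TRUE, n_torsions))
  make_search_space(lower, upper, periodic, quat_block = 4:7)
}

#' Per-dimension velocity limit
#'
#' The velocity clamp is half the dimension's range:
#' `vmax[j] = (upper[j] - lower[j]) / 2`.
#'
#' @param space a `search_space`.
#' @return numeric vector of length `space$n`.
#' @export
vmax <- function(space) {
  stopifnot(inherits(space, "search_space"))
  (space$upper - space$lower) / 2
}

#' Repair a position vector into the search space
#'
#' Periodic dimensions are wrapped into their range, non-periodic
#' dimensions clipped to the bounds, and the quaternion block (if any) is
#' renormalized to unit length; an all-zero quaternion is reset to the
#' identity rotation `(1, 0, 0, 0)`.
#'
#' Repair is idempotent: applying it twice gives the same vector.
#'
#' @param space a `search_space`.
#' @param x numeric vector of length `space$n`.
#' @return repaired numeric vector.
#' @export
repair <- function(space, x) {
  stopifnot(inherits(space, "search_space"))
  if (length(x) != space$n)
    stop(sprintf("x has length %d, expected %d", length(x), space$n))
  per <- space$periodic
  if (any(per)) {
    rng <- space$upper[per] - space$lower[per]
    x[per] <- space$lower[per] + (x[per] - space$lower[per]) %% rng
  }
  np <- !per
  x[np] <- pmin(pmax(x[np], space$lower[np]), space$upper[np])
  qb <- space$quat_block
  if (!is.null(qb)) {
    q <- x[qb]
    nrm <- sqrt(sum(q^2))
    x[qb] <- if (nrm == 0) c(1, 0, 0, 0) else q / nrm
  }
  x
}

## matrix form used by the swarm updates: one row per particle
repair_rows <- function(space, X) {
  t(apply(X, 1L, function(row) repair(space, row)))
}

#' Draw uniform random positions within the bounds
#'
#' Each dimension is sampled independently from `U(lower[j], upper[j])`;
#' rows are then repaired (which normalizes the quaternion block). Draws
#' use the current RNG state, particle-major then dimension-minor.
#'
#' @param space a `search_space`.
#' @param m number of positions.
#' @return an `m x n` matrix, one position per row.
#' @export
random_positions <- function(space, m) {
  stopifnot(inherits(space, "search_space"), m >= 1)
  u <- matrix(runif(m * space$n), nrow = m, byrow = TRUE)
  X <- sweep(sweep(u, 2L, space$upper - space$lower, "*"),
             2L, space$lower, "+")
  repair_rows(space, X)
}
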