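#' Docking evaluation indexes
#'
#' Coordinate RMSD against the reference pose, differences to the
#' per-case reference algorithm, success counting at the 2-Angstrom
#' criterion, and the rank conventions used for multi-run docking
#' reports.
#'
#' @name evaluation
NULL

#' Root mean squared deviation between matched coordinate sets
#'
#' `rmsd = sqrt(mean(d_i^2))` over the per-atom Euclidean displacements,
#' with identity atom mapping: no superposition and no symmetry
#' correction.
#'
#' @param a,b coordinate matrices with one atom per row, equal sizes and
#'   matched ordering.
#' @return the RMSD (Angstrom).
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    stop("coordinate sets must have identical dimensions")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Difference to the reference value
#'
#' `dref = value_test - value_ref`. With the per-case minimum as the
#' reference, the reference algorithm's own difference is 0 and every
#' other algorithm's is non-negative.
#'
#' @param value_test,value_ref finite indicator values (e.g. mean or
#'   best energy).
#' @return the difference.
#' @export
dref <- function(value_test, value_ref) {
  if (!all(is.finite(value_test)) || !all(is.finite(value_ref)))
    stop("values must be finite")
  value_test - value_ref
}

#' Summarize repeated docking runs of one case
#'
#' @param runs data frame with one row per repeat and columns `rmsd`,
#'   `docked_energy`, `binding_score`.
#' @param success_threshold RMSD success cutoff in Angstrom (default 2.0,
#'   ties count as success).
#' @return list with `R` (number of runs), `NS` (successful runs,
#'   `rmsd <= threshold`), `mean_docked`, `best_docked`, `ME` (mean
#'   binding score), `LE` (lowest binding score among successful runs,
#'   `NA` when `NS = 0`), `rank` (position of the LE conformation when
#'   all `R` conformations are sorted ascending by binding score, ties
#'   broken by run index; recorded as `R + 1` when `NS = 0`).
#' @export
summarize_case <- function(runs, success_threshold = 2.0) {
  need <- c("rmsd", "docked_energy", "binding_score")
  if (!all(need %in% names(runs)))
    stop("runs must have columns ", paste(need, collapse = ", "))
  R <- nrow(runs)
  if (R < 1) stop("at least one run is required")
  if (any(runs$rmsd < 0)) stop("rmsd must be non-negative")
  ok <- runs$rmsd <= success_threshold
  NS <- sum(ok)
  ord <- order(runs$binding_score, seq_len(R))  # ties by run index
  if (NS == 0) {
    LE <- NA_real_
    rank <- R + 1L
  } else {
    ile <- which(ok)[which.min(runs$binding_score[ok])]
    LE <- runs$binding_score[ile]
    rank <- which(ord == ile)
  }
  list(R = R, NS = NS,
       mean_docked = mean(runs$docked_energy),
       best_docked = min(runs$docked_energy),
       ME = mean(runs$binding_score),
       LE = LE, rank = as.integer(rank))
}

#' Cross-algorithm difference table
#'
#' Given one indicator value per algorithm for each case, subtracts the
#' per-case minimum, so the per-case best algorithm scores 0.
#'
#' @param values matrix or data frame, cases in rows, algorithms in
#'   columns.
#' @return matrix of differences with the same shape.
#' @export
dref_table <- function(values) {
  values <- as.matrix(values)
  ref <- apply(values, 1L, min)
  sweep(values, 1L, ref)
}
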