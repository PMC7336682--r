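#' Simplified grid-based flexible-ligand docking objective
#'
#' The objective mirrors the classic docking-engine layout: the rigid
#' receptor is precomputed into per-atom-type affinity grids plus one
#' electrostatic grid; posing a ligand applies its torsion tree, a rigid
#' quaternion rotation and a translation; scoring interpolates the grids
#' trilinearly at each atom and adds a pairwise ligand internal energy.
#' The docked energy (the optimized quantity) is the intermolecular grid
#' energy plus the internal energy; the binding score used for ranking
#' final conformations is the intermolecular energy plus a torsional
#' penalty `w_tor * n_torsions`. The force field here is a deliberately
#' simple van der Waals + distance-dependent-dielectric Coulomb
#' surrogate with a small closed atom-type alphabet, not a calibrated
#' semi-empirical free-energy model.
#'
#' @name docking_problem
NULL

## Toy force-field table: well depth (energy units) and van der Waals
## radius (Angstrom) per atom type. Pair parameters use Lorentz-Berthelot
## style mixing: req = r_i + r_j, eps = sqrt(eps_i * eps_j).
atom_type_table <- function() {
  data.frame(
    type = c("C", "N", "O", "H", "X"),
    eps = c(0.10, 0.25, 0.45, 0.02, 0.15),
    radius = c(2.00, 1.75, 1.60, 1.20, 2.00),
    stringsAsFactors = FALSE
  )
}

type_index <- function(types) {
  tab <- atom_type_table()
  idx <- match(types, tab$type)
  idx[is.na(idx)] <- match("X", tab$type)
  idx
}

#' Construct a ligand model
#'
#' @param atoms data frame with columns `name`, `type` (one of C, N, O,
#'   H, X), `charge` (partial charge, e), `x`, `y`, `z` (reference
#'   coordinates, Angstrom).
#' @param bonds two-column integer matrix of bonded atom index pairs.
#' @param root integer indices of the rigid root fragment.
#' @param branches ordered list (root-outward) of rotatable branches,
#'   each `list(axis = c(i, j), moved = <indices>)`: rotating branch `k`
#'   moves exactly its `moved` set about the `i -> j` axis. Moved sets
#'   must be nested or disjoint, and together with the root cover all
#'   atoms.
#' @return an object of class `ligand_model` with `n_torsions` equal to
#'   the number of branches; internal non-bonded pairs (atoms three or
#'   more bonds apart) are precomputed with their pair parameters.
#' @export
ligand_model <- function(atoms, bonds, root, branches = list()) {
  need <- c("name", "type", "charge", "x", "y", "z")
  if (!all(need %in% names(atoms))) stop("atoms must have columns ", paste(need, collapse = ", "))
  na <- nrow(atoms)
  if (length(branches) > 0) {
    moved_all <- unlist(lapply(branches, `[[`, "moved"))
    cover <- sort(unique(c(root, moved_all)))
    if (!identical(cover, seq_len(na)))
      stop("root and branch moved-sets must cover all atoms")
    for (k in seq_along(branches)) {
      mk <- branches[[k]]$moved
      for (l in seq_along(branches)) {
        if (l == k) next
        ml <- branches[[l]]$moved
        ov <- length(intersect(mk, ml))
        if (ov > 0 && ov != min(length(mk), length(ml)))
          stop("branch moved-sets must be nested or disjoint")
      }
    }
  } else if (!identical(sort(unique(as.integer(root))), seq_len(na))) {
    stop("root must cover all atoms when there are no branches")
  }
  obj <- structure(list(
    atoms = atoms, bonds = bonds, root = as.integer(root),
    branches = branches, n_torsions = length(branches),
    type_idx = type_index(atoms$type)
  ), class = "ligand_model")
  obj$pairs <- internal_pairs(obj)
  obj
}

#' @export
print.ligand_model <- function(x, ...) {
  cat(sprintf("ligand_model: %d atoms, %d bonds, %d torsions\n",
              nrow(x$atoms), nrow(x$bonds), x$n_torsions))
  invisible(x)
}

## bond-graph distances by BFS; internal energy includes pairs >= 3
## bonds apart (1-2 and 1-3 excluded, 1-4 and beyond unscaled)
internal_pairs <- function(lig) {
  na <- nrow(lig$atoms)
  adj <- vector("list", na)
  if (nrow(lig$bonds) > 0) {
    for (b in seq_len(nrow(lig$bonds))) {
      i <- lig$bonds[b, 1]; j <- lig$bonds[b, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  tab <- atom_type_table()
  out <- matrix(numeric(0), ncol = 4)
  for (i in seq_len(na)) {
    dist <- rep(NA_integer_, na)
    dist[i] <- 0L
    frontier <- i
    d <- 0L
    while (length(frontier) > 0 && d < 3L) {
      d <- d + 1L
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(dist[nxt])]
      dist[nxt] <- d
      frontier <- nxt
    }
    far <- which((is.na(dist) | dist >= 3L) & seq_len(na) > i)
    if (length(far) > 0) {
      ti <- lig$type_idx[i]; tf <- lig$type_idx[far]
      out <- rbind(out, cbind(i, far,
                              sqrt(tab$eps[ti] * tab$eps[tf]),
                              tab$radius[ti] + tab$radius[tf]))
    }
  }
  colnames(out) <- c("i", "j", "eps", "req")
  out
}

#' Split a flat genotype vector into its blocks
#'
#' @param x numeric vector of length `7 + n_torsions`.
#' @param n_torsions torsion count.
#' @return list with `translation` (3), `quaternion` (4, as stored, not
#'   yet normalized) and `torsions`.
#' @export
split_genotype <- function(x, n_torsions) {
  if (length(x) != 7 + n_torsions)
    stop(sprintf("genotype has length %d, expected %d", length(x), 7 + n_torsions))
  list(translation = x[1:3], quaternion = x[4:7],
       torsions = if (n_torsions > 0) x[7 + seq_len(n_torsions)] else numeric(0))
}

#' Pose a ligand according to a genotype
#'
#' Torsions are applied innermost-branch-first as rotations of each
#' branch's moved set about its axis (in the reference frame), then the
#' whole ligand is rotated by the quaternion about its root anchor (the
#' first root atom) and translated. The reference coordinates are never
#' modified.
#'
#' @param ligand a `ligand_model`.
#' @param genotype numeric vector of length `7 + n_torsions`.
#' @return matrix of posed coordinates, one atom per row.
#' @export
apply_pose <- function(ligand, genotype) {
  stopifnot(inherits(ligand, "ligand_model"))
  g <- split_genotype(genotype, ligand$n_torsions)
  ref <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  dimnames(ref) <- NULL
  .apply_pose_cpp(ref, ligand$branches, g$torsions, g$quaternion,
                  g$translation, ligand$root[1])
}

#' Grid maps container
#'
#' @param type_grids named list of 3-D arrays, one affinity grid per
#'   atom type in the toy alphabet.
#' @param elec 3-D electrostatic grid array.
#' @param origin grid origin (coordinates of node `[1,1,1]`, Angstrom).
#' @param spacing node spacing (Angstrom).
#' @param penalty energy added per atom outside the grid (default 1e5).
#' @return an object of class `grid_maps`.
#' @export
grid_maps <- function(type_grids, elec, origin, spacing, penalty = 1e5) {
  npts <- dim(elec)
  for (g in type_grids)
    if (!identical(dim(g), npts)) stop("all grids must share dimensions")
  if (spacing <= 0) stop("spacing must be positive")
  structure(list(type_grids = type_grids, elec = elec,
                 origin = as.numeric(origin), spacing = spacing,
                 npts = as.integer(npts), penalty = penalty),
            class = "grid_maps")
}

#' @export
print.grid_maps <- function(x, ...) {
  cat(sprintf("grid_maps: %s nodes @ %.3f A, origin (%.2f, %.2f, %.2f), %d type maps\n",
              paste(x$npts, collapse = "x"), x$spacing,
              x$origin[1], x$origin[2], x$origin[3], length(x$type_grids)))
  invisible(x)
}

#' Trilinear interpolation of a grid at a point
#'
#' Standard 8-node trilinear interpolation; points outside the grid
#' return the out-of-grid penalty rather than raising an error, so the
#' scoring function stays finite everywhere.
#'
#' @param grid a 3-D numeric array.
#' @param point length-3 coordinates (Angstrom).
#' @param origin,spacing grid geometry.
#' @param penalty value returned outside the grid.
#' @return interpolated value.
#' @export
trilinear <- function(grid, point, origin, spacing, penalty = 1e5) {
  .trilinear_cpp(grid, dim(grid), as.numeric(origin), spacing,
                 as.numeric(point), penalty)
}

#' Build receptor grid maps
#'
#' Every node of every atom-type map accumulates the 12-6 van der Waals
#' term over all receptor atoms (pair parameters from the toy type
#' table), and the electrostatic map accumulates
#' `q_rec / (4 r^2)` (distance-dependent dielectric `4r`). Node values
#' are capped at a ceiling so near-clash nodes stay finite.
#'
#' @param receptor data frame with columns `type`, `charge`, `x`, `y`,
#'   `z` for the rigid receptor atoms.
#' @param center box center (length 3, Angstrom).
#' @param edge box edge length (Angstrom); the maps cover the box
#'   exactly.
#' @param spacing node spacing (default 0.375 Angstrom).
#' @param cap node value ceiling (default 10): a soft repulsion ceiling
#'   that keeps near-clash regions finite and navigable for stochastic
#'   search.
#' @param penalty out-of-grid penalty stored on the result (default 1e5).
#' @param exponents dispersion-repulsion exponent pair `(m, n)` of the
#'   Mie potential `eps/(m - n) * (n*(req/r)^m - m*(req/r)^n)`, which
#'   has its minimum `-eps` at `req` for any `m > n`. The default
#'   `c(4, 2)` gives much wider, softer wells than the classic `c(12, 6)`,
#'   broadening the docking funnel.
#' @return a `grid_maps` object with one affinity map per type in the
#'   toy alphabet.
#' @export
build_maps <- function(receptor, center, edge, spacing = 0.375,
                       cap = 10, penalty = 1e5, exponents = c(4, 2)) {
  if (nrow(receptor) == 0) stop("at least one receptor atom is required")
  tab <- atom_type_table()
  nt <- nrow(tab)
  pair_eps <- sqrt(outer(tab$eps, tab$eps))
  pair_req <- outer(tab$radius, tab$radius, "+")
  n_int <- max(1L, as.integer(round(edge / spacing)))
  npts <- rep(n_int + 1L, 3L)
  origin <- as.numeric(center) - edge / 2
  rec_xyz <- as.matrix(receptor[, c("x", "y", "z")])
  dimnames(rec_xyz) <- NULL
  if (length(exponents) != 2L || exponents[1] <= exponents[2])
    stop("exponents must be a pair (m, n) with m > n")
  res <- .build_maps_cpp(rec_xyz, receptor$charge, pair_eps, pair_req,
                         type_index(receptor$type), nt,
                         npts, origin, spacing, cap,
                         exponents[1], exponents[2])
  names(res$type_grids) <- tab$type
  grid_maps(res$type_grids, res$elec, origin, spacing, penalty)
}

#' Score a docking genotype
#'
#' Poses the ligand and evaluates the docked energy
#' `E_inter + E_internal` and the binding score
#' `E_inter + w_tor * n_torsions`, where `E_inter` sums each atom's
#' type-map affinity plus its charge times the electrostatic map (both
#' trilinearly interpolated) and `E_internal` sums the 12-6 plus Coulomb
#' terms over ligand atom pairs three or more bonds apart. Atoms outside
#' the grid each contribute the out-of-grid penalty.
#'
#' @param ligand a `ligand_model`.
#' @param maps a `grid_maps`.
#' @param genotype numeric genotype vector.
#' @param w_tor torsional penalty weight for the binding score
#'   (default 0.3 energy units per rotatable bond).
#' @return an object of class `pose`: `genotype`, `coordinates`,
#'   `docked_energy`, `binding_score`, `E_inter`, `E_internal`.
#' @export
score_pose <- function(ligand, maps, genotype, w_tor = 0.3) {
  stopifnot(inherits(ligand, "ligand_model"), inherits(maps, "grid_maps"))
  coords <- apply_pose(ligand, genotype)
  grids <- maps$type_grids[atom_type_table()$type]
  sc <- .score_coords_cpp(coords, ligand$type_idx, ligand$atoms$charge,
                          grids, maps$elec, maps$npts, maps$origin,
                          maps$spacing, ligand$pairs, maps$penalty)
  structure(list(
    genotype = genotype, coordinates = coords,
    E_inter = sc$E_inter, E_internal = sc$E_internal,
    docked_energy = sc$E_inter + sc$E_internal,
    binding_score = sc$E_inter + w_tor * ligand$n_torsions
  ), class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("pose: docked energy %.4f (inter %.4f, internal %.4f), binding score %.4f\n",
              x$docked_energy, x$E_inter, x$E_internal, x$binding_score))
  invisible(x)
}

#' Docked-energy objective over the flat genotype vector
#'
#' Convenience closure used by the search driver.
#'
#' @param ligand a `ligand_model`.
#' @param maps a `grid_maps`.
#' @return function mapping a genotype vector to its docked energy.
#' @export
docking_objective <- function(ligand, maps) {
  ref <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  dimnames(ref) <- NULL
  grids <- maps$type_grids[atom_type_table()$type]
  branches <- ligand$branches
  anchor <- ligand$root[1]
  ntor <- ligand$n_torsions
  type_idx <- ligand$type_idx
  charges <- ligand$atoms$charge
  pairs <- ligand$pairs
  function(x) {
    coords <- .apply_pose_cpp(ref, branches,
                              if (ntor > 0) x[7 + seq_len(ntor)] else numeric(0),
                              x[4:7], x[1:3], anchor)
    sc <- .score_coords_cpp(coords, type_idx, charges, grids, maps$elec,
                            maps$npts, maps$origin, maps$spacing,
                            pairs, maps$penalty)
    sc$E_inter + sc$E_internal
  }
}
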