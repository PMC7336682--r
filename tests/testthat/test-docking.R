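quat_to_mat_R <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rotate_axis_R <- function(coords, a, b, theta) {
  u <- b - a
  u <- u / sqrt(sum(u^2))
  c_ <- cos(theta); s <- sin(theta); t <- 1 - c_
  R <- matrix(c(
    t * u[1]^2 + c_, t * u[1] * u[2] - s * u[3], t * u[1] * u[3] + s * u[2],
    t * u[1] * u[2] + s * u[3], t * u[2]^2 + c_, t * u[2] * u[3] - s * u[1],
    t * u[1] * u[3] - s * u[2], t * u[2] * u[3] + s * u[1], t * u[3]^2 + c_),
    3, 3, byrow = TRUE)
  sweep(sweep(coords, 2, a) %*% t(R), 2, a, "+")
}

test_that("the identity genotype reproduces the reference coordinates", {
  lig <- tiny_ligand()
  g <- c(0, 0, 0, 1, 0, 0, 0, 0)
  expect_equal(apply_pose(lig, g),
               unname(as.matrix(lig$atoms[, c("x", "y", "z")])))
  expect_error(apply_pose(lig, numeric(7)), "length")
})

test_that("a pure translation shifts every atom rigidly", {
  lig <- tiny_ligand()
  t0 <- c(2.5, -1, 4)
  g <- c(t0, 1, 0, 0, 0, 0)
  ref <- unname(as.matrix(lig$atoms[, c("x", "y", "z")]))
  expect_equal(apply_pose(lig, g), sweep(ref, 2, t0, "+"))
})

test_that("torsion rotation moves exactly the branch set, matching a matrix oracle", {
  lig <- tiny_ligand()
  ref <- unname(as.matrix(lig$atoms[, c("x", "y", "z")]))
  for (theta in c(pi, 0.7, -1.9)) {
    g <- c(0, 0, 0, 1, 0, 0, 0, theta)
    posed <- apply_pose(lig, g)
    expect_equal(posed[1:4, ], ref[1:4, ])  # root untouched
    oracle <- rotate_axis_R(ref[5:6, , drop = FALSE], ref[3, ], ref[5, ], theta)
    expect_equal(posed[5:6, ], oracle, tolerance = 1e-12)
  }
})

test_that("rigid fragments keep their interatomic distances under any genotype", {
  lig <- tiny_ligand()
  set.seed(15)
  ref <- unname(as.matrix(lig$atoms[, c("x", "y", "z")]))
  for (k in 1:20) {
    g <- c(runif(3, -5, 5), rnorm(4), runif(1, -pi, pi))
    posed <- apply_pose(lig, g)
    # whole-molecule distances within the root, and within the branch
    expect_equal(as.vector(dist(posed[1:4, ])), as.vector(dist(ref[1:4, ])),
                 tolerance = 1e-9)
    expect_equal(as.vector(dist(posed[5:6, ])), as.vector(dist(ref[5:6, ])),
                 tolerance = 1e-9)
    # quaternion rotation is proper: chirality-preserving determinant 1
    expect_equal(det(quat_to_mat_R(g[4:7])), 1)
  }
})

test_that("trilinear interpolation matches nodes, edge midpoints and an oracle", {
  set.seed(16)
  grid <- array(rnorm(5 * 6 * 7), dim = c(5, 6, 7))
  origin <- c(-1, 0, 2)
  h <- 0.5
  # exact node
  expect_equal(trilinear(grid, origin + h * c(2, 3, 4), origin, h),
               grid[3, 4, 5])
  # midpoint of an axis-aligned edge is the mean of the two nodes
  expect_equal(trilinear(grid, origin + h * c(2.5, 3, 4), origin, h),
               (grid[3, 4, 5] + grid[4, 4, 5]) / 2)
  # random interior points against an independent loop implementation
  for (k in 1:100) {
    p <- origin + h * c(runif(1, 0, 4), runif(1, 0, 5), runif(1, 0, 6))
    expect_equal(trilinear(grid, p, origin, h),
                 trilinear_oracle(grid, p, origin, h), tolerance = 1e-12)
  }
  # outside the grid: the penalty, not an error
  expect_equal(trilinear(grid, origin - 1, origin, h, penalty = 1e5), 1e5)
})

test_that("maps of a single receptor atom have the analytic well and cap", {
  maps <- single_atom_maps(type = "C", charge = 0.5, cap = 10)
  tab <- swarmdock:::atom_type_table()
  # node at the C-C equilibrium distance holds the -eps_CC minimum
  req <- 2 * tab$radius[tab$type == "C"]
  eps <- tab$eps[tab$type == "C"]
  val <- trilinear(maps$type_grids$C, c(req, 0, 0), maps$origin, maps$spacing)
  expect_equal(val, -eps, tolerance = 1e-6)
  # node on top of the receptor atom is capped, not infinite
  expect_equal(trilinear(maps$type_grids$C, c(0, 0, 0), maps$origin,
                         maps$spacing), 10)
  # electrostatic node: q / (4 r^2) with the distance-dependent dielectric
  expect_equal(trilinear(maps$elec, c(2, 0, 0), maps$origin, maps$spacing),
               0.5 / (4 * 4), tolerance = 1e-9)
})

test_that("doubling receptor charges doubles the electrostatic map", {
  rec <- data.frame(name = c("A", "B"), type = c("C", "O"),
                    charge = c(0.2, -0.4), x = c(1, -1), y = 0, z = 0,
                    stringsAsFactors = FALSE)
  m1 <- build_maps(rec, c(0, 0, 0), 6, spacing = 1, cap = 1e5)
  rec2 <- rec; rec2$charge <- rec$charge * 2
  m2 <- build_maps(rec2, c(0, 0, 0), 6, spacing = 1, cap = 1e5)
  keep <- m1$elec < 1e4 & m2$elec < 1e4  # away from the cap ceiling
  expect_equal(m2$elec[keep], 2 * m1$elec[keep], tolerance = 1e-9)
  expect_error(build_maps(rec[0, ], c(0, 0, 0), 6), "at least one")
})

test_that("scoring a single neutral atom returns the map value alone", {
  maps <- single_atom_maps()
  atoms <- data.frame(name = "C1", type = "C", charge = 0,
                      x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  lig <- ligand_model(atoms, matrix(integer(0), 0, 2), root = 1L)
  g <- c(3.5, 0, 0, 1, 0, 0, 0)
  pose <- score_pose(lig, maps, g)
  expect_equal(pose$E_internal, 0)
  expect_equal(pose$E_inter,
               trilinear(maps$type_grids$C, c(3.5, 0, 0), maps$origin,
                         maps$spacing))
  expect_equal(pose$docked_energy, pose$E_inter)
  expect_equal(pose$binding_score, pose$E_inter)  # no torsional penalty
})

test_that("a ligand outside the grid is dominated by the penalty", {
  maps <- single_atom_maps(edge = 6)
  lig <- tiny_ligand()
  g <- c(500, 500, 500, 1, 0, 0, 0, 0)
  pose <- score_pose(lig, maps, g)
  expect_gte(pose$E_inter, 6 * 1e5)
})

test_that("grid scoring agrees with a continuous pairwise oracle", {
  # fine maps around a small receptor; compare E_inter for in-pocket
  # poses against the direct (no-grid) sum over receptor atoms
  rec <- data.frame(name = paste0("R", 1:3), type = c("C", "O", "N"),
                    charge = c(0.3, -0.2, 0.1),
                    x = c(4, -4, 0), y = c(0, 3, -4), z = c(1, -1, 3),
                    stringsAsFactors = FALSE)
  maps <- build_maps(rec, c(0, 0, 0), 16, spacing = 0.25)
  lig <- tiny_ligand()
  tab <- swarmdock:::atom_type_table()
  mie <- function(eps, req, r, m = 4, n = 2) {
    s <- req / r
    eps / (m - n) * (n * s^m - m * s^n)
  }
  rec_xyz <- as.matrix(rec[, c("x", "y", "z")])
  direct_inter <- function(coords) {
    e <- 0
    for (i in seq_len(nrow(coords))) {
      ti <- lig$type_idx[i]
      for (a in seq_len(nrow(rec))) {
        ta <- swarmdock:::type_index(rec$type[a])
        r <- sqrt(sum((coords[i, ] - rec_xyz[a, ])^2))
        e <- e + mie(sqrt(tab$eps[ti] * tab$eps[ta]),
                     tab$radius[ti] + tab$radius[ta], r) +
          lig$atoms$charge[i] * rec$charge[a] / (4 * r^2)
      }
    }
    e
  }
  set.seed(18)
  checked <- 0
  while (checked < 10) {
    g <- c(runif(3, -1.5, 1.5), rnorm(4), runif(1, -pi, pi))
    pose <- score_pose(lig, maps, g)
    # keep clear of the node-value cap and the grid border, where the
    # grid and the continuous oracle legitimately differ
    dmin <- min(vapply(seq_len(nrow(pose$coordinates)), function(i) {
      min(sqrt(rowSums(sweep(rec_xyz, 2, pose$coordinates[i, ])^2)))
    }, 0))
    if (dmin < 3 || any(abs(pose$coordinates) > 7)) next
    checked <- checked + 1
    expect_equal(pose$E_inter, direct_inter(pose$coordinates),
                 tolerance = 0.5)
    expect_equal(pose$docked_energy, pose$E_inter + pose$E_internal)
  }
})

test_that("scoring is invariant under consistent atom relabeling", {
  maps <- single_atom_maps(edge = 10)
  lig <- tiny_ligand()
  g <- c(1, 0.5, -0.5, rnorm(4), 0.6)
  p1 <- score_pose(lig, maps, g)
  # relabel two root atoms consistently (anchor and axis atoms keep
  # their physical identity, so the pose itself is unchanged)
  atoms4 <- lig$atoms[c(1, 3, 2, 4, 5, 6), ]
  rownames(atoms4) <- NULL
  remap4 <- order(c(1, 3, 2, 4, 5, 6))
  bonds4 <- matrix(remap4[lig$bonds], ncol = 2)
  lig4 <- ligand_model(atoms4, bonds4, root = 1:4,
                       branches = list(list(axis = c(remap4[3], remap4[5]),
                                            moved = remap4[c(5, 6)])))
  p4 <- score_pose(lig4, maps, g)
  expect_equal(p4$docked_energy, p1$docked_energy, tolerance = 1e-9)
  expect_equal(p4$binding_score, p1$binding_score, tolerance = 1e-9)
})
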