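# shared toy objectives and small fixtures for the suite

sphere <- function(x) sum(x^2)

rastrigin <- function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x))

box_space <- function(n, half = 5) {
  make_search_space(rep(-half, n), rep(half, n))
}

# a tiny ligand built by hand: 4-atom root + one 2-atom branch
tiny_ligand <- function() {
  atoms <- data.frame(
    name = c("C1", "C2", "N3", "O4", "C5", "O6"),
    type = c("C", "C", "N", "O", "C", "O"),
    charge = c(0.1, -0.2, 0.15, -0.3, 0.05, 0.2),
    x = c(0, 1.5, 2.0, 3.5, 2.5, 3.2),
    y = c(0, 0, 1.4, 1.4, 2.8, 4.0),
    z = c(0, 0, 0, 0, 0.5, 1.0),
    stringsAsFactors = FALSE
  )
  bonds <- rbind(c(1, 2), c(2, 3), c(3, 4), c(3, 5), c(5, 6))
  ligand_model(atoms, bonds, root = 1:4,
               branches = list(list(axis = c(3L, 5L), moved = c(5L, 6L))))
}

# grid maps with analytically known content: a single receptor atom
single_atom_maps <- function(type = "C", charge = 0.5, edge = 8,
                             spacing = 0.5, ...) {
  receptor <- data.frame(name = "R1", type = type, charge = charge,
                         x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  build_maps(receptor, center = c(0, 0, 0), edge = edge,
             spacing = spacing, ...)
}

# independent R implementation of trilinear interpolation (loop form)
trilinear_oracle <- function(grid, point, origin, spacing) {
  g <- (point - origin) / spacing
  i <- pmin(floor(g), dim(grid) - 2) + 1  # 1-based lower node
  f <- g - (i - 1)
  val <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) *
         (if (dy) f[2] else 1 - f[2]) *
         (if (dz) f[3] else 1 - f[3])
    val <- val + w * grid[i[1] + dx, i[2] + dy, i[3] + dz]
  }
  val
}
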