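#' PDBQT-subset ligand and receptor I/O
#'
#' The subset covers what the torsion-tree search needs: `ROOT`/`ENDROOT`
#' around the rigid root fragment, nested `BRANCH i j`/`ENDBRANCH i j`
#' blocks for rotatable bonds (serial numbers of the axis atoms), a
#' `TORSDOF n` record, and fixed-column `ATOM`/`HETATM` records carrying
#' the partial charge (columns 71-76) and atom type (columns 78-79).
#' Bonds are not part of the format; they are reconstructed from the
#' reference coordinates with a distance cutoff, which is exact for the
#' idealized geometries this toolkit generates.
#'
#' @name pdbqt
NULL

parse_atom_line <- function(line, lineno) {
  if (nchar(line) < 79)
    stop(sprintf("line %d: ATOM record too short for the PDBQT subset", lineno))
  serial <- suppressWarnings(as.integer(substr(line, 7, 11)))
  name <- trimws(substr(line, 13, 16))
  x <- suppressWarnings(as.numeric(substr(line, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(line, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(line, 47, 54)))
  charge <- suppressWarnings(as.numeric(substr(line, 71, 76)))
  type <- trimws(substr(line, 78, 79))
  if (is.na(serial) || is.na(x) || is.na(y) || is.na(z) || is.na(charge) ||
      name == "" || type == "")
    stop(sprintf("line %d: malformed ATOM columns", lineno))
  list(serial = serial, name = name, x = x, y = y, z = z,
       charge = charge, type = type)
}

## fixed columns: serial 7-11, name 13-16, x/y/z 31-54, charge 71-76,
## type 78-79 (79 characters total)
format_atom_line <- function(serial, name, x, y, z, charge, type,
                             record = "ATOM") {
  sprintf("%-6s%5d %-4s%-3s %s%4d     %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
          record, serial, name, "LIG", "A", 1L, x, y, z, 1.0, 0.0,
          charge, type)
}

#' Parse a ligand PDBQT (subset) into a `ligand_model`
#'
#' The torsion tree is rebuilt from the `BRANCH` nesting: each branch's
#' moved set is every atom inside its block (including nested branches);
#' the axis atoms are looked up by serial number. A `TORSDOF` count that
#' disagrees with the number of branches raises a warning; an unclosed
#' or mismatched `BRANCH` is an error.
#'
#' @param text character vector of lines, or a single string with
#'   newlines.
#' @param bond_cutoff distance (Angstrom) below which two atoms are
#'   considered bonded (default 1.9).
#' @return a `ligand_model`.
#' @export
parse_pdbqt <- function(text, bond_cutoff = 1.9) {
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  atoms <- list()
  serials <- integer(0)
  root <- integer(0)
  in_root <- FALSE
  branch_stack <- list()  # each: list(axis = c(i, j) serials, moved = idx, id)
  branches <- list()
  n_seen <- 0L  # branches in file (pre-order), assigns each its slot
  torsdof <- NA_integer_
  for (ln in seq_along(text)) {
    line <- text[ln]
    rec <- toupper(substr(line, 1, 6))
    if (startsWith(rec, "ROOT")) {
      in_root <- TRUE
    } else if (startsWith(rec, "ENDROO")) {
      in_root <- FALSE
    } else if (startsWith(rec, "BRANCH")) {
      ij <- suppressWarnings(as.integer(strsplit(trimws(substr(line, 7, nchar(line))), "\\s+")[[1]]))
      if (length(ij) != 2L || any(is.na(ij)))
        stop(sprintf("line %d: BRANCH needs two serial numbers", ln))
      n_seen <- n_seen + 1L
      branch_stack[[length(branch_stack) + 1L]] <-
        list(axis = ij, moved = integer(0), id = n_seen)
    } else if (startsWith(rec, "ENDBRA")) {
      if (length(branch_stack) == 0L)
        stop(sprintf("line %d: ENDBRANCH without open BRANCH", ln))
      top <- branch_stack[[length(branch_stack)]]
      branch_stack[[length(branch_stack)]] <- NULL
      ij <- suppressWarnings(as.integer(strsplit(trimws(substr(line, 10, nchar(line))), "\\s+")[[1]]))
      if (length(ij) == 2L && !any(is.na(ij)) && !all(ij == top$axis))
        stop(sprintf("line %d: ENDBRANCH %d %d does not match open BRANCH %d %d",
                     ln, ij[1], ij[2], top$axis[1], top$axis[2]))
      branches[[top$id]] <- top
      # atoms of a closed inner branch also move with every enclosing branch
      if (length(branch_stack) > 0L) {
        for (k in seq_along(branch_stack))
          branch_stack[[k]]$moved <- c(branch_stack[[k]]$moved, top$moved)
      }
    } else if (startsWith(rec, "TORSDO")) {
      torsdof <- suppressWarnings(as.integer(trimws(substr(line, 8, nchar(line)))))
    } else if (startsWith(rec, "ATOM") || startsWith(rec, "HETATM")) {
      a <- parse_atom_line(line, ln)
      atoms[[length(atoms) + 1L]] <- a
      serials <- c(serials, a$serial)
      idx <- length(atoms)
      if (in_root) {
        root <- c(root, idx)
      } else if (length(branch_stack) > 0L) {
        for (k in seq_along(branch_stack))
          branch_stack[[k]]$moved <- c(branch_stack[[k]]$moved, idx)
      } else {
        root <- c(root, idx)  # tolerate atoms outside any block
      }
    }
  }
  if (length(branch_stack) > 0L) {
    top <- branch_stack[[length(branch_stack)]]
    stop(sprintf("unclosed BRANCH %d %d at end of input", top$axis[1], top$axis[2]))
  }
  if (length(atoms) == 0L) stop("no ATOM/HETATM records found")
  df <- data.frame(
    name = vapply(atoms, `[[`, "", "name"),
    type = vapply(atoms, `[[`, "", "type"),
    charge = vapply(atoms, `[[`, 0.0, "charge"),
    x = vapply(atoms, `[[`, 0.0, "x"),
    y = vapply(atoms, `[[`, 0.0, "y"),
    z = vapply(atoms, `[[`, 0.0, "z"),
    stringsAsFactors = FALSE
  )
  br <- lapply(branches, function(b) {
    ai <- match(b$axis[1], serials)
    aj <- match(b$axis[2], serials)
    if (is.na(ai) || is.na(aj))
      stop(sprintf("BRANCH %d %d refers to unknown atom serials",
                   b$axis[1], b$axis[2]))
    list(axis = c(ai, aj), moved = sort(unique(b$moved)))
  })
  if (!is.na(torsdof) && torsdof != length(br))
    warning(sprintf("TORSDOF %d disagrees with %d BRANCH records",
                    torsdof, length(br)))
  xyz <- as.matrix(df[, c("x", "y", "z")])
  dd <- as.matrix(stats::dist(xyz))
  bonds <- which(dd > 0 & dd < bond_cutoff & upper.tri(dd), arr.ind = TRUE)
  bonds <- unname(cbind(bonds[, 1], bonds[, 2]))
  ligand_model(df, bonds, sort(root), br)
}

#' Write a `ligand_model` as PDBQT (subset)
#'
#' Emits `ROOT`, nested `BRANCH` blocks and `TORSDOF`, optionally at a
#' posed conformation. Writing then parsing reproduces the model's
#' atoms, torsion tree and (for idealized geometries) bonds.
#'
#' @param ligand a `ligand_model`.
#' @param genotype optional genotype; when given, coordinates are the
#'   posed conformation instead of the reference.
#' @return character vector of lines.
#' @export
write_pdbqt <- function(ligand, genotype = NULL) {
  stopifnot(inherits(ligand, "ligand_model"))
  coords <- if (is.null(genotype)) {
    as.matrix(ligand$atoms[, c("x", "y", "z")])
  } else {
    apply_pose(ligand, genotype)
  }
  atom_line <- function(i) {
    format_atom_line(i, ligand$atoms$name[i], coords[i, 1], coords[i, 2],
                     coords[i, 3], ligand$atoms$charge[i],
                     ligand$atoms$type[i])
  }
  out <- c("ROOT", vapply(ligand$root, atom_line, ""), "ENDROOT")
  # emit branches in stored (root-outward) order; close in reverse so
  # nested moved-sets sit inside their parents
  nb <- length(ligand$branches)
  if (nb > 0) {
    owners <- lapply(ligand$branches, `[[`, "moved")
    is_subset <- function(a, b) all(a %in% b) && length(a) < length(b)
    parent_of <- vapply(seq_len(nb), function(k) {
      # parent = smallest strict superset of this branch's moved set
      sup <- which(vapply(owners, function(o) is_subset(owners[[k]], o), TRUE))
      if (length(sup) == 0L) 0L else sup[which.min(lengths(owners[sup]))]
    }, 0L)
    emit_branch <- function(k) {
      b <- ligand$branches[[k]]
      children <- which(parent_of == k)
      own <- setdiff(owners[[k]], unlist(owners[children]))
      lines <- c(sprintf("BRANCH %4d %4d", b$axis[1], b$axis[2]),
                 vapply(own, atom_line, ""))
      for (ch in children) lines <- c(lines, emit_branch(ch))
      c(lines, sprintf("ENDBRANCH %4d %4d", b$axis[1], b$axis[2]))
    }
    for (k in which(parent_of == 0L)) out <- c(out, emit_branch(k))
  }
  c(out, sprintf("TORSDOF %d", ligand$n_torsions))
}

#' Parse receptor atoms from PDBQT-subset text
#'
#' Only `ATOM`/`HETATM` records are read.
#'
#' @param text character vector of lines or one newline-joined string.
#' @return data frame with `name`, `type`, `charge`, `x`, `y`, `z`.
#' @export
parse_receptor_pdbqt <- function(text) {
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  keep <- grepl("^(ATOM|HETATM)", text)
  atoms <- lapply(which(keep), function(ln) parse_atom_line(text[ln], ln))
  if (length(atoms) == 0L) stop("no ATOM/HETATM records found")
  data.frame(
    name = vapply(atoms, `[[`, "", "name"),
    type = vapply(atoms, `[[`, "", "type"),
    charge = vapply(atoms, `[[`, 0.0, "charge"),
    x = vapply(atoms, `[[`, 0.0, "x"),
    y = vapply(atoms, `[[`, 0.0, "y"),
    z = vapply(atoms, `[[`, 0.0, "z"),
    stringsAsFactors = FALSE
  )
}

#' Write receptor atoms as PDBQT-subset text
#'
#' @param receptor data frame with `name`, `type`, `charge`, `x`, `y`, `z`.
#' @return character vector of lines.
#' @export
write_receptor_pdbqt <- function(receptor) {
  vapply(seq_len(nrow(receptor)), function(i) {
    format_atom_line(i, receptor$name[i], receptor$x[i], receptor$y[i],
                     receptor$z[i], receptor$charge[i], receptor$type[i])
  }, "")
}

#' Write grid maps to plain-text files
#'
#' Each map goes to `<prefix>.<label>.map`: a header with origin,
#' spacing and node counts, then one node value per line in z-major
#' order (x varies fastest).
#'
#' @param maps a `grid_maps`.
#' @param prefix file path prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_maps <- function(maps, prefix) {
  stopifnot(inherits(maps, "grid_maps"))
  labels <- c(names(maps$type_grids), "elec")
  grids <- c(maps$type_grids, list(elec = maps$elec))
  paths <- character(0)
  for (k in seq_along(grids)) {
    path <- sprintf("%s.%s.map", prefix, labels[k])
    con <- file(path, "w")
    writeLines(c(
      sprintf("ORIGIN %.6f %.6f %.6f", maps$origin[1], maps$origin[2], maps$origin[3]),
      sprintf("SPACING %.6f", maps$spacing),
      sprintf("NPTS %d %d %d", maps$npts[1], maps$npts[2], maps$npts[3]),
      sprintf("PENALTY %.6g", maps$penalty),
      format(as.vector(grids[[k]]), digits = 10, trim = TRUE, scientific = TRUE)
    ), con)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read grid maps written by [write_maps()]
#'
#' @param prefix the file path prefix used when writing.
#' @return a `grid_maps`.
#' @export
read_maps <- function(prefix) {
  labels <- c(atom_type_table()$type, "elec")
  grids <- list()
  origin <- NULL; spacing <- NULL; npts <- NULL; penalty <- 1e5
  for (lab in labels) {
    path <- sprintf("%s.%s.map", prefix, lab)
    if (!file.exists(path)) stop("missing map file: ", path)
    lines <- readLines(path)
    origin <- as.numeric(strsplit(lines[1], "\\s+")[[1]][2:4])
    spacing <- as.numeric(strsplit(lines[2], "\\s+")[[1]][2])
    npts <- as.integer(strsplit(lines[3], "\\s+")[[1]][2:4])
    penalty <- as.numeric(strsplit(lines[4], "\\s+")[[1]][2])
    vals <- as.numeric(lines[-(1:4)])
    grids[[lab]] <- array(vals, dim = npts)
  }
  grid_maps(grids[atom_type_table()$type], grids$elec, origin, spacing,
            penalty)
}
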