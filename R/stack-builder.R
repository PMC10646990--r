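# Rigid-body poses are stored as 3x3 rotation matrices plus translations;
# monomer templates are atom tibbles centered on their geometric center.

random_rotation_small <- function(sd_deg) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- rnorm(1, 0, sd_deg * pi / 180)
  rotation_about(ax, ang)
}

rotation_about <- function(axis, angle) {
  c1 <- cos(angle); s1 <- sin(angle); C <- 1 - c1
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(
    c1 + x * x * C, x * y * C - z * s1, x * z * C + y * s1,
    y * x * C + z * s1, c1 + y * y * C, y * z * C - x * s1,
    z * x * C - y * s1, z * y * C + x * s1, c1 + z * z * C
  ), nrow = 3, byrow = TRUE)
}

apply_pose <- function(xyz, rot, trans) {
  sweep(xyz %*% t(rot), 2, trans, `+`)
}

# energy of one monomer against the others: capped soft-core repulsion,
# Debye-screened Coulomb between partial charges, and a harmonic restraint
# tying consecutive centers to target_spacing along the stack axis
stack_pair_energy <- function(xyz_i, q_i, xyz_j, q_j, kappa, lb,
                              core = 2.5, cap = 100) {
  dx <- outer(xyz_i[, 1], xyz_j[, 1], `-`)
  dy <- outer(xyz_i[, 2], xyz_j[, 2], `-`)
  dz <- outer(xyz_i[, 3], xyz_j[, 3], `-`)
  r <- sqrt(dx^2 + dy^2 + dz^2)
  rep_e <- sum(pmin((core / pmax(r, 1e-6))^12, cap))
  qq <- outer(q_i, q_j)
  elec <- lb * sum(qq * exp(-kappa * r) / pmax(r, 0.5))
  rep_e + elec
}

#' Build a stacked assembly by rigid-body Monte Carlo docking
#'
#' Stacks `n_units` copies of a rigid monomer along +z at roughly
#' `target_spacing` and refines their poses by Metropolis Monte Carlo over
#' rigid rotations and translations. The score is a capped soft-core steric
#' repulsion plus Debye-screened Coulomb interactions between partial charges
#' plus a harmonic restraint pulling each consecutive center-to-center vector
#' toward `target_spacing * (0,0,1)` (which both spaces and aligns the
#' stack). The monomer template is used as supplied (no internal degrees of
#' freedom); its in-plane orientation relative to the stack axis is the
#' caller's responsibility and a warning is raised when the template looks
#' elongated along z rather than perpendicular to it.
#'
#' @param monomer An [atomic_configuration()] (its box is ignored) or an
#'   atom tibble with the columns of [atomic_configuration()].
#' @param n_units Number of monomers in the stack.
#' @param target_spacing Target center-to-center spacing, \eqn{\AA}.
#' @param seed Integer seed; runs are bit-reproducible for a fixed seed.
#' @param n_iter Monte Carlo moves (default `150 * n_units`).
#' @param k_spacing Restraint constant, score units per \eqn{\AA^2}.
#' @param kappa Inverse screening length for the screened electrostatics, \eqn{\AA^{-1}}
#'   (default: 250 mM 1:1 electrolyte at 298 K).
#' @param hard_core Minimum allowed distance between atoms of different
#'   monomers, \eqn{\AA}; failure to reach an overlap-free configuration is
#'   an error.
#' @param temperature_schedule Length-2 numeric: initial and final Metropolis
#'   temperatures (score units), annealed geometrically.
#' @return A list of class `stack_assembly`: `monomer` (centered atom
#'   tibble), `poses` (list of `list(rot, trans)`), `axis`, `score_trace`
#'   (best score at each recorded improvement) and `score`.
#' @export
build_stack_mc <- function(monomer, n_units, target_spacing, seed,
                           n_iter = 150L * n_units, k_spacing = 5,
                           kappa = debye_kappa(0.25), hard_core = 1.2,
                           temperature_schedule = c(5, 0.05)) {
  atoms <- if (inherits(monomer, "atomic_configuration")) monomer$atoms
           else tibble::as_tibble(monomer)
  if (nrow(atoms) < 1L) abort("monomer must contain at least one atom")
  stopifnot(n_units >= 1L, target_spacing > 0)
  xyz0 <- as.matrix(atoms[, c("x", "y", "z")])
  xyz0 <- sweep(xyz0, 2, colMeans(xyz0))
  qv <- atoms$charge
  ext <- apply(xyz0, 2, function(v) diff(range(v)))
  if (nrow(atoms) > 3L && ext[3] > max(ext[1], ext[2])) {
    warn("monomer is elongated along z (the stack axis); expected the molecular plane perpendicular to the axis")
  }
  poses <- lapply(seq_len(n_units) - 1L, function(i) {
    list(rot = diag(3), trans = c(0, 0, i * target_spacing))
  })
  if (n_units == 1L) {
    # identity pose: materialized atoms reproduce the input exactly
    ctr <- colMeans(as.matrix(atoms[, c("x", "y", "z")]))
    return(structure(list(monomer = atoms_centered(atoms, xyz0),
                          poses = list(list(rot = diag(3), trans = ctr)),
                          axis = c(0, 0, 1),
                          score_trace = numeric(0), score = 0),
                     class = "stack_assembly"))
  }

  with_preserved_seed(seed, {
    coords <- lapply(poses, function(p) apply_pose(xyz0, p$rot, p$trans))
    lb <- bjerrum_length()
    # screened interactions are negligible beyond a couple of spacings;
    # monomer pairs further apart than this contribute zero to the score
    cutoff <- 2.5 * target_spacing
    pair_fn <- function(xyz_i, ci, j) {
      if (sqrt(sum((ci - centers[j, ])^2)) > cutoff) return(0)
      stack_pair_energy(xyz_i, qv, coords[[j]], qv, kappa, lb)
    }
    centers <- t(vapply(poses, `[[`, numeric(3), "trans"))
    pair_e <- matrix(0, n_units, n_units)
    for (i in seq_len(n_units - 1)) {
      for (j in (i + 1):n_units) {
        pair_e[i, j] <- pair_fn(coords[[i]], centers[i, ], j)
      }
    }
    restraint <- function(centers) {
      dvec <- diff(centers)
      k_spacing * sum((sweep(dvec, 2, c(0, 0, target_spacing)))^2)
    }
    score <- sum(pair_e) + restraint(centers)
    best <- list(score = score, poses = poses, coords = coords)
    trace <- score
    temps <- exp(seq(log(temperature_schedule[1]),
                     log(temperature_schedule[2]), length.out = n_iter))
    for (it in seq_len(n_iter)) {
      k <- sample.int(n_units, 1)
      cand <- poses[[k]]
      cand$rot <- random_rotation_small(4) %*% cand$rot
      cand$trans <- cand$trans + rnorm(3, 0, 0.25)
      new_xyz <- apply_pose(xyz0, cand$rot, cand$trans)
      new_e <- numeric(n_units)
      for (j in seq_len(n_units)) {
        if (j == k) next
        new_e[j] <- pair_fn(new_xyz, cand$trans, j)
      }
      old_k <- ifelse(seq_len(n_units) < k, pair_e[, k], pair_e[k, ])
      cen2 <- centers; cen2[k, ] <- cand$trans
      d_score <- (sum(new_e) - sum(old_k)) +
        (restraint(cen2) - restraint(centers))
      if (d_score <= 0 || runif(1) < exp(-d_score / temps[it])) {
        poses[[k]] <- cand
        coords[[k]] <- new_xyz
        centers <- cen2
        pair_e[, k] <- ifelse(seq_len(n_units) < k, new_e, 0)
        pair_e[k, ] <- ifelse(seq_len(n_units) > k, new_e, 0)
        score <- score + d_score
        if (score < best$score) {
          best <- list(score = score, poses = poses, coords = coords)
          trace <- c(trace, score)
        }
      }
    }
    min_d <- min_intermonomer_distance(best$coords)
    if (min_d < hard_core) {
      abort(sprintf(
        "no overlap-free stack found: closest inter-monomer contact %.2f A (best score %.3g)",
        min_d, best$score))
    }
    ord <- order(vapply(best$poses, function(p) p$trans[3], numeric(1)))
    structure(list(monomer = atoms_centered(atoms, xyz0),
                   poses = best$poses[ord], axis = c(0, 0, 1),
                   score_trace = trace, score = best$score),
              class = "stack_assembly")
  })
}

atoms_centered <- function(atoms, xyz0) {
  atoms$x <- xyz0[, 1]; atoms$y <- xyz0[, 2]; atoms$z <- xyz0[, 3]
  atoms
}

min_intermonomer_distance <- function(coords) {
  n <- length(coords)
  m <- Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- outer(coords[[i]][, 1], coords[[j]][, 1], `-`)
      dy <- outer(coords[[i]][, 2], coords[[j]][, 2], `-`)
      dz <- outer(coords[[i]][, 3], coords[[j]][, 3], `-`)
      m <- min(m, sqrt(min(dx^2 + dy^2 + dz^2)))
    }
  }
  m
}

# run code under a fixed seed, restoring the caller's RNG state afterwards
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Atoms of a stack assembly
#'
#' Materializes the posed monomer copies into one atom tibble, with
#' `molecule_id` renumbered consecutively per monomer.
#'
#' @param assembly A `stack_assembly` from [build_stack_mc()].
#' @return Atom tibble (columns of [atomic_configuration()]).
#' @export
stack_atoms <- function(assembly) {
  xyz0 <- as.matrix(assembly$monomer[, c("x", "y", "z")])
  purrr::imap_dfr(assembly$poses, function(p, i) {
    a <- assembly$monomer
    xyz <- apply_pose(xyz0, p$rot, p$trans)
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    a$molecule_id <- i
    a
  })
}

#' Solvate stacks in a periodic cubic box
#'
#' Places the stacks on the box diagonal mid-plane with centers separated by
#' half the box width, then inserts rigid 3-site waters (OH 1.0 \eqn{\AA},
#' HOH 109.47 deg, SPC/E-like charges) and monovalent counterions at random
#' positions, rejecting insertions that put any heavy atom within `min_dist`
#' of another heavy atom (or any atom within 0.8 \eqn{\AA} of any other).
#'
#' @param stacks List of `stack_assembly` objects (may be empty).
#' @param n_waters Number of water molecules.
#' @param n_counterions Number of Na+ ions (+1 e each).
#' @param box_side Cubic box edge, \eqn{\AA}.
#' @param seed Integer seed.
#' @param min_dist Minimum heavy-atom insertion distance, \eqn{\AA}.
#' @param max_attempts Attempts per inserted molecule before giving up.
#' @return An [atomic_configuration()] with site labels `Ow`, `Hw`, `Na` for
#'   the solvent.
#' @export
solvate_box <- function(stacks, n_waters, n_counterions, box_side, seed,
                        min_dist = 2.0, max_attempts = 500L) {
  total_atoms <- n_waters * 3 + n_counterions +
    sum(vapply(stacks, function(s) {
      nrow(s$monomer) * length(s$poses)
    }, numeric(1)))
  if (total_atoms / box_side^3 > 0.12) {
    abort("requested contents exceed 0.12 atoms/A^3")
  }
  solute <- place_stacks(stacks, box_side)
  with_preserved_seed(seed, {
    grid <- new_cell_grid(box_side, cell = max(min_dist, 2.0))
    if (nrow(solute)) {
      grid_add(grid, as.matrix(solute[, c("x", "y", "z")]),
               solute$element != "H")
    }
    mol0 <- if (nrow(solute)) max(solute$molecule_id) else 0L
    ions <- insert_points(grid, n_counterions, box_side, min_dist,
                          max_attempts, what = "counterion")
    water_parts <- insert_waters(grid, n_waters, box_side, min_dist,
                                 max_attempts)
    ion_tbl <- tibble::tibble(
      site_label = rep("Na", n_counterions), element = "Na",
      x = ions[, 1], y = ions[, 2], z = ions[, 3], charge = 1,
      exchangeable = FALSE,
      molecule_id = mol0 + seq_len(n_counterions)
    )
    nw <- nrow(water_parts) / 3L
    wat_tbl <- tibble::tibble(
      site_label = rep(c("Ow", "Hw", "Hw"), nw),
      element = rep(c("O", "H", "H"), nw),
      x = water_parts[, 1], y = water_parts[, 2], z = water_parts[, 3],
      charge = rep(c(-0.8476, 0.4238, 0.4238), nw),
      exchangeable = rep(c(FALSE, TRUE, TRUE), nw),
      molecule_id = mol0 + n_counterions + rep(seq_len(nw), each = 3L)
    )
    atomic_configuration(dplyr::bind_rows(solute, ion_tbl, wat_tbl),
                         box_side)
  })
}

place_stacks <- function(stacks, box_side) {
  if (length(stacks) == 0L) {
    return(tibble::tibble(site_label = character(), element = character(),
                          x = numeric(), y = numeric(), z = numeric(),
                          charge = numeric(), exchangeable = logical(),
                          molecule_id = integer()))
  }
  n <- length(stacks)
  # centers on the box mid-plane, consecutive centers box_side/2 apart in x
  cx <- box_side / 2 + (seq_len(n) - (n + 1) / 2) * box_side / 2
  mol0 <- 0L
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- stack_atoms(stacks[[i]])
    ctr <- c(mean(range(a$x)), mean(range(a$y)), mean(range(a$z)))
    a$x <- a$x - ctr[1] + cx[i] %% box_side
    a$y <- a$y - ctr[2] + box_side / 2
    a$z <- a$z - ctr[3] + box_side / 2
    a$molecule_id <- a$molecule_id + mol0
    mol0 <- max(a$molecule_id)
    out[[i]] <- a
  }
  dplyr::bind_rows(out)
}

# mutable cell grid (environment) for neighbour queries under PBC;
# storage is preallocated and grown by doubling
new_cell_grid <- function(box, cell, capacity = 4096L) {
  ncell <- max(1L, floor(box / cell))
  e <- new.env(parent = emptyenv())
  e$box <- box
  e$ncell <- ncell
  e$size <- box / ncell
  e$cells <- vector("list", ncell^3)
  e$xyz <- matrix(NA_real_, capacity, 3)
  e$heavy <- logical(capacity)
  e$n <- 0L
  e
}

cell_index <- function(grid, xyz) {
  ijk <- floor(xyz / grid$size) %% grid$ncell
  as.integer(ijk[, 1] + grid$ncell * (ijk[, 2] + grid$ncell * ijk[, 3])) + 1L
}

grid_add <- function(grid, xyz, heavy) {
  k <- nrow(xyz)
  while (grid$n + k > nrow(grid$xyz)) {
    grid$xyz <- rbind(grid$xyz, matrix(NA_real_, nrow(grid$xyz), 3))
    grid$heavy <- c(grid$heavy, logical(length(grid$heavy)))
  }
  idx <- grid$n + seq_len(k)
  grid$xyz[idx, ] <- xyz
  grid$heavy[idx] <- heavy
  grid$n <- grid$n + k
  ci <- cell_index(grid, xyz)
  for (j in seq_len(k)) {
    grid$cells[[ci[j]]] <- c(grid$cells[[ci[j]]], idx[j])
  }
}

grid_neighbours <- function(grid, p) {
  ijk <- floor(p / grid$size)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  cells <- sweep(off, 2, ijk, `+`) %% grid$ncell
  ids <- unique(as.integer(cells[, 1] +
                             grid$ncell * (cells[, 2] +
                                             grid$ncell * cells[, 3])) + 1L)
  unlist(grid$cells[ids], use.names = FALSE)
}

# minimum-image distance from point p to stored atoms idx
grid_dist <- function(grid, p, idx) {
  d <- grid$xyz[idx, , drop = FALSE]
  dd <- sweep(d, 2, p, `-`)
  dd <- dd - grid$box * round(dd / grid$box)
  sqrt(rowSums(dd^2))
}

insertion_ok <- function(grid, p, heavy_new, min_dist) {
  idx <- grid_neighbours(grid, p)
  if (length(idx) == 0L) return(TRUE)
  d <- grid_dist(grid, p, idx)
  req <- ifelse(grid$heavy[idx] & heavy_new, min_dist, 0.8)
  all(d >= req)
}

insert_points <- function(grid, n, box, min_dist, max_attempts, what) {
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      p <- runif(3, 0, box)
      if (insertion_ok(grid, p, TRUE, min_dist)) {
        out[i, ] <- p
        grid_add(grid, matrix(p, 1), TRUE)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(sprintf("failed to insert %s %d of %d after %d attempts",
                    what, i, n, max_attempts))
    }
  }
  out
}

#' Rigid 3-site water geometry
#'
#' Oxygen at the origin plus two hydrogens at the reference geometry
#' (OH 1.0 \eqn{\AA}, HOH 109.47 deg) rotated by the given matrix.
#'
#' @param rot 3x3 rotation matrix.
#' @return 3x3 matrix of O, H, H positions (rows).
#' @export
water_geometry <- function(rot = diag(3)) {
  half <- (109.47 / 2) * pi / 180
  h1 <- c(sin(half), 0, cos(half))
  h2 <- c(-sin(half), 0, cos(half))
  rbind(c(0, 0, 0), h1, h2) %*% t(rot)
}

random_rotation_uniform <- function() {
  # uniform over SO(3) via normalized quaternion
  u <- rnorm(4); u <- u / sqrt(sum(u^2))
  a <- u[1]; b <- u[2]; cc <- u[3]; d <- u[4]
  matrix(c(
    a^2 + b^2 - cc^2 - d^2, 2 * (b * cc - a * d), 2 * (b * d + a * cc),
    2 * (b * cc + a * d), a^2 - b^2 + cc^2 - d^2, 2 * (cc * d - a * b),
    2 * (b * d - a * cc), 2 * (cc * d + a * b), a^2 - b^2 - cc^2 + d^2
  ), 3, 3, byrow = TRUE)
}

insert_waters <- function(grid, n, box, min_dist, max_attempts) {
  out <- matrix(NA_real_, 3L * n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      p <- runif(3, 0, box)
      if (!insertion_ok(grid, p, TRUE, min_dist)) next
      w <- water_geometry(random_rotation_uniform())
      hpos <- sweep(w[2:3, , drop = FALSE], 2, p, `+`) %% box
      if (insertion_ok(grid, hpos[1, ], FALSE, min_dist) &&
          insertion_ok(grid, hpos[2, ], FALSE, min_dist)) {
        rows <- (3L * (i - 1L) + 1L):(3L * i)
        out[rows, ] <- rbind(p, hpos)
        grid_add(grid, rbind(p, hpos), c(TRUE, FALSE, FALSE))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(sprintf("failed to insert water %d of %d after %d attempts",
                    i, n, max_attempts))
    }
  }
  out
}
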