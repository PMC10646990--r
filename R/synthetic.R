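#' Synthetic noisy SANS curve from the composite model
#'
#' Evaluates [composite_intensity()] on a `q` grid and applies i.i.d.
#' multiplicative Gaussian noise, \eqn{I = I_{model}(1 + \epsilon)},
#' \eqn{\epsilon \sim N(0, f^2)}; the uncertainty column is set to
#' \eqn{f \cdot I_{model}}.
#'
#' @param params A [sans_model_params()].
#' @param q Momentum-transfer grid, \eqn{\AA^{-1}}.
#' @param noise_fraction Relative noise level `f` (0 gives the exact model).
#' @param seed Integer seed (the generator is deterministic for fixed seed).
#' @param model Optional precomputed model curve on `q` (from
#'   [composite_intensity()]); supplying it avoids re-evaluating the model
#'   when many noise realizations of one parameter set are needed.
#' @return A [scattering_curve()] in \eqn{cm^{-1}}.
#' @export
synth_sans_curve <- function(params, q, noise_fraction = 0.01, seed = 1,
                             model = NULL) {
  stopifnot(noise_fraction >= 0)
  if (is.null(model)) model <- composite_intensity(q, params)
  stopifnot(nrow(model) == length(q))
  with_preserved_seed(seed, {
    eps <- rnorm(length(q), 0, noise_fraction)
    scattering_curve(model$q, model$intensity * (1 + eps),
                     sigma = if (noise_fraction > 0)
                       noise_fraction * model$intensity else NA_real_,
                     unit_tag = curve_unit(model))
  })
}

#' Synthetic orientation-biased hydration shell
#'
#' Places `n_waters` rigid 3-site waters around a single site at the box
#' center, with oxygen distances drawn from a Gaussian and orientations
#' controlled by the bias \eqn{\omega \in [-1, 1]}: with probability
#' \eqn{|\omega|} the water adopts the ideal orientation (for
#' \eqn{\omega > 0} one OH bond points straight at the site - the perfect
#' acceptor environment; for \eqn{\omega < 0} the dipole points straight
#' away, both hydrogens anti - the perfect donor environment), otherwise the
#' radially neutral orientation in which both hydrogens sit at exactly the
#' oxygen's distance from the site (dipole tilted just past tangential,
#' random azimuth). The neutral choice - rather than a uniformly random
#' rotation - is what makes "no orientational bias" actually recover
#' \eqn{\Delta = 0}: a uniformly rotated rigid water puts its hydrogen
#' density per volume \eqn{\propto 1/s} across the whole \eqn{[r-1, r+1]}
#' shell, so the first X-Hw peak would sit near \eqn{r - 1} and mimic a
#' strong acceptor even with no bias. With this parameterization all three
#' anchor points (\eqn{\omega = -1, 0, +1 \to \Delta = -1, 0, +1}) are
#' realized exactly and the recovered index is a monotone (step-like)
#' function of \eqn{\omega}.
#'
#' @param n_waters Number of waters.
#' @param omega Orientation bias in `[-1, 1]`.
#' @param seed Integer seed.
#' @param site_label Label of the central site.
#' @param site_element,site_charge Element / charge of the central site.
#' @param r_mean,r_sd Gaussian radial distance of the water oxygen from the
#'   site, \eqn{\AA} (defaults: a typical 2.8 \eqn{\AA} hydrogen-bond
#'   distance with a tight 0.1 \eqn{\AA} spread).
#' @param box_side Cubic box edge, \eqn{\AA}.
#' @return An [atomic_configuration()] with the site plus waters
#'   (labels `Ow`, `Hw`).
#' @export
synth_hydration_shell <- function(n_waters, omega, seed = 1,
                                  site_label = "X", site_element = "O",
                                  site_charge = 0,
                                  r_mean = 2.8, r_sd = 0.1,
                                  box_side = 40) {
  stopifnot(n_waters >= 1L, omega >= -1, omega <= 1, r_mean > 1)
  ctr <- rep(box_side / 2, 3)
  with_preserved_seed(seed, {
    u <- matrix(rnorm(3 * n_waters), ncol = 3)
    u <- u / sqrt(rowSums(u^2))          # random directions site -> oxygen
    rr <- pmax(rnorm(n_waters, r_mean, r_sd), 1.2)
    opos <- sweep(u * rr, 2, ctr, `+`)
    ideal <- runif(n_waters) < abs(omega)
    azim <- runif(n_waters, 0, 2 * pi)
    blocks <- lapply(seq_len(n_waters), function(i) {
      rhat <- u[i, ]
      if (ideal[i] && omega > 0) {
        w <- oriented_water(rhat, mode = "oh_toward", azimuth = azim[i])
      } else if (ideal[i] && omega < 0) {
        w <- oriented_water(rhat, mode = "dipole_away", azimuth = azim[i])
      } else {
        w <- oriented_water(rhat, mode = "neutral", azimuth = azim[i],
                            r = rr[i])
      }
      sweep(w, 2, opos[i, ], `+`)
    })
    xyz <- do.call(rbind, blocks)
    atoms <- tibble::tibble(
      site_label = c(site_label, rep(c("Ow", "Hw", "Hw"), n_waters)),
      element = c(site_element, rep(c("O", "H", "H"), n_waters)),
      x = c(ctr[1], xyz[, 1]), y = c(ctr[2], xyz[, 2]),
      z = c(ctr[3], xyz[, 3]),
      charge = c(site_charge, rep(c(-0.8476, 0.4238, 0.4238), n_waters)),
      exchangeable = c(FALSE, rep(c(FALSE, TRUE, TRUE), n_waters)),
      molecule_id = c(1L, rep(seq_len(n_waters) + 1L, each = 3L))
    )
    atomic_configuration(atoms, box_side)
  })
}

# rigid water with oxygen at origin, oriented relative to the outward unit
# vector rhat (pointing from the site toward the oxygen):
#  - "oh_toward":   one OH bond along -rhat (hydrogen straight at the site)
#  - "dipole_away": HOH bisector along +rhat (both hydrogens anti)
#  - "neutral":     both hydrogens at the oxygen's site distance r, i.e. on
#                   the cone u.rhat = -1/(2r), separated by the HOH angle
oriented_water <- function(rhat, mode, azimuth = 0, r = NULL) {
  theta <- 109.47 * pi / 180
  half <- theta / 2
  basis <- perpendicular_basis(rhat)
  e1 <- cos(azimuth) * basis$e1 + sin(azimuth) * basis$e2
  e2 <- -sin(azimuth) * basis$e1 + cos(azimuth) * basis$e2
  if (mode == "oh_toward") {
    h1 <- -rhat
    h2 <- cos(theta) * (-rhat) + sin(theta) * e1
  } else if (mode == "dipole_away") {
    h1 <- cos(half) * rhat + sin(half) * e1
    h2 <- cos(half) * rhat - sin(half) * e1
  } else {
    cc <- max(-1, -1 / (2 * r))
    s <- sqrt(1 - cc^2)
    # two cone vectors with mutual angle theta
    cdphi <- (cos(theta) - cc^2) / (1 - cc^2)
    cdphi <- max(-1, min(1, cdphi))
    dphi <- acos(cdphi)
    h1 <- cc * rhat + s * (cos(dphi / 2) * e1 + sin(dphi / 2) * e2)
    h2 <- cc * rhat + s * (cos(dphi / 2) * e1 - sin(dphi / 2) * e2)
  }
  rbind(c(0, 0, 0), h1, h2)
}

perpendicular_basis <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- a - sum(a * v) * v
  e1 <- p / sqrt(sum(p^2))
  e2 <- c(v[2] * e1[3] - v[3] * e1[2],
          v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Toy rigid hairpin monomer
#'
#' A deterministic 172-atom geometric stand-in for a capped 10-residue
#' beta-hairpin: two antiparallel strands joined by a turn, lying in the
#' x-y plane (so stacks grow along z), about 22 x 12 \eqn{\AA} across with
#' a thin +-0.8 \eqn{\AA} z-profile. It is *not* a crystal structure - it
#' exists so that stack building, solvation and bookkeeping run at the
#' documented composition. It carries labeled chemistry probes: `YHH`
#' (a tyrosine-hydroxyl-like positively charged hydrogen-bond-donor
#' hydrogen) and `EOE1`/`EOE2` (glutamate-like carboxylate oxygens), with
#' backbone amide hydrogens (`HN`) flagged exchangeable. Partial charges
#' sum to exactly -2 e.
#'
#' @return Atom tibble with the columns of [atomic_configuration()] and a
#'   total charge of -2 e.
#' @export
toy_hairpin_monomer <- function() {
  # backbone: 2 strands x 20 nodes (y: -9.5..9.5), turn arc of 6 nodes
  strand_y <- seq(-9.5, 9.5, by = 1.0)
  bb <- rbind(
    cbind(x = -2.25, y = strand_y, z = 0),
    cbind(x = 2.25, y = rev(strand_y), z = 0),
    cbind(x = 2.25 * cos(seq(0, pi, length.out = 6)),
          y = 10.6 + 1.2 * sin(seq(0, pi, length.out = 6)), z = 0)
  )
  nb <- nrow(bb)  # 46 backbone nodes
  # decorate: three satellites per backbone node -> 46 * 3 = 138; 138+46 > 172,
  # so trim satellites from the turn region to land exactly on 172 atoms
  sat_off <- rbind(c(-0.9, 0.25, 0.8), c(0.9, -0.25, 0.8), c(0, 0.55, -0.8))
  keep <- rep(TRUE, nb * 3)
  n_excess <- nb * 4 - 172          # 12 satellites to drop
  drop_nodes <- order(bb[, "y"], decreasing = TRUE)[seq_len(ceiling(n_excess / 3))]
  drop_idx <- as.vector(outer(seq_len(3), (drop_nodes - 1) * 3, `+`))
  keep[drop_idx[seq_len(n_excess)]] <- FALSE
  sats <- do.call(rbind, lapply(seq_len(nb), function(i) {
    sweep(sat_off, 2, bb[i, ], `+`)
  }))[keep, ]
  xyz <- rbind(bb, sats)
  n <- nrow(xyz)
  stopifnot(n == 172L)
  elem <- rep("C", n)
  lab <- rep("CA", n)
  # backbone pattern: alternate amide N (with exchangeable H sat) and carbonyl
  elem[seq(1, nb, by = 2)] <- "N"
  lab[seq(1, nb, by = 2)] <- "N"
  elem[seq(2, nb, by = 2)] <- "C"
  lab[seq(2, nb, by = 2)] <- "CA"
  sat_elem <- rep(c("H", "O", "H"), length.out = n - nb)
  sat_lab <- rep(c("HN", "O", "HA"), length.out = n - nb)
  elem[(nb + 1):n] <- sat_elem
  lab[(nb + 1):n] <- sat_lab
  # chemistry probes: donor-like hydroxyl hydrogen and acceptor-like oxygens
  lab[nb + 1] <- "YHH"; elem[nb + 1] <- "H"
  lab[nb + 2] <- "EOE1"; elem[nb + 2] <- "O"
  lab[nb + 5] <- "EOE2"; elem[nb + 5] <- "O"
  charge <- rep(0, n)
  charge[lab == "N"] <- -0.40
  charge[lab == "CA"] <- 0.25
  charge[lab == "HN"] <- 0.30
  charge[lab == "O"] <- -0.45
  charge[lab == "YHH"] <- 0.43
  charge[lab %in% c("EOE1", "EOE2")] <- -0.80
  # absorb the remainder into the HA sites so the total is exactly -2 e
  ha <- which(lab == "HA")
  charge[ha] <- (-2 - sum(charge[-ha])) / length(ha)
  tibble::tibble(
    site_label = lab, element = elem,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = charge,
    exchangeable = lab %in% c("HN", "YHH"),
    molecule_id = 1L
  )
}

#' Reference solvated two-stack box
#'
#' Builds the full reference configuration at the documented composition:
#' two stacks of seven [toy_hairpin_monomer()] copies (8.5 \eqn{\AA}
#' spacing, built with [build_stack_mc()]) in a cubic box of side 61.506
#' \eqn{\AA}, hydrated with 6944 waters and 28 Na+ counterions - 23268
#' atoms at 0.100 atoms/\eqn{\AA^3} and zero net charge.
#'
#' @param seed Integer seed.
#' @param n_mc_iter Monte Carlo moves per stack build (pass a smaller value
#'   for quick smoke runs).
#' @return An [atomic_configuration()].
#' @export
synth_reference_config <- function(seed = 1, n_mc_iter = 1400L) {
  mono <- toy_hairpin_monomer()
  s1 <- build_stack_mc(mono, n_units = 7, target_spacing = 8.5,
                       seed = seed, n_iter = n_mc_iter)
  s2 <- build_stack_mc(mono, n_units = 7, target_spacing = 8.5,
                       seed = seed + 1L, n_iter = n_mc_iter)
  solvate_box(list(s1, s2), n_waters = 6944, n_counterions = 28,
              box_side = 61.506, seed = seed + 2L)
}
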