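#' Percus-Yevick hard-sphere structure factor
#'
#' Closed-form (Ashcroft-Lekner) structure factor of the Percus-Yevick
#' hard-sphere fluid, used as the zero-charge limit reference for
#' [charged_structure_factor()].
#'
#' @param q Momentum transfer, \eqn{\AA^{-1}} (vector).
#' @param phi Hard-sphere volume fraction in `(0, 0.74)`.
#' @param diameter Hard-sphere diameter, \eqn{\AA}.
#' @return Numeric vector of \eqn{S(q)} values.
#' @export
hard_sphere_sq <- function(q, phi, diameter) {
  stopifnot(phi > 0, phi < 0.74, diameter > 0)
  s <- q * diameter
  eta <- phi
  a <- (1 + 2 * eta)^2 / (1 - eta)^4
  b <- -6 * eta * (1 + eta / 2)^2 / (1 - eta)^4
  g <- eta * (1 + 2 * eta)^2 / (2 * (1 - eta)^4)
  t1 <- t2 <- t3 <- numeric(length(s))
  big <- s > 0.05
  sb <- s[big]
  t1[big] <- (sin(sb) - sb * cos(sb)) / sb^3
  t2[big] <- (2 * sb * sin(sb) + (2 - sb^2) * cos(sb) - 2) / sb^4
  t3[big] <- (-sb^4 * cos(sb) +
                4 * ((3 * sb^2 - 6) * cos(sb) +
                       (sb^3 - 6 * sb) * sin(sb) + 6)) / sb^6
  if (any(!big)) {
    ss <- s[!big]
    t1[!big] <- 1 / 3 - ss^2 / 30
    t2[!big] <- 1 / 4 - ss^2 / 36
    t3[!big] <- 1 / 6 - ss^2 / 48
  }
  rho_c <- -24 * eta * (a * t1 + b * t2 + g * t3)
  1 / (1 - rho_c)
}

#' Debye screening length from ionic strength
#'
#' \eqn{\kappa^2 = 4\pi \lambda_B \sum_i \rho_i z_i^2} with the Bjerrum length
#' \eqn{\lambda_B = e^2/(4\pi\varepsilon_0 \varepsilon_r k_B T)}; for a 1:1
#' electrolyte at ionic strength `I` the ion number density sum is
#' \eqn{2 I N_A \times 10^{-27}} \eqn{\AA^{-3}}.
#'
#' @param ionic_strength Ionic strength, mol/L.
#' @param temperature Temperature, K.
#' @param dielectric Relative dielectric constant of the solvent.
#' @return Inverse screening length \eqn{\kappa}, \eqn{\AA^{-1}}.
#' @export
debye_kappa <- function(ionic_strength, temperature = 298,
                        dielectric = 78) {
  lb <- bjerrum_length(temperature, dielectric)
  n_ion <- 2 * ionic_strength * 6.02214076e23 * 1e-27   # ions / A^3
  sqrt(4 * pi * lb * n_ion)
}

#' @rdname debye_kappa
#' @return `bjerrum_length()`: the Bjerrum length, \eqn{\AA}.
#' @export
bjerrum_length <- function(temperature = 298, dielectric = 78) {
  e <- 1.602176634e-19
  eps0 <- 8.8541878128e-12
  kb <- 1.380649e-23
  # e^2/(4 pi eps0 eps_r kB T) in m, converted to A
  e^2 / (4 * pi * eps0 * dielectric * kb * temperature) * 1e10
}

# DST-I of f over i = 1..N: F_j = sum_i f_i sin(pi i j / (N + 1)),
# computed with a length-2(N+1) FFT.
dst1 <- function(f) {
  n <- length(f)
  y <- c(0, f, 0, -rev(f))
  -Im(fft(y))[2:(n + 1)] / 2
}

# Ornstein-Zernike solver with the MSA closure on a hard core plus tail:
#   h(r) = -1          for r < d,
#   c(r) = -beta_u(r)  for r >= d.
# Picard iteration on gamma = h - c using discrete sine transforms; grids are
# tied to the core so that d falls exactly on a node. Returns the solution on
# the internal q grid plus the contact value g(d+).
solve_oz_msa <- function(rho, d, beta_u, m_core = 128L, n_grid = 4095L,
                         mix = 0.5, tol = 1e-9, maxit = 20000L) {
  dr <- d / m_core
  r <- dr * seq_len(n_grid)
  dq <- pi / ((n_grid + 1) * dr)
  q <- dq * seq_len(n_grid)
  core <- r < d - 1e-9 * d
  c_tail_full <- -beta_u(r)
  fwd <- 4 * pi * dr / q     # prefactor: f(r) -> fhat(q)
  inv <- dq / (2 * pi^2 * r) # prefactor: fhat(q) -> f(r)
  make_step <- function(c_tail) {
    function(gam) {
      cr <- c_tail
      cr[core] <- -1 - gam[core]
      # c(r) jumps at the core edge; sampling the node at r = d with the mean
      # of its one-sided limits keeps the transform second-order accurate
      cr[m_core] <- ((-1 - gam[m_core]) + c_tail[m_core]) / 2
      chat <- fwd * dst1(r * cr)
      ghat <- rho * chat^2 / (1 - rho * chat)
      list(gam = inv * dst1(q * ghat), chat = chat, cr = cr)
    }
  }
  # Picard iteration with Ng (depth-2 Anderson) acceleration; the rare very
  # strong couplings are reached by ramping the potential amplitude upward,
  # warm-starting gamma at each rung
  iterate <- function(gam, step, alpha, budget) {
    res <- Inf
    fg1 <- fg2 <- d1 <- d2 <- NULL
    for (it in seq_len(budget)) {
      fg <- step(gam)$gam
      d <- fg - gam
      res_new <- max(abs(d))
      if (!is.finite(res_new)) return(list(gam = gam, res = Inf))
      if (res_new < tol) return(list(gam = fg, res = res_new))
      gam_new <- NULL
      if (!is.null(d2)) {
        e1 <- d - d1; e2 <- d - d2
        a11 <- sum(e1 * e1); a12 <- sum(e1 * e2); a22 <- sum(e2 * e2)
        b1 <- sum(d * e1); b2 <- sum(d * e2)
        det <- a11 * a22 - a12^2
        if (is.finite(det) && abs(det) > 1e-300) {
          c1 <- (b1 * a22 - b2 * a12) / det
          c2 <- (b2 * a11 - b1 * a12) / det
          cand <- (1 - c1 - c2) * fg + c1 * fg1 + c2 * fg2
          if (all(is.finite(cand))) gam_new <- cand
        }
      }
      if (is.null(gam_new)) gam_new <- gam + alpha * d
      if (res_new > 10 * res) {  # diverging: damp down and forget history
        alpha <- max(0.02, alpha * 0.5)
        gam_new <- gam + alpha * d
        fg1 <- fg2 <- d1 <- d2 <- NULL
      } else {
        fg2 <- fg1; fg1 <- fg
        d2 <- d1; d1 <- d
      }
      res <- res_new
      gam <- gam_new
    }
    list(gam = gam, res = res)
  }
  gam <- numeric(n_grid)
  ramps <- 1
  if (max(abs(c_tail_full[!core])) > 20) ramps <- c(0.3, 1)
  out <- NULL
  for (fr in ramps) {
    st_fn <- make_step(fr * c_tail_full)
    out <- iterate(gam, st_fn, mix, maxit %/% length(ramps))
    gam <- out$gam
  }
  if (!is.finite(out$res) || out$res >= tol * 100) {
    abort(sprintf(
      "MSA solver did not converge (residual %.2e; rho=%.3g, d=%.3g)",
      out$res, rho, d))
  }
  c_tail <- c_tail_full
  st <- make_step(c_tail)(gam)
  hq <- st$chat / (1 - rho * st$chat)
  sq <- 1 + rho * hq
  hr <- gam + st$cr
  # contact value just outside the core (tail branch of c at r = d)
  g_contact <- 1 + gam[m_core] + c_tail[m_core]
  list(q = q, s = sq, r = r, g = 1 + hr, g_contact = g_contact)
}

#' Screened-Coulomb (rescaled MSA) structure factor
#'
#' Structure factor of charged spheres interacting through a hard core plus
#' screened-Coulomb (Yukawa/DLVO) repulsion,
#' \deqn{\beta u(r) = \frac{Z^2 \lambda_B}{(1 + \kappa d/2)^2}
#'   \frac{e^{-\kappa (r - d)}}{r}, \quad r > d,}
#' solved in the mean spherical approximation by numerical Ornstein-Zernike
#' iteration. When the plain MSA yields an unphysical negative contact value
#' of \eqn{g(r)} (dilute, highly charged systems) the hard core is rescaled
#' downward at fixed density and potential until \eqn{g(d'^+) = 0}, the
#' standard rescaled-MSA prescription. At `charge = 0` the closure reduces
#' exactly to Percus-Yevick hard spheres.
#'
#' @param q Momentum transfer, \eqn{\AA^{-1}} (vector).
#' @param phi Volume fraction of the spheres, in `(0, 0.5]`.
#' @param charge Sphere charge `Z`, e (sign irrelevant).
#' @param diameter Effective hard-core diameter, \eqn{\AA}.
#' @param ionic_strength Ionic strength, mol/L.
#' @param temperature Temperature, K.
#' @param dielectric Relative dielectric constant.
#' @param m_core,n_grid Solver resolution: nodes per core diameter and total
#'   radial nodes.
#' @return Numeric vector of \eqn{S_{ER}(q) > 0}.
#' @export
charged_structure_factor <- function(q, phi, charge, diameter,
                                     ionic_strength = 0.25,
                                     temperature = 298, dielectric = 78,
                                     m_core = 128L, n_grid = 4095L) {
  stopifnot(diameter > 0)
  if (phi <= 0 || phi > 0.5) abort("phi must be in (0, 0.5]")
  if (phi < 1e-7) return(rep(1, length(q)))
  rho <- 6 * phi / (pi * diameter^3)
  kap <- debye_kappa(ionic_strength, temperature, dielectric)
  lb <- bjerrum_length(temperature, dielectric)
  amp <- charge^2 * lb / (1 + kap * diameter / 2)^2
  sol <- solve_for_core(rho, diameter, amp, kap, m_core, n_grid)
  interp_sq(sol, q)
}

solve_for_core <- function(rho, d0, amp, kap, m_core, n_grid) {
  beta_u_for <- function(d) {
    force(d)
    function(r) amp * exp(-kap * (r - d0)) / r
  }
  sol <- solve_oz_msa(rho, d0, beta_u_for(d0), m_core, n_grid)
  if (sol$g_contact >= 0 || amp == 0) return(sol)
  # rescaled MSA: under strong repulsion the physical g(r) vanishes well
  # beyond the nominal core, so grow the effective core (same density, same
  # potential tail) until the contact value of g is exactly zero
  phi_of <- function(s) pi * rho * (s * d0)^3 / 6
  contact <- function(s) {
    solve_oz_msa(rho, s * d0, beta_u_for(s * d0), m_core, n_grid)$g_contact
  }
  hi <- 1.1
  while (contact(hi) < 0 && phi_of(hi * 1.1) < 0.7) hi <- hi * 1.1
  if (contact(hi) < 0) {
    abort("rescaled MSA found no physical core size; parameters look extreme")
  }
  s_star <- uniroot(contact, c(1, hi), tol = 1e-4)$root
  solve_oz_msa(rho, s_star * d0, beta_u_for(s_star * d0), m_core, n_grid)
}

interp_sq <- function(sol, q) {
  sf <- splinefun(sol$q, sol$s, method = "natural")
  out <- sf(q)
  out[q > max(sol$q)] <- 1
  pmax(out, 1e-8)
}

#' Equal-volume-sphere effective diameter of a cylinder
#'
#' Diameter of the sphere whose volume equals that of an elliptical cylinder,
#' used to map cylinder geometry onto the structure-factor hard core.
#'
#' @param length_a Cylinder length, \eqn{\AA}.
#' @param r_minor,r_major Cross-section semi-axes, \eqn{\AA}.
#' @return Diameter, \eqn{\AA}.
#' @export
equivalent_sphere_diameter <- function(length_a, r_minor, r_major) {
  v <- pi * r_minor * r_major * length_a
  2 * (3 * v / (4 * pi))^(1 / 3)
}
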