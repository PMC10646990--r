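#' Momentum transfer from diffraction geometry
#'
#' For elastic scattering the momentum transfer is
#' \eqn{Q = 4\pi \sin\theta / \lambda}, where \eqn{2\theta} is the scattering
#' angle and \eqn{\lambda} the neutron wavelength.
#'
#' @param wavelength Neutron wavelength \eqn{\lambda}, \eqn{\AA}, positive.
#' @param two_theta Scattering angle \eqn{2\theta}, degrees, in `(0, 180]`.
#' @return Momentum transfer, \eqn{\AA^{-1}}.
#' @examples
#' q_from_geometry(2 * pi, 60) # sin(30 deg) = 1/2 -> Q = 1
#' @export
q_from_geometry <- function(wavelength, two_theta) {
  stopifnot(is.numeric(wavelength), is.numeric(two_theta))
  if (any(wavelength <= 0)) abort("wavelength must be positive")
  if (any(two_theta <= 0 | two_theta > 180)) {
    abort("scattering angle 2*theta must be in (0, 180] degrees")
  }
  4 * pi * sin(two_theta / 2 * pi / 180) / wavelength
}

#' Bragg repeat distance from momentum transfer
#'
#' The distance between repeated layers is inversely related to the peak
#' position: \eqn{d = 2\pi/Q}. The map is an involution, so the same formula
#' converts a real-space repeat back to `q` (see [q_from_d()]).
#'
#' @param q Momentum transfer, \eqn{\AA^{-1}}, positive.
#' @return Repeat distance, \eqn{\AA}.
#' @examples
#' d_from_q(0.45) # ~14 A, lower end of a typical SANS window
#' @export
d_from_q <- function(q) {
  stopifnot(is.numeric(q))
  if (any(!is.finite(q)) || any(q <= 0)) abort("q must be positive")
  2 * pi / q
}

#' @rdname d_from_q
#' @param d Repeat distance, \eqn{\AA}, positive.
#' @export
q_from_d <- function(d) d_from_q(d)

#' Solute molarity from a solute:solvent mole ratio
#'
#' Converts a mole ratio (e.g. 1 solute per 500 waters) to molar
#' concentration using the molarity of the pure solvent.
#'
#' @param ratio Solute:solvent mole ratio (solute moles per solvent mole).
#' @param solvent_molarity Molarity of the pure solvent; defaults to 55.5 M
#'   (water).
#' @return Concentration, mol/L.
#' @examples
#' molar_from_mole_ratio(1 / 500) # 0.111 M = 111 mM
#' @export
molar_from_mole_ratio <- function(ratio, solvent_molarity = 55.5) {
  stopifnot(ratio >= 0, solvent_molarity > 0)
  ratio * solvent_molarity
}

# Bound coherent neutron scattering lengths, fm (Sears, Neutron News 3 (1992) 26).
NEUTRON_B <- c(H = -3.7390, D = 6.671, C = 6.6460, N = 9.36, O = 5.803,
               Na = 3.63)

#' Coherent neutron scattering lengths
#'
#' Tabulated bound coherent scattering lengths for the supported elements,
#' in fm.
#'
#' @return Named numeric vector (H, D, C, N, O, Na), fm.
#' @export
neutron_scattering_lengths <- function() NEUTRON_B

#' Effective scattering length under H/D exchange
#'
#' Exchangeable hydrogens equilibrate with the solvent hydrogen pool, so in a
#' solvent with deuterium fraction `x_d` they scatter with the population
#' average \eqn{(1-x_D) b_H + x_D b_D}. Non-exchangeable sites keep their
#' tabulated coherent scattering length.
#'
#' @param element Element symbol(s), from H, D, C, N, O, Na.
#' @param exchangeable Logical: does the site exchange with solvent hydrogen?
#' @param x_d Solvent deuterium fraction in `[0, 1]`.
#' @return Scattering length(s), fm.
#' @export
effective_scattering_length <- function(element, exchangeable, x_d) {
  stopifnot(is.numeric(x_d), all(x_d >= 0 & x_d <= 1))
  bad <- setdiff(unique(element), names(NEUTRON_B))
  if (length(bad)) abort(paste0("unsupported element(s): ",
                                paste(bad, collapse = ", ")))
  b <- unname(NEUTRON_B[element])
  mix <- (1 - x_d) * NEUTRON_B[["H"]] + x_d * NEUTRON_B[["D"]]
  ifelse(as.logical(exchangeable) & element %in% c("H", "D"), mix, b)
}

#' Build a composition table
#'
#' Per-atom-type number fractions, elements and exchangeable flags, together
#' with the solvent deuterium fraction and atomic number density: everything
#' needed to weight partial structure factors into a total intensity.
#'
#' @param type Atom-type labels (must match the pair labels of the partial
#'   structure factors they will weight).
#' @param element Element symbol per type.
#' @param fraction Number fraction per type; must sum to 1.
#' @param exchangeable Logical per type.
#' @param x_d Solvent deuterium fraction in `[0, 1]`.
#' @param rho Atomic number density, atoms/\eqn{\AA^3}.
#' @return A tibble of class `composition_table` with attributes `x_d`, `rho`.
#' @export
composition_table <- function(type, element, fraction,
                              exchangeable = FALSE, x_d = 0, rho = 0.1) {
  stopifnot(length(type) == length(element),
            length(fraction) == length(type))
  if (abs(sum(fraction) - 1) > 1e-12) abort("fractions must sum to 1")
  if (rho <= 0) abort("number density must be positive")
  if (x_d < 0 || x_d > 1) abort("x_d must be in [0, 1]")
  out <- tibble::tibble(
    type = as.character(type), element = as.character(element),
    fraction = as.numeric(fraction),
    exchangeable = rep_len(as.logical(exchangeable), length(type)),
    b = effective_scattering_length(element,
                                    rep_len(as.logical(exchangeable),
                                            length(type)), x_d)
  )
  attr(out, "x_d") <- x_d
  attr(out, "rho") <- rho
  class(out) <- unique(c("composition_table", class(tibble::tibble())))
  out
}

#' Partial structure factor from a radial distribution function
#'
#' Fourier (sine) transform of a single site-site RDF:
#' \deqn{S_{\alpha\beta}(q) = \rho \int_0^{r_{max}} 4\pi r^2
#'   [g_{\alpha\beta}(r) - 1] \frac{\sin qr}{qr}\, dr,}
#' evaluated by trapezoidal quadrature on the (uniform) `r` grid. The self
#' (unity) term is excluded, so \eqn{S \to 0} at high `q` and the weighted sum
#' over pairs is a pure interference term. An optional Lorch-style taper
#' window \eqn{\sin(\pi r/r_{max})/(\pi r/r_{max})} damps truncation ripple.
#'
#' @param rdf Tibble with columns `r` (\eqn{\AA}, uniform grid) and `g`.
#' @param rho Atomic number density, atoms/\eqn{\AA^3}.
#' @param q Output momentum-transfer grid, \eqn{\AA^{-1}}; `q = 0` is handled
#'   by the \eqn{\sin(qr)/(qr) \to 1} limit.
#' @param window `"none"` (default) or `"lorch"`.
#' @return Tibble with columns `q` and `s`.
#' @export
sq_from_gr <- function(rdf, rho, q, window = c("none", "lorch")) {
  window <- match.arg(window)
  r <- rdf$r
  h <- rdf$g - 1
  check_uniform(r, "r")
  if (window == "lorch") {
    x <- pi * r / max(r)
    w <- ifelse(x == 0, 1, sin(x) / x)
    h <- h * w
  }
  dr <- r[2] - r[1]
  # trapezoid weights on the uniform grid
  wt <- rep(dr, length(r)); wt[c(1, length(r))] <- dr / 2
  kern <- outer(q, r, function(qq, rr) {
    x <- qq * rr
    ifelse(x == 0, 1, sin(x) / x)
  })
  s <- as.numeric(kern %*% (4 * pi * r^2 * h * wt)) * rho
  tibble::tibble(q = q, s = s)
}

#' Radial distribution function from a partial structure factor
#'
#' Inverse sine transform, the reciprocal of [sq_from_gr()]:
#' \deqn{g_{\alpha\beta}(r) = 1 + \frac{1}{2\pi^2 \rho} \int_0^{q_{max}} q^2
#'   S_{\alpha\beta}(q) \frac{\sin qr}{qr}\, dq.}
#'
#' @param psf Tibble with columns `q` (uniform grid) and `s`.
#' @param rho Atomic number density, atoms/\eqn{\AA^3}.
#' @param r Output distance grid, \eqn{\AA}.
#' @param window `"none"` (default) or `"lorch"` taper in `q`.
#' @return Tibble with columns `r` and `g`.
#' @export
gr_from_sq <- function(psf, rho, r, window = c("none", "lorch")) {
  window <- match.arg(window)
  q <- psf$q
  s <- psf$s
  check_uniform(q, "q")
  if (window == "lorch") {
    x <- pi * q / max(q)
    s <- s * ifelse(x == 0, 1, sin(x) / x)
  }
  dq <- q[2] - q[1]
  wt <- rep(dq, length(q)); wt[c(1, length(q))] <- dq / 2
  kern <- outer(r, q, function(rr, qq) {
    x <- qq * rr
    ifelse(x == 0, 1, sin(x) / x)
  })
  g <- 1 + as.numeric(kern %*% (q^2 * s * wt)) / (2 * pi^2 * rho)
  tibble::tibble(r = r, g = g)
}

check_uniform <- function(x, what) {
  if (length(x) < 3L) abort(paste0(what, " grid too short"))
  dx <- diff(x)
  if (any(dx <= 0) || (max(dx) - min(dx)) > 1e-8 * max(abs(dx))) {
    abort(paste0(what, " grid must be uniform and increasing"))
  }
  invisible(TRUE)
}

#' Total scattering intensity from partial structure factors
#'
#' Weighted sum over unordered atom-type pairs,
#' \deqn{I(q) = \sum_{\alpha \le \beta} (2 - \delta_{\alpha\beta})
#'   c_\alpha c_\beta b_\alpha b_\beta S_{\alpha\beta}(q),}
#' with effective scattering lengths from the composition table, so the same
#' set of partials predicts distinct H2O / HDO / D2O contrasts once the
#' solvent deuterium fraction changes the exchangeable-hydrogen weights.
#'
#' @param psf Long tibble with columns `q`, `s` and `pair`, where `pair` is
#'   `"alpha-beta"` joining two type labels of `comp`.
#' @param comp A [composition_table()].
#' @param convert_to_barns Multiply by \eqn{10^{-2}} (the \eqn{fm^2}-to-barn
#'   factor) so that scattering lengths tabulated in fm yield intensities in
#'   barns/sr/atom. Off by default: the plain weighted sum carries the square
#'   of whatever unit `b` is in.
#' @return A [scattering_curve()] (unit tag `barns/sr/atom`).
#' @export
total_iq_from_partials <- function(psf, comp, convert_to_barns = FALSE) {
  stopifnot(all(c("q", "s", "pair") %in% names(psf)))
  pairs <- unique(psf$pair)
  split_pairs <- strsplit(pairs, "-", fixed = TRUE)
  if (any(lengths(split_pairs) != 2L)) {
    abort("pair labels must be 'alpha-beta'")
  }
  types <- unique(unlist(split_pairs))
  missing_types <- setdiff(types, comp$type)
  if (length(missing_types)) {
    abort(paste0("composition table missing type(s): ",
                 paste(missing_types, collapse = ", ")))
  }
  cb <- setNames(comp$fraction * comp$b, comp$type)
  w <- vapply(split_pairs, function(p) {
    (2 - (p[1] == p[2])) * cb[[p[1]]] * cb[[p[2]]]
  }, numeric(1))
  names(w) <- pairs
  unit_factor <- if (convert_to_barns) 1e-2 else 1
  out <- psf |>
    dplyr::mutate(wi = w[.data$pair] * .data$s * unit_factor) |>
    dplyr::group_by(.data$q) |>
    dplyr::summarise(intensity = sum(.data$wi), .groups = "drop")
  scattering_curve(out$q, out$intensity, unit_tag = "barns/sr/atom")
}

#' Pair weights of the total-intensity sum
#'
#' The concentration/scattering-length weights
#' \eqn{(2-\delta_{\alpha\beta}) c_\alpha c_\beta b_\alpha b_\beta} for every
#' unordered pair of types in a composition table. Their sum equals
#' \eqn{(\sum_\alpha c_\alpha b_\alpha)^2}.
#'
#' @param comp A [composition_table()].
#' @return Tibble with columns `pair`, `weight` (fm^2).
#' @export
pair_weights <- function(comp) {
  n <- nrow(comp)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  cb <- comp$fraction * comp$b
  tibble::tibble(
    pair = paste(comp$type[idx[, 1]], comp$type[idx[, 2]], sep = "-"),
    weight = (2 - (idx[, 1] == idx[, 2])) * cb[idx[, 1]] * cb[idx[, 2]]
  )
}
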