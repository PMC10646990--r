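#' Orientationally averaged elliptical-cylinder form factor
#'
#' Normalized single-particle form factor \eqn{P_{EC}(q)} of a right cylinder
#' of length `L` with elliptical cross section (semi-axes `r_minor`,
#' `r_major`), averaged over orientations:
#' \deqn{P(q) = \int_0^{\pi/2}\!\! \sin\alpha \, d\alpha \;
#'   \frac{2}{\pi}\int_0^{\pi/2}\!\! d\psi\; A^2(q, \alpha, \psi),}
#' \deqn{A = \frac{\sin(qL\cos\alpha/2)}{qL\cos\alpha/2} \cdot
#'   \frac{2 J_1(q \rho(\psi) \sin\alpha)}{q \rho(\psi) \sin\alpha},
#'   \quad \rho(\psi) = \sqrt{r_{major}^2 \sin^2\psi +
#'                            r_{minor}^2 \cos^2\psi}.}
#' \eqn{\alpha} is the angle between the cylinder axis and `q`, \eqn{\psi}
#' the azimuth of `q` in the cross-section plane. The average uses fixed-order
#' Gauss-Legendre quadrature in both angles; \eqn{P(0) = 1}.
#'
#' @param q Momentum transfer, \eqn{\AA^{-1}}, non-negative (vector).
#' @param length_a Cylinder length, \eqn{\AA}.
#' @param r_minor,r_major Cross-section semi-axes, \eqn{\AA},
#'   `r_major >= r_minor`.
#' @param n_alpha,n_psi Gauss-Legendre orders for the polar and azimuthal
#'   averages.
#' @return Numeric vector of \eqn{P_{EC}(q)} values in `(0, 1]`.
#' @export
elliptical_cylinder_form_factor <- function(q, length_a, r_minor, r_major,
                                            n_alpha = 76L, n_psi = 24L) {
  stopifnot(length_a > 0, r_minor > 0, r_major >= r_minor)
  if (any(q < 0)) abort("q must be non-negative")
  ga <- gauss_legendre_01(n_alpha)   # alpha/(pi/2) in [0,1]
  gp <- gauss_legendre_01(n_psi)
  alpha <- ga$x * pi / 2
  psi <- gp$x * pi / 2
  rho <- sqrt(r_major^2 * sin(psi)^2 + r_minor^2 * cos(psi)^2)
  # amplitude factorizes: axial(q, alpha) * radial(q, alpha, psi)
  sinc <- function(x) ifelse(abs(x) < 1e-8, 1 - x^2 / 6, sin(x) / x)
  j1c <- function(x) ifelse(abs(x) < 1e-8, 1 - x^2 / 8, 2 * besselJ(x, 1) / x)
  vapply(q, function(qq) {
    ax <- sinc(qq * length_a * cos(alpha) / 2)        # [n_alpha]
    rad <- j1c(outer(qq * sin(alpha), rho))           # [n_alpha, n_psi]
    inner <- as.numeric((rad^2) %*% gp$w)             # azimuth average
    sum(ga$w * (pi / 2) * sin(alpha) * ax^2 * inner)
  }, numeric(1))
}

# Gauss-Legendre nodes/weights on [0, 1]; weights of the psi rule are
# normalized to average (sum w = 1), the alpha rule keeps measure d(alpha).
gauss_legendre_01 <- function(n) {
  gl <- gauss_legendre_cache(n)
  list(x = (gl$x + 1) / 2, w = gl$w / 2)
}

the_gl_cache <- new.env(parent = emptyenv())

gauss_legendre_cache <- function(n) {
  key <- as.character(n)
  if (!is.null(the_gl_cache[[key]])) return(the_gl_cache[[key]])
  # Golub-Welsch: eigen-decomposition of the Jacobi matrix on [-1, 1]
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  res <- list(x = x[ord], w = w[ord])
  the_gl_cache[[key]] <- res
  res
}
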