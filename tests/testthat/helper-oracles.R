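# Independent oracles used across test files. These deliberately use
# different algorithms (plain loops, closed forms, Monte Carlo) from the
# package implementations they check.

# O(N^2) double-loop RDF with explicit minimum-image convention, mirroring
# the estimator definition bin by bin
brute_force_rdf <- function(frames, site_pair, bin_width, r_max) {
  if (inherits(frames, "atomic_configuration")) frames <- list(frames)
  box <- frames[[1]]$box_side
  nbin <- ceiling(r_max / bin_width)
  counts <- numeric(nbin)
  same <- site_pair[1] == site_pair[2]
  n_alpha <- 0; rho_beta <- 0
  for (f in frames) {
    a <- f$atoms
    ia <- which(a$site_label == site_pair[1])
    ib <- which(a$site_label == site_pair[2])
    for (i in ia) {
      for (j in ib) {
        if (i == j) next
        dx <- a$x[i] - a$x[j]; dx <- dx - box * round(dx / box)
        dy <- a$y[i] - a$y[j]; dy <- dy - box * round(dy / box)
        dz <- a$z[i] - a$z[j]; dz <- dz - box * round(dz / box)
        d <- sqrt(dx^2 + dy^2 + dz^2)
        if (d > 0 && d < r_max) {
          k <- min(floor(d / bin_width) + 1, nbin)
          counts[k] <- counts[k] + 1
        }
      }
    }
    n_alpha <- n_alpha + length(ia)
    rho_beta <- rho_beta + (length(ib) - same) / box^3
  }
  nf <- length(frames)
  edges <- bin_width * (0:nbin)
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nbin + 1)]^3)
  g <- counts / ((n_alpha / nf) * (rho_beta / nf) * shell * nf)
  tibble::tibble(r = edges[-(nbin + 1)] + bin_width / 2, g = g)
}

# closed-form circular-cylinder form factor: 1D orientation integral of the
# Bessel-function kernel, via adaptive quadrature
circular_cylinder_pq <- function(q, length_a, radius) {
  vapply(q, function(qq) {
    if (qq == 0) return(1)
    f <- function(alpha) {
      x <- qq * radius * sin(alpha)
      y <- qq * length_a * cos(alpha) / 2
      fr <- ifelse(x < 1e-10, 1, 2 * besselJ(x, 1) / x)
      fa <- ifelse(abs(y) < 1e-10, 1, sin(y) / y)
      (fr * fa)^2 * sin(alpha)
    }
    integrate(f, 0, pi / 2, rel.tol = 1e-10)$value
  }, numeric(1))
}

# Monte Carlo orientational average of the elliptical-cylinder amplitude
mc_elliptical_pq <- function(q, length_a, r_minor, r_major, n = 1e6,
                             seed = 999) {
  set.seed(seed)
  cosa <- runif(n)            # uniform orientation: cos(alpha) ~ U(0,1)
  sina <- sqrt(1 - cosa^2)
  psi <- runif(n, 0, pi / 2)
  rho <- sqrt(r_major^2 * sin(psi)^2 + r_minor^2 * cos(psi)^2)
  sapply(q, function(qq) {
    x <- qq * sina * rho
    y <- qq * length_a * cosa / 2
    fr <- ifelse(x < 1e-10, 1, 2 * besselJ(x, 1) / x)
    fa <- ifelse(abs(y) < 1e-10, 1, sin(y) / y)
    a2 <- (fr * fa)^2
    c(mean = mean(a2), se = sd(a2) / sqrt(n))
  })
}

write_curve_file <- function(lines) {
  path <- tempfile(fileext = ".dat")
  writeLines(lines, path)
  path
}

# small random configuration for oracle comparisons
random_config <- function(n_a, n_b, box, seed = 11) {
  set.seed(seed)
  n <- n_a + n_b
  atomic_configuration(
    tibble::tibble(
      site_label = c(rep("A", n_a), rep("B", n_b)),
      element = "O",
      x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
      charge = 0, exchangeable = FALSE, molecule_id = seq_len(n)
    ),
    box_side = box
  )
}

# all-pairs minimum-image distance matrix (diagonal set to Inf)
minimum_image_matrix <- function(xyz, box) {
  wrap <- function(d) d - box * round(d / box)
  dx <- wrap(outer(xyz[, 1], xyz[, 1], `-`))
  dy <- wrap(outer(xyz[, 2], xyz[, 2], `-`))
  dz <- wrap(outer(xyz[, 3], xyz[, 3], `-`))
  d <- sqrt(dx^2 + dy^2 + dz^2)
  diag(d) <- Inf
  d
}
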