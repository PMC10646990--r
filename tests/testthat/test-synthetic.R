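test_that("synthetic curves are exact at zero noise and seed-reproducible", {
  p <- paper_sans_params()
  q <- exp(seq(log(0.01), log(2), length.out = 80))
  model <- composite_intensity(q, p, sf_m_core = 64L, sf_n_grid = 2047L)
  clean <- synth_sans_curve(p, q, 0, seed = 1, model = model)
  expect_equal(clean$intensity, model$intensity)

  a <- synth_sans_curve(p, q, 0.01, seed = 7, model = model)
  b <- synth_sans_curve(p, q, 0.01, seed = 7, model = model)
  expect_identical(a$intensity, b$intensity)
  c <- synth_sans_curve(p, q, 0.01, seed = 8, model = model)
  expect_false(identical(a$intensity, c$intensity))
  expect_equal(a$sigma, 0.01 * model$intensity)
})

test_that("noise statistics match the requested level and are symmetric", {
  p <- paper_sans_params()
  q <- exp(seq(log(0.01), log(2), length.out = 400))
  model <- composite_intensity(q, p, sf_m_core = 64L, sf_n_grid = 2047L)
  crv <- synth_sans_curve(p, q, 0.01, seed = 2, model = model)
  res <- crv$intensity / model$intensity - 1
  expect_gt(sd(res), 0.008)
  expect_lt(sd(res), 0.012)

  # skewness sanity at 1e4 points (grid recycled to reach 1e4 draws)
  q2 <- exp(seq(log(0.01), log(2), length.out = 1e4))
  model2 <- scattering_curve(q2, rep(1, 1e4))
  big <- synth_sans_curve(p, q2, 0.05, seed = 3, model = model2)
  r2 <- big$intensity - 1
  skew <- mean((r2 - mean(r2))^3) / sd(r2)^3
  expect_lt(abs(skew), 0.3)
})

test_that("shell geometry realizes the index endpoints by construction", {
  acc <- synth_hydration_shell(1500, 1, seed = 5)
  gow <- compute_rdf(acc, c("X", "Ow"), bin_width = 0.05, r_max = 8)
  ghw <- compute_rdf(acc, c("X", "Hw"), bin_width = 0.05, r_max = 8)
  p_ow <- first_shell_peak(gow)
  p_hw <- first_shell_peak(ghw)
  expect_lt(abs((p_ow - p_hw) - 1.0), 0.06)  # the OH bond length

  don <- synth_hydration_shell(1500, -1, seed = 6)
  gow2 <- compute_rdf(don, c("X", "Ow"), bin_width = 0.05, r_max = 8)
  ghw2 <- compute_rdf(don, c("X", "Hw"), bin_width = 0.05, r_max = 8)
  d2 <- first_shell_peak(gow2) - first_shell_peak(ghw2)
  expect_lt(d2, 0)
  # offset is R_acceptor plus a small finite-distance (curvature) excess
  expect_gt(abs(d2), water_r_acceptor() - 0.05)
  expect_lt(abs(d2), water_r_acceptor() + 0.15)

  same <- synth_hydration_shell(100, 0.5, seed = 9)
  same2 <- synth_hydration_shell(100, 0.5, seed = 9)
  expect_identical(same$atoms, same2$atoms)
})

test_that("the toy monomer has the documented size, charge and labels", {
  m <- toy_hairpin_monomer()
  expect_equal(nrow(m), 172)
  expect_equal(sum(m$charge), -2, tolerance = 1e-12)
  expect_true(all(c("YHH", "EOE1", "EOE2") %in% m$site_label))
  expect_true(all(m$element %in% c("H", "C", "N", "O")))
  expect_true(any(m$exchangeable))
  # internally clash-free
  d <- as.matrix(dist(as.matrix(m[, c("x", "y", "z")])))
  diag(d) <- Inf
  expect_gt(min(d), 0.8)
  # planar: thin along the stacking axis
  expect_lt(diff(range(m$z)), diff(range(m$x)))
  expect_lt(diff(range(m$z)), diff(range(m$y)))
})
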