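test_that("form factor is normalized and bounded", {
  q <- c(1e-6, 1e-4, 0.001)
  p <- elliptical_cylinder_form_factor(q, 60, 6.5, 12.6)
  expect_equal(p[1], 1, tolerance = 1e-6)
  qs <- exp(seq(log(1e-3), log(3), length.out = 60))
  pv <- elliptical_cylinder_form_factor(qs, 60, 6.5, 12.6)
  expect_true(all(pv > 0 & pv <= 1 + 1e-12))
})

test_that("equal radii reproduce the circular-cylinder closed form", {
  q <- c(0.02, 0.05, 0.1, 0.3, 0.7, 1.5)
  for (geom in list(c(60, 8), c(25, 4), c(120, 15))) {
    mine <- elliptical_cylinder_form_factor(q, geom[1], geom[2], geom[2])
    oracle <- circular_cylinder_pq(q, geom[1], geom[2])
    expect_equal(mine, oracle, tolerance = 1e-6)
  }
})

test_that("quadrature agrees with a Monte Carlo orientational average", {
  q <- c(0.05, 0.2, 1.0)
  set.seed(31)
  geoms <- list(c(60, 6.5, 12.6), c(40, 5, 9), c(90, 8, 10))
  for (g in geoms) {
    mine <- elliptical_cylinder_form_factor(q, g[1], g[2], g[3])
    mc <- mc_elliptical_pq(q, g[1], g[2], g[3], n = 1e6)
    expect_true(all(abs(mine - mc["mean", ]) <= 3 * mc["se", ] + 1e-9))
  }
})

test_that("low-q envelope decreases monotonically (Guinier region)", {
  q <- seq(0.001, 0.05, by = 0.001)
  p <- elliptical_cylinder_form_factor(q, 60, 6.5, 12.6)
  expect_true(all(diff(p) < 0))
})
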