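test_that("zero charge reduces the MSA solver to Percus-Yevick hard spheres", {
  q <- seq(0.05, 15, by = 0.05)
  for (phi in c(0.1, 0.2, 0.3)) {
    mine <- charged_structure_factor(q, phi, charge = 0, diameter = 1)
    py <- hard_sphere_sq(q, phi, 1)
    expect_lt(max(abs(mine - py) / abs(py)), 1e-3)
  }
})

test_that("PY closed form matches its own q->0 compressibility limit", {
  phi <- 0.25
  s0 <- (1 - phi)^4 / (1 + 2 * phi)^2
  expect_equal(hard_sphere_sq(1e-8, phi, 1), s0, tolerance = 1e-6)
})

test_that("dilute and high-q limits give S = 1", {
  q <- seq(0.01, 2, by = 0.01)
  dil <- charged_structure_factor(q, phi = 1e-6, charge = 14, diameter = 31)
  expect_lt(max(abs(dil - 1)), 1e-3)

  qh <- seq(51 / 31, 3, by = 0.02)  # q * diameter > 50
  high <- charged_structure_factor(qh, phi = 0.11, charge = 14,
                                   diameter = 31)
  expect_lt(max(abs(high - 1)), 1e-2)
})

test_that("charge suppresses low-q structure relative to hard spheres", {
  q <- c(0.01, 0.05)
  neutral <- charged_structure_factor(q, 0.11, charge = 0, diameter = 31)
  charged <- charged_structure_factor(q, 0.11, charge = 14, diameter = 31,
                                      ionic_strength = 0.25)
  expect_true(all(charged < neutral))
  expect_true(all(charged > 0))
})

test_that("screening length follows the Debye formula", {
  # 250 mM 1:1 electrolyte at 298 K in water: ~6.1 A screening length
  kap <- debye_kappa(0.25, 298, 78)
  expect_equal(1 / kap, 6.1, tolerance = 0.02)
  # kappa scales as sqrt(ionic strength)
  expect_equal(debye_kappa(1) / debye_kappa(0.25), 2, tolerance = 1e-10)
})
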