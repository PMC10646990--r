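test_that("momentum transfer follows the elastic-scattering geometry", {
  expect_equal(q_from_geometry(2 * pi, 60), 1, tolerance = 1e-12)
  expect_equal(q_from_geometry(1, 180), 4 * pi, tolerance = 1e-12)
  # hand evaluation of 4 pi sin(14.343 deg)
  expect_equal(q_from_geometry(1, 28.686), 3.1133, tolerance = 1e-4)
  expect_error(q_from_geometry(-1, 60), "positive")
  expect_error(q_from_geometry(1, 0), "angle")
})

test_that("Bragg conversion is an involution with the documented values", {
  expect_equal(d_from_q(0.45), 13.96, tolerance = 1e-3)
  expect_equal(d_from_q(2 * pi), 1)
  expect_equal(d_from_q(0.02), 314.2, tolerance = 1e-3)
  qs <- c(0.003, 0.45, 2, 30)
  expect_equal(q_from_d(d_from_q(qs)), qs, tolerance = 1e-15)
  expect_error(d_from_q(0), "positive")
})

test_that("mole-ratio concentration arithmetic matches the worked value", {
  expect_equal(molar_from_mole_ratio(1 / 500, 55.5), 0.111)
})

test_that("effective scattering lengths mix only for exchangeable hydrogen", {
  b <- neutron_scattering_lengths()
  expect_equal(effective_scattering_length("H", TRUE, 1), b[["D"]])
  expect_equal(effective_scattering_length("H", TRUE, 0.5),
               (b[["H"]] + b[["D"]]) / 2)
  expect_equal(effective_scattering_length("H", FALSE, 0.7), b[["H"]])
  expect_equal(effective_scattering_length("O", TRUE, 0.7), b[["O"]])
  expect_error(effective_scattering_length("Xe", FALSE, 0), "unsupported")
})

test_that("pair weights satisfy the (sum c b)^2 identity for random compositions", {
  set.seed(21)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    fr <- runif(k); fr <- fr / sum(fr)
    els <- sample(c("H", "D", "C", "N", "O", "Na"), k, replace = TRUE)
    comp <- composition_table(paste0("t", 1:k), els, fr,
                              exchangeable = sample(c(TRUE, FALSE), k,
                                                    replace = TRUE),
                              x_d = runif(1))
    expect_equal(sum(pair_weights(comp)$weight),
                 sum(comp$fraction * comp$b)^2, tolerance = 1e-12)
  }
})

test_that("total intensity weights partials by concentration and contrast", {
  q <- seq(0.5, 5, by = 0.5)
  s <- exp(-q)
  one <- composition_table("a", "O", 1)
  one$b <- 1  # unit scattering length makes I identical to S
  psf <- tibble::tibble(q = q, s = s, pair = "a-a")
  out <- total_iq_from_partials(psf, one)
  expect_equal(out$intensity, s)

  two <- composition_table(c("a", "b"), c("O", "O"), c(0.5, 0.5))
  two$b <- c(1, 1)
  cross <- tibble::tibble(q = q, s = s, pair = "a-b")
  out2 <- total_iq_from_partials(cross, two)
  expect_equal(out2$intensity, 0.5 * s)  # 2 * 0.25 * 1 * 1

  expect_error(total_iq_from_partials(cross, one), "missing type")
})

test_that("H2O, HDO and D2O contrasts differ for the same partials", {
  q <- seq(0.1, 10, by = 0.1)
  psf <- dplyr::bind_rows(
    tibble::tibble(q = q, s = 0.5 * sin(q) / q, pair = "Ow-Ow"),
    tibble::tibble(q = q, s = -0.3 * sin(2 * q) / (2 * q), pair = "Ow-Hw"),
    tibble::tibble(q = q, s = 0.2 * cos(q) * exp(-q / 5), pair = "Hw-Hw")
  )
  curves <- lapply(c(0, 0.5, 1), function(xd) {
    comp <- composition_table(c("Ow", "Hw"), c("O", "H"), c(1 / 3, 2 / 3),
                              exchangeable = c(FALSE, TRUE), x_d = xd)
    total_iq_from_partials(psf, comp)$intensity
  })
  expect_false(isTRUE(all.equal(curves[[1]], curves[[2]])))
  expect_false(isTRUE(all.equal(curves[[2]], curves[[3]])))
})
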