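test_that("an ideal gas has zero partial structure factor", {
  r <- seq(0.025, 25, by = 0.05)
  flat <- tibble::tibble(r = r, g = rep(1, length(r)))
  s <- sq_from_gr(flat, rho = 0.1, q = c(0, 0.5, 1, 5, 20))
  expect_equal(s$s, rep(0, 5))
})

test_that("a unit-area shell transforms to sin(qr0)/(qr0)", {
  rho <- 0.05
  dr <- 0.02
  r <- seq(dr, 30, by = dr)
  r0 <- 3
  i0 <- which.min(abs(r - r0))
  g <- rep(1, length(r))
  # single-bin spike carrying unit integral of rho 4 pi r^2 (g-1) dr
  g[i0] <- 1 + 1 / (rho * 4 * pi * r[i0]^2 * dr)
  q <- c(0.2, 0.7, 1.3, 2.9, 8.1)
  s <- sq_from_gr(tibble::tibble(r = r, g = g), rho, q)
  expect_equal(s$s, sin(q * r[i0]) / (q * r[i0]), tolerance = 1e-10)
  # q = 0 point uses the sinc limit
  s0 <- sq_from_gr(tibble::tibble(r = r, g = g), rho, 0)
  expect_equal(s0$s, 1, tolerance = 1e-10)
})

test_that("forward/inverse transform roundtrip recovers a smooth g(r)", {
  rho <- 0.0334
  r <- seq(0.02, 30, by = 0.02)
  # smooth water-like shells: damped oscillations about 1
  g <- 1 + 1.8 * exp(-(r - 2.8)^2 / 0.15) * cos((r - 2.8) / 1.5) *
    exp(-r / 8)
  q <- seq(0.02, 40, by = 0.02)
  s <- sq_from_gr(tibble::tibble(r = r, g = g), rho, q)
  back <- gr_from_sq(s, rho, r)
  expect_lt(max(abs(back$g - g)), 1e-3)

  null <- gr_from_sq(tibble::tibble(q = q, s = rep(0, length(q))), rho,
                     seq(0.5, 10, by = 0.5))
  expect_equal(null$g, rep(1, 20))
})

test_that("the taper window suppresses truncation ripple", {
  rho <- 0.0334
  r <- seq(0.02, 30, by = 0.02)
  g <- 1 + 2 * exp(-(r - 2.8)^2 / 0.05)
  qtrunc <- seq(0.02, 6, by = 0.02)   # deliberately short q range
  s <- sq_from_gr(tibble::tibble(r = r, g = g), rho, qtrunc)
  rr <- seq(4.5, 15, by = 0.01)       # outside the peak: g should be 1
  raw <- gr_from_sq(s, rho, rr)
  win <- gr_from_sq(s, rho, rr, window = "lorch")
  ripple_raw <- max(abs(raw$g - 1))
  ripple_win <- max(abs(win$g - 1))
  expect_lt(ripple_win, ripple_raw)

  bad <- tibble::tibble(q = c(0.1, 0.2, 0.5), s = c(0, 0, 0))
  expect_error(gr_from_sq(bad, rho, r), "uniform")
})
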