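test_that("an ideal gas normalizes to g = 1 within counting noise", {
  set.seed(8)
  box <- 20
  frames <- lapply(1:50, function(i) {
    n <- 200
    atomic_configuration(
      tibble::tibble(
        site_label = c("A", rep("B", n)), element = "O",
        x = runif(n + 1, 0, box), y = runif(n + 1, 0, box),
        z = runif(n + 1, 0, box),
        charge = 0, exchangeable = FALSE, molecule_id = seq_len(n + 1)
      ), box)
  })
  g <- compute_rdf(frames, c("A", "B"), bin_width = 0.25, r_max = 10)
  keep <- g$r > 1
  # Poisson counting: expected counts per bin = norm, se(g) = 1/sqrt(counts)
  rho <- attr(g, "rho_beta")
  expected <- 50 * rho * 4 * pi * g$r[keep]^2 * 0.25
  expect_true(all(abs(g$g[keep] - 1) <= 3.5 / sqrt(expected)))
})

test_that("the RDF engine equals the brute-force double loop exactly", {
  cfg <- random_config(40, 60, box = 12, seed = 11)
  mine <- compute_rdf(cfg, c("A", "B"), bin_width = 0.1, r_max = 6)
  oracle <- brute_force_rdf(cfg, c("A", "B"), 0.1, 6)
  expect_equal(mine$g, oracle$g, tolerance = 1e-14)

  # same-species case with self-pair exclusion, multiple frames
  frames <- list(random_config(50, 0, 10, seed = 3),
                 random_config(50, 0, 10, seed = 4))
  mine2 <- compute_rdf(frames, c("A", "A"), bin_width = 0.2, r_max = 5)
  oracle2 <- brute_force_rdf(frames, c("A", "A"), 0.2, 5)
  expect_equal(mine2$g, oracle2$g, tolerance = 1e-14)
})

test_that("a single pair lands in a single bin", {
  box <- 50
  cfg <- atomic_configuration(
    tibble::tibble(site_label = c("A", "B"), element = "O",
                   x = c(10, 13), y = c(10, 10), z = c(10, 10),
                   charge = 0, exchangeable = FALSE, molecule_id = 1:2),
    box)
  g <- compute_rdf(cfg, c("A", "B"), bin_width = 0.1, r_max = 10)
  occupied <- which(g$g > 0)
  expect_length(occupied, 1)
  expect_equal(g$r[occupied], 3.05)  # bin [3.0, 3.1)
  expect_error(compute_rdf(cfg, c("A", "B"), r_max = 30), "half the box")
  expect_error(compute_rdf(cfg, c("A", "C")), "no atoms")
})

test_that("first-shell peaks are located and refined", {
  r <- seq(0.025, 6, by = 0.05)
  g1 <- tibble::tibble(r = r, g = 1 + 2 * exp(-(r - 1.8)^2 / 0.02))
  expect_lt(abs(first_shell_peak(g1) - 1.8), 0.025)

  flat <- tibble::tibble(r = r, g = rep(1, length(r)))
  expect_true(is.na(first_shell_peak(flat)))

  two <- tibble::tibble(
    r = r, g = 1 + 2 * exp(-(r - 1.8)^2 / 0.02) +
      3 * exp(-(r - 3.2)^2 / 0.02))
  expect_lt(abs(first_shell_peak(two) - 1.8), 0.025)  # first, not highest
})

test_that("the hydrogen-bonding index matches its worked examples", {
  # Glu-side-chain-like oxygen: peak offset 0.95 A, acceptor
  rec <- hbond_delta(2.75, 1.80)
  expect_equal(rec$delta, 0.95 / 0.96, tolerance = 1e-9)
  expect_equal(round(rec$delta, 3), 0.990)
  expect_equal(rec$class, "acceptor")

  neutral <- hbond_delta(2.8, 2.8)
  expect_equal(neutral$delta, 0)
  expect_equal(neutral$class, "neutral")

  donor <- hbond_delta(2.8, 2.8 + water_r_acceptor())
  expect_equal(donor$delta, -1)
  expect_equal(donor$class, "donor")

  buried <- hbond_delta(NA_real_, 2.0)
  expect_equal(buried$class, "buried")
  expect_true(is.na(buried$delta))

  # clamping keeps finite-temperature overshoots inside [-1, 1]
  expect_equal(hbond_delta(2.8, 3.6)$delta, -1)
  expect_equal(water_r_acceptor(), cos(109.47 / 2 * pi / 180),
               tolerance = 1e-12)
})

test_that("recovered Delta tracks the orientation bias monotonically", {
  omegas <- c(-1, -0.5, 0, 0.5, 1)
  deltas <- sapply(omegas, function(w) {
    mean(sapply(1:3, function(s) {
      cfg <- synth_hydration_shell(2000, w, seed = 100 * s + round(10 * w))
      gow <- compute_rdf(cfg, c("X", "Ow"), bin_width = 0.05, r_max = 8)
      ghw <- compute_rdf(cfg, c("X", "Hw"), bin_width = 0.05, r_max = 8)
      hbond_delta(first_shell_peak(gow), first_shell_peak(ghw))$delta
    }))
  })
  # a first-peak statistic of a mixture is step-like: monotone
  # non-decreasing with exact endpoints
  expect_true(all(diff(deltas) >= -0.05))
  expect_gt(deltas[5], deltas[1])
  expect_lt(abs(deltas[1] - (-1)), 0.1)
  expect_lt(abs(deltas[5] - 1), 0.1)
  expect_lt(abs(deltas[3]), 0.1)
})

test_that("the surface map classifies donor/acceptor/buried sites correctly", {
  # donor-biased shell around a TyrOH-like hydrogen, acceptor-biased around
  # a carboxylate-like oxygen, merged into one frame
  don <- synth_hydration_shell(800, -1, seed = 21, site_label = "YHH",
                               site_element = "H", box_side = 60)
  acc <- synth_hydration_shell(800, 1, seed = 22, site_label = "EOE1",
                               site_element = "O", box_side = 60)
  shift <- acc$atoms
  shift$x <- shift$x + 25
  shift$molecule_id <- shift$molecule_id + max(don$atoms$molecule_id)
  cfg <- atomic_configuration(dplyr::bind_rows(don$atoms, shift), 60)
  res <- delta_surface_map(cfg, sites = c("YHH", "EOE1"))
  expect_equal(res$class[res$site_label == "YHH"], "donor")
  expect_equal(res$class[res$site_label == "EOE1"], "acceptor")
  expect_lt(res$delta[res$site_label == "YHH"], 0)
  expect_gt(res$delta[res$site_label == "EOE1"], 0)

  # a site with no nearby water is buried
  dry <- atomic_configuration(
    dplyr::bind_rows(
      tibble::tibble(site_label = "DRY", element = "C", x = 5, y = 5, z = 5,
                     charge = 0, exchangeable = FALSE, molecule_id = 999L),
      shift),
    60)
  res2 <- delta_surface_map(dry, sites = "DRY")
  expect_equal(res2$class, "buried")
  expect_true(is.na(res2$delta))
})

test_that("pooling equivalent sites agrees with per-site averaging", {
  a <- synth_hydration_shell(1500, 0.6, seed = 31, site_label = "S",
                             box_side = 80)
  b <- synth_hydration_shell(1500, 0.6, seed = 32, site_label = "S",
                             box_side = 80)
  shift <- b$atoms
  shift$x <- shift$x + 35
  shift$molecule_id <- shift$molecule_id + max(a$atoms$molecule_id)
  pooled_cfg <- atomic_configuration(dplyr::bind_rows(a$atoms, shift), 80)
  pooled <- delta_surface_map(pooled_cfg, sites = "S")
  sep <- lapply(list(a, b), function(cfg) delta_surface_map(cfg, sites = "S"))
  expect_equal(pooled$class, sep[[1]]$class)
  expect_equal(pooled$class, sep[[2]]$class)
  expect_lt(abs(pooled$delta - mean(c(sep[[1]]$delta, sep[[2]]$delta))),
            0.1)
})

test_that("hydrophobicity scales normalize to [0,1] with polarity control", {
  sc <- tibble::tibble(residue = c("A", "B", "C"), value = c(0, 5, 10))
  norm <- normalize_hydrophobicity(sc)
  expect_equal(norm$normalized, c(0, 0.5, 1))

  again <- normalize_hydrophobicity(
    tibble::tibble(residue = c("A", "B", "C"), value = c(0, 0.5, 1)))
  expect_equal(again$normalized, c(0, 0.5, 1))

  flipped <- normalize_hydrophobicity(sc, hydrophilic_high = FALSE)
  expect_equal(flipped$normalized, c(1, 0.5, 0))

  expect_error(normalize_hydrophobicity(
    tibble::tibble(residue = c("A", "B"), value = c(2, 2))), "constant")
})
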