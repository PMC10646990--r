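test_that("a single-unit stack is the identity", {
  mono <- toy_hairpin_monomer()
  s <- build_stack_mc(mono, 1, 8.5, seed = 1)
  a <- stack_atoms(s)
  expect_equal(a$x, mono$x, tolerance = 1e-12)
  expect_equal(a$y, mono$y, tolerance = 1e-12)
  expect_equal(a$z, mono$z, tolerance = 1e-12)
})

test_that("a 7-mer stack spans ~6 spacings and is reproducible", {
  mono <- toy_hairpin_monomer()
  s <- build_stack_mc(mono, 7, 8.5, seed = 42)
  centers <- t(vapply(s$poses, `[[`, numeric(3), "trans"))
  span <- centers[7, 3] - centers[1, 3]
  expect_lt(abs(span - 6 * 8.5), 3)           # restraint tolerance
  expect_true(all(diff(centers[, 3]) > 0))    # ordered along the axis

  s2 <- build_stack_mc(mono, 7, 8.5, seed = 42)
  expect_identical(s$poses, s2$poses)         # bit-identical for same seed

  s3 <- build_stack_mc(mono, 7, 8.5, seed = 43)
  expect_false(identical(s$poses, s3$poses))
})

test_that("the best-so-far score never increases", {
  mono <- toy_hairpin_monomer()
  s <- build_stack_mc(mono, 4, 8.5, seed = 7)
  expect_true(all(diff(s$score_trace) <= 0))
})

test_that("stacks keep monomers clash-free", {
  mono <- toy_hairpin_monomer()
  s <- build_stack_mc(mono, 5, 8.5, seed = 3)
  a <- stack_atoms(s)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  diag(d) <- Inf
  inter <- outer(a$molecule_id, a$molecule_id, `!=`)
  expect_gt(min(d[inter]), 1.2)
})

test_that("solvation packs the requested contents with safe separations", {
  cfg <- solvate_box(list(), n_waters = 10, n_counterions = 0,
                     box_side = 10, seed = 5)
  expect_equal(nrow(cfg$atoms), 30)
  heavy <- cfg$atoms$element != "H"
  xyz <- as.matrix(cfg$atoms[heavy, c("x", "y", "z")])
  dm <- minimum_image_matrix(xyz, cfg$box_side)
  expect_gte(min(dm), 2.0)
  all_d <- minimum_image_matrix(as.matrix(cfg$atoms[, c("x", "y", "z")]),
                                cfg$box_side)
  # intramolecular OH (1.0 A) is the shortest allowed contact
  expect_gte(min(all_d), 0.8)
  expect_equal(sum(cfg$atoms$charge), 0, tolerance = 1e-12)
})

test_that("an overfull box is refused", {
  expect_error(solvate_box(list(), 50, 0, box_side = 10, seed = 1),
               "0.12 atoms")
})

test_that("a small solvated two-stack box survives the PDB roundtrip", {
  mono <- toy_hairpin_monomer()
  s1 <- build_stack_mc(mono, 2, 8.5, seed = 11, n_iter = 100L)
  s2 <- build_stack_mc(mono, 2, 8.5, seed = 12, n_iter = 100L)
  cfg <- solvate_box(list(s1, s2), n_waters = 300, n_counterions = 4,
                     box_side = 40, seed = 13)
  expect_equal(nrow(cfg$atoms), 2 * 2 * 172 + 300 * 3 + 4)
  expect_equal(sum(cfg$atoms$charge), 2 * 2 * -2 + 4, tolerance = 1e-9)

  pdb <- tempfile(fileext = ".pdb")
  csv <- tempfile(fileext = ".csv")
  write_structure(cfg, pdb)
  write_charge_table(cfg, csv)
  back <- read_structure(pdb, read_charge_table(csv))
  expect_equal(nrow(back$atoms), nrow(cfg$atoms))
  expect_equal(sum(back$atoms$charge), sum(cfg$atoms$charge),
               tolerance = 1e-9)
  expect_equal(table(back$atoms$element), table(cfg$atoms$element))
})
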