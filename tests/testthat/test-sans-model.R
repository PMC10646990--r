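test_that("the composite model is exactly the sum of its terms", {
  p <- paper_sans_params()
  q <- exp(seq(log(0.003), log(3), length.out = 50))
  comp <- sans_model_components(q, p)
  total <- composite_intensity(q, p)
  expect_equal(comp$cylinder + comp$gauss_ip + comp$gauss_is +
                 comp$power_law + comp$bkg, comp$total)
  expect_equal(total$intensity, comp$total)
})

test_that("degenerate parameter sets reduce to their single active term", {
  q <- c(0.01, 0.1, 1)
  flat <- sans_model_params(phi = 0, delta_rho = 3e-6, length_a = 60,
                            r_minor = 6.5, r_major = 12.6, charge = 0,
                            bkg = 0.7)
  expect_equal(composite_intensity(q, flat)$intensity, rep(0.7, 3))

  pl <- sans_model_params(phi = 0, delta_rho = 3e-6, length_a = 60,
                          r_minor = 6.5, r_major = 12.6, charge = 0,
                          pl_amp = 1, pl_exp = 3, bkg = 0)
  expect_equal(composite_intensity(0.1, pl)$intensity, 1000)
})

test_that("the reference parameter set shows twin mid-q peaks and a low-q inflection", {
  p <- paper_sans_params()
  q <- exp(seq(log(0.01), log(3), length.out = 500))
  i <- composite_intensity(q, p)$intensity
  # local maxima near 1 A^-1
  mid <- which(q > 0.4 & q < 2.5)
  loc <- mid[which(i[mid] > i[mid - 1] & i[mid] > i[mid + 1])]
  expect_equal(length(loc), 2)
  expect_lt(abs(q[loc[1]] - p$q_ip), 0.1)
  expect_lt(abs(q[loc[2]] - p$q_is), 0.1)
  # electrostatic repulsion depresses the lowest q (inflection near 0.1):
  # removing the charge raises the cylinder term at q = 0.05
  comp <- sans_model_components(c(0.05), p)
  ser <- charged_structure_factor(0.05, p$phi, p$charge,
                                  equivalent_sphere_diameter(
                                    p$length_a, p$r_minor, p$r_major))
  expect_lt(ser, 1)
  uncharged <- charged_structure_factor(0.05, p$phi, 0,
                                        equivalent_sphere_diameter(
                                          p$length_a, p$r_minor, p$r_major))
  expect_gt(uncharged, ser)
})

test_that("stack metrics reproduce the geometric bookkeeping", {
  p <- paper_sans_params()
  p$length_a <- 60
  m <- stack_metrics(p, per_monomer_charge = -2)
  expect_equal(m$n_units, 7)
  expect_equal(round(m$aspect_ratio, 2), 1.94)
  expect_equal(m$total_charge, -14)
  expect_equal(m$d_ip, 8.5, tolerance = 1e-12)
  expect_equal(m$d_is, 4.5, tolerance = 1e-12)

  swapped <- p
  swapped$q_ip <- 1.4; swapped$q_is <- 0.74
  expect_warning(m2 <- stack_metrics(swapped, -2), "swap")
  expect_gt(m2$d_ip, m2$d_is)
})

test_that("a noiseless curve is recovered to better than 0.1% by the staged fit", {
  truth <- paper_sans_params()
  q <- exp(seq(log(0.003), log(3), length.out = 400))
  # generate and fit at the same solver resolution: pure self-consistency
  model <- composite_intensity(q, truth, sf_m_core = 64L, sf_n_grid = 2047L)
  crv <- synth_sans_curve(truth, q, 0, seed = 1, model = model)
  fit <- staged_fit(crv, recovery_init(truth))
  for (term in c("length_a", "r_minor", "r_major", "q_ip", "q_is",
                 "pl_exp", "bkg")) {
    expect_lt(abs(fit$params[[term]] - truth[[term]]) / truth[[term]],
              1e-3)
  }
})

test_that("the fit errors out when the curve misses the power-law window", {
  truth <- paper_sans_params()
  q <- exp(seq(log(0.02), log(3), length.out = 200))
  crv <- synth_sans_curve(truth, q, 0.01, seed = 1)
  expect_error(staged_fit(crv, recovery_init(truth)), "stage 1")
})

test_that("median recovery over 20 noisy seeds is within 5% for the key parameters", {
  study <- cached_recovery_study()
  truth <- paper_sans_params()
  expect_gte(nrow(study), 20)
  expect_lt(abs(median(study$length_a) - truth$length_a) / truth$length_a,
            0.05)
  expect_lt(abs(median(study$r_minor) - truth$r_minor) / truth$r_minor,
            0.05)
  expect_lt(abs(median(study$r_major) - truth$r_major) / truth$r_major,
            0.05)
  expect_lt(abs(median(study$pl_exp) - truth$pl_exp) / truth$pl_exp, 0.05)
})

test_that("tidy, glance and augment expose the fit in broom style", {
  truth <- paper_sans_params()
  q <- exp(seq(log(0.003), log(3), length.out = 150))
  crv <- synth_sans_curve(truth, q, 0.01, seed = 3)
  fit <- staged_fit(crv, recovery_init(truth))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  expect_true("length_a" %in% td$term)
  expect_true(all(is.finite(td$std.error[td$term %in%
                                           c("length_a", "r_minor")])))
  gl <- glance(fit)
  expect_equal(gl$n_points, 150)
  aug <- augment(fit)
  expect_true(all(c(".fitted", "cylinder") %in% names(aug)))
  expect_s3_class(autoplot(fit), "ggplot")
})
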