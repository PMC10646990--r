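#' Fit the low-q power-law term alone
#'
#' Weighted least-squares fit of \eqn{\gamma q^{-n} + c} to the portion of a
#' curve below `qmax` (the window where sparse large aggregates dominate the
#' signal). This is stage 1 of [staged_fit()], usable on its own for curves
#' that only cover the power-law regime.
#'
#' @param curve A [scattering_curve()].
#' @param qmax Upper edge of the fit window, \eqn{\AA^{-1}}.
#' @param init Named list with starting `pl_amp` and `pl_exp`.
#' @return List with `pl_amp`, `pl_exp`, `offset`, `se` (named), `chisq`.
#' @export
fit_power_law <- function(curve, qmax = Inf,
                          init = list(pl_amp = 1e-5, pl_exp = 3)) {
  i1 <- which(curve$q < qmax)
  if (length(i1) < 5L) {
    abort(sprintf(
      "stage 1: only %d points below q = %g; curve does not cover the power-law window",
      length(i1), qmax))
  }
  w1 <- fit_weights(curve, i1)
  q1 <- curve$q[i1]; y1 <- curve$intensity[i1]
  fn1 <- function(th) {
    (exp(th[["log_gamma"]]) * q1^(-th[["n"]]) + th[["offset"]] - y1) * w1
  }
  f1 <- run_lm(
    par = c(log_gamma = log(max(init$pl_amp, 1e-12)), n = init$pl_exp,
            offset = max(min(y1), 0)),
    fn = fn1,
    lower = c(log_gamma = log(1e-12), n = 0.3, offset = 0),
    upper = c(log_gamma = log(1e6), n = 8, offset = max(y1)),
    stage = "1 (power law)"
  )
  s1 <- lm_se(f1)
  list(pl_amp = exp(f1$par[["log_gamma"]]), pl_exp = f1$par[["n"]],
       offset = f1$par[["offset"]],
       se = c(pl_amp = exp(f1$par[["log_gamma"]]) * s1[["log_gamma"]],
              pl_exp = s1[["n"]], offset = s1[["offset"]]),
       chisq = sum(f1$fvec^2), summary = stage_summary(f1, i1))
}

#' Default starting point for a recovery study
#'
#' A fixed, deliberately wrong perturbation of a truth parameter set (length
#' +13%, radii -8%/+7%, charge -20%, displaced peak centers and widths,
#' halved power-law exponent error, etc.), so that fits in a recovery study
#' never start at the answer.
#'
#' @param truth A [sans_model_params()].
#' @return A [sans_model_params()] to use as `init` in [staged_fit()].
#' @export
recovery_init <- function(truth) {
  sans_model_params(
    phi = truth$phi * 0.82, delta_rho = truth$delta_rho,
    length_a = truth$length_a * 1.13,
    r_minor = truth$r_minor * 0.92, r_major = truth$r_major * 1.07,
    charge = truth$charge * 0.8,
    ionic_strength = truth$ionic_strength,
    temperature = truth$temperature, dielectric = truth$dielectric,
    gauss_amp_ip = truth$gauss_amp_ip * 1.3,
    gauss_amp_is = truth$gauss_amp_is * 1.2,
    q_ip = truth$q_ip * 1.05, q_is = truth$q_is * 0.97,
    sigma_ip = truth$sigma_ip * 1.2, sigma_is = truth$sigma_is * 0.9,
    pl_amp = truth$pl_amp * 2, pl_exp = truth$pl_exp * 0.85,
    bkg = truth$bkg * 0.8
  )
}

#' Parameter-recovery study for the staged SANS fit
#'
#' Generates one noiseless model curve from `truth`, then for each seed adds
#' multiplicative Gaussian noise ([synth_sans_curve()]) and runs the staged
#' fit from a fixed perturbed starting point ([recovery_init()]). The
#' per-seed fitted parameters quantify how well the staged procedure
#' recovers a known geometry under realistic counting noise.
#'
#' @param truth A [sans_model_params()] (default [paper_sans_params()]).
#' @param seeds Integer vector of noise seeds.
#' @param noise_fraction Relative noise level.
#' @param q Momentum-transfer grid (default: 400 log-spaced points over
#'   0.003-3 \eqn{\AA^{-1}}).
#' @param stages A [stage_config()].
#' @return Tibble with one row per seed: fitted `length_a`, `r_minor`,
#'   `r_major`, `q_ip`, `q_is`, `d_ip`, `d_is`, `pl_exp`, `charge`, `phi`.
#' @export
sans_recovery_study <- function(truth = paper_sans_params(),
                                seeds = 1:20, noise_fraction = 0.01,
                                q = exp(seq(log(0.003), log(3),
                                            length.out = 400)),
                                stages = stage_config()) {
  model <- composite_intensity(q, truth)
  init <- recovery_init(truth)
  purrr::map_dfr(seeds, function(s) {
    crv <- synth_sans_curve(truth, q, noise_fraction, seed = s,
                            model = model)
    fit <- staged_fit(crv, init, stages)
    pp <- fit$params
    tibble::tibble(
      seed = s, length_a = pp$length_a, r_minor = pp$r_minor,
      r_major = pp$r_major, q_ip = pp$q_ip, q_is = pp$q_is,
      d_ip = d_from_q(pp$q_ip), d_is = d_from_q(pp$q_is),
      pl_exp = pp$pl_exp, charge = pp$charge, phi = pp$phi
    )
  })
}

#' Power-law-only recovery study
#'
#' Generates the power-law-plus-background portion of the model on a low-q
#' grid, adds noise per seed and refits with [fit_power_law()]; used to
#' check recovery of the aggregate power-law exponent in isolation.
#'
#' @param truth A [sans_model_params()]; only `pl_amp`, `pl_exp`, `bkg` are
#'   used.
#' @param seeds Integer vector of noise seeds.
#' @param noise_fraction Relative noise level.
#' @param q Low-q grid (default: 100 log-spaced points over 0.003-0.03
#'   \eqn{\AA^{-1}}).
#' @return Tibble with one row per seed: `pl_amp`, `pl_exp`.
#' @export
power_law_recovery_study <- function(truth = paper_sans_params(),
                                     seeds = 1:20, noise_fraction = 0.01,
                                     q = exp(seq(log(0.003), log(0.03),
                                                 length.out = 100))) {
  ideal <- truth$pl_amp * q^(-truth$pl_exp) + truth$bkg
  model <- scattering_curve(q, ideal, unit_tag = "cm^-1")
  init <- list(pl_amp = truth$pl_amp * 2, pl_exp = truth$pl_exp * 0.85)
  purrr::map_dfr(seeds, function(s) {
    crv <- with_preserved_seed(s, {
      eps <- rnorm(length(q), 0, noise_fraction)
      scattering_curve(q, ideal * (1 + eps),
                       sigma = noise_fraction * ideal, unit_tag = "cm^-1")
    })
    f <- fit_power_law(crv, qmax = Inf, init = init)
    tibble::tibble(seed = s, pl_amp = f$pl_amp, pl_exp = f$pl_exp)
  })
}
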