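#' Configuration of the staged fit
#'
#' The composite model is fit term by term to keep the optimisation stable:
#' each stage works on the `q` window where its term dominates, with the
#' already-fitted terms frozen.
#'
#' \describe{
#'   \item{stage 1}{power law \eqn{(\gamma, n)} on `q < pl_qmax`, together
#'     with a local constant offset that absorbs the (charge-suppressed)
#'     cylinder plateau plus background under the window; only
#'     \eqn{(\gamma, n)} are retained.}
#'   \item{stage 2}{the two Gaussians plus a local flat baseline on
#'     `gauss_window`; the baseline becomes the background estimate.}
#'   \item{stage 3}{cylinder scale, `L`, `R_minor`, `R_major` and `|Z|` on
#'     `cyl_window`, with stage-1/2 terms and background frozen.}
#'   \item{stage 4}{optional global polish of all parameters with bounds
#'     around the stage estimates (off by default).}
#' }
#'
#' @param pl_qmax Upper `q` of the power-law window, \eqn{\AA^{-1}}.
#' @param gauss_window Length-2 `q` window for the Gaussian stage.
#' @param cyl_window Length-2 `q` window for the cylinder stage.
#' @param n_cycles Number of stage-2/stage-3 passes: in the second and
#'   later passes each stage is refit with the other's term frozen at its
#'   current estimate, removing the small coupling bias of a single pass.
#' @param polish Run the optional global refinement stage?
#' @param n_alpha,n_psi Form-factor quadrature orders used during fitting.
#' @param sf_m_core,sf_n_grid Structure-factor solver resolution used during
#'   fitting (modest defaults; the solution differs from the high-resolution
#'   default by well under 0.1%).
#' @return A list of class `stage_config`.
#' @export
stage_config <- function(pl_qmax = 0.01, gauss_window = c(0.5, 3),
                         cyl_window = c(0.02, 0.5), n_cycles = 2L,
                         polish = FALSE, n_alpha = 76L, n_psi = 24L,
                         sf_m_core = 64L, sf_n_grid = 2047L) {
  structure(list(pl_qmax = pl_qmax, gauss_window = sort(gauss_window),
                 cyl_window = sort(cyl_window),
                 n_cycles = max(1L, as.integer(n_cycles)), polish = polish,
                 n_alpha = n_alpha, n_psi = n_psi,
                 sf_m_core = sf_m_core, sf_n_grid = sf_n_grid),
            class = "stage_config")
}

fit_weights <- function(curve, idx) {
  s <- curve$sigma[idx]
  if (all(is.na(s)) ) {
    # uniform on log I: w = 1/I^2 makes squared residuals ~ (d log I)^2
    1 / pmax(abs(curve$intensity[idx]), 1e-300)
  } else {
    if (any(is.na(s) | s <= 0)) {
      abort("sigma must be positive wherever present for weighted fitting")
    }
    1 / s
  }
}

run_lm <- function(par, fn, lower, upper, stage, maxit = 200) {
  fit <- minpack.lm::nls.lm(
    par = par, fn = fn, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = maxit, ftol = 1e-12,
                                         ptol = 1e-12)
  )
  if (fit$info == 0 || fit$info == 9) {
    abort(sprintf("stage %s did not converge (%s)", stage, fit$message))
  }
  at_bound <- names(par)[which(fit$par <= lower + 1e-12 |
                                 fit$par >= upper - 1e-12)]
  if (length(at_bound)) {
    warn(paste0("stage ", stage, ": parameter(s) at bound: ",
                paste(at_bound, collapse = ", ")))
  }
  fit
}

lm_se <- function(fit) {
  p <- length(fit$par)
  n <- length(fit$fvec)
  se <- rep(NA_real_, p)
  h <- try(solve(fit$hessian), silent = TRUE)
  if (!inherits(h, "try-error") && n > p) {
    s2 <- sum(fit$fvec^2) / (n - p)
    d <- diag(h)
    se[d > 0] <- sqrt(d[d > 0] * s2)
  }
  setNames(se, names(fit$par))
}

#' Staged fit of the composite SANS model
#'
#' Fits [sans_model_params()] to a measured curve term by term (see
#' [stage_config()]): the low-`q` power law first, then the mid-`q` Gaussian
#' peaks and the flat background, then the cylinder geometry and charge with
#' the other terms frozen, optionally followed by a bounded global polish.
#' Residuals are weighted by \eqn{1/\sigma} where uncertainties are present
#' and uniformly in \eqn{\log I} otherwise.
#'
#' During stage 3 the cylinder amplitude is fit as the combined scale
#' \eqn{\phi \Delta\rho^2 V_{block}}; the volume fraction entering the
#' structure factor is re-derived from that scale with the (fixed) contrast
#' of `init`, keeping amplitude and interparticle interference consistent.
#'
#' @param curve A [scattering_curve()] spanning the enabled stage windows.
#' @param init A [sans_model_params()] with starting values; `delta_rho`,
#'   `ionic_strength`, `temperature` and `dielectric` are taken as known and
#'   not fitted.
#' @param stages A [stage_config()].
#' @return An object of class `sans_fit`: list with elements `params` (fitted
#'   [sans_model_params()]), `se` (named 1-sigma uncertainties from the
#'   stage covariances), `stages` (per-stage chi-square summaries), `init`,
#'   `config` and `curve`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
staged_fit <- function(curve, init, stages = stage_config()) {
  stopifnot(inherits(init, "sans_model_params"),
            inherits(stages, "stage_config"))
  p <- unclass(init)
  se <- c()
  info <- list()

  ## ---- stage 1: power law (+ local offset) --------------------------------
  f1 <- fit_power_law(curve, stages$pl_qmax,
                      init = list(pl_amp = p$pl_amp, pl_exp = p$pl_exp))
  p$pl_amp <- f1$pl_amp
  p$pl_exp <- f1$pl_exp
  se["pl_exp"] <- f1$se[["pl_exp"]]
  se["pl_amp"] <- f1$se[["pl_amp"]]
  info$power_law <- f1$summary

  ## ---- stages 2 and 3, cycled ---------------------------------------------
  i2 <- which(curve$q >= stages$gauss_window[1] &
                curve$q <= stages$gauss_window[2])
  if (length(i2) < 8L) {
    abort("stage 2: too few points in the Gaussian window")
  }
  w2 <- fit_weights(curve, i2)
  q2 <- curve$q[i2]; y2 <- curve$intensity[i2]
  i3 <- which(curve$q >= stages$cyl_window[1] &
                curve$q <= stages$cyl_window[2])
  if (length(i3) < 10L) {
    abort("stage 3: too few points in the cylinder window")
  }
  w3 <- fit_weights(curve, i3)
  q3 <- curve$q[i3]; y3 <- curve$intensity[i3]
  scale0 <- sans_scale(init)

  gmodel <- function(th, q) {
    th[["a1"]] * exp(-(q - th[["q1"]])^2 / (2 * th[["s1"]]^2)) +
      th[["a2"]] * exp(-(q - th[["q2"]])^2 / (2 * th[["s2"]]^2)) +
      th[["base"]]
  }
  cyl_eval <- function(th, qv) {
    L <- th[["L"]]; rmin <- th[["r_minor"]]
    rmaj <- rmin * th[["axial_ratio"]]
    v <- pi * rmin * rmaj * L
    phi <- exp(th[["log_scale"]]) / (p$delta_rho^2 * v * 1e8)
    # outside the physical window for the liquid-state solver: steer back
    # with a penalty rather than erroring mid-optimisation
    if (!is.finite(phi) || phi <= 0 || phi > 0.45) return(NULL)
    pec <- elliptical_cylinder_form_factor(qv, L, rmin, rmaj,
                                           stages$n_alpha, stages$n_psi)
    ser <- tryCatch(
      charged_structure_factor(
        qv, phi, th[["z"]], equivalent_sphere_diameter(L, rmin, rmaj),
        p$ionic_strength, p$temperature, p$dielectric,
        stages$sf_m_core, stages$sf_n_grid),
      error = function(e) NULL)
    if (is.null(ser)) return(NULL)
    exp(th[["log_scale"]]) * pec * ser
  }

  cyl_on_q2 <- 0  # first pass: cylinder tail under the Gaussian window unknown
  for (cycle in seq_len(stages$n_cycles)) {
    ## stage 2: Gaussians + baseline
    frozen2 <- p$pl_amp * q2^(-p$pl_exp) + cyl_on_q2
    fn2 <- function(th) (gmodel(th, q2) + frozen2 - y2) * w2
    f2 <- run_lm(
      par = c(a1 = max(p$gauss_amp_ip, 1e-6), q1 = p$q_ip, s1 = p$sigma_ip,
              a2 = max(p$gauss_amp_is, 1e-6), q2 = p$q_is, s2 = p$sigma_is,
              base = max(p$bkg, 1e-6)),
      fn = fn2,
      lower = c(a1 = 0, q1 = stages$gauss_window[1], s1 = 1e-3,
                a2 = 0, q2 = stages$gauss_window[1], s2 = 1e-3, base = 0),
      upper = c(a1 = max(y2) * 2, q1 = stages$gauss_window[2], s1 = 2,
                a2 = max(y2) * 2, q2 = stages$gauss_window[2], s2 = 2,
                base = max(y2)),
      stage = "2 (Gaussians)"
    )
    th2 <- f2$par
    s2se <- lm_se(f2)
    if (th2[["q1"]] > th2[["q2"]]) {  # keep q_ip as the lower-q peak
      th2 <- th2[c("a2", "q2", "s2", "a1", "q1", "s1", "base")]
      s2se <- s2se[c("a2", "q2", "s2", "a1", "q1", "s1", "base")]
      names(th2) <- names(s2se) <-
        c("a1", "q1", "s1", "a2", "q2", "s2", "base")
    }
    p$gauss_amp_ip <- th2[["a1"]]; p$q_ip <- th2[["q1"]]
    p$sigma_ip <- th2[["s1"]]
    p$gauss_amp_is <- th2[["a2"]]; p$q_is <- th2[["q2"]]
    p$sigma_is <- th2[["s2"]]
    p$bkg <- th2[["base"]]
    se[c("gauss_amp_ip", "q_ip", "sigma_ip",
         "gauss_amp_is", "q_is", "sigma_is", "bkg")] <-
      s2se[c("a1", "q1", "s1", "a2", "q2", "s2", "base")]
    info$gaussians <- stage_summary(f2, i2)

    ## stage 3: cylinder geometry + charge
    frozen3 <- p$pl_amp * q3^(-p$pl_exp) +
      p$gauss_amp_ip * exp(-(q3 - p$q_ip)^2 / (2 * p$sigma_ip^2)) +
      p$gauss_amp_is * exp(-(q3 - p$q_is)^2 / (2 * p$sigma_is^2)) +
      p$bkg
    fn3 <- function(th) {
      cyl <- cyl_eval(th, q3)
      if (is.null(cyl)) return(rep(1e6, length(q3)))
      (cyl + frozen3 - y3) * w3
    }
    f3 <- run_lm(
      par = c(log_scale = log(sans_scale(structure(p, class = "sans_model_params"))),
              L = p$length_a, r_minor = p$r_minor,
              axial_ratio = p$r_major / p$r_minor, z = abs(p$charge)),
      fn = fn3,
      lower = c(log_scale = log(scale0) - log(4), L = 10, r_minor = 2,
                axial_ratio = 1, z = 0),
      upper = c(log_scale = log(scale0) + log(4), L = 300, r_minor = 30,
                axial_ratio = 10, z = 60),
      stage = "3 (cylinder)", maxit = 100
    )
    th3 <- f3$par
    s3se <- lm_se(f3)
    p$length_a <- th3[["L"]]
    p$r_minor <- th3[["r_minor"]]
    p$r_major <- th3[["r_minor"]] * th3[["axial_ratio"]]
    p$charge <- sign(init$charge %||% -1) * th3[["z"]]
    p$phi <- exp(th3[["log_scale"]]) /
      (p$delta_rho^2 * pi * p$r_minor * p$r_major * p$length_a * 1e8)
    se["length_a"] <- s3se[["L"]]
    se["r_minor"] <- s3se[["r_minor"]]
    # var(rM) ~ (ratio*se_rmin)^2 + (rmin*se_ratio)^2, correlations ignored
    se["r_major"] <- sqrt((th3[["axial_ratio"]] * s3se[["r_minor"]])^2 +
                            (th3[["r_minor"]] * s3se[["axial_ratio"]])^2)
    se["charge"] <- s3se[["z"]]
    se["phi"] <- p$phi * s3se[["log_scale"]]
    info$cylinder <- stage_summary(f3, i3)

    if (cycle < stages$n_cycles) {
      cyl_on_q2 <- cyl_eval(f3$par, q2) %||% 0
    }
  }

  ## ---- stage 4: optional global polish ------------------------------------
  if (isTRUE(stages$polish)) {
    wa <- fit_weights(curve, seq_len(nrow(curve)))
    qa <- curve$q; ya <- curve$intensity
    pack <- function(p) c(
      log_scale = log(p$phi * p$delta_rho^2 * pi * p$r_minor * p$r_major *
                        p$length_a * 1e8),
      L = p$length_a, r_minor = p$r_minor,
      axial_ratio = p$r_major / p$r_minor, z = abs(p$charge),
      a1 = p$gauss_amp_ip, q1 = p$q_ip, s1 = p$sigma_ip,
      a2 = p$gauss_amp_is, q2 = p$q_is, s2 = p$sigma_is,
      log_gamma = log(max(p$pl_amp, 1e-300)), n = p$pl_exp, bkg = p$bkg)
    th0 <- pack(p)
    unpack <- function(th, base) {
      out <- base
      out$length_a <- th[["L"]]; out$r_minor <- th[["r_minor"]]
      out$r_major <- th[["r_minor"]] * th[["axial_ratio"]]
      out$charge <- sign(base$charge %||% -1) * th[["z"]]
      out$phi <- exp(th[["log_scale"]]) /
        (base$delta_rho^2 * pi * out$r_minor * out$r_major *
           out$length_a * 1e8)
      out$gauss_amp_ip <- th[["a1"]]; out$q_ip <- th[["q1"]]
      out$sigma_ip <- th[["s1"]]
      out$gauss_amp_is <- th[["a2"]]; out$q_is <- th[["q2"]]
      out$sigma_is <- th[["s2"]]
      out$pl_amp <- exp(th[["log_gamma"]]); out$pl_exp <- th[["n"]]
      out$bkg <- th[["bkg"]]
      out
    }
    fn4 <- function(th) {
      pp <- unpack(th, p)
      comp <- tryCatch(
        sans_model_components(qa,
                              structure(pp, class = "sans_model_params"),
                              stages$n_alpha, stages$n_psi,
                              stages$sf_m_core, stages$sf_n_grid),
        error = function(e) NULL)
      if (is.null(comp)) return(rep(1e6, length(qa)))
      (comp$total - ya) * wa
    }
    span <- abs(th0) * 0.5 + 1e-3
    f4 <- run_lm(th0, fn4, lower = pmax(th0 - span,
                                        c(-Inf, 10, 2, 1, 0, 0, 0.01, 1e-3,
                                          0, 0.01, 1e-3, -Inf, 0.3, 0)),
                 upper = th0 + span, stage = "4 (polish)", maxit = 60)
    p <- unpack(f4$par, p)
    info$polish <- stage_summary(f4, seq_len(nrow(curve)))
  }

  params <- structure(p, class = "sans_model_params")
  validate_sans_params(params)
  structure(list(params = params, se = se, stages = info, init = init,
                 config = stages, curve = curve),
            class = "sans_fit")
}
stage_summary <- function(fit, idx) {
  n <- length(idx); k <- length(fit$par)
  chisq <- sum(fit$fvec^2)
  list(n_points = n, n_par = k, chisq = chisq,
       chisq_reduced = chisq / max(n - k, 1), info = fit$info,
       iterations = fit$niter)
}

#' @export
print.sans_fit <- function(x, ...) {
  cat("<sans_fit> staged composite-model fit\n")
  m <- stack_metrics(x$params, per_monomer_charge = NA_real_)
  cat(sprintf("  L = %.2f A, R_minor = %.2f A, R_major = %.2f A (aspect %.2f)\n",
              x$params$length_a, x$params$r_minor, x$params$r_major,
              m$aspect_ratio))
  cat(sprintf("  d_ip = %.2f A, d_is = %.2f A, n = %.2f, Z = %.1f e, phi = %.3f\n",
              m$d_ip, m$d_is, x$params$pl_exp, x$params$charge,
              x$params$phi))
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  stage %-10s chi2/dof = %.3f (%d points)\n",
                nm, st$chisq_reduced, st$n_points))
  }
  invisible(x)
}

#' @export
tidy.sans_fit <- function(x, ...) {
  est <- unclass(x$params)
  fitted_terms <- c("phi", "length_a", "r_minor", "r_major", "charge",
                    "gauss_amp_ip", "q_ip", "sigma_ip",
                    "gauss_amp_is", "q_is", "sigma_is",
                    "pl_amp", "pl_exp", "bkg")
  tibble::tibble(
    term = fitted_terms,
    estimate = unlist(est[fitted_terms]),
    std.error = unname(x$se[fitted_terms])
  )
}

#' @export
glance.sans_fit <- function(x, ...) {
  tibble::tibble(
    n_points = nrow(x$curve),
    chisq_power_law = x$stages$power_law$chisq_reduced,
    chisq_gaussians = x$stages$gaussians$chisq_reduced,
    chisq_cylinder = x$stages$cylinder$chisq_reduced,
    polished = !is.null(x$stages$polish)
  )
}

#' @export
augment.sans_fit <- function(x, ...) {
  comp <- sans_model_components(x$curve$q, x$params,
                                x$config$n_alpha, x$config$n_psi)
  dplyr::bind_cols(tibble::as_tibble(x$curve),
                   comp[, c("cylinder", "gauss_ip", "gauss_is",
                            "power_law", "total")]) |>
    dplyr::rename(.fitted = "total")
}

#' @export
autoplot.sans_fit <- function(object, ...) {
  aug <- augment(object)
  long <- aug |>
    dplyr::select("q", "cylinder", "gauss_ip", "gauss_is", "power_law",
                  ".fitted") |>
    tidyr::pivot_longer(-"q", names_to = "component", values_to = "value")
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$q)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity),
                        alpha = 0.4, size = 0.6) +
    ggplot2::geom_line(data = long,
                       ggplot2::aes(y = .data$value,
                                    colour = .data$component)) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(Q ~ (ring(A)^-1)),
                  y = paste0("I(Q) (", curve_unit(object$curve), ")"),
                  colour = NULL)
  }
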