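#' Construct a scattering curve
#'
#' A scattering curve holds a measured (or modelled) differential scattering
#' cross section \eqn{I(Q)} on a strictly increasing momentum-transfer grid,
#' with optional 1-sigma uncertainties. It is an ordinary tibble with columns
#' `q` (\eqn{\AA^{-1}}), `intensity` and `sigma`, carrying the intensity unit
#' as an attribute so that absolute-scale (`"cm^-1"`) and per-atom
#' (`"barns/sr/atom"`) data are never silently mixed.
#'
#' Rows are sorted by `q`; duplicated `q` values are averaged (intensities by
#' mean, sigmas combined in quadrature of the mean) so the grid stays strictly
#' increasing.
#'
#' @param q Momentum transfer grid, \eqn{\AA^{-1}}, positive.
#' @param intensity Intensity per `q` point.
#' @param sigma Optional 1-sigma uncertainty per point (same unit as
#'   `intensity`); `NA` when absent.
#' @param unit_tag Intensity unit, one of `"cm^-1"` or `"barns/sr/atom"`.
#' @return A tibble of class `scattering_curve` with columns `q`, `intensity`,
#'   `sigma` and attribute `unit_tag`.
#' @examples
#' scattering_curve(c(0.1, 0.2), c(5, 3), c(0.5, 0.3))
#' @export
scattering_curve <- function(q, intensity, sigma = NA_real_,
                             unit_tag = c("cm^-1", "barns/sr/atom")) {
  unit_tag <- match.arg(unit_tag)
  if (length(q) == 0L) abort("scattering curve is empty")
  if (!is.numeric(q) || !is.numeric(intensity)) {
    abort("q and intensity must be numeric")
  }
  sigma <- rep_len(as.numeric(sigma), length(q))
  if (length(intensity) != length(q)) {
    abort("q and intensity lengths differ")
  }
  if (any(!is.finite(q)) || any(q <= 0)) {
    abort("q must be finite and positive")
  }
  if (any(sigma < 0, na.rm = TRUE)) abort("sigma must be non-negative")
  out <- tibble::tibble(q = as.numeric(q), intensity = as.numeric(intensity),
                        sigma = sigma)
  out <- dplyr::arrange(out, .data$q)
  if (anyDuplicated(out$q)) {
    out <- out |>
      dplyr::group_by(.data$q) |>
      dplyr::summarise(
        sigma = if (all(is.na(.data$sigma))) NA_real_ else
          sqrt(sum(.data$sigma^2, na.rm = TRUE)) / dplyr::n(),
        intensity = mean(.data$intensity),
        .groups = "drop"
      ) |>
      dplyr::select("q", "intensity", "sigma")
  }
  new_scattering_curve(out, unit_tag)
}

new_scattering_curve <- function(df, unit_tag) {
  attr(df, "unit_tag") <- unit_tag
  class(df) <- unique(c("scattering_curve", class(tibble::tibble())))
  df
}

#' Intensity unit of a scattering curve
#' @param curve A [scattering_curve()].
#' @return The unit tag string.
#' @export
curve_unit <- function(curve) attr(curve, "unit_tag") %||% "cm^-1"

#' Read a scattering curve from delimited text
#'
#' Reads 2- or 3-column whitespace- or comma-delimited text (`Q`, `I`,
#' optionally `sigma`). Lines starting with `#` are comments. Rows are sorted
#' in `q` and exact duplicate `q` values averaged.
#'
#' @param path File path.
#' @param unit_tag Intensity unit of the file, see [scattering_curve()].
#' @return A [scattering_curve()].
#' @export
read_curve <- function(path, unit_tag = c("cm^-1", "barns/sr/atom")) {
  unit_tag <- match.arg(unit_tag)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  idx <- which(keep)
  if (length(idx) == 0L) abort(paste0("empty curve file: ", path))
  rows <- strsplit(gsub(",", " ", lines[idx]), "[[:space:]]+")
  ncol <- lengths(rows)
  if (any(ncol < 2L | ncol > 3L)) {
    bad <- idx[which(ncol < 2L | ncol > 3L)[1]]
    abort(paste0("line ", bad, " of ", path, " does not have 2 or 3 columns"))
  }
  vals <- suppressWarnings(lapply(rows, as.numeric))
  bad <- vapply(vals, function(v) any(is.na(v)), logical(1))
  if (any(bad)) {
    abort(paste0("non-numeric value on line ", idx[which(bad)[1]], " of ", path))
  }
  q <- vapply(vals, `[`, numeric(1), 1L)
  i <- vapply(vals, `[`, numeric(1), 2L)
  s <- vapply(vals, function(v) if (length(v) >= 3L) v[3] else NA_real_,
              numeric(1))
  scattering_curve(q, i, s, unit_tag)
}

#' Write a scattering curve to delimited text
#'
#' @param curve A [scattering_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  header <- paste0("# q(A^-1) intensity(", curve_unit(curve), ") sigma")
  has_sigma <- !all(is.na(curve$sigma))
  body <- if (has_sigma) {
    sprintf("%.12g %.12g %.12g", curve$q, curve$intensity, curve$sigma)
  } else {
    sprintf("%.12g %.12g", curve$q, curve$intensity)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Stitch a wide-angle curve onto an absolutely scaled small-angle curve
#'
#' Rescales the wide-angle curve by the least-squares scalar that best matches
#' the small-angle curve over a shared overlap window, then merges the two:
#' inside the overlap the (absolutely scaled) small-angle points are kept,
#' outside it each instrument contributes its own grid. This mirrors the
#' standard reduction step in which per-atom wide-angle data are rescaled onto
#' the absolute \eqn{cm^{-1}} scale of a dedicated SANS instrument.
#'
#' The scale minimises \eqn{\sum (s\,I_{wide} - I_{small})^2} over the overlap,
#' with the wide curve linearly interpolated onto the small curve's overlap
#' grid: \eqn{s = \sum I_w I_s / \sum I_w^2}.
#'
#' @param wide Wide-angle [scattering_curve()] (arbitrary scale).
#' @param small Small-angle [scattering_curve()] on absolute scale.
#' @param overlap Length-2 numeric, the `q` interval shared by both curves.
#' @return A [scattering_curve()] on the union grid, with `unit_tag` taken
#'   from `small` and attribute `stitch_scale` recording the fitted scalar.
#' @export
stitch_curves <- function(wide, small, overlap) {
  stopifnot(length(overlap) == 2L)
  overlap <- sort(as.numeric(overlap))
  in_w <- wide$q >= overlap[1] & wide$q <= overlap[2]
  in_s <- small$q >= overlap[1] & small$q <= overlap[2]
  if (sum(in_w) < 3L || sum(in_s) < 3L) {
    abort("overlap interval must contain at least 3 points of each curve")
  }
  qs <- small$q[in_s]
  iw <- approx(wide$q, wide$intensity, xout = qs, rule = 1)$y
  is <- small$intensity[in_s]
  ok <- is.finite(iw)
  if (sum(ok) < 3L) abort("curves do not overlap on the stated interval")
  scale <- sum(iw[ok] * is[ok]) / sum(iw[ok]^2)
  if (!is.finite(scale) || scale <= 0) {
    abort("fitted stitch scale is non-positive; curves look incompatible")
  }
  keep_wide <- !(wide$q >= overlap[1] & wide$q <= overlap[2])
  out <- scattering_curve(
    q = c(wide$q[keep_wide], small$q),
    intensity = c(scale * wide$intensity[keep_wide], small$intensity),
    sigma = c(scale * wide$sigma[keep_wide], small$sigma),
    unit_tag = curve_unit(small)
  )
  attr(out, "stitch_scale") <- scale
  out
}

#' Subtract a buffer scan from a sample curve
#'
#' Point-by-point subtraction `I_sample - fraction * I_buffer`, the usual
#' solvent-background correction against a pure-solvent (e.g. 100% D2O) scan.
#' The buffer is linearly interpolated onto the sample grid when the grids
#' differ; uncertainties combine in quadrature.
#'
#' @param sample Sample [scattering_curve()].
#' @param buffer Buffer [scattering_curve()].
#' @param fraction Buffer volume fraction in `[0, 1]`; defaults to 1 (pure
#'   solvent scan subtracted in full).
#' @return A [scattering_curve()] on the sample grid.
#' @export
subtract_buffer <- function(sample, buffer, fraction = 1) {
  stopifnot(is.numeric(fraction), length(fraction) == 1L)
  if (fraction < 0 || fraction > 1) abort("fraction must be in [0, 1]")
  ib <- approx(buffer$q, buffer$intensity, xout = sample$q, rule = 1)$y
  if (all(is.na(ib))) abort("sample and buffer q grids do not overlap")
  sb <- if (all(is.na(buffer$sigma))) rep(NA_real_, nrow(sample)) else
    approx(buffer$q, buffer$sigma, xout = sample$q, rule = 1)$y
  keep <- is.finite(ib)
  sig <- ifelse(is.na(sample$sigma) & is.na(sb), NA_real_,
                sqrt(ifelse(is.na(sample$sigma), 0, sample$sigma^2) +
                       fraction^2 * ifelse(is.na(sb), 0, sb^2)))
  scattering_curve(
    q = sample$q[keep],
    intensity = (sample$intensity - fraction * ib)[keep],
    sigma = sig[keep],
    unit_tag = curve_unit(sample)
  )
}

#' @export
autoplot.scattering_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$q, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = expression(Q ~ (ring(A)^-1)),
      y = paste0("I(Q) (", curve_unit(object), ")")
    )
}
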