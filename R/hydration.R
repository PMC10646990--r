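#' Site-site radial distribution function
#'
#' Histogram of minimum-image distances between two site types in a periodic
#' cubic box, normalized per frame to the bulk density of the second type:
#' \deqn{g_{\alpha\beta}(r) = \frac{n_{\alpha\beta}(r)}
#'   {N_\alpha\, \rho_\beta\, 4\pi r^2 \Delta r},}
#' averaged over the supplied frames. For \eqn{\alpha = \beta} self pairs are
#' excluded and \eqn{\rho_\beta} uses \eqn{N_\beta - 1} (each remaining atom
#' sees the other \eqn{N_\beta - 1}).
#'
#' @param ensemble A single [atomic_configuration()] or a list of them
#'   (frames of one system; equal box sides required).
#' @param site_pair Character vector of two site labels `c(alpha, beta)`.
#' @param bin_width Histogram bin width, \eqn{\AA}.
#' @param r_max Histogram range, \eqn{\AA}; must not exceed half the box.
#' @return Tibble with columns `r` (bin centers) and `g`, plus attributes
#'   `pair`, `rho_beta` (mean bulk density of beta, \eqn{\AA^{-3}}),
#'   `n_alpha`, `n_frames`.
#' @export
compute_rdf <- function(ensemble, site_pair, bin_width = 0.05, r_max = NULL) {
  frames <- as_frames(ensemble)
  stopifnot(length(site_pair) == 2L)
  box <- frames[[1]]$box_side
  if (any(vapply(frames, function(f) f$box_side, numeric(1)) != box)) {
    abort("all frames must share the same box side")
  }
  if (is.null(r_max)) r_max <- box / 2
  if (r_max > box / 2 + 1e-9) abort("r_max must not exceed half the box side")
  nbin <- ceiling(r_max / bin_width)
  edges <- bin_width * (0:nbin)
  counts <- numeric(nbin)
  same <- site_pair[1] == site_pair[2]
  n_alpha_tot <- 0
  rho_beta_tot <- 0
  for (f in frames) {
    ia <- which(f$atoms$site_label == site_pair[1])
    ib <- which(f$atoms$site_label == site_pair[2])
    if (length(ia) == 0L || length(ib) == 0L) {
      missing_lab <- if (length(ia) == 0L) site_pair[1] else site_pair[2]
      abort(paste0("no atoms with label ", missing_lab, " in a frame"))
    }
    xa <- as.matrix(f$atoms[ia, c("x", "y", "z")])
    xb <- as.matrix(f$atoms[ib, c("x", "y", "z")])
    d <- minimum_image_distances(xa, xb, box)
    if (same) d[cbind(seq_along(ia), seq_along(ia))] <- NA
    d <- d[!is.na(d) & d < r_max & d > 0]
    counts <- counts + tabulate(pmin(floor(d / bin_width) + 1L, nbin), nbin)
    n_alpha_tot <- n_alpha_tot + length(ia)
    nb_eff <- if (same) length(ib) - 1L else length(ib)
    rho_beta_tot <- rho_beta_tot + nb_eff / box^3
  }
  n_frames <- length(frames)
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nbin + 1)]^3)
  norm <- (n_alpha_tot / n_frames) * (rho_beta_tot / n_frames) * shell *
    n_frames
  g <- counts / norm
  out <- tibble::tibble(r = edges[-(nbin + 1)] + bin_width / 2, g = g)
  attr(out, "pair") <- paste(site_pair, collapse = "-")
  attr(out, "rho_beta") <- rho_beta_tot / n_frames
  attr(out, "n_alpha") <- n_alpha_tot / n_frames
  attr(out, "n_frames") <- n_frames
  out
}

as_frames <- function(ensemble) {
  if (inherits(ensemble, "atomic_configuration")) return(list(ensemble))
  if (length(ensemble) == 0L) abort("ensemble is empty")
  stopifnot(all(vapply(ensemble, inherits, logical(1),
                       "atomic_configuration")))
  ensemble
}

minimum_image_distances <- function(xa, xb, box) {
  dx <- outer(xa[, 1], xb[, 1], `-`)
  dy <- outer(xa[, 2], xb[, 2], `-`)
  dz <- outer(xa[, 3], xb[, 3], `-`)
  dx <- dx - box * round(dx / box)
  dy <- dy - box * round(dy / box)
  dz <- dz - box * round(dz / box)
  sqrt(dx^2 + dy^2 + dz^2)
}

#' First hydration-shell peak position
#'
#' Position of the first local maximum of an RDF with `g` at or above a
#' threshold inside a search window, refined by quadratic interpolation
#' through the three bins around the maximum. Returns `NA` (the "no shell"
#' signal, which drives the buried classification downstream) when no
#' qualifying maximum exists.
#'
#' Besides the absolute height threshold, a candidate must reach a fraction
#' of the window maximum (`min_fraction_of_max`): counting noise on the
#' steep flank of a strong peak would otherwise register as a spurious
#' "first" maximum whenever the RDF is far above 1 (as it is around a
#' strongly hydrated site).
#'
#' @param rdf Tibble with columns `r`, `g` (e.g. from [compute_rdf()]).
#' @param window Length-2 search window in `r`, \eqn{\AA}.
#' @param threshold Minimum peak height.
#' @param min_fraction_of_max Minimum peak height relative to the largest
#'   `g` inside the window.
#' @return Peak position, \eqn{\AA}, or `NA_real_`.
#' @export
first_shell_peak <- function(rdf, window = c(1.0, 3.5), threshold = 1.2,
                             min_fraction_of_max = 0.3) {
  r <- rdf$r; g <- rdf$g
  n <- length(r)
  if (window[1] < min(r) - (r[2] - r[1]) || window[2] > max(r) + (r[2] - r[1])) {
    abort("search window extends beyond the r grid")
  }
  in_win <- r >= window[1] & r <= window[2]
  if (!any(in_win)) abort("search window contains no grid points")
  g_floor <- max(threshold, min_fraction_of_max * max(g[in_win]))
  for (i in 2:(n - 1)) {
    if (r[i] < window[1] || r[i] > window[2]) next
    if (g[i] >= g_floor && g[i] >= g[i - 1] && g[i] >= g[i + 1]) {
      denom <- g[i - 1] - 2 * g[i] + g[i + 1]
      if (denom < 0) {
        dr <- r[i + 1] - r[i]
        return(r[i] + dr / 2 * (g[i - 1] - g[i + 1]) / denom)
      }
      return(r[i])
    }
  }
  NA_real_
}

#' Hydrogen-bonding index from first-peak positions
#'
#' The orientation of first-shell waters around a surface site X shows up as
#' the offset between the first peaks of the X-Ow and X-Hw RDFs:
#' \eqn{D = r_{X\mathrm{-}O_w} - r_{X\mathrm{-}H_w}}. A hydrogen-bond
#' acceptor pulls one water hydrogen inward (\eqn{D > 0}); a donor pushes
#' both hydrogens outward (\eqn{D < 0}). Normalizing gives the index
#' \deqn{\Delta = D / R_{donor} \ (D \ge 0), \qquad
#'       \Delta = D / R_{acceptor} \ (D < 0),}
#' clamped to \eqn{[-1, 1]}: +1 is a perfect acceptor (one OH bond pointing
#' straight at X), -1 a perfect donor (both hydrogens pointing straight
#' away). `R_donor` is the water OH bond length as quoted for the index
#' definition (0.96 \eqn{\AA}); `R_acceptor` is the radial hydrogen offset
#' when both hydrogens point away, \eqn{r_{OH} \cos(\theta_{HOH}/2)}
#' (0.577 \eqn{\AA} for the 3-site reference geometry, see
#' [water_r_acceptor()]).
#'
#' @param r_xow First-peak position of the site-Ow RDF, \eqn{\AA} (or `NA`).
#' @param r_xhw First-peak position of the site-Hw RDF, \eqn{\AA} (or `NA`).
#' @param r_donor Donor-side normalization, \eqn{\AA}.
#' @param r_acceptor Acceptor-side normalization, \eqn{\AA}.
#' @param neutral_threshold Sites with \eqn{|\Delta|} below this are classed
#'   `"neutral"`.
#' @return Tibble with one row: `r_xow`, `r_xhw`, `d` (peak offset),
#'   `delta`, `class` (acceptor / donor / neutral / buried).
#' @export
hbond_delta <- function(r_xow, r_xhw, r_donor = 0.96,
                        r_acceptor = water_r_acceptor(),
                        neutral_threshold = 0.1) {
  if (is.na(r_xow) || is.na(r_xhw)) {
    return(tibble::tibble(r_xow = r_xow, r_xhw = r_xhw, d = NA_real_,
                          delta = NA_real_, class = "buried"))
  }
  d <- r_xow - r_xhw
  delta <- if (d >= 0) d / r_donor else d / r_acceptor
  delta <- max(-1, min(1, delta))
  cls <- if (abs(delta) < neutral_threshold) "neutral" else
    if (d >= 0) "acceptor" else "donor"
  tibble::tibble(r_xow = r_xow, r_xhw = r_xhw, d = d, delta = delta,
                 class = cls)
}

#' Acceptor-side normalization of the reference water geometry
#'
#' Radial offset of the water hydrogens when both point directly away from
#' the site: \eqn{r_{OH}\cos(\theta_{HOH}/2)}.
#'
#' @param r_oh Water OH bond length, \eqn{\AA}.
#' @param theta_hoh HOH angle, degrees.
#' @return Offset, \eqn{\AA} (0.577 for OH 1.0 \eqn{\AA}, 109.47 deg).
#' @export
water_r_acceptor <- function(r_oh = 1.0, theta_hoh = 109.47) {
  r_oh * cos(theta_hoh / 2 * pi / 180)
}

#' Hydrogen-bonding map of an assembly surface
#'
#' For each requested surface site label: pools the equivalent atoms across
#' all monomers and frames (equivalent sites are assumed to share one
#' hydration structure), computes the site-Ow and site-Hw RDFs, locates the
#' first-shell peaks and evaluates the hydrogen-bonding index. Sites whose
#' first-shell water-oxygen coordination number falls below `buried_cutoff`
#' are classified `buried`.
#'
#' @param ensemble A single [atomic_configuration()] or list of frames.
#' @param sites Character vector of site labels to analyse; default: every
#'   label that is not a solvent/ion label.
#' @param water_labels Length-2 labels of water oxygen and hydrogen.
#' @param bin_width,r_max RDF resolution, see [compute_rdf()].
#' @param window,threshold Peak search, see [first_shell_peak()].
#' @param r_donor,r_acceptor,neutral_threshold Index normalization, see
#'   [hbond_delta()].
#' @param shell_rmax First-shell radius for the coordination count,
#'   \eqn{\AA}.
#' @param buried_cutoff Minimum first-shell Ow coordination for a site to be
#'   considered solvent-exposed.
#' @return Tibble with one row per site: `site_label`, `r_xow`, `r_xhw`,
#'   `d`, `r_used`, `delta`, `class`, `coordination`.
#' @export
delta_surface_map <- function(ensemble, sites = NULL,
                              water_labels = c("Ow", "Hw"),
                              bin_width = 0.05, r_max = NULL,
                              window = c(1.0, 3.5), threshold = 1.2,
                              r_donor = 0.96,
                              r_acceptor = water_r_acceptor(),
                              neutral_threshold = 0.1,
                              shell_rmax = 3.5, buried_cutoff = 0.5) {
  frames <- as_frames(ensemble)
  labels <- unique(frames[[1]]$atoms$site_label)
  if (is.null(sites)) {
    sites <- setdiff(labels, c(water_labels, "Na"))
  }
  missing_sites <- setdiff(sites, labels)
  if (length(missing_sites)) {
    abort(paste0("site label(s) not present: ",
                 paste(missing_sites, collapse = ", ")))
  }
  purrr::map_dfr(sites, function(s) {
    gow <- compute_rdf(frames, c(s, water_labels[1]), bin_width, r_max)
    coord <- coordination_number(gow, shell_rmax)
    if (coord < buried_cutoff) {
      rec <- hbond_delta(NA_real_, NA_real_)
    } else {
      ghw <- compute_rdf(frames, c(s, water_labels[2]), bin_width, r_max)
      rec <- hbond_delta(first_shell_peak(gow, window, threshold),
                         first_shell_peak(ghw, window, threshold),
                         r_donor, r_acceptor, neutral_threshold)
    }
    dplyr::bind_cols(
      tibble::tibble(site_label = s),
      rec |> dplyr::mutate(
        r_used = dplyr::case_when(
          is.na(.data$d) ~ NA_real_,
          .data$d >= 0 ~ r_donor,
          TRUE ~ r_acceptor),
        coordination = coord)
    )
  })
}

# first-shell coordination number: rho_beta * integral of g * 4 pi r^2 dr
coordination_number <- function(rdf, r_shell) {
  keep <- rdf$r <= r_shell
  dr <- rdf$r[2] - rdf$r[1]
  attr(rdf, "rho_beta") * sum(rdf$g[keep] * 4 * pi * rdf$r[keep]^2 * dr)
}

#' Normalize a hydrophobicity scale to [0, 1]
#'
#' Min-max normalization of a per-residue hydrophobicity scale with an
#' orientation flag so that 1 always means hydrophilic; scales published
#' with the opposite polarity are flipped exactly (order reversed).
#'
#' @param scale Tibble with columns `residue` and `value` (at least two
#'   distinct values).
#' @param hydrophilic_high Does a high raw value mean hydrophilic? If
#'   `FALSE` the normalized scale is reversed.
#' @return The input tibble with a `normalized` column in `[0, 1]`.
#' @export
normalize_hydrophobicity <- function(scale, hydrophilic_high = TRUE) {
  stopifnot(all(c("residue", "value") %in% names(scale)))
  v <- scale$value
  rng <- range(v)
  if (diff(rng) == 0) abort("constant scale cannot be normalized")
  z <- (v - rng[1]) / diff(rng)
  if (!hydrophilic_high) z <- 1 - z
  dplyr::mutate(tibble::as_tibble(scale), normalized = z)
}

#' Write a structure with the hydrogen-bonding index in the B-factor column
#'
#' Mirrors the usual surface-colouring workflow: each atom's B-factor is set
#' to the Delta of its site label (0 for sites without a record), so any
#' molecular viewer can colour the surface by hydrogen-bonding character.
#'
#' @param config An [atomic_configuration()].
#' @param delta_map Tibble from [delta_surface_map()].
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_delta_pdb <- function(config, delta_map, path) {
  write_structure(config, path)
  lines <- readLines(path)
  at <- startsWith(lines, "ATOM")
  lab <- trimws(substr(lines[at], 13, 16))
  dv <- setNames(delta_map$delta, delta_map$site_label)[lab]
  dv[is.na(dv)] <- 0
  substr(lines[at], 61, 66) <- sprintf("%6.2f", dv)
  writeLines(lines, path)
  invisible(path)
}

#' Plot a hydrogen-bonding surface map
#'
#' Bar chart of the per-site index, coloured by donor/acceptor class.
#'
#' @param delta_map Tibble from [delta_surface_map()].
#' @return A ggplot object.
#' @export
plot_delta_map <- function(delta_map) {
  df <- dplyr::filter(delta_map, !is.na(.data$delta))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$site_label, .data$delta),
    y = .data$delta, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = NULL, y = expression(Delta), fill = NULL)
}
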