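#' Construct an atomic configuration
#'
#' An atomic configuration is a periodic cubic box of typed, charged atoms
#' grouped into molecules: the container for simulation snapshots used by the
#' RDF and hydration analysis. Atoms live in a tibble with one row per atom;
#' coordinates are wrapped into `[0, box_side)`.
#'
#' @param atoms Tibble (or data frame) with columns `site_label` (chemically
#'   distinct site name, e.g. `"Ow"`, `"TyrHH"`), `element` (one of H, D, C,
#'   N, O, Na), `x`, `y`, `z` (\eqn{\AA}), `charge` (partial charge, e),
#'   `exchangeable` (logical: swaps with solvent H/D) and `molecule_id`
#'   (integer grouping).
#' @param box_side Cubic box edge, \eqn{\AA}, positive.
#' @return A list of class `atomic_configuration` with elements `box_side`
#'   and `atoms`.
#' @export
atomic_configuration <- function(atoms, box_side) {
  stopifnot(is.numeric(box_side), length(box_side) == 1L)
  if (!is.finite(box_side) || box_side <= 0) abort("box_side must be positive")
  atoms <- tibble::as_tibble(atoms)
  need <- c("site_label", "element", "x", "y", "z", "charge",
            "exchangeable", "molecule_id")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) abort(paste0("atoms is missing column(s): ",
                                 paste(miss, collapse = ", ")))
  if (any(!nzchar(atoms$site_label))) abort("site_label must be nonempty")
  bad <- setdiff(unique(atoms$element), supported_elements())
  if (length(bad)) abort(paste0("unsupported element(s): ",
                                paste(bad, collapse = ", ")))
  for (cc in c("x", "y", "z")) {
    atoms[[cc]] <- wrap_coord(atoms[[cc]], box_side)
  }
  structure(list(box_side = box_side, atoms = atoms),
            class = "atomic_configuration")
}

supported_elements <- function() c("H", "D", "C", "N", "O", "Na")

wrap_coord <- function(x, box) {
  x <- x %% box
  x[x == box] <- 0  # guard against floating-point x %% box == box
  x
}

#' @export
print.atomic_configuration <- function(x, ...) {
  cat(sprintf("<atomic_configuration> %d atoms, %d molecules, box %.3f A\n",
              nrow(x$atoms), length(unique(x$atoms$molecule_id)), x$box_side))
  cat(sprintf("  net charge %+.3f e, density %.4f atoms/A^3\n",
              sum(x$atoms$charge), nrow(x$atoms) / x$box_side^3))
  invisible(x)
}

#' Read a charge side table
#'
#' CSV with columns `site_label`, `charge_e`, `exchangeable` (0/1): the
#' per-site partial charges and exchangeable-hydrogen flags that a structure
#' file cannot carry.
#'
#' @param path CSV path.
#' @return Tibble with columns `site_label`, `charge_e`, `exchangeable`.
#' @export
read_charge_table <- function(path) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("site_label", "charge_e", "exchangeable")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("charge table missing column(s): ",
                                 paste(miss, collapse = ", ")))
  df$exchangeable <- as.logical(df$exchangeable)
  df
}

#' Read a periodic structure from PDB
#'
#' Parses a single-frame PDB file with a `CRYST1` record defining a cubic box.
#' Atom names are used as site labels and must each resolve to a row of the
#' charge side table, which supplies partial charges and exchangeable flags.
#' Coordinates are wrapped into the box. Elements come from the PDB element
#' column when present, else from the leading letters of the atom name.
#'
#' @param path PDB file path.
#' @param charge_table Tibble from [read_charge_table()] (or equivalent) with
#'   columns `site_label`, `charge_e`, `exchangeable`.
#' @return An [atomic_configuration()].
#' @export
read_structure <- function(path, charge_table) {
  lines <- readLines(path, warn = FALSE)
  cry <- lines[startsWith(lines, "CRYST1")]
  if (length(cry) == 0L) abort(paste0("no CRYST1 record in ", path))
  box <- as.numeric(substr(cry[1], 7, 15))
  if (!is.finite(box) || box <= 0) abort("CRYST1 box edge is not positive")
  at <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (length(at) == 0L) abort(paste0("no atoms in ", path))
  name <- trimws(substr(at, 13, 16))
  resid <- suppressWarnings(as.integer(trimws(substr(at, 23, 26))))
  x <- as.numeric(substr(at, 31, 38))
  y <- as.numeric(substr(at, 39, 46))
  z <- as.numeric(substr(at, 47, 54))
  elem <- trimws(substr(at, 77, 78))
  guess <- sub("[^A-Za-z].*$", "", name)
  guess <- ifelse(toupper(substr(guess, 1, 2)) == "NA", "Na",
                  toupper(substr(guess, 1, 1)))
  elem <- ifelse(nzchar(elem), elem, guess)
  elem <- ifelse(toupper(elem) == "NA", "Na",
                 ifelse(nchar(elem) == 1L, toupper(elem), elem))
  unknown <- setdiff(unique(name), charge_table$site_label)
  if (length(unknown)) {
    abort(paste0("atom name(s) not in charge table: ",
                 paste(unknown, collapse = ", ")))
  }
  idx <- match(name, charge_table$site_label)
  atomic_configuration(
    tibble::tibble(
      site_label = name, element = elem, x = x, y = y, z = z,
      charge = charge_table$charge_e[idx],
      exchangeable = as.logical(charge_table$exchangeable[idx]),
      molecule_id = resid
    ),
    box_side = box
  )
}

#' Write a configuration to PDB
#'
#' Emits a `CRYST1` record for the cubic box plus one `ATOM` record per atom
#' (site label in the atom-name field, molecule id in the residue field,
#' element in the element field). Charges are not representable in PDB; write
#' the matching side table with [write_charge_table()].
#'
#' @param config An [atomic_configuration()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(config, path) {
  a <- config$atoms
  cry <- sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                 config$box_side, config$box_side, config$box_side)
  if (any(nchar(a$site_label) > 4L)) {
    abort("site labels longer than 4 characters do not fit the PDB name field")
  }
  serial <- ((seq_len(nrow(a)) - 1L) %% 99999L) + 1L
  resid <- ((as.integer(a$molecule_id) - 1L) %% 9999L) + 1L
  nm <- ifelse(nchar(a$site_label) < 4L, paste0(" ", a$site_label),
               a$site_label)
  rec <- sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 serial, nm, "MOL", resid, a$x, a$y, a$z, 1, 0,
                 ifelse(a$element == "Na", "NA", a$element))
  writeLines(c(cry, rec, "END"), path)
  invisible(path)
}

#' Write the charge side table matching a configuration
#'
#' One row per distinct `site_label` with its partial charge and exchangeable
#' flag (sites sharing a label must share both).
#'
#' @param config An [atomic_configuration()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_charge_table <- function(config, path) {
  tab <- config$atoms |>
    dplyr::distinct(.data$site_label, charge_e = .data$charge,
                    exchangeable = as.integer(.data$exchangeable))
  if (anyDuplicated(tab$site_label)) {
    abort("site labels with inconsistent charge/exchangeable flags")
  }
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
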