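#' Concentric-sphere cell phantom
#'
#' The cell is modelled as two concentric spheres of unit-density water: a
#' nucleus of radius `r_nucleus_um` inside a cell of radius `r_cell_um`.
#' The Monte Carlo source can be a smaller central sphere of radius
#' `r_source_um`, representing the condensed chromatin region where a
#' DNA-intercalated radionuclide actually decays. Defaults are the measured
#' PC3 average dimensions (2 um nucleus, 4 um cell) with a 0.7 um chromatin
#' source.
#'
#' @param r_source_um Radius of the central emitting sphere, um.
#' @param r_nucleus_um Nucleus radius, um.
#' @param r_cell_um Cell radius, um.
#' @param density_g_cm3 Mass density, g/cm^3 (liquid water default 1.0).
#' @return An object of class `cell_phantom`.
#' @examples
#' cell_phantom()
#' region_masses(cell_phantom())
#' @export
cell_phantom <- function(r_source_um = 0.7, r_nucleus_um = 2,
                         r_cell_um = 4, density_g_cm3 = 1.0) {
  if (!(r_source_um > 0 && r_source_um <= r_nucleus_um &&
        r_nucleus_um < r_cell_um)) {
    stop("phantom radii must satisfy 0 < r_source <= r_nucleus < r_cell",
         call. = FALSE)
  }
  if (density_g_cm3 <= 0) stop("`density_g_cm3` must be positive", call. = FALSE)
  structure(
    list(r_source_um = r_source_um, r_nucleus_um = r_nucleus_um,
         r_cell_um = r_cell_um, density_g_cm3 = density_g_cm3),
    class = "cell_phantom"
  )
}

#' @export
print.cell_phantom <- function(x, ...) {
  m <- region_masses(x)
  cat(sprintf("Cell phantom: source %g um | nucleus %g um | cell %g um (density %g g/cm3)\n",
              x$r_source_um, x$r_nucleus_um, x$r_cell_um, x$density_g_cm3))
  cat(sprintf("  masses: nucleus %.4g kg, cytoplasm %.4g kg\n",
              m$nucleus_kg, m$cytoplasm_kg))
  invisible(x)
}

#' Compartment masses of a cell phantom
#'
#' Sphere-volume masses: the nucleus is the inner ball, the cytoplasm the
#' shell between nucleus and cell radius.
#'
#' @param phantom A [cell_phantom()].
#' @return List with `nucleus_kg` and `cytoplasm_kg`.
#' @export
region_masses <- function(phantom) {
  stopifnot(inherits(phantom, "cell_phantom"))
  rho_kg_m3 <- phantom$density_g_cm3 * 1000
  vol <- function(r_um) 4 / 3 * pi * (r_um * 1e-6)^3
  v_n <- vol(phantom$r_nucleus_um)
  v_cell <- vol(phantom$r_cell_um)
  list(nucleus_kg = v_n * rho_kg_m3,
       cytoplasm_kg = (v_cell - v_n) * rho_kg_m3)
}

#' Discrete electron emission spectrum
#'
#' A set of monoenergetic electron lines, each with an energy in keV and a
#' yield (electrons emitted per nuclear decay).
#'
#' @param energy_keV Line energies, keV (> 0).
#' @param yield_per_decay Yields per decay (>= 0), same length.
#' @param label Spectrum label.
#' @return An object of class `electron_spectrum` (a data frame with
#'   attributes).
#' @examples
#' electron_spectrum(1, 1, label = "1 keV test line")
#' @export
electron_spectrum <- function(energy_keV, yield_per_decay, label = "spectrum") {
  if (length(energy_keV) == 0L) {
    stop("spectrum must contain at least one line", call. = FALSE)
  }
  if (length(energy_keV) != length(yield_per_decay)) {
    stop("`energy_keV` and `yield_per_decay` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(energy_keV)) || any(energy_keV <= 0)) {
    stop("line energies must be positive", call. = FALSE)
  }
  if (any(!is.finite(yield_per_decay)) || any(yield_per_decay < 0)) {
    stop("yields must be non-negative", call. = FALSE)
  }
  structure(
    data.frame(energy_keV = energy_keV, yield_per_decay = yield_per_decay),
    label = label,
    class = c("electron_spectrum", "data.frame")
  )
}

#' Total electron energy emitted per decay
#'
#' @param spectrum An [electron_spectrum()].
#' @return Sum of energy x yield over all lines, keV per decay.
#' @export
spectrum_energy_per_decay <- function(spectrum) {
  stopifnot(inherits(spectrum, "electron_spectrum"))
  sum(spectrum$energy_keV * spectrum$yield_per_decay)
}

#' Read an electron spectrum from a text file
#'
#' Accepts two-column text: energy in keV and yield per decay, separated by
#' whitespace or commas; lines starting with `#` and blank lines are ignored.
#'
#' @param path File path.
#' @param label Spectrum label; defaults to the file name.
#' @return An [electron_spectrum()].
#' @export
read_spectrum <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop("spectrum file contains no data lines", call. = FALSE)
  e <- numeric(length(keep)); y <- numeric(length(keep))
  for (i in seq_along(keep)) {
    fields <- strsplit(trimws(lines[keep[i]]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2L || any(is.na(vals[1:2]))) {
      stop(sprintf("malformed spectrum line %d: '%s'", keep[i], lines[keep[i]]),
           call. = FALSE)
    }
    e[i] <- vals[1]; y[i] <- vals[2]
  }
  electron_spectrum(e, y, label = label)
}

#' Write an electron spectrum to a two-column text file
#'
#' @param spectrum An [electron_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "electron_spectrum"))
  header <- c(sprintf("# %s", attr(spectrum, "label")),
              "# energy_keV  yield_per_decay")
  body <- sprintf("%.6g\t%.6g", spectrum$energy_keV, spectrum$yield_per_decay)
  writeLines(c(header, body), path)
  invisible(path)
}
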