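# Monte Carlo electron transport in the concentric-sphere phantom.
#
# The engine is a straight-ahead continuous-slowing-down (CSDA) transport:
# each electron travels along its emission direction, losing energy at the
# stopping-power rate, with deposits split between nucleus and cytoplasm at
# the sphere boundaries by exact ray-sphere intersection. No angular
# scattering, secondaries or photons are modelled: at the micron scale of a
# two-compartment cell the dose partition is dominated by chord-length
# geometry, which this captures exactly for the straight path.

KEV_TO_J <- 1.602176634e-16

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Sample isotropic emission points in a phantom region
#'
#' Points are uniform in the named volume; for balls and shells the radius is
#' drawn by inverse-CDF sampling on r^3 so that density is uniform per unit
#' volume.
#'
#' @param region One of `"central_sphere"` (the chromatin source ball),
#'   `"nucleus"` (homogeneous nucleus, the MIRD-like configuration) or
#'   `"cytoplasm_shell"`.
#' @param phantom A [cell_phantom()].
#' @param n Number of points.
#' @param seed Optional RNG seed (the global RNG state is restored on exit).
#' @return An `n` x 3 matrix of coordinates in um.
#' @export
sample_emission_point <- function(region, phantom, n = 1L, seed = NULL) {
  stopifnot(inherits(phantom, "cell_phantom"))
  if (!region %in% c("central_sphere", "nucleus", "cytoplasm_shell")) {
    stop("unknown source region: ", region, call. = FALSE)
  }
  with_seed(seed, {
    u <- stats::runif(n)
    r <- switch(region,
      central_sphere = phantom$r_source_um * u^(1 / 3),
      nucleus = phantom$r_nucleus_um * u^(1 / 3),
      cytoplasm_shell = {
        r3_in <- phantom$r_nucleus_um^3
        r3_out <- phantom$r_cell_um^3
        (r3_in + u * (r3_out - r3_in))^(1 / 3)
      })
    z <- stats::runif(n, -1, 1)
    phi <- stats::runif(n, 0, 2 * pi)
    s <- sqrt(pmax(1 - z^2, 0))
    cbind(x = r * s * cos(phi), y = r * s * sin(phi), z = r * z)
  })
}

#' Sample isotropic unit direction vectors
#'
#' @param n Number of directions.
#' @param seed Optional RNG seed.
#' @return An `n` x 3 matrix of unit vectors.
#' @export
sample_direction <- function(n = 1L, seed = NULL) {
  with_seed(seed, {
    z <- stats::runif(n, -1, 1)
    phi <- stats::runif(n, 0, 2 * pi)
    s <- sqrt(pmax(1 - z^2, 0))
    cbind(x = s * cos(phi), y = s * sin(phi), z = z)
  })
}

# Ray path lengths through the nested spheres. start and dir are n x 3
# matrices; returns cut points (s1, s2, s3) along the ray: the nucleus is
# traversed on [s1, s2], the cytoplasm on [0, s1] and [s2, s3], and the
# electron leaves the cell at s3.
.ray_cuts <- function(start, dir, phantom) {
  b <- rowSums(start * dir)
  p2 <- rowSums(start * start)
  c_n <- p2 - phantom$r_nucleus_um^2
  c_c <- p2 - phantom$r_cell_um^2
  disc_c <- b^2 - c_c
  s3 <- -b + sqrt(pmax(disc_c, 0))      # always real: start is inside the cell
  disc_n <- b^2 - c_n
  has_n <- disc_n > 0
  sq <- sqrt(pmax(disc_n, 0))
  t1 <- -b - sq
  t2 <- -b + sq
  s1 <- ifelse(has_n & t2 > 0, pmax(t1, 0), 0)
  s2 <- ifelse(has_n & t2 > 0, pmax(pmin(t2, s3), 0), 0)
  s1 <- pmin(s1, s3)
  cbind(s1 = s1, s2 = s2, s3 = s3)
}

# Core scorer: per-history energy deposits for a monoenergetic line.
# Deposits are computed as telescoping differences of the residual energy at
# the cut points, so nucleus + cytoplasm + escaped equals the initial energy
# exactly in floating point.
.trace_histories <- function(start, dir, energy_keV, phantom, model) {
  cuts <- .ray_cuts(start, dir, phantom)
  r0 <- model$range(energy_keV)
  e_at <- function(s) ifelse(s >= r0, 0, model$energy_at_range(r0 - s))
  e1 <- e_at(cuts[, "s1"])
  e2 <- e_at(cuts[, "s2"])
  e3 <- e_at(cuts[, "s3"])
  list(
    nucleus = e1 - e2,
    cytoplasm = (energy_keV - e1) + (e2 - e3),
    escaped = e3
  )
}

#' Transport one electron and score per-region energy deposits
#'
#' Traces a single electron from `start` along `direction`, depositing energy
#' continuously at the stopping-power rate. Deposits are split between
#' nucleus and cytoplasm at the sphere boundaries; residual energy below the
#' transport floor is deposited locally; energy carried beyond the cell
#' boundary is scored as escaped.
#'
#' @param start Numeric length-3 starting point, um (must be inside the cell).
#' @param direction Numeric length-3 direction (normalized internally; the
#'   zero vector is an error).
#' @param energy_keV Initial electron energy, keV.
#' @param phantom A [cell_phantom()].
#' @param model A [stopping_model()].
#' @return List with `nucleus`, `cytoplasm` and `escaped` energies in keV;
#'   the three sum exactly to `energy_keV`.
#' @examples
#' csda_deposit(c(0, 0, 0), c(0, 0, 1), 0.05, cell_phantom())
#' @export
csda_deposit <- function(start, direction, energy_keV, phantom = cell_phantom(),
                         model = stopping_model()) {
  stopifnot(length(start) == 3L, length(direction) == 3L,
            inherits(phantom, "cell_phantom"), inherits(model, "stopping_model"))
  if (energy_keV <= 0) stop("`energy_keV` must be positive", call. = FALSE)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("`direction` must be a non-zero vector", call. = FALSE)
  if (sum(start^2) > phantom$r_cell_um^2 * (1 + 1e-9)) {
    stop("`start` must lie inside the cell", call. = FALSE)
  }
  d <- .trace_histories(matrix(start, 1), matrix(direction / nrm, 1),
                        energy_keV, phantom, model)
  lapply(d, as.numeric)
}

#' Monte Carlo cellular S-values for a discrete electron spectrum
#'
#' Runs `n_histories` electron histories per spectrum line from the chosen
#' source region and scores per-decay energy deposits in nucleus and
#' cytoplasm. Per-decay quantities are yield-weighted sums over lines;
#' standard errors come from the history-level variance of each line.
#' S-values are deposits converted to dose: S(target <- source) =
#' E_target / m_target in Gy/(Bq·s).
#'
#' @param spectrum An [electron_spectrum()].
#' @param phantom A [cell_phantom()].
#' @param source_region `"central_sphere"` (default; the chromatin-source
#'   configuration), `"nucleus"` (homogeneous, MIRD-like) or
#'   `"cytoplasm_shell"`.
#' @param n_histories Histories per spectrum line.
#' @param seed RNG seed (required for a reproducible result).
#' @param model A [stopping_model()].
#' @return An object of class `transport_result`: per-decay energy deposits
#'   (keV) with standard errors, escaped energy, S-value estimates for
#'   nucleus and cytoplasm targets with standard errors, and the run
#'   configuration.
#' @examples
#' sp <- electron_spectrum(0.1, 1)
#' res <- run_s_value_mc(sp, n_histories = 100, seed = 1)
#' @export
run_s_value_mc <- function(spectrum, phantom = cell_phantom(),
                           source_region = c("central_sphere", "nucleus",
                                             "cytoplasm_shell"),
                           n_histories = 1e5, seed = NULL,
                           model = stopping_model()) {
  stopifnot(inherits(spectrum, "electron_spectrum"),
            inherits(phantom, "cell_phantom"),
            inherits(model, "stopping_model"))
  source_region <- match.arg(source_region)
  if (nrow(spectrum) == 0L) stop("spectrum is empty", call. = FALSE)
  n_histories <- as.integer(n_histories)
  if (n_histories < 1L) stop("`n_histories` must be >= 1", call. = FALSE)

  with_seed(seed, {
    mean_n <- mean_cy <- mean_esc <- var_n <- var_cy <- numeric(nrow(spectrum))
    for (i in seq_len(nrow(spectrum))) {
      start <- sample_emission_point(source_region, phantom, n_histories)
      dir <- sample_direction(n_histories)
      d <- .trace_histories(start, dir, spectrum$energy_keV[i], phantom, model)
      mean_n[i] <- mean(d$nucleus)
      mean_cy[i] <- mean(d$cytoplasm)
      mean_esc[i] <- mean(d$escaped)
      var_n[i] <- stats::var(d$nucleus)
      var_cy[i] <- stats::var(d$cytoplasm)
    }
    y <- spectrum$yield_per_decay
    edep_n <- sum(y * mean_n)
    edep_cy <- sum(y * mean_cy)
    edep_esc <- sum(y * mean_esc)
    se_n <- sqrt(sum(y^2 * var_n / n_histories))
    se_cy <- sqrt(sum(y^2 * var_cy / n_histories))
    m <- region_masses(phantom)
    structure(
      list(edep_nucleus_keV_per_decay = edep_n,
           edep_cytoplasm_keV_per_decay = edep_cy,
           edep_escaped_keV_per_decay = edep_esc,
           edep_nucleus_se = se_n,
           edep_cytoplasm_se = se_cy,
           s_nucleus_gy_per_bqs = edep_n * KEV_TO_J / m$nucleus_kg,
           s_nucleus_se = se_n * KEV_TO_J / m$nucleus_kg,
           s_cytoplasm_gy_per_bqs = edep_cy * KEV_TO_J / m$cytoplasm_kg,
           s_cytoplasm_se = se_cy * KEV_TO_J / m$cytoplasm_kg,
           energy_per_decay_keV = spectrum_energy_per_decay(spectrum),
           source_region = source_region,
           n_histories = n_histories,
           seed = seed,
           spectrum_label = attr(spectrum, "label"),
           phantom = phantom),
      class = "transport_result"
    )
  })
}

#' @export
print.transport_result <- function(x, ...) {
  cat(sprintf("MC transport [%s source, %d histories/line, seed %s]\n",
              x$source_region, x$n_histories,
              if (is.null(x$seed)) "none" else x$seed))
  cat(sprintf("  E/decay emitted %.4g keV: nucleus %.4g, cytoplasm %.4g, escaped %.4g keV\n",
              x$energy_per_decay_keV, x$edep_nucleus_keV_per_decay,
              x$edep_cytoplasm_keV_per_decay, x$edep_escaped_keV_per_decay))
  cat(sprintf("  S(N<-src) = %.4g +/- %.2g, S(Cy<-src) = %.4g +/- %.2g Gy/(Bq.s)\n",
              x$s_nucleus_gy_per_bqs, x$s_nucleus_se,
              x$s_cytoplasm_gy_per_bqs, x$s_cytoplasm_se))
  cat(sprintf("  nuclear dose share %.2f%%\n", 100 * nuclear_dose_share_mc(x)))
  invisible(x)
}

#' Nuclear share of the total cell dose in a Monte Carlo result
#'
#' Mirrors the compartment-dose share used in the S-value formalism:
#' D_N / (D_N + D_Cy), with each compartment dose equal to its energy deposit
#' divided by its mass.
#'
#' @param result A `transport_result` from [run_s_value_mc()].
#' @return Nuclear dose share in \[0, 1\].
#' @export
nuclear_dose_share_mc <- function(result) {
  stopifnot(inherits(result, "transport_result"))
  m <- region_masses(result$phantom)
  d_n <- result$edep_nucleus_keV_per_decay / m$nucleus_kg
  d_cy <- result$edep_cytoplasm_keV_per_decay / m$cytoplasm_kg
  if (d_n + d_cy <= 0) {
    stop("nuclear dose share undefined: no energy deposited in the cell",
         call. = FALSE)
  }
  d_n / (d_n + d_cy)
}

#' Compare a homogeneous-nucleus MC run against a reference S-value
#'
#' Runs the engine in the MIRD-like configuration (homogeneous source in the
#' nucleus) and reports the relative deviation of the estimated S(N<-N) from
#' a reference value, by default the published 99mTc MIRD S-value. Meant for
#' validation with a full radionuclide electron spectrum (e.g. the ICRP-107
#' line data, which must be supplied by the user).
#'
#' @param spectrum An [electron_spectrum()].
#' @param phantom A [cell_phantom()].
#' @param s_ref Reference S(N<-N), Gy/(Bq·s). Default from [s_value_tc99m()].
#' @param n_histories,seed,model Passed to [run_s_value_mc()].
#' @return List with `s_mc`, `s_mc_se`, `s_ref`, `relative_deviation` and the
#'   underlying `transport_result`.
#' @export
validate_mird_agreement <- function(spectrum, phantom = cell_phantom(),
                                    s_ref = s_value_tc99m()$s_n_n,
                                    n_histories = 1e5, seed = NULL,
                                    model = stopping_model()) {
  res <- run_s_value_mc(spectrum, phantom, source_region = "nucleus",
                        n_histories = n_histories, seed = seed, model = model)
  list(s_mc = res$s_nucleus_gy_per_bqs,
       s_mc_se = res$s_nucleus_se,
       s_ref = s_ref,
       relative_deviation = (res$s_nucleus_gy_per_bqs - s_ref) / s_ref,
       result = res)
}

#' Write a transport result as a JSON report
#'
#' @param result A `transport_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transport_json <- function(result, path) {
  stopifnot(inherits(result, "transport_result"))
  x <- result
  x$phantom <- unclass(x$phantom)
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
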