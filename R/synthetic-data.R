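# Seed-deterministic generators emulating the statistical structure of the
# cellular uptake and clonogenic experiments, so the full pipeline can be
# exercised and calibrated without any measured data.

#' Parameters of the synthetic uptake generator
#'
#' The internalized fraction of the applied activity follows a saturable
#' (hyperbolic) curve f(A) = f_int_max / (1 + A / k_sat_bq), reproducing the
#' observed pattern of maximal percent uptake at the lowest applied
#' activities. Counts carry Poisson noise at the gamma-counter efficiency
#' over a fixed counting window; the nuclear fraction of internalized
#' activity is drawn from a normal distribution truncated to \[0, 1\],
#' reflecting its near-constancy across applied activities.
#'
#' Compound presets mirror the two studied DNA intercalators: `"C3"`
#' internalizes weakly (8% at low activity, falling to about 3% at 7.4 MBq)
#' but concentrates in the nucleus (mean fraction 0.45); `"C5"` internalizes
#' strongly (24% falling to about 5%) with a lower nuclear fraction (0.22).
#'
#' @param compound Preset, `"C3"` (default) or `"C5"`; individual arguments
#'   override preset values.
#' @param f_int_max Internalized fraction of applied activity at low activity.
#' @param k_sat_bq Activity scale of uptake saturation, Bq.
#' @param surface_to_internal_ratio Ratio of surface-bound to internalized
#'   activity.
#' @param nuclear_fraction_mean,nuclear_fraction_sd Mean and SD of the
#'   truncated-normal nuclear fraction.
#' @param efficiency Gamma-counter efficiency.
#' @param count_window_min Counting window, minutes.
#' @return An object of class `uptake_model_params`.
#' @export
uptake_model_params <- function(compound = c("C3", "C5"),
                                f_int_max = NULL, k_sat_bq = NULL,
                                surface_to_internal_ratio = NULL,
                                nuclear_fraction_mean = NULL,
                                nuclear_fraction_sd = 0.05,
                                efficiency = 0.54,
                                count_window_min = 1) {
  compound <- match.arg(compound)
  preset <- switch(compound,
    C3 = list(f_int_max = 0.08, k_sat_bq = 4.5e6,
              surface_to_internal_ratio = 4.0, nuclear_fraction_mean = 0.45),
    C5 = list(f_int_max = 0.24, k_sat_bq = 1.95e6,
              surface_to_internal_ratio = 1.6, nuclear_fraction_mean = 0.22))
  p <- list(
    compound = compound,
    f_int_max = if (is.null(f_int_max)) preset$f_int_max else f_int_max,
    k_sat_bq = if (is.null(k_sat_bq)) preset$k_sat_bq else k_sat_bq,
    surface_to_internal_ratio =
      if (is.null(surface_to_internal_ratio)) preset$surface_to_internal_ratio
      else surface_to_internal_ratio,
    nuclear_fraction_mean =
      if (is.null(nuclear_fraction_mean)) preset$nuclear_fraction_mean
      else nuclear_fraction_mean,
    nuclear_fraction_sd = nuclear_fraction_sd,
    efficiency = efficiency,
    count_window_min = count_window_min)
  with(p, {
    if (f_int_max < 0 || f_int_max > 1 ||
        nuclear_fraction_mean < 0 || nuclear_fraction_mean > 1) {
      stop("fractions must lie in [0, 1]", call. = FALSE)
    }
    if (k_sat_bq <= 0 || count_window_min <= 0 ||
        efficiency <= 0 || efficiency > 1) {
      stop("scales must be positive and efficiency in (0, 1]", call. = FALSE)
    }
  })
  structure(p, class = "uptake_model_params")
}

.rtruncnorm01 <- function(n, mean, sd) {
  if (sd == 0) return(rep(pmin(pmax(mean, 0), 1), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= 0 & x <= 1])
  }
  out[seq_len(n)]
}

#' Generate a synthetic uptake table
#'
#' For each applied activity, the internalized cellular activity is
#' f(A) * A, converted to expected counts at the counter efficiency over the
#' counting window. With `noise = TRUE` the counts are Poisson draws; with
#' `noise = FALSE` they equal the expectation exactly.
#'
#' @param params An [uptake_model_params()].
#' @param activities_bq Applied activities, Bq (> 0).
#' @param seed RNG seed (mandatory when `noise = TRUE`).
#' @param noise Draw Poisson counting noise and a random nuclear fraction?
#'   Default TRUE.
#' @param time_h Measurement time, hours. Default 24.
#' @return A data frame in the uptake-CSV schema (`compound`,
#'   `applied_activity_bq`, `surface_cpm`, `internalized_cpm`,
#'   `nuclear_fraction`, `time_h`).
#' @examples
#' generate_uptake_table(uptake_model_params("C3"), c(1.85e5, 7.4e6), seed = 1)
#' @export
generate_uptake_table <- function(params, activities_bq, seed = NULL,
                                  noise = TRUE, time_h = 24) {
  stopifnot(inherits(params, "uptake_model_params"))
  if (any(activities_bq <= 0)) {
    stop("`activities_bq` must be positive", call. = FALSE)
  }
  if (noise && is.null(seed)) {
    stop("`seed` is mandatory when `noise = TRUE`", call. = FALSE)
  }
  with_seed(seed, {
    f_int <- params$f_int_max / (1 + activities_bq / params$k_sat_bq)
    a_int <- f_int * activities_bq
    a_surf <- a_int * params$surface_to_internal_ratio
    to_cpm <- function(a_bq) a_bq * 60 * params$efficiency
    n <- length(activities_bq)
    if (noise) {
      w <- params$count_window_min
      int_cpm <- stats::rpois(n, to_cpm(a_int) * w) / w
      surf_cpm <- stats::rpois(n, to_cpm(a_surf) * w) / w
      nf <- .rtruncnorm01(n, params$nuclear_fraction_mean,
                          params$nuclear_fraction_sd)
    } else {
      int_cpm <- to_cpm(a_int)
      surf_cpm <- to_cpm(a_surf)
      nf <- rep(params$nuclear_fraction_mean, n)
    }
    data.frame(compound = params$compound,
               applied_activity_bq = activities_bq,
               surface_cpm = surf_cpm,
               internalized_cpm = int_cpm,
               nuclear_fraction = nf,
               time_h = time_h)
  })
}

#' Parameters of the synthetic survival generator
#'
#' @param kappa_true True slope of the exponential survival model, 1/Gy.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise on SF.
#' @param doses_gy Dose points, Gy.
#' @param replicates Replicates per dose point.
#' @return An object of class `survival_model_params`.
#' @export
survival_model_params <- function(kappa_true = 0.3, noise_cv = 0.05,
                                  doses_gy = c(0.25, 0.5, 1, 1.5, 2, 3),
                                  replicates = 1L) {
  if (kappa_true <= 0) stop("`kappa_true` must be positive", call. = FALSE)
  if (noise_cv < 0) stop("`noise_cv` must be non-negative", call. = FALSE)
  structure(
    list(kappa_true = kappa_true, noise_cv = noise_cv, doses_gy = doses_gy,
         replicates = as.integer(replicates)),
    class = "survival_model_params"
  )
}

#' Generate synthetic clonogenic survival data
#'
#' SF = exp(-kappa * D) times a mean-one lognormal factor with the requested
#' coefficient of variation. The untreated control point (0, 1) is always
#' included, noiseless, matching its survival fraction being 1 by
#' construction.
#'
#' @param params A [survival_model_params()].
#' @param seed RNG seed (mandatory when `noise_cv > 0`).
#' @return Data frame with columns `dose_gy` and `sf`.
#' @examples
#' generate_survival_data(survival_model_params(kappa_true = 0.5), seed = 1)
#' @export
generate_survival_data <- function(params, seed = NULL) {
  stopifnot(inherits(params, "survival_model_params"))
  if (params$noise_cv > 0 && is.null(seed)) {
    stop("`seed` is mandatory when `noise_cv > 0`", call. = FALSE)
  }
  with_seed(seed, {
    d <- rep(params$doses_gy, each = params$replicates)
    sf <- exp(-params$kappa_true * d)
    if (params$noise_cv > 0) {
      sdlog <- sqrt(log(1 + params$noise_cv^2))
      sf <- sf * stats::rlnorm(length(d), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    rbind(data.frame(dose_gy = 0, sf = 1),
          data.frame(dose_gy = d, sf = sf))
  })
}

#' Fixture electron spectra for the transport engine
#'
#' Fully specified toy spectra:
#' \describe{
#'   \item{`single_line`}{One monoenergetic line (`energy_keV`, `yield`).}
#'   \item{`low_energy_only`}{Sub-keV lines whose CSDA ranges are far below
#'     the nucleus radius, so essentially all energy is absorbed near the
#'     source.}
#'   \item{`tc99m_like`}{A documented approximate mix of the 99mTc electron
#'     emissions: grouped sub-keV Auger lines, the ~1.6-2.1 keV conversion
#'     electrons of the highly converted 2.17 keV transition, K-shell Auger
#'     electrons, and the 119.5-140 keV conversion-electron lines of the
#'     140.5/142.6 keV transitions. This is a synthetic fixture, not the
#'     ICRP-107 dataset; supply the ICRP-107 line data via
#'     [read_spectrum()] for absolute validation work.}
#' }
#'
#' @param kind One of `"single_line"`, `"low_energy_only"`, `"tc99m_like"`.
#' @param energy_keV,yield Line parameters for `"single_line"`.
#' @return An [electron_spectrum()].
#' @examples
#' toy_spectrum("tc99m_like")
#' @export
toy_spectrum <- function(kind = c("single_line", "low_energy_only", "tc99m_like"),
                         energy_keV = 1, yield = 1) {
  if (!is.character(kind) || !kind[1] %in%
      c("single_line", "low_energy_only", "tc99m_like")) {
    stop("unknown spectrum kind: ", kind[1], call. = FALSE)
  }
  kind <- kind[1]
  switch(kind,
    single_line = electron_spectrum(energy_keV, yield,
                                    label = sprintf("single %g keV line", energy_keV)),
    low_energy_only = electron_spectrum(
      c(0.05, 0.1, 0.3, 0.5),
      c(1.0, 1.0, 0.8, 0.5),
      label = "low-energy-only fixture"),
    tc99m_like = electron_spectrum(
      c(0.03, 0.12, 0.25, 0.45, 1.8, 2.05, 15.4, 119.5, 121.6, 137.5, 140.0),
      c(1.2, 1.0, 0.8, 0.9, 0.55, 0.30, 0.021, 0.088, 0.0066, 0.011, 0.003),
      label = "Tc-99m-like synthetic fixture (not ICRP-107)"))
}
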