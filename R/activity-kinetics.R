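#' Physical decay and counting parameters
#'
#' Bundles the physical half-life of the radionuclide and the gamma-counter
#' efficiency used to convert counts per minute into activity.
#'
#' @param half_life_h Physical half-life in hours. Default 6.02 h (99mTc).
#' @param counter_efficiency Detection efficiency of the gamma counter,
#'   a fraction in (0, 1]. Default 0.54.
#'
#' @return An object of class `decay_params`.
#' @examples
#' decay_params()                  # 99mTc defaults
#' decay_params(half_life_h = 66)  # e.g. 99Mo
#' @export
decay_params <- function(half_life_h = 6.02, counter_efficiency = 0.54) {
  if (!is.numeric(half_life_h) || length(half_life_h) != 1L || !is.finite(half_life_h) ||
      half_life_h <= 0) {
    stop("`half_life_h` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(counter_efficiency) || length(counter_efficiency) != 1L ||
      !is.finite(counter_efficiency) ||
      counter_efficiency <= 0 || counter_efficiency > 1) {
    stop("`counter_efficiency` must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(half_life_h = half_life_h, counter_efficiency = counter_efficiency),
    class = "decay_params"
  )
}

#' @export
print.decay_params <- function(x, ...) {
  cat(sprintf("Decay parameters: T1/2 = %g h, counter efficiency = %g\n",
              x$half_life_h, x$counter_efficiency))
  invisible(x)
}

#' One gamma-counter uptake measurement
#'
#' A single row of an internalization experiment: the activity applied to the
#' well, the surface-bound and internalized counts measured after incubation,
#' and the fraction of the internalized activity recovered in the nuclear
#' pellet. Surface-bound counts are carried for bookkeeping but never
#' contribute to absorbed dose.
#'
#' @param applied_activity_bq Activity applied at the start of incubation (Bq).
#' @param internalized_cpm Internalized activity, counts per minute.
#' @param surface_cpm Surface-bound (membrane) activity, counts per minute.
#' @param nuclear_fraction Fraction of internalized activity in the nucleus,
#'   in \[0, 1\].
#' @param measurement_time_h Time after incubation start at which the counts
#'   were measured, hours. Default 24.
#' @param compound Optional compound label.
#'
#' @return An object of class `uptake_record`.
#' @examples
#' uptake_record(1.85e5, internalized_cpm = 1.2e5, nuclear_fraction = 0.45)
#' @export
uptake_record <- function(applied_activity_bq,
                          internalized_cpm,
                          surface_cpm = 0,
                          nuclear_fraction = 0,
                          measurement_time_h = 24,
                          compound = NA_character_) {
  stopifnot(is.numeric(applied_activity_bq), length(applied_activity_bq) == 1L,
            is.numeric(internalized_cpm), length(internalized_cpm) == 1L,
            is.numeric(surface_cpm), length(surface_cpm) == 1L,
            is.numeric(nuclear_fraction), length(nuclear_fraction) == 1L,
            is.numeric(measurement_time_h), length(measurement_time_h) == 1L)
  if (applied_activity_bq < 0 || internalized_cpm < 0 || surface_cpm < 0) {
    stop("activities and counts must be non-negative", call. = FALSE)
  }
  if (nuclear_fraction < 0 || nuclear_fraction > 1) {
    stop("`nuclear_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (measurement_time_h <= 0) {
    stop("`measurement_time_h` must be positive", call. = FALSE)
  }
  structure(
    list(applied_activity_bq = applied_activity_bq,
         internalized_cpm = internalized_cpm,
         surface_cpm = surface_cpm,
         nuclear_fraction = nuclear_fraction,
         measurement_time_h = measurement_time_h,
         compound = compound),
    class = "uptake_record"
  )
}

#' Read an uptake table from CSV
#'
#' Expects columns `compound`, `applied_activity_bq`, `surface_cpm`,
#' `internalized_cpm`, `nuclear_fraction`, `time_h` (header required, UTF-8,
#' decimal point). Extra columns are preserved.
#'
#' @param path Path to the CSV file.
#' @return A data frame, one row per measurement, validated against the
#'   `uptake_record` invariants.
#' @export
read_uptake_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("compound", "applied_activity_bq", "surface_cpm",
                "internalized_cpm", "nuclear_fraction", "time_h")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("uptake CSV is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(df$nuclear_fraction < 0 | df$nuclear_fraction > 1 |
               df$surface_cpm < 0 | df$internalized_cpm < 0 |
               df$applied_activity_bq < 0 | df$time_h <= 0)
  if (length(bad) > 0L) {
    stop("invalid uptake rows (counts < 0, fraction outside [0,1], or time <= 0): row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df
}

#' Convert gamma-counter counts to activity
#'
#' Counts per minute are normalized to a per-second count rate and divided by
#' the detector efficiency.
#'
#' @param counts Counts per minute (vectorized).
#' @param efficiency Counting efficiency in (0, 1]. Default 0.54.
#' @return Activity in Bq.
#' @examples
#' cpm_to_bq(32.4, 0.54)  # 1 Bq
#' @export
cpm_to_bq <- function(counts, efficiency = 0.54) {
  if (!is.numeric(efficiency) || length(efficiency) != 1L ||
      !is.finite(efficiency) || efficiency <= 0 || efficiency > 1) {
    stop("`efficiency` must be in (0, 1]", call. = FALSE)
  }
  if (any(counts < 0)) stop("`counts` must be non-negative", call. = FALSE)
  (counts / 60) / efficiency
}

#' Back-extrapolate the initial activity from a later measurement
#'
#' Inverts the exponential decay law: the activity measured at time `t_h` is
#' assumed to have been present from t = 0 and to have undergone physical
#' decay only, so A0 = A(t) * exp(ln(2) * t / T1/2).
#'
#' @param activity_at_t Activity measured at `t_h`, in Bq (vectorized).
#' @param t_h Elapsed time in hours.
#' @param params A [decay_params()] object.
#' @return The back-extrapolated activity at t = 0, in Bq.
#' @examples
#' back_extrapolate_a0(1, 6.02)  # one half-life: 2 Bq
#' @export
back_extrapolate_a0 <- function(activity_at_t, t_h, params = decay_params()) {
  stopifnot(inherits(params, "decay_params"))
  if (any(activity_at_t < 0)) stop("`activity_at_t` must be non-negative", call. = FALSE)
  if (any(t_h < 0)) stop("`t_h` must be non-negative", call. = FALSE)
  activity_at_t * exp(log(2) * t_h / params$half_life_h)
}

#' Time-integrated (cumulated) activity over a finite interval
#'
#' Integrates the exponential decay law from 0 to `delta_t_h`:
#' \deqn{\tilde A = 1.44\,T_p\,A_0\,(1 - e^{-\ln 2\,\Delta t / T_p})}
#' with \eqn{T_p} converted to seconds, so the result is in Bq·s (decays).
#' `1.44` is the mean-life factor \eqn{1/\ln 2}.
#'
#' @param a0 Initial activity in Bq (vectorized).
#' @param delta_t_h Integration interval in hours. Default 24 (the incubation
#'   time). `Inf` gives the total-decay asymptote.
#' @param params A [decay_params()] object.
#' @return Cumulated activity in Bq·s.
#' @examples
#' time_integrated_activity(1, Inf)  # all decays of 1 Bq of 99mTc
#' @export
time_integrated_activity <- function(a0, delta_t_h = 24, params = decay_params()) {
  stopifnot(inherits(params, "decay_params"))
  if (any(a0 < 0)) stop("`a0` must be non-negative", call. = FALSE)
  if (any(delta_t_h < 0)) stop("`delta_t_h` must be non-negative", call. = FALSE)
  tp_s <- params$half_life_h * 3600
  (tp_s / log(2)) * a0 * (1 - exp(-log(2) * delta_t_h / params$half_life_h))
}

#' Cumulated activity split between nucleus and cytoplasm
#'
#' Container for the number of decays assigned to each compartment.
#'
#' @param nucleus_bqs Decays in the nucleus, Bq·s.
#' @param cytoplasm_bqs Decays in the cytoplasm, Bq·s.
#' @param a0_bq Back-extrapolated initial cellular activity, Bq.
#' @param delta_t_h Integration interval, hours.
#' @param params Optional [decay_params()] used to check the infinite-time
#'   bound nucleus + cytoplasm <= T_p(s)/ln(2) * A0.
#' @return An object of class `cumulated_activity`.
#' @export
cumulated_activity <- function(nucleus_bqs, cytoplasm_bqs,
                               a0_bq = NA_real_, delta_t_h = NA_real_,
                               params = NULL) {
  if (nucleus_bqs < 0 || cytoplasm_bqs < 0) {
    stop("cumulated activities must be non-negative", call. = FALSE)
  }
  if (!is.null(params) && is.finite(a0_bq)) {
    stopifnot(inherits(params, "decay_params"))
    bound <- (params$half_life_h * 3600 / log(2)) * a0_bq
    if (nucleus_bqs + cytoplasm_bqs > bound * (1 + 1e-12)) {
      stop("cumulated activity exceeds the infinite-time bound 1.44 * T_p * A0",
           call. = FALSE)
    }
  }
  structure(
    list(nucleus_bqs = nucleus_bqs, cytoplasm_bqs = cytoplasm_bqs,
         a0_bq = a0_bq, delta_t_h = delta_t_h),
    class = "cumulated_activity"
  )
}

#' @export
print.cumulated_activity <- function(x, ...) {
  cat(sprintf("Cumulated activity: nucleus %.4g Bq.s, cytoplasm %.4g Bq.s (A0 = %.4g Bq, dt = %g h)\n",
              x$nucleus_bqs, x$cytoplasm_bqs, x$a0_bq, x$delta_t_h))
  invisible(x)
}

#' Partition the cumulated cellular activity into nucleus and cytoplasm
#'
#' Chains the full decay bookkeeping for one measurement: internalized cpm are
#' converted to Bq at the counter efficiency, back-extrapolated to the start
#' of incubation, integrated over the incubation interval, and split by the
#' nuclear fraction. Surface-bound activity is deliberately excluded: decays
#' at the cell membrane are taken to contribute negligibly to nucleus dose
#' given the sub-micron range of Auger electrons.
#'
#' @param record An [uptake_record()].
#' @param params A [decay_params()] object.
#' @param delta_t_h Integration interval in hours; defaults to the record's
#'   measurement time (instant-uptake model: activity present from t = 0).
#' @return A [cumulated_activity()] object. The nucleus and cytoplasm parts
#'   sum exactly to the total cumulated activity.
#' @export
partition_cumulated_activity <- function(record, params = decay_params(),
                                         delta_t_h = record$measurement_time_h) {
  stopifnot(inherits(record, "uptake_record"), inherits(params, "decay_params"))
  a_t <- cpm_to_bq(record$internalized_cpm, params$counter_efficiency)
  a0 <- back_extrapolate_a0(a_t, record$measurement_time_h, params)
  atilde <- time_integrated_activity(a0, delta_t_h, params)
  cumulated_activity(
    nucleus_bqs = atilde * record$nuclear_fraction,
    cytoplasm_bqs = atilde * (1 - record$nuclear_fraction),
    a0_bq = a0,
    delta_t_h = delta_t_h,
    params = params
  )
}
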