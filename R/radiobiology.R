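#' Colony count from a clonogenic assay
#'
#' @param cells_seeded Number of cells seeded (>= 1).
#' @param colonies_formed Number of colonies counted (>= 0); by convention
#'   only colonies of at least 50 cells are scored, recorded in
#'   `min_colony_size`.
#' @param treatment_label Label for the treatment condition.
#' @param applied_activity_bq Applied activity, Bq (if activity-indexed).
#' @param dose_gy Absorbed dose, Gy (if dose-indexed).
#' @param min_colony_size Scoring threshold metadata flag. Default 50.
#' @return An object of class `colony_count`.
#' @export
colony_count <- function(cells_seeded, colonies_formed,
                         treatment_label = NA_character_,
                         applied_activity_bq = NA_real_, dose_gy = NA_real_,
                         min_colony_size = 50L) {
  if (cells_seeded < 1) stop("`cells_seeded` must be >= 1", call. = FALSE)
  if (colonies_formed < 0) stop("`colonies_formed` must be >= 0", call. = FALSE)
  structure(
    list(cells_seeded = cells_seeded, colonies_formed = colonies_formed,
         treatment_label = treatment_label,
         applied_activity_bq = applied_activity_bq, dose_gy = dose_gy,
         min_colony_size = min_colony_size),
    class = "colony_count"
  )
}

#' Plating efficiency
#'
#' Percentage of seeded (untreated) cells forming colonies:
#' PE = colonies / cells seeded x 100.
#'
#' @param count A [colony_count()], or a number of colonies if
#'   `cells_seeded` is given.
#' @param cells_seeded Number of cells seeded (when `count` is numeric).
#' @return Plating efficiency in percent.
#' @examples
#' plating_efficiency(37, 200)  # 18.5
#' @export
plating_efficiency <- function(count, cells_seeded = NULL) {
  if (inherits(count, "colony_count")) {
    colonies <- count$colonies_formed
    cells_seeded <- count$cells_seeded
  } else {
    colonies <- count
    if (is.null(cells_seeded)) stop("`cells_seeded` is required", call. = FALSE)
  }
  if (any(cells_seeded < 1)) stop("`cells_seeded` must be >= 1", call. = FALSE)
  colonies / cells_seeded * 100
}

#' Survival fraction
#'
#' Colony formation of treated cells normalized by seeding number and the
#' plating efficiency of untreated controls:
#' SF = colonies_treated / (cells_seeded x PE_control / 100).
#' The control sample itself has SF = 1 by construction.
#'
#' @param treated A [colony_count()] for the treated condition, or a number
#'   of colonies if `cells_seeded` is given.
#' @param control_pe Control plating efficiency in percent (> 0).
#' @param cells_seeded Cells seeded in the treated condition (when `treated`
#'   is numeric).
#' @return Survival fraction (dimensionless).
#' @examples
#' survival_fraction(25, control_pe = 50, cells_seeded = 100)  # 0.5
#' @export
survival_fraction <- function(treated, control_pe, cells_seeded = NULL) {
  if (inherits(treated, "colony_count")) {
    colonies <- treated$colonies_formed
    cells_seeded <- treated$cells_seeded
  } else {
    colonies <- treated
    if (is.null(cells_seeded)) stop("`cells_seeded` is required", call. = FALSE)
  }
  if (any(control_pe <= 0)) {
    stop("`control_pe` must be positive: cannot normalize by a zero control plating efficiency",
         call. = FALSE)
  }
  colonies / (cells_seeded * control_pe / 100)
}

#' Fit the single-hit exponential survival model
#'
#' Fits SF = exp(-kappa * D) by least squares on the log scale
#' (ln SF = -kappa * D, no intercept), optionally weighted by 1/se^2 of
#' ln SF. This one-parameter "linear" model (linear on the log-survival
#' scale) is the form under which the RBE expressions close in terms of
#' kappa alone. Points with SF = 0 cannot enter a log fit and are dropped
#' with a warning.
#'
#' @param dose_gy Doses (or activities, see `covariate`).
#' @param sf Survival fractions, same length.
#' @param se Optional standard errors of `sf`, used as weights
#'   (propagated to the log scale as se/sf).
#' @param covariate Label of the independent variable, `"dose_gy"` or
#'   `"activity_bq"`.
#' @return An object of class `survival_fit` with elements `kappa`,
#'   `kappa_se`, `model_label`, `covariate`, `n` and the `lm` fit.
#' @examples
#' d <- c(0, 1, 2, 4)
#' fit_linear_survival(d, exp(-0.5 * d))  # recovers kappa = 0.5 exactly
#' @export
fit_linear_survival <- function(dose_gy, sf, se = NULL,
                                covariate = c("dose_gy", "activity_bq")) {
  covariate <- match.arg(covariate)
  stopifnot(length(dose_gy) == length(sf))
  if (any(dose_gy < 0)) stop("doses must be non-negative", call. = FALSE)
  keep <- sf > 0
  if (any(!keep)) {
    warning(sum(!keep), " zero-survival point(s) dropped from the log-scale fit",
            call. = FALSE)
  }
  d <- dose_gy[keep]
  y <- log(sf[keep])
  if (length(d) < 2L || all(d == 0)) {
    stop("underdetermined fit: need at least two points with SF > 0 and a nonzero dose",
         call. = FALSE)
  }
  w <- if (!is.null(se)) {
    se <- se[keep]
    if (any(se <= 0)) stop("`se` must be positive where given", call. = FALSE)
    (sf[keep] / se)^2     # delta method: se(ln SF) = se(SF)/SF
  } else NULL
  fit <- stats::lm(y ~ 0 + d, weights = w)
  kappa <- -unname(stats::coef(fit)[1])
  # vcov warns on zero-residual (noiseless) data; the se is then 0 below
  kappa_se <- unname(sqrt(diag(suppressWarnings(stats::vcov(fit))))[1])
  # a noiseless exponential leaves zero residual; lm then reports se = 0/0 guard
  if (!is.finite(kappa_se)) kappa_se <- 0
  structure(
    list(kappa = kappa, kappa_se = kappa_se, model_label = "linear",
         covariate = covariate, n = length(d), fit = fit),
    class = "survival_fit"
  )
}

#' Construct a survival fit from known parameters
#'
#' For reference radiations whose fitted slope is supplied rather than
#' refitted (e.g. a 60Co reference curve).
#'
#' @param kappa Slope of the exponential survival model, 1/Gy (> 0).
#' @param kappa_se Standard error of `kappa` (>= 0).
#' @param covariate Independent variable label.
#' @return A `survival_fit` object.
#' @export
survival_fit <- function(kappa, kappa_se = 0, covariate = "dose_gy") {
  if (kappa <= 0) stop("`kappa` must be positive", call. = FALSE)
  if (kappa_se < 0) stop("`kappa_se` must be non-negative", call. = FALSE)
  structure(
    list(kappa = kappa, kappa_se = kappa_se, model_label = "linear",
         covariate = covariate, n = NA_integer_, fit = NULL),
    class = "survival_fit"
  )
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("Exponential survival fit: kappa = %.4g +/- %.2g per unit %s\n",
              x$kappa, x$kappa_se, x$covariate))
  invisible(x)
}

#' Predict survival from a fit
#'
#' @param object A `survival_fit`.
#' @param dose Doses (or activities) at which to evaluate SF.
#' @param ... Unused.
#' @return Survival fractions exp(-kappa * dose).
#' @export
predict.survival_fit <- function(object, dose, ...) {
  exp(-object$kappa * dose)
}

#' Activity giving 50% inhibition of clonogenic survival
#'
#' Fits the exponential survival-versus-activity curve SF = exp(-lambda * A)
#' and returns the activity at which it crosses SF = 0.5:
#' IC50 = ln(2) / lambda. Requires the data to bracket SF = 0.5 or at least
#' support a decreasing monotone fit (lambda > 0).
#'
#' @param activity_bq Applied activities, Bq.
#' @param sf Survival fractions.
#' @param require_bracket If TRUE (default), error unless the observed SF
#'   values bracket 0.5.
#' @return List with `ic50_bq`, `lambda`, `lambda_se` and `ic50_se`
#'   (delta method).
#' @examples
#' a <- c(0, 0.5e6, 1e6, 2e6, 4e6)
#' ic50_from_activity(a, exp(-a * log(2) / 2e6))$ic50_bq  # 2 MBq
#' @export
ic50_from_activity <- function(activity_bq, sf, require_bracket = TRUE) {
  stopifnot(length(activity_bq) == length(sf))
  if (require_bracket && !(min(sf) <= 0.5 && max(sf) >= 0.5)) {
    stop("no crossing: survival fractions do not bracket 0.5", call. = FALSE)
  }
  fit <- fit_linear_survival(activity_bq, sf, covariate = "activity_bq")
  if (fit$kappa <= 0) {
    stop("no crossing: fitted survival does not decrease with activity",
         call. = FALSE)
  }
  lambda <- fit$kappa
  ic50 <- log(2) / lambda
  list(ic50_bq = ic50, lambda = lambda, lambda_se = fit$kappa_se,
       ic50_se = ic50 * fit$kappa_se / lambda)
}

#' Relative biological effectiveness of a test radiation
#'
#' Under the exponential survival model the two standard RBE endpoints have
#' closed forms in the fitted slopes:
#' \deqn{RBE_{0.5} = D_{ref}(SF{=}0.5) / D_{test}(SF{=}0.5)
#'       = \kappa_{test}/\kappa_{ref}}
#' \deqn{RBE_{2Gy} = SF_{ref}(2\,Gy) / SF_{test}(2\,Gy)
#'       = e^{2(\kappa_{test} - \kappa_{ref})}}
#' Standard errors are first-order (delta-method) propagations of the two
#' kappa uncertainties, assumed independent.
#'
#' @param reference A `survival_fit` for the reference radiation (e.g. 60Co).
#' @param test A `survival_fit` for the test radiation, fitted against
#'   absorbed dose (conventionally the total cellular dose).
#' @param dose_gy Fixed dose for the iso-dose endpoint, Gy. Default 2.
#' @param reference_label Label stored in the result. Default "60Co".
#' @return An object of class `rbe_result` with `rbe_05`, `rbe_05_se`,
#'   `rbe_2gy`, `rbe_2gy_se` and `reference_label`.
#' @examples
#' rbe(survival_fit(0.3, 0.02), survival_fit(0.6, 0.05))
#' @export
rbe <- function(reference, test, dose_gy = 2, reference_label = "60Co") {
  stopifnot(inherits(reference, "survival_fit"), inherits(test, "survival_fit"))
  kr <- reference$kappa; sr <- reference$kappa_se
  kt <- test$kappa; st <- test$kappa_se
  if (kr <= 0) stop("reference kappa must be positive", call. = FALSE)
  rbe05 <- kt / kr
  rbe05_se <- rbe05 * sqrt((st / kt)^2 + (sr / kr)^2)
  rbe2 <- exp(dose_gy * (kt - kr))
  rbe2_se <- rbe2 * dose_gy * sqrt(st^2 + sr^2)
  structure(
    list(rbe_05 = rbe05, rbe_05_se = rbe05_se,
         rbe_2gy = rbe2, rbe_2gy_se = rbe2_se,
         dose_gy = dose_gy, reference_label = reference_label),
    class = "rbe_result"
  )
}

#' @export
print.rbe_result <- function(x, ...) {
  cat(sprintf("RBE vs %s: RBE_0.5 = %.3g +/- %.2g, RBE_%gGy = %.3g +/- %.2g\n",
              x$reference_label, x$rbe_05, x$rbe_05_se, x$dose_gy,
              x$rbe_2gy, x$rbe_2gy_se))
  invisible(x)
}

#' Sampling-based uncertainty propagation for RBE
#'
#' Draws kappa pairs from independent normal distributions and recomputes the
#' RBE endpoints; used to validate the first-order propagation in [rbe()].
#'
#' @param reference,test `survival_fit` objects.
#' @param n Number of draws.
#' @param dose_gy Fixed dose for the iso-dose endpoint.
#' @param seed Optional RNG seed.
#' @return List with empirical `rbe_05_se` and `rbe_2gy_se`.
#' @export
rbe_sampling_se <- function(reference, test, n = 1e5, dose_gy = 2, seed = NULL) {
  with_seed(seed, {
    kr <- stats::rnorm(n, reference$kappa, reference$kappa_se)
    kt <- stats::rnorm(n, test$kappa, test$kappa_se)
    ok <- kr > 0
    list(rbe_05_se = stats::sd(kt[ok] / kr[ok]),
         rbe_2gy_se = stats::sd(exp(dose_gy * (kt - kr))))
  })
}

#' Summaries of gamma-H2AX foci counts
#'
#' Mean and standard deviation of foci per nucleus, with the treated mean
#' normalized to the control both as a difference (treated - control) and as
#' a ratio (treated / control); "normalized to control" is reported both
#' ways since either convention is in use.
#'
#' @param per_cell_counts Integer foci counts per nucleus, treated sample.
#' @param control_counts Foci counts per nucleus, control sample.
#' @param min_nuclei Minimum recommended number of analyzed nuclei; a warning
#'   is raised below it. Default 200.
#' @return List with `mean`, `sd`, `n`, `control_mean`,
#'   `normalized_difference` and `normalized_ratio`.
#' @export
foci_summary <- function(per_cell_counts, control_counts, min_nuclei = 200L) {
  if (length(per_cell_counts) == 0L || length(control_counts) == 0L) {
    stop("foci count vectors must be non-empty", call. = FALSE)
  }
  if (any(per_cell_counts < 0) || any(control_counts < 0)) {
    stop("foci counts must be non-negative", call. = FALSE)
  }
  if (length(per_cell_counts) < min_nuclei) {
    warning("fewer than ", min_nuclei, " analyzed nuclei; summary may be unstable",
            call. = FALSE)
  }
  m <- mean(per_cell_counts)
  cm <- mean(control_counts)
  list(mean = m,
       sd = stats::sd(per_cell_counts),
       n = length(per_cell_counts),
       control_mean = cm,
       normalized_difference = m - cm,
       normalized_ratio = if (cm > 0) m / cm else NA_real_)
}

#' Micronucleus yield per 1000 binucleated cells
#'
#' @param mn_counts Number of micronuclei counted.
#' @param binucleated_cells Number of binucleated cells scored (>= 1).
#' @param control_yield Optional control yield (per 1000 BN cells) for
#'   normalization.
#' @return List with `yield_per_1000` and, when a control is given,
#'   `normalized`.
#' @examples
#' mn_yield(7, 350)  # 20 per 1000 BN cells
#' @export
mn_yield <- function(mn_counts, binucleated_cells, control_yield = NULL) {
  if (any(binucleated_cells < 1)) {
    stop("`binucleated_cells` must be >= 1", call. = FALSE)
  }
  if (any(mn_counts < 0)) stop("`mn_counts` must be non-negative", call. = FALSE)
  y <- mn_counts / binucleated_cells * 1000
  out <- list(yield_per_1000 = y)
  if (!is.null(control_yield)) {
    if (any(control_yield <= 0)) {
      stop("`control_yield` must be positive", call. = FALSE)
    }
    out$normalized <- y / control_yield
  }
  out
}
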