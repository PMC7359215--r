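#' Cellular S-value matrix for nucleus/cytoplasm source-target pairs
#'
#' An S-value is the absorbed dose in a target region per decay in a source
#' region, in Gy/(Bq·s). The 2x2 cellular matrix covers the nucleus (N) and
#' cytoplasm (Cy) compartments. For short-range emitters the self-dose terms
#' dominate: a warning is raised if s_n_n > s_cy_cy > s_n_cy does not hold.
#'
#' @param s_n_n Dose to nucleus per decay in nucleus, Gy/(Bq·s).
#' @param s_cy_n Dose to cytoplasm per decay in nucleus.
#' @param s_n_cy Dose to nucleus per decay in cytoplasm.
#' @param s_cy_cy Dose to cytoplasm per decay in cytoplasm.
#' @param radionuclide Label for the radionuclide.
#' @return An object of class `s_value_matrix`. The `reciprocal` attribute
#'   records whether the cross terms are equal.
#' @seealso [s_value_tc99m()] for the packaged 99mTc default.
#' @export
s_value_matrix <- function(s_n_n, s_cy_n, s_n_cy, s_cy_cy,
                           radionuclide = "unspecified") {
  vals <- c(s_n_n = s_n_n, s_cy_n = s_cy_n, s_n_cy = s_n_cy, s_cy_cy = s_cy_cy)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all S-values must be positive finite numbers", call. = FALSE)
  }
  if (!(s_n_n > s_cy_cy && s_cy_cy > s_n_cy)) {
    warning("S-value ordering s_n_n > s_cy_cy > s_n_cy expected for short-range emitters",
            call. = FALSE)
  }
  structure(
    list(s_n_n = s_n_n, s_cy_n = s_cy_n, s_n_cy = s_n_cy, s_cy_cy = s_cy_cy,
         radionuclide = radionuclide,
         reciprocal = isTRUE(all.equal(s_n_cy, s_cy_n))),
    class = "s_value_matrix"
  )
}

#' MIRD cellular S-values for 99mTc
#'
#' The published MIRD cellular S-values for the 99mTc electron emission
#' spectrum (Auger + internal conversion), for a 2 um nucleus inside a 4 um
#' cell: S(N<-N) = 1.19e-2, S(Cy<-N) = S(N<-Cy) = 1.82e-4,
#' S(Cy<-Cy) = 1.74e-3 Gy/(Bq·s).
#'
#' @return An `s_value_matrix` labelled "Tc99m_MIRD".
#' @export
s_value_tc99m <- function() {
  s_value_matrix(s_n_n = 1.19e-2, s_cy_n = 1.82e-4,
                 s_n_cy = 1.82e-4, s_cy_cy = 1.74e-3,
                 radionuclide = "Tc99m_MIRD")
}

#' @export
print.s_value_matrix <- function(x, ...) {
  cat(sprintf("S-value matrix [%s], Gy/(Bq.s):\n", x$radionuclide))
  m <- matrix(c(x$s_n_n, x$s_n_cy, x$s_cy_n, x$s_cy_cy), 2, 2,
              dimnames = list(target = c("N", "Cy"), source = c("N", "Cy")))
  print(signif(m, 4))
  invisible(x)
}

#' Read / write an S-value matrix as JSON
#'
#' The on-disk format is a flat JSON object with keys `radionuclide`,
#' `s_n_n`, `s_cy_n`, `s_n_cy`, `s_cy_cy` and `units` ("Gy/Bq.s").
#'
#' @param path File path.
#' @return `read_s_value_json()` returns an `s_value_matrix`;
#'   `write_s_value_json()` returns `path` invisibly.
#' @export
read_s_value_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("s_n_n", "s_cy_n", "s_n_cy", "s_cy_cy")
  if (!all(need %in% names(x))) {
    stop("S-value JSON must contain keys: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  s_value_matrix(x$s_n_n, x$s_cy_n, x$s_n_cy, x$s_cy_cy,
                 radionuclide = if (is.null(x$radionuclide)) "unspecified" else x$radionuclide)
}

#' @rdname read_s_value_json
#' @param s An `s_value_matrix`.
#' @export
write_s_value_json <- function(s, path) {
  stopifnot(inherits(s, "s_value_matrix"))
  jsonlite::write_json(
    list(radionuclide = s$radionuclide, s_n_n = s$s_n_n, s_cy_n = s$s_cy_n,
         s_n_cy = s$s_n_cy, s_cy_cy = s$s_cy_cy, units = "Gy/Bq.s"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Compartment absorbed doses from cumulated activities
#'
#' The standard MIRD bilinear form:
#' \deqn{D_N = \tilde A_N S(N \leftarrow N) + \tilde A_{Cy} S(N \leftarrow Cy)}
#' \deqn{D_{Cy} = \tilde A_N S(Cy \leftarrow N) + \tilde A_{Cy} S(Cy \leftarrow Cy)}
#'
#' The total cellular dose is, by default, the sum of the two compartment
#' doses (`total = "sum"`); this is the convention under which the nuclear
#' dose share follows directly from the nuclear uptake fraction and the
#' S-value matrix. A mass-weighted alternative
#' (`total = "mass_weighted"`, energy per total cell mass) is available; it
#' requires a [cell_phantom()] for the compartment masses.
#'
#' @param act A [cumulated_activity()] object.
#' @param s An [s_value_matrix()].
#' @param total Total-dose convention, `"sum"` (default) or `"mass_weighted"`.
#' @param phantom A [cell_phantom()], needed only for `"mass_weighted"`.
#' @return A `dose_result`: list with `dose_nucleus_gy`, `dose_cytoplasm_gy`,
#'   `dose_cell_gy` and `nuclear_dose_fraction` = D_N / (D_N + D_Cy).
#' @examples
#' act <- cumulated_activity(100, 100)
#' compartment_doses(act, s_value_tc99m())
#' @export
compartment_doses <- function(act, s, total = c("sum", "mass_weighted"),
                              phantom = NULL) {
  stopifnot(inherits(act, "cumulated_activity"), inherits(s, "s_value_matrix"))
  total <- match.arg(total)
  d_n <- act$nucleus_bqs * s$s_n_n + act$cytoplasm_bqs * s$s_n_cy
  d_cy <- act$nucleus_bqs * s$s_cy_n + act$cytoplasm_bqs * s$s_cy_cy
  if (total == "sum") {
    d_cell <- d_n + d_cy
  } else {
    if (is.null(phantom)) {
      stop("`phantom` is required for the mass-weighted total", call. = FALSE)
    }
    m <- region_masses(phantom)
    d_cell <- (d_n * m$nucleus_kg + d_cy * m$cytoplasm_kg) /
      (m$nucleus_kg + m$cytoplasm_kg)
  }
  frac <- if (d_n + d_cy > 0) d_n / (d_n + d_cy) else NA_real_
  structure(
    list(dose_nucleus_gy = d_n, dose_cytoplasm_gy = d_cy,
         dose_cell_gy = d_cell, nuclear_dose_fraction = frac),
    class = "dose_result"
  )
}

#' @export
print.dose_result <- function(x, ...) {
  cat(sprintf("Absorbed dose: nucleus %.4g Gy, cytoplasm %.4g Gy, cell %.4g Gy (nuclear share %.1f%%)\n",
              x$dose_nucleus_gy, x$dose_cytoplasm_gy, x$dose_cell_gy,
              100 * x$nuclear_dose_fraction))
  invisible(x)
}

#' Nuclear share of total cell dose implied by a nuclear uptake fraction
#'
#' For an internalized activity split (f, 1 - f) between nucleus and
#' cytoplasm, returns D_N / (D_N + D_Cy). The result is independent of the
#' total amount of activity (the bilinear form is homogeneous of degree 1),
#' so a unit cumulated activity is used internally.
#'
#' With the 99mTc defaults, the mean nuclear uptake fractions 0.45 and 0.22
#' give shares of about 0.84 and 0.66: most of the cell dose is delivered to
#' the nucleus even when less than half the activity resides there, because
#' the nuclear self-dose S-value is an order of magnitude larger than the
#' cytoplasm terms.
#'
#' @param nuclear_fraction Fraction of internalized activity in the nucleus
#'   (vectorized), in \[0, 1\].
#' @param s An [s_value_matrix()].
#' @return Nuclear dose fraction(s) in \[0, 1\].
#' @examples
#' nuclear_dose_fraction_from_uptake(c(0.45, 0.22), s_value_tc99m())
#' @export
nuclear_dose_fraction_from_uptake <- function(nuclear_fraction, s = s_value_tc99m()) {
  stopifnot(inherits(s, "s_value_matrix"))
  if (any(nuclear_fraction < 0 | nuclear_fraction > 1)) {
    stop("`nuclear_fraction` must lie in [0, 1]", call. = FALSE)
  }
  f <- nuclear_fraction
  d_n <- f * s$s_n_n + (1 - f) * s$s_n_cy
  d_cy <- f * s$s_cy_n + (1 - f) * s$s_cy_cy
  d_n / (d_n + d_cy)
}

#' Per-measurement dose table
#'
#' Chains the activity bookkeeping and the S-value dose computation for a set
#' of uptake measurements, one dose row per record, sorted by applied
#' activity.
#'
#' @param records A list of [uptake_record()] objects, or a data frame as
#'   returned by [read_uptake_csv()].
#' @param params A [decay_params()] object.
#' @param s An [s_value_matrix()].
#' @param nuclear_fraction_mode How the nuclear fraction enters the dose
#'   split: `"mean"` (default) replaces each record's fraction with the mean
#'   over all records of the same compound, mirroring the use of a
#'   per-compound mean nuclear uptake; `"per_record"` uses each record's own
#'   fraction.
#' @param total Total-dose convention passed to [compartment_doses()].
#' @param phantom Optional [cell_phantom()] for the mass-weighted total.
#' @param cells_per_sample Number of cells contributing to each measured
#'   count, used to normalize the cumulated activity to the average single
#'   cell before applying the per-cell S-values. Default 1 (counts already
#'   per cell). Dose shares are unaffected by this scale factor.
#' @return A data frame with columns `compound`, `applied_activity_bq`,
#'   `dose_nucleus_gy`, `dose_cytoplasm_gy`, `dose_cell_gy`,
#'   `nuclear_dose_fraction`.
#' @export
dose_table <- function(records, params = decay_params(), s = s_value_tc99m(),
                       nuclear_fraction_mode = c("mean", "per_record"),
                       total = "sum", phantom = NULL, cells_per_sample = 1) {
  stopifnot(cells_per_sample >= 1)
  nuclear_fraction_mode <- match.arg(nuclear_fraction_mode)
  if (is.data.frame(records)) {
    records <- lapply(seq_len(nrow(records)), function(i) {
      uptake_record(records$applied_activity_bq[i],
                    internalized_cpm = records$internalized_cpm[i],
                    surface_cpm = records$surface_cpm[i],
                    nuclear_fraction = records$nuclear_fraction[i],
                    measurement_time_h = records$time_h[i],
                    compound = records$compound[i])
    })
  }
  if (length(records) == 0L) {
    return(data.frame(compound = character(), applied_activity_bq = numeric(),
                      dose_nucleus_gy = numeric(), dose_cytoplasm_gy = numeric(),
                      dose_cell_gy = numeric(), nuclear_dose_fraction = numeric()))
  }
  stopifnot(all(vapply(records, inherits, logical(1), "uptake_record")))

  compounds <- vapply(records, function(r) as.character(r$compound), character(1))
  compounds[is.na(compounds)] <- "<unlabelled>"
  fracs <- vapply(records, function(r) r$nuclear_fraction, numeric(1))
  if (nuclear_fraction_mode == "mean") {
    mean_by <- tapply(fracs, compounds, mean)
    fracs <- as.numeric(mean_by[compounds])
  }

  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    r$nuclear_fraction <- fracs[i]
    act <- partition_cumulated_activity(r, params)
    act$nucleus_bqs <- act$nucleus_bqs / cells_per_sample
    act$cytoplasm_bqs <- act$cytoplasm_bqs / cells_per_sample
    d <- compartment_doses(act, s, total = total, phantom = phantom)
    data.frame(compound = compounds[i],
               applied_activity_bq = r$applied_activity_bq,
               dose_nucleus_gy = d$dose_nucleus_gy,
               dose_cytoplasm_gy = d$dose_cytoplasm_gy,
               dose_cell_gy = d$dose_cell_gy,
               nuclear_dose_fraction = d$nuclear_dose_fraction)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$compound, out$applied_activity_bq), , drop = FALSE]
  rownames(out) <- NULL
  out
}
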