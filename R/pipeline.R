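# Pipeline entry points tying the modules together: each run_* function is a
# pure function of (inputs, config, seed) that optionally writes CSV/JSON
# reports. The thin command-line dispatcher in inst/cli/celldose.R calls
# these directly.

# Rolling hash of the deparsed config, so every report can state which
# configuration produced it.
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.report_meta <- function(config) {
  list(package = "celldose",
       version = as.character(utils::packageVersion("celldose")),
       config = config,
       config_hash = .config_hash(config))
}

#' Parse an activity string with unit suffix
#'
#' Accepts plain numbers (Bq) or values with `kBq`/`MBq`/`GBq`/`Bq`
#' suffixes; the canonical internal unit is Bq.
#'
#' @param x Character or numeric vector.
#' @return Activities in Bq.
#' @examples
#' parse_activity(c("7.4 MBq", "185 kBq", "100"))
#' @export
parse_activity <- function(x) {
  if (is.numeric(x)) return(x)
  m <- regmatches(x, regexec("^\\s*([0-9.eE+-]+)\\s*([kMG]?Bq)?\\s*$", x))
  vapply(m, function(g) {
    if (length(g) == 0L || g[2] == "") {
      stop("cannot parse activity: ", paste(g, collapse = ""), call. = FALSE)
    }
    v <- as.numeric(g[2])
    mult <- switch(ifelse(g[3] == "", "Bq", g[3]),
                   Bq = 1, kBq = 1e3, MBq = 1e6, GBq = 1e9)
    v * mult
  }, numeric(1))
}

#' Run the MIRD dose pipeline over an uptake CSV
#'
#' Reads an uptake table, chains the activity bookkeeping and the S-value
#' dose computation, and writes a per-activity dose report plus a JSON
#' summary with per-compound mean nuclear dose shares.
#'
#' @param uptake_csv Path to an uptake CSV (see [read_uptake_csv()]), or a
#'   data frame in the same schema.
#' @param out_csv,out_json Optional output paths.
#' @param params A [decay_params()] object.
#' @param s An [s_value_matrix()], or a path to an S-value JSON file.
#' @param nuclear_fraction_mode Passed to [dose_table()].
#' @param total Total-dose convention passed to [compartment_doses()].
#' @param phantom Optional [cell_phantom()] for the mass-weighted total.
#' @param cells_per_sample Per-cell normalization passed to [dose_table()].
#' @return List with the dose `table` (data frame), the per-compound
#'   `summary` and the report metadata; invisibly if any output was written.
#' @export
run_dose_mird <- function(uptake_csv, out_csv = NULL, out_json = NULL,
                          params = decay_params(), s = s_value_tc99m(),
                          nuclear_fraction_mode = "mean",
                          total = "sum", phantom = NULL, cells_per_sample = 1) {
  records <- if (is.data.frame(uptake_csv)) uptake_csv else read_uptake_csv(uptake_csv)
  if (is.character(s)) s <- read_s_value_json(s)
  tab <- dose_table(records, params = params, s = s,
                    nuclear_fraction_mode = nuclear_fraction_mode,
                    total = total, phantom = phantom,
                    cells_per_sample = cells_per_sample)
  summary <- if (nrow(tab) > 0L) {
    agg <- stats::aggregate(
      cbind(nuclear_dose_fraction, dose_cell_gy) ~ compound, data = tab,
      FUN = mean)
    names(agg) <- c("compound", "mean_nuclear_dose_share", "mean_cell_dose_gy")
    agg
  } else {
    data.frame(compound = character(), mean_nuclear_dose_share = numeric(),
               mean_cell_dose_gy = numeric())
  }
  config <- list(input = if (is.character(uptake_csv)) uptake_csv else "<data frame>",
                 half_life_h = params$half_life_h,
                 counter_efficiency = params$counter_efficiency,
                 s_matrix = s[c("s_n_n", "s_cy_n", "s_n_cy", "s_cy_cy", "radionuclide")],
                 nuclear_fraction_mode = nuclear_fraction_mode,
                 total = total)
  out <- list(table = tab, summary = summary, meta = .report_meta(config))
  wrote <- FALSE
  if (!is.null(out_csv)) {
    utils::write.csv(tab, out_csv, row.names = FALSE)
    wrote <- TRUE
  }
  if (!is.null(out_json)) {
    jsonlite::write_json(list(summary = summary, meta = out$meta), out_json,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    wrote <- TRUE
  }
  if (wrote) invisible(out) else out
}

#' Run the Monte Carlo transport pipeline
#'
#' @param spectrum An [electron_spectrum()] or path to a two-column spectrum
#'   file.
#' @param out_json Optional JSON report path.
#' @param phantom A [cell_phantom()].
#' @param source_region,n_histories,seed,model Passed to [run_s_value_mc()].
#' @return The `transport_result`; invisibly if a report was written.
#' @export
run_dose_mc <- function(spectrum, out_json = NULL, phantom = cell_phantom(),
                        source_region = "central_sphere",
                        n_histories = 1e5, seed = 1L,
                        model = stopping_model()) {
  if (is.character(spectrum)) spectrum <- read_spectrum(spectrum)
  res <- run_s_value_mc(spectrum, phantom, source_region = source_region,
                        n_histories = n_histories, seed = seed, model = model)
  if (!is.null(out_json)) {
    write_transport_json(res, out_json)
    return(invisible(res))
  }
  res
}

#' Read a clonogenic assay CSV
#'
#' Expected columns: `label` (compound), `activity_bq` (0 for the untreated
#' control) or `dose_gy`, `cells_seeded`, `colonies`.
#'
#' @param path CSV path.
#' @return A validated data frame.
#' @export
read_clonogenic_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("label", "cells_seeded", "colonies")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L || !any(c("activity_bq", "dose_gy") %in% names(df))) {
    stop("clonogenic CSV needs columns label, cells_seeded, colonies and ",
         "activity_bq or dose_gy", call. = FALSE)
  }
  if (any(df$cells_seeded < 1) || any(df$colonies < 0)) {
    stop("invalid clonogenic rows: cells_seeded >= 1 and colonies >= 0 required",
         call. = FALSE)
  }
  df
}

#' Survival, IC50 and RBE from clonogenic counts and a dose report
#'
#' For each compound: survival fractions are computed against the compound's
#' untreated control (activity 0); activities are joined to total cellular
#' doses from a MIRD dose report; the exponential survival model is fitted
#' against dose; IC50 is estimated on the activity scale; and RBE endpoints
#' are computed against the reference fit.
#'
#' @param clonogenic Path to a clonogenic CSV (see [read_clonogenic_csv()])
#'   or a data frame in that schema with an `activity_bq` column.
#' @param reference A `survival_fit` for the reference radiation (e.g. the
#'   60Co curve, supplied as [survival_fit()] with its fitted slope).
#' @param dose_report A dose table from [run_dose_mird()]/[dose_table()] (or
#'   path to its CSV) with columns `compound`, `applied_activity_bq` and
#'   `dose_cell_gy`.
#' @param out_json Optional JSON report path.
#' @param activity_tol Relative tolerance when matching clonogenic
#'   activities to dose-report activities. Default 1e-6.
#' @return A list per compound with the survival fit, IC50 and `rbe_result`;
#'   invisibly if a report was written.
#' @export
run_rbe <- function(clonogenic, reference, dose_report, out_json = NULL,
                    activity_tol = 1e-6) {
  stopifnot(inherits(reference, "survival_fit"))
  df <- if (is.data.frame(clonogenic)) clonogenic else read_clonogenic_csv(clonogenic)
  doses <- if (is.data.frame(dose_report)) dose_report
           else utils::read.csv(dose_report, stringsAsFactors = FALSE)
  stopifnot(all(c("compound", "applied_activity_bq", "dose_cell_gy") %in% names(doses)))

  out <- list()
  for (cmp in unique(df$label)) {
    sub <- df[df$label == cmp, ]
    ctrl <- sub[sub$activity_bq == 0, ]
    if (nrow(ctrl) == 0L) {
      stop("no untreated control row (activity_bq = 0) for compound ", cmp,
           call. = FALSE)
    }
    pe <- plating_efficiency(sum(ctrl$colonies), sum(ctrl$cells_seeded))
    trt <- sub[sub$activity_bq > 0, ]
    sf <- survival_fraction(trt$colonies, pe, trt$cells_seeded)

    dsub <- doses[doses$compound == cmp, ]
    idx <- vapply(trt$activity_bq, function(a) {
      hit <- which(abs(dsub$applied_activity_bq - a) <=
                     activity_tol * pmax(a, dsub$applied_activity_bq))
      if (length(hit) == 0L) NA_integer_ else hit[1]
    }, integer(1))
    if (anyNA(idx)) {
      stop("activities with no matching dose-report row for compound ", cmp,
           ": ", paste(unique(trt$activity_bq[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    }
    dose_gy <- dsub$dose_cell_gy[idx]

    fit <- fit_linear_survival(dose_gy, sf)
    ic50 <- tryCatch(
      ic50_from_activity(c(0, trt$activity_bq), c(1, sf)),
      error = function(e) NULL)
    out[[cmp]] <- list(compound = cmp, control_pe = pe,
                       survival = data.frame(activity_bq = trt$activity_bq,
                                             dose_gy = dose_gy, sf = sf),
                       fit = fit, ic50 = ic50,
                       rbe = rbe(reference, fit))
  }
  if (!is.null(out_json)) {
    flat <- lapply(out, function(x) {
      list(compound = x$compound, control_pe = x$control_pe,
           kappa = x$fit$kappa, kappa_se = x$fit$kappa_se,
           ic50_bq = if (is.null(x$ic50)) NA else x$ic50$ic50_bq,
           rbe_05 = x$rbe$rbe_05, rbe_05_se = x$rbe$rbe_05_se,
           rbe_2gy = x$rbe$rbe_2gy, rbe_2gy_se = x$rbe$rbe_2gy_se)
    })
    meta <- .report_meta(list(reference_kappa = reference$kappa,
                              reference_kappa_se = reference$kappa_se))
    jsonlite::write_json(list(compounds = flat, meta = meta), out_json,
                         auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}

#' Generate and write a synthetic uptake experiment
#'
#' @param out_csv Output CSV path.
#' @param compound Preset passed to [uptake_model_params()].
#' @param activities_bq Applied activities, Bq.
#' @param seed RNG seed (mandatory).
#' @param ... Further arguments to [uptake_model_params()].
#' @return The generated data frame, invisibly.
#' @export
run_simulate_uptake <- function(out_csv, compound = "C3",
                                activities_bq = c(1.85e5, 3.7e5, 7.4e5,
                                                  1.85e6, 3.7e6, 7.4e6),
                                seed, ...) {
  tab <- generate_uptake_table(uptake_model_params(compound, ...),
                               activities_bq, seed = seed)
  utils::write.csv(tab, out_csv, row.names = FALSE)
  invisible(tab)
}
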