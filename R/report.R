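# Report tables: the dose-translation table, descriptive-statistics tables
# in the study's reporting layout, and the cross-species exposure report.

#' Mouse-equivalent-dose translation table
#'
#' Regenerates the dose-translation table: each human daily dose in mg, its
#' weight-normalised mg/kg value (2-decimal display) and the allometric
#' mouse equivalent dose (integer display).
#'
#' @param doses_mg Human daily doses in mg (default 5, 15, 45).
#' @param body_weight_kg Human reference weight (default 60 kg).
#' @return A data.frame with columns `human_dose_mg`, `human_dose_mg_kg`,
#'   `med_mg_kg`.
#' @examples
#' med_table()
#' @export
med_table <- function(doses_mg = c(5, 15, 45), body_weight_kg = 60) {
  mgkg_raw <- dose_mg_per_kg(doses_mg, body_weight_kg, digits = NULL)
  data.frame(human_dose_mg = doses_mg,
             human_dose_mg_kg = round(mgkg_raw, 2),
             med_mg_kg = mouse_equivalent_dose(mgkg_raw)$med_display)
}

#' Descriptive-statistics table in the study layout
#'
#' One row per group with the columns used in the study's parameter tables:
#' Mean, SD, Median, Max, Geometric Mean, Geometric CV (%).
#'
#' @param values Named list of numeric vectors (one per group), or a single
#'   numeric vector.
#' @return A data.frame with a `group` column and the six statistics.
#' @export
summary_table <- function(values) {
  if (is.numeric(values)) values <- list(value = values)
  rows <- lapply(names(values), function(g) {
    s <- pk_summary(values[[g]])
    data.frame(group = g, mean = s$mean, sd = s$sd, median = s$median,
               max = s$max, geo_mean = s$geo_mean, geo_cv_pct = s$geo_cv_pct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-species exposure-matching report
#'
#' Assembles the interspecies comparison in one object: the allometric
#' mouse equivalent dose for a human regimen, the exposure fold-difference
#' allometry predicts, the exposure ratio actually observed, and the
#' empirical correction factor between the predicted and the
#' exposure-matched dose.
#'
#' @param human_dose_mg Human daily dose, mg.
#' @param auc_tau_mouse Observed mouse steady-state AUC(0-tau), h*ng/mL.
#' @param auc_tau_human Observed human steady-state AUC(0-tau), h*ng/mL.
#' @param matched_dose_mgkg The tested mouse dose (mg/kg/day) whose
#'   exposure matches (brackets) the human exposure.
#' @param body_weight_kg Human reference weight, kg.
#' @return An object of class `exposure_report`: list with
#'   `human_dose_mgkg`, `med` (from [mouse_equivalent_dose()]),
#'   `predicted` (from [allometric_exposure_prediction()]), `observed`
#'   (from [observed_exposure_ratio()]), and `correction` (from
#'   [empirical_dose_correction()]).
#' @examples
#' exposure_report(15, auc_tau_mouse = 143.57, auc_tau_human = 76.79,
#'                 matched_dose_mgkg = 0.3)
#' @export
exposure_report <- function(human_dose_mg, auc_tau_mouse, auc_tau_human,
                            matched_dose_mgkg, body_weight_kg = 60) {
  mgkg <- dose_mg_per_kg(human_dose_mg, body_weight_kg, digits = NULL)
  med <- mouse_equivalent_dose(mgkg)
  structure(list(
    human_dose_mgkg = mgkg,
    med = med,
    predicted = allometric_exposure_prediction(),
    observed = observed_exposure_ratio(auc_tau_mouse, auc_tau_human),
    correction = empirical_dose_correction(med$med_display, matched_dose_mgkg)),
    class = "exposure_report")
}

#' @export
print.exposure_report <- function(x, ...) {
  cat(sprintf("Human dose: %.2f mg/kg -> allometric mouse equivalent dose %.2f mg/kg (displayed %d)\n",
              x$human_dose_mgkg, x$med$med_mgkg, x$med$med_display))
  cat(sprintf("Allometric prediction: mouse exposure %d times lower (raw %.2f)\n",
              x$predicted$headline, x$predicted$fold))
  cat(sprintf("Observed: mouse exposure %d times higher (raw %.2f)\n",
              x$observed$headline, x$observed$fold))
  cat(sprintf("Empirical dose correction: %d times lower than predicted (raw %.2f)\n",
              x$correction$headline, x$correction$fold))
  invisible(x)
}

#' Run NCA over a set of profiles and collect a result table
#'
#' Averages replicates within each subject x route x dose group, applies
#' the censoring rule and runs [run_nca()] on each averaged profile.
#' Profiles that fail (e.g. entirely censored) are reported as warnings and
#' omitted.
#'
#' @param profiles List of `pk_profile` objects (replicates allowed).
#' @param tau Optional steady-state dosing interval (h).
#' @param ... Passed to [run_nca()].
#' @return A data.frame, one row per subject group.
#' @export
nca_table <- function(profiles, tau = NULL, ...) {
  if (inherits(profiles, "pk_profile")) profiles <- list(profiles)
  key <- vapply(profiles, function(p) {
    paste(p$subject_id, p$route, p$dose_ng, sep = "\r")
  }, character(1))
  groups <- split(profiles, factor(key, levels = unique(key)))
  rows <- lapply(groups, function(g) {
    tryCatch(run_nca(average_replicates(g), tau = tau, ...),
             error = function(e) {
               warning("profile '", g[[1L]]$subject_id, "' skipped: ",
                       conditionMessage(e), call. = FALSE)
               NULL
             })
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a result table as delimited text
#'
#' Numeric columns are written with full precision so repeated runs of the
#' same pipeline are byte-identical.
#'
#' @param table A data.frame.
#' @param path Output path.
#' @param sep Separator (default tab).
#' @return `path`, invisibly.
#' @export
write_result_table <- function(table, path, sep = "\t") {
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
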