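# Interspecies dose translation by body-surface-area (Km factor) scaling
# and the exposure-matching comparison between species.

#' Species body-surface-area conversion factors
#'
#' Reference body weights and Km factors (body weight / body surface area)
#' in the standard animal-to-human dose conversion convention. The
#' human-to-animal equivalent dose is
#' `animal dose (mg/kg) = human dose (mg/kg) * Km_human / Km_animal`.
#'
#' @return A data.frame with columns `species`, `body_weight_kg`, `km`.
#' @export
species_factors <- function() {
  data.frame(
    species = c("human", "mouse", "rat", "rabbit", "dog"),
    body_weight_kg = c(60, 0.025, 0.15, 1.8, 10),
    km = c(37, 3, 6, 12, 20),
    stringsAsFactors = FALSE)
}

.km <- function(species) {
  tab <- species_factors()
  i <- match(species, tab$species)
  if (anyNA(i)) stop("unknown species: ", species[is.na(i)][1L], call. = FALSE)
  tab$km[i]
}

#' Weight-normalised dose
#'
#' @param dose_mg Dose in mg.
#' @param body_weight_kg Body weight in kg (default: the 60 kg human
#'   reference).
#' @param digits Display rounding (2 decimals, the convention of the dose
#'   translation table); use `NULL` for the unrounded value.
#' @return Dose in mg/kg.
#' @examples
#' dose_mg_per_kg(15)  # 0.25 mg/kg
#' @export
dose_mg_per_kg <- function(dose_mg, body_weight_kg = 60, digits = 2) {
  if (any(dose_mg <= 0) || body_weight_kg <= 0) {
    stop("dose and body weight must be positive", call. = FALSE)
  }
  x <- dose_mg / body_weight_kg
  if (is.null(digits)) x else round(x, digits)
}

#' Mouse equivalent dose by Km-factor scaling
#'
#' Translates a human mg/kg dose to the mouse equivalent dose
#' `MED = dose * Km_human / Km_mouse` (37/3 with the default factors). The
#' raw value is returned together with the integer display rounding used in
#' dose-translation tables.
#'
#' @param human_dose_mgkg Human dose in mg/kg.
#' @param km_human,km_mouse Km factors (defaults 37 and 3).
#' @return List with `med_mgkg` (raw) and `med_display` (rounded).
#' @examples
#' mouse_equivalent_dose(0.25)  # 3.08 -> displayed as 3 mg/kg
#' @export
mouse_equivalent_dose <- function(human_dose_mgkg, km_human = .km("human"),
                                  km_mouse = .km("mouse")) {
  if (any(human_dose_mgkg <= 0)) stop("dose must be positive", call. = FALSE)
  med <- human_dose_mgkg * km_human / km_mouse
  list(med_mgkg = med, med_display = round(med))
}

#' Exposure fold-difference predicted by allometry
#'
#' Under body-surface-area scaling, giving the mouse the same mg/kg dose as
#' the human should under-expose it by the Km ratio: the predicted
#' exposure in the mouse is `Km_human / Km_mouse` times lower (37/3 = 12.3,
#' headline 12, with the default factors).
#'
#' @param km_human,km_mouse Km factors.
#' @return List with `fold` (raw ratio) and `headline` (integer-rounded).
#' @export
allometric_exposure_prediction <- function(km_human = .km("human"),
                                           km_mouse = .km("mouse")) {
  fold <- km_human / km_mouse
  list(fold = fold, headline = round(fold))
}

#' Observed interspecies exposure ratio
#'
#' Ratio of the measured steady-state exposures (AUC over one dosing
#' interval) in the two species, with the integer-rounded headline figure.
#'
#' @param auc_tau_mouse,auc_tau_human Steady-state AUC(0-tau), h*ng/mL.
#' @return List with `fold` and `headline`.
#' @examples
#' observed_exposure_ratio(143.57, 76.79)  # 1.87 -> headline 2
#' @export
observed_exposure_ratio <- function(auc_tau_mouse, auc_tau_human) {
  if (auc_tau_mouse <= 0 || auc_tau_human <= 0) {
    stop("AUCs must be positive", call. = FALSE)
  }
  fold <- auc_tau_mouse / auc_tau_human
  list(fold = fold, headline = round(fold))
}

#' Empirical correction to the allometric dose prediction
#'
#' Ratio of the allometric mouse equivalent dose to the dose empirically
#' found to match (or bracket) the human exposure: how many times lower a
#' dose than predicted is actually needed.
#'
#' @param med_mgkg Allometric mouse equivalent dose, mg/kg.
#' @param matched_dose_mgkg Empirically exposure-matched dose, mg/kg.
#' @return List with `fold` and `headline`.
#' @examples
#' empirical_dose_correction(3, 0.3)  # 10-fold
#' @export
empirical_dose_correction <- function(med_mgkg, matched_dose_mgkg) {
  if (med_mgkg <= 0 || matched_dose_mgkg <= 0) {
    stop("doses must be positive", call. = FALSE)
  }
  fold <- med_mgkg / matched_dose_mgkg
  list(fold = fold, headline = round(fold))
}

#' Dose proportionality of steady-state exposure
#'
#' Ordinary least-squares line of the average steady-state concentration on
#' the administered dose rate, with the coefficient of determination. A
#' degenerate response with zero variance is reported as `r_squared = 0`.
#'
#' @param doses Dose rates (e.g. mg/kg/day), at least 3 levels.
#' @param cav Average concentrations (ng/mL), same length.
#' @return An object of class `prop_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @examples
#' dose_proportionality(c(0.1, 0.3, 1), c(2.47, 6.49, 26.14))
#' @export
dose_proportionality <- function(doses, cav) {
  doses <- as.numeric(doses); cav <- as.numeric(cav)
  if (length(doses) != length(cav)) stop("length mismatch", call. = FALSE)
  if (length(unique(doses)) < 3L) {
    stop("need at least 3 dose levels", call. = FALSE)
  }
  fit <- stats::lm(cav ~ doses)
  sxy <- sum((doses - mean(doses)) * (cav - mean(cav)))
  sxx <- sum((doses - mean(doses))^2)
  syy <- sum((cav - mean(cav))^2)
  r2 <- if (syy == 0) 0 else sxy^2 / (sxx * syy)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2, n = length(doses)),
            class = "prop_fit")
}

#' @export
print.prop_fit <- function(x, ...) {
  cat(sprintf("<prop_fit> Cav = %.4g + %.4g * dose | r^2 = %.3f (n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}
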