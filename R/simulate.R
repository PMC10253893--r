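# Closed-form simulators for every administration route in the study:
# biexponential i.v. bolus, first-order absorption (single and double
# depot, with lags), zero-order minipump infusion, and repeated oral dosing
# by linear superposition. All models are evaluated in closed form; no ODE
# integration is involved, so simulated values can be checked exactly.

#' Route model
#'
#' Parameter container for the closed-form concentration simulators.
#'
#' Kinds and their fields:
#' \describe{
#'   \item{`iv_biexp`}{macro-constants `A`, `B` (ng/mL) and rates `alpha`,
#'     `beta` (1/min, the mouse i.v. reporting convention); requires
#'     `alpha > beta > 0` and `A, B >= 0`.}
#'   \item{`first_order`, `double_peak_oral`, `repeat_oral_reabsorption`}{a
#'     `depots` data.frame with columns `fraction` (of dose absorbed),
#'     `ka` (1/h) and `lag` (h) — one depot for s.c./i.p., two for the
#'     double-peak oral and reabsorption models — plus volume `v_ml` (mL)
#'     and elimination rate `ke` (1/h). Depot fractions must sum to <= 1.}
#'   \item{`zero_order_infusion`}{release rate `r0_ng_day` (ng/day),
#'     clearance `cl_ml_min` (mL/min) and onset rate `ke` (1/h).}
#' }
#'
#' @param kind Model kind (see above).
#' @param ... Fields for that kind.
#' @return An object of class `route_model`.
#' @export
route_model <- function(kind = c("iv_biexp", "first_order", "double_peak_oral",
                                 "zero_order_infusion", "repeat_oral_reabsorption"),
                        ...) {
  kind <- match.arg(kind)
  m <- list(kind = kind, ...)
  if (kind == "iv_biexp") {
    stopifnot(is.numeric(m$A), is.numeric(m$B), is.numeric(m$alpha), is.numeric(m$beta))
    if (m$A < 0 || m$B < 0) stop("macro-amplitudes A and B must be >= 0", call. = FALSE)
    if (!(m$alpha > m$beta && m$beta > 0)) {
      stop("iv_biexp requires alpha > beta > 0", call. = FALSE)
    }
  } else if (kind == "zero_order_infusion") {
    stopifnot(is.numeric(m$r0_ng_day), is.numeric(m$cl_ml_min), is.numeric(m$ke))
    if (m$r0_ng_day <= 0 || m$cl_ml_min <= 0 || m$ke <= 0) {
      stop("infusion rate, clearance and ke must be positive", call. = FALSE)
    }
  } else {
    stopifnot(is.data.frame(m$depots), is.numeric(m$v_ml), is.numeric(m$ke))
    need <- c("fraction", "ka", "lag")
    if (!all(need %in% names(m$depots))) {
      stop("depots must have columns fraction, ka, lag", call. = FALSE)
    }
    if (any(m$depots$fraction <= 0) || sum(m$depots$fraction) > 1 + 1e-12) {
      stop("depot fractions must be positive and sum to <= 1", call. = FALSE)
    }
    if (any(m$depots$ka <= 0) || m$ke <= 0 || m$v_ml <= 0) {
      stop("rates and volume must be positive", call. = FALSE)
    }
  }
  structure(m, class = "route_model")
}

#' @export
print.route_model <- function(x, ...) {
  cat("<route_model>", x$kind, "\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Calibrate a biexponential i.v. model from reported NCA parameters
#'
#' Solves for the macro-amplitudes of `C(t) = A exp(-Kd t) + B exp(-Ke t)`
#' given the four quantities a bolus i.v. study reports: the
#' back-extrapolated `C0 = A + B`, the distribution and elimination rates
#' `Kd` and `Ke`, and `AUC(0-inf) = A/Kd + B/Ke`. These are two linear
#' equations in `(A, B)`.
#'
#' @param c0 Back-extrapolated concentration at t = 0, ng/mL.
#' @param kd Distribution macro-rate, 1/min.
#' @param ke Elimination macro-rate, 1/min (`kd > ke > 0`).
#' @param auc_0_inf AUC to infinity, h*ng/mL.
#' @return A `route_model` of kind `iv_biexp`.
#' @examples
#' calibrate_iv(c0 = 294.40, kd = 0.12, ke = 0.0058, auc_0_inf = 75.57)
#' @export
calibrate_iv <- function(c0, kd, ke, auc_0_inf) {
  if (c0 <= 0 || auc_0_inf <= 0) stop("c0 and AUC must be positive", call. = FALSE)
  if (kd == ke) stop("calibration error: kd = ke gives a singular system", call. = FALSE)
  if (!(kd > ke && ke > 0)) stop("require kd > ke > 0", call. = FALSE)
  auc_min <- auc_0_inf * 60
  B <- (auc_min - c0 / kd) / (1 / ke - 1 / kd)
  A <- c0 - B
  if (A < -1e-9 || B < -1e-9) {
    stop(sprintf(paste0("calibration error: infeasible constraints give A = %.4g, ",
                        "B = %.4g (AUC must lie in [C0/Kd, C0/Ke] = [%.4g, %.4g] h*ng/mL)"),
                 A, B, c0 / kd / 60, c0 / ke / 60), call. = FALSE)
  }
  route_model("iv_biexp", A = max(A, 0), B = max(B, 0), alpha = kd, beta = ke)
}

#' Simulate an i.v. bolus profile
#'
#' Evaluates `C(t) = A exp(-alpha t) + B exp(-beta t)` (rates per minute,
#' times supplied in hours) without noise; apply [add_noise()] afterwards
#' for replicates, noise and LLOQ censoring.
#'
#' @param model A `route_model` of kind `iv_biexp`.
#' @param times_h Sampling times, hours.
#' @param ... Profile metadata passed to [pk_profile()] (`subject_id`,
#'   `dose`, `lloq`, ...).
#' @return A `pk_profile`.
#' @export
simulate_iv <- function(model, times_h, ...) {
  stopifnot(inherits(model, "route_model"), model$kind == "iv_biexp")
  tmin <- times_h * 60
  conc <- model$A * exp(-model$alpha * tmin) + model$B * exp(-model$beta * tmin)
  .sim_profile(times_h, conc, route = "iv", ...)
}

# Bateman term per unit dose/volume: ka/(ka-ke) (e^{-ke t} - e^{-ka t}),
# with the ka -> ke limit ka * t * e^{-ka t}.
.bateman <- function(t, ka, ke, lag = 0) {
  tt <- t - lag
  out <- numeric(length(t))
  on <- tt > 0
  if (abs(ka - ke) < 1e-10 * ka) {
    out[on] <- ka * tt[on] * exp(-ka * tt[on])
  } else {
    out[on] <- ka / (ka - ke) * (exp(-ke * tt[on]) - exp(-ka * tt[on]))
  }
  out
}

.sim_profile <- function(times_h, conc, route, subject_id = "sim",
                         species = "mouse", dose = 1, dose_unit = "ng",
                         dose_per_kg = NA_real_, lloq = 1e-6, replicate = 1L) {
  pk_profile(subject_id = subject_id, species = species, route = route,
             time = times_h, conc = pmax(conc, 0), blq = NULL, lloq = lloq,
             dose = dose, dose_unit = dose_unit, dose_per_kg = dose_per_kg,
             replicate = replicate)
}

#' Simulate first-order absorption (single or multiple depots)
#'
#' Sum of Bateman inputs over the model's depots:
#' `C(t) = (Dose/V) * sum_i f_i * ka_i/(ka_i - ke) * (e^{-ke (t-lag_i)} -
#' e^{-ka_i (t-lag_i)})` for `t >= lag_i` (0 before), with the `ka = ke`
#' limiting form `ka t e^{-ka t}`. One depot reproduces the sharp
#' subcutaneous/intraperitoneal peak; two lagged depots produce the
#' double-peak oral profile.
#'
#' @param model A `route_model` of kind `first_order`, `double_peak_oral`
#'   or `repeat_oral_reabsorption`.
#' @param dose_ng Administered dose, ng.
#' @param times_h Sampling times, hours.
#' @param route Route label for the returned profile.
#' @param ... Profile metadata passed to [pk_profile()].
#' @return A `pk_profile`.
#' @export
simulate_absorption <- function(model, dose_ng, times_h, route = "sc", ...) {
  stopifnot(inherits(model, "route_model"),
            model$kind %in% c("first_order", "double_peak_oral",
                              "repeat_oral_reabsorption"))
  conc <- .absorption_conc(model, dose_ng, times_h)
  .sim_profile(times_h, conc, route = route, dose = dose_ng, ...)
}

.absorption_conc <- function(model, dose_ng, times_h) {
  conc <- numeric(length(times_h))
  for (i in seq_len(nrow(model$depots))) {
    d <- model$depots[i, ]
    conc <- conc + d$fraction * dose_ng / model$v_ml *
      .bateman(times_h, d$ka, model$ke, d$lag)
  }
  conc
}

#' Simulate a zero-order (osmotic minipump) infusion
#'
#' During the infusion `C(t) = Css (1 - e^{-ke t})` with the steady-state
#' plateau `Css = R0 / CL`; after the pump is exhausted the concentration
#' decays monoexponentially.
#'
#' @param model A `route_model` of kind `zero_order_infusion`.
#' @param duration_h Infusion duration, hours.
#' @param times_h Sampling times, hours.
#' @param ... Profile metadata passed to [pk_profile()].
#' @return A `pk_profile`.
#' @export
simulate_infusion <- function(model, duration_h, times_h, ...) {
  stopifnot(inherits(model, "route_model"), model$kind == "zero_order_infusion")
  css <- model$r0_ng_day / (model$cl_ml_min * 60 * 24)  # ng/mL
  conc <- ifelse(times_h <= duration_h,
                 css * (1 - exp(-model$ke * times_h)),
                 css * (1 - exp(-model$ke * duration_h)) *
                   exp(-model$ke * (times_h - duration_h)))
  .sim_profile(times_h, conc, route = "minipump", ...)
}

#' Simulate repeated oral dosing by superposition
#'
#' Linear superposition of the single-dose absorption curve at dose times
#' `0, tau, 2 tau, ...`. With first-order elimination the trough builds up
#' towards steady state as `1 - e^{-ke n tau}` after the n-th dose (see
#' [steady_state_fraction()]).
#'
#' @param model A `route_model` of an absorption kind (for the human
#'   once-daily scenario: `repeat_oral_reabsorption`, a primary depot plus
#'   a delayed reabsorption depot).
#' @param dose_ng Dose per administration, ng.
#' @param tau_h Dosing interval, hours.
#' @param n_doses Number of doses.
#' @param times_h Absolute sampling times, hours (from the first dose).
#' @param route Route label for the returned profile.
#' @param ... Profile metadata passed to [pk_profile()].
#' @return A `pk_profile`.
#' @export
simulate_repeat_oral <- function(model, dose_ng, tau_h, n_doses, times_h,
                                 route = "oral", ...) {
  stopifnot(inherits(model, "route_model"),
            model$kind %in% c("first_order", "double_peak_oral",
                              "repeat_oral_reabsorption"))
  if (n_doses < 1L) stop("n_doses must be >= 1", call. = FALSE)
  if (n_doses > 1L && tau_h <= 0) stop("tau must be > 0 for repeated dosing", call. = FALSE)
  conc <- numeric(length(times_h))
  for (d in seq_len(n_doses) - 1L) {
    conc <- conc + .absorption_conc(model, dose_ng, times_h - d * tau_h)
  }
  .sim_profile(times_h, conc, route = route, dose = dose_ng, ...)
}

#' Fraction of steady state reached after n doses
#'
#' For first-order elimination, the trough concentration after the n-th of
#' an infinite series of doses is `1 - e^{-ke n tau}` of its steady-state
#' value (geometric-series accumulation).
#'
#' @param ke Elimination rate constant, 1/h.
#' @param n_doses Number of doses given.
#' @param tau_h Dosing interval, hours.
#' @return Fraction in `[0, 1)`.
#' @export
steady_state_fraction <- function(ke, n_doses, tau_h) {
  if (any(ke <= 0) || any(tau_h <= 0) || any(n_doses < 1)) {
    stop("invalid arguments", call. = FALSE)
  }
  1 - exp(-ke * n_doses * tau_h)
}

#' Add log-normal assay noise and duplicate sampling to a profile
#'
#' Emulates the study's duplicate volumetric microsampling: each replicate
#' observation is `C_true * exp(eps)` with `eps ~ N(0, sigma_ln^2)`,
#' independently per point and replicate. Censoring is applied after the
#' noise: values below the profile's LLOQ are flagged censored. The random
#' state is fully determined by `seed` and the caller's RNG state is left
#' untouched.
#'
#' @param profile A noiseless `pk_profile`.
#' @param sigma_ln Log-scale SD of the multiplicative noise (>= 0).
#' @param n_replicates Number of replicates (default 2, duplicate sampling).
#' @param seed Optional integer seed.
#' @return A list of `pk_profile` replicates.
#' @export
add_noise <- function(profile, sigma_ln, n_replicates = 2L, seed = NULL) {
  stopifnot(inherits(profile, "pk_profile"), sigma_ln >= 0, n_replicates >= 1L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  lapply(seq_len(n_replicates), function(r) {
    eps <- stats::rnorm(length(profile$time), 0, sigma_ln)
    conc <- profile$conc * exp(eps)
    blq <- conc < profile$lloq
    conc[blq] <- NA_real_
    pk_profile(subject_id = profile$subject_id, species = profile$species,
               route = profile$route, time = profile$time, conc = conc,
               blq = blq, lloq = profile$lloq, dose = profile$dose_ng,
               dose_unit = "ng", dose_per_kg = profile$dose_per_kg,
               replicate = r)
  })
}

# mouse disposition shared by the s.c./i.p./oral fixtures: terminal-phase
# decline calibrated so that the s.c. concentration falls to ~30% of Cmax
# 45 min after dosing.
.mouse_abs_ke <- 2.4      # 1/h (= 0.04 /min)
.mouse_weight_kg <- 0.025

# absorption rate giving a Bateman tmax at `tmax_h` for elimination `ke`
.solve_ka <- function(tmax_h, ke) {
  stats::uniroot(function(ka) log(ka / ke) / (ka - ke) - tmax_h,
                 c(ke * 1.0001, 1e4), tol = 1e-12)$root
}

#' Study scenario: calibrated model, regimen and sampling grid
#'
#' Returns, for each administration scenario of the cross-species study,
#' the calibrated [route_model()], the [dosing_regimen()], the exact
#' sampling grid used in the study, and the scenario's default noise level
#' and LLOQ. Calibration anchors (see the methods vignette for the full
#' derivation):
#' \itemize{
#'   \item `mouse_iv` — biexponential model solved from the reported
#'     C0 = 294.40 ng/mL, Kd = 0.12 /min, Ke = 0.0058 /min and
#'     AUC = 75.57 h*ng/mL; grid 1, 5, 10, 15, 30, 45 min and
#'     1, 2, 3, 6, 24 h.
#'   \item `mouse_sc` / `mouse_ip` — single-depot Bateman model with
#'     tmax = 10 min, Cmax = 90.92 (s.c.) / 70.54 (i.p.) ng/mL and a drop
#'     to ~30% of Cmax at 45 min; same acute grid.
#'   \item `mouse_oral` — two lagged depots (total bioavailable fraction
#'     0.33 of the s.c. reference) placing local maxima at 15 and 60 min.
#'   \item `human_single_5mg|15mg|45mg` — primary depot (tmax ~30 min) plus
#'     a delayed reabsorption depot; per-dose terminal half-life 28.21,
#'     19.22, 26.64 h and AUC 38.27, 90.09, 321.05 h*ng/mL; sampling
#'     10-150 min then 3-168 h.
#'   \item `human_multi_15mg` — same shape with the mean half-life 24.69 h,
#'     volume calibrated to the steady-state AUC(0-24) of 76.79 h*ng/mL;
#'     14 once-daily doses, sampled on days 1-14.
#'   \item `minipump_0.1|0.3|1` — zero-order release at 0.1/0.3/1
#'     mg/kg/day for a 25 g mouse; clearance calibrated so that
#'     0.3 mg/kg/day plateaus at Cav = 6.49 ng/mL, the other doses scaling
#'     linearly; sampled at 24 h and 1, 3, 5 weeks.
#' }
#'
#' @param scenario Scenario name (see above).
#' @return A list with elements `scenario`, `species`, `route`, `model`,
#'   `regimen`, `times_h`, `dose_ng`, `dose_per_kg`, `lloq`, `sigma_ln`,
#'   and for repeated/continuous dosing `tau_h`, `n_doses` or `duration_h`.
#' @export
pk_scenario <- function(scenario = c("mouse_iv", "mouse_sc", "mouse_ip",
                                     "mouse_oral", "human_single_5mg",
                                     "human_single_15mg", "human_single_45mg",
                                     "human_multi_15mg", "minipump_0.1",
                                     "minipump_0.3", "minipump_1")) {
  if (length(scenario) != 1L || !scenario %in% eval(formals(pk_scenario)$scenario)) {
    stop("unknown scenario: ", paste(scenario, collapse = ", "), call. = FALSE)
  }
  mouse_acute_grid <- c(c(1, 5, 10, 15, 30, 45) / 60, 1, 2, 3, 6, 24)
  human_grid <- c(c(10, 20, 30, 45, 60, 75, 90, 105, 120, 150) / 60,
                  3, 4, 6, 8, 12, 16, 24, 36, 48, 72, 96, 120, 144, 168)
  pump_grid <- c(24, 7 * 24, 21 * 24, 35 * 24)
  mouse_dose_ng <- 7500  # 7.5 ug = 0.3 mg/kg at 25 g

  if (scenario == "mouse_iv") {
    model <- calibrate_iv(c0 = 294.40, kd = 0.12, ke = 0.0058, auc_0_inf = 75.57)
    return(list(scenario = scenario, species = "mouse", route = "iv",
                model = model,
                regimen = dosing_regimen(mouse_dose_ng, "iv"),
                times_h = mouse_acute_grid, dose_ng = mouse_dose_ng,
                dose_per_kg = 0.3, lloq = 0.05, sigma_ln = 0.23))
  }
  if (scenario %in% c("mouse_sc", "mouse_ip", "mouse_oral")) {
    ke <- .mouse_abs_ke
    ka <- .solve_ka(10 / 60, ke)
    peak <- .bateman(10 / 60, ka, ke)           # unit-dose shape at tmax
    v_sc <- mouse_dose_ng * peak / 90.92        # Cmax anchor, s.c.
    if (scenario == "mouse_oral") {
      ka_or <- .solve_ka(15 / 60, ke)
      model <- route_model("double_peak_oral",
                           depots = data.frame(fraction = c(0.20, 0.13),
                                               ka = ka_or, lag = c(0, 0.8)),
                           v_ml = v_sc, ke = ke)
      route <- "oral"
    } else {
      v <- if (scenario == "mouse_sc") v_sc else mouse_dose_ng * peak / 70.54
      model <- route_model("first_order",
                           depots = data.frame(fraction = 1, ka = ka, lag = 0),
                           v_ml = v, ke = ke)
      route <- if (scenario == "mouse_sc") "sc" else "ip"
    }
    return(list(scenario = scenario, species = "mouse", route = route,
                model = model, regimen = dosing_regimen(mouse_dose_ng, route),
                times_h = mouse_acute_grid, dose_ng = mouse_dose_ng,
                dose_per_kg = 0.3, lloq = 0.05, sigma_ln = 0.23))
  }
  if (grepl("^human", scenario)) {
    anchors <- list(human_single_5mg = c(dose_mg = 5, t_half = 28.21, auc = 38.27),
                    human_single_15mg = c(dose_mg = 15, t_half = 19.22, auc = 90.09),
                    human_single_45mg = c(dose_mg = 45, t_half = 26.64, auc = 321.05),
                    human_multi_15mg = c(dose_mg = 15, t_half = 24.69, auc = 76.79))
    a <- anchors[[scenario]]
    ke <- log(2) / a[["t_half"]]
    dose_ng <- a[["dose_mg"]] * 1e6
    v_ml <- dose_ng / (ke * a[["auc"]])  # apparent V/F from the AUC anchor
    model <- route_model("repeat_oral_reabsorption",
                         depots = data.frame(fraction = c(0.8, 0.2),
                                             ka = c(12, 0.5), lag = c(0, 4)),
                         v_ml = v_ml, ke = ke)
    multi <- scenario == "human_multi_15mg"
    return(list(scenario = scenario, species = "human", route = "oral",
                model = model,
                regimen = dosing_regimen(a[["dose_mg"]], "oral", dose_unit = "mg",
                                         tau = if (multi) 24 else 0,
                                         n_doses = if (multi) 14L else 1L),
                times_h = if (multi) 24 * c(1, 2, 4, 6, 8, 12, 14) else human_grid,
                tau_h = if (multi) 24 else 0,
                n_doses = if (multi) 14L else 1L,
                dose_ng = dose_ng, dose_per_kg = a[["dose_mg"]] / 60,
                lloq = 0.05, sigma_ln = 0.5))
  }
  # minipump_0.1 / 0.3 / 1
  dose_mgkg_day <- as.numeric(sub("^minipump_", "", scenario))
  r0 <- dose_mgkg_day * .mouse_weight_kg * 1e6          # ng/day
  cl_ml_min <- (0.3 * .mouse_weight_kg * 1e6 / 6.49) / (24 * 60)  # Cav anchor
  model <- route_model("zero_order_infusion", r0_ng_day = r0,
                       cl_ml_min = cl_ml_min, ke = log(2) / 2)  # ~2 h mouse half-life
  list(scenario = scenario, species = "mouse", route = "minipump",
       model = model,
       regimen = dosing_regimen(r0, "minipump", infusion_rate = r0,
                                infusion_duration = 35 * 24),
       times_h = pump_grid, duration_h = 35 * 24,
       dose_ng = r0, dose_per_kg = dose_mgkg_day, lloq = 0.05, sigma_ln = 0.42)
}

#' Simulate a full scenario with replicates and noise
#'
#' Convenience wrapper: builds the scenario with [pk_scenario()], evaluates
#' the noiseless model on the study sampling grid (or custom `times_h`) and
#' applies duplicate sampling with log-normal noise and LLOQ censoring.
#'
#' @param scenario Scenario name, see [pk_scenario()].
#' @param n_subjects Number of subjects/animals to simulate.
#' @param sigma_ln Log-scale noise SD; default: the scenario's calibrated
#'   value (0 gives noiseless singles).
#' @param n_replicates Replicates per subject (default 2).
#' @param seed Integer seed.
#' @param times_h Optional custom sampling grid (hours).
#' @return A list of `pk_profile` objects (subjects x replicates).
#' @export
simulate_scenario <- function(scenario, n_subjects = 1L, sigma_ln = NULL,
                              n_replicates = 2L, seed = 1L, times_h = NULL) {
  sc <- pk_scenario(scenario)
  if (is.null(sigma_ln)) sigma_ln <- sc$sigma_ln
  if (is.null(times_h)) times_h <- sc$times_h
  truth <- scenario_truth(sc, times_h)
  out <- list()
  for (s in seq_len(n_subjects)) {
    p <- truth
    p$subject_id <- sprintf("%s_%02d", scenario, s)
    if (sigma_ln == 0 && n_replicates == 1L) {
      reps <- list(p)
    } else {
      reps <- add_noise(p, sigma_ln = sigma_ln, n_replicates = n_replicates,
                        seed = seed + s - 1L)
    }
    out <- c(out, reps)
  }
  out
}

#' Noiseless model curve for a scenario
#'
#' @param sc A scenario list from [pk_scenario()] (or a scenario name).
#' @param times_h Sampling times, hours (default: the study grid).
#' @return A noiseless `pk_profile`.
#' @export
scenario_truth <- function(sc, times_h = NULL) {
  if (is.character(sc)) sc <- pk_scenario(sc)
  if (is.null(times_h)) times_h <- sc$times_h
  meta <- list(subject_id = sc$scenario, species = sc$species,
               dose_unit = "ng", dose_per_kg = sc$dose_per_kg, lloq = sc$lloq)
  m <- sc$model
  if (m$kind == "iv_biexp") {
    do.call(simulate_iv,
            c(list(model = m, times_h = times_h, dose = sc$dose_ng), meta))
  } else if (m$kind == "zero_order_infusion") {
    do.call(simulate_infusion,
            c(list(model = m, duration_h = sc$duration_h, times_h = times_h,
                   dose = sc$dose_ng), meta))
  } else if (!is.null(sc$n_doses) && sc$n_doses > 1L) {
    do.call(simulate_repeat_oral,
            c(list(model = m, dose_ng = sc$dose_ng, tau_h = sc$tau_h,
                   n_doses = sc$n_doses, times_h = times_h, route = sc$route),
              meta))
  } else {
    do.call(simulate_absorption,
            c(list(model = m, dose_ng = sc$dose_ng, times_h = times_h,
                   route = sc$route), meta))
  }
}
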