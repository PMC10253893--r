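# Non-compartmental analysis and i.v. curve stripping.
#
# All rate constants are per hour internally (profile time base); reporting
# in per-minute (the convention for the mouse i.v. parameters) uses the
# exact factor 1/60.

.quantifiable <- function(profile) {
  keep <- !profile$blq & is.finite(profile$conc)
  list(time = profile$time[keep], conc = profile$conc[keep])
}

#' Maximum observed concentration and its time
#'
#' @param profile A `pk_profile` (censored points are ignored).
#' @return A list with `cmax` (ng/mL), `tmax_h` and `tmax_min`. Ties are
#'   broken by the earliest time.
#' @export
cmax_tmax <- function(profile) {
  q <- .quantifiable(profile)
  if (length(q$conc) < 1L) stop("no quantifiable points", call. = FALSE)
  i <- which.max(q$conc)  # first maximum -> earliest tie
  list(cmax = q$conc[i], tmax_h = q$time[i], tmax_min = q$time[i] * 60)
}

#' Trapezoidal area under the concentration-time curve
#'
#' Piecewise trapezoidal integral over `[t_start, t_end]`. The default
#' `"linuplogdown"` method uses the log-trapezoid
#' `(C1 - C2) * dt / log(C1 / C2)` on strictly decreasing positive segments
#' and the linear trapezoid elsewhere (including any segment touching a
#' zero concentration); `"linear"` uses the linear rule throughout.
#' Endpoints interior to a sampling interval are obtained by linear
#' interpolation.
#'
#' @param profile A `pk_profile`, or a numeric time vector (hours) when
#'   `conc` is given.
#' @param conc Concentrations, when `profile` is a plain time vector.
#' @param t_start,t_end Integration limits in hours (default: full range).
#' @param method `"linuplogdown"` (default) or `"linear"`.
#' @return AUC in h*ng/mL.
#' @export
auc_trapezoid <- function(profile, conc = NULL, t_start = NULL, t_end = NULL,
                          method = c("linuplogdown", "linear")) {
  method <- match.arg(method)
  if (inherits(profile, "pk_profile")) {
    q <- .quantifiable(profile)
    tt <- q$time; cc <- q$conc
  } else {
    tt <- as.numeric(profile); cc <- as.numeric(conc)
  }
  if (is.null(t_start)) t_start <- tt[1L]
  if (is.null(t_end)) t_end <- tt[length(tt)]
  if (t_end <= t_start) stop("t_end must exceed t_start", call. = FALSE)
  if (t_start < tt[1L] || t_end > tt[length(tt)]) {
    stop("integration limits outside the sampled range", call. = FALSE)
  }
  inside <- tt > t_start & tt < t_end
  tt2 <- c(t_start, tt[inside], t_end)
  cc2 <- c(stats::approx(tt, cc, t_start)$y, cc[inside],
           stats::approx(tt, cc, t_end)$y)
  if (length(tt2) < 2L) stop("need >= 2 points in the integration window", call. = FALSE)
  c1 <- cc2[-length(cc2)]; c2 <- cc2[-1L]
  dt <- diff(tt2)
  seg <- (c1 + c2) / 2 * dt
  if (method == "linuplogdown") {
    logok <- c1 > c2 & c2 > 0
    seg[logok] <- (c1[logok] - c2[logok]) * dt[logok] / log(c1[logok] / c2[logok])
  }
  sum(seg)
}

#' Fit the terminal elimination slope
#'
#' Ordinary least squares of `log(C)` on time over a terminal window of the
#' last `n` quantifiable points strictly after tmax. The window is chosen
#' automatically by maximising the adjusted r-squared over
#' `n = n_min .. n_max` (ties go to the larger window, i.e. the longer
#' terminal phase).
#'
#' @param profile A `pk_profile`.
#' @param n_min,n_max Smallest/largest candidate window (defaults 3 and 8).
#' @return A list with `lambda_z` (1/h), `intercept` (ng/mL, the
#'   back-extrapolated concentration at t = 0), `r2_adj`, `n_points`, and
#'   `t_window` (the fitted time range, hours).
#' @export
fit_lambda_z <- function(profile, n_min = 3L, n_max = 8L) {
  q <- .quantifiable(profile)
  imax <- which.max(q$conc)
  tt <- q$time[-seq_len(imax)]
  cc <- q$conc[-seq_len(imax)]
  pos <- cc > 0
  tt <- tt[pos]; cc <- cc[pos]
  if (length(tt) < n_min) {
    stop("need at least ", n_min, " positive post-Cmax points for the terminal fit",
         call. = FALSE)
  }
  best <- NULL
  for (n in seq(n_min, min(n_max, length(tt)))) {
    idx <- seq.int(length(tt) - n + 1L, length(tt))
    x <- tt[idx]; y <- log(cc[idx])
    mx <- mean(x); my <- mean(y)
    sxx <- sum((x - mx)^2)
    slope <- sum((x - mx) * (y - my)) / sxx
    if (slope >= 0) next
    r2 <- sum((x - mx) * (y - my))^2 / (sxx * sum((y - my)^2))
    if (!is.finite(r2)) next
    r2a <- 1 - (1 - r2) * (n - 1) / (n - 2)
    if (is.null(best) || r2a > best$r2_adj + 1e-9 ||
        (abs(r2a - best$r2_adj) <= 1e-9 && n > best$n_points)) {
      best <- list(lambda_z = -slope, intercept = exp(my - slope * mx),
                   r2_adj = r2a, n_points = n, t_window = range(x))
    }
  }
  if (is.null(best)) {
    stop("no-terminal-phase error: no candidate window has a negative slope",
         call. = FALSE)
  }
  best
}

#' Half-life from a first-order rate constant
#'
#' `t1/2 = log(2) / lambda`, in the reciprocal of the rate's unit.
#'
#' @param lambda_z Positive first-order rate constant.
#' @return Half-life.
#' @export
half_life <- function(lambda_z) {
  if (any(!is.finite(lambda_z)) || any(lambda_z <= 0)) {
    stop("domain error: lambda_z must be positive", call. = FALSE)
  }
  log(2) / lambda_z
}

#' Extrapolate AUC to infinity
#'
#' `AUC(0-inf) = AUC(0-t) + C_last / lambda_z`, with the extrapolated
#' fraction of the total reported alongside.
#'
#' @param auc_0_t Observed AUC to the last quantifiable point (h*ng/mL).
#' @param c_last Last quantifiable concentration (ng/mL), > 0.
#' @param lambda_z Terminal rate constant (1/h), > 0.
#' @return A list with `auc_0_inf` and `extrapolated_fraction`.
#' @export
extrapolate_auc <- function(auc_0_t, c_last, lambda_z) {
  if (c_last <= 0 || lambda_z <= 0) {
    stop("c_last and lambda_z must be positive", call. = FALSE)
  }
  tail_area <- c_last / lambda_z
  auc_inf <- auc_0_t + tail_area
  list(auc_0_inf = auc_inf, extrapolated_fraction = tail_area / auc_inf)
}

#' Biexponential stripping of an i.v. bolus profile
#'
#' Method of residuals (feathering): the terminal phase is fitted first by
#' [fit_lambda_z()] giving the elimination macro-constant (`beta`, reported
#' as Ke) and its intercept `B`; the back-extrapolated terminal curve is
#' then subtracted from the points before the terminal window, and the
#' residuals are fitted on the log scale to give the distribution
#' macro-constant (`alpha`, reported as Kd) and its intercept `A`. The
#' residual fit uses the distribution-dominant points — those whose
#' residual exceeds the back-extrapolated terminal component — because the
#' log-residual of a point dominated by the terminal phase amplifies assay
#' noise by the factor `C/residual`; when fewer than two points pass that
#' filter, all positive residuals are used. The back-extrapolated
#' concentration at the moment of injection is `C0 = A + B`. If fewer than
#' two early points have positive residuals (or the residual slope is not
#' steeper than beta) the profile is treated as monoexponential (`A = 0`)
#' with a warning.
#'
#' @param profile An i.v. `pk_profile`.
#' @param n_min,n_max Terminal window bounds passed to [fit_lambda_z()].
#' @return An object of class `biexp_fit`: list with `A`, `alpha`, `B`,
#'   `beta` (rates in 1/h), `c0 = A + B` (ng/mL), `r2_adj` and
#'   `n_terminal` from the terminal fit, and `monoexponential` flag.
#' @export
strip_iv <- function(profile, n_min = 3L, n_max = 8L) {
  term <- fit_lambda_z(profile, n_min = n_min, n_max = n_max)
  beta <- term$lambda_z
  B <- term$intercept
  q <- .quantifiable(profile)
  early <- q$time < term$t_window[1L]
  terminal_part <- B * exp(-beta * q$time[early])
  resid <- q$conc[early] - terminal_part
  keep <- resid > terminal_part          # distribution-dominant points
  # fall back to any residual clearly above numerical noise
  if (sum(keep) < 2L) keep <- resid > 1e-8 * q$conc[early]
  mono <- FALSE
  if (sum(keep) < 2L) {
    warning("fewer than 2 positive early residuals: monoexponential fit (A = 0)",
            call. = FALSE)
    mono <- TRUE
  } else {
    x <- q$time[early][keep]; y <- log(resid[keep])
    mx <- mean(x); my <- mean(y)
    slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
    alpha <- -slope
    A <- exp(my - slope * mx)
    if (!is.finite(alpha) || alpha <= beta) {
      warning("residual phase not steeper than the terminal phase: monoexponential fit (A = 0)",
              call. = FALSE)
      mono <- TRUE
    }
  }
  if (mono) {
    A <- 0; alpha <- NA_real_
  }
  structure(list(A = A, alpha = alpha, B = B, beta = beta, c0 = A + B,
                 r2_adj = term$r2_adj, n_terminal = term$n_points,
                 monoexponential = mono, rate_unit = "1/h"),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf("<biexp_fit> C(t) = %.4g*exp(-%.4g t) + %.4g*exp(-%.4g t)  [t in h]\n",
              x$A, x$alpha, x$B, x$beta))
  cat(sprintf("  C0 = %.4g ng/mL | Kd = %.4g /min | Ke = %.4g /min%s\n",
              x$c0, x$alpha / 60, x$beta / 60,
              if (x$monoexponential) " | monoexponential" else ""))
  invisible(x)
}

#' Volume of distribution and clearance from an i.v. fit
#'
#' Reports both clearance conventions: `cl_vk = Vd * Ke` and
#' `cl_auc = Dose / AUC(0-inf)`, together with the two textbook volume
#' estimates `vd_c0 = Dose / C0` and `vd_area = Dose / (AUC * Ke)`. When an
#' externally determined `vd_l` is supplied it is used for the `Vd * Ke`
#' convention; otherwise `vd_area` is used (which makes the two clearance
#' conventions coincide).
#'
#' @param fit A `biexp_fit`.
#' @param dose_ng Administered dose in ng.
#' @param auc_0_inf AUC extrapolated to infinity, h*ng/mL.
#' @param vd_l Optional externally determined volume of distribution (L).
#' @return List with `vd_c0_ml`, `vd_area_ml`, `cl_vk_ml_min`,
#'   `cl_auc_ml_min`, `ke_per_min`.
#' @export
iv_derived_params <- function(fit, dose_ng, auc_0_inf, vd_l = NULL) {
  stopifnot(inherits(fit, "biexp_fit"))
  if (dose_ng <= 0) stop("dose must be positive", call. = FALSE)
  if (auc_0_inf <= 0) stop("domain error: AUC must be positive", call. = FALSE)
  ke_min <- fit$beta / 60
  auc_min <- auc_0_inf * 60              # min*ng/mL
  vd_c0 <- dose_ng / fit$c0              # mL
  vd_area <- dose_ng / (auc_min * ke_min)
  vd_used <- if (is.null(vd_l)) vd_area else vd_l * 1000
  list(vd_c0_ml = vd_c0, vd_area_ml = vd_area,
       cl_vk_ml_min = vd_used * ke_min,
       cl_auc_ml_min = dose_ng / auc_min,
       ke_per_min = ke_min)
}

#' Steady-state exposure over one dosing interval
#'
#' AUC over the final interval of length `tau` in the profile and the
#' average steady-state concentration `Cav = AUC(0-tau) / tau`.
#'
#' @param profile A `pk_profile` sampled at steady state, spanning >= `tau`.
#' @param tau Dosing interval, hours.
#' @param method Trapezoid method, see [auc_trapezoid()].
#' @return List with `auc_0_tau` (h*ng/mL) and `cav` (ng/mL).
#' @export
steady_state_metrics <- function(profile, tau, method = c("linuplogdown", "linear")) {
  method <- match.arg(method)
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  q <- .quantifiable(profile)
  span <- q$time[length(q$time)] - q$time[1L]
  if (span < tau - 1e-9) {
    stop("profile spans ", signif(span, 4), " h, less than tau = ", tau, " h",
         call. = FALSE)
  }
  t_end <- q$time[length(q$time)]
  auc <- auc_trapezoid(q$time, q$conc, t_start = t_end - tau, t_end = t_end,
                       method = method)
  list(auc_0_tau = auc, cav = auc / tau)
}

#' Relative bioavailability from dose-normalised AUCs
#'
#' `F = (AUC_test / Dose_test) / (AUC_ref / Dose_ref)`.
#'
#' @param auc_test,dose_test AUC and dose of the test route.
#' @param auc_ref,dose_ref AUC and dose of the reference route (usually i.v.).
#' @return The bioavailable fraction.
#' @export
bioavailability <- function(auc_test, dose_test, auc_ref, dose_ref) {
  if (any(c(auc_test, dose_test, auc_ref, dose_ref) <= 0)) {
    stop("all inputs must be positive", call. = FALSE)
  }
  (auc_test / dose_test) / (auc_ref / dose_ref)
}

#' Accumulation ratio under repeated dosing
#'
#' Ratio of the steady-state interval AUC to the single-dose AUC, with a
#' flag for the clinically relevant "less than twofold" threshold.
#'
#' @param auc_tau_ss Steady-state AUC over one dosing interval.
#' @param auc_single Single-dose AUC (same units).
#' @return List with `ratio` and `less_than_twofold`.
#' @export
accumulation_ratio <- function(auc_tau_ss, auc_single) {
  if (auc_tau_ss <= 0 || auc_single <= 0) stop("inputs must be positive", call. = FALSE)
  r <- auc_tau_ss / auc_single
  list(ratio = r, less_than_twofold = r < 2)
}

#' Full non-compartmental analysis of one profile
#'
#' Orchestrates the censoring rule, Cmax/tmax, trapezoidal AUC to the last
#' quantifiable point, terminal-slope fit, extrapolation to infinity and,
#' for i.v. profiles, biexponential stripping with derived volume and
#' clearance; for steady-state profiles (when `tau` is given), the interval
#' AUC and Cav.
#'
#' @param profile A `pk_profile`.
#' @param tau Optional dosing interval (h) for steady-state metrics.
#' @param censor_rule Passed to [censor_blq()].
#' @param method Trapezoid method, see [auc_trapezoid()].
#' @param n_min,n_max Terminal window bounds, see [fit_lambda_z()].
#' @param vd_l Optional external volume of distribution (L) for the
#'   `Vd * Ke` clearance convention (i.v. only).
#' @return A one-row data.frame with the NCA parameter set: `id`, `species`,
#'   `route`, `dose_ng`, `cmax`, `tmax_min`, `auc_0_t`, `auc_0_inf`,
#'   `extrapolated_fraction`, `lambda_z_per_h`, `t_half_h`, `n_lambda_points`,
#'   `r2_adj`, `c0`, `kd_per_min`, `ke_per_min`, `vd_ml`, `cl_ml_min`,
#'   `auc_0_tau`, `cav` (entries that do not apply are `NA`).
#' @export
run_nca <- function(profile, tau = NULL, censor_rule = "zero-drop",
                    method = "linuplogdown", n_min = 3L, n_max = 8L,
                    vd_l = NULL) {
  stopifnot(inherits(profile, "pk_profile"))
  p <- censor_blq(profile, rule = censor_rule)
  pk <- cmax_tmax(p)
  out <- data.frame(id = p$subject_id, species = p$species, route = p$route,
                    dose_ng = p$dose_ng, cmax = pk$cmax, tmax_min = pk$tmax_min,
                    auc_0_t = NA_real_, auc_0_inf = NA_real_,
                    extrapolated_fraction = NA_real_,
                    lambda_z_per_h = NA_real_, t_half_h = NA_real_,
                    n_lambda_points = NA_integer_, r2_adj = NA_real_,
                    c0 = NA_real_, kd_per_min = NA_real_, ke_per_min = NA_real_,
                    vd_ml = NA_real_, cl_ml_min = NA_real_,
                    auc_0_tau = NA_real_, cav = NA_real_,
                    stringsAsFactors = FALSE)
  q <- .quantifiable(p)
  if (length(q$time) >= 2L) {
    out$auc_0_t <- auc_trapezoid(p, method = method)
  }
  lam <- tryCatch(fit_lambda_z(p, n_min = n_min, n_max = n_max),
                  error = function(e) NULL)
  if (!is.null(lam)) {
    out$lambda_z_per_h <- lam$lambda_z
    out$t_half_h <- half_life(lam$lambda_z)
    out$n_lambda_points <- lam$n_points
    out$r2_adj <- lam$r2_adj
    c_last <- q$conc[length(q$conc)]
    if (is.finite(out$auc_0_t) && c_last > 0) {
      ext <- extrapolate_auc(out$auc_0_t, c_last, lam$lambda_z)
      out$auc_0_inf <- ext$auc_0_inf
      out$extrapolated_fraction <- ext$extrapolated_fraction
    }
  }
  if (p$route == "iv" && !is.null(lam)) {
    fit <- strip_iv(p, n_min = n_min, n_max = n_max)
    out$c0 <- fit$c0
    out$kd_per_min <- fit$alpha / 60
    out$ke_per_min <- fit$beta / 60
    if (is.finite(out$auc_0_inf)) {
      dp <- iv_derived_params(fit, p$dose_ng, out$auc_0_inf, vd_l = vd_l)
      out$vd_ml <- if (is.null(vd_l)) dp$vd_area_ml else vd_l * 1000
      out$cl_ml_min <- dp$cl_vk_ml_min
    }
  }
  if (!is.null(tau)) {
    ss <- steady_state_metrics(p, tau, method = method)
    out$auc_0_tau <- ss$auc_0_tau
    out$cav <- ss$cav
  }
  out
}
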