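# non-compartmental estimation: Cmax/tmax, AUC, terminal slope, stripping,
# derived parameters, steady state, bioavailability

test_that("cmax_tmax finds the maximum with earliest-time tie-breaking", {
  dec <- make_profile(c(0.1, 0.5, 1), c(100, 50, 25))
  expect_equal(cmax_tmax(dec)$cmax, 100)   # strictly decreasing: first sample
  expect_equal(cmax_tmax(dec)$tmax_min, 6)
  tie <- make_profile(c(0.25, 1, 2), c(80, 80, 10), route = "sc")
  expect_equal(cmax_tmax(tie)$tmax_min, 15)
  allb <- make_profile(c(1, 2), c(NA, NA), blq = c(TRUE, TRUE))
  expect_error(cmax_tmax(allb), "quantifiable")
})

test_that("auc_trapezoid matches closed forms and method inequalities", {
  # rectangle: constant 3.20 ng/mL over 24 h
  expect_equal(auc_trapezoid(c(0, 24), c(3.20, 3.20)), 76.8)
  # dense monoexponential vs analytic integral
  tt <- seq(0, 10, by = 0.01)
  cc <- 100 * exp(-0.5 * tt)
  truth <- 100 / 0.5 * (1 - exp(-5))
  expect_lt(abs(auc_trapezoid(tt, cc, method = "linear") - truth) / truth, 0.001)
  expect_lt(abs(auc_trapezoid(tt, cc) - truth) / truth, 1e-6)  # log-down exact
  # linear >= log-down on a convex decaying segment
  seg_t <- c(0, 1); seg_c <- c(100, 10)
  expect_gte(auc_trapezoid(seg_t, seg_c, method = "linear"),
             auc_trapezoid(seg_t, seg_c, method = "linuplogdown"))
  # zero concentration falls back to the linear rule instead of failing
  expect_equal(auc_trapezoid(c(0, 1), c(10, 0)), 5)
  expect_error(auc_trapezoid(c(0, 1), c(1, 2), t_start = 0.5, t_end = 0.5),
               "t_end")
})

test_that("fit_lambda_z recovers a noiseless monoexponential exactly", {
  p <- mono_profile(c0 = 100, ke = 0.5)
  fit <- fit_lambda_z(p)
  expect_equal(fit$lambda_z, 0.5, tolerance = 1e-10)
  expect_equal(fit$intercept, 100, tolerance = 1e-8)
  expect_equal(fit$r2_adj, 1, tolerance = 1e-12)
})

test_that("fit_lambda_z isolates beta from a biexponential tail", {
  tmin <- c(1, 5, 10, 15, 30, 45, 60, 120, 180, 360, 1440)
  cc <- 281.7 * exp(-0.12 * tmin) + 12.68 * exp(-0.0058 * tmin)
  p <- make_profile(tmin / 60, cc)
  fit <- fit_lambda_z(p)
  expect_equal(fit$lambda_z / 60, 0.0058, tolerance = 1e-4)
  # constant profile has no terminal phase
  flat <- make_profile(1:5, rep(3, 5))
  expect_error(fit_lambda_z(flat), "no-terminal-phase")
  # too few post-Cmax points
  short <- make_profile(c(1, 2, 3), c(10, 8, 5))
  expect_error(fit_lambda_z(short), "at least 3")
})

test_that("half_life converts rates in the rate's own unit", {
  expect_equal(half_life(log(2)), 1)                       # 1/h -> 1 h
  expect_equal(half_life(0.0058) , log(2) / 0.0058)        # stays per-min
  expect_lt(abs(half_life(0.0058) - 119.43) / 119.43, 0.001)
  expect_error(half_life(0), "domain")
  expect_error(half_life(-1), "domain")
})

test_that("extrapolate_auc adds the exact exponential tail", {
  # pure monoexponential from t = 0: AUC = C0/Ke
  ext <- extrapolate_auc(0, c_last = 294.4, lambda_z = 0.348)
  expect_equal(ext$auc_0_inf, 294.4 / 0.348)
  expect_equal(ext$extrapolated_fraction, 1)
  # c_last -> 0 leaves AUC unchanged in the limit
  expect_equal(extrapolate_auc(50, 1e-12, 0.3)$auc_0_inf, 50, tolerance = 1e-10)
  # dense-sampled biexponential approaches A/alpha + B/beta
  tt <- seq(0, 48, by = 0.002)
  cc <- 281.7 * exp(-7.2 * tt) + 12.68 * exp(-0.348 * tt)
  p <- make_profile(tt[-1], cc[-1])  # drop t=0 to keep times positive-increasing from 0.002
  auc_t <- auc_trapezoid(p)
  fit <- fit_lambda_z(p)
  ext2 <- extrapolate_auc(auc_t, cc[length(cc)], fit$lambda_z)
  analytic <- 281.7 / 7.2 + 12.68 / 0.348
  # missing sliver before the first sample accounts for the tolerance
  expect_equal(ext2$auc_0_inf, analytic, tolerance = 0.01)
  expect_error(extrapolate_auc(10, 0, 0.3), "positive")
})

test_that("strip_iv recovers biexponential macro-parameters from noiseless data", {
  tmin <- c(1, 5, 10, 15, 30, 45, 60, 120, 180, 360, 1440)
  cc <- 250 * exp(-0.12 * tmin) + 44.4 * exp(-0.0058 * tmin)
  p <- make_profile(tmin / 60, cc)
  fit <- strip_iv(p)
  expect_equal(fit$A, 250, tolerance = 1e-4)
  expect_equal(fit$alpha / 60, 0.12, tolerance = 1e-4)
  expect_equal(fit$B, 44.4, tolerance = 1e-4)
  expect_equal(fit$beta / 60, 0.0058, tolerance = 1e-4)
  expect_equal(fit$c0, 294.4, tolerance = 1e-4)
})

test_that("strip_iv degrades to a monoexponential fit when there is no fast phase", {
  p <- mono_profile(c0 = 100, ke = 0.5, times = seq(0.1, 12, by = 0.4))
  expect_warning(fit <- strip_iv(p), "monoexponential")
  expect_equal(fit$A, 0)
  expect_true(fit$monoexponential)
  expect_equal(fit$c0, fit$B)
  expect_equal(fit$c0, 100, tolerance = 1e-6)
})

test_that("iv_derived_params reports both clearance conventions", {
  fit <- structure(list(A = 281.7, alpha = 7.2, B = 12.7, beta = 0.348,
                        c0 = 294.4, monoexponential = FALSE),
                   class = "biexp_fit")
  dp <- iv_derived_params(fit, dose_ng = 7500, auc_0_inf = 75.57, vd_l = 1.80)
  expect_equal(dp$cl_vk_ml_min, 1800 * 0.0058, tolerance = 1e-6)     # 10.44
  expect_equal(dp$cl_auc_ml_min, 7500 / (75.57 * 60), tolerance = 1e-9) # 1.65
  expect_equal(dp$vd_c0_ml, 7500 / 294.4)
  # without an external Vd the two conventions coincide
  dp2 <- iv_derived_params(fit, 7500, 75.57)
  expect_equal(dp2$cl_vk_ml_min, dp2$cl_auc_ml_min)
  expect_error(iv_derived_params(fit, 7500, 0), "domain")
})

test_that("steady_state_metrics satisfies cav * tau = auc exactly", {
  tt <- seq(0, 48, by = 0.25)
  p <- make_profile(tt[-1], 3 + sin(tt[-1]), route = "minipump")
  ss <- steady_state_metrics(p, tau = 24)
  expect_equal(ss$cav * 24, ss$auc_0_tau)
  # constant profile: cav equals the constant
  cst <- make_profile(c(0.5, 10, 24.5), rep(6.49, 3), route = "minipump")
  expect_equal(steady_state_metrics(cst, 24)$cav, 6.49)
  expect_error(steady_state_metrics(cst, 100), "less than tau")
})

test_that("bioavailability and accumulation ratios follow the printed AUCs", {
  expect_equal(bioavailability(30.20, 7500, 97.42, 7500), 0.31, tolerance = 0.003)
  expect_equal(bioavailability(97.42, 7500, 75.57, 7500), 1.29, tolerance = 0.003)
  expect_equal(bioavailability(10, 5, 10, 5), 1.0)
  acc <- accumulation_ratio(76.79, 90.09)
  expect_equal(acc$ratio, 0.85, tolerance = 0.003)
  expect_true(acc$less_than_twofold)
  expect_equal(accumulation_ratio(10, 10)$ratio, 1)
  expect_false(accumulation_ratio(25, 10)$less_than_twofold)
})

test_that("run_nca assembles a complete i.v. parameter row", {
  p <- scenario_truth("mouse_iv")
  res <- run_nca(p, vd_l = 1.80)
  expect_equal(res$cmax, cmax_tmax(p)$cmax)
  expect_equal(res$ke_per_min, 0.0058, tolerance = 1e-4)
  expect_equal(res$kd_per_min, 0.12, tolerance = 1e-4)
  expect_equal(res$c0, 294.40, tolerance = 1e-4)
  expect_equal(res$cl_ml_min, 10.44, tolerance = 1e-3)
  expect_gte(res$auc_0_inf, res$auc_0_t)
  expect_true(res$extrapolated_fraction >= 0 && res$extrapolated_fraction < 1)
  expect_equal(res$t_half_h * 60, log(2) / res$ke_per_min)
})
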