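# closed-form simulators, calibration, noise and the study scenarios

test_that("simulate_iv evaluates the biexponential exactly", {
  m <- route_model("iv_biexp", A = 250, B = 44.4, alpha = 0.12, beta = 0.0058)
  p <- simulate_iv(m, times_h = c(1e-12, 1, 2))
  expect_equal(p$conc[1L], 294.4, tolerance = 1e-9)   # C(0) = A + B
  expect_equal(p$conc[2L], 250 * exp(-0.12 * 60) + 44.4 * exp(-0.0058 * 60))
  expect_error(route_model("iv_biexp", A = 1, B = 1, alpha = 0.005, beta = 0.12),
               "alpha > beta")
})

test_that("calibrate_iv solves the reported-parameter constraints", {
  m <- calibrate_iv(c0 = 294.40, kd = 0.12, ke = 0.0058, auc_0_inf = 75.57)
  expect_equal(m$A + m$B, 294.40)
  expect_equal(m$A / m$alpha + m$B / m$beta, 75.57 * 60)  # min*ng/mL
  expect_error(calibrate_iv(294.4, 0.0058, 0.0058, 75.57), "singular")
  # AUC = C0/Ke is the monoexponential limit: A = 0
  m2 <- calibrate_iv(100, 0.12, 0.01, 100 / 0.01 / 60)
  expect_equal(m2$A, 0)
  expect_equal(m2$B, 100)
  # infeasible AUC below C0/Kd
  expect_error(calibrate_iv(294.4, 0.12, 0.0058, 1), "infeasible")
})

test_that("single-depot absorption peaks at the Bateman tmax", {
  ka <- 12; ke <- 2.4
  m <- route_model("first_order", depots = data.frame(fraction = 1, ka = ka, lag = 0),
                   v_ml = 50, ke = ke)
  tmax_true <- log(ka / ke) / (ka - ke)
  tt <- seq(0.001, 2, by = 0.0005)
  p <- simulate_absorption(m, 7500, tt)
  expect_equal(p$time[which.max(p$conc)], tmax_true, tolerance = 1e-3)
  # ka -> ke limiting form stays finite and continuous
  m_eq <- route_model("first_order", depots = data.frame(fraction = 1, ka = 2.4, lag = 0),
                      v_ml = 50, ke = 2.4)
  p_eq <- simulate_absorption(m_eq, 7500, tt)
  expect_true(all(is.finite(p_eq$conc)))
  expect_equal(max(p_eq$conc), 7500 / 50 * exp(-1), tolerance = 1e-4)  # peak of ka*t*e^{-ka t} at t = 1/ka
})

test_that("all simulators are homogeneous of degree 1 in dose", {
  tt <- c(0.1, 0.5, 1, 3, 6)
  m_abs <- pk_scenario("mouse_sc")$model
  p1 <- simulate_absorption(m_abs, 7500, tt)
  p3 <- simulate_absorption(m_abs, 3 * 7500, tt)
  expect_equal(p3$conc, 3 * p1$conc)
  sc <- pk_scenario("minipump_0.3")
  m1 <- sc$model
  m3 <- route_model("zero_order_infusion", r0_ng_day = 3 * m1$r0_ng_day,
                    cl_ml_min = m1$cl_ml_min, ke = m1$ke)
  i1 <- simulate_infusion(m1, 840, tt)
  i3 <- simulate_infusion(m3, 840, tt)
  expect_equal(i3$conc, 3 * i1$conc)
})

test_that("repeated dosing equals brute-force superposition of shifted curves", {
  sc <- pk_scenario("human_multi_15mg")
  tt <- seq(0.5, 7 * 24, by = 1.5)
  p <- simulate_repeat_oral(sc$model, sc$dose_ng, tau_h = 24, n_doses = 7L,
                            times_h = tt)
  # oracle: explicit sum of single-dose curves evaluated at shifted times
  oracle <- numeric(length(tt))
  for (d in 0:6) {
    shifted <- tt - d * 24
    ok <- shifted > 0
    single <- simulate_absorption(sc$model, sc$dose_ng, shifted[ok], route = "oral")
    oracle[ok] <- oracle[ok] + single$conc
  }
  expect_equal(p$conc, oracle, tolerance = 1e-12)
  # n = 1 is the single-dose curve
  p1 <- simulate_repeat_oral(sc$model, sc$dose_ng, 24, 1L, tt)
  s1 <- simulate_absorption(sc$model, sc$dose_ng, tt, route = "oral")
  expect_equal(p1$conc, s1$conc)
})

test_that("steady-state accumulation follows the geometric series", {
  ke <- log(2) / 24.69
  # accumulation ratio at steady state = 1/(1 - e^{-ke tau})
  r_inf <- 1 / (1 - exp(-ke * 24))
  sc <- pk_scenario("human_multi_15mg")
  tt <- seq(0.25, 60 * 24, by = 0.25)
  p_many <- simulate_repeat_oral(sc$model, sc$dose_ng, 24, 60L, tt)
  trough_late <- p_many$conc[tt == 60 * 24 - 0.25]
  p_one <- simulate_absorption(sc$model, sc$dose_ng, tt, route = "oral")
  # trough after many doses approaches r_inf times the single-dose value
  expect_equal(trough_late / p_one$conc[tt == 24 - 0.25], r_inf, tolerance = 0.01)
  expect_equal(steady_state_fraction(ke, 6, 24), 1 - exp(-ke * 144))
  expect_gte(steady_state_fraction(ke, 6, 24), 0.95)
})

test_that("infusion is monotone nondecreasing and plateaus at R0/CL", {
  sc <- pk_scenario("minipump_0.3")
  m <- sc$model
  css <- m$r0_ng_day / (m$cl_ml_min * 60 * 24)
  tt <- seq(0.1, 840, by = 0.5)
  p <- simulate_infusion(m, 840, tt)
  expect_true(all(diff(p$conc) >= -1e-12))
  expect_equal(p$conc[length(tt)], css, tolerance = 1e-9)
  # half the plateau after one half-life of onset
  t_half <- log(2) / m$ke
  p_h <- simulate_infusion(m, 840, t_half)
  expect_equal(p_h$conc, css / 2, tolerance = 1e-9)
})

test_that("add_noise is deterministic under seed and censors after noise", {
  truth <- scenario_truth("mouse_iv")
  r0 <- add_noise(truth, sigma_ln = 0, n_replicates = 2, seed = 5)
  # zero noise reproduces the truth wherever it is quantifiable; the 24 h
  # point is genuinely below the LLOQ and so is censored even without noise
  expect_equal(r0[[1L]]$conc[!r0[[1L]]$blq], truth$conc[truth$conc >= truth$lloq])
  expect_identical(r0[[1L]]$blq, truth$conc < truth$lloq)
  a <- add_noise(truth, sigma_ln = 0.1, n_replicates = 2, seed = 5)
  b <- add_noise(truth, sigma_ln = 0.1, n_replicates = 2, seed = 5)
  expect_identical(a[[1L]]$conc, b[[1L]]$conc)
  expect_identical(a[[2L]]$conc, b[[2L]]$conc)
  # the 24 h point (true value ~0.003 ng/mL) falls below the 0.05 LLOQ
  expect_true(a[[1L]]$blq[length(truth$time)])
  # caller RNG state untouched
  set.seed(99); x1 <- rnorm(1)
  set.seed(99); invisible(add_noise(truth, 0.1, seed = 3)); x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("log-normal noise reproduces the assay-level CV", {
  truth <- make_profile(1 / 6, 90.92, route = "sc")
  reps <- add_noise(truth, sigma_ln = 0.23, n_replicates = 4000, seed = 8)
  vals <- vapply(reps, `[[`, numeric(1), "conc")
  cv <- sd(vals) / mean(vals)
  expect_equal(cv, sqrt(exp(0.23^2) - 1), tolerance = 0.05)  # ~23%
})

test_that("scenarios carry the study sampling grids and calibration anchors", {
  iv <- pk_scenario("mouse_iv")
  expect_length(iv$times_h, 11L)          # 1-45 min and 1-24 h
  expect_equal(iv$times_h[1:6] * 60, c(1, 5, 10, 15, 30, 45))
  hs <- pk_scenario("human_single_15mg")
  expect_equal(max(hs$times_h), 168)
  pump <- pk_scenario("minipump_0.3")
  expect_equal(pump$times_h, c(24, 168, 504, 840))
  expect_error(pk_scenario("rat_iv"), "unknown scenario")
  # iv model solves the four reported constraints
  expect_equal(iv$model$A + iv$model$B, 294.40)
  # simulate_scenario produces subjects x replicates profiles
  profs <- simulate_scenario("mouse_iv", n_subjects = 3, seed = 2)
  expect_length(profs, 6L)
  expect_equal(profs[[1L]]$replicate, 1L)
  expect_equal(profs[[2L]]$replicate, 2L)
})

test_that("noiseless NCA on dense simulated profiles recovers generating values", {
  sc <- pk_scenario("mouse_sc")
  tt <- seq(0.002, 24, by = 0.002)
  p <- scenario_truth(sc, tt)
  res <- run_nca(p)
  expect_equal(res$lambda_z_per_h, sc$model$ke, tolerance = 5e-3)
  auc_true <- sc$dose_ng / (sc$model$v_ml * sc$model$ke)
  expect_equal(res$auc_0_inf, auc_true, tolerance = 5e-3)
  expect_equal(res$tmax_min, 10, tolerance = 0.2)
})
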