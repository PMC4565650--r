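# Clamp, cascade and oral-challenge protocol simulation.

test_that("TG polynomial interpolation recovers exact generating polynomials", {
  # degree-0: constant data reproduced exactly
  const <- data.frame(t = seq(0, 360, 60), v = rep(1234, 7))
  f0 <- fit_tg_polynomial(const, degree = 0)
  expect_equal(f0(c(0, 100, 360)), rep(1234, 3))

  # cubic data, degree 3: near machine-precision recovery
  tt <- seq(0, 360, by = 30)
  cubic <- 1000 + 2 * tt - 0.02 * tt^2 + 4e-5 * tt^3
  f3 <- fit_tg_polynomial(data.frame(t = tt, v = cubic), degree = 3)
  expect_equal(f3(tt), cubic, tolerance = 1e-9)

  # clamped extrapolation at both boundaries
  expect_equal(f3(-50), f3(0))
  expect_equal(f3(500), f3(360))

  expect_error(fit_tg_polynomial(data.frame(t = c(0, 0, 10),
                                            v = c(1, 2, 3)), 1),
               "repeated times")
  expect_error(fit_tg_polynomial(data.frame(t = c(0, 10), v = c(1, 2)), 3),
               "degree \\+ 1")
})

test_that("window averaging matches direct quadrature", {
  # constant integrand: average is the constant, exactly
  t <- seq(0, 120, by = 1)
  expect_equal(window_average(t, rep(3.5, length(t)), c(60, 120)), 3.5)

  # linear integrand a + b t: closed-form mean over the window
  a <- 0.4; b <- 0.01
  y <- a + b * t
  expect_equal(window_average(t, y, c(60, 120)), a + b * 90,
               tolerance = 1e-12)

  # off-grid window endpoints are closed by interpolation
  expect_equal(window_average(t, y, c(60.5, 119.5)), a + b * 90,
               tolerance = 1e-10)

  expect_error(window_average(t, y, c(60, 200)), "not covered")
})

test_that("clamp averages commute with grid refinement and match flux quadrature", {
  p <- default_p
  protos <- c(clamp1_design(p)[2], clamp2_design(p)[c(1, 6)])
  for (proto in protos) {
    r1 <- simulate_clamp(proto, p, dt = 1)
    r2 <- simulate_clamp(proto, p, dt = 0.5)
    expect_lt(abs(r1$EGP_avg - r2$EGP_avg) / max(r2$EGP_avg, 0.01), 1e-4)
    expect_lt(abs(r1$GU_avg - r2$GU_avg) / r2$GU_avg, 1e-4)

    # independent quadrature of the recorded instantaneous fluxes
    w <- proto$measurement_window
    keep <- r1$sim$time >= w[1] & r1$sim$time <= w[2]
    tt <- r1$sim$time[keep]
    manual <- function(y) sum(diff(tt) * (y[-1] + y[-length(y)]) / 2) /
      (w[2] - w[1])
    gu <- r1$sim$fluxes$U_ii[keep] + r1$sim$fluxes$U_id[keep]
    expect_equal(r1$GU_avg, manual(gu), tolerance = 1e-10)
    expect_equal(r1$EGP_avg, manual(r1$sim$fluxes$EGP[keep]),
                 tolerance = 1e-8)
  }
})

test_that("missing clamp targets raise a protocol error", {
  proto <- protocol(kind = "clamp", clamped = list(glucose = 85),
                    t_end = 120)
  expect_error(simulate_clamp(proto, default_p), "clamp values required")
})

test_that("raising the NEFA plateau under hyperinsulinemia raises EGP and lowers GU", {
  p <- default_p
  res <- lapply(clamp1_design(p), simulate_clamp, params = p)
  egp <- vapply(res, `[[`, numeric(1), "EGP_avg")
  gu <- vapply(res, `[[`, numeric(1), "GU_avg")
  # designs are ordered high / mid / low NEFA
  expect_true(egp[["clamp1_high"]] > egp[["clamp1_mid"]])
  expect_true(egp[["clamp1_mid"]] > egp[["clamp1_low"]])
  expect_true(gu[["clamp1_high"]] < gu[["clamp1_mid"]])
  expect_true(gu[["clamp1_mid"]] < gu[["clamp1_low"]])
})

test_that("glucose effectiveness is preserved: hyperglycemia raises uptake at basal insulin", {
  p <- default_p
  base <- list(insulin = p$basal[["Ib"]], NEFA = p$basal[["NEFA0"]])
  eu <- protocol(kind = "clamp",
                 clamped = c(list(glucose = p$basal[["Gb"]]), base),
                 t_end = 120)
  hyper <- protocol(kind = "clamp",
                    clamped = c(list(glucose = 250), base), t_end = 120)
  expect_gt(simulate_clamp(hyper, p)$GU_avg, simulate_clamp(eu, p)$GU_avg)
})

test_that("a one-step cascade is equivalent to the steady clamp machinery", {
  p <- default_p
  casc <- cascade_protocol(insulin_steps = 300, glucose = 90,
                           step_min = 120, tg = 1000, nefa0 = 450)
  r_casc <- simulate_insulin_cascade(casc, p)
  # feed the cascade's simulated NEFA back as a clamp: with identical
  # glucose/insulin/NEFA signals, the clamp protocol must reproduce the
  # cascade's glucose fluxes and delay-chain states
  nefa_traj <- data.frame(t = r_casc$sim$time,
                          value = r_casc$sim$states$NEFA)
  clamp <- protocol(kind = "clamp",
                    clamped = list(glucose = 90, insulin = 300,
                                   NEFA = nefa_traj),
                    tg = 1000, t_end = 120, nefa0 = 450)
  r_clamp <- simulate_clamp(clamp, p)
  # the clamp sees the piecewise-linear 1-min resampling of the cascade's
  # NEFA curve, so agreement is limited by that interpolation error
  expect_equal(r_clamp$sim$states$Gt, r_casc$sim$states$Gt,
               tolerance = 2e-3)
  expect_equal(r_clamp$sim$states$Nd1, r_casc$sim$states$Nd1,
               tolerance = 2e-3)
  expect_equal(r_clamp$sim$fluxes$EGP, r_casc$sim$fluxes$EGP,
               tolerance = 5e-3)
  expect_equal(r_casc$step_table$NEFA_end[1],
               r_casc$sim$states$NEFA[121], tolerance = 1e-9)
})

test_that("stepwise insulin increases produce monotone end-of-step NEFA decline", {
  cs <- simulate_insulin_cascade(campbell_cascade_design(), default_p)
  ends <- cs$step_table$NEFA_end
  expect_length(ends, 5)              # supra-physiological step excluded
  expect_true(all(diff(ends) < 0))
  expect_true(all(ends > 0))
})

test_that("a null cascade at basal insulin reduces to the fasting drift", {
  p <- default_p
  casc <- cascade_protocol(insulin_steps = p$basal[["Ib"]],
                           glucose = p$basal[["Gb"]], step_min = 120,
                           tg = p$basal[["TGb"]],
                           nefa0 = p$basal[["NEFA0"]])
  r <- simulate_insulin_cascade(casc, p)
  free_run <- simulate_model(p, model_inputs(), seq(0, 120, by = 1))
  # clamping at basal only suppresses the small feedback of the NEFA
  # drift onto glucose and insulin, so the drifts agree closely
  expect_equal(r$sim$states$NEFA, free_run$states$NEFA, tolerance = 5e-3)
})

test_that("a zero-dose oral challenge at basal TG stays at the basal trajectory", {
  proto <- protocol(kind = "oral_challenge", glucose_dose_g = 0,
                    t_end = 360)
  sim <- simulate_oral_challenge(proto, decoupled_p)
  conc <- plasma_concentrations(sim)
  expect_equal(conc$glucose, rep(decoupled_p$basal[["Gb"]], 361),
               tolerance = 1e-6)
  expect_equal(conc$insulin, rep(decoupled_p$basal[["Ib"]], 361),
               tolerance = 1e-6)
})

test_that("a too-short TG trajectory is rejected", {
  proto <- protocol(kind = "oral_challenge", glucose_dose_g = 100,
                    tg = data.frame(t = c(0, 100), v = c(1100, 1200)),
                    t_end = 360)
  expect_error(simulate_oral_challenge(proto, default_p), "shorter")
})

test_that("protocols survive a JSON round trip", {
  p <- default_p
  proto <- clamp2_design(p)[["clamp2_C_lip"]]
  path <- tempfile(fileext = ".json")
  write_protocol(proto, path)
  back <- read_protocol(path)
  expect_equal(back$kind, proto$kind)
  expect_equal(back$measurement_window, proto$measurement_window)
  expect_equal(back$clamped$NEFA$value, proto$clamped$NEFA$value)
  r1 <- simulate_clamp(proto, p)
  r2 <- simulate_clamp(back, p)
  expect_equal(r1$EGP_avg, r2$EGP_avg, tolerance = 1e-10)
})
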