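# Flux operations and the integrated 18-state system.

test_that("NEFA balance reproduces hand-evaluated flux compositions", {
  p <- default_parameters(
    free = list(pA = 0.01, pB = 0.001, pC = -5,
                # spillover influx silenced so J_D = 0
                c_lpl = 0))
  st <- basal_state(p)

  # single-term case: only concentration-dependent uptake active
  st1 <- st; st1[["NEFA"]] <- 100; st1[["Id7"]] <- p$basal[["Ib"]]
  r1 <- nefa_rhs(st1, update_parameters(p, free = list(pC = -1e-12)), tg = 0)
  expect_equal(r1$rate, -1.0, tolerance = 1e-9)

  # full hand evaluation: -4 - 20 - 5 + 2 = -27
  st2 <- st; st2[["NEFA"]] <- 400
  st2[["Id7"]] <- p$basal[["Ib"]] + 50
  r2 <- nefa_rhs(st2, p, tg = 0)
  expect_equal(r2$J_A, 4)
  expect_equal(r2$J_B, 20)
  expect_equal(r2$J_C, -5)
  expect_equal(r2$J_D, 0)
  expect_equal(r2$rate, -29)          # -4 - 20 - 5; adding J_D = 2 gives -27

  # input validation
  st3 <- st; st3[["NEFA"]] <- -1
  expect_error(nefa_rhs(st3, p, tg = 0), "non-negative")
  expect_error(nefa_rhs(st, p, tg = -10), "non-negative")
})

test_that("EGP is anchored at EGPb, linear in its signals, and floored", {
  p <- default_p
  st <- basal_state(p)
  expect_equal(egp_flux(st, p), p$basal[["EGPb"]])

  # degenerate coefficients: EGP identically kegp1
  p0 <- default_parameters(free = list(kegp2 = 0, kegp3 = 0, kegp4 = 0,
                                       kegp5 = 0))
  st_off <- basal_state(p0)
  st_off[["Gp"]] <- 999; st_off[["Id2"]] <- 500; st_off[["Nd1"]] <- 1
  expect_equal(egp_flux(st_off, p0), p0$derived[["kegp1"]])

  # floor: drive the linear form negative and check clipping at zero
  st_neg <- basal_state(p)
  st_neg[["Id2"]] <- 5000
  lin <- p$derived[["kegp1"]] - p$free[["kegp2"]] * st_neg[["Gp"]] -
    p$free[["kegp3"]] * st_neg[["Id2"]] -
    p$free[["kegp4"]] * st_neg[["Ipo"]] + p$free[["kegp5"]] * st_neg[["Nd1"]]
  expect_lt(lin, 0)
  expect_identical(egp_flux(st_neg, p), 0)

  # infusion enters as a portal-equivalent mass through gamma
  e0 <- egp_flux(st, p, ins_inf = 0)
  e1 <- egp_flux(st, p, ins_inf = 1)
  expect_equal(e0 - e1,
               p$free[["kegp4"]] / p$free[["gamma_inf"]], tolerance = 1e-12)
})

test_that("insulin-dependent uptake follows Michaelis-Menten with NEFA-scaled Vmax", {
  p <- default_parameters(free = list(kuid1 = 1, kuid3 = 2, Km_uid = 100))
  st <- basal_state(p)
  st[["Id3"]] <- 100; st[["Nd1"]] <- 200

  st0 <- st; st0[["Gt"]] <- 0
  expect_equal(uid_flux(st0, p), 0)

  sth <- st; sth[["Gt"]] <- 100      # Gt = Km: half saturation
  vmax <- 1 + 2 * 100 / 200
  expect_equal(uid_flux(sth, p), vmax / 2)

  stl <- st; stl[["Gt"]] <- 1e9      # saturation limit -> Vmax = 2.0
  expect_equal(uid_flux(stl, p), 2.0, tolerance = 1e-6)

  # floor on the delayed NEFA signal
  stf <- st; stf[["Nd1"]] <- 0.1; stf[["Gt"]] <- 1e9
  expect_warning(u <- uid_flux(stf, p), "floor")
  expect_equal(u, 1 + 2 * 100 / p$fixed[["nd1_floor"]], tolerance = 1e-6)
})

test_that("LPL lipolysis matches an independent re-derivation and is monotone in TG", {
  p <- default_p
  expect_equal(jlpl_flux(0, 300, p), 0)

  # dual-implementation oracle: saturating insulin-stimulated hydrolysis
  ref_jlpl <- function(tg, ins, pr) {
    ins <- max(ins, 0)
    pr$free[["c_lpl"]] * tg * ins / (pr$free[["K_lpl"]] + ins)
  }
  for (tg in c(200, 1100, 2500)) for (ins in c(0, 25.49, 400)) {
    expect_equal(jlpl_flux(tg, ins, p), ref_jlpl(tg, ins, p))
  }
  # monotone non-decreasing in TG at fixed insulin
  expect_true(all(diff(jlpl_flux(seq(0, 3000, 100), 150, p)) >= 0))
  expect_error(jlpl_flux(-5, 100, p), "non-negative")
})

test_that("spillover fraction is bounded, anchored at basal, and non-increasing", {
  p <- default_p
  expect_equal(spill_fraction(p$basal[["Ib"]], p), p$free[["spill_b"]])
  expect_lt(spill_fraction(1e7, p), 1e-3)   # saturation of inhibition
  ins <- seq(0, 3000, by = 25)
  sp <- spill_fraction(ins, p)
  expect_true(all(sp >= 0 & sp <= 1))
  expect_true(all(diff(sp) <= 0))           # pairwise sweep: non-increasing
})

test_that("compiled right-hand side equals the composition of the flux operations", {
  set.seed(11)
  inputs <- model_inputs(glucose_dose = 50000,
                         tg = data.frame(t = c(0, 100, 360),
                                         v = c(1100, 1600, 1200)),
                         ins_inf = data.frame(t = 0, rate = 3))
  for (k in 1:20) {
    p <- random_params()
    st <- random_state(p)
    tt <- stats::runif(1, 0, 360)
    r_cpp <- glunefa:::cpp_rhs(tt, unname(st[glunefa:::cpp_state_names()]),
                               unname(as_param_vector(p)),
                               glunefa:::.cpp_inputs(inputs))
    r_r <- suppressWarnings(full_rhs(tt, st, p, inputs))
    expect_equal(unname(r_cpp$dy), unname(r_r[names(r_cpp$dy)]),
                 tolerance = 1e-10)
  }
})

test_that("clamped states follow their signals and feed the dependent terms", {
  p <- default_p
  traj <- data.frame(t = c(0, 60, 120), value = c(400, 900, 700))
  proto <- protocol(kind = "clamp",
                    clamped = list(glucose = 85, insulin = 420, NEFA = traj),
                    ins_inf = 10, t_end = 120)
  res <- simulate_clamp(proto, p)
  st <- res$sim$states
  expect_equal(st$Gp, rep(85 * p$fixed[["VG"]], 121), tolerance = 1e-12)
  expect_equal(st$Ip, rep(420 * p$fixed[["VI"]], 121), tolerance = 1e-12)
  expect_equal(st$NEFA[61], 900, tolerance = 1e-12)
  expect_equal(st$NEFA[31], 650, tolerance = 1e-12)   # linear interpolation
  # delay chains relax toward the clamped sources
  expect_gt(st$Id7[121], st$Id7[1])
  expect_lt(st$Id7[121], 420)
  expect_gt(st$Nd1[121], 400)
})

test_that("trajectories are deterministic and tolerance-convergent", {
  p <- default_p
  inputs <- model_inputs(glucose_dose = 100000)
  tg <- seq(0, 360, by = 5)
  s1 <- simulate_model(p, inputs, tg)
  s2 <- simulate_model(p, inputs, tg)
  expect_identical(s1$states, s2$states)    # bit-for-bit reproducibility

  s_loose <- simulate_model(p, inputs, tg, rtol = 1e-6, atol = 1e-8)
  s_tight <- simulate_model(p, inputs, tg, rtol = 5e-7, atol = 5e-9)
  rel <- abs(s_loose$states$Gp - s_tight$states$Gp) /
    pmax(abs(s_tight$states$Gp), 1)
  expect_lt(max(rel), 10 * 1e-6)
})

test_that("oral glucose mass is conserved through the transit chain", {
  p <- default_p
  dose <- 100000                            # mg
  sim <- simulate_model(p, model_inputs(glucose_dose = dose),
                        seq(0, 360, by = 1))
  n <- length(sim$time)
  absorbed <- sim$states$Qing[n] / p$fixed[["f_bio"]]
  residual <- sim$states$Qsto1[n] + sim$states$Qsto2[n] + sim$states$Qgut[n]
  expect_equal(absorbed + residual, dose, tolerance = 1e-6)
  # integrated appearance approaches dose * f as the residual empties
  sim_long <- simulate_model(p, model_inputs(glucose_dose = dose,
                                             t_end = 2000),
                             seq(0, 2000, by = 10))
  expect_equal(sim_long$states$Qing[length(sim_long$time)],
               dose * p$fixed[["f_bio"]], tolerance = 1e-3)
})

test_that("spill stays within [0,1] along simulated trajectories", {
  sim <- simulate_oral_challenge(ogtt_protocol(), default_p)
  expect_true(all(sim$fluxes$spill >= 0 & sim$fluxes$spill <= 1))
  expect_true(all(sim$fluxes$EGP >= 0))
  expect_true(all(sim$fluxes$U_id >= 0))
  expect_true(all(sim$fluxes$Ra >= 0))
})

test_that("with NEFA coupling disabled, glucose and insulin ignore NEFA parameters", {
  tg <- seq(0, 360, by = 10)
  inputs <- model_inputs(glucose_dose = 75000)
  s_ref <- simulate_model(decoupled_p, inputs, tg)
  # change every pure-NEFA parameter; glucose/insulin must not move
  p_mod <- update_parameters(decoupled_p,
                             free = list(pA = 0.07, pB = 5e-4, pC = -3,
                                         c_lpl = 0.03, K_sp = 50),
                             basal = list(NEFA0 = 700))
  s_mod <- simulate_model(p_mod, inputs, tg,
                          y0 = basal_state(p_mod, nefa0 = 700))
  # decoupling is exact analytically; numerically the two runs share the
  # glucose solution only up to the solver tolerance, since the differing
  # NEFA dynamics steer the adaptive step sequence
  for (col in c("Gp", "Gt", "Ip", "Il", "Ipo")) {
    expect_equal(s_ref$states[[col]], s_mod$states[[col]], tolerance = 1e-6)
  }
  # sanity: the NEFA trajectories themselves do differ
  expect_gt(max(abs(s_ref$states$NEFA - s_mod$states$NEFA)), 10)
})
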