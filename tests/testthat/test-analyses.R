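# Perturbation and contribution analyses of the OGTT response.

test_that("AUC matches trapezoid quadrature on a refined grid", {
  p <- default_p
  sim1 <- simulate_oral_challenge(ogtt_protocol(), p,
                                  t_grid = seq(0, 360, by = 1))
  sim_fine <- simulate_oral_challenge(ogtt_protocol(), p,
                                      t_grid = seq(0, 360, by = 0.5))
  a1 <- auc(sim1$time, sim1$states$NEFA)
  a2 <- auc(sim_fine$time, sim_fine$states$NEFA)
  expect_lt(abs(a1 - a2) / a2, 1e-3)
  # closed form on a hand-made series
  expect_equal(auc(c(0, 1, 3), c(2, 4, 4)), 3 + 8)
})

test_that("a null perturbation leaves every AUC unchanged", {
  r <- perturb_ogtt(default_p, perturbation("P_bas", 1))
  expect_equal(unname(r$dAUC), c(0, 0, 0), tolerance = 1e-10)
})

test_that("perturbation magnitudes are validated", {
  expect_error(perturbation("P_bas", 0), "positive")
  expect_error(perturbation("P_lip", 1.5), "\\(0, 1\\]")
})

test_that("raising fasting NEFA raises the NEFA and insulin AUC but spares glucose", {
  for (m in c(1.5, 2)) {
    r <- perturb_ogtt(default_p, perturbation("P_bas", m))
    expect_gt(r$dAUC[["NEFA"]], 0)
    expect_gt(r$dAUC[["insulin"]], 0)
    expect_lt(abs(r$dAUC[["glucose"]]), abs(r$dAUC[["insulin"]]))
  }
})

test_that("reducing lipolysis inhibition hits the requested NEFA-fall reduction", {
  p <- default_p
  target_reduction <- 0.3
  r <- perturb_ogtt(p, perturbation("P_lip", target_reduction))
  expect_lt(r$perturbed_value, p$free[["pB"]])
  expect_gt(r$dAUC[["NEFA"]], 0)

  base_conc <- plasma_concentrations(r$base)
  pert_conc <- plasma_concentrations(r$perturbed)
  nefa0 <- p$basal[["NEFA0"]]
  fall0 <- nefa0 - min(base_conc$NEFA)
  fall1 <- nefa0 - min(pert_conc$NEFA)
  expect_equal(fall1 / fall0, 1 - target_reduction, tolerance = 1e-2)
})

test_that("contribution terms vanish exactly when their couplings are removed", {
  p_no_uid <- default_parameters(free = list(kuid3 = 0, kuid1 = NA_real_))
  co1 <- contribution_ogtt(p_no_uid)
  expect_identical(co1$R_N_Uid_max, 0)
  expect_true(all(co1$terms$T_N_uid == 0))

  p_no_egp <- default_parameters(free = list(kegp5 = 0))
  co2 <- contribution_ogtt(p_no_egp)
  expect_identical(co2$R_N_EGP_max, 0)
  expect_true(all(co2$terms$T_N_egp == 0))
})

test_that("the decomposition matches a hand-computed split on a trajectory snapshot", {
  p <- default_p
  co <- contribution_ogtt(p)
  sim <- co$sim
  i <- which(sim$time == 120)
  st <- sim$states[i, ]
  fr <- p$free; bs <- p$basal; d <- p$derived

  # U_id split: Vmax(t) - Vmax_b must equal T_I + T_N exactly
  vmax_t <- fr[["kuid3"]] * st$Id3 / st$Nd1
  vmax_b <- fr[["kuid3"]] * bs[["Ib"]] / bs[["NEFA0"]]
  expect_equal(co$terms$T_I_uid[i] + co$terms$T_N_uid[i],
               vmax_t - vmax_b, tolerance = 1e-10)
  expect_equal(co$terms$T_N_uid[i],
               fr[["kuid3"]] * st$Id3 * (1 / st$Nd1 - 1 / bs[["NEFA0"]]),
               tolerance = 1e-12)

  # EGP split: the four terms must sum to the (unfloored) suppression
  lin_egp <- d[["kegp1"]] - fr[["kegp2"]] * st$Gp -
    fr[["kegp3"]] * st$Id2 - fr[["kegp4"]] * st$Ipo +
    fr[["kegp5"]] * st$Nd1
  tot <- co$terms$T_G_egp[i] + co$terms$T_I_egp[i] +
    co$terms$T_P_egp[i] + co$terms$T_N_egp[i]
  expect_equal(tot, bs[["EGPb"]] - lin_egp, tolerance = 1e-9)
})

test_that("reported contributions sit at the masked argmax and lie in [0,1] here", {
  co <- contribution_ogtt(default_p)
  expect_true(co$R_N_Uid_max >= 0 && co$R_N_Uid_max <= 1)
  expect_true(is.finite(co$R_N_EGP_max))
  expect_true(co$t_max_uid %in% co$sim$time)
  # the argmax really is the maximum of |T_N| over unmasked times
  tot_uid <- co$terms$T_I_uid + co$terms$T_N_uid
  mask <- abs(tot_uid) >= 0.01 * max(abs(tot_uid))
  i_max <- which(co$sim$time == co$t_max_uid)
  expect_equal(abs(co$terms$T_N_uid[i_max]),
               max(abs(co$terms$T_N_uid[mask])))
})
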