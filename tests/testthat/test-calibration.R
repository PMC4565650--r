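# Cost function, EGP sub-cost, multi-start optimizer and ensemble selection.
# (perfect_fit_dataset comes from helper-glunefa.R)

test_that("cost is zero at a perfect fit and follows exact hand-computable cases", {
  p <- default_p
  d0 <- perfect_fit_dataset(p)
  expect_equal(cost(p, d0), 0, tolerance = 1e-12)

  # two observations displaced by exactly 1 and 2 standard errors -> V = 5
  d5 <- d0
  d5$value[1] <- d5$value[1] + 1 * d5$se[1]
  d5$value[2] <- d5$value[2] + 2 * d5$se[2]
  d5 <- dataset(as.data.frame(d5)[1:2, ], attr(d0, "protocols"))
  expect_equal(cost(p, d5), 5, tolerance = 1e-9)

  # doubling every standard error divides the cost by four
  d5_wide <- d5
  d5_wide$se <- d5_wide$se * 2
  d5_wide <- dataset(as.data.frame(d5_wide), attr(d0, "protocols"))
  expect_equal(cost(p, d5_wide), 5 / 4, tolerance = 1e-9)
})

test_that("cost records simulation failures as infinite, not as errors", {
  d <- perfect_fit_dataset(default_p)
  p_bad <- default_p
  p_bad$free[["kd7"]] <- NaN          # invalid without re-validation
  expect_silent(v <- cost(p_bad, d))
  expect_identical(v, Inf)
})

test_that("the EGP sub-cost equals the cost on the EGP-filtered dataset", {
  p <- default_p
  study <- synthetic_study(p, seed = 3)
  d <- study$data
  expect_equal(v_egp(p, d),
               cost(p, dataset(as.data.frame(d)[d$observable == "EGP_avg", ],
                               attr(d, "protocols"))))
  expect_lte(v_egp(p, d), cost(p, d))
  # no EGP observations -> zero by definition
  d_meal <- dataset(as.data.frame(d)[d$source == "D_MEAL", ],
                    attr(d, "protocols"))
  expect_identical(v_egp(p, d_meal), 0)

  # detail mode agrees with the two scalar entry points
  cd <- cost(p, d, detail = TRUE)
  expect_equal(cd$V, cost(p, d))
  expect_equal(cd$V_EGP, v_egp(p, d))
})

test_that("the multi-start optimizer solves a convex problem from all starts", {
  # quadratic in log-space with a known interior minimum
  target <- c(pA = 0.02, kn1 = 0.08)
  objective <- function(vals)
    sum((log10(vals[names(target)]) - log10(target))^2)
  cfg <- list(free = names(target), n_starts = 6L, seed = 5L, maxit = 60L,
              bounds = rbind(lower = target / 50, upper = target * 50))
  fit <- multistart_optimize(config = cfg, objective = objective)
  expect_lt(min(fit$archive$V), 1e-8)
  best <- fit$archive[fit$best, ]
  expect_equal(best$pA, target[["pA"]], tolerance = 1e-3)
  expect_equal(best$kn1, target[["kn1"]], tolerance = 1e-3)

  # determinism: the same seed reproduces the archive exactly
  fit2 <- multistart_optimize(config = cfg, objective = objective)
  expect_identical(fit$archive, fit2$archive)
})

test_that("ensemble selection matches brute-force enumeration on a hand-built archive", {
  # five members; V_min = 10 so the 120% band is V <= 12
  arch <- data.frame(
    start = 1:5,
    kra3 = c(0.012, 0.008, 0.020, 0.015, 0.030),
    kegp5 = c(1e-3, 5e-3, 2e-4, 8e-4, 9e-4),
    V = c(10, 11, 12, 30, 11.5),
    V_EGP = c(1, 2, 3, 4, 5))

  # brute force: band = rows 1,2,3,5; extremes of kra3 -> rows 2,5;
  # extremes of kegp5 -> rows 3,2; plus the min-cost member (row 1):
  # S_ext = {1,2,3,5}
  ens <- select_ensemble(arch)
  sext <- ens$members[ens$members$in_Sext, ]
  expect_setequal(sext$start, c(1, 2, 3, 5))

  # stage 2 drops kra3 = 0.008 < 0.009 before taking extremes:
  # pool = rows 1,3,5; kra3 extremes -> 1,5; kegp5 extremes -> 3,1
  ssel <- ens$members[ens$members$in_Ssel, ]
  expect_setequal(ssel$start, c(1, 3, 5))

  # the row at the threshold boundary is in S_ext but not S_sel
  row2 <- ens$members[ens$members$start == 2, ]
  expect_true(row2$in_Sext)
  expect_false(row2$in_Ssel)

  # the minimum-cost member is always selected in stage 2
  expect_true(1 %in% ssel$start)
})

test_that("a singleton archive selects itself when kra3 passes", {
  arch <- data.frame(start = 1, kra3 = 0.012, kegp5 = 1e-3, V = 4,
                     V_EGP = 1)
  ens <- select_ensemble(arch)
  expect_equal(nrow(ens$members), 1)
  expect_true(ens$members$in_Sext)
  expect_true(ens$members$in_Ssel)

  arch$kra3 <- 0.0089
  ens2 <- select_ensemble(arch)
  expect_true(ens2$members$in_Sext)
  expect_false(ens2$members$in_Ssel)
})

test_that("ingestion parameters are excluded from extremeness", {
  arch <- data.frame(
    start = 1:3,
    kegp5 = c(1e-3, 1e-3, 1e-3),
    D_oftt = c(100, 900, 500),
    V = c(10, 11, 11.9),
    V_EGP = 1:3)
  ens <- select_ensemble(arch)
  # all kegp5 equal: extremes collapse onto the first row only; the
  # spread in D_oftt must not pull rows 2 and 3 in
  expect_equal(sum(ens$members$in_Sext), 1)
})

test_that("duplicate parameter vectors are merged in the ensemble", {
  # rows 1 and 2 carry identical parameter vectors; row 2 is the cost
  # minimum, row 1 is picked as an extreme -> they must merge
  arch <- data.frame(
    start = 1:3,
    kra3 = c(0.012, 0.012, 0.013),
    kegp5 = c(1e-3, 1e-3, 2e-3),
    V = c(11, 10, 11),
    V_EGP = 1:3)
  ens <- select_ensemble(arch)
  expect_equal(nrow(ens$members), 2)
  keys <- paste(ens$members$kra3, ens$members$kegp5)
  expect_false(any(duplicated(keys)))
})
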