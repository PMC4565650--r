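# Synthetic calibration/validation datasets with the structure of the
# digitized clamp and meal studies: arms are simulated under a known
# ground-truth parameter set and observed with independent Gaussian noise.

.default_noise <- c(glucose = 0.03, insulin = 0.08, NEFA = 0.08,
                    TG = 0.08, EGP_avg = 0.10, GU_avg = 0.10)

#' Design of the six-hour three-plateau NEFA clamp study
#'
#' Three arms of a hyperinsulinemic (70 uU/mL = 420 pmol/L), euglycemic
#' (85 mg/dL) clamp held for 6 h, with plasma NEFA clamped at plateaus of
#' 766, 562 and 51 umol/L (lipid+heparin, lipid-only and saline arms).
#' EGP and glucose uptake are averaged over the final 3 h. Contributes
#' 3 EGP and 3 GU observations.
#'
#' @param params parameter set used to compute the reported insulin
#'   infusion rate.
#' @return named list of `glunefa_protocol` objects.
#' @export
clamp1_design <- function(params = default_parameters()) {
  ins <- uU_per_mL_to_pmol_per_L(70)
  inf <- steady_insulin_infusion(params, ins)
  plateaus <- c(high = 766, mid = 562, low = 51)
  protos <- lapply(names(plateaus), function(nm) {
    protocol(kind = "clamp",
             clamped = list(glucose = 85, insulin = ins,
                            NEFA = unname(plateaus[nm])),
             ins_inf = inf, t_end = 360,
             measurement_window = c(180, 360),
             id = paste0("clamp1_", nm))
  })
  stats::setNames(protos, paste0("clamp1_", names(plateaus)))
}

#' Design of the two-hour mixed clamp study
#'
#' Three glycemia/insulinemia combinations, each with (+) and without (-)
#' a lipid+heparin infusion, 2 h clamps averaged over the final hour:
#' group A hyperinsulinemic (basal + 100 uU/mL) euglycemic, group B
#' hyperglycemic (200 mg/dL) hyperinsulinemic (50 uU/mL), group C
#' hyperglycemic (300 mg/dL) at near-basal insulin. NEFA follows a
#' linearly interpolated trajectory (suppressed in the vehicle arms,
#' rising under lipid infusion). GU is observed in all six arms; EGP only
#' in group C. Contributes 2 EGP and 6 GU observations.
#'
#' @inheritParams clamp1_design
#' @return named list of `glunefa_protocol` objects.
#' @export
clamp2_design <- function(params = default_parameters()) {
  Ib <- params$basal[["Ib"]]; Gb <- params$basal[["Gb"]]
  nefa0 <- params$basal[["NEFA0"]]
  arms <- list(
    A_veh = list(glucose = Gb, insulin = Ib + uU_per_mL_to_pmol_per_L(100),
                 nefa = c(nefa0, 120, 50)),
    A_lip = list(glucose = Gb, insulin = Ib + uU_per_mL_to_pmol_per_L(100),
                 nefa = c(nefa0, 700, 900)),
    B_veh = list(glucose = 200, insulin = uU_per_mL_to_pmol_per_L(50),
                 nefa = c(nefa0, 150, 70)),
    B_lip = list(glucose = 200, insulin = uU_per_mL_to_pmol_per_L(50),
                 nefa = c(nefa0, 750, 1000)),
    C_veh = list(glucose = 300, insulin = 80,
                 nefa = c(nefa0, 330, 290)),
    C_lip = list(glucose = 300, insulin = 80,
                 nefa = c(nefa0, 900, 1300))
  )
  protos <- lapply(names(arms), function(nm) {
    a <- arms[[nm]]
    nefa_traj <- data.frame(t = c(0, 30, 120), value = a$nefa)
    protocol(kind = "clamp",
             clamped = list(glucose = a$glucose, insulin = a$insulin,
                            NEFA = nefa_traj),
             ins_inf = steady_insulin_infusion(params, a$insulin),
             t_end = 120, measurement_window = c(60, 120),
             id = paste0("clamp2_", nm))
  })
  stats::setNames(protos, paste0("clamp2_", names(arms)))
}

#' Generate a synthetic clamp dataset
#'
#' Simulates every arm of the requested design under the ground-truth
#' parameter set, averages EGP/GU over the design's measurement window and
#' adds independent Gaussian observation noise with relative standard
#' errors from `noise`. Generating both designs yields the canonical
#' 5 EGP + 9 GU observations.
#'
#' @param truth ground-truth `glunefa_params`.
#' @param design `"clamp1"`, `"clamp2"`, or both.
#' @param seed integer seed; the dataset is reproducible given the seed.
#' @param noise named relative-SE vector (see package defaults).
#' @return a `glunefa_dataset`.
#' @export
make_clamp_dataset <- function(truth, design = c("clamp1", "clamp2"),
                               seed = 1, noise = .default_noise) {
  design <- match.arg(design, several.ok = TRUE)
  protos <- list()
  if ("clamp1" %in% design) protos <- c(protos, clamp1_design(truth))
  if ("clamp2" %in% design) protos <- c(protos, clamp2_design(truth))
  set.seed(seed)
  rows <- list()
  for (pid in names(protos)) {
    res <- tryCatch(simulate_clamp(protos[[pid]], truth),
                    error = function(e)
                      stop("generator error: truth fails to simulate arm ",
                           pid, ": ", conditionMessage(e)))
    obs <- c(GU_avg = res$GU_avg)
    # EGP observed in all clamp1 arms but only in group C of clamp2
    if (grepl("^clamp1", pid) || grepl("^clamp2_C", pid))
      obs <- c(EGP_avg = res$EGP_avg, obs)
    for (ob in names(obs)) {
      sd_noise <- abs(obs[[ob]]) * noise[[ob]]
      rows[[length(rows) + 1L]] <- data.frame(
        protocol_id = pid, observable = ob, time = NA_real_,
        value = obs[[ob]] + stats::rnorm(1, 0, sd_noise),
        se = max(sd_noise, 1e-3),  # reported SE never exactly zero
        source = toupper(paste0("D_", substr(pid, 1, 6))))
    }
  }
  dataset(do.call(rbind, rows), protos)
}

#' Meal sampling grid
#'
#' Dense early sampling (every 10 min to 120 min) then sparse sampling
#' (every 30 min to 360 min); with `gap = TRUE` no samples fall in the
#' open interval (120, 240) min, emulating the unobserved mid-afternoon
#' window of the source meal study.
#'
#' @param gap drop observations in (120, 240) min.
#' @return numeric vector of times, min.
#' @export
meal_grid <- function(gap = TRUE) {
  tt <- sort(unique(c(seq(0, 120, by = 10), seq(150, 360, by = 30))))
  if (gap) tt <- tt[!(tt > 120 & tt < 240)]
  tt
}

# ground-truth TG input curves for the synthetic meal study
.tg_truth_ogtt <- function(params) {
  tgb <- params$basal[["TGb"]]
  function(t) tgb * (1 - 0.05 * sin(pi * pmin(t, 360) / 360))
}

.tg_truth_oftt <- function(params) {
  tgb <- params$basal[["TGb"]]
  function(t) {
    x <- pmax(t, 0) / 210
    tgb + 600 * x^2 * exp(2 * (1 - x))   # slow transient peaking ~ 3.5 h
  }
}

#' Generate a synthetic meal dataset (OGTT + OFTT)
#'
#' Simulates the 100 g oral glucose challenge and the oral fat challenge
#' under the ground-truth parameters (the OFTT glucose ingestion is the
#' truth's fitted `D_oftt`), samples plasma glucose, insulin, NEFA and TG
#' on the meal grid and adds Gaussian noise. The attached calibration
#' protocols carry TG inputs re-fitted by polynomial interpolation of the
#' noisy TG observations, as in the calibration procedure.
#'
#' @inheritParams make_clamp_dataset
#' @param gap emulate the unobserved (120, 240) min window.
#' @param tg_degree degree of the TG interpolation polynomial.
#' @return a `glunefa_dataset`.
#' @export
make_meal_dataset <- function(truth, seed = 1, noise = .default_noise,
                              gap = TRUE, tg_degree = 5) {
  set.seed(seed + 1L)
  grid <- meal_grid(gap)
  tg_fns <- list(OGTT = .tg_truth_ogtt(truth), OFTT = .tg_truth_oftt(truth))
  doses <- c(OGTT = 100, OFTT = truth$free[["D_oftt"]] / 1000)
  fat <- c(OGTT = 0, OFTT = 40)
  rows <- list(); protos <- list()
  for (ch in c("OGTT", "OFTT")) {
    proto_truth <- protocol(kind = "oral_challenge",
                            glucose_dose_g = doses[[ch]],
                            fat_dose_g = fat[[ch]],
                            tg = tg_fns[[ch]], t_end = 360, id = ch)
    sim <- tryCatch(simulate_oral_challenge(proto_truth, truth),
                    error = function(e)
                      stop("generator error: truth fails to simulate ", ch,
                           ": ", conditionMessage(e)))
    conc <- plasma_concentrations(sim)
    for (ob in c("glucose", "insulin", "NEFA", "TG")) {
      mu <- stats::approx(conc$time, conc[[ob]], xout = grid)$y
      sd_noise <- abs(mu) * noise[[ob]]
      rows[[length(rows) + 1L]] <- data.frame(
        protocol_id = ch, observable = ob, time = grid,
        value = mu + stats::rnorm(length(mu), 0, sd_noise),
        se = pmax(sd_noise, 1e-3), source = "D_MEAL")
    }
  }
  obs <- do.call(rbind, rows)
  # calibration protocols use the polynomial fitted to the noisy TG data
  for (ch in c("OGTT", "OFTT")) {
    tg_obs <- obs[obs$protocol_id == ch & obs$observable == "TG", ]
    tg_fit <- fit_tg_polynomial(tg_obs[, c("time", "value")],
                                degree = tg_degree)
    protos[[ch]] <- protocol(kind = "oral_challenge",
                             glucose_dose_g = doses[[ch]],
                             fat_dose_g = fat[[ch]], tg = tg_fit,
                             t_end = 360, id = ch)
  }
  dataset(obs, protos)
}

#' Multi-step insulin cascade design (independent validation)
#'
#' Euglycemic clamp with plasma insulin stepped up every two hours; the
#' supra-physiological final step (13450 pmol/L in the source study) is
#' excluded by default. TG is fixed at 1000 umol/L since it was not
#' measured.
#'
#' @param include_final include the supra-physiological final step.
#' @return a `glunefa_protocol` from [cascade_protocol()].
#' @export
campbell_cascade_design <- function(include_final = FALSE) {
  steps <- c(112, 258, 526, 1125, 2250, 13450)
  excl <- c(rep(FALSE, 5), !include_final)
  cascade_protocol(insulin_steps = steps, glucose = 90, step_min = 120,
                   tg = 1000, nefa0 = 475, exclude = excl,
                   id = "campbell_cascade")
}

#' Generate a full synthetic study
#'
#' Bundles both clamp designs and the meal dataset generated from one
#' ground-truth parameter set under a single seed.
#'
#' @inheritParams make_clamp_dataset
#' @param gap see [make_meal_dataset()].
#' @return list with `data` (combined `glunefa_dataset`), `truth`, `seed`,
#'   `noise`.
#' @export
synthetic_study <- function(truth = default_parameters(), seed = 1,
                            noise = .default_noise, gap = TRUE) {
  clamps <- make_clamp_dataset(truth, seed = seed, noise = noise)
  meals <- make_meal_dataset(truth, seed = seed, noise = noise, gap = gap)
  list(data = combine_datasets(clamps, meals), truth = truth,
       seed = seed, noise = noise)
}
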