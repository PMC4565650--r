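# Flux operations of the glucose-insulin-NEFA model, implemented in plain R.
# These are the unit-testable definitions of each flux; the compiled
# right-hand side in src/model.cpp implements the same expressions and is
# cross-checked against their composition in the test suite.

#' Plasma NEFA balance
#'
#' dNEFA/dt = -J_A - J_B + J_C + J_D with
#' J_A = pA * NEFA (concentration-dependent uptake),
#' J_B = pB * (Id7 - Ib) * NEFA (insulin-dependent inhibition of lipolysis;
#' negative when the remote insulin signal is below basal),
#' J_C = pC (constant net basal uptake, < 0), and
#' J_D = spill * J_lpl(TG) / V_NEFA (spillover influx from lipoprotein
#' lipolysis).
#'
#' @param state named state vector (see [basal_state()]).
#' @param params a `glunefa_params` object.
#' @param tg plasma triglyceride concentration, umol/L.
#' @return list with `rate` (umol/L/min) and components `J_A`, `J_B`, `J_C`,
#'   `J_D`, `J_lpl`, `spill`.
#' @export
nefa_rhs <- function(state, params, tg) {
  if (state[["NEFA"]] < 0) stop("NEFA must be non-negative")
  if (tg < 0) stop("TG must be non-negative")
  fr <- params$free; bs <- params$basal
  J_A <- fr[["pA"]] * state[["NEFA"]]
  J_B <- fr[["pB"]] * (state[["Id7"]] - bs[["Ib"]]) * state[["NEFA"]]
  J_C <- fr[["pC"]]
  J_lpl <- jlpl_flux(tg, state[["Id7"]], params)
  spill <- spill_fraction(state[["Id7"]], params)
  J_D <- spill * J_lpl / bs[["V_NEFA"]]
  list(rate = unname(-J_A - J_B + J_C + J_D),
       J_A = unname(J_A), J_B = unname(J_B), J_C = unname(J_C),
       J_D = unname(J_D), J_lpl = unname(J_lpl), spill = unname(spill))
}

#' Endogenous glucose production
#'
#' EGP = kegp1 - kegp2*Gp - kegp3*Id2 - kegp4*(Ipo + ins_inf/gamma) +
#' kegp5*Nd1, floored at zero. `kegp1` is the derived intercept that anchors
#' EGP at `EGPb` in the fasting state.
#'
#' @inheritParams nefa_rhs
#' @param ins_inf insulin infusion rate, pmol/kg/min.
#' @return EGP in mg/kg/min.
#' @export
egp_flux <- function(state, params, ins_inf = 0) {
  fr <- params$free; d <- params$derived
  if (fr[["gamma_inf"]] == 0) stop("gamma_inf must be nonzero")
  egp <- d[["kegp1"]] - fr[["kegp2"]] * state[["Gp"]] -
    fr[["kegp3"]] * state[["Id2"]] -
    fr[["kegp4"]] * (state[["Ipo"]] + ins_inf / fr[["gamma_inf"]]) +
    fr[["kegp5"]] * state[["Nd1"]]
  unname(max(egp, 0))
}

#' Insulin-dependent glucose uptake
#'
#' Michaelis-Menten uptake of tissue glucose with an insulin- and
#' NEFA-dependent Vmax: `Vmax = kuid1 + kuid3 * Id3 / Nd1`, capturing the
#' reciprocal relationship between circulating NEFA and insulin-stimulated
#' uptake. `Nd1` is floored at `nd1_floor` (default 1 umol/L) to avoid
#' division blow-up; a warning is issued when the floor engages.
#'
#' @inheritParams nefa_rhs
#' @return U_id in mg/kg/min.
#' @export
uid_flux <- function(state, params) {
  fr <- params$free; fx <- params$fixed
  nd1 <- state[["Nd1"]]
  if (nd1 < fx[["nd1_floor"]]) {
    warning("Nd1 at or below the configured floor; clipped")
    nd1 <- fx[["nd1_floor"]]
  }
  vmax <- max(fr[["kuid1"]] + fr[["kuid3"]] * state[["Id3"]] / nd1, 0)
  gt <- max(state[["Gt"]], 0)
  unname(vmax * gt / (fr[["Km_uid"]] + gt))
}

#' Lipoprotein-lipase lipolysis of plasma TG
#'
#' Insulin-stimulated, saturating LPL activity acting proportionally on the
#' circulating TG concentration:
#' `J_lpl = c_lpl * TG * I / (K_lpl + I)` with `I` the (non-negative) remote
#' insulin signal. Zero at zero TG and monotone non-decreasing in TG.
#'
#' @param tg plasma TG, umol/L.
#' @param insulin_signal remote insulin signal, pmol/L.
#' @param params a `glunefa_params` object.
#' @return J_lpl in umol/kg/min.
#' @export
jlpl_flux <- function(tg, insulin_signal, params) {
  if (any(tg < 0)) stop("TG must be non-negative")
  fr <- params$free
  ins <- pmax(insulin_signal, 0)
  unname(fr[["c_lpl"]] * tg * ins / (fr[["K_lpl"]] + ins))
}

#' Insulin-inhibited spillover fraction
#'
#' Fraction of LPL-liberated fatty acids that enters plasma directly.
#' Parameterized by the basal fraction `spill_b` (attained at `Ib`) and an
#' inhibition scale `K_sp`:
#' `spill(I) = smax * K_sp / (K_sp + I)` with
#' `smax = min(1, spill_b * (K_sp + Ib) / K_sp)`. Bounded in [0, 1] and
#' non-increasing in the insulin signal.
#'
#' @inheritParams jlpl_flux
#' @return dimensionless fraction in [0, 1].
#' @export
spill_fraction <- function(insulin_signal, params) {
  fr <- params$free; bs <- params$basal
  smax <- min(1, fr[["spill_b"]] * (fr[["K_sp"]] + bs[["Ib"]]) / fr[["K_sp"]])
  ins <- pmax(insulin_signal, 0)
  unname(pmax(smax * fr[["K_sp"]] / (fr[["K_sp"]] + ins), 0))
}

#' Model inputs for a simulation
#'
#' Bundles the exogenous drivers of the system: the oral glucose dose
#' (delivered to the solid stomach compartment at t = 0), the plasma TG
#' input signal, the insulin infusion schedule, and any state clamps.
#'
#' @param glucose_dose oral glucose mass, mg, in `Qsto1` at t = 0.
#' @param tg TG input: `NULL` (constant at `TGb`), a single number, a
#'   function of time returning umol/L, or a two-column matrix/data.frame
#'   of (time, value) pairs interpolated linearly.
#' @param ins_inf insulin infusion: `NULL`, a single rate, or a data.frame
#'   with columns `t` and `rate` (piecewise-constant from each `t`).
#' @param clamps named list of clamp signals for states `Gp`, `Ip`, `NEFA`,
#'   `Ipo`: each a single value (held constant) or a data.frame with
#'   columns `t` and `value` (interpolated linearly, or stepwise if an
#'   attribute `interp = "step"` is set).
#' @param t_end horizon used to tabulate functional TG inputs, min.
#' @return an object of class `glunefa_inputs` ready for [simulate_model()].
#' @export
model_inputs <- function(glucose_dose = 0, tg = NULL, ins_inf = NULL,
                         clamps = NULL, t_end = 360) {
  if (glucose_dose < 0) stop("glucose_dose must be non-negative")
  tg_sig <- .as_signal(tg, t_end, what = "tg")
  inf_sig <- .as_signal(ins_inf, t_end, what = "ins_inf")
  clamp_list <- NULL
  if (!is.null(clamps)) {
    idx <- c(Gp = 3L, Ip = 5L, NEFA = 16L, Ipo = 9L)  # 0-based C++ indices
    bad <- setdiff(names(clamps), names(idx))
    if (length(bad)) stop("unsupported clamp state(s): ",
                          paste(bad, collapse = ", "))
    clamp_list <- lapply(names(clamps), function(nm) {
      s <- .as_signal(clamps[[nm]], t_end, what = nm)
      c(list(state = idx[[nm]]), s)
    })
  }
  structure(list(dose = glucose_dose, tg = tg_sig, ins_inf = inf_sig,
                 clamps = clamp_list, t_end = t_end),
            class = "glunefa_inputs")
}

.as_signal <- function(x, t_end, what) {
  if (is.null(x)) return(NULL)
  if (is.function(x)) {
    tt <- seq(0, t_end, by = 1)
    vv <- x(tt)                                  # vectorized evaluation
    if (length(vv) != length(tt)) vv <- vapply(tt, x, numeric(1))
    if (any(!is.finite(vv)) || any(vv < 0))
      stop(what, " signal must be finite and non-negative")
    return(list(t = tt, v = as.numeric(vv), type = 0L))
  }
  if (is.numeric(x) && length(x) == 1) {
    if (x < 0) stop(what, " signal must be non-negative")
    return(list(t = c(0, t_end), v = c(x, x), type = 0L))
  }
  x <- as.data.frame(x)
  type <- if (identical(attr(x, "interp"), "step")) 1L else 0L
  names(x)[1:2] <- c("t", "v")
  if (any(x$v < 0)) stop(what, " signal must be non-negative")
  if (is.unsorted(x$t, strictly = TRUE)) stop(what, " times must increase")
  list(t = as.numeric(x$t), v = as.numeric(x$v), type = type)
}

#' Simulate the full model
#'
#' Integrates the 18-state system with the adaptive RK45 solver (forced
#' stops at every output time and input breakpoint, so output times are hit
#' exactly) and recomputes all instantaneous fluxes at the output times.
#' Results are deterministic given identical parameters, inputs and
#' tolerances.
#'
#' @param params a `glunefa_params` object.
#' @param inputs a `glunefa_inputs` object from [model_inputs()].
#' @param t_grid increasing vector of output times, min.
#' @param y0 optional initial state; defaults to [basal_state()] (with a
#'   clamped initial NEFA if a NEFA clamp is present).
#' @param rtol,atol solver tolerances.
#' @return a list of class `glunefa_sim` with `time`, `states` (data.frame,
#'   one column per state) and `fluxes` (data.frame: EGP, Ra, U_ii, U_id, E,
#'   J_A..J_D, J_lpl, spill, ins_inf, TG, S).
#' @export
simulate_model <- function(params, inputs = model_inputs(),
                           t_grid = seq(0, 360, by = 1), y0 = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "glunefa_params"))
  if (is.unsorted(t_grid, strictly = TRUE)) stop("t_grid must increase")
  if (is.null(y0)) y0 <- basal_state(params)
  y0 <- y0[cpp_state_names()]
  pv <- as_param_vector(params)
  cl <- inputs$clamps
  # start clamped states on their signal
  if (!is.null(cl)) {
    for (ci in cl) y0[ci$state + 1L] <- .signal_at(ci, t_grid[1])
  }
  y0["Qsto1"] <- y0["Qsto1"] + inputs$dose
  res <- cpp_simulate(unname(pv), .cpp_inputs(inputs), as.numeric(t_grid),
                      unname(y0), rtol, atol)
  out <- list(time = res$time,
              states = as.data.frame(res$states),
              fluxes = as.data.frame(res$fluxes),
              params = params, inputs = inputs)
  class(out) <- "glunefa_sim"
  out
}

.cpp_inputs <- function(inputs) {
  list(dose = inputs$dose, tg = inputs$tg, ins_inf = inputs$ins_inf,
       clamps = inputs$clamps)
}

.signal_at <- function(sig, tt) {
  if (sig$type == 1L) {
    i <- findInterval(tt, sig$t, rightmost.closed = FALSE)
    return(sig$v[max(i, 1L)])
  }
  stats::approx(sig$t, sig$v, xout = tt, rule = 2)$y
}

#' Full right-hand side, composed in R
#'
#' Reference implementation assembling all 18 derivatives from the
#' individually documented flux operations. Used as the compositional oracle
#' for the compiled right-hand side; not called by the solver.
#'
#' @param t time, min.
#' @param state named state vector.
#' @param params a `glunefa_params` object.
#' @param inputs a `glunefa_inputs` object.
#' @return named derivative vector.
#' @export
full_rhs <- function(t, state, params, inputs = model_inputs()) {
  fx <- params$fixed; fr <- params$free; bs <- params$basal
  d <- params$derived
  st <- state
  # clamp overrides
  clamped <- character(0)
  slopes <- numeric(0)
  if (!is.null(inputs$clamps)) {
    nms <- c(`3` = "Gp", `5` = "Ip", `16` = "NEFA", `9` = "Ipo")
    for (ci in inputs$clamps) {
      nm <- nms[[as.character(ci$state)]]
      st[[nm]] <- .signal_at(ci, t)
      clamped <- c(clamped, nm)
      slopes[nm] <- .signal_slope(ci, t)
    }
  }
  ins_inf <- if (is.null(inputs$ins_inf)) 0 else {
    i <- max(findInterval(t, inputs$ins_inf$t), 1L)
    max(inputs$ins_inf$v[i], 0)
  }
  tg <- if (is.null(inputs$tg)) bs[["TGb"]] else max(.signal_at(inputs$tg, t), 0)

  G <- st[["Gp"]] / fx[["VG"]]; I <- st[["Ip"]] / fx[["VI"]]
  dy <- stats::setNames(numeric(18), cpp_state_names())

  kempt <- fx[["kmax"]]
  if (inputs$dose > 0) {
    qsto <- st[["Qsto1"]] + st[["Qsto2"]]
    aa <- 5 / (2 * inputs$dose * (1 - fx[["b_empt"]]))
    bb <- 5 / (2 * inputs$dose * fx[["d_empt"]])
    kempt <- fr[["kra3"]] + (fx[["kmax"]] - fr[["kra3"]]) / 2 *
      (tanh(aa * (qsto - fx[["b_empt"]] * inputs$dose)) -
         tanh(bb * (qsto - fx[["d_empt"]] * inputs$dose)) + 2)
  }
  dy["Qsto1"] <- -fx[["kgri"]] * st[["Qsto1"]]
  dy["Qsto2"] <- -kempt * st[["Qsto2"]] + fx[["kgri"]] * st[["Qsto1"]]
  dy["Qgut"] <- -fx[["kabs"]] * st[["Qgut"]] + kempt * st[["Qsto2"]]
  Ra <- fx[["f_bio"]] * fx[["kabs"]] * st[["Qgut"]] / bs[["BW"]]
  dy["Qing"] <- Ra * bs[["BW"]]

  EGP <- egp_flux(st, params, ins_inf)
  Uii <- fx[["Fcns"]]
  Uid <- suppressWarnings(uid_flux(st, params))
  E <- fx[["ke1"]] * max(st[["Gp"]] - fx[["ke2"]], 0)
  dy["Gp"] <- EGP + Ra - Uii - E - fx[["k1"]] * st[["Gp"]] +
    fx[["k2"]] * st[["Gt"]]
  dy["Gt"] <- -Uid + fx[["k1"]] * st[["Gp"]] - fx[["k2"]] * st[["Gt"]]

  S <- fx[["gamma_sec"]] * st[["Ipo"]]
  HE <- min(max(-fx[["m5"]] * S + d[["m6"]], 0), 0.9)
  m3 <- HE * fx[["m1"]] / (1 - HE)
  dy["Il"] <- -(fx[["m1"]] + m3) * st[["Il"]] + fx[["m2"]] * st[["Ip"]] + S
  dy["Ip"] <- -(fx[["m2"]] + fx[["m4"]]) * st[["Ip"]] +
    fx[["m1"]] * st[["Il"]] + ins_inf

  dG <- (if ("Gp" %in% clamped) slopes[["Gp"]] else dy[["Gp"]]) / fx[["VG"]]
  Spo <- st[["Y"]] + d[["Sb"]] + if (dG > 0) fx[["Ksec"]] * dG else 0
  Spo <- max(Spo, 0)
  dy["Ipo"] <- -fx[["gamma_sec"]] * st[["Ipo"]] + Spo
  ytarget <- fx[["beta_sec"]] * (G - bs[["Gb"]])
  dy["Y"] <- if (ytarget >= -d[["Sb"]])
    -fx[["alpha_sec"]] * (st[["Y"]] - ytarget)
  else -fx[["alpha_sec"]] * (st[["Y"]] + d[["Sb"]])

  dy["X"] <- -fx[["p2U"]] * st[["X"]] + fx[["p2U"]] * (I - bs[["Ib"]])
  dy["I1"] <- -fx[["ki"]] * (st[["I1"]] - I)
  dy["Id"] <- -fx[["ki"]] * (st[["Id"]] - st[["I1"]])
  dy["Id2"] <- -fr[["kd2"]] * (st[["Id2"]] - st[["Id"]])
  dy["Id3"] <- -fr[["kd3"]] * (st[["Id3"]] - I)
  dy["Id7"] <- -fr[["kd7"]] * (st[["Id7"]] - I)
  dy["Nd1"] <- -fr[["kn1"]] * (st[["Nd1"]] - st[["NEFA"]])

  dy["NEFA"] <- nefa_rhs(st, params, tg)$rate

  for (nm in clamped) dy[nm] <- slopes[[nm]]
  if (any(!is.finite(dy)))
    stop("non-finite derivative at t = ", t, "; state: ",
         paste(names(st), signif(unlist(st), 4), sep = "=", collapse = " "))
  dy
}

.signal_slope <- function(sig, tt) {
  if (sig$type == 1L || length(sig$t) < 2) return(0)
  if (tt <= sig$t[1] || tt >= sig$t[length(sig$t)]) return(0)
  i <- findInterval(tt, sig$t)
  (sig$v[i + 1] - sig$v[i]) / (sig$t[i + 1] - sig$t[i])
}

#' @export
print.glunefa_sim <- function(x, ...) {
  cat("<glunefa_sim> ", length(x$time), " time points over [",
      x$time[1], ", ", x$time[length(x$time)], "] min\n", sep = "")
  invisible(x)
}

#' Extract plasma concentrations from a simulation
#'
#' @param sim a `glunefa_sim` object.
#' @return data.frame with time (min), glucose (mg/dL), insulin (pmol/L),
#'   NEFA (umol/L) and TG (umol/L, the input signal).
#' @export
plasma_concentrations <- function(sim) {
  vg <- sim$params$fixed[["VG"]]; vi <- sim$params$fixed[["VI"]]
  data.frame(time = sim$time,
             glucose = sim$states$Gp / vg,
             insulin = sim$states$Ip / vi,
             NEFA = sim$states$NEFA,
             TG = sim$fluxes$TG)
}
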