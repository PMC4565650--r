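# Experimental protocol descriptions and their simulation: steady clamps
# with measurement-window averaging, multi-step insulin cascades, and oral
# glucose/fat tolerance tests.

#' Declare an experimental protocol
#'
#' A declarative description of one experiment. Clamped states are removed
#' from the integrated system and supplied as exogenous signals to every
#' dependent term; the delay chains evolve freely from the clamped sources.
#' When plasma insulin is clamped the portal secretion state `Ipo` is also
#' clamped (to its basal value by default) unless an explicit `Ipo` entry
#' is given.
#'
#' @param kind one of `"clamp"`, `"insulin_cascade"`, `"oral_challenge"`.
#' @param clamped named list of clamp targets for `Gp`, `Ip`, `NEFA`, `Ipo`.
#'   Entries may be given in plasma-concentration units via the helper names
#'   `glucose` (mg/dL), `insulin` (pmol/L) and `NEFA` (umol/L); single
#'   values are held constant, data.frames `(t, value)` are interpolated
#'   linearly (set `attr(x, "interp") <- "step"` for stepwise signals).
#' @param ins_inf insulin infusion schedule (single rate or data.frame
#'   `(t, rate)`), pmol/kg/min.
#' @param glucose_dose_g oral glucose dose, g.
#' @param fat_dose_g oral fat dose, g (drives no model input directly; the
#'   measured TG trajectory is the lipid signal).
#' @param tg TG input passed to [model_inputs()].
#' @param t_end protocol horizon, min.
#' @param measurement_window `[t_start, t_stop]` for flux averaging, min.
#'   Defaults to the final half of the protocol for horizons >= 4 h and the
#'   final hour otherwise.
#' @param nefa0 initial NEFA concentration override, umol/L.
#' @param id protocol identifier used to key observations.
#' @return an object of class `glunefa_protocol`.
#' @export
protocol <- function(kind = c("clamp", "insulin_cascade", "oral_challenge"),
                     clamped = NULL, ins_inf = NULL, glucose_dose_g = 0,
                     fat_dose_g = 0, tg = NULL, t_end = 360,
                     measurement_window = NULL, nefa0 = NULL, id = NULL) {
  kind <- match.arg(kind)
  if (is.null(measurement_window))
    measurement_window <- if (t_end >= 240) c(t_end / 2, t_end)
      else c(t_end - 60, t_end)
  if (measurement_window[1] < 0 || measurement_window[2] > t_end ||
      diff(measurement_window) <= 0)
    stop("measurement_window must be an increasing interval within [0, t_end]")
  structure(list(kind = kind, clamped = clamped, ins_inf = ins_inf,
                 glucose_dose_g = glucose_dose_g, fat_dose_g = fat_dose_g,
                 tg = tg, t_end = t_end,
                 measurement_window = measurement_window,
                 nefa0 = nefa0, id = id),
            class = "glunefa_protocol")
}

# translate concentration-unit clamp targets into state-unit clamp signals
.protocol_clamps <- function(proto, params) {
  cl <- proto$clamped
  if (is.null(cl)) return(NULL)
  fx <- params$fixed
  out <- list()
  conv <- function(x, fac) {
    if (is.numeric(x) && length(x) == 1) return(x * fac)
    x <- as.data.frame(x)
    interp <- attr(proto$clamped[[nm]], "interp")
    x[[2]] <- x[[2]] * fac
    attr(x, "interp") <- interp
    x
  }
  for (nm in names(cl)) {
    out[[switch(nm, glucose = "Gp", insulin = "Ip", nm)]] <-
      switch(nm,
             glucose = conv(cl[[nm]], fx[["VG"]]),   # mg/dL -> mg/kg
             insulin = conv(cl[[nm]], fx[["VI"]]),   # pmol/L -> pmol/kg
             conv(cl[[nm]], 1))
  }
  # clamping plasma insulin implies controlled secretion: clamp Ipo at basal
  if (("Ip" %in% names(out)) && !("Ipo" %in% names(out)))
    out[["Ipo"]] <- unname(params$derived[["Ipob"]])
  out
}

#' Simulate a clamp protocol
#'
#' Runs the model with the protocol's states held exogenously and averages
#' EGP and total glucose uptake (GU = U_ii + U_id) over the measurement
#' window by trapezoidal quadrature on the output grid.
#'
#' @param proto a `glunefa_protocol` of kind `"clamp"` (or
#'   `"insulin_cascade"`).
#' @param params a `glunefa_params` object.
#' @param dt output grid spacing, min.
#' @return a list of class `glunefa_clamp_result` with `EGP_avg`, `GU_avg`
#'   (mg/kg/min), `window` and the full `sim` trajectory.
#' @export
simulate_clamp <- function(proto, params, dt = 1) {
  stopifnot(inherits(proto, "glunefa_protocol"))
  if (proto$kind == "oral_challenge")
    stop("protocol error: use simulate_oral_challenge() for oral challenges")
  cl <- .protocol_clamps(proto, params)
  need <- c("Gp", "Ip", "NEFA")
  if (!all(need %in% names(cl)))
    stop("protocol error: clamp values required for ",
         paste(setdiff(need, names(cl)), collapse = ", "))
  inputs <- model_inputs(glucose_dose = 0, tg = proto$tg,
                         ins_inf = proto$ins_inf, clamps = cl,
                         t_end = proto$t_end)
  y0 <- basal_state(params, nefa0 = proto$nefa0)
  sim <- simulate_model(params, inputs, t_grid = seq(0, proto$t_end, by = dt),
                        y0 = y0)
  w <- proto$measurement_window
  gu <- sim$fluxes$U_ii + sim$fluxes$U_id
  res <- list(EGP_avg = window_average(sim$time, sim$fluxes$EGP, w),
              GU_avg = window_average(sim$time, gu, w),
              window = w, sim = sim, id = proto$id)
  class(res) <- "glunefa_clamp_result"
  res
}

#' Time-average of a sampled flux over a window
#'
#' Trapezoidal quadrature of `(t, y)` restricted to `window`, divided by the
#' window length. Window endpoints must be covered by `t`.
#'
#' @param t,y sampled time series.
#' @param window numeric length-2 interval.
#' @return scalar average.
#' @export
window_average <- function(t, y, window) {
  if (window[1] < min(t) || window[2] > max(t))
    stop("measurement window not covered by the trajectory")
  keep <- t >= window[1] & t <= window[2]
  tt <- t[keep]; yy <- y[keep]
  # close the window ends exactly by interpolation
  if (tt[1] > window[1]) {
    tt <- c(window[1], tt)
    yy <- c(stats::approx(t, y, xout = window[1])$y, yy)
  }
  n <- length(tt)
  if (tt[n] < window[2]) {
    tt <- c(tt, window[2])
    yy <- c(yy, stats::approx(t, y, xout = window[2])$y)
  }
  trapz(tt, yy) / diff(window)
}

#' Trapezoidal integral
#' @param t,y sampled series.
#' @return scalar integral.
#' @export
trapz <- function(t, y) sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Simulate a multi-step insulin cascade
#'
#' Glucose and insulin are clamped stepwise (values per step, each lasting
#' `step_min`), NEFA evolves freely under the model, and TG is held at a
#' constant value. Steps flagged as excluded (e.g. supra-physiological
#' insulin) are dropped before simulation.
#'
#' @param proto a `glunefa_protocol` of kind `"insulin_cascade"` whose
#'   `clamped$insulin`/`clamped$glucose` are stepwise data.frames, or a
#'   design from [cascade_protocol()].
#' @param params a `glunefa_params` object.
#' @return a list with the full `sim`, and `step_table` reporting the NEFA
#'   concentration at the end of each step.
#' @export
simulate_insulin_cascade <- function(proto, params) {
  stopifnot(inherits(proto, "glunefa_protocol"),
            proto$kind == "insulin_cascade")
  cl <- .protocol_clamps(proto, params)
  if (is.null(cl$Ip) || is.null(cl$Gp))
    stop("protocol error: cascade requires stepwise glucose and insulin clamps")
  inputs <- model_inputs(glucose_dose = 0, tg = proto$tg, clamps = cl,
                         ins_inf = proto$ins_inf, t_end = proto$t_end)
  y0 <- basal_state(params, nefa0 = proto$nefa0)
  sim <- simulate_model(params, inputs,
                        t_grid = seq(0, proto$t_end, by = 1), y0 = y0)
  steps <- attr(proto, "steps")
  step_table <- NULL
  if (!is.null(steps)) {
    idx <- vapply(steps$t_stop, function(ts) which.min(abs(sim$time - ts)),
                  integer(1))
    step_table <- data.frame(step = seq_len(nrow(steps)),
                             insulin = steps$insulin,
                             t_stop = steps$t_stop,
                             NEFA_end = sim$states$NEFA[idx])
  }
  list(sim = sim, step_table = step_table, id = proto$id)
}

#' Build a stepwise insulin-cascade protocol
#'
#' @param insulin_steps plasma insulin level per step, pmol/L.
#' @param glucose constant clamped glucose, mg/dL.
#' @param step_min duration of each step, min.
#' @param tg constant TG level, umol/L.
#' @param nefa0 measured initial NEFA concentration, umol/L.
#' @param exclude logical vector marking steps to drop (e.g. the
#'   supra-physiological final step of the source protocol).
#' @param id protocol id.
#' @return a `glunefa_protocol` with a `steps` attribute.
#' @export
cascade_protocol <- function(insulin_steps, glucose = 90, step_min = 120,
                             tg = 1000, nefa0 = 475, exclude = NULL,
                             id = "cascade") {
  if (!is.null(exclude)) insulin_steps <- insulin_steps[!exclude]
  n <- length(insulin_steps)
  if (n < 1) stop("protocol error: cascade needs at least one step")
  starts <- (seq_len(n) - 1) * step_min
  t_end <- n * step_min
  ins <- data.frame(t = c(starts, t_end),
                    value = c(insulin_steps, insulin_steps[n]))
  attr(ins, "interp") <- "step"
  proto <- protocol(kind = "insulin_cascade",
                    clamped = list(glucose = glucose, insulin = ins),
                    tg = tg, t_end = t_end, nefa0 = nefa0, id = id)
  attr(proto, "steps") <- data.frame(insulin = insulin_steps,
                                     t_start = starts,
                                     t_stop = starts + step_min)
  proto
}

#' Simulate an oral challenge (OGTT / OFTT)
#'
#' The glucose dose is delivered to the solid stomach compartment at t = 0;
#' the plasma TG input is the protocol's measured trajectory (typically a
#' fitted polynomial, see [fit_tg_polynomial()]).
#'
#' @param proto a `glunefa_protocol` of kind `"oral_challenge"`.
#' @param params a `glunefa_params` object.
#' @param t_grid output times, min.
#' @return a `glunefa_sim`.
#' @export
simulate_oral_challenge <- function(proto, params,
                                    t_grid = seq(0, proto$t_end, by = 1)) {
  stopifnot(inherits(proto, "glunefa_protocol"),
            proto$kind == "oral_challenge")
  if (!is.null(proto$tg) && !is.function(proto$tg) &&
      !(is.numeric(proto$tg) && length(proto$tg) == 1)) {
    tg_tab <- as.data.frame(proto$tg)
    if (max(tg_tab[[1]]) < proto$t_end)
      stop("protocol error: TG trajectory shorter than t_end")
  }
  dose <- proto$glucose_dose_g * 1000
  inputs <- model_inputs(glucose_dose = dose, tg = proto$tg,
                         t_end = proto$t_end)
  simulate_model(params, inputs, t_grid = t_grid,
                 y0 = basal_state(params, nefa0 = proto$nefa0))
}

#' Fit the TG interpolation polynomial
#'
#' Least-squares polynomial through measured TG points. The returned
#' function clips evaluations at zero and holds the boundary fitted value
#' constant outside the data range.
#'
#' @param tg_points data.frame or matrix with columns time and value.
#' @param degree polynomial degree (default 5 for 6-h meal data).
#' @return a function of time, with attributes `coef` and `range`.
#' @export
fit_tg_polynomial <- function(tg_points, degree = 5) {
  tg_points <- as.data.frame(tg_points)
  names(tg_points)[1:2] <- c("t", "v")
  if (anyDuplicated(tg_points$t)) stop("fit error: repeated times")
  if (nrow(tg_points) < degree + 1)
    stop("fit error: need at least degree + 1 points")
  if (any(tg_points$v < 0)) stop("TG values must be non-negative")
  X <- outer(tg_points$t, 0:degree, `^`)
  cf <- qr.coef(qr(X), tg_points$v)
  cf[is.na(cf)] <- 0
  rng <- range(tg_points$t)
  f <- function(t) {
    t <- pmin(pmax(t, rng[1]), rng[2])
    pmax(drop(outer(t, 0:degree, `^`) %*% cf), 0)
  }
  attr(f, "coef") <- cf
  attr(f, "range") <- rng
  f
}

#' Read or write a protocol as JSON
#' @param proto a `glunefa_protocol`.
#' @param path file path.
#' @return `read_protocol` returns a `glunefa_protocol`.
#' @export
write_protocol <- function(proto, path) {
  ser <- unclass(proto)
  ser$clamped <- lapply(proto$clamped, function(x) {
    if (is.data.frame(x)) list(t = x[[1]], value = x[[2]],
                               interp = attr(x, "interp"))
    else x
  })
  if (is.function(ser$tg)) {
    ser$tg <- list(poly_coef = attr(proto$tg, "coef"),
                   range = attr(proto$tg, "range"))
  }
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  clamped <- NULL
  if (!is.null(raw$clamped)) {
    clamped <- lapply(raw$clamped, function(x) {
      if (is.list(x) && !is.null(x$t)) {
        df <- data.frame(t = unlist(x$t), value = unlist(x$value))
        if (!is.null(x$interp)) attr(df, "interp") <- x$interp
        df
      } else unlist(x)
    })
  }
  tg <- raw$tg
  if (is.list(tg) && !is.null(tg$poly_coef)) {
    cf <- unlist(tg$poly_coef); rng <- unlist(tg$range)
    deg <- length(cf) - 1
    tg <- function(t) {
      t <- pmin(pmax(t, rng[1]), rng[2])
      pmax(drop(outer(t, 0:deg, `^`) %*% cf), 0)
    }
  }
  protocol(kind = raw$kind, clamped = clamped, ins_inf = raw$ins_inf,
           glucose_dose_g = raw$glucose_dose_g %||% 0,
           fat_dose_g = raw$fat_dose_g %||% 0, tg = tg,
           t_end = raw$t_end,
           measurement_window = unlist(raw$measurement_window),
           nefa0 = raw$nefa0, id = raw$id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Approximate steady insulin infusion for a clamped insulin level
#'
#' Constant infusion rate that sustains a clamped plasma insulin mass
#' against clearance, assuming basal portal secretion. Used by the synthetic
#' clamp designs to populate the protocol's reported infusion rate.
#'
#' @param params a `glunefa_params` object.
#' @param insulin target plasma insulin concentration, pmol/L.
#' @return infusion rate, pmol/kg/min (floored at 0).
#' @export
steady_insulin_infusion <- function(params, insulin) {
  fx <- params$fixed; d <- params$derived
  Ipc <- insulin * fx[["VI"]]
  S <- fx[["gamma_sec"]] * d[["Ipob"]]
  HE <- min(max(-fx[["m5"]] * S + d[["m6"]], 0), 0.9)
  m3 <- HE * fx[["m1"]] / (1 - HE)
  Ilc <- (fx[["m2"]] * Ipc + S) / (fx[["m1"]] + m3)
  max((fx[["m2"]] + fx[["m4"]]) * Ipc - fx[["m1"]] * Ilc, 0)
}
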