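# Parameter sets: fixed glucose-insulin core constants, the 21 calibrated
# (free) parameters, basal anchors, and the derived basal-closure quantities.

.free_param_names <- c(
  "pA", "pB", "pC", "kegp2", "kegp3", "kegp4", "gamma_inf", "kegp5",
  "kuid1", "kuid3", "Km_uid", "kra3", "kd2", "kd3", "kd7", "kn1",
  "c_lpl", "K_lpl", "spill_b", "K_sp", "D_oftt"
)

.fixed_param_names <- c(
  "VG", "k1", "k2", "VI", "m1", "m2", "m4", "m5", "HEb",
  "kmax", "kabs", "kgri", "f_bio", "b_empt", "d_empt",
  "Fcns", "p2U", "ki", "Ksec", "alpha_sec", "beta_sec", "gamma_sec",
  "ke1", "ke2", "nd1_floor"
)

.basal_param_names <- c("Gb", "Ib", "EGPb", "NEFA0", "TGb", "V_NEFA", "BW")

.derived_param_names <- c(
  "kegp1", "Gpb", "Gtb", "Ipb", "Ilb", "Sb", "Ipob", "m3b", "m6"
)

.glunefa_param_names <- c(
  .fixed_param_names, .free_param_names, .basal_param_names,
  .derived_param_names
)

#' Default model parameter set
#'
#' Fixed glucose-insulin parameters are the published normal-subject values
#' of the Dalla Man meal-simulation model. The 21 free parameters carry the
#' package's shipped defaults: a hand-calibrated set that reproduces the
#' qualitative clamp and meal physiology (NEFA raising EGP and lowering
#' glucose uptake under hyperinsulinemia; postprandial NEFA undershoot and
#' overshoot). Basal anchors are population means for lean, healthy adults.
#'
#' `kuid1` defaults to the basal-consistent value returned by
#' [consistent_kuid1()], which places the glucose subsystem exactly at its
#' fasting fixed point.
#'
#' @param free named list or vector of free-parameter overrides.
#' @param basal named list or vector of basal-constant overrides.
#' @param fixed named list or vector of fixed-parameter overrides.
#' @return an object of class `glunefa_params`: a list with elements
#'   `fixed`, `free`, `basal` (named numeric vectors) and `derived`
#'   (computed by [derive_parameters()]).
#' @export
#' @examples
#' p <- default_parameters()
#' p$derived[["kegp1"]]
default_parameters <- function(free = NULL, basal = NULL, fixed = NULL) {
  fx <- c(
    VG = 1.88, k1 = 0.065, k2 = 0.079,          # glucose kinetics
    VI = 0.05, m1 = 0.190, m2 = 0.484, m4 = 0.194, m5 = 0.0304, HEb = 0.6,
    kmax = 0.0558, kabs = 0.057, kgri = 0.0558, # GI transit
    f_bio = 0.90, b_empt = 0.82, d_empt = 0.010,
    Fcns = 1.0, p2U = 0.0331,                   # utilization
    ki = 0.0079,                                # EGP insulin delay chain
    Ksec = 2.30, alpha_sec = 0.050, beta_sec = 0.11, gamma_sec = 0.5,
    ke1 = 0.0005, ke2 = 339,                    # renal excretion
    nd1_floor = 1.0                             # umol/L floor in U_id
  )
  fr <- c(
    pA = 0.03,          # 1/min, concentration-dependent NEFA uptake
    pB = 2e-4,          # 1/(pmol/L)/min, insulin inhibition of lipolysis
    pC = -1.0,          # umol/L/min, basal net NEFA uptake (< 0)
    kegp2 = 0.0021, kegp3 = 0.0013, kegp4 = 0.0618,
    gamma_inf = 0.5,    # 1/min, infusion-to-portal conversion in EGP
    kegp5 = 0.001,      # mg/kg/min per umol/L, NEFA stimulation of EGP
    kuid1 = NA_real_,   # filled below with the basal-consistent value
    kuid3 = 35,         # mg/kg/min per (pmol/L)/(umol/L)
    Km_uid = 2000,      # mg/kg (quasi-linear uptake over the Gt range)
    kra3 = 0.012,       # 1/min, minimal stomach emptying (OGTT)
    kd2 = 0.0079, kd3 = 0.06, kd7 = 0.025, kn1 = 0.05,  # delay rates, 1/min
    c_lpl = 0.016,      # LPL lipolysis rate scale
    K_lpl = 60,         # pmol/L, insulin half-saturation of LPL
    spill_b = 0.4,      # basal spillover fraction
    K_sp = 200,         # pmol/L, insulin inhibition scale of spillover
    D_oftt = 500        # mg, fitted glucose ingestion during an OFTT
  )
  bs <- c(
    Gb = 91.76,         # mg/dL
    Ib = 25.49,         # pmol/L
    EGPb = 1.92,        # mg/kg/min
    NEFA0 = 400,        # umol/L
    TGb = 1100,         # umol/L
    V_NEFA = 0.16,      # L/kg
    BW = 70             # kg
  )
  fx <- .override(fx, fixed)
  fr <- .override(fr, free)
  bs <- .override(bs, basal)
  p <- structure(list(fixed = fx, free = fr, basal = bs),
                 class = "glunefa_params")
  if (is.na(p$free[["kuid1"]])) p$free[["kuid1"]] <- consistent_kuid1(p)
  derive_parameters(p)
}

.override <- function(base, upd) {
  if (is.null(upd)) return(base)
  upd <- unlist(upd)
  bad <- setdiff(names(upd), names(base))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  base[names(upd)] <- upd
  base
}

#' Update free or basal parameters of an existing set
#'
#' @param params a `glunefa_params` object.
#' @param free,basal,fixed named overrides, as in [default_parameters()].
#' @return the updated `glunefa_params` with derived quantities recomputed.
#' @export
update_parameters <- function(params, free = NULL, basal = NULL, fixed = NULL) {
  stopifnot(inherits(params, "glunefa_params"))
  params$fixed <- .override(params$fixed, fixed)
  params$free <- .override(params$free, free)
  params$basal <- .override(params$basal, basal)
  derive_parameters(params)
}

#' Derived basal-closure quantities
#'
#' Computes the fasting fixed point of the insulin subsystem, the basal
#' tissue-glucose mass, and `kegp1`, the EGP intercept chosen so that EGP
#' evaluated at the basal state equals `EGPb` exactly. `m6` is re-derived
#' from `m5`, the basal secretion and the basal hepatic extraction so that
#' hepatic extraction is anchored at `HEb` in the fasting state.
#'
#' @param params a `glunefa_params` object.
#' @return `params` with its `derived` element replaced.
#' @export
derive_parameters <- function(params) {
  fx <- params$fixed; fr <- params$free; bs <- params$basal
  validate_parameters(params)
  Gpb <- bs[["Gb"]] * fx[["VG"]]
  Ipb <- bs[["Ib"]] * fx[["VI"]]
  m3b <- fx[["HEb"]] * fx[["m1"]] / (1 - fx[["HEb"]])
  Ilb <- (fx[["m2"]] + fx[["m4"]]) * Ipb / fx[["m1"]]
  Sb <- (fx[["m1"]] + m3b) * Ilb - fx[["m2"]] * Ipb
  Ipob <- Sb / fx[["gamma_sec"]]
  m6 <- fx[["m5"]] * Sb + fx[["HEb"]]
  # basal tissue glucose: root of Gt' = 0 given Gp = Gpb
  Vmaxb <- fr[["kuid1"]] + fr[["kuid3"]] * bs[["Ib"]] / bs[["NEFA0"]]
  a <- fx[["k2"]]
  b <- Vmaxb + fx[["k2"]] * fr[["Km_uid"]] - fx[["k1"]] * Gpb
  cc <- -fx[["k1"]] * Gpb * fr[["Km_uid"]]
  Gtb <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  kegp1 <- bs[["EGPb"]] + fr[["kegp2"]] * Gpb + fr[["kegp3"]] * bs[["Ib"]] +
    fr[["kegp4"]] * Ipob - fr[["kegp5"]] * bs[["NEFA0"]]
  params$derived <- c(
    kegp1 = unname(kegp1), Gpb = unname(Gpb), Gtb = unname(Gtb),
    Ipb = unname(Ipb), Ilb = unname(Ilb), Sb = unname(Sb),
    Ipob = unname(Ipob), m3b = unname(m3b), m6 = unname(m6)
  )
  params
}

#' Basal-consistent insulin-independent part of Vmax
#'
#' Returns the value of `kuid1` for which insulin-dependent glucose uptake at
#' the fasting state balances the basal glucose fluxes
#' (`U_id,b = EGPb - Fcns - Eb`), so that the glucose subsystem starts at an
#' exact fixed point.
#'
#' @param params a `glunefa_params` object (its `kuid1` entry is ignored).
#' @return scalar `kuid1`, mg/kg/min.
#' @export
consistent_kuid1 <- function(params) {
  fx <- params$fixed; fr <- params$free; bs <- params$basal
  Gpb <- bs[["Gb"]] * fx[["VG"]]
  Eb <- fx[["ke1"]] * max(Gpb - fx[["ke2"]], 0)
  Uidb <- bs[["EGPb"]] - fx[["Fcns"]] - Eb
  if (Uidb <= 0) stop("EGPb must exceed Fcns + basal excretion")
  Gtb <- (fx[["k1"]] * Gpb - Uidb) / fx[["k2"]]
  Vmaxb <- Uidb * (fr[["Km_uid"]] + Gtb) / Gtb
  unname(Vmaxb - fr[["kuid3"]] * bs[["Ib"]] / bs[["NEFA0"]])
}

#' Validate a parameter set
#'
#' Checks the structural invariants: `pC < 0`, positive volumes and delay
#' rates, `kra3 > 0`, `gamma_inf != 0`, positive standard basal constants.
#'
#' @param params a `glunefa_params` object.
#' @return invisibly `TRUE`; stops with a message otherwise.
#' @export
validate_parameters <- function(params) {
  fx <- params$fixed; fr <- params$free; bs <- params$basal
  if (!is.na(fr[["pC"]]) && fr[["pC"]] >= 0)
    stop("pC must be negative (basal net NEFA uptake)")
  if (fr[["kra3"]] <= 0) stop("kra3 must be positive")
  if (fr[["gamma_inf"]] == 0) stop("gamma_inf must be nonzero")
  pos <- c(fx[["VG"]], fx[["VI"]], bs[["V_NEFA"]], bs[["BW"]],
           fr[["kd2"]], fr[["kd3"]], fr[["kd7"]], fr[["kn1"]],
           bs[["NEFA0"]], bs[["TGb"]])
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("volumes, delay rates and basal concentrations must be positive")
  invisible(TRUE)
}

#' Flatten a parameter set to the canonical numeric vector
#'
#' The ordering matches the compiled model; it is asserted against
#' `cpp_param_names()` in the test suite.
#'
#' @param params a `glunefa_params` object.
#' @return named numeric vector of length 61.
#' @export
as_param_vector <- function(params) {
  stopifnot(inherits(params, "glunefa_params"))
  v <- c(params$fixed[.fixed_param_names],
         params$free[.free_param_names],
         params$basal[.basal_param_names],
         params$derived[.derived_param_names])
  names(v) <- .glunefa_param_names
  v
}

#' Fasting initial state
#'
#' Builds the 18-component initial state: glucose and insulin states at the
#' fasting fixed point of the glucose-insulin core, delayed signals at their
#' sources, NEFA at `NEFA0` (deliberately not a steady state), and the
#' ingestion bookkeeping state at zero.
#'
#' @param params a `glunefa_params` object.
#' @param nefa0 optional override of the initial NEFA concentration, umol/L.
#' @return named numeric state vector.
#' @export
basal_state <- function(params, nefa0 = NULL) {
  d <- params$derived; bs <- params$basal
  if (is.null(nefa0)) nefa0 <- bs[["NEFA0"]]
  c(Qsto1 = 0, Qsto2 = 0, Qgut = 0,
    Gp = unname(d[["Gpb"]]), Gt = unname(d[["Gtb"]]),
    Ip = unname(d[["Ipb"]]), Il = unname(d[["Ilb"]]),
    I1 = unname(bs[["Ib"]]), Id = unname(bs[["Ib"]]),
    Ipo = unname(d[["Ipob"]]), Y = 0, X = 0,
    Id2 = unname(bs[["Ib"]]), Id3 = unname(bs[["Ib"]]),
    Id7 = unname(bs[["Ib"]]),
    Nd1 = unname(nefa0), NEFA = unname(nefa0), Qing = 0)
}

#' Balance the NEFA equation at the fasting state
#'
#' Returns a parameter set in which `pC` is replaced so that dNEFA/dt = 0 at
#' the fasting state (spillover influx exactly offset by uptake). Used to
#' construct full fixed-point scenarios in tests and analyses; note the
#' returned `pC` must still be negative for the set to be valid.
#'
#' @param params a `glunefa_params` object.
#' @return updated `glunefa_params`.
#' @export
balance_nefa <- function(params) {
  st <- basal_state(params)
  f <- nefa_rhs(st, params, tg = params$basal[["TGb"]])
  pC_new <- params$free[["pC"]] - f$rate
  update_parameters(params, free = list(pC = pC_new))
}

#' Read or write a parameter set as JSON
#'
#' The file format is a flat object `{name: {value, unit, role}}` with roles
#' `fixed`, `free`, `basal` or `derived`; derived entries are recomputed on
#' read.
#'
#' @param params a `glunefa_params` object.
#' @param path file path.
#' @return `read_parameters` returns a `glunefa_params`;
#'   `write_parameters` returns `path` invisibly.
#' @export
write_parameters <- function(params, path) {
  entry <- function(vals, role) {
    lapply(seq_along(vals), function(i)
      list(value = unname(vals[[i]]), unit = .param_unit(names(vals)[i]),
           role = role))
  }
  out <- c(
    stats::setNames(entry(params$fixed, "fixed"), names(params$fixed)),
    stats::setNames(entry(params$free, "free"), names(params$free)),
    stats::setNames(entry(params$basal, "basal"), names(params$basal)),
    stats::setNames(entry(params$derived, "derived"), names(params$derived))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  raw <- jsonlite::read_json(path)
  vals <- vapply(raw, function(e) as.numeric(e$value), numeric(1))
  roles <- vapply(raw, function(e) as.character(e$role), character(1))
  p <- structure(list(
    fixed = vals[roles == "fixed"][.fixed_param_names],
    free = vals[roles == "free"][.free_param_names],
    basal = vals[roles == "basal"][.basal_param_names]
  ), class = "glunefa_params")
  derive_parameters(p)
}

.param_units_table <- c(
  VG = "dL/kg", k1 = "1/min", k2 = "1/min", VI = "L/kg",
  m1 = "1/min", m2 = "1/min", m4 = "1/min", m5 = "min*kg/pmol", HEb = "-",
  kmax = "1/min", kabs = "1/min", kgri = "1/min", f_bio = "-",
  b_empt = "-", d_empt = "-", Fcns = "mg/kg/min", p2U = "1/min",
  ki = "1/min", Ksec = "pmol/kg per mg/dL", alpha_sec = "1/min",
  beta_sec = "pmol/kg/min per mg/dL", gamma_sec = "1/min",
  ke1 = "1/min", ke2 = "mg/kg", nd1_floor = "umol/L",
  pA = "1/min", pB = "1/(pmol/L)/min", pC = "umol/L/min",
  kegp2 = "mg/kg/min per mg/kg", kegp3 = "mg/kg/min per pmol/L",
  kegp4 = "mg/kg/min per pmol/kg", gamma_inf = "1/min",
  kegp5 = "mg/kg/min per umol/L", kuid1 = "mg/kg/min",
  kuid3 = "mg/kg/min per (pmol/L)/(umol/L)", Km_uid = "mg/kg",
  kra3 = "1/min", kd2 = "1/min", kd3 = "1/min", kd7 = "1/min",
  kn1 = "1/min", c_lpl = "umol/kg/min per umol/L", K_lpl = "pmol/L",
  spill_b = "-", K_sp = "pmol/L", D_oftt = "mg",
  Gb = "mg/dL", Ib = "pmol/L", EGPb = "mg/kg/min", NEFA0 = "umol/L",
  TGb = "umol/L", V_NEFA = "L/kg", BW = "kg",
  kegp1 = "mg/kg/min", Gpb = "mg/kg", Gtb = "mg/kg", Ipb = "pmol/kg",
  Ilb = "pmol/kg", Sb = "pmol/kg/min", Ipob = "pmol/kg", m3b = "1/min",
  m6 = "-"
)

.param_unit <- function(name) {
  u <- .param_units_table[name]
  if (is.na(u)) "-" else unname(u)
}

#' @export
print.glunefa_params <- function(x, ...) {
  cat("<glunefa_params>\n")
  cat("  free:   ", length(x$free), "calibrated parameters\n")
  cat("  basal:  Gb =", x$basal[["Gb"]], "mg/dL, Ib =", x$basal[["Ib"]],
      "pmol/L, NEFA0 =", x$basal[["NEFA0"]], "umol/L\n")
  cat("  derived: kegp1 =", signif(x$derived[["kegp1"]], 5), "mg/kg/min\n")
  invisible(x)
}
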