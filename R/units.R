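#' Unit conversions used throughout the model
#'
#' All insulin concentrations are handled internally in pmol/L, glucose
#' concentrations in mg/dL, glucose masses in mg/kg body weight, NEFA and
#' triglycerides in umol/L. The clamp literature reports insulin in uU/mL;
#' the conversion factor is 6.0 pmol/L per uU/mL.
#'
#' @param x numeric vector of values to convert.
#' @return converted numeric vector.
#' @name units
NULL

#' @rdname units
#' @export
uU_per_mL_to_pmol_per_L <- function(x) x * 6.0

#' @rdname units
#' @export
pmol_per_L_to_uU_per_mL <- function(x) x / 6.0

#' @rdname units
#' @export
mg_per_dL_to_mmol_per_L <- function(x) x / 18.016

#' @rdname units
#' @export
mmol_per_L_to_mg_per_dL <- function(x) x * 18.016
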