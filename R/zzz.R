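#' @useDynLib glunefa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"

.onLoad <- function(libname, pkgname) {
  # the R-side canonical parameter order must match the compiled layout
  stopifnot(identical(.glunefa_param_names, as.character(cpp_param_names())))
}
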