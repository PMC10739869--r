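# Vacuum permittivity, CODATA value. Shared by every module; never redefined.
.eps0 <- 8.8541878128e-12

#' Vacuum permittivity
#'
#' Returns the electric constant \eqn{\varepsilon_0} used throughout the
#' package, in farads per metre (CODATA 2018 value, 8.8541878128e-12 F/m).
#'
#' @return A length-one numeric, F/m.
#' @export
#' @examples
#' vacuum_permittivity()
vacuum_permittivity <- function() .eps0
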