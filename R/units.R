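#' @keywords internal
#' @useDynLib daemfit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

## Internal unit conventions:
##   energy        J mol^-1   (kJ mol^-1 only at I/O boundaries)
##   temperature   K          (degrees C only at I/O boundaries)
##   heating rate  K s^-1     (degrees C min^-1 only at I/O boundaries)
## so that R_GAS = 8.314 J mol^-1 K^-1 needs no unit juggling inside integrals.

#' Ideal gas constant, J mol^-1 K^-1
#' @export
R_GAS <- 8.314

#' Temperature unit conversions
#'
#' @param x numeric vector of temperatures.
#' @return Converted numeric vector.
#' @examples
#' celsius_to_kelvin(330)    # 603.15
#' kelvin_to_celsius(603.15) # 330
#' @export
celsius_to_kelvin <- function(x) x + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(x) x - 273.15

#' Heating-rate conversion from degrees C per minute to K per second
#'
#' @param x heating rate in C min^-1 (e.g. 5 for a slow-pyrolysis ramp).
#' @return Heating rate in K s^-1.
#' @export
c_per_min_to_k_per_s <- function(x) x / 60

## exponent clipping bound: exp(+-700) is the edge of double range;
## beyond it we prefer graceful under/overflow to non-finite propagation
.EXP_CLIP <- 700

.clipped_exp <- function(x) exp(pmin(x, .EXP_CLIP))

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
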