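#' Thermal energy at a given temperature
#'
#' Converts a temperature in degrees Celsius to the thermal energy scale
#' \eqn{k_B T} in pN nm, the natural unit for single-molecule force
#' spectroscopy. The default of 22 degrees C is the temperature at which
#' constant-force replication assays are typically run; experiments probing
#' pyrophosphate release are sometimes run warmer (e.g. 28 degrees C), so the
#' value is a parameter throughout the package rather than a constant.
#'
#' @param celsius temperature in degrees Celsius.
#' @return thermal energy in pN nm (about 4.075 pN nm at 22 degrees C).
#' @examples
#' kbt()      # 22 C
#' kbt(28)    # PPi-titration conditions
#' @export
kbt <- function(celsius = 22) {
  if (!is.numeric(celsius) || any(!is.finite(celsius))) {
    stop("'celsius' must be a finite number", call. = FALSE)
  }
  if (any(celsius < -273.15)) stop("temperature below absolute zero", call. = FALSE)
  # Boltzmann constant: 1.380649e-23 J/K = 1.380649e-2 pN nm / K
  1.380649e-2 * (celsius + 273.15)
}
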