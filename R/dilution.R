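#' Final concentration after adding a stimulant bolus
#'
#' Stimulants are prepared as concentrated stocks and added to the imaging
#' chamber as a fraction of the original bath volume, so the concentration
#' on the cells is the stock diluted by the combined volume. Adding a
#' fraction \eqn{f} of the original volume yields
#' \deqn{c_{final} = c_{stock} \cdot f / (1 + f).}
#' A 3x stock added at 50\% of the original volume therefore lands at one
#' third of the stock concentration (300 uM histamine -> 100 uM; 3 mM
#' Ca2+ -> 1 mM).
#'
#' @param stock stock concentration (any unit; the result carries the same
#'   unit).
#' @param added_volume_fraction volume added, as a fraction of the original
#'   bath volume; must be > 0.
#' @return final concentration in the units of `stock`.
#' @examples
#' final_concentration(300, 0.5)  # 100
#' final_concentration(3, 0.5)    # 1
#' @seealso [final_concentration_dilution()] for a plain dilution factor.
#' @export
final_concentration <- function(stock, added_volume_fraction) {
  if (!is.numeric(stock) || any(!is.finite(stock)) || any(stock < 0))
    stop_invalid("'stock' must be finite and >= 0")
  f <- added_volume_fraction
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0)
    stop_invalid("'added_volume_fraction' must be a single number > 0")
  stock * f / (1 + f)
}

#' Final concentration from a dilution factor
#'
#' Variant for reagents described by a plain dilution ratio, e.g. DMSO
#' stock (14.07 M) applied 1:10,000 gives 1.407 mM on the cells.
#'
#' @param stock stock concentration.
#' @param dilution_factor dilution factor d (> 0); the result is stock / d.
#' @return final concentration in the units of `stock`.
#' @export
final_concentration_dilution <- function(stock, dilution_factor) {
  if (!is.numeric(stock) || any(!is.finite(stock)) || any(stock < 0))
    stop_invalid("'stock' must be finite and >= 0")
  d <- dilution_factor
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0)
    stop_invalid("'dilution_factor' must be a single number > 0")
  stock / d
}
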