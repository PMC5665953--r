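#' Circulating antagonist concentration after head-hemolymph injection
#'
#' An injected bolus is diluted into the effective circulating volume:
#' `nM = 1000 * injected_conc_uM * injected_volume_ul /
#'       (injected_volume_ul + effective_dilution_volume_ul)`
#' (the factor 1000 converts micromolar to nanomolar). The effective
#' dilution volume is a property of the animal, so it can be calibrated
#' once from a known injection / circulating-concentration pair with
#' [calibrate_dilution_volume()] and then applied to any other compound:
#' calibrating on flupentixol (3 ul of 100 uM circulating at 350 nM) gives
#' an effective volume of about 854 ul, under which 3 ul of 2 uM epinastine
#' circulates at 7.0 nM.
#'
#' @param injected_volume_ul Injected volume in microliters (> 0).
#' @param injected_conc_uM Injected concentration in micromolar (> 0).
#' @param effective_dilution_volume_ul Effective circulating volume in
#'   microliters (> 0).
#' @return Circulating concentration in nM.
#' @examples
#' v <- calibrate_dilution_volume(3, 100, 350)
#' circulating_concentration(3, 2, v) # 7.0 nM
#' @export
circulating_concentration <- function(injected_volume_ul, injected_conc_uM,
                                      effective_dilution_volume_ul) {
  stopifnot(injected_volume_ul > 0, injected_conc_uM > 0,
            effective_dilution_volume_ul > 0)
  1000 * injected_conc_uM * injected_volume_ul /
    (injected_volume_ul + effective_dilution_volume_ul)
}

#' @rdname circulating_concentration
#' @param circulating_nM Observed circulating concentration in nM (> 0,
#'   below the undiluted injected concentration).
#' @return `calibrate_dilution_volume()` returns the effective dilution
#'   volume in microliters solving the formula above.
#' @export
calibrate_dilution_volume <- function(injected_volume_ul, injected_conc_uM,
                                      circulating_nM) {
  stopifnot(injected_volume_ul > 0, injected_conc_uM > 0, circulating_nM > 0)
  if (circulating_nM >= 1000 * injected_conc_uM) {
    abort("circulating concentration must be below the injected concentration")
  }
  1000 * injected_conc_uM * injected_volume_ul / circulating_nM - injected_volume_ul
}
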