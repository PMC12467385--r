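#' Convert between millimetres of mercury and pascal
#'
#' The model works in SI units (Pa) internally; clinical pressures are
#' quoted in mmHg. The conversion factor is 133.322 Pa per mmHg.
#'
#' @param p Numeric vector of pressures.
#' @return Numeric vector of converted pressures.
#' @examples
#' mmhg_to_pa(16)       # 2133.15 Pa
#' pa_to_mmhg(mmhg_to_pa(32.5))
#' @export
mmhg_to_pa <- function(p) p * 133.322

#' @rdname mmhg_to_pa
#' @export
pa_to_mmhg <- function(p) p / 133.322
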