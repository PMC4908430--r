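#' Physical constants and unit conversions
#'
#' The gas constant is carried in kcal units throughout the package so that
#' activation energies come out in kcal/mol, the unit in which peripheral-helix
#' stabilities are tabulated. The thermochemical calorie (4.184 J) is used for
#' conversion to SI units.
#'
#' @name constants
NULL

#' Gas constant in kcal mol^-1 K^-1
#' @export
R_KCAL <- 1.98720e-3

#' Thermal energy RT in kcal/mol
#'
#' @param temperature temperature in Kelvin (default 310.15 K, i.e. 37 degrees C)
#' @return RT in kcal/mol
#' @examples
#' rt_kcal()          # 0.61633 kcal/mol at 37 C
#' @export
rt_kcal <- function(temperature = 310.15) {
  stopifnot(is.numeric(temperature), temperature > 0)
  R_KCAL * temperature
}

#' Convert kcal/mol to kJ/mol
#'
#' Uses the thermochemical calorie: 1 kcal = 4.184 kJ exactly.
#'
#' @param x energy in kcal/mol
#' @return energy in kJ/mol
#' @examples
#' kcal_to_kJ(4)   # 16.736, i.e. ~17 kJ/mol
#' @export
kcal_to_kJ <- function(x) {
  stopifnot(is.numeric(x))
  x * 4.184
}

# Internal: run code with a temporarily fixed RNG state so that generators are
# pure functions of (parameters, seed) and never disturb the caller's stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
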