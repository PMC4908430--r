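#' Solution condition for a cleavage experiment
#'
#' The reference state is the one the rate comparisons are made at:
#' 37 degrees C (310.15 K), pH 7.5, 150 mM monovalent cation (K+ plus Na+),
#' and sub-millimolar to millimolar Mg2+.
#'
#' @param temperature Kelvin (> 0)
#' @param pH dimensionless
#' @param monovalent total K+ + Na+ in mM
#' @param mg Mg2+ in mM (>= 0); 0.3 and 1 are the typical working values
#' @return an object of class `reaction_condition`
#' @export
reaction_condition <- function(temperature = 310.15, pH = 7.5,
                               monovalent = 150, mg = 1) {
  stopifnot(is.numeric(temperature), temperature > 0,
            is.numeric(pH), is.numeric(monovalent), monovalent >= 0,
            is.numeric(mg), mg >= 0)
  structure(list(temperature = temperature, pH = pH,
                 monovalent = monovalent, mg = mg),
            class = "reaction_condition")
}

#' @export
print.reaction_condition <- function(x, ...) {
  cat(sprintf("<condition> %.2f K, pH %.2f, %g mM monovalent, %g mM Mg2+\n",
              x$temperature, x$pH, x$monovalent, x$mg))
  invisible(x)
}

#' Baseline model for uncatalyzed phosphodiester cleavage
#'
#' Two modes are supported. `"constant"` returns `k_ref` at every condition:
#' because all downstream regressions depend only on *differences* of
#' activation energy across constructs at a fixed condition, the absolute
#' baseline cancels and a declared constant is sufficient. `"parameterized"`
#' evaluates an empirical rate law around a reference condition: log-linear in
#' pH within the base-catalyzed regime (one decade per pH unit above
#' `ph_min`), Arrhenius in temperature with activation energy `ea_uncat`, and
#' a linear divalent-ion acceleration term. The default coefficients are a
#' package-bundled transcription of literature values for spontaneous RNA
#' transesterification (see `inst/extdata/uncat_baseline.yaml`); swap the
#' table to use a different calibration.
#'
#' @param mode `"constant"` or `"parameterized"`
#' @param k_ref baseline rate (s^-1) at the reference condition
#' @param coefficients named list of empirical coefficients (parameterized
#'   mode); see [default_uncat_coefficients()]
#' @return an object of class `uncat_model`
#' @export
uncat_model <- function(mode = c("constant", "parameterized"),
                        k_ref = 1e-9,
                        coefficients = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(k_ref), k_ref > 0)
  if (mode == "parameterized") {
    if (is.null(coefficients)) coefficients <- default_uncat_coefficients()
    needed <- c("ph_ref", "ph_min", "ph_slope", "temp_ref", "ea_uncat",
                "mg_alpha", "mg_ref")
    missing <- setdiff(needed, names(coefficients))
    if (length(missing)) {
      stop("parameterized baseline is missing coefficients: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(mode = mode, k_ref = k_ref, coefficients = coefficients),
            class = "uncat_model")
}

#' Default coefficient table for the parameterized baseline
#'
#' Read from the YAML file bundled with the package. Coefficients: `ph_ref`,
#' `ph_min` (lower edge of the base-catalyzed, hydroxide-first-order regime),
#' `ph_slope` (decades per pH unit), `temp_ref` (K), `ea_uncat` (kcal/mol,
#' Arrhenius slope of the background cleavage), `mg_alpha` (per mM, linear
#' divalent acceleration) and `mg_ref` (mM).
#'
#' @return named list of coefficients
#' @export
default_uncat_coefficients <- function() {
  path <- system.file("extdata", "uncat_baseline.yaml", package = "ribopinch")
  cfg <- yaml::read_yaml(path)
  cfg$coefficients
}

#' Evaluate the uncatalyzed cleavage rate at a condition
#'
#' @param model an [uncat_model()]
#' @param cond a [reaction_condition()]
#' @return baseline rate in s^-1 (always > 0)
#' @export
eval_k_uncat <- function(model, cond) {
  stopifnot(inherits(model, "uncat_model"), inherits(cond, "reaction_condition"))
  if (model$mode == "constant") return(model$k_ref)
  cf <- model$coefficients
  # pH term: first order in hydroxide above ph_min, flat below
  ph_eff <- max(cond$pH, cf$ph_min)
  ph_ref_eff <- max(cf$ph_ref, cf$ph_min)
  log10k <- log10(model$k_ref) + cf$ph_slope * (ph_eff - ph_ref_eff)
  # Arrhenius temperature scaling relative to the reference temperature
  log10k <- log10k + (cf$ea_uncat / (R_KCAL * log(10))) *
    (1 / cf$temp_ref - 1 / cond$temperature)
  # divalent-ion acceleration, linear in [Mg2+]
  log10k <- log10k + log10(1 + cf$mg_alpha * cond$mg) -
    log10(1 + cf$mg_alpha * cf$mg_ref)
  10^log10k
}

#' Apparent activation energy from a rate comparison
#'
#' `E_a = -R T ln(k_obs / k_uncat)`: the activation-energy-scale expression of
#' the rate enhancement of a ribozyme over background phosphodiester
#' cleavage. Negative values mean the ribozyme is faster than background.
#' Depends only on the rate ratio, so any common scale factor cancels.
#'
#' @param k_obs observed self-cleavage rate constant (s^-1, > 0)
#' @param k_uncat uncatalyzed baseline rate (s^-1, > 0)
#' @param cond a [reaction_condition()] supplying the temperature
#' @return apparent activation energy in kcal/mol
#' @export
apparent_Ea <- function(k_obs, k_uncat, cond = reaction_condition()) {
  stopifnot(inherits(cond, "reaction_condition"))
  if (any(k_obs <= 0) || any(k_uncat <= 0)) {
    stop("rates must be strictly positive", call. = FALSE)
  }
  -rt_kcal(cond$temperature) * log(k_obs / k_uncat)
}

#' Build a per-construct energy ledger
#'
#' Tabulates, for each construct, the observed rate, the baseline rate
#' evaluated at its condition, and the apparent activation energy, together
#' with the constants used, so every downstream regression is traceable to
#' its inputs.
#'
#' @param construct_id character vector of construct labels
#' @param k_obs observed rate constants (s^-1)
#' @param model an [uncat_model()]
#' @param cond a single [reaction_condition()] or a list of them (one per
#'   construct)
#' @return a `data.frame` with columns `construct_id`, `k_obs`, `k_uncat`,
#'   `temperature`, `pH`, `mg`, `E_a_apparent`, `R_kcal`, `baseline_mode`
#' @export
energy_ledger <- function(construct_id, k_obs, model,
                          cond = reaction_condition()) {
  stopifnot(length(construct_id) == length(k_obs))
  conds <- if (inherits(cond, "reaction_condition")) {
    rep(list(cond), length(k_obs))
  } else cond
  stopifnot(length(conds) == length(k_obs))
  rows <- lapply(seq_along(k_obs), function(i) {
    cc <- conds[[i]]
    ku <- eval_k_uncat(model, cc)
    data.frame(construct_id = construct_id[i],
               k_obs = k_obs[i],
               k_uncat = ku,
               temperature = cc$temperature,
               pH = cc$pH,
               mg = cc$mg,
               E_a_apparent = apparent_Ea(k_obs[i], ku, cc),
               R_kcal = R_KCAL,
               baseline_mode = model$mode,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
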