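#' Mg2+ titration of observed self-cleavage rates
#'
#' @param mg_conc Mg2+ concentrations in mM, strictly increasing, all > 0
#' @param k_obs observed rate constants in s^-1, all > 0, same length
#' @return an object of class `mg_titration`
#' @export
mg_titration <- function(mg_conc, k_obs) {
  mg_conc <- as.numeric(mg_conc)
  k_obs <- as.numeric(k_obs)
  if (length(mg_conc) != length(k_obs)) {
    stop("`mg_conc` and `k_obs` must have the same length", call. = FALSE)
  }
  if (length(mg_conc) < 3) {
    stop("need at least 3 titration points", call. = FALSE)
  }
  if (any(mg_conc <= 0) || any(k_obs <= 0)) {
    stop("concentrations and rates must be strictly positive", call. = FALSE)
  }
  if (any(diff(mg_conc) <= 0)) {
    stop("`mg_conc` must be strictly increasing", call. = FALSE)
  }
  structure(list(mg_conc = mg_conc, k_obs = k_obs), class = "mg_titration")
}

new_hill_fit <- function(n, k_max, K_half, method, saturation_flag,
                         scale = NA_real_, rss = NA_real_) {
  structure(
    list(n = unname(n), k_max = unname(k_max), K_half = unname(K_half),
         method = method, saturation_flag = saturation_flag,
         scale = unname(scale), rss = unname(rss)),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> method = %s: n = %.3f", x$method, x$n))
  if (is.finite(x$k_max)) cat(sprintf(", k_max = %.4g /s", x$k_max))
  if (is.finite(x$K_half)) cat(sprintf(", K_1/2 = %.4g mM", x$K_half))
  cat(sprintf("  [saturation %sobserved]\n", if (x$saturation_flag) "" else "not "))
  invisible(x)
}

# Warn when the titration visibly bends, i.e. the local log-log slope at the
# top of the concentration range has dropped well below the slope at the
# bottom -- the hallmark of approaching K_1/2.
warn_if_saturating <- function(lx, ly) {
  m <- length(lx)
  h <- max(3L, floor(m / 2))
  s_lo <- stats::coef(stats::lm(ly[1:h] ~ lx[1:h]))[2]
  s_hi <- stats::coef(stats::lm(ly[(m - h + 1):m] ~ lx[(m - h + 1):m]))[2]
  if (is.finite(s_lo) && is.finite(s_hi) && s_lo > 0 && s_hi < 0.9 * s_lo) {
    warning("titration bends at high [Mg2+]: data may approach saturation, ",
            "log-log slope underestimates the Hill coefficient", call. = FALSE)
  }
  invisible(NULL)
}

#' Hill coefficient from the log-log slope
#'
#' Ordinary least-squares slope of `log(k_obs)` versus `log([Mg2+])`. This
#' estimates the Hill coefficient exactly when the working concentrations sit
#' far below `K_1/2` (sub-saturation regime), where the Hill curve reduces to
#' a power law. A warning is issued when the data show curvature consistent
#' with approaching saturation.
#'
#' @param tit an [mg_titration()]
#' @return a `hill_fit` with `method = "loglog"`; `k_max` and `K_half` are
#'   undefined (`NA`) for this method
#' @export
fit_loglog_slope <- function(tit) {
  stopifnot(inherits(tit, "mg_titration"))
  lx <- log(tit$mg_conc)
  ly <- log(tit$k_obs)
  warn_if_saturating(lx, ly)
  fit <- stats::lm(ly ~ lx)
  new_hill_fit(n = stats::coef(fit)[2], k_max = NA_real_, K_half = NA_real_,
               method = "loglog", saturation_flag = FALSE,
               scale = exp(stats::coef(fit)[1]),
               rss = sum(stats::resid(fit)^2))
}

#' Nonlinear Hill fit of a Mg2+ titration
#'
#' Fits `k_obs = k_max [Mg]^n / (K_half^n + [Mg]^n)`. When the data constrain
#' saturation (the fitted `K_half` falls within the measured concentration
#' range) the full three-parameter fit is returned. When they do not, `k_max`
#' and `K_half` are individually unidentifiable -- only the lumped scale
#' `k_max / K_half^n` enters the likelihood -- so the model is refit in its
#' identifiable sub-saturation parameterization `log k = log(scale) + n log[Mg]`
#' and `k_max`/`K_half` are reported as `NA` with `saturation_flag = FALSE`.
#'
#' @param tit an [mg_titration()]
#' @param fix_n optionally fix the Hill coefficient and fit only the remaining
#'   parameters
#' @param weighting `"log"` (default; least squares on log rates, matching the
#'   log-log design) or `"linear"` (least squares on the rates themselves)
#' @return a `hill_fit` with `method = "nonlinear"`
#' @export
fit_hill_nonlinear <- function(tit, fix_n = NULL,
                               weighting = c("log", "linear")) {
  stopifnot(inherits(tit, "mg_titration"))
  weighting <- match.arg(weighting)
  mg <- tit$mg_conc
  k <- tit$k_obs
  d <- data.frame(mg = mg, lk = log(k), k = k)

  n_seeds <- if (is.null(fix_n)) c(0.5, 1, 1.5, 2) else fix_n
  K_seeds <- c(stats::median(mg), max(mg), 10 * max(mg), 100 * max(mg))
  starts <- list()
  for (nn in n_seeds) for (KK in K_seeds) {
    sc <- max(k) * (KK^nn + max(mg)^nn) / max(mg)^nn
    starts[[length(starts) + 1L]] <-
      if (is.null(fix_n)) list(lkmax = log(sc), lK = log(KK), n = nn)
      else list(lkmax = log(sc), lK = log(KK))
  }
  form <- if (weighting == "log") {
    if (is.null(fix_n)) {
      lk ~ lkmax + n * log(mg) - log(exp(lK)^n + mg^n)
    } else {
      substitute(lk ~ lkmax + n0 * log(mg) - log(exp(lK)^n0 + mg^n0),
                 list(n0 = fix_n))
    }
  } else {
    if (is.null(fix_n)) {
      k ~ exp(lkmax) * mg^n / (exp(lK)^n + mg^n)
    } else {
      substitute(k ~ exp(lkmax) * mg^n0 / (exp(lK)^n0 + mg^n0),
                 list(n0 = fix_n))
    }
  }
  lower <- if (is.null(fix_n)) c(-Inf, -Inf, 1e-3) else c(-Inf, -Inf)
  upper <- if (is.null(fix_n)) c(Inf, Inf, 10) else c(Inf, Inf)
  fit <- run_nls_starts(stats::as.formula(form), d, starts, lower, upper)
  if (is.null(fit)) {
    # the full model refuses to converge exactly when saturation is absent
    # and K_half/k_max are unidentifiable; the sub-saturation branch below
    # then carries the fit
    saturated <- FALSE
    K_hat <- Inf
    n_hat <- fix_n
  } else {
    cf <- coef(fit)
    K_hat <- exp(cf[["lK"]])
    n_hat <- if (is.null(fix_n)) cf[["n"]] else fix_n
    saturated <- max(mg) >= K_hat
  }

  if (!saturated) {
    # identifiability guard: refit the power law the data actually constrain
    if (!is.null(fix_n)) {
      lfit <- stats::lm(I(lk - fix_n * log(mg)) ~ 1, data = d)
      return(new_hill_fit(fix_n, NA_real_, NA_real_, "nonlinear", FALSE,
                          scale = exp(stats::coef(lfit)[1]),
                          rss = sum(stats::resid(lfit)^2)))
    }
    lfit <- stats::lm(lk ~ log(mg), data = d)
    return(new_hill_fit(stats::coef(lfit)[2], NA_real_, NA_real_,
                        "nonlinear", FALSE,
                        scale = exp(stats::coef(lfit)[1]),
                        rss = sum(stats::resid(lfit)^2)))
  }
  new_hill_fit(n_hat, exp(cf[["lkmax"]]), K_hat, "nonlinear", TRUE,
               scale = exp(cf[["lkmax"]]) / K_hat^n_hat,
               rss = deviance(fit))
}

#' Extrapolate k_obs along an unsaturated Hill curve
#'
#' In the sub-saturation regime the rate follows the power law
#' `k = k_ref * (c / c_ref)^n`. With a Hill coefficient of unity this is the
#' familiar linear extrapolation (e.g. 0.2 s^-1 at 1 mM predicts 2 s^-1 at
#' 10 mM Mg2+).
#'
#' @param k_ref rate constant at the reference concentration (s^-1)
#' @param conc_ref reference concentration (mM)
#' @param conc_new target concentration (mM)
#' @param n Hill coefficient (default 1)
#' @return predicted rate constant at `conc_new`
#' @export
extrapolate_kobs <- function(k_ref, conc_ref, conc_new, n = 1) {
  stopifnot(k_ref > 0, conc_ref > 0, all(conc_new > 0), n > 0)
  k_ref * (conc_new / conc_ref)^n
}
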