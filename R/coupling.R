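#' Assemble per-construct records for coupling analysis
#'
#' Builds the table consumed by the coupling regressions: one row per
#' construct with its peripheral-helix descriptors, condition, observed rate
#' and apparent activation energy. `stability` is a folding free energy in
#' kcal/mol (negative = stable); when `p12_bp` and `p12_bits` are both given
#' they must satisfy bits = 2 * bp.
#'
#' @param construct_id character labels
#' @param stability helix free energy (kcal/mol, typically <= 0) or an
#'   externally computed minimum-free-energy value per construct
#' @param k_obs observed rate constants (s^-1, > 0)
#' @param E_a_apparent apparent activation energies (kcal/mol); if missing,
#'   computed from `k_obs`, `k_uncat` and `cond`
#' @param p12_bp,p12_bits optional helix length descriptors
#' @param linker_class label of the connecting-strand variant (default
#'   `"pooled"`)
#' @param condition_id condition label
#' @param is_wt logical, marks the wild-type construct (excluded from line
#'   fits by default)
#' @param k_uncat,cond used only when `E_a_apparent` is missing
#' @return a `data.frame` of construct records
#' @export
construct_records <- function(construct_id, stability, k_obs,
                              E_a_apparent = NULL,
                              p12_bp = NA_integer_, p12_bits = NA_real_,
                              linker_class = "pooled",
                              condition_id = "condition",
                              is_wt = FALSE,
                              k_uncat = NULL, cond = reaction_condition()) {
  n <- length(construct_id)
  stopifnot(length(stability) == n, length(k_obs) == n, all(k_obs > 0))
  if (is.null(E_a_apparent)) {
    if (is.null(k_uncat)) {
      stop("supply either `E_a_apparent` or `k_uncat`", call. = FALSE)
    }
    E_a_apparent <- apparent_Ea(k_obs, k_uncat, cond)
  }
  d <- data.frame(construct_id = construct_id,
                  p12_bp = rep_len(p12_bp, n),
                  p12_bits = rep_len(p12_bits, n),
                  stability = stability,
                  linker_class = rep_len(linker_class, n),
                  condition_id = rep_len(condition_id, n),
                  k_obs = k_obs,
                  E_a_apparent = E_a_apparent,
                  is_wt = rep_len(is_wt, n),
                  stringsAsFactors = FALSE)
  bad <- !is.na(d$p12_bp) & !is.na(d$p12_bits) &
    abs(d$p12_bits - 2 * d$p12_bp) > 1e-9
  if (any(bad)) {
    stop("records with p12_bits != 2 * p12_bp: ",
         paste(d$construct_id[bad], collapse = ", "), call. = FALSE)
  }
  d
}

new_coupling_fit <- function(slope, intercept, r_squared, n_points, group,
                             model = "linear", breakpoint = NA_real_,
                             rss = NA_real_) {
  structure(
    list(slope = unname(slope),               # dE_a/dDeltaG, signed-energy axis
         slope_magnitude = unname(-slope),    # dE_a per kcal/mol of stabilization
         intercept = unname(intercept),
         breakpoint = unname(breakpoint),     # kcal/mol of stabilization
         r_squared = unname(r_squared),
         n_points = n_points, group = group, model = model,
         rss = unname(rss)),
    class = "coupling_fit"
  )
}

#' @export
print.coupling_fit <- function(x, ...) {
  cat(sprintf("<coupling_fit> [%s, %s] slope = %.3f (dE_a/dDeltaG), r^2 = %.3f, n = %d\n",
              x$group, x$model, x$slope, x$r_squared, x$n_points))
  if (is.finite(x$breakpoint)) {
    cat(sprintf("  plateau beyond %.2f kcal/mol of helix stabilization\n",
                x$breakpoint))
  }
  invisible(x)
}

drop_wt <- function(records, exclude_wt) {
  if (!exclude_wt) return(records)
  wt <- if ("is_wt" %in% names(records)) records$is_wt else FALSE
  wt <- wt | tolower(records$construct_id) %in% c("wt", "wild_type", "wildtype")
  records[!wt, , drop = FALSE]
}

#' Linear coupling between helix stability and activation energy
#'
#' Ordinary least squares of apparent activation energy on helix free energy.
#' On the signed free-energy axis (more negative = more stable) the expected
#' coupling slope is positive: a fraction of every kcal/mol of helix
#' stabilization reappears as activation-barrier lowering. Because linearity
#' holds only among constructs sharing a connecting-strand architecture,
#' per-linker-class fits can be requested; each group must then be internally
#' condition-matched. The wild-type construct is excluded by default.
#'
#' @param records data frame from [construct_records()] (columns `stability`,
#'   `E_a_apparent`, and optionally `linker_class`, `condition_id`, `is_wt`)
#' @param group_by_linker fit each `linker_class` separately
#' @param exclude_wt drop wild-type rows before fitting
#' @return a `coupling_fit`, or a named list of them when grouping
#' @export
linear_coupling_fit <- function(records, group_by_linker = FALSE,
                                exclude_wt = TRUE) {
  records <- drop_wt(records, exclude_wt)
  fit_one <- function(d, group) {
    if (nrow(d) < 3) {
      stop(sprintf("group '%s': need >= 3 records, got %d", group, nrow(d)),
           call. = FALSE)
    }
    if ("condition_id" %in% names(d) && length(unique(d$condition_id)) > 1) {
      stop(sprintf("group '%s' mixes conditions: %s", group,
                   paste(unique(d$condition_id), collapse = ", ")),
           call. = FALSE)
    }
    if (stats::sd(d$stability) == 0) {
      stop(sprintf("group '%s': stabilities are constant (rank-deficient fit)",
                   group), call. = FALSE)
    }
    fit <- stats::lm(E_a_apparent ~ stability, data = d)
    rss <- sum(stats::resid(fit)^2)
    tss <- sum((d$E_a_apparent - mean(d$E_a_apparent))^2)
    new_coupling_fit(slope = stats::coef(fit)[2],
                     intercept = stats::coef(fit)[1],
                     r_squared = if (tss > 0) 1 - rss / tss else 1,
                     n_points = nrow(d), group = group,
                     rss = rss)
  }
  if (!group_by_linker) return(fit_one(records, "pooled"))
  groups <- split(records, records$linker_class)
  stats::setNames(lapply(names(groups), function(g) fit_one(groups[[g]], g)),
                  names(groups))
}

# Stabilization magnitude: kcal/mol the helix contributes. Signed free
# energies (<= 0) are negated; tables already given as positive
# contributions pass through.
stab_magnitude <- function(stability) {
  if (all(stability <= 0)) -stability else stability
}

#' Hinge (segmented) fit: linear coupling with a plateau
#'
#' Fits the continuous two-segment model `E_a = a + b * min(m, theta)` where
#' `m` is the helix stabilization magnitude (kcal/mol): activation energy
#' falls linearly with stabilization until a breakpoint `theta` beyond which
#' extra helix stability no longer helps. The breakpoint is profiled over a
#' grid (default resolution 0.1 kcal/mol) spanning the observed range and the
#' total residual sum of squares is minimized. If the hinge does not improve
#' corrected AIC over the plain line, the linear fit is returned (with a
#' warning when the data cannot span a breakpoint at all).
#'
#' @param records data frame with `stability` and `E_a_apparent`
#' @param grid_res breakpoint grid resolution, kcal/mol
#' @param exclude_wt drop wild-type rows before fitting
#' @return a `coupling_fit` with `model = "hinge"` (and a `breakpoint`) or
#'   `model = "linear"` when the hinge is not supported
#' @export
hinge_fit <- function(records, grid_res = 0.1, exclude_wt = TRUE) {
  records <- drop_wt(records, exclude_wt)
  if (nrow(records) < 5) {
    stop("hinge fit needs >= 5 records spanning the candidate breakpoint",
         call. = FALSE)
  }
  m <- stab_magnitude(records$stability)
  y <- records$E_a_apparent
  n <- length(y)

  lin <- stats::lm(y ~ m)
  rss_lin <- sum(stats::resid(lin)^2)
  tss <- sum((y - mean(y))^2)
  r2_lin <- if (tss > 0) 1 - rss_lin / tss else 1

  lo <- ceiling(min(m) / grid_res) * grid_res
  hi <- floor(max(m) / grid_res) * grid_res
  if (hi - lo < grid_res) {
    warning("stability range too narrow to place a breakpoint; ",
            "falling back to the linear fit", call. = FALSE)
    return(new_coupling_fit(-stats::coef(lin)[2], stats::coef(lin)[1],
                            r2_lin, n, "pooled",
                            model = "linear", rss = rss_lin))
  }
  grid <- seq(lo, hi, by = grid_res)
  best <- NULL
  for (theta in grid) {
    z <- pmin(m, theta)
    if (stats::sd(z) == 0) next
    fit <- stats::lm(y ~ z)
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(theta = theta, fit = fit, rss = rss)
    }
  }
  # nested models: the hinge can never do worse than the line in rss; adopt
  # it only when it improves materially (ties go to the simpler model --
  # relevant for noiseless data where both rss are at numerical zero) and
  # AICc (3 vs 2 mean parameters) supports the extra parameter
  tie <- !is.null(best) &&
    (rss_lin - best$rss) <= 1e-10 * (1 + rss_lin)
  if (is.null(best) || tie ||
      aicc(best$rss, n, 3L) >= aicc(rss_lin, n, 2L)) {
    return(new_coupling_fit(-stats::coef(lin)[2], stats::coef(lin)[1],
                            r2_lin, n, "pooled",
                            model = "linear", rss = rss_lin))
  }
  cf <- stats::coef(best$fit)
  r2 <- if (tss > 0) 1 - best$rss / tss else 1
  new_coupling_fit(slope = cf[2],       # per unit magnitude; sign flip below
                   intercept = cf[1],
                   r_squared = r2, n_points = n, group = "pooled",
                   model = "hinge", breakpoint = best$theta,
                   rss = best$rss) -> out
  # slope bookkeeping: cf[2] is dE_a/dm (magnitude axis, expected negative);
  # the signed-energy-axis slope is its negation
  out$slope_magnitude <- unname(cf[2])
  out$slope <- unname(-cf[2])
  out
}

#' Information-activity relationship
#'
#' Ordinary least squares of `log10(k_obs)` on helix information content in
#' bits; the headline statistic is the fold-change in rate per 10 additional
#' bits (i.e. per 5 base pairs), `10^(10 * slope)`.
#'
#' @param records data frame with `p12_bits` and `k_obs`
#' @param exclude_wt drop wild-type rows before fitting
#' @return list with `fold_per_10bits`, `slope_log10_per_bit`, `r_squared`,
#'   `n_points`
#' @export
info_activity_fit <- function(records, exclude_wt = TRUE) {
  records <- drop_wt(records, exclude_wt)
  d <- records[!is.na(records$p12_bits), , drop = FALSE]
  if (nrow(d) < 3) stop("need >= 3 records with information content", call. = FALSE)
  if (any(d$k_obs <= 0)) stop("k_obs must be positive", call. = FALSE)
  fit <- stats::lm(log10(k_obs) ~ p12_bits, data = d)
  slope <- stats::coef(fit)[2]
  y <- log10(d$k_obs)
  tss <- sum((y - mean(y))^2)
  rss <- sum(stats::resid(fit)^2)
  list(fold_per_10bits = unname(10^(10 * slope)),
       slope_log10_per_bit = unname(slope),
       r_squared = if (tss > 0) 1 - rss / tss else 1,
       n_points = nrow(d))
}
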