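#' Dimer-to-total ratio of a densitometry lane
#'
#' The redox-state readout of non-reducing gels: dimer band intensity divided
#' by dimer plus monomer intensity.
#'
#' @param monomer,dimer Band intensities in arbitrary units (>= 0); a lane
#'   with both zero is unquantifiable.
#' @return Ratio in \[0, 1\], vectorized.
#' @export
dimer_total_ratio <- function(monomer, dimer) {
  if (any(monomer < 0) || any(dimer < 0)) stop("band intensities must be >= 0")
  total <- monomer + dimer
  if (any(total == 0)) stop("unquantifiable lane: monomer and dimer both zero")
  dimer / total
}

#' Fit a single-exponential decay to monomer band intensities
#'
#' Least-squares fit of `monomer(t) = amplitude * exp(-k_obs * t) + offset` to
#' the time-dependent disappearance of the reduced (monomer) band at one
#' oxidant concentration. A free offset is retained because gels typically
#' show residual unreacted monomer. Fitting is by Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]) with an analytic Jacobian, which also handles the
#' noise-free (zero-residual) case. The reported standard error of `k_obs` is
#' a heteroscedasticity-robust (HC3) sandwich estimate, since gel intensities
#' carry multiplicative noise. Degenerate inputs (no decay) return `k_obs = 0`
#' flagged `"degenerate"`; a fit wandering to negative `k_obs` is clamped to
#' zero and flagged `"clamped_negative"`; a noisy slow decay that defeats the
#' free-offset parameterization is refit with the offset fixed at zero and
#' flagged `"offset_dropped"`.
#'
#' @param time Times in seconds (>= 3 distinct values spanning > 0 s).
#' @param monomer Monomer band intensities (arbitrary units >= 0).
#' @param offset Logical; fit a free plateau term (default TRUE). With
#'   `FALSE` the offset is fixed at zero.
#' @return Object of class `"pfo_fit"`: list with `k_obs` (s^-1), `amplitude`,
#'   `offset`, `se` (robust SE of `k_obs`), `n`, `fitted`, `residuals`,
#'   `flags`, and the `nls.lm` object in `$fit` (NULL when degenerate).
#' @export
#' @examples
#' t <- c(0, 5, 10, 20, 30)
#' fit_monomer_decay(t, 100 * exp(-0.1 * t))
fit_monomer_decay <- function(time, monomer, offset = TRUE) {
  stopifnot(length(time) == length(monomer))
  if (length(unique(time)) < 3L) stop("need >= 3 distinct time points")
  if (diff(range(time)) <= 0) stop("time points must span > 0 s")
  if (any(monomer < 0)) stop("monomer intensities must be >= 0")
  ord <- order(time)
  time <- time[ord]; monomer <- monomer[ord]

  flags <- character()
  span <- max(monomer) - min(monomer)
  if (span <= sqrt(.Machine$double.eps) * max(abs(monomer), 1)) {
    # constant signal: no decay to fit
    out <- list(k_obs = 0, amplitude = 0, offset = mean(monomer),
                se = NA_real_, n = length(time),
                fitted = rep(mean(monomer), length(time)),
                residuals = monomer - mean(monomer),
                flags = "degenerate", fit = NULL)
    return(structure(out, class = "pfo_fit"))
  }

  # starting values from a crude log-linear slope above the apparent plateau
  off0 <- if (offset) max(min(monomer) - 0.05 * span, 0) else 0
  pos <- monomer - off0 > span * 1e-3
  k0 <- if (sum(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(monomer[pos] - off0) ~ time[pos]))[2]
    max(-sl, 1e-6)
  } else 1 / diff(range(time))
  a0 <- max(monomer) - off0

  model <- function(p) {
    if (offset) p["a"] * exp(-p["k"] * time) + p["c0"]
    else p["a"] * exp(-p["k"] * time)
  }
  jacobian <- function(p) {
    e <- exp(-p["k"] * time)
    J <- cbind(a = e, k = -p["a"] * time * e)
    if (offset) J <- cbind(J, c0 = rep(1, length(time)))
    J
  }
  run_lm <- function(start) {
    minpack.lm::nls.lm(par = start, fn = function(p) monomer - model(p),
                       control = minpack.lm::nls.lm.control(maxiter = 500,
                                                            maxfev = 5000))
  }
  start <- if (offset) c(a = a0, k = unname(k0), c0 = off0) else c(a = a0, k = unname(k0))
  fit <- run_lm(start)
  # nls.lm info codes 1:4 indicate convergence by one of its criteria
  if (!fit$info %in% 1:4) {
    # a free offset can leave a flat valley on noisy slow decays; retry fixed
    if (offset) {
      offset <- FALSE
      fit <- run_lm(c(a = a0 + off0, k = unname(k0)))
      flags <- c(flags, "offset_dropped")
    }
    if (!fit$info %in% 1:4) {
      stop("exponential fit failed to converge: ", fit$message)
    }
  }
  cf <- fit$par
  k <- unname(cf["k"])
  # heteroscedasticity-robust (HC3 sandwich) SE: gel intensity noise is
  # multiplicative, so the classical homoscedastic SE under-covers
  se <- tryCatch({
    J <- jacobian(cf)
    r <- monomer - model(cf)
    XtXi <- solve(crossprod(J))
    h <- pmin(rowSums((J %*% XtXi) * J), 0.9999)
    covm <- XtXi %*% crossprod(J * (r / (1 - h)), J * (r / (1 - h))) %*% XtXi
    sqrt(covm["k", "k"])
  }, error = function(e) NA_real_)
  if (k < 0) {
    k <- 0
    flags <- c(flags, "clamped_negative")
  }
  fitted_vals <- model(cf)
  structure(list(
    k_obs = k,
    amplitude = unname(cf["a"]),
    offset = if (offset) unname(cf["c0"]) else 0,
    se = se, n = length(time),
    fitted = fitted_vals, residuals = monomer - fitted_vals,
    flags = flags, fit = fit), class = "pfo_fit")
}

#' @export
print.pfo_fit <- function(x, ...) {
  cat("Pseudo-first-order exponential fit\n")
  cat(sprintf("  k_obs = %.4g s^-1 (SE %.2g), amplitude %.4g, offset %.4g, n = %d\n",
              x$k_obs, x$se, x$amplitude, x$offset, x$n))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.pfo_fit <- function(object, ...) {
  c(k_obs = object$k_obs, amplitude = object$amplitude, offset = object$offset)
}

#' Second-order rate constant from k_obs versus oxidant concentration
#'
#' Linear regression of observed pseudo-first-order constants on the oxidant
#' concentration. The slope is the second-order rate constant; the intercept
#' is reported as a background first-order loss (e.g. autoxidation) rather
#' than forced to zero. When per-point standard errors are supplied the
#' regression is inverse-variance weighted.
#'
#' @param oxidant_conc Oxidant concentrations in mol/L (>= 3 distinct values).
#' @param k_obs Pseudo-first-order constants in s^-1.
#' @param k_obs_se Optional standard errors of `k_obs` for weighting.
#' @param temperature Temperature in degC recorded on the result.
#' @param reactant_pair Label recorded on the result.
#' @return A [rate_constant()] of order `"second"`; `$details` holds the
#'   intercept, its SE, the regression `r.squared` and the `lm` fit.
#' @export
second_order_from_kobs <- function(oxidant_conc, k_obs, k_obs_se = NULL,
                                   temperature = NA_real_,
                                   reactant_pair = NA_character_) {
  stopifnot(length(oxidant_conc) == length(k_obs))
  if (length(unique(oxidant_conc)) < 3L) {
    stop("insufficient design: need >= 3 distinct oxidant concentrations")
  }
  # inverse-variance weights only when all SEs are informative; near-zero
  # SEs (noise-free fits) degenerate numerically, so fall back to OLS there
  w <- if (!is.null(k_obs_se) && all(is.finite(k_obs_se)) &&
           all(k_obs_se > 1e-8 * max(k_obs))) 1 / k_obs_se^2
  fit <- stats::lm(k_obs ~ oxidant_conc, weights = w)
  cf <- lm_summary_quiet(fit)$coefficients
  if (!"oxidant_conc" %in% rownames(cf) || anyNA(cf["oxidant_conc", ])) {
    w <- NULL
    fit <- stats::lm(k_obs ~ oxidant_conc)
    cf <- lm_summary_quiet(fit)$coefficients
  }
  slope <- cf["oxidant_conc", "Estimate"]
  se <- cf["oxidant_conc", "Std. Error"]
  if (!is.null(w)) {
    # with known per-point variances the propagation-based slope SE is
    # better calibrated than the residual-based one at few concentrations;
    # report the more conservative of the two
    xw <- sum(w * oxidant_conc) / sum(w)
    se_prop <- sqrt(1 / sum(w * (oxidant_conc - xw)^2))
    se <- max(se, se_prop)
  }
  flags <- character()
  if (slope < 0) {
    flags <- "clamped_negative"
    slope <- 0
  }
  rate_constant(slope, se = se,
                order = "second", temperature = temperature,
                reactant_pair = reactant_pair, flags = flags,
                details = list(intercept = cf["(Intercept)", "Estimate"],
                               intercept_se = cf["(Intercept)", "Std. Error"],
                               r_squared = lm_summary_quiet(fit)$r.squared,
                               fit = fit))
}

#' Single-time-point rate-constant estimate from a dimer fraction
#'
#' Initial-rate estimate used when only one time point is available (the
#' low-reactivity Prx4 situation): the oxidation velocity is approximated as
#' `v = dimer_fraction * enzyme_conc / time` and the second-order constant as
#' `k = v / (enzyme_conc * oxidant_conc)`. The initial-rate assumption is
#' strained once an appreciable share of the enzyme has reacted, so estimates
#' with `dimer_fraction > 0.2` are flagged `"unreliable"`.
#'
#' @param dimer_fraction Fraction of enzyme oxidized at `time`, in \[0, 1).
#' @param enzyme_conc Enzyme concentration, mol/L (> 0).
#' @param oxidant_conc Oxidant concentration, mol/L (> 0).
#' @param time Reaction time, s (> 0).
#' @param temperature,reactant_pair Recorded on the result.
#' @return A [rate_constant()] of order `"second"`.
#' @export
#' @examples
#' single_point_k(0.02, 20e-6, 20e-6, 10)  # 100 M^-1 s^-1
single_point_k <- function(dimer_fraction, enzyme_conc, oxidant_conc, time,
                           temperature = NA_real_,
                           reactant_pair = NA_character_) {
  if (dimer_fraction < 0 || dimer_fraction >= 1) {
    stop("dimer_fraction must be in [0, 1); complete conversion cannot be inverted")
  }
  stopifnot(enzyme_conc > 0, oxidant_conc > 0, time > 0)
  v <- dimer_fraction * enzyme_conc / time
  k <- v / (enzyme_conc * oxidant_conc)
  flags <- if (dimer_fraction > 0.2) "unreliable" else character()
  rate_constant(k, order = "second", temperature = temperature,
                reactant_pair = reactant_pair, flags = flags,
                details = list(v = v, dimer_fraction = dimer_fraction))
}

#' Protein amount from a band-intensity standard curve
#'
#' Inverts a recombinant-protein standard curve (band intensity against loaded
#' ng) to express an endogenous band as fmol per ug tissue loaded:
#' `ng = (intensity - intercept) / slope`, `fmol = ng * 1e6 / MW`, divided by
#' the tissue amount loaded. Intensities outside the calibrated range are
#' still inverted but flagged extrapolated.
#'
#' @param intensity Band intensity (same units as the standard curve).
#' @param slope Standard-curve slope, intensity per ng (> 0).
#' @param intercept Standard-curve intercept (default 0).
#' @param molecular_weight Protein molecular weight in g/mol.
#' @param tissue_loaded_ug Tissue protein loaded in the lane, ug (> 0).
#' @param calibrated_range Optional numeric length-2 intensity range covered
#'   by the standards; outside it the result is flagged.
#' @return List with `fmol_per_ug`, `ng`, `extrapolated`.
#' @export
quantify_from_standard_curve <- function(intensity, slope, intercept = 0,
                                         molecular_weight, tissue_loaded_ug,
                                         calibrated_range = NULL) {
  if (slope <= 0) stop("invalid standard curve: slope must be positive")
  stopifnot(molecular_weight > 0, tissue_loaded_ug > 0)
  ng <- (intensity - intercept) / slope
  if (any(ng < 0)) stop("intensity below the curve intercept: negative amount")
  extrapolated <- if (is.null(calibrated_range)) {
    rep(FALSE, length(intensity))
  } else {
    intensity < min(calibrated_range) | intensity > max(calibrated_range)
  }
  fmol <- ng * 1e6 / molecular_weight
  list(fmol_per_ug = fmol / tissue_loaded_ug, ng = ng,
       extrapolated = extrapolated)
}

#' Full blot-kinetics pipeline: densitometry table to second-order constant
#'
#' Groups a densitometry table by oxidant concentration, fits the
#' single-exponential monomer decay at each concentration
#' ([fit_monomer_decay()]), and regresses the resulting `k_obs` values on
#' concentration ([second_order_from_kobs()]). Warns when the oxidant excess
#' over the enzyme is less than 4-fold anywhere in the design, since the
#' pseudo-first-order treatment is then approximate.
#'
#' @param lanes data.frame with columns `oxidant_conc` (mol/L), `time_s`,
#'   `monomer` (as produced by [gen_blot_timecourse()] or
#'   [read_densitometry()]).
#' @param enzyme_conc Enzyme concentration in mol/L, used only for the excess
#'   warning (NA to skip).
#' @param offset Passed to [fit_monomer_decay()].
#' @param temperature,reactant_pair Recorded on the result.
#' @return A [rate_constant()]; `$details$per_conc` holds the per-concentration
#'   `k_obs` table.
#' @export
blot_rate_constant <- function(lanes, enzyme_conc = NA_real_, offset = TRUE,
                               temperature = NA_real_,
                               reactant_pair = NA_character_) {
  need <- c("oxidant_conc", "time_s", "monomer")
  if (!all(need %in% names(lanes))) {
    stop("lanes must have columns ", paste(need, collapse = ", "))
  }
  concs <- sort(unique(lanes$oxidant_conc))
  if (is.finite(enzyme_conc) && any(concs < 4 * enzyme_conc)) {
    warning("oxidant excess over enzyme is < 4-fold for some concentrations; ",
            "pseudo-first-order treatment is approximate there")
  }
  per <- lapply(concs, function(cc) {
    sub <- lanes[lanes$oxidant_conc == cc, ]
    fit <- fit_monomer_decay(sub$time_s, sub$monomer, offset = offset)
    data.frame(oxidant_conc = cc, k_obs = fit$k_obs, k_obs_se = fit$se)
  })
  per <- do.call(rbind, per)
  k <- second_order_from_kobs(per$oxidant_conc, per$k_obs,
                              k_obs_se = per$k_obs_se,
                              temperature = temperature,
                              reactant_pair = reactant_pair)
  k$details$per_conc <- per
  k
}
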