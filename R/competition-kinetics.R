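#' Initial rate from a concentration time course
#'
#' Least-squares slope of concentration against time over an initial window
#' (default the first 30 s, where NADPH-coupled assays are close to linear).
#' The rate is reported as a positive consumption velocity; a window fit with
#' `r^2 < 0.98` is flagged nonlinear.
#'
#' @param time,conc Time course (s, mol/L).
#' @param window Numeric length-2 window in seconds (default `c(0, 30)`).
#' @return Object of class `"initial_rate"`: `v0` (mol/L/s, >= 0),
#'   `r_squared`, `window`, `n`, `flags`.
#' @export
initial_rate <- function(time, conc, window = c(0, 30)) {
  stopifnot(length(time) == length(conc), window[2] > window[1])
  sel <- time >= window[1] & time <= window[2]
  if (sum(sel) < 4L) stop("invalid window: need >= 4 points inside it")
  fit <- stats::lm(conc[sel] ~ time[sel])
  v0 <- -unname(stats::coef(fit)[2])
  r2 <- lm_summary_quiet(fit)$r.squared
  flags <- character()
  if (v0 < 0) {
    v0 <- 0
    flags <- c(flags, "clamped_negative")
  }
  if (v0 > 0 && is.finite(r2) && r2 < 0.98) {
    warning("initial-rate window is nonlinear (r^2 = ", signif(r2, 3), ")")
    flags <- c(flags, "nonlinear")
  }
  structure(list(v0 = v0, r_squared = r2, window = window, n = sum(sel),
                 flags = flags), class = "initial_rate")
}

#' @export
print.initial_rate <- function(x, ...) {
  cat(sprintf("Initial rate: v0 = %.4g M s^-1 over [%g, %g] s (r^2 = %.4f, n = %d)\n",
              x$v0, x$window[1], x$window[2], x$r_squared, x$n))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Bimolecular rate constant from an initial-rate series
#'
#' For initial rates measured at a fixed enzyme concentration over several
#' substrate concentrations, `v0 = k * E * [S]`, so the second-order constant
#' is the regression slope of `v0` against `[S]` divided by `E`.
#'
#' @param substrate_conc Substrate concentrations, mol/L (>= 3 distinct
#'   levels).
#' @param v0 Initial rates, mol/L/s.
#' @param enzyme_conc Fixed enzyme concentration, mol/L (> 0).
#' @param temperature,reactant_pair Recorded on the result.
#' @return A [rate_constant()] of order `"second"`.
#' @export
bimolecular_k_from_rates <- function(substrate_conc, v0, enzyme_conc,
                                     temperature = NA_real_,
                                     reactant_pair = NA_character_) {
  if (enzyme_conc <= 0) stop("enzyme concentration must be positive")
  if (length(unique(substrate_conc)) < 3L) {
    stop("insufficient design: need >= 3 substrate levels")
  }
  fit <- stats::lm(v0 ~ substrate_conc)
  cf <- lm_summary_quiet(fit)$coefficients
  slope <- cf["substrate_conc", "Estimate"]
  flags <- character()
  if (slope < 0) {
    slope <- 0
    flags <- "clamped_negative"
  }
  rate_constant(slope / enzyme_conc,
                se = cf["substrate_conc", "Std. Error"] / enzyme_conc,
                order = "second", temperature = temperature,
                reactant_pair = reactant_pair, flags = flags,
                details = list(fit = fit))
}

#' Competitor rate constant from signal suppression
#'
#' Competition-kinetics inversion: two scavengers compete for one oxidant, one
#' with a known rate constant (`k_ref` at `ref_conc`), and the observed signal
#' of the monitored channel retains a fraction `f` of its value when the other
#' scavenger is present. Under flux partitioning:
#'
#' * monitored = `"competitor"` (the unknown's own product is measured, e.g.
#'   tryptophan-oxidation products suppressed by added peroxiredoxin):
#'   `f = k_c C / (k_c C + k_ref R)`, giving
#'   `k_c = f/(1-f) * k_ref * R / C`.
#' * monitored = `"reference"` (the known enzyme's signal is suppressed by the
#'   unknown competitor): `k_c = (1-f)/f * k_ref * R / C`.
#'
#' `f = 1` (no suppression) leaves the unknown below detection; the result is
#' then flagged `"upper_bound"` with value `k_ref * R / C` (the constant that
#' would have produced 50 percent suppression). `f = 0` is rejected.
#' Uncertainty in `f` propagates to the estimate by the delta method.
#'
#' @param observed_fraction Signal with competitor divided by signal without,
#'   in (0, 1\].
#' @param k_ref Known rate constant, M^-1 s^-1.
#' @param ref_conc Concentration of the known scavenger, mol/L.
#' @param comp_conc Concentration of the unknown scavenger, mol/L.
#' @param monitored Which channel the fraction refers to (see above).
#' @param fraction_se Optional standard error of `observed_fraction`.
#' @param temperature,reactant_pair Recorded on the result.
#' @return A [rate_constant()] of order `"second"`.
#' @export
#' @examples
#' competitor_k_from_suppression(0.12, k_ref = 2e7, ref_conc = 4e-6,
#'                               comp_conc = 20e-6)
competitor_k_from_suppression <- function(observed_fraction, k_ref, ref_conc,
                                          comp_conc,
                                          monitored = c("competitor", "reference"),
                                          fraction_se = NA_real_,
                                          temperature = NA_real_,
                                          reactant_pair = NA_character_) {
  monitored <- match.arg(monitored)
  stopifnot(k_ref > 0, ref_conc > 0, comp_conc > 0)
  f <- observed_fraction
  if (f <= 0) stop("zero observed fraction gives an unbounded estimate; rejected")
  if (f > 1) stop("observed fraction must be in (0, 1]")
  base <- k_ref * ref_conc / comp_conc
  if (f == 1) {
    return(rate_constant(base, order = "second", flags = "upper_bound",
                         temperature = temperature,
                         reactant_pair = reactant_pair,
                         details = list(monitored = monitored, fraction = 1)))
  }
  if (monitored == "competitor") {
    k <- f / (1 - f) * base
    deriv <- base / (1 - f)^2
  } else {
    k <- (1 - f) / f * base
    deriv <- -base / f^2
  }
  se <- if (is.finite(fraction_se)) abs(deriv) * fraction_se else NA_real_
  rate_constant(k, se = se, order = "second", temperature = temperature,
                reactant_pair = reactant_pair,
                details = list(monitored = monitored, fraction = f))
}

#' Depletion-aware competition inversion from a product yield
#'
#' Refinement of the flux-partitioning inversion for assays in which the
#' reference scavenger has no reductant and is consumed 1:1 by the oxidant
#' while the competitor is catalytic. Integrating the two parallel channels
#' gives the conservation relation
#' `Prod + P0 * (1 - exp(-k_ref * Prod / (k_c * C))) = H0`, where `Prod` is
#' the final competitor-product concentration, `P0` the initial reference
#' scavenger, `C` the competitor and `H0` the initial oxidant. The relation is
#' solved for `k_c` by bracketed root finding. As `P0` consumption becomes
#' negligible the estimate converges to [competitor_k_from_suppression()].
#'
#' @param product_conc Final product concentration, mol/L (must be < oxidant0).
#' @param oxidant0 Initial oxidant concentration, mol/L.
#' @param k_ref Reference scavenger rate constant, M^-1 s^-1.
#' @param ref_conc Initial reference scavenger concentration `P0`, mol/L.
#' @param comp_conc Competitor concentration `C` (catalytic), mol/L.
#' @param bracket Search bracket for `k_c` in M^-1 s^-1.
#' @param temperature,reactant_pair Recorded on the result.
#' @return A [rate_constant()] of order `"second"`.
#' @export
refine_by_depletion <- function(product_conc, oxidant0, k_ref, ref_conc,
                                comp_conc, bracket = c(1e1, 1e12),
                                temperature = NA_real_,
                                reactant_pair = NA_character_) {
  stopifnot(oxidant0 > 0, k_ref > 0, ref_conc > 0, comp_conc > 0)
  if (product_conc >= oxidant0) {
    stop("impossible observation: product yield >= initial oxidant")
  }
  if (product_conc <= 0) {
    return(rate_constant(0, order = "second", temperature = temperature,
                         reactant_pair = reactant_pair,
                         flags = "no_product"))
  }
  if (product_conc + ref_conc < oxidant0) {
    stop("impossible observation: product plus reference capacity cannot ",
         "account for the oxidant consumed")
  }
  g <- function(log10k) {
    k <- 10^log10k
    product_conc +
      ref_conc * (1 - exp(-k_ref * product_conc / (k * comp_conc))) - oxidant0
  }
  lo <- log10(bracket[1]); hi <- log10(bracket[2])
  # g is decreasing in k: small k -> reference fully consumed -> g > 0
  if (g(lo) < 0 || g(hi) > 0) {
    stop("no root in bracket; widen `bracket`")
  }
  root <- stats::uniroot(g, c(lo, hi), tol = 1e-12)
  rate_constant(10^root$root, order = "second", temperature = temperature,
                reactant_pair = reactant_pair,
                details = list(yield_fraction = product_conc / oxidant0,
                               uniroot = root[c("f.root", "iter")]))
}
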