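#' Hydroperoxide concentration trace from a 340 nm progression curve
#'
#' Converts an NADPH-coupled progression curve (absorbance at 340 nm against
#' time) into the remaining hydroperoxide concentration, assuming 1:1
#' NADPH:ROOH stoichiometry through the glutathione-reductase couple:
#' `[ROOH](t) = rooh0 - (A(0) - A(t)) / (epsilon * path)`, clipped at zero.
#' The NADPH coefficient is 6220 M^-1 cm^-1.
#'
#' @param time Times in seconds, strictly increasing.
#' @param a340 Absorbance values at 340 nm, non-increasing within noise.
#' @param rooh0 Initial hydroperoxide concentration in mol/L (> 0).
#' @param path_cm Optical path length, cm.
#' @param noise_tol Largest tolerated absorbance *increase* between the trace
#'   minimum-so-far and a later point before the trace is declared invalid
#'   (default 0.01 AU).
#' @return data.frame with columns `time_s` and `conc` (mol/L).
#' @export
substrate_trace <- function(time, a340, rooh0, path_cm = 1, noise_tol = 0.01) {
  stopifnot(length(time) == length(a340), rooh0 > 0, path_cm > 0)
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  if (any(a340 - cummin(a340) > noise_tol)) {
    stop("absorbance increases beyond noise tolerance: invalid trace")
  }
  eps <- lookup_epsilon("NADPH")
  consumed <- (a340[1] - a340) / (eps * path_cm)
  data.frame(time_s = time, conc = pmax(rooh0 - consumed, 0))
}

#' Pseudo-first-order rate constant from a log-linear window
#'
#' Minus the least-squares slope of `ln[ROOH]` against time over a window.
#' Windows containing non-positive concentrations are rejected. By default the
#' window is restricted to the span where the concentration is at least 10
#' percent of its initial value, to keep the logarithm well conditioned.
#'
#' @param time,conc Concentration trace (s, mol/L).
#' @param window Numeric length-2 `(t_start, t_end)` in seconds, or NULL for
#'   the default span.
#' @param min_fraction Smallest `conc/conc[1]` admitted into the default
#'   window (default 0.1).
#' @return List with `k_prime` (s^-1), `se`, `r_squared`, `n`, `window`.
#' @export
pseudo_first_order <- function(time, conc, window = NULL, min_fraction = 0.1) {
  stopifnot(length(time) == length(conc))
  if (is.null(window)) {
    ok <- conc >= min_fraction * conc[1]
    window <- range(time[ok])
  }
  sel <- time >= window[1] & time <= window[2]
  if (sum(sel) < 4L) stop("need >= 4 points inside the window")
  if (any(conc[sel] <= 0)) stop("window rejected: non-positive concentrations")
  fit <- stats::lm(log(conc[sel]) ~ time[sel])
  cf <- lm_summary_quiet(fit)$coefficients
  list(k_prime = -unname(cf[2, "Estimate"]), se = unname(cf[2, "Std. Error"]),
       r_squared = lm_summary_quiet(fit)$r.squared, n = sum(sel), window = window)
}

#' Sliding-window pseudo-first-order constants
#'
#' Applies [pseudo_first_order()] over consecutive windows of fixed width
#' (default 5 s), mirroring interval-wise analysis of progression curves.
#'
#' @param time,conc Concentration trace.
#' @param width Window width in seconds.
#' @return data.frame with `t_mid`, `k_prime` per accepted window.
#' @export
sliding_k_prime <- function(time, conc, width = 5) {
  starts <- seq(min(time), max(time) - width, by = width)
  rows <- lapply(starts, function(s) {
    res <- tryCatch(pseudo_first_order(time, conc, window = c(s, s + width)),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(t_mid = s + width / 2, k_prime = res$k_prime)
  })
  do.call(rbind, rows)
}

#' Correct an observed rate constant for the non-enzymatic channel
#'
#' Subtracts the background rate measured with enzyme buffer alone from the
#' total observed rate, flooring at zero. Results where the background exceeds
#' half the total (or exceeds the total) are flagged, since the enzymatic
#' component is then poorly determined.
#'
#' @param k_total,k_background Observed and background first-order constants,
#'   s^-1 (>= 0).
#' @return List with `k` (corrected, >= 0) and `flags`.
#' @export
correct_nonenzymatic <- function(k_total, k_background) {
  stopifnot(k_total >= 0, k_background >= 0)
  flags <- character()
  if (k_background > k_total) flags <- c(flags, "negative_corrected")
  else if (k_total > 0 && k_background > 0.5 * k_total) {
    flags <- c(flags, "background_dominant")
  }
  list(k = max(k_total - k_background, 0), flags = flags)
}

#' Second-order constant from the GSH dependence of k'
#'
#' Regression of pseudo-first-order constants on the glutathione
#' concentration; the slope is the second-order rate constant of the
#' GSH-dependent channel, the intercept the GSH-independent background.
#' A statistically flat dependence is flagged `"gsh_independent"`.
#'
#' @param gsh_conc GSH concentrations, mol/L (>= 3 distinct levels).
#' @param k_prime Pseudo-first-order constants, s^-1.
#' @param temperature,reactant_pair Recorded on the result.
#' @return A [rate_constant()] of order `"second"` with intercept details.
#' @export
gsh_second_order <- function(gsh_conc, k_prime, temperature = NA_real_,
                             reactant_pair = NA_character_) {
  if (length(unique(gsh_conc)) < 3L) {
    stop("insufficient design: need >= 3 GSH levels")
  }
  fit <- stats::lm(k_prime ~ gsh_conc)
  cf <- lm_summary_quiet(fit)$coefficients
  slope <- cf["gsh_conc", "Estimate"]
  se <- cf["gsh_conc", "Std. Error"]
  flags <- character()
  if (abs(slope) <= .Machine$double.eps^0.5 * max(abs(k_prime), 1) ||
      (is.finite(se) && se > 0 && abs(slope) < 2 * se && slope <= 0)) {
    flags <- "gsh_independent"
  }
  if (slope < 0) slope <- 0
  rate_constant(slope, se = se, order = "second", temperature = temperature,
                reactant_pair = reactant_pair, flags = flags,
                details = list(intercept = cf["(Intercept)", "Estimate"],
                               fit = fit))
}

#' Dalziel-coefficient fit for a ping-pong peroxidase
#'
#' Fits the linearized steady-state rate law of glutathione peroxidases,
#' `E/v0 = phi0 + phi1/[ROOH] + phi2/[GSH]`, by linear regression of `E/v0`
#' on `1/[ROOH]` and `1/[GSH]`. `phi0` (the reciprocal turnover number) is
#' fixed to zero by default, as holds for the glutathione peroxidase family;
#' a free-`phi0` mode is available for other enzymes. The reciprocal
#' coefficients are the second-order constants of the peroxidatic
#' (`k_plus1 = 1/phi1`) and reductive (`k_plus2 = 1/phi2`) half-reactions;
#' their standard errors follow by the delta method.
#'
#' @param enzyme_conc,v0,rooh_conc,gsh_conc Vectors (recycled to common
#'   length): enzyme concentration (mol/L), initial rate (mol/L/s),
#'   hydroperoxide and GSH concentrations (mol/L) for each measurement.
#'   The design needs variation in `1/[GSH]` (and in `1/[ROOH]` too when both
#'   coefficients are to be separated from a grid).
#' @param fix_phi0 Fix `phi0 = 0` (default TRUE).
#' @param weights Optional regression weights. `E/v0` computed from noisy
#'   local rates has variance roughly proportional to `1/v0^4` (delta
#'   method), so `weights = v0^2` is a reasonable choice for windowed
#'   measurements; NULL (default) fits unweighted.
#' @return Object of class `"dalziel_fit"`: `phi0`, `phi1`, `phi2` (s, M s,
#'   M s), `k_plus1`, `k_plus2` (M^-1 s^-1), standard errors, `r_squared`,
#'   and the `lm` fit.
#' @export
dalziel_fit <- function(enzyme_conc, v0, rooh_conc, gsh_conc,
                        fix_phi0 = TRUE, weights = NULL) {
  n <- max(length(enzyme_conc), length(v0), length(rooh_conc), length(gsh_conc))
  enzyme_conc <- rep_len(enzyme_conc, n); v0 <- rep_len(v0, n)
  rooh_conc <- rep_len(rooh_conc, n); gsh_conc <- rep_len(gsh_conc, n)
  if (any(v0 <= 0)) stop("initial rates must be positive")
  stopifnot(all(enzyme_conc > 0), all(rooh_conc > 0), all(gsh_conc > 0))
  y <- enzyme_conc / v0
  x1 <- 1 / rooh_conc
  x2 <- 1 / gsh_conc
  if (length(unique(round(x2 / max(x2), 12))) < 2L &&
      length(unique(round(x1 / max(x1), 12))) < 2L) {
    stop("rank-deficient design: cannot separate phi1 and phi2 from a single ",
         "(ROOH, GSH) level")
  }
  fit <- if (fix_phi0) stats::lm(y ~ x1 + x2 - 1, weights = weights)
         else stats::lm(y ~ x1 + x2, weights = weights)
  cf <- lm_summary_quiet(fit)$coefficients
  get <- function(term, col) {
    if (term %in% rownames(cf)) unname(cf[term, col]) else NA_real_
  }
  phi1 <- get("x1", "Estimate"); phi1_se <- get("x1", "Std. Error")
  phi2 <- get("x2", "Estimate"); phi2_se <- get("x2", "Std. Error")
  phi0 <- if (fix_phi0) 0 else get("(Intercept)", "Estimate")
  if (is.na(phi1) || phi1 <= 0) {
    stop("phi1 estimate is non-positive or inestimable; check the design")
  }
  flags <- character()
  if (is.na(phi2) || phi2 <= 0) {
    flags <- c(flags, "gsh_saturated")  # E/v0 independent of GSH
    phi2 <- max(phi2, 0, na.rm = TRUE)
  }
  structure(list(
    phi0 = phi0, phi1 = phi1, phi2 = phi2,
    phi0_se = if (fix_phi0) 0 else get("(Intercept)", "Std. Error"),
    phi1_se = phi1_se, phi2_se = phi2_se,
    k_plus1 = 1 / phi1,
    k_plus1_se = phi1_se / phi1^2,
    k_plus2 = if (phi2 > 0) 1 / phi2 else Inf,
    k_plus2_se = if (phi2 > 0) phi2_se / phi2^2 else NA_real_,
    r_squared = lm_summary_quiet(fit)$r.squared,
    n = n, flags = flags, fit = fit), class = "dalziel_fit")
}

#' @export
print.dalziel_fit <- function(x, ...) {
  cat("Dalziel-coefficient fit (E/v0 = phi0 + phi1/[ROOH] + phi2/[GSH])\n")
  cat(sprintf("  phi0 = %.3g s, phi1 = %.3g M s, phi2 = %.3g M s\n",
              x$phi0, x$phi1, x$phi2))
  cat(sprintf("  k+1 = %.4g +/- %.2g M^-1 s^-1\n", x$k_plus1, x$k_plus1_se))
  cat(sprintf("  k+2 = %.4g M^-1 s^-1\n", x$k_plus2))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.dalziel_fit <- function(object, ...) {
  c(phi0 = object$phi0, phi1 = object$phi1, phi2 = object$phi2)
}

#' Windowed Dalziel measurement points from a concentration trace
#'
#' Converts one progression-curve concentration trace into local
#' rate/concentration pairs for [dalziel_fit()]: the trace is cut into
#' consecutive windows (default 5 s), the local velocity is the central
#' finite-difference slope over the window and the local substrate
#' concentration its midpoint value. Working with local rates at the local
#' substrate concentration removes the depletion bias an endpoint initial
#' rate would carry into the regression. Windows with velocities at or below
#' zero or with substrate below `min_fraction` of the initial concentration
#' are dropped.
#'
#' @param time,conc Concentration trace (s, mol/L), e.g. from
#'   [substrate_trace()].
#' @param enzyme_conc Enzyme concentration, mol/L.
#' @param gsh_conc GSH concentration held constant in the curve, mol/L.
#' @param width Window width in seconds (default 5).
#' @param min_fraction Smallest `conc/conc[1]` retained (default 0.1).
#' @return data.frame with columns `enzyme_conc`, `v0`, `rooh_conc`,
#'   `gsh_conc`, one row per accepted window.
#' @export
dalziel_points <- function(time, conc, enzyme_conc, gsh_conc, width = 5,
                           min_fraction = 0.1) {
  stopifnot(length(time) == length(conc))
  starts <- seq(min(time), max(time) - width, by = width)
  rows <- lapply(starts, function(s) {
    sel <- time >= s & time <= s + width
    if (sum(sel) < 2L) return(NULL)
    tt <- time[sel]; cc <- conc[sel]
    v <- -stats::coef(stats::lm(cc ~ tt))[2]
    cmid <- stats::approx(tt, cc, xout = s + width / 2, rule = 2)$y
    if (v <= 0 || cmid < min_fraction * conc[1]) return(NULL)
    data.frame(enzyme_conc = enzyme_conc, v0 = unname(v),
               rooh_conc = cmid, gsh_conc = gsh_conc)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no usable windows in the trace")
  out
}
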