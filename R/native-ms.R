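#' Charge-state-resolved native-MS peak areas
#'
#' Container for the ion abundances entering the dissociation-constant
#' calculation: per charge state, the peak area of the unbound protein ion and
#' of each ligand-bound complex, together with the solution-phase total
#' concentrations of protein and ligand(s).
#'
#' @param charge_states Integer vector of positive charge states.
#' @param unbound_areas Numeric vector of unbound-protein peak areas, one per
#'   charge state (>= 0, at least one positive).
#' @param bound_areas Numeric vector (single ligand) or matrix with one column
#'   per ligand and one row per charge state (>= 0).
#' @param p0 Total protein concentration, mol/L (> 0).
#' @param l0 Total ligand concentration(s), mol/L (> 0), one per ligand.
#' @param ligands Optional ligand labels (defaults to column names or L1,
#'   L2, ...).
#' @return Object of class `"peak_set"`.
#' @export
peak_set <- function(charge_states, unbound_areas, bound_areas, p0, l0,
                     ligands = NULL) {
  charge_states <- as.integer(charge_states)
  if (any(charge_states < 1)) stop("charge states must be positive integers")
  if (is.null(dim(bound_areas))) {
    bound_areas <- matrix(bound_areas, ncol = 1)
  }
  stopifnot(length(unbound_areas) == length(charge_states),
            nrow(bound_areas) == length(charge_states),
            length(l0) == ncol(bound_areas))
  if (any(unbound_areas < 0) || any(bound_areas < 0)) {
    stop("peak areas must be >= 0")
  }
  if (all(unbound_areas == 0)) {
    stop("all unbound areas are zero: bound/unbound ratio undefined")
  }
  stopifnot(p0 > 0, all(l0 > 0))
  if (is.null(ligands)) {
    ligands <- colnames(bound_areas)
    if (is.null(ligands)) ligands <- paste0("L", seq_len(ncol(bound_areas)))
  }
  colnames(bound_areas) <- ligands
  structure(list(charge_states = charge_states,
                 unbound_areas = unbound_areas, bound_areas = bound_areas,
                 p0 = p0, l0 = stats::setNames(l0, ligands),
                 ligands = ligands),
            class = "peak_set")
}

#' Sum peak areas over charge states
#'
#' @param peaks A [peak_set()].
#' @return List with `P` (total unbound area) and `PL` (named vector of total
#'   bound areas per ligand).
#' @export
aggregate_charge_states <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  list(P = sum(peaks$unbound_areas),
       PL = colSums(peaks$bound_areas))
}

#' Dissociation constants from relative native-MS peak areas
#'
#' Computes per-ligand dissociation constants from charge-state-summed ion
#' abundances under the equal-response assumption (bound and unbound protein
#' ionize identically):
#' \deqn{K_{d,i} = \frac{\sum_n P^{n+}}{\sum_n PL_i^{n+}}
#'   \left( [L_i]_0 - \frac{\sum_n PL_i^{n+}}
#'   {\sum_n P^{n+} + \sum_i \sum_n PL_i^{n+}} [P]_0 \right)}
#' The abundance ratios estimate the solution mole fractions, so the term
#' subtracted from the total ligand is the bound-complex concentration. The
#' formula is algebraically exact for 1:1 binding under equal response. A
#' `response_ratio` other than 1 divides the bound areas first, supporting
#' sensitivity sweeps of the equal-response assumption.
#'
#' @param peaks A [peak_set()].
#' @param response_ratio Assumed bound:unbound instrument response factor
#'   (default 1).
#' @return Object of class `"binding_result"`: `kd` (named, mol/L), `ratio`
#'   (bound/unbound abundance ratios), `pl_conc` (inferred complex
#'   concentrations, mol/L), `flags` (per ligand: `"undetectable"` when no
#'   bound signal, `"over_titrated"` when the formula turns negative).
#' @export
kd_from_areas <- function(peaks, response_ratio = 1) {
  stopifnot(inherits(peaks, "peak_set"), response_ratio > 0)
  agg <- aggregate_charge_states(peaks)
  P <- agg$P
  PL <- agg$PL / response_ratio
  denom <- P + sum(PL)
  pl_conc <- PL / denom * peaks$p0
  kd <- numeric(length(PL))
  flags <- character(length(PL))
  for (i in seq_along(PL)) {
    if (PL[i] == 0) {
      kd[i] <- Inf
      flags[i] <- "undetectable"
      next
    }
    kd[i] <- (P / PL[i]) * (peaks$l0[i] - pl_conc[i])
    if (kd[i] <= 0) flags[i] <- "over_titrated"
  }
  structure(list(kd = stats::setNames(kd, peaks$ligands),
                 ratio = stats::setNames(PL / P, peaks$ligands),
                 pl_conc = stats::setNames(pl_conc, peaks$ligands),
                 p0 = peaks$p0, l0 = peaks$l0,
                 flags = stats::setNames(flags, peaks$ligands)),
            class = "binding_result")
}

#' @export
print.binding_result <- function(x, ...) {
  cat("Native-MS dissociation constants (equal-response assumption)\n")
  for (i in seq_along(x$kd)) {
    cat(sprintf("  %s: Kd = %.4g M (bound/unbound ratio %.4g)%s\n",
                names(x$kd)[i], x$kd[i], x$ratio[i],
                if (nzchar(x$flags[i])) paste0(" [", x$flags[i], "]") else ""))
  }
  invisible(x)
}

#' Summarize replicate dissociation constants
#'
#' Mean and standard error of the mean across independently measured
#' dissociation constants (e.g. triplicate emitters or ligand concentrations).
#'
#' @param kd_values Numeric vector of per-replicate Kd values, mol/L.
#' @return List with `mean`, `sem`, `n`.
#' @export
kd_replicate_summary <- function(kd_values) {
  kd_values <- kd_values[is.finite(kd_values)]
  n <- length(kd_values)
  if (n == 0L) stop("no finite Kd values")
  list(mean = mean(kd_values),
       sem = if (n > 1) stats::sd(kd_values) / sqrt(n) else NA_real_,
       n = n)
}

#' Equilibrium bound-complex concentration for 1:1 binding
#'
#' Exact forward model used as the oracle for the peak-area inversion: the
#' physically admissible (smaller) root of
#' `[PL]^2 - (P0 + L0 + Kd) [PL] + P0 L0 = 0`, evaluated in the numerically
#' stable form `2 P0 L0 / (b + sqrt(b^2 - 4 P0 L0))` with `b = P0 + L0 + Kd`.
#'
#' @param kd Dissociation constant, mol/L (> 0).
#' @param p0,l0 Total protein and ligand concentrations, mol/L (> 0).
#' @return Bound-complex concentration in `[0, min(p0, l0)]`.
#' @export
#' @examples
#' equilibrium_bound(5e-6, 10e-6, 10e-6)  # 5 uM
equilibrium_bound <- function(kd, p0, l0) {
  stopifnot(all(kd > 0), all(p0 > 0), all(l0 > 0))
  b <- p0 + l0 + kd
  2 * p0 * l0 / (b + sqrt(b^2 - 4 * p0 * l0))
}

#' Neutral mass from a charge-state m/z shift
#'
#' A ligand adduct shifts a protein ion of charge `z` by `delta_mz = M / z`,
#' so the neutral ligand mass is `delta_mz * z`.
#'
#' @param delta_mz Observed m/z shift (Th).
#' @param charge Charge state (positive integer).
#' @return Neutral mass in Da.
#' @export
#' @examples
#' neutral_mass_from_shift(27.5, 8)  # 220 Da
neutral_mass_from_shift <- function(delta_mz, charge) {
  if (any(charge < 1) || any(charge != round(charge))) {
    stop("charge must be a positive integer")
  }
  delta_mz * charge
}

#' Windowed-sum peak integration on a synthetic spectrum
#'
#' Minimal helper summing spectrum intensity over an m/z window; intended for
#' synthetic spectra in tests and examples, not a general peak picker.
#'
#' @param mz,intensity Spectrum vectors.
#' @param window Numeric length-2 m/z window.
#' @return Summed intensity.
#' @export
integrate_peak <- function(mz, intensity, window) {
  stopifnot(length(mz) == length(intensity), window[2] > window[1])
  sum(intensity[mz >= window[1] & mz <= window[2]])
}
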