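# Seeded generators emulating each assay the analysis stages consume.
# All generators are deterministic given `seed`; the global RNG state is left
# untouched (see with_seed in rate-constant.R).

# multiplicative lognormal noise with coefficient of variation cv
mult_noise <- function(x, cv) {
  if (cv <= 0) return(x)
  sdlog <- sqrt(log(1 + cv^2))
  x * stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic densitometry table of monomer decay
#'
#' Forward-simulates the disappearance of reduced peroxidase monomer reacting
#' with a hydroperoxide and emits a densitometry table in the dialect the
#' blot-kinetics stage reads. The monomer decays as
#' `dM/dt = -k2 [WOOH] M`; oxidant consumption follows the chosen
#' stoichiometry: `per_dimer` (default) consumes one hydroperoxide per
#' disulfide, i.e. half a hydroperoxide per monomer lost, `per_thiol` one per
#' monomer. With `pseudo_first_order = TRUE` the oxidant is held at its
#' initial value, generating data that satisfy exactly the excess assumption
#' the exponential-fit analysis makes; otherwise the bimolecular system is
#' integrated exactly. Dimer intensity is `(enzyme0 - monomer)/2` on the same
#' intensity scale. Noise is multiplicative lognormal (gel intensities are
#' positive and scale-dependent).
#'
#' @param k2 Generating second-order constant, M^-1 s^-1 (>= 0).
#' @param enzyme0 Initial enzyme (monomer) concentration, mol/L.
#' @param oxidant_concs Vector of oxidant concentrations, mol/L.
#' @param times Sampling times, s.
#' @param stoichiometry `"per_dimer"` or `"per_thiol"` (see above).
#' @param pseudo_first_order Hold the oxidant constant (default FALSE).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0).
#' @param seed Integer seed, or NULL.
#' @param temperature Recorded in the table, degC.
#' @param intensity_scale Intensity corresponding to `enzyme0` (default 100).
#' @return data.frame with columns `condition`, `oxidant_conc` (mol/L),
#'   `time_s`, `temperature_C`, `monomer`, `dimer`.
#' @export
gen_blot_timecourse <- function(k2, enzyme0, oxidant_concs, times,
                                stoichiometry = c("per_dimer", "per_thiol"),
                                pseudo_first_order = FALSE,
                                noise_cv = 0, seed = NULL,
                                temperature = 25, intensity_scale = 100) {
  stoichiometry <- match.arg(stoichiometry)
  stopifnot(k2 >= 0, enzyme0 > 0, all(oxidant_concs >= 0), all(times >= 0))
  s_w <- if (stoichiometry == "per_dimer") 0.5 else 1
  times <- sort(unique(times))
  rows <- lapply(oxidant_concs, function(w0) {
    monomer <- if (k2 == 0 || w0 == 0) {
      rep(enzyme0, length(times))
    } else if (pseudo_first_order) {
      enzyme0 * exp(-k2 * w0 * times)
    } else {
      derivs <- function(t, y, p) {
        rate <- k2 * y["W"] * y["M"]
        list(c(M = -rate, W = -s_w * rate))
      }
      grid <- if (times[1] == 0) times else c(0, times)
      sol <- deSolve::ode(y = c(M = enzyme0, W = w0), times = grid,
                          func = derivs, parms = NULL, method = "lsoda",
                          rtol = 1e-10, atol = 1e-14)
      as.data.frame(unclass(sol))$M[match(times, grid)]
    }
    data.frame(condition = sprintf("oxidant_%.3guM", w0 * 1e6),
               oxidant_conc = w0, time_s = times,
               temperature_C = temperature,
               monomer = intensity_scale * monomer / enzyme0,
               dimer = intensity_scale * (enzyme0 - monomer) / (2 * enzyme0))
  })
  out <- do.call(rbind, rows)
  with_seed(seed, {
    out$monomer <- mult_noise(out$monomer, noise_cv)
    out$dimer <- mult_noise(out$dimer, noise_cv)
  })
  rownames(out) <- NULL
  out
}

#' Generate a synthetic NADPH progression curve
#'
#' Forward-simulates hydroperoxide consumption under the ping-pong peroxidase
#' rate law plus a non-enzymatic glutathione channel,
#' `d[ROOH]/dt = -E [ROOH] [GSH] / (phi1 [GSH] + phi2 [ROOH])
#'  - k_ne [ROOH] [GSH]`,
#' and converts it to a 340 nm absorbance trace via 1:1 NADPH:ROOH
#' stoichiometry (`A(t) = a0 - 6220 * (rooh0 - [ROOH](t)) * path`). GSH is
#' held constant (reductase/NADPH regeneration). Setting `enzyme = 0` yields
#' the pure background ("enzyme buffer") control. Absorbance noise is additive
#' Gaussian.
#'
#' @param phi1,phi2 Dalziel coefficients, M s (> 0; `phi2` may be 0 for a
#'   purely peroxidatic limit).
#' @param enzyme Enzyme concentration, mol/L (>= 0).
#' @param rooh0 Initial hydroperoxide concentration, mol/L (default 20 uM).
#' @param gsh GSH concentration, mol/L.
#' @param k_ne Non-enzymatic GSH rate constant, M^-1 s^-1 (default 0).
#' @param dt Sampling interval, s (default 1).
#' @param duration Trace length, s.
#' @param a0 Starting absorbance; default from 160 uM NADPH.
#' @param path_cm Path length, cm.
#' @param noise_sd Additive absorbance noise SD in AU (default 0).
#' @param seed Integer seed, or NULL.
#' @return data.frame with columns `time_s`, `a340`; attributes
#'   `enzyme_conc`, `gsh_conc`, `rooh0`, `path_cm`.
#' @export
gen_progression_curve <- function(phi1, phi2, enzyme, rooh0 = 20e-6, gsh,
                                  k_ne = 0, dt = 1, duration = 120,
                                  a0 = NULL, path_cm = 1, noise_sd = 0,
                                  seed = NULL) {
  stopifnot(phi1 > 0, phi2 >= 0, enzyme >= 0, rooh0 > 0, gsh > 0, k_ne >= 0)
  eps <- lookup_epsilon("NADPH")
  if (is.null(a0)) a0 <- eps * 160e-6 * path_cm
  if (a0 < eps * rooh0 * path_cm) {
    stop("a0 corresponds to less NADPH than needed to consume rooh0")
  }
  times <- seq(0, duration, by = dt)
  derivs <- function(t, y, p) {
    r <- max(y[1], 0)
    v_enz <- if (enzyme > 0) enzyme * r * gsh / (phi1 * gsh + phi2 * r) else 0
    list(-v_enz - k_ne * r * gsh)
  }
  sol <- deSolve::ode(y = c(R = rooh0), times = times, func = derivs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-14)
  r <- pmax(as.data.frame(unclass(sol))$R, 0)
  a340 <- a0 - eps * (rooh0 - r) * path_cm
  if (noise_sd > 0) {
    a340 <- with_seed(seed, a340 + stats::rnorm(length(a340), 0, noise_sd))
  }
  structure(data.frame(time_s = times, a340 = a340),
            enzyme_conc = enzyme, gsh_conc = gsh, rooh0 = rooh0,
            path_cm = path_cm)
}

#' Generate a synthetic competition dataset
#'
#' Forward-simulates the oxidant-partitioning network ([ido_prx_network()])
#' at a known competitor rate constant and emits per-replicate product totals
#' with multiplicative noise, in the shape the competition stage inverts.
#'
#' @param k_comp Competitor (IDO1-channel) rate constant, M^-1 s^-1.
#' @param k_ref Reference (Prx2) rate constant, M^-1 s^-1 (default 2e7).
#' @param h2o2,ref_conc,comp_conc Initial concentrations, mol/L (defaults 2,
#'   4, 20 uM).
#' @param replicates Number of replicates (default 3).
#' @param noise_cv Multiplicative noise CV on the product totals (default 0).
#' @param seed Integer seed, or NULL.
#' @return data.frame with columns `replicate`, `product_conc` (mol/L),
#'   `yield` (fraction of initial oxidant).
#' @export
gen_competition_dataset <- function(k_comp, k_ref = 2e7, h2o2 = 2e-6,
                                    ref_conc = 4e-6, comp_conc = 20e-6,
                                    replicates = 3, noise_cv = 0,
                                    seed = NULL) {
  stopifnot(k_comp >= 0, k_ref >= 0, replicates >= 1)
  yield <- if (k_comp == 0) 0 else {
    net <- ido_prx_network(k_ido1 = k_comp, k_prx2 = k_ref, h2o2 = h2o2,
                           prx2 = ref_conc, ido1 = comp_conc)
    product_yield(net, product = "TrpOx")
  }
  prod <- with_seed(seed, mult_noise(rep(yield * h2o2, replicates), noise_cv))
  data.frame(replicate = seq_len(replicates), product_conc = prod,
             yield = prod / h2o2)
}

#' Generate synthetic native-MS peak areas at binding equilibrium
#'
#' Computes the exact 1:1 equilibrium partition ([equilibrium_bound()]) and
#' distributes the free-protein and complex populations over charge states by
#' fixed weights, scaling bound areas by an instrument response ratio and
#' applying multiplicative noise.
#'
#' @param kd Generating dissociation constant, mol/L (> 0).
#' @param p0,l0 Total protein and ligand concentrations, mol/L.
#' @param charge_weights Named numeric vector of charge-state weights
#'   (names = charge states; default a single 8+ state).
#' @param response_ratio Bound:unbound response factor (default 1).
#' @param total_area Area corresponding to `p0` (default 1000).
#' @param noise_cv Multiplicative noise CV per peak (default 0).
#' @param seed Integer seed, or NULL.
#' @return A [peak_set()].
#' @export
gen_native_ms_peaks <- function(kd, p0, l0, charge_weights = c("8" = 1),
                                response_ratio = 1, total_area = 1000,
                                noise_cv = 0, seed = NULL) {
  stopifnot(kd > 0, p0 > 0, l0 > 0, all(charge_weights > 0))
  w <- charge_weights / sum(charge_weights)
  pl <- equilibrium_bound(kd, p0, l0)
  pfree <- p0 - pl
  unbound <- total_area * (pfree / p0) * w
  bound <- total_area * (pl / p0) * response_ratio * w
  with_seed(seed, {
    unbound <- mult_noise(unbound, noise_cv)
    bound <- mult_noise(bound, noise_cv)
  })
  peak_set(charge_states = as.integer(names(charge_weights)),
           unbound_areas = unname(unbound), bound_areas = unname(bound),
           p0 = p0, l0 = l0)
}
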