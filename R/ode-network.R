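#' Define a mass-action reaction network
#'
#' Constructs a deterministic mass-action network: named species with initial
#' concentrations and a list of uni- or bimolecular reactions. Each reaction
#' is a list with elements `reactants` (character, 1 or 2 names), `products`
#' (character, possibly empty), `k` (rate constant, s^-1 for unimolecular or
#' M^-1 s^-1 for bimolecular), and optionally `catalytic` (logical, one per
#' reactant; catalytic reactants enter the rate law but are not consumed).
#'
#' @param species Named numeric vector of initial concentrations in mol/L
#'   (all >= 0, names unique).
#' @param reactions List of reaction specifications as above.
#' @return Object of class `"reaction_network"`.
#' @export
#' @examples
#' net <- reaction_network(
#'   species = c(A = 1e-5, B = 1e-5, C = 0),
#'   reactions = list(list(reactants = c("A", "B"), products = "C", k = 1e5)))
reaction_network <- function(species, reactions) {
  if (is.null(names(species)) || any(names(species) == "") ||
      anyDuplicated(names(species))) {
    stop("species must be a uniquely named numeric vector")
  }
  if (any(species < 0)) stop("initial concentrations must be >= 0")
  reactions <- lapply(seq_along(reactions), function(i) {
    r <- reactions[[i]]
    if (is.null(r$reactants) || !length(r$reactants) %in% 1:2) {
      stop("reaction ", i, ": need 1 or 2 reactants")
    }
    if (is.null(r$k) || r$k < 0) stop("reaction ", i, ": rate constant must be >= 0")
    unknown <- setdiff(c(r$reactants, r$products), names(species))
    if (length(unknown)) {
      stop("reaction ", i, ": unknown species ", paste(unknown, collapse = ", "))
    }
    if (is.null(r$catalytic)) r$catalytic <- rep(FALSE, length(r$reactants))
    if (length(r$catalytic) != length(r$reactants)) {
      stop("reaction ", i, ": catalytic flags must match reactants")
    }
    if (is.null(r$products)) r$products <- character()
    r
  })
  structure(list(species = species, reactions = reactions),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Mass-action reaction network:", length(x$species), "species,",
      length(x$reactions), "reactions\n")
  for (r in x$reactions) {
    lhs <- paste(ifelse(r$catalytic, paste0("(", r$reactants, ")"),
                        r$reactants), collapse = " + ")
    rhs <- if (length(r$products)) paste(r$products, collapse = " + ") else "0"
    cat(sprintf("  %s -> %s   k = %.3g\n", lhs, rhs, r$k))
  }
  cat("initial concentrations (M):\n")
  print(x$species)
  invisible(x)
}

# stoichiometry + rate-law closure shared by simulate and product_yield
network_derivs <- function(network) {
  sp <- names(network$species)
  function(t, y, parms) {
    y <- pmax(y, 0)
    dy <- stats::setNames(numeric(length(y)), sp)
    for (r in network$reactions) {
      rate <- r$k * prod(y[r$reactants])
      consumed <- r$reactants[!r$catalytic]
      for (s in consumed) dy[s] <- dy[s] - rate
      for (s in r$products) dy[s] <- dy[s] + rate
    }
    list(dy)
  }
}

#' Simulate a reaction network
#'
#' Integrates the mass-action rate equations with the stiff-capable `lsoda`
#' integrator from \pkg{deSolve} (relative tolerance 1e-8, absolute 1e-12 M by
#' default). Catalytic reactants are not consumed; concentrations are clipped
#' at zero within solver tolerance.
#'
#' @param object A [reaction_network()].
#' @param nsim,seed Ignored (deterministic simulation); present for
#'   compatibility with the [stats::simulate()] generic.
#' @param duration Simulation horizon in seconds (> 0).
#' @param times Optional output time grid (overrides `duration`).
#' @param rtol,atol Solver tolerances.
#' @param ... Passed on to [deSolve::ode()].
#' @return Object of class `"trajectory"`: a data.frame with column `time`
#'   plus one column per species (mol/L); solver diagnostics in
#'   `attr(, "diagnostics")`.
#' @export
simulate.reaction_network <- function(object, nsim = 1, seed = NULL,
                                      duration = NULL, times = NULL,
                                      rtol = 1e-8, atol = 1e-12, ...) {
  if (is.null(times)) {
    if (is.null(duration) || duration <= 0) stop("duration must be > 0")
    times <- seq(0, duration, length.out = 201)
  }
  sol <- deSolve::ode(y = object$species, times = times,
                      func = network_derivs(object), parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol, ...)
  diag <- attributes(sol)[c("istate", "rstate")]
  out <- as.data.frame(unclass(sol))
  for (s in names(object$species)) out[[s]] <- pmax(out[[s]], 0)
  structure(out, diagnostics = c(diag, list(rtol = rtol, atol = atol)),
            class = c("trajectory", "data.frame"))
}

#' @export
plot.trajectory <- function(x, species = setdiff(names(x), "time"), ...) {
  graphics::matplot(x$time, as.matrix(x[species]), type = "l", lty = 1,
                    xlab = "time (s)", ylab = "concentration (M)", ...)
  graphics::legend("topright", legend = species, col = seq_along(species),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Fraction of the oxidant converted to a product at completion
#'
#' Runs the network to completion (the horizon is extended geometrically until
#' the oxidant residual falls below `residual_tol` of its initial value) and
#' returns `product_final / oxidant_initial`.
#'
#' @param network A [reaction_network()].
#' @param oxidant Name of the oxidant species (default `"H2O2"`).
#' @param product Name of the product species.
#' @param duration Starting horizon in seconds (default 60).
#' @param residual_tol Largest tolerated oxidant residual as a fraction of its
#'   initial concentration (default 1e-3).
#' @param max_duration Give up and error beyond this horizon.
#' @return Yield fraction in \[0, 1\].
#' @export
product_yield <- function(network, product, oxidant = "H2O2",
                          duration = 60, residual_tol = 1e-3,
                          max_duration = 1e8) {
  stopifnot(oxidant %in% names(network$species),
            product %in% names(network$species))
  h0 <- network$species[[oxidant]]
  if (h0 <= 0) stop("oxidant initial concentration must be positive")
  # integrate with a terminal root at completion rather than through the
  # flat post-completion tail, where interpolated dense output degrades
  i_ox <- match(oxidant, names(network$species))
  rootfun <- function(t, y, parms) y[i_ox] - residual_tol * h0
  repeat {
    sol <- deSolve::ode(y = network$species, times = c(0, duration),
                        func = network_derivs(network), parms = NULL,
                        method = "lsodar", rootfunc = rootfun,
                        rtol = 1e-8, atol = 1e-14 * h0)
    final <- sol[nrow(sol), ]
    residual <- final[[oxidant]]
    if (residual <= residual_tol * h0 * (1 + 1e-6)) break
    duration <- duration * 10
    if (duration > max_duration) {
      stop("oxidant not consumed within max_duration (residual ",
           signif(residual / h0, 3), " of initial); the network may not ",
           "consume it fully")
    }
  }
  unname(final[[product]] / h0)
}

#' Invert a product yield for an unknown rate constant
#'
#' Finds the rate constant of one reaction such that the network's product
#' yield matches a target, by Brent root finding on `log10(k)`. Monotonicity
#' of the yield in the free constant over the bracket is verified numerically
#' from the bracket endpoints; targets outside the attainable range return the
#' nearer bracket edge flagged `"bracket_edge"`.
#'
#' @param target_yield Target yield fraction in (0, 1).
#' @param network A [reaction_network()] template.
#' @param free_reaction Index of the reaction whose constant is free.
#' @param product,oxidant Passed to [product_yield()].
#' @param bracket Bracket for the free constant (default `c(1e2, 1e8)`
#'   M^-1 s^-1).
#' @param tol Relative tolerance on the recovered constant.
#' @return A [rate_constant()] of order `"second"`.
#' @export
invert_yield <- function(target_yield, network, free_reaction, product,
                         oxidant = "H2O2", bracket = c(1e2, 1e8),
                         tol = 1e-6) {
  stopifnot(target_yield > 0, target_yield < 1)
  yield_at <- function(k) {
    network$reactions[[free_reaction]]$k <- k
    product_yield(network, product = product, oxidant = oxidant)
  }
  ylo <- yield_at(bracket[1]); yhi <- yield_at(bracket[2])
  increasing <- yhi >= ylo
  lo <- min(ylo, yhi); hi <- max(ylo, yhi)
  if (target_yield <= lo || target_yield >= hi) {
    edge <- if ((target_yield <= lo) == increasing) bracket[1] else bracket[2]
    return(rate_constant(edge, order = "second", flags = "bracket_edge",
                         details = list(attainable = c(lo, hi))))
  }
  root <- stats::uniroot(function(lk) yield_at(10^lk) - target_yield,
                         log10(bracket), tol = tol / log(10))
  rate_constant(10^root$root, order = "second",
                details = list(iter = root$iter, increasing = increasing))
}

#' The hydrogen peroxide partitioning network between Prx2 and IDO1
#'
#' Convenience constructor for the two-channel competition network used to
#' rationalize tryptophan-hydroperoxide formation in the presence of reduced
#' peroxiredoxin 2: H2O2 reacts stoichiometrically with reduced Prx2
#' (consuming both, 1:1 per peroxidatic thiol; no reductant present, so no
#' recycling) and catalytically with IDO1, which converts it to tryptophan
#' oxidation products (cis-WOOH plus OIA, pooled as one product species;
#' L-tryptophan at 100 uM is non-limiting and folded into the IDO1 rate
#' constant).
#'
#' @param k_ido1 Rate constant for IDO1 + H2O2, M^-1 s^-1.
#' @param k_prx2 Rate constant for Prx2 + H2O2, M^-1 s^-1 (default 2e7).
#' @param h2o2,prx2,ido1 Initial concentrations in mol/L (defaults 2, 4 and
#'   20 uM respectively).
#' @return A [reaction_network()] with species `H2O2`, `Prx2`, `IDO1`,
#'   `Prx2ox`, `TrpOx`; reaction 1 is the Prx2 channel, reaction 2 the IDO1
#'   channel.
#' @export
ido_prx_network <- function(k_ido1, k_prx2 = 2e7, h2o2 = 2e-6, prx2 = 4e-6,
                            ido1 = 20e-6) {
  reaction_network(
    species = c(H2O2 = h2o2, Prx2 = prx2, IDO1 = ido1, Prx2ox = 0, TrpOx = 0),
    reactions = list(
      list(reactants = c("H2O2", "Prx2"), products = "Prx2ox", k = k_prx2),
      list(reactants = c("H2O2", "IDO1"), products = "TrpOx", k = k_ido1,
           catalytic = c(FALSE, TRUE))))
}
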