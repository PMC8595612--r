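# Closed-form oracles used across the kinetics tests. These are independent
# of the package's solvers and fitters: plain textbook integrated rate laws.

# Second-order A + B -> products with unequal initial concentrations:
# remaining [A](t) given d[A]/dt = d[B]/dt = -k[A][B].
second_order_unequal <- function(a0, b0, k, t) {
  if (abs(a0 - b0) < 1e-15) return(second_order_equal(a0, k, t))
  d <- b0 - a0
  a0 * d / (b0 * exp(d * k * t) - a0)
}

# Equal-concentration second order: 1/[A] - 1/[A0] = kt.
second_order_equal <- function(a0, k, t) {
  1 / (1 / a0 + k * t)
}

# Conservation relation for the two-channel competition network with a
# stoichiometric reference scavenger (P0, k_ref) and a catalytic competitor
# (C, k_comp): final product Prod satisfies
#   Prod + P0 * (1 - exp(-k_ref * Prod / (k_comp * C))) = H0.
# Solved here by bisection on Prod, independently of the ODE solver.
competition_yield_oracle <- function(h0, p0, k_ref, comp_conc, k_comp) {
  g <- function(prod) {
    prod + p0 * (1 - exp(-k_ref * prod / (k_comp * comp_conc))) - h0
  }
  uniroot(g, c(1e-18, h0 * (1 - 1e-12)), tol = 1e-18)$root / h0
}

# Exact 1:1 binding quadratic solved with the textbook formula (the package
# uses the numerically stable variant; the tests use the naive one).
binding_quadratic_naive <- function(kd, p0, l0) {
  b <- p0 + l0 + kd
  (b - sqrt(b^2 - 4 * p0 * l0)) / 2
}
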