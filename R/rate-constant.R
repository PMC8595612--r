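#' Kinetic rate constant with uncertainty
#'
#' Container for an inferred rate constant. First-order constants carry units
#' of s^-1, second-order constants M^-1 s^-1. All concentrations feeding these
#' estimates are in mol/L and times in seconds; conversion to and from the
#' micromolar file dialect happens at the I/O boundary only.
#'
#' @param value Estimated constant (>= 0; zero is a legitimate estimate for an
#'   unreactive pair).
#' @param se Asymptotic standard error in the same units (NA when the design
#'   does not support one).
#' @param order `"first"` or `"second"`.
#' @param temperature Temperature in degrees Celsius at which the constant was
#'   measured, or NA.
#' @param reactant_pair Free-text label of the reacting pair, e.g.
#'   `"Prx2 + cis-WOOH"`.
#' @param flags Character vector of quality flags (e.g. `"upper_bound"`,
#'   `"clamped_negative"`).
#' @param details Optional list of fit diagnostics kept with the object.
#' @return An object of class `"rate_constant"`.
#' @export
rate_constant <- function(value, se = NA_real_, order = c("second", "first"),
                          temperature = NA_real_, reactant_pair = NA_character_,
                          flags = character(), details = list()) {
  order <- match.arg(order)
  stopifnot(is.numeric(value), length(value) == 1L)
  if (is.finite(value) && value < 0) {
    stop("rate constants must be non-negative; got ", value)
  }
  if (is.finite(se) && se < 0) stop("standard error must be non-negative")
  structure(
    list(value = value, se = se, order = order,
         units = if (order == "second") "M^-1 s^-1" else "s^-1",
         temperature = temperature, reactant_pair = reactant_pair,
         flags = flags, details = details),
    class = "rate_constant")
}

#' @export
print.rate_constant <- function(x, ...) {
  pair <- if (is.na(x$reactant_pair)) "" else paste0(" (", x$reactant_pair, ")")
  cat(sprintf("%s-order rate constant%s\n", x$order, pair))
  if (is.na(x$se)) {
    cat(sprintf("  k = %.4g %s\n", x$value, x$units))
  } else {
    cat(sprintf("  k = %.4g +/- %.2g %s\n", x$value, x$se, x$units))
  }
  if (!is.na(x$temperature)) cat(sprintf("  temperature: %g degC\n", x$temperature))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.rate_constant <- function(object, ...) {
  c(k = object$value)
}

# summary.lm warns on zero-residual fits; noise-free oracle data trip this
# constantly, so that one warning is muffled
lm_summary_quiet <- function(fit) {
  withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

# run expr with a local RNG state seeded by `seed`; global state is untouched
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
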