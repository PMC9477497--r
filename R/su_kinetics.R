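#' Synthesizing-unit specification
#'
#' A synthesizing unit (SU) is a stylized representation of the biochemical
#' machinery that transforms one or more substrates into a product. An
#' `su_spec` bundles the per-substrate stoichiometric yields (substrate units
#' required per unit of product) with the kinetic rule used to combine the
#' substrate supply fluxes.
#'
#' Two rules are supported:
#' * `"minimum"` — Liebig's minimum law: production runs at the rate allowed
#'   by the single scarcest substrate (a perfectly efficient idealization).
#' * `"pcsu"` — the parallel complementary SU, which binds complementary
#'   substrates in parallel and is less efficient: at equal, stoichiometrically
#'   balanced supply its rate is exactly 2/3 of the minimum rule's.
#'
#' @param rule Character, `"minimum"` or `"pcsu"`.
#' @param yields Numeric vector of strictly positive, finite stoichiometric
#'   coefficients, one per substrate.
#' @param label Character tag used in error messages.
#' @return An object of class `su_spec`.
#' @examples
#' su <- su_spec("pcsu", yields = c(1, 1), label = "growth")
#' production_rate(c(1, 1), "pcsu")  # 2/3
#' @export
su_spec <- function(rule = c("minimum", "pcsu"), yields, label = "su") {
  rule <- match.arg(rule)
  yields <- as.numeric(yields)
  if (length(yields) < 1L || anyNA(yields) || any(!is.finite(yields)) ||
      any(yields <= 0)) {
    stop("su_spec '", label, "': yields must be strictly positive and finite",
         call. = FALSE)
  }
  structure(list(rule = rule, yields = yields, label = as.character(label)[1L]),
            class = "su_spec")
}

#' @export
print.su_spec <- function(x, ...) {
  cat(sprintf("<su_spec '%s'> rule=%s, yields=(%s)\n",
              x$label, x$rule, paste(format(x$yields), collapse = ", ")))
  invisible(x)
}

#' Scale raw substrate arrival fluxes to product-equivalent rates
#'
#' Divides each raw arrival flux by its stoichiometric yield so that every
#' substrate is expressed in product-equivalents per unit time; these scaled
#' rates are the natural arguments of [production_rate()].
#'
#' @param arrivals Nonnegative numeric vector of raw per-substrate arrival
#'   fluxes, same length as `spec$yields`.
#' @param spec An [su_spec()].
#' @return Numeric vector of scaled rates (product-equivalents per time).
#' @export
scaled_arrivals <- function(arrivals, spec) {
  stopifnot(inherits(spec, "su_spec"))
  if (length(arrivals) != length(spec$yields)) {
    stop("SU '", spec$label, "': got ", length(arrivals),
         " arrival fluxes for ", length(spec$yields), " substrates",
         call. = FALSE)
  }
  if (anyNA(arrivals) || any(arrivals < 0)) {
    stop("SU '", spec$label, "': arrivals must be nonnegative", call. = FALSE)
  }
  arrivals / spec$yields
}

#' Synthesizing-unit production rate
#'
#' Combines scaled (product-equivalent) substrate supply rates into a product
#' synthesis rate. Under the minimum rule the rate is `min(rho)`. Under the
#' parallel complementary rule for two substrates the closed form is
#' \deqn{j = \left(\frac{1}{\rho_1} + \frac{1}{\rho_2} -
#'   \frac{1}{\rho_1+\rho_2}\right)^{-1}.}
#' For k > 2 substrates the inclusion-exclusion generalization
#' \eqn{1/j = \sum_A (-1)^{|A|+1} / \sum_{i \in A} \rho_i} over nonempty
#' subsets A is used. A single substrate is fully processed under either rule.
#' If any required rate is zero the production rate is zero.
#'
#' @param rho Nonnegative numeric vector of scaled arrival rates.
#' @param rule `"minimum"` or `"pcsu"`.
#' @return Scalar production rate (product units per time).
#' @export
production_rate <- function(rho, rule = c("minimum", "pcsu")) {
  if (length(rule) != 1L || !rule %in% c("minimum", "pcsu"))
    rule <- match.arg(rule)
  if (anyNA(rho) || any(rho < 0)) {
    stop("production_rate: scaled arrival rates must be nonnegative",
         call. = FALSE)
  }
  k <- length(rho)
  if (k == 0L) return(0)
  if (any(rho == 0)) return(0)
  if (k == 1L) return(rho[[1L]])
  if (rule == "minimum") return(min(rho))
  if (k == 2L) {
    # closed form for the two-substrate case (hot path)
    return(1 / (1 / rho[[1L]] + 1 / rho[[2L]] - 1 / (rho[[1L]] + rho[[2L]])))
  }
  # PCSU: inclusion-exclusion over nonempty substrate subsets
  inv <- 0
  for (mask in seq_len(2L^k - 1L)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    inv <- inv + (-1)^(length(idx) + 1L) / sum(rho[idx])
  }
  1 / inv
}

#' Rejected (surplus) substrate fluxes at a synthesizing unit
#'
#' Given the raw arrivals and the realized production rate, each substrate's
#' surplus is what arrived minus what the SU consumed
#' (`yield_i * j_prod`). Tiny negative residuals (|x| <= 1e-12 on the
#' arrival scale) are clipped to zero; larger negatives indicate a wiring bug
#' and raise an error.
#'
#' @param arrivals Raw arrival fluxes (same units as fed to
#'   [scaled_arrivals()]).
#' @param spec An [su_spec()].
#' @param j_prod Production rate as returned by [production_rate()] for these
#'   arrivals.
#' @return Numeric vector of nonnegative rejected fluxes, raw substrate units.
#' @export
rejected_fluxes <- function(arrivals, spec, j_prod) {
  rej <- arrivals - spec$yields * j_prod
  scale <- max(1, abs(arrivals))
  bad <- rej < -1e-12 * scale
  if (any(bad)) {
    stop("SU '", spec$label, "': internal inconsistency, rejected flux ",
         paste(format(rej[bad]), collapse = ", "),
         " < 0 (production rate does not match arrivals)", call. = FALSE)
  }
  pmax(rej, 0)
}

#' One-shot SU evaluation
#'
#' Convenience wrapper running [scaled_arrivals()], [production_rate()] and
#' [rejected_fluxes()] in sequence.
#'
#' @inheritParams rejected_fluxes
#' @return List with elements `j_prod`, `consumed` (per substrate, raw units)
#'   and `rejected`.
#' @export
su_process <- function(arrivals, spec) {
  rho <- scaled_arrivals(arrivals, spec)
  j <- production_rate(rho, spec$rule)
  list(j_prod = j,
       consumed = spec$yields * j,
       rejected = rejected_fluxes(arrivals, spec, j))
}

#' Saturating (hyperbolic) acquisition flux
#'
#' Single-substrate SU bound to an environmental concentration: the specific
#' acquisition flux follows the familiar hyperbolic form
#' `j_max * conc / (conc + K)`. Only acquisition SUs saturate with the
#' environment; internal SUs are demand-unconstrained and process whatever
#' arrives.
#'
#' @param conc Nonnegative environmental concentration (environment units).
#' @param j_max Maximum specific flux (> 0).
#' @param K Half-saturation constant (> 0, same units as `conc`).
#' @return Specific flux in `[0, j_max)`.
#' @export
saturating_uptake <- function(conc, j_max, K) {
  if (anyNA(conc) || any(conc < 0)) {
    stop("saturating_uptake: concentration must be nonnegative", call. = FALSE)
  }
  stopifnot(j_max > 0, K > 0)
  j_max * conc / (conc + K)
}
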