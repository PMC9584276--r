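#' Early-time exponential rate of the prevalence
#'
#' The log-prevalence of an evolving pathogen at early times follows
#' xi(t) = -alpha0 (1 - R0) t + (1/2) sigma^2 alpha0^2 R0^2 t^3:
#' the linear term is the sub-pandemic decay of the wild-type, the cubic
#' term the mutation-driven proliferation that eventually dominates.
#'
#' @param t Time(s), >= 0.
#' @param alpha0 Wild-type recovery rate.
#' @param R0 Wild-type reproduction number.
#' @param sigma Mutation rate (fitness-step scale).
#' @return xi(t), vectorized over `t`.
#' @examples
#' xi(10, alpha0 = 0.1, R0 = 0.25, sigma = 0)   # -0.75
#' @export
xi <- function(t, alpha0, R0, sigma) {
  stopifnot(all(t >= 0), alpha0 > 0, sigma >= 0)
  -alpha0 * (1 - R0) * t + 0.5 * sigma^2 * alpha0^2 * R0^2 * t^3
}

#' Early-time theoretical prevalence
#'
#' eta(t) = eta0 * exp(xi(t)). Valid while the susceptible pool is not yet
#' depleted; it is the decaying-then-recovering envelope against which the
#' unit line 1/N is compared.
#'
#' @inheritParams xi
#' @param eta0 Initial prevalence (> 0).
#' @return eta(t), vectorized over `t`.
#' @export
eta_theory <- function(t, eta0, alpha0, R0, sigma) {
  stopifnot(eta0 > 0)
  eta0 * exp(xi(t, alpha0, R0, sigma))
}

#' Critical-mutation timescale
#'
#' The time at which the cubic (mutation) term of [xi()] overtakes the
#' linear decay -- the minimum of xi(t) and the anticipated appearance
#' time of the critical mutation:
#' tau_c = sqrt(2 (1 - R0) / (3 alpha0 sigma^2 R0^2)).
#' Defined for sub-pandemic wild-types (0 < R0 < 1) with sigma > 0.
#'
#' @inheritParams xi
#' @return tau_c (positive scalar).
#' @examples
#' tau_c(0.1, 0.25, 2)   # sqrt(20) = 4.47
#' @export
tau_c <- function(alpha0, R0, sigma) {
  stopifnot(alpha0 > 0)
  if (R0 <= 0 || R0 >= 1) stop("tau_c is defined for 0 < R0 < 1")
  if (sigma <= 0) stop("tau_c is undefined for sigma = 0 (no mutations)")
  sqrt(2 * (1 - R0) / (3 * alpha0 * sigma^2 * R0^2))
}

#' Critical inter-host fitness
#'
#' psi_c = 1 / R0: the fitness at which a strain's reproduction number
#' psi * R0 reaches 1, so that crossing it turns an initially
#' sub-pandemic pathogen pandemic.
#'
#' @param R0 Wild-type reproduction number (> 0).
#' @return psi_c.
#' @examples
#' psi_critical(0.25)   # 4
#' @export
psi_critical <- function(R0) {
  if (any(R0 <= 0)) stop("`R0` must be positive")
  1 / R0
}

#' Lower critical mutation rate (infection-free / mutation-driven boundary)
#'
#' The minimal mutation rate for a sub-pandemic wild-type to reach its
#' critical mutation before extinction:
#' sigma_c = c_lower * sqrt(alpha0 (1 - R0)^3) / (2 R0 ln(I0)),
#' where I0 is the initially infected population. The scaling is exact;
#' the multiplicative prefactor `c_lower` is only determined up to a
#' model-dependent constant and can be fitted with
#' [calibrate_prefactors()].
#'
#' @inheritParams xi
#' @param I0 Number of initially infected individuals (>= 2).
#' @param c_lower Multiplicative prefactor (default 1: the bare formula).
#' @return sigma_c (non-negative scalar).
#' @examples
#' sigma_c_lower(0.1, 1, 100)      # 0: an R0 = 1 pathogen needs no mutations
#' @export
sigma_c_lower <- function(alpha0, R0, I0, c_lower = 1) {
  stopifnot(alpha0 > 0, c_lower > 0)
  if (R0 <= 0 || R0 > 1) stop("the lower boundary is defined for 0 < R0 <= 1")
  if (I0 <= 1) stop("`I0` must exceed 1 (ln(I0) must be positive)")
  c_lower * sqrt(alpha0 * (1 - R0)^3) / (2 * R0 * log(I0))
}

#' Upper critical mutation rate (mutation-driven / volatile boundary)
#'
#' Above sigma_c = c_upper * sqrt(alpha0 / 3) (psi_max R0 - 1)^(3/2) / R0
#' mutations outpace inter-host selection: fitness gains are lost before
#' they can be locked in, and the pathogen fails to spread despite
#' transiently reaching critical fitness. psi_max is the maximal
#' attainable inter-host fitness. Requires psi_max * R0 >= 1, otherwise
#' no strain can ever be pandemic (signalled as an error of class
#' `evoepi_no_pandemic`).
#'
#' @inheritParams xi
#' @param psi_max Maximal inter-host fitness over all potential strains.
#' @param c_upper Multiplicative prefactor (default 1: the bare formula).
#' @return sigma_c (non-negative scalar).
#' @export
sigma_c_upper <- function(alpha0, R0, psi_max, c_upper = 1) {
  stopifnot(alpha0 > 0, R0 > 0, psi_max > 0, c_upper > 0)
  if (psi_max * R0 < 1) {
    stop(structure(
      class = c("evoepi_no_pandemic", "error", "condition"),
      list(message = "psi_max * R0 < 1: no attainable strain can be pandemic",
           call = sys.call(-1))))
  }
  c_upper * sqrt(alpha0 / 3) * (psi_max * R0 - 1)^1.5 / R0
}

#' Package prefactors calibrated on the reference simulation grid
#'
#' The boundary formulas of [sigma_c_lower()] and [sigma_c_upper()] hold
#' up to multiplicative constants. These defaults were fitted once, with
#' [calibrate_prefactors()], to a simulated phase diagram of this
#' package's own dynamics on the reference Erdos-Renyi setting (N = 5000,
#' mean degree 15, alpha0 = 0.1, eta0 = 0.02, psi_max = 6); see the
#' package vignette. Because the simulator takes exactly one fitness step
#' per transmission, the fitted constants are of order 10 rather than
#' order 1.
#'
#' @return Named list with `c_lower` and `c_upper`.
#' @export
calibrated_prefactors <- function() {
  list(c_lower = 23, c_upper = 12)
}

#' Classify a scenario into the pandemic phase diagram
#'
#' Labels a point of the (sigma, R0) plane: `pandemic` when R0 >= 1;
#' otherwise `infection-free`, `mutation-driven` or `volatile` according
#' to the position of sigma relative to the two boundaries.
#'
#' @inheritParams xi
#' @param I0 Initially infected population (for the lower boundary).
#' @param psi_max Maximal attainable fitness (for the upper boundary).
#' @param prefactors List with `c_lower`, `c_upper`; defaults to
#'   [calibrated_prefactors()].
#' @return Object of class `phase_label`: list with `label`,
#'   `boundary_margin` (signed sigma-distance to the nearest boundary,
#'   `NA` for the pandemic phase), `sigma_c_lower`, `sigma_c_upper`.
#' @examples
#' classify_phase(0.1, 1.2, sigma = 0.02, I0 = 100, psi_max = 6)$label
#' @export
classify_phase <- function(alpha0, R0, sigma, I0, psi_max,
                           prefactors = calibrated_prefactors()) {
  stopifnot(sigma >= 0)
  if (R0 >= 1) {
    lab <- "pandemic"
    lo <- 0
    hi <- tryCatch(
      sigma_c_upper(alpha0, R0, psi_max, prefactors$c_upper),
      evoepi_no_pandemic = function(e) NA_real_)
    margin <- NA_real_
  } else {
    lo <- sigma_c_lower(alpha0, R0, I0, prefactors$c_lower)
    hi <- tryCatch(
      sigma_c_upper(alpha0, R0, psi_max, prefactors$c_upper),
      evoepi_no_pandemic = function(e) NA_real_)
    if (is.na(hi)) {
      ## no strain can ever spread: infection-free at every sigma
      lab <- "infection-free"
      margin <- NA_real_
    } else if (sigma <= lo) {
      lab <- "infection-free"
      margin <- lo - sigma
    } else if (sigma >= hi) {
      lab <- "volatile"
      margin <- sigma - hi
    } else {
      lab <- "mutation-driven"
      margin <- min(sigma - lo, hi - sigma)
    }
  }
  structure(list(label = lab, boundary_margin = margin,
                 sigma_c_lower = lo, sigma_c_upper = hi),
            class = "phase_label")
}

#' @export
print.phase_label <- function(x, ...) {
  cat(sprintf("<phase_label> %s (boundaries: sigma_c_lower=%.4g, sigma_c_upper=%.4g)\n",
              x$label, x$sigma_c_lower, x$sigma_c_upper))
  invisible(x)
}

#' Unit-line criterion for mutation-driven spread
#'
#' Checks whether the theoretical prevalence at the critical-mutation
#' timescale is still above the unit line, i.e. whether on the order of
#' one or more infected individuals remain when the critical mutation is
#' due: eta(tau_c) > threshold_mult / N. Because a pathogen carried by
#' just a couple of hosts still goes extinct with high probability, the
#' unit line is read softly; the default multiplier 6 is anchored so that
#' the known critical scenario (R0 = 0.25, sigma = 0.16, eta0 = 0.02,
#' N = 5000) sits on the boundary (see the vignette).
#'
#' @inheritParams eta_theory
#' @param N Population size.
#' @param threshold_mult Multiplier on the 1/N threshold (order unity).
#' @return Logical: `TRUE` if the critical mutation arrives while the
#'   expected infected pool is still macroscopic.
#' @examples
#' unit_line_check(0.02, 5000, 0.1, 0.25, 0.5)   # TRUE
#' unit_line_check(0.02, 5000, 0.1, 0.25, 0.1)   # FALSE
#' @export
unit_line_check <- function(eta0, N, alpha0, R0, sigma, threshold_mult = 6) {
  stopifnot(N >= 1, threshold_mult > 0)
  tc <- tau_c(alpha0, R0, sigma)
  eta_theory(tc, eta0, alpha0, R0, sigma) > threshold_mult / N
}

#' Export the theoretical phase-boundary curves
#'
#' Evaluates both boundaries on a grid of R0 values, for plotting or for
#' overlay on a simulated phase diagram.
#'
#' @inheritParams classify_phase
#' @param R0_values Grid of reproduction numbers in (0, 1].
#' @return Data frame with columns `R0`, `sigma_c_lower`, `sigma_c_upper`.
#' @export
boundary_curves <- function(R0_values, alpha0, I0, psi_max,
                            prefactors = calibrated_prefactors()) {
  stopifnot(all(R0_values > 0), all(R0_values <= 1))
  data.frame(
    R0 = R0_values,
    sigma_c_lower = vapply(R0_values, sigma_c_lower, numeric(1),
                           alpha0 = alpha0, I0 = I0,
                           c_lower = prefactors$c_lower),
    sigma_c_upper = vapply(R0_values, function(r) {
      tryCatch(sigma_c_upper(alpha0, r, psi_max, prefactors$c_upper),
               evoepi_no_pandemic = function(e) NA_real_)
    }, numeric(1))
  )
}
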