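#' Epidemiological scenario parameters
#'
#' Bundles the wild-type rates and the evolutionary parameters of the
#' reduced model. The wild-type reproduction number is R0 = kbar * beta0 /
#' alpha0; exactly one of `beta0` and `R0` must be supplied (the other is
#' derived via beta0 = alpha0 * R0 / kbar; supplying both consistently is
#' also accepted).
#'
#' Each strain carries an inter-host fitness psi, defined as the ratio
#' (beta/beta0) / (alpha/alpha0), so a strain with fitness psi has
#' reproduction number psi * R0. The wild-type has psi = 1. Which rate
#' absorbs the fitness is set by `mutation_mode`: under alpha-mutations
#' (the default, as in the reference scenarios) beta is frozen at beta0 and
#' alpha = alpha0 / psi; under beta-mutations alpha is frozen and
#' beta = beta0 * psi.
#'
#' @param alpha0 Wild-type recovery rate (per unit time).
#' @param beta0 Wild-type per-edge infection rate (per unit time).
#' @param R0 Wild-type reproduction number; used with `kbar` to derive
#'   `beta0` when the latter is missing.
#' @param kbar Mean degree assumed by the beta0/R0 conversion rule.
#' @param sigma Mutation-step scale: each transmission perturbs the parent
#'   fitness by a Normal(drift, sigma^2) draw.
#' @param mutation_mode `"alpha"` or `"beta"`, see Details.
#' @param eta0 Initial prevalence in (0, 1]; `round(eta0 * N)` nodes are
#'   seeded infected with the wild-type.
#' @param psi_max Cap on the fitness walk (the maximal inter-host fitness
#'   over all attainable strains). `Inf` disables the cap. The default 6
#'   is chosen so that, at the reference sub-pandemic R0 = 0.25, the
#'   fittest attainable strain is comfortably supercritical
#'   (psi_max > 1/R0) while under saturating mutation rates the mean
#'   offspring reproduction at the cap drops below 1, so that the
#'   volatile phase exists (see the vignette).
#' @param psi_min Floor applied to psi only when dividing alpha0 by it
#'   (alpha mode), keeping recovery rates finite.
#' @param t_max Simulation horizon.
#' @param drift Optional mean of the per-transmission fitness step
#'   (0 = unbiased walk; positive values model, e.g., drug-resistance bias).
#' @return An object of class `epi_params`.
#' @examples
#' p <- epi_params(alpha0 = 0.1, R0 = 1.2, kbar = 15, sigma = 0.02)
#' p$beta0        # 0.008
#' @export
epi_params <- function(alpha0 = 0.1, beta0 = NULL, R0 = NULL, kbar = 15,
                       sigma = 0, mutation_mode = c("alpha", "beta"),
                       eta0 = 0.02, psi_max = 6, psi_min = 1e-3,
                       t_max = 2000, drift = 0) {
  mutation_mode <- match.arg(mutation_mode)
  stopifnot(alpha0 > 0, kbar > 0, sigma >= 0, eta0 > 0, eta0 <= 1,
            psi_max > 0, psi_min > 0, t_max > 0)
  if (is.null(beta0) && is.null(R0)) stop("supply `beta0` or `R0`")
  if (is.null(beta0)) beta0 <- alpha0 * R0 / kbar
  if (is.null(R0)) R0 <- kbar * beta0 / alpha0
  if (abs(beta0 - alpha0 * R0 / kbar) > 1e-9 * beta0) {
    stop("`beta0` and `R0` conflict: beta0 must equal alpha0 * R0 / kbar")
  }
  stopifnot(beta0 > 0)
  structure(
    list(alpha0 = alpha0, beta0 = beta0, R0 = R0, kbar = kbar,
         sigma = sigma, mutation_mode = mutation_mode, eta0 = eta0,
         psi_max = psi_max, psi_min = psi_min, t_max = t_max, drift = drift),
    class = "epi_params"
  )
}

#' @export
print.epi_params <- function(x, ...) {
  cat(sprintf(
    "<epi_params> alpha0=%g beta0=%g (R0=%g at kbar=%g) sigma=%g [%s-mutations]\n",
    x$alpha0, x$beta0, x$R0, x$kbar, x$sigma, x$mutation_mode))
  cat(sprintf("  eta0=%g psi_max=%g psi_min=%g t_max=%g drift=%g\n",
              x$eta0, x$psi_max, x$psi_min, x$t_max, x$drift))
  invisible(x)
}

#' Per-strain recovery and infection rates
#'
#' Maps a strain's inter-host fitness psi onto its rates. Both modes
#' preserve the defining identity (beta/beta0)/(alpha/alpha0) = psi, up to
#' the psi_min floor used in alpha mode to keep alpha finite.
#'
#' @param psi Non-negative fitness value(s).
#' @param params An `epi_params`.
#' @return List with vectors `alpha` and `beta`.
#' @examples
#' p <- epi_params(alpha0 = 0.1, beta0 = 0.008, kbar = 15)
#' strain_rates(1, p)   # wild-type: alpha0, beta0
#' @export
strain_rates <- function(psi, params) {
  stopifnot(all(psi >= 0))
  if (params$mutation_mode == "alpha") {
    list(alpha = params$alpha0 / pmax(psi, params$psi_min),
         beta = rep_len(params$beta0, length(psi)))
  } else {
    list(alpha = rep_len(params$alpha0, length(psi)),
         beta = params$beta0 * psi)
  }
}

#' Per-transmission fitness jump
#'
#' The transmitted strain's fitness is the parent fitness plus a
#' Normal(drift, sigma^2) step, clamped to [0, psi_max]. With sigma = 0 and
#' drift = 0 fitness is inherited unchanged and the model reduces to the
#' classic SIR/SIS.
#'
#' @param psi_parent Fitness(es) of the transmitting strain.
#' @param params An `epi_params`.
#' @param n Number of draws (default one per parent value).
#' @return Numeric vector of offspring fitness values.
#' @export
psi_jump <- function(psi_parent, params, n = length(psi_parent)) {
  stopifnot(all(psi_parent >= 0))
  step <- if (params$sigma > 0) stats::rnorm(n, params$drift, params$sigma)
          else rep_len(params$drift, n)
  pmin(pmax(psi_parent + step, 0), params$psi_max)
}

#' Schedule a mitigation that rescales the wild-type reproduction number
#'
#' From time `t_R` onwards the wild-type infection rate beta0 is rescaled
#' so that the wild-type reproduction number becomes `R_R` (circulating
#' strains keep their fitness values; their rates are re-derived from the
#' new beta0). `t_R = 0` is equivalent to running with `R_R` from the
#' start, and `R_R` equal to the current R0 is a no-op.
#'
#' @param params An `epi_params`.
#' @param t_R Time at which mitigation is applied (>= 0).
#' @param R_R Post-mitigation wild-type reproduction number (<= R0).
#' @return An object of class `mitigation_schedule` accepted by
#'   [run_sir()].
#' @examples
#' p <- epi_params(R0 = 1.2, sigma = 0.03)
#' apply_mitigation(p, t_R = 75, R_R = 0.6)
#' @export
apply_mitigation <- function(params, t_R, R_R) {
  stopifnot(inherits(params, "epi_params"))
  if (t_R < 0) stop("`t_R` must be non-negative")
  if (R_R <= 0) stop("`R_R` must be positive")
  if (R_R > params$R0) stop("`R_R` must not exceed the pre-mitigation R0")
  structure(
    list(t_R = t_R, R_R = R_R,
         beta0_new = params$alpha0 * R_R / params$kbar),
    class = "mitigation_schedule"
  )
}

#' @export
print.mitigation_schedule <- function(x, ...) {
  cat(sprintf("<mitigation_schedule> at t=%g rescale wild-type to R_R=%g (beta0 -> %g)\n",
              x$t_R, x$R_R, x$beta0_new))
  invisible(x)
}
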