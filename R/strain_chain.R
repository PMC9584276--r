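#' Intra-host strain chain
#'
#' Strains are sites on a one-dimensional lattice indexed by genetic
#' distance from the wild-type (index 1 here; the chain centre is used as
#' the default infecting strain). Replication mutates a strain into either
#' neighbour with probability `p` each (staying put with 1 - 2p; mass at
#' the chain ends reflects). Every strain carries two independent fitness
#' values: the intra-host replication fitness phi (drawn per host,
#' Normal(1, sigma_phi^2) clamped at 0) and the inter-host transmissibility
#' fitness psi (drawn once per chain, Normal(1, sigma_psi^2) clamped at 0).
#' Intra-host selection acts on phi only, so psi is carried along
#' neutrally -- the source of the effective random walk in psi-space.
#'
#' @param n_strains Number of strains on the chain (>= 2).
#' @param p Per-replication mutation probability to each neighbour, in
#'   [0, 0.5].
#' @param sigma_phi Spread of the intra-host fitness draws.
#' @param sigma_psi Spread of the inter-host fitness draws.
#' @param seed Optional integer seed; the same seed reproduces the draws.
#' @return An object of class `strain_chain` with fields `n_strains`, `p`,
#'   `sigma_phi`, `sigma_psi`, `phi`, `psi`.
#' @examples
#' ch <- build_strain_chain(21, p = 0.25, sigma_phi = 0.1, sigma_psi = 0.1,
#'                          seed = 1)
#' mutation_matrix(ch)[10, 9:11]   # (p, 1 - 2p, p)
#' @export
build_strain_chain <- function(n_strains = 201, p = 0.01, sigma_phi = 0.1,
                               sigma_psi = 0.1, seed = NULL) {
  if (n_strains < 2) stop("`n_strains` must be at least 2")
  if (p < 0 || p > 0.5) {
    stop("`p` must lie in [0, 0.5] (the diagonal 1 - 2p would go negative)")
  }
  stopifnot(sigma_phi >= 0, sigma_psi >= 0)
  with_seed_(seed, {
    phi <- pmax(stats::rnorm(n_strains, 1, sigma_phi), 0)
    psi <- pmax(stats::rnorm(n_strains, 1, sigma_psi), 0)
    structure(
      list(n_strains = as.integer(n_strains), p = p,
           sigma_phi = sigma_phi, sigma_psi = sigma_psi,
           phi = phi, psi = psi),
      class = "strain_chain"
    )
  })
}

#' @export
print.strain_chain <- function(x, ...) {
  cat(sprintf("<strain_chain> %d strains, p=%g, sigma_phi=%g, sigma_psi=%g\n",
              x$n_strains, x$p, x$sigma_phi, x$sigma_psi))
  invisible(x)
}

#' Dense mutation matrix of a strain chain
#'
#' Row-stochastic tridiagonal matrix: off-diagonals `p`, diagonal
#' `1 - 2p`, with reflecting ends (mass that would leave the chain stays
#' put, so the end diagonal is `1 - p`).
#'
#' @param chain A `strain_chain`.
#' @return An `n_strains` x `n_strains` matrix.
#' @export
mutation_matrix <- function(chain) {
  n <- chain$n_strains
  p <- chain$p
  M <- diag(1 - 2 * p, n)
  if (n > 1) {
    idx <- seq_len(n - 1)
    M[cbind(idx, idx + 1)] <- p
    M[cbind(idx + 1, idx)] <- p
  }
  M[1, 1] <- 1 - p
  M[n, n] <- 1 - p
  M
}

#' Multistrain composition of a host
#'
#' The frequency vector Z over the strains of a chain: entry mu is the
#' fraction of the host's pathogen population that is strain mu.
#'
#' @param chain A `strain_chain`.
#' @param strain Index of the single initially present strain (default:
#'   chain centre), ignored when `freqs` is given.
#' @param freqs Optional full frequency vector (will be normalized).
#' @return An object of class `multistrain` with fields `freqs` and
#'   `rho_elapsed`.
#' @export
multistrain <- function(chain, strain = NULL, freqs = NULL) {
  stopifnot(inherits(chain, "strain_chain"))
  n <- chain$n_strains
  if (is.null(freqs)) {
    if (is.null(strain)) strain <- (n + 1L) %/% 2L
    stopifnot(strain >= 1, strain <= n)
    freqs <- numeric(n)
    freqs[strain] <- 1
  } else {
    stopifnot(length(freqs) == n, all(freqs >= 0), sum(freqs) > 0)
    freqs <- freqs / sum(freqs)
  }
  structure(list(freqs = freqs, rho_elapsed = 0L), class = "multistrain")
}

#' @export
print.multistrain <- function(x, ...) {
  top <- order(x$freqs, decreasing = TRUE)[1:min(3, length(x$freqs))]
  cat(sprintf("<multistrain> %d strains, %d replication cycles elapsed\n",
              length(x$freqs), x$rho_elapsed))
  cat("  top strains:",
      paste(sprintf("#%d (%.3f)", top, x$freqs[top]), collapse = ", "), "\n")
  invisible(x)
}

#' Replicator-mutator update of a multistrain
#'
#' Applies `rho` replication cycles: frequencies are multiplied by the
#' intra-host fitness phi (selection), passed through the mutation matrix
#' (diffusion along the chain) and renormalized. The update is
#' deterministic in the frequencies; the stochastic lineage picture is
#' recovered by [sample_transmission()].
#'
#' @param chain A `strain_chain`.
#' @param z A `multistrain`.
#' @param rho Number of replication cycles (positive integer).
#' @return The updated `multistrain`.
#' @examples
#' ch <- build_strain_chain(3, p = 0, sigma_phi = 0, sigma_psi = 0)
#' ch$phi <- c(2, 1, 1)
#' z <- multistrain(ch, freqs = c(0.5, 0.5, 0))
#' replicate_select(ch, z, 1)$freqs   # (2/3, 1/3, 0)
#' @export
replicate_select <- function(chain, z, rho) {
  stopifnot(inherits(chain, "strain_chain"), inherits(z, "multistrain"),
            rho >= 1)
  n <- chain$n_strains
  p <- chain$p
  phi <- chain$phi
  f <- z$freqs
  for (r in seq_len(rho)) {
    w <- f * phi
    s <- sum(w)
    if (s <= 0) {
      stop("degenerate chain: all currently present strains have fitness 0")
    }
    w <- w / s
    f <- (1 - 2 * p) * w
    f[1] <- f[1] + p * w[1]
    f[n] <- f[n] + p * w[n]
    f[-1] <- f[-1] + p * w[-n]
    f[-n] <- f[-n] + p * w[-1]
  }
  structure(list(freqs = f / sum(f), rho_elapsed = z$rho_elapsed + as.integer(rho)),
            class = "multistrain")
}

#' Marginal fitness distributions of a multistrain
#'
#' Collapses the composition onto the two fitness axes: the probability
#' that a randomly sampled pathogen has intra-host fitness phi,
#' respectively inter-host fitness psi. Returned as weighted empirical
#' distributions (mass on each distinct fitness value).
#'
#' @param chain A `strain_chain`.
#' @param z A `multistrain`.
#' @return List of two data frames `phi` and `psi`, each with columns
#'   `value` and `mass` (masses sum to 1).
#' @export
fitness_marginals <- function(chain, z) {
  stopifnot(inherits(chain, "strain_chain"), inherits(z, "multistrain"))
  marg <- function(values) {
    agg <- rowsum(z$freqs, group = values)
    data.frame(value = as.numeric(rownames(agg)), mass = as.numeric(agg))
  }
  list(phi = marg(chain$phi), psi = marg(chain$psi))
}

#' Sample the transmitted pathogen from a host
#'
#' Draws one strain with probability equal to its current frequency and
#' returns its fitness pair; this seeds the recipient's intra-host
#' dynamics.
#'
#' @param chain A `strain_chain`.
#' @param z A `multistrain`.
#' @param seed Optional integer seed.
#' @return Named numeric vector `c(phi =, psi =)` with attribute `strain`
#'   (the sampled index).
#' @export
sample_transmission <- function(chain, z, seed = NULL) {
  stopifnot(inherits(chain, "strain_chain"), inherits(z, "multistrain"))
  with_seed_(seed, {
    mu <- sample.int(chain$n_strains, 1L, prob = z$freqs)
    structure(c(phi = chain$phi[mu], psi = chain$psi[mu]), strain = mu)
  })
}

#' Estimate the effective inter-host mutation rate
#'
#' Simulates independent host passages: each passage infects a fresh host
#' (fresh fitness draws) with the centre strain, runs `rho` replication
#' cycles of [replicate_select()], and samples the transmitted pathogen.
#' Because intra-host selection ignores psi, the per-passage change
#' delta_psi = psi(transmitted) - psi(initial) is a zero-mean draw whose
#' standard deviation is the effective mutation rate sigma of the reduced
#' inter-host random walk; that standard deviation is what is returned.
#'
#' @param n_strains,p,sigma_phi,sigma_psi Chain parameters, see
#'   [build_strain_chain()].
#' @param rho Replication cycles per passage.
#' @param n_passages Number of independent passages; below 100 the
#'   estimate is flagged (attribute `wide_ci = TRUE`), not rejected.
#' @param seed Optional integer seed.
#' @return The estimated sigma, with attributes `delta_psi` (the raw
#'   per-passage changes), `mean_delta` and `se_mean`, and `wide_ci`.
#' @examples
#' sig <- estimate_effective_sigma(21, p = 0.05, sigma_phi = 0.05,
#'                                 sigma_psi = 0.1, rho = 200,
#'                                 n_passages = 50, seed = 1)
#' @export
estimate_effective_sigma <- function(n_strains, p, sigma_phi, sigma_psi,
                                     rho, n_passages = 200, seed = NULL) {
  stopifnot(n_passages >= 2)
  with_seed_(seed, {
    dpsi <- vapply(seq_len(n_passages), function(k) {
      ch <- build_strain_chain(n_strains, p, sigma_phi, sigma_psi)
      z0 <- multistrain(ch)
      psi0 <- ch$psi[(n_strains + 1L) %/% 2L]
      z1 <- if (p == 0 && sigma_phi == 0) z0 else replicate_select(ch, z0, rho)
      unname(sample_transmission(ch, z1)["psi"]) - psi0
    }, numeric(1))
    est <- stats::sd(dpsi)
    if (p == 0) est <- 0  # no mutation: delta_psi is identically zero
    structure(est,
              delta_psi = dpsi,
              mean_delta = mean(dpsi),
              se_mean = stats::sd(dpsi) / sqrt(n_passages),
              wide_ci = n_passages < 100)
  })
}

#' Write a chain + composition as a tidy CSV table
#'
#' One row per strain: index, intra-host fitness, inter-host fitness and
#' current frequency.
#'
#' @param chain A `strain_chain`.
#' @param z Optional `multistrain` (frequencies default to NA).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_strain_chain <- function(chain, path, z = NULL) {
  df <- data.frame(strain = seq_len(chain$n_strains),
                   phi = chain$phi, psi = chain$psi,
                   freq = if (is.null(z)) NA_real_ else z$freqs)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
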