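#' Intrinsic noise from the linear-noise approximation
#'
#' Deterministic companion to the stochastic simulator: stationary means
#' from the ODE equilibrium and the stationary covariance of the linearised
#' fluctuations, obtained by solving the Lyapunov equation
#' `A S + S A' + B = 0` with `A` the Jacobian of the 2n-species model at
#' equilibrium and `B` the (diagonal) diffusion matrix of birth and death
#' fluxes. Exact for the unregulated gene and accurate to `O(1/P_eq)` for
#' the autoregulated one; the test suite cross-checks it against the exact
#' simulator. Because it is noise-free, it resolves the sub-percent Fano
#' differences between heterozygotes and homozygotes that drive noise
#' under-dominance, which Monte-Carlo error would otherwise swamp.
#'
#' @inheritParams derivatives
#' @return A list with `mean_P`, `var_P`, `fano_P`, `mean_M`, `fano_M` and
#'   the full stationary covariance matrix `covariance` (state order
#'   `m_1..m_n, p_1..p_n`).
#' @examples
#' lna_moments(homozygote(10), default_params())$fano_P
#' @export
lna_moments <- function(genotype, params) {
  n <- genotype$ploidy
  eq <- equilibrium_state(genotype, params)
  fp <- repression_deriv(eq$P, genotype$K, genotype$h)
  A <- matrix(0, 2 * n, 2 * n)
  for (i in seq_len(n)) {
    A[i, i] <- -params$delta_m
    A[i, n + seq_len(n)] <- params$beta_r * fp[i]
    A[n + i, i] <- params$alpha
    A[n + i, n + i] <- -params$delta_p
  }
  rate_tx <- params$beta_b + params$beta_r * repression(eq$P, genotype$K,
                                                        genotype$h)
  B <- diag(c(rate_tx + params$delta_m * eq$m,
              params$alpha * eq$m + params$delta_p * eq$p), 2 * n)
  I <- diag(2 * n)
  S <- matrix(solve(kronecker(I, A) + kronecker(A, I), -as.vector(B)), 2 * n)
  ip <- n + seq_len(n)
  im <- seq_len(n)
  list(mean_P = eq$P, var_P = sum(S[ip, ip]),
       fano_P = sum(S[ip, ip]) / eq$P,
       mean_M = eq$M, fano_M = sum(S[im, im]) / eq$M,
       covariance = S)
}

#' Noise-selection landscape: optimum and under-dominance thresholds
#'
#' Characterises selection on binding strength when fitness is the
#' stationary intrinsic noise (protein Fano factor), using the
#' linear-noise approximation for the curve shapes:
#' \itemize{
#'   \item `K_noise_opt` — the homozygote dissociation constant minimising
#'     the Fano factor (the noise-optimal binding strength);
#'   \item `K_het_threshold` — the strongest binding (smallest `K_res`)
#'     reachable without a heterozygote noise increase: the root of the
#'     heterozygote-vs-resident Fano change for a mutation of size
#'     `delta_eps`, below which mutations are deleterious in the
#'     heterozygote;
#'   \item `K_hom_threshold` — the analogous root for the mutant
#'     homozygote, i.e. where further strengthening stops reducing noise
#'     even in homozygotes.
#' }
#' Noise under-dominance is summarised by
#' `ratio_het_threshold = K_het_threshold / K_noise_opt`: how many-fold
#' weaker the maximum evolvable binding is than the noise optimum.
#'
#' @param params an [model_params()].
#' @param delta_eps mutation size in kT (default 1).
#' @param h Hill coefficient (default 1).
#' @param search_range search interval for thresholds, as multiples of
#'   `K_noise_opt`.
#' @return A list with `K_noise_opt`, `K_het_threshold`,
#'   `K_hom_threshold`, `ratio_het_threshold`, `ratio_hom_threshold`.
#' @examples
#' \donttest{
#' noise_selection_landscape(default_params())
#' }
#' @export
noise_selection_landscape <- function(params, delta_eps = 1, h = 1,
                                      search_range = c(1e-2, 1e4)) {
  fano_hom <- function(K) lna_moments(homozygote(K, h), params)$fano_P
  pct_het <- function(K) {
    fr <- fano_hom(K)
    (lna_moments(heterozygote(K, K * exp(-delta_eps), h), params)$fano_P - fr) / fr
  }
  pct_hom <- function(K) {
    fr <- fano_hom(K)
    (fano_hom(K * exp(-delta_eps)) - fr) / fr
  }
  # locate the Fano minimum over log K
  red <- qss_reduce(params, homozygote(1, h))
  K_ref <- optimal_Kd(red, h)
  op <- optimize(function(lk) fano_hom(exp(lk)),
                 interval = log(K_ref * c(1e-3, 1e3)), tol = 1e-8)
  K_noise_opt <- exp(op$minimum)
  root_of <- function(f) {
    lo <- log(K_noise_opt * search_range[1])
    hi <- log(K_noise_opt * search_range[2])
    exp(uniroot(function(lk) f(exp(lk)), lower = lo, upper = hi,
                tol = 1e-10)$root)
  }
  K_het <- root_of(pct_het)
  K_hom <- root_of(pct_hom)
  list(K_noise_opt = K_noise_opt,
       K_het_threshold = K_het, K_hom_threshold = K_hom,
       ratio_het_threshold = K_het / K_noise_opt,
       ratio_hom_threshold = K_hom / K_noise_opt)
}
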