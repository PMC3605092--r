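#' Hill repression function
#'
#' Fraction of maximal regulated transcription remaining when the total
#' cellular protein concentration is `P`:
#' `f(P) = 1 / (1 + (P/K)^h)`. Strictly decreasing in `P`, strictly
#' increasing in `K`; equals 1 at `P = 0` and 1/2 at `P = K`.
#'
#' @param P total protein concentration (>= 0); vectorised.
#' @param K dissociation constant (> 0).
#' @param h Hill coefficient (>= 1).
#' @return Repression fraction in (0, 1].
#' @examples
#' repression(0, K = 1)        # 1: no repressor present
#' repression(2, K = 2)        # 0.5: half-maximum at P = K
#' repression(4, K = 2, h = 8) # nearly full repression for steep h
#' @export
repression <- function(P, K, h = 1) {
  if (!is.numeric(K) || any(K <= 0))
    stop("'K' must be strictly positive", call. = FALSE)
  if (!is.numeric(h) || any(h < 1))
    stop("'h' must be >= 1", call. = FALSE)
  if (any(P < 0)) stop("'P' must be non-negative", call. = FALSE)
  1 / (1 + (P / K)^h)
}

# derivative of the repression function with respect to P (vectorised over
# all three arguments with recycling; the P = 0 limit is -1/K for h = 1 and
# 0 for h > 1)
repression_deriv <- function(P, K, h = 1) {
  n <- max(length(P), length(K), length(h))
  P <- rep_len(P, n); K <- rep_len(K, n); h <- rep_len(h, n)
  out <- numeric(n)
  nz <- P > 0
  x <- (P[nz] / K[nz])^h[nz]
  out[nz] <- -(h[nz] / P[nz]) * x / (1 + x)^2
  out[!nz] <- ifelse(h[!nz] == 1, -1 / K[!nz], 0)
  out
}

#' Time derivatives of the two-allele expression model
#'
#' The deterministic model: each allele `i` transcribes mRNA at rate
#' `beta_b + beta_r * f(P; K_i, h_i)` where `P` is the *total* protein
#' concentration (both alleles repress through the shared pool), mRNA decays
#' at `delta_m`, protein is translated at `alpha` per mRNA and decays at
#' `delta_p`:
#' \deqn{dm_i/dt = \beta_b + \beta_r f(P; K_i, h_i) - \delta_m m_i, \quad
#'       dp_i/dt = \alpha m_i - \delta_p p_i.}
#'
#' @param state an [system_state()] whose dimension matches the ploidy.
#' @param genotype an [genotype()].
#' @param params an [model_params()].
#' @return A list with per-allele derivative vectors `dm` and `dp`.
#' @examples
#' pr <- default_params()
#' g <- homozygote(1)
#' eq <- equilibrium_state(g, pr)
#' derivatives(eq, g, pr)  # all (numerically) zero at the fixed point
#' @export
derivatives <- function(state, genotype, params) {
  check_state(state, genotype)
  P <- state$P
  f <- repression(P, genotype$K, genotype$h)
  list(dm = params$beta_b + params$beta_r * f - params$delta_m * state$m,
       dp = params$alpha * state$m - params$delta_p * state$p)
}

#' Equilibrium total protein concentration
#'
#' Solves the scalar fixed-point condition for the total protein level,
#' \deqn{P = \frac{\alpha}{\delta_m \delta_p}
#'       \sum_i \left[\beta_b + \beta_r f(P; K_i, h_i)\right],}
#' whose right-hand side is strictly decreasing in `P`, so the positive
#' solution is unique. Solved by bisection between the closed-form
#' full-repression and no-repression limits.
#'
#' @inheritParams derivatives
#' @param tol relative tolerance of the bisection (default: near machine
#'   precision).
#' @return The equilibrium total protein concentration (scalar).
#' @examples
#' pr <- default_params()
#' equilibrium_total_protein(homozygote(1), pr)
#' # K -> Inf removes repression: 2 * alpha * beta_max / (delta_m * delta_p)
#' equilibrium_total_protein(homozygote(1e12), pr)
#' @export
equilibrium_total_protein <- function(genotype, params, tol = 8e-16) {
  a <- params$alpha / (params$delta_m * params$delta_p)
  P_min <- a * genotype$ploidy * params$beta_b
  P_max <- a * genotype$ploidy * params$beta_max
  resid <- function(P)
    a * sum(params$beta_b + params$beta_r * repression(P, genotype$K, genotype$h)) - P
  lo <- P_min * (1 - 1e-9)
  hi <- P_max * (1 + 1e-9)
  # monotone residual: positive at lo, negative at hi
  for (i in 1:120) {
    mid <- 0.5 * (lo + hi)
    if (resid(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol * P_max) break
  }
  0.5 * (lo + hi)
}

#' Per-allele equilibrium state
#'
#' The allelic split of the equilibrium: each allele's mRNA settles at its
#' own transcription rate over `delta_m`, evaluated at the shared equilibrium
#' total protein `P_eq`; protein follows as `alpha * m / delta_p`. In a
#' heterozygote the more strongly binding allele (smaller `K`) is more
#' strongly repressed and therefore expressed at the lower level.
#'
#' @inheritParams derivatives
#' @return An [system_state()] at equilibrium; `sum(p)` reproduces
#'   [equilibrium_total_protein()].
#' @examples
#' eq <- equilibrium_state(heterozygote(10, 1), default_params())
#' eq$p  # the K = 1 allele is the more repressed, lower-expressed one
#' @export
equilibrium_state <- function(genotype, params) {
  P_eq <- equilibrium_total_protein(genotype, params)
  m <- (params$beta_b +
          params$beta_r * repression(P_eq, genotype$K, genotype$h)) / params$delta_m
  system_state(m = m, p = params$alpha * m / params$delta_p)
}

#' Integrate the full expression model
#'
#' Reference trajectory integration of the two-allele model with
#' `deSolve::ode` (lsoda). This is the package's reference numerical path;
#' the compiled fixed-step integrator behind [response_time()] is
#' cross-validated against it.
#'
#' @inheritParams derivatives
#' @param times numeric vector of output times (first element is the initial
#'   time).
#' @param state initial [system_state()]; defaults to the all-zero state.
#' @param rtol,atol integrator tolerances.
#' @return A data.frame with columns `time`, `m1`, `p1` (and `m2`, `p2`
#'   for diploids) plus the totals `M`, `P`.
#' @examples
#' tr <- integrate_model(homozygote(1), default_params(), times = seq(0, 5, 0.1))
#' head(tr)
#' @export
integrate_model <- function(genotype, params, times,
                            state = NULL, rtol = 1e-10, atol = 1e-12) {
  n <- genotype$ploidy
  if (is.null(state)) state <- system_state(rep(0, n), rep(0, n))
  check_state(state, genotype)
  y0 <- c(state$m, state$p)
  rhs <- function(t, y, parms) {
    st <- list(m = y[seq_len(n)], p = y[n + seq_len(n)], P = sum(y[n + seq_len(n)]))
    d <- derivatives(structure(st, class = "nar_state"), genotype, params)
    list(c(d$dm, d$dp))
  }
  out <- deSolve::ode(y0, times, rhs, parms = NULL, rtol = rtol, atol = atol)
  out <- as.data.frame(out)
  names(out) <- c("time", paste0("m", seq_len(n)), paste0("p", seq_len(n)))
  out$M <- rowSums(out[, paste0("m", seq_len(n)), drop = FALSE])
  out$P <- rowSums(out[, paste0("p", seq_len(n)), drop = FALSE])
  out
}
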