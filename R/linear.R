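#' Quasi-steady-state reduction of the expression model
#'
#' When mRNA turns over much faster than protein (`delta_m > delta_p`), the
#' transcription output equilibrates rapidly and the 2n-dimensional model
#' reduces to n protein equations,
#' \deqn{dp_i/dt = c\,(b + f(P; K_i, h_i)) - \delta_p p_i,}
#' with effective production scale `c = alpha * beta_r / delta_m` per allele
#' and rescaled basal rate `b = beta_b / beta_r`. The reduction is exact at
#' fixed points and approximates the slow dynamics away from them.
#'
#' @inheritParams derivatives
#' @return An object of class `nar_reduced` with fields `c`, `b`, `delta_p`,
#'   `K`, `h`, `ploidy`.
#' @examples
#' red <- qss_reduce(default_params(), homozygote(1))
#' red$c  # alpha * beta_r / delta_m
#' @export
qss_reduce <- function(params, genotype) {
  stopifnot(inherits(params, "nar_params"), inherits(genotype, "nar_genotype"))
  if (params$delta_m <= params$delta_p)
    warning("timescale separation delta_m > delta_p violated; ",
            "the quasi-steady-state reduction may be inaccurate",
            call. = FALSE)
  structure(list(c = params$alpha * params$beta_r / params$delta_m,
                 b = params$beta_b / params$beta_r,
                 delta_p = params$delta_p,
                 K = genotype$K, h = genotype$h, ploidy = genotype$ploidy),
            class = "nar_reduced")
}

# replace the allele set of a reduced model
reduced_with <- function(red, K, h) {
  red$K <- rep_len(K, red$ploidy)
  red$h <- rep_len(h, red$ploidy)
  red
}

#' @describeIn qss_reduce time derivatives of the reduced (protein-only)
#'   system at protein vector `p`.
#' @param red an `nar_reduced` model.
#' @param p per-allele protein concentrations.
#' @export
reduced_derivatives <- function(red, p) {
  P <- sum(p)
  red$c * (red$b + repression(P, red$K, red$h)) - red$delta_p * p
}

#' @describeIn qss_reduce equilibrium of the reduced system: a list with
#'   per-allele `p` and total `P` (identical to the full model's equilibrium).
#' @export
reduced_equilibrium <- function(red) {
  P_min <- red$ploidy * red$c * red$b / red$delta_p
  P_max <- red$ploidy * red$c * (red$b + 1) / red$delta_p
  resid <- function(P)
    sum(red$c * (red$b + repression(P, red$K, red$h))) / red$delta_p - P
  lo <- P_min * (1 - 1e-9); hi <- P_max * (1 + 1e-9)
  for (i in 1:120) {
    mid <- 0.5 * (lo + hi)
    if (resid(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < 8e-16 * P_max) break
  }
  P <- 0.5 * (lo + hi)
  list(p = red$c * (red$b + repression(P, red$K, red$h)) / red$delta_p, P = P)
}

#' @describeIn qss_reduce integrate the reduced system from protein vector
#'   `p0` over `times` (deSolve reference path).
#' @param times output times.
#' @param p0 initial per-allele protein concentrations.
#' @export
integrate_reduced <- function(red, times, p0) {
  out <- deSolve::ode(p0, times, function(t, y, parms)
    list(reduced_derivatives(red, y)), parms = NULL,
    rtol = 1e-10, atol = 1e-12)
  out <- as.data.frame(out)
  names(out) <- c("time", paste0("p", seq_along(p0)))
  out$P <- rowSums(out[, -1, drop = FALSE])
  out
}

#' @describeIn qss_reduce response time of the reduced system, measured
#'   with the same settle-time (last band-exit) protocol as
#'   [response_time()]. Exact timescale separation would make this equal to
#'   the full model's response time; the residual difference quantifies the
#'   quality of the reduction.
#' @param pert an [perturbation()] (mRNA handling does not apply: the
#'   reduced state is protein only).
#' @param horizon integration horizon.
#' @export
reduced_response_time <- function(red, pert = perturbation(),
                                  horizon = 80 / red$delta_p) {
  if (pert$gamma >= pert$theta) return(0)
  eq <- reduced_equilibrium(red)
  tr <- integrate_reduced(red, seq(0, horizon, by = 0.002 / red$delta_p),
                          p0 = pert$gamma * eq$p)
  w <- (1 - pert$theta) * eq$P
  outside <- abs(tr$P - eq$P) > w
  if (outside[nrow(tr)])
    stop("no recovery within horizon ", signif(horizon, 4), call. = FALSE)
  if (!any(outside)) return(0)
  i <- max(which(outside))
  lev <- if (tr$P[i] < eq$P) eq$P - w else eq$P + w
  tr$time[i] + (lev - tr$P[i]) / (tr$P[i + 1] - tr$P[i]) *
    (tr$time[i + 1] - tr$time[i])
}

#' Relaxation rate (Lyapunov exponent) of a homozygote
#'
#' The eigenvalue of the reduced system that governs the relaxation of the
#' total protein level around equilibrium for a genotype whose alleles all
#' carry `(K, h)`:
#' \deqn{\lambda = -\delta_p + n\,c\,f'(P_{eq}; K, h),}
#' with `n` the ploidy. Always strictly negative, and at most
#' `-delta_p` — negative autoregulation can only speed relaxation relative to
#' the unregulated rate. Its magnitude is the recovery rate for small
#' perturbations.
#'
#' @param K,h allele dissociation constant and Hill coefficient.
#' @param red an `nar_reduced` model (provides `c`, `b`, `delta_p`, ploidy).
#' @return The (negative) relaxation eigenvalue.
#' @examples
#' red <- qss_reduce(default_params(), homozygote(1))
#' lyapunov_homozygote(1, 1, red)
#' @export
lyapunov_homozygote <- function(K, h, red) {
  r <- reduced_with(red, K, h)
  eq <- reduced_equilibrium(r)
  -red$delta_p + red$ploidy * red$c * repression_deriv(eq$P, K, h)
}

#' Relaxation rate of a heterozygote
#'
#' The eigenvalue of the reduced two-allele Jacobian
#' `[[c f1' - delta_p, c f1'], [c f2', c f2' - delta_p]]` (evaluated at the
#' heterozygote equilibrium) whose mode carries the total protein level:
#' \deqn{\lambda = -\delta_p + c\,(f_1' + f_2').}
#' The Jacobian's other eigenvalue, exactly `-delta_p`, belongs to the
#' allelic-difference mode `p_1 - p_2`, which is invisible to the total and
#' therefore does not affect recovery of `P`.
#'
#' @param K1,h1,K2,h2 the two alleles' parameters.
#' @param red an `nar_reduced` model with ploidy 2.
#' @return The (negative) relaxation eigenvalue of the total-protein mode.
#' @export
lyapunov_heterozygote <- function(K1, h1, K2, h2, red) {
  if (red$ploidy != 2L)
    stop("heterozygote analysis requires a diploid reduced model",
         call. = FALSE)
  r <- reduced_with(red, c(K1, K2), c(h1, h2))
  eq <- reduced_equilibrium(r)
  -red$delta_p + red$c * (repression_deriv(eq$P, K1, h1) +
                            repression_deriv(eq$P, K2, h2))
}

#' Under-dominance decomposition of the heterozygote relaxation rate
#'
#' Splits the heterozygote's relaxation eigenvalue into the rate of an
#' *expression-matched* homozygote (a homozygote-form system whose
#' equilibrium total protein equals the heterozygote's) minus a
#' non-negative correction driven by allelic divergence:
#' \deqn{|\lambda_{het}| = |\lambda_{hom}(P_{het})| - \mathrm{correction},}
#' where the correction vanishes iff the alleles are identical and grows
#' with the squared difference of their mean steady-state expression levels
#' `delta_sq = (p1_eq - p2_eq)^2`. Signed eigenvalues are returned (both
#' negative); on magnitudes the identity reads as above, equivalently
#' `lambda_het = lambda_hom_matched + correction` for the signed values.
#' The decomposition is derived for alleles sharing the Hill coefficient.
#'
#' @param K1,K2 the two alleles' dissociation constants.
#' @param h shared Hill coefficient.
#' @param red an `nar_reduced` model with ploidy 2.
#' @return An object of class `nar_decomposition`: list with `lambda_het`,
#'   `lambda_hom_matched`, `delta_sq`, `correction`, `P_het`, `K_matched`.
#' @examples
#' red <- qss_reduce(default_params(), homozygote(1))
#' decompose_heterozygote(10, 10 * exp(-1), 1, red)
#' @export
decompose_heterozygote <- function(K1, K2, h, red) {
  if (length(h) != 1L)
    stop("the decomposition requires a Hill coefficient shared by both ",
         "alleles", call. = FALSE)
  if (red$ploidy != 2L)
    stop("requires a diploid reduced model", call. = FALSE)
  r <- reduced_with(red, c(K1, K2), h)
  eq <- reduced_equilibrium(r)
  lam_het <- -red$delta_p + red$c * sum(repression_deriv(eq$P, c(K1, K2), h))
  # homozygote-form system with the same equilibrium total protein:
  # f(P_het; K_m, h) must equal the mean of the two allelic repression levels
  if (K1 == K2) {
    K_m <- K1
  } else {
    f_bar <- mean(repression(eq$P, c(K1, K2), h))
    K_m <- eq$P / (1 / f_bar - 1)^(1 / h)
  }
  lam_hom <- -red$delta_p + 2 * red$c * repression_deriv(eq$P, K_m, h)
  structure(list(lambda_het = lam_het,
                 lambda_hom_matched = lam_hom,
                 delta_sq = diff(eq$p)^2,
                 correction = lam_het - lam_hom,
                 P_het = eq$P, K_matched = K_m),
            class = "nar_decomposition")
}

#' @export
print.nar_decomposition <- function(x, ...) {
  cat(sprintf(paste0("<nar_decomposition> lambda_het = %.6g, ",
                     "lambda_hom_matched = %.6g\n  correction = %.6g, ",
                     "delta_sq = %.6g (P_het = %.6g)\n"),
              x$lambda_het, x$lambda_hom_matched, x$correction, x$delta_sq,
              x$P_het))
  invisible(x)
}

#' Optimal equilibrium protein level for fast small-perturbation recovery
#'
#' The equilibrium total protein level that maximises the magnitude of the
#' homozygote relaxation eigenvalue over binding strengths, found by
#' golden-section search on log K subject to the equilibrium constraint.
#' For `h = 1` the maximiser satisfies the closed-form stationarity
#' condition `P_eq / K = sqrt(1 + 1/b)`, used as an analytic cross-check in
#' the test suite.
#'
#' @param red an `nar_reduced` model.
#' @param h Hill coefficient (default 1).
#' @return `P_opt`, the optimal equilibrium total protein level.
#' @examples
#' red <- qss_reduce(default_params(), homozygote(1))
#' optimal_equilibrium_protein(red, 1)
#' @export
optimal_equilibrium_protein <- function(red, h = 1) {
  K_opt <- optimal_Kd_search(red, h)
  reduced_equilibrium(reduced_with(red, K_opt, h))$P
}

#' Optimal binding strength (dissociation constant)
#'
#' The dissociation constant whose equilibrium protein level equals
#' [optimal_equilibrium_protein()], i.e. the binding strength at which small
#' perturbations decay fastest. Obtained by monotone inversion of the
#' equilibrium map `K -> P_eq(K)`.
#'
#' @inheritParams optimal_equilibrium_protein
#' @return `K_opt`.
#' @examples
#' optimal_Kd(qss_reduce(default_params(), homozygote(1)), 1)
#' @export
optimal_Kd <- function(red, h = 1) {
  P_opt <- optimal_equilibrium_protein(red, h)
  P_max <- red$ploidy * red$c * (red$b + 1) / red$delta_p
  # P_eq(K) is strictly increasing in K
  g <- function(lk) reduced_equilibrium(reduced_with(red, exp(lk), h))$P - P_opt
  uniroot(g, lower = log(P_max) - 40, upper = log(P_max) + 15,
          tol = 1e-12)$root |> exp()
}

# argmax of |lambda_hom| over log K (shared by both optimal_* fronts)
optimal_Kd_search <- function(red, h) {
  P_max <- red$ploidy * red$c * (red$b + 1) / red$delta_p
  bounds <- log(P_max) + c(-40, 15)
  op <- optimize(function(lk) lyapunov_homozygote(exp(lk), h, red),
                 interval = bounds, tol = 1e-10)
  if (min(abs(op$minimum - bounds)) < 1e-3)
    stop("relaxation-rate maximiser at search boundary; widen the search",
         call. = FALSE)
  exp(op$minimum)
}

#' Eigenvalues of the full (unreduced) model Jacobian
#'
#' Analytic Jacobian of the 2n-dimensional mRNA/protein system at its
#' equilibrium, eigen-decomposed numerically. Exposed for cross-validating
#' the quasi-steady-state eigenvalues: the full spectrum contains n fast
#' mRNA modes near `-delta_m` and n slow modes that approach the reduced
#' system's eigenvalues as `delta_m / delta_p` grows.
#'
#' @inheritParams derivatives
#' @return Numeric vector of eigenvalues sorted by decreasing real part
#'   (real parts only; the spectrum is real for this model near the default
#'   regimes — complex pairs are returned by their real part with a warning).
#' @export
full_model_eigenvalues <- function(genotype, params) {
  n <- genotype$ploidy
  eq <- equilibrium_state(genotype, params)
  fp <- repression_deriv(eq$P, genotype$K, genotype$h)
  # state order (m_1..m_n, p_1..p_n)
  J <- matrix(0, 2 * n, 2 * n)
  for (i in seq_len(n)) {
    J[i, i] <- -params$delta_m
    J[i, n + seq_len(n)] <- params$beta_r * fp[i]  # dm_i/dt depends on total P
    J[n + i, i] <- params$alpha
    J[n + i, n + i] <- -params$delta_p
  }
  ev <- eigen(J, only.values = TRUE)$values
  if (any(abs(Im(ev)) > 1e-8 * abs(ev)))
    warning("complex eigenvalues encountered; returning real parts",
            call. = FALSE)
  sort(Re(ev), decreasing = TRUE)
}
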