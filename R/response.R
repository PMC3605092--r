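#' Perturbation/recovery experiment specification
#'
#' A perturbation reduces the protein level (and, by default, also the mRNA
#' level) to a fraction `gamma` of its equilibrium value; the genotype has
#' recovered once the total protein concentration has returned to within
#' `(1 - theta)` of its own equilibrium and stays there. `gamma = 0`
#' corresponds to complete loss (e.g. following division or resource
#' deprivation); `gamma` close to 1 probes the small-perturbation regime
#' captured analytically by the Lyapunov analysis.
#'
#' @param gamma fraction of the equilibrium retained after the perturbation,
#'   in `[0, 1]`.
#' @param theta recovery threshold as a fraction of equilibrium, in (0, 1).
#'   If `gamma >= theta` the recovery time is 0 by definition.
#' @param perturb_mrna whether mRNA is also scaled by `gamma` (default TRUE,
#'   matching the stochastic protocol which reduces both mRNA and protein).
#' @return An object of class `nar_perturbation`.
#' @examples
#' perturbation()                  # full knock-down, 90% recovery threshold
#' perturbation(gamma = 0.5, theta = 0.99)
#' @export
perturbation <- function(gamma = 0, theta = 0.9, perturb_mrna = TRUE) {
  if (!is.numeric(gamma) || gamma < 0 || gamma > 1)
    stop("'gamma' must be in [0, 1]", call. = FALSE)
  if (!is.numeric(theta) || theta <= 0 || theta >= 1)
    stop("'theta' must be in (0, 1)", call. = FALSE)
  structure(list(gamma = gamma, theta = theta,
                 perturb_mrna = isTRUE(perturb_mrna)),
            class = "nar_perturbation")
}

# initial condition of a perturbation experiment
perturbed_state <- function(eq, pert) {
  m0 <- if (pert$perturb_mrna) pert$gamma * eq$m else eq$m
  system_state(m = m0, p = pert$gamma * eq$p)
}

#' Deterministic response time
#'
#' Integrates the full model from the perturbed state and returns the time of
#' the *last exit* from the recovery band
#' `|P(t) - P_eq| <= (1 - theta) * P_eq` around the genotype's own
#' equilibrium. For the typical monotone recovery this equals the first
#' upward crossing of `theta * P_eq`; for strongly binding genotypes whose
#' recovery overshoots the equilibrium, the time also accounts for the decay
#' of the overshoot back into the band, which is what makes over-regulation
#' past the optimal binding strength costly.
#'
#' @inheritParams derivatives
#' @param pert an [perturbation()].
#' @param horizon integration horizon (time units). If the trajectory has not
#'   settled inside the band by then, an error is raised.
#' @param rtol relative tolerance of the adaptive Dormand-Prince (RK45)
#'   integrator (default 1e-8; absolute tolerances are scaled to the
#'   equilibrium state).
#' @param hmax maximum integrator step; the default `0.02/delta_p` also
#'   bounds how long a band excursion can hide between accepted steps.
#' @return Recovery time (scalar, >= 0).
#' @examples
#' pr <- default_params()
#' response_time(homozygote(1), pr)
#' response_time(homozygote(1), pr, perturbation(gamma = 0.95))  # 0 by definition
#' @export
response_time <- function(genotype, params, pert = perturbation(),
                          horizon = 80 / params$delta_p, rtol = 1e-8,
                          hmax = NULL) {
  rt_settle(genotype, params, pert, horizon, rtol, hmax,
            track_alleles = FALSE)[["total"]]
}

#' Per-allele response times
#'
#' Recovery time of each allele's own protein level `p_i(t)` to within
#' `(1 - theta)` of that allele's equilibrium expression in this genotype
#' (last band exit, as in [response_time()]). In a heterozygote the weaker-
#' binding (resident) allele recovers more slowly than it would in the
#' resident homozygote, while the stronger-binding allele recovers faster —
#' the allelic signature of cross-talk through the shared protein pool.
#'
#' @inheritParams response_time
#' @return Named numeric vector with elements `total`, `allele1` (and
#'   `allele2` for diploids).
#' @examples
#' allele_response_times(heterozygote(10, 1), default_params())
#' @export
allele_response_times <- function(genotype, params, pert = perturbation(),
                                  horizon = 80 / params$delta_p, rtol = 1e-8,
                                  hmax = NULL) {
  rt_settle(genotype, params, pert, horizon, rtol, hmax,
            track_alleles = TRUE)
}

# shared driver for the compiled settle-time integrator
rt_settle <- function(genotype, params, pert, horizon, rtol, hmax,
                      track_alleles) {
  stopifnot(inherits(genotype, "nar_genotype"), inherits(params, "nar_params"),
            inherits(pert, "nar_perturbation"))
  n <- genotype$ploidy
  nm <- c("total", if (track_alleles) paste0("allele", seq_len(n)))
  if (pert$gamma >= pert$theta)
    return(setNames(rep(0, length(nm)), nm))
  eq <- equilibrium_state(genotype, params)
  st <- perturbed_state(eq, pert)
  if (is.null(hmax)) hmax <- 0.02 / params$delta_p
  res <- .rt_settle_cpp(c(st$m, st$p), genotype$K, genotype$h,
                        params$beta_b, params$beta_r, params$alpha,
                        params$delta_m, params$delta_p,
                        eq$P, eq$p, scale = c(eq$m, eq$p), pert$theta,
                        hmax, rtol, horizon,
                        confirm = 12 / params$delta_p,
                        track_alleles = track_alleles)
  k <- length(res)
  if (res[k] != 1)
    stop("no recovery within horizon ", signif(horizon, 4),
         "; increase 'horizon'", call. = FALSE)
  out <- res[seq_len(if (track_alleles) 1 + n else 1)]
  setNames(out, nm)
}

#' Reference response time via deSolve
#'
#' Independent implementation of the settle-time measurement using
#' `deSolve::ode` on a dense time grid with interpolated band crossings.
#' Slower than [response_time()]; used to cross-validate the compiled
#' integrator.
#'
#' @inheritParams response_time
#' @param dt output grid spacing for crossing localisation.
#' @return Recovery time (scalar).
#' @export
response_time_ref <- function(genotype, params, pert = perturbation(),
                              horizon = 80 / params$delta_p, dt = 0.002) {
  if (pert$gamma >= pert$theta) return(0)
  eq <- equilibrium_state(genotype, params)
  st <- perturbed_state(eq, pert)
  tr <- integrate_model(genotype, params, times = seq(0, horizon, by = dt),
                        state = st)
  w <- (1 - pert$theta) * eq$P
  outside <- abs(tr$P - eq$P) > w
  if (outside[nrow(tr)])
    stop("no recovery within horizon ", signif(horizon, 4), call. = FALSE)
  if (!any(outside)) return(0)
  i <- max(which(outside))
  lev <- if (tr$P[i] < eq$P) eq$P - w else eq$P + w
  # linear interpolation across the bracketing grid interval
  tr$time[i] + (lev - tr$P[i]) / (tr$P[i + 1] - tr$P[i]) * dt
}

#' Mutant-invasibility grid
#'
#' Response-time differences between a mutation's carrier genotype and the
#' resident homozygote, over a grid of resident dissociation constants and
#' mutation effect sizes. A mutation of size `delta_eps` (in units of kT)
#' strengthens binding to `K_mut = K_res * exp(-delta_eps)`. In
#' `"heterozygote"` mode the carrier is the heterozygote
#' `(K_res, K_mut)` — the genotype in which a new mutation actually occurs —
#' while in `"mutant_homozygote"` mode it is the mutant homozygote
#' `(K_mut, K_mut)`. Cells with `delta_t <= 0` (carrier at least as fast)
#' are favoured by selection for faster response; cells with `delta_t > 0`
#' are disfavoured. Under-dominance shows up as cells disfavoured in
#' heterozygote mode but favoured in mutant-homozygote mode.
#'
#' @param K_res_axis resident dissociation constants (typically log-spaced).
#' @param mutation_axis mutation effect sizes `delta_eps` in kT units (> 0
#'   strengthens binding).
#' @param params an [model_params()].
#' @param pert an [perturbation()].
#' @param mode `"both"` (default), `"heterozygote"` or `"mutant_homozygote"`.
#' @param h shared Hill coefficient of resident and mutant (default 1).
#' @param tie_tol relative tolerance below which a response-time difference
#'   is classified as a tie (favoured), default `1e-9`.
#' @return A data.frame in long format with columns `K_res`, `delta_eps`,
#'   `K_mut`, and per requested mode `delta_t_het`/`delta_t_hom` plus
#'   logical `favoured_het`/`favoured_hom`.
#' @examples
#' pr <- default_params()
#' g <- invasibility_grid(c(1, 10), c(0.5, 2), pr)
#' g
#' @export
invasibility_grid <- function(K_res_axis, mutation_axis, params,
                              pert = perturbation(),
                              mode = c("both", "heterozygote",
                                       "mutant_homozygote"),
                              h = 1, tie_tol = 1e-9) {
  mode <- match.arg(mode)
  stopifnot(length(K_res_axis) > 0, length(mutation_axis) > 0)
  grid <- expand.grid(delta_eps = mutation_axis, K_res = K_res_axis,
                      KEEP.OUT.ATTRS = FALSE)[, c("K_res", "delta_eps")]
  grid$K_mut <- grid$K_res * exp(-grid$delta_eps)
  t_res <- vapply(K_res_axis, function(K)
    response_time(homozygote(K, h), params, pert), numeric(1))
  names(t_res) <- as.character(K_res_axis)
  base <- t_res[as.character(grid$K_res)]
  if (mode %in% c("both", "heterozygote")) {
    t_het <- mapply(function(Kr, Km)
      response_time(heterozygote(Kr, Km, h), params, pert),
      grid$K_res, grid$K_mut)
    grid$delta_t_het <- unname(t_het - base)
    grid$favoured_het <- grid$delta_t_het <= tie_tol * base
  }
  if (mode %in% c("both", "mutant_homozygote")) {
    t_hom <- vapply(grid$K_mut, function(Km)
      response_time(homozygote(Km, h), params, pert), numeric(1))
    grid$delta_t_hom <- unname(t_hom - base)
    grid$favoured_hom <- grid$delta_t_hom <= tie_tol * base
  }
  attr(grid, "t_res") <- t_res
  grid
}

#' Default invasibility axes
#'
#' The default grid spans resident binding from 100-fold stronger to 100-fold
#' weaker than the small-perturbation optimal dissociation constant `K_opt`
#' (40 log-spaced points) and mutation sizes from 0.05 to 5 kT (50 points),
#' covering the empirically typical 1-3 kT range for transcription-factor
#' binding sites.
#'
#' @param params an [model_params()].
#' @param n_K,n_eps number of grid points on each axis.
#' @return A list with elements `K_res` and `delta_eps`.
#' @export
default_invasibility_axes <- function(params, n_K = 40, n_eps = 50) {
  red <- qss_reduce(params, homozygote(1))
  K_opt <- optimal_Kd(red, h = 1)
  list(K_res = K_opt * 10^seq(-2, 2, length.out = n_K),
       delta_eps = seq(0.05, 5, length.out = n_eps))
}

#' Hill-coefficient mutation scan
#'
#' Ratio of the response time of a heterozygote carrying one allele with
#' Hill coefficient `h_res` and one with `h_mut` to that of the
#' `h_res` homozygote, across resident binding strengths. Ratios above 1
#' flag under-dominance of the steepness-increasing mutation.
#'
#' @param K_axis dissociation constants shared by both alleles.
#' @param h_res,h_mut resident and mutant Hill coefficients
#'   (`h_mut >= h_res >= 1`).
#' @inheritParams invasibility_grid
#' @return data.frame with columns `K`, `t_hom`, `t_het`, `ratio`.
#' @export
hill_mutation_scan <- function(K_axis, h_res, h_mut, params,
                               pert = perturbation()) {
  if (!(h_mut >= h_res && h_res >= 1))
    stop("'h_mut >= h_res >= 1' required", call. = FALSE)
  t_hom <- vapply(K_axis, function(K)
    response_time(homozygote(K, h_res), params, pert), numeric(1))
  t_het <- vapply(K_axis, function(K)
    response_time(genotype(c(K, K), c(h_res, h_mut)), params, pert),
    numeric(1))
  data.frame(K = K_axis, t_hom = t_hom, t_het = t_het, ratio = t_het / t_hom)
}

#' Response time across perturbation sizes
#'
#' Response times of one genotype for a vector of retained fractions
#' `gamma`. For weak regulation the times are non-increasing in `gamma`
#' (retaining more of the equilibrium shortens recovery); under strong
#' autoregulation a full knock-down can recover *faster* than a partial
#' one, because the derepressed promoter transcribes maximally at low
#' protein levels.
#'
#' @inheritParams response_time
#' @param gamma_values retained fractions in `[0, 1]`.
#' @param theta recovery threshold.
#' @param perturb_mrna passed to [perturbation()].
#' @return data.frame with columns `gamma` and `time`.
#' @export
perturbation_scan <- function(genotype, params, gamma_values, theta = 0.9,
                              perturb_mrna = TRUE) {
  stopifnot(all(gamma_values >= 0 & gamma_values <= 1))
  times <- vapply(gamma_values, function(g)
    response_time(genotype, params,
                  perturbation(g, theta, perturb_mrna)), numeric(1))
  data.frame(gamma = gamma_values, time = times)
}

#' Directly optimised binding strength for large perturbations
#'
#' The homozygote dissociation constant minimising the full-perturbation
#' response time, found by golden-section search on log K. For large
#' perturbations this direct optimum is stronger (smaller K) than the
#' small-perturbation optimum [optimal_Kd()], because the initial unrepressed
#' rise toward a lower equilibrium favours stronger binding than the local
#' relaxation rate does; the gap widens as the background transcription
#' ratio `beta_b/beta_r` decreases.
#'
#' @inheritParams invasibility_grid
#' @param interval search interval for K (defaults to
#'   `[1e-4, 1e4] * K_opt`).
#' @return A list with `K` (the minimiser) and `time` (its response time).
#' @export
response_time_optimal_K <- function(params, pert = perturbation(), h = 1,
                                    interval = NULL) {
  if (is.null(interval)) {
    K_opt <- optimal_Kd(qss_reduce(params, homozygote(1)), h = h)
    interval <- K_opt * c(1e-4, 1e4)
  }
  obj <- function(lk) response_time(homozygote(exp(lk), h), params, pert)
  op <- optimize(obj, interval = log(interval), tol = 1e-6)
  if (min(abs(op$minimum - log(interval))) < 1e-3)
    stop("minimiser at search boundary; widen 'interval'", call. = FALSE)
  list(K = exp(op$minimum), time = op$objective)
}
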