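#' Stochastic simulation configuration
#'
#' Ensemble settings for the exact (direct-method) stochastic simulations.
#' Times are in the model's time units (protein lifetimes under
#' [default_params()]).
#'
#' @param seed master seed; every replicate derives its own RNG stream from
#'   it (see [derive_seeds()]).
#' @param n_replicates ensemble size (>= 1).
#' @param burn_in burn-in before stationary sampling starts.
#' @param sample_window duration of the stationary sampling window.
#' @param max_time hard horizon for first-passage simulations.
#' @return An object of class `nar_ssa_config`.
#' @export
ssa_config <- function(seed = 1L, n_replicates = 8L, burn_in = 20,
                       sample_window = 300, max_time = 1000) {
  if (n_replicates < 1) stop("'n_replicates' must be >= 1", call. = FALSE)
  if (burn_in <= 0 || sample_window <= 0)
    stop("'burn_in' and 'sample_window' must be positive", call. = FALSE)
  structure(list(seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates),
                 burn_in = burn_in, sample_window = sample_window,
                 max_time = max_time),
            class = "nar_ssa_config")
}

#' Derive per-replicate seeds from a master seed
#'
#' Sub-stream seeds are drawn as a reproducible function of the master seed:
#' the master seed initialises R's RNG, from which `n` distinct integer
#' seeds are sampled. The same master seed therefore always yields the same
#' sequence of replicate streams, independent of evaluation order.
#'
#' @param master master seed (integer).
#' @param n number of seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Reaction propensities of the birth-death scheme
#'
#' Per-reaction transition rates at integer molecule counts. Each allele `i`
#' contributes four reactions (in this order): transcription at
#' `beta_b + beta_r * f(P; K_i, h_i)` with `P` the total protein *count*,
#' mRNA degradation at `delta_m * m_i`, translation at `alpha * m_i`, and
#' protein degradation at `delta_p * p_i`.
#'
#' @param m,p integer per-allele mRNA and protein counts.
#' @inheritParams derivatives
#' @return Named numeric vector of length `4 * ploidy`.
#' @examples
#' propensities(c(0, 0), c(0, 0), homozygote(1), default_params())
#' @export
propensities <- function(m, p, genotype, params) {
  n <- genotype$ploidy
  if (length(m) != n || length(p) != n)
    stop("state dimension does not match ploidy", call. = FALSE)
  if (any(m < 0) || any(p < 0) || any(m != floor(m)) || any(p != floor(p)))
    stop("molecule counts must be non-negative integers", call. = FALSE)
  P <- sum(p)
  out <- numeric(0)
  for (i in seq_len(n)) {
    out <- c(out,
             params$beta_b + params$beta_r * repression(P, genotype$K[i],
                                                        genotype$h[i]),
             params$delta_m * m[i],
             params$alpha * m[i],
             params$delta_p * p[i])
  }
  names(out) <- paste0(rep(c("transcription", "mrna_decay", "translation",
                             "protein_decay"), n),
                       rep(seq_len(n), each = 4))
  out
}

# default initial counts: the deterministic equilibrium, rounded
ssa_initial_counts <- function(genotype, params) {
  eq <- equilibrium_state(genotype, params)
  list(m = as.integer(round(eq$m)), p = as.integer(round(eq$p)))
}

#' Exact stochastic trajectory
#'
#' One realisation of the continuous-time Markov chain by the direct
#' (Gillespie) method, sampled at `sample_times` (piecewise-constant
#' between events). Bit-identical reproducibility is guaranteed given the
#' same seed.
#'
#' @inheritParams derivatives
#' @param config an [ssa_config()]; its `seed` seeds this trajectory
#'   directly.
#' @param sample_times times at which to record the state.
#' @param initial_state optional [system_state()] of integer counts;
#'   defaults to the rounded deterministic equilibrium.
#' @return data.frame with columns `time`, `m1`, `p1` (and `m2`, `p2`),
#'   `M`, `P`.
#' @export
ssa_simulate <- function(genotype, params, config = ssa_config(),
                         sample_times = seq(0, 50, by = 0.1),
                         initial_state = NULL) {
  n <- genotype$ploidy
  init <- if (is.null(initial_state))
    ssa_initial_counts(genotype, params)
  else {
    check_state(initial_state, genotype)
    list(m = as.integer(initial_state$m), p = as.integer(initial_state$p))
  }
  mat <- .ssa_trajectory_cpp(init$m, init$p, genotype$K, genotype$h,
                             params$beta_b, params$beta_r, params$alpha,
                             params$delta_m, params$delta_p,
                             as.numeric(sample_times), config$seed)
  out <- data.frame(time = sample_times)
  for (i in seq_len(n)) out[[paste0("m", i)]] <- mat[, i]
  for (i in seq_len(n)) out[[paste0("p", i)]] <- mat[, n + i]
  out$M <- rowSums(mat[, seq_len(n), drop = FALSE])
  out$P <- rowSums(mat[, n + seq_len(n), drop = FALSE])
  out
}

#' Stationary moments and Fano factor
#'
#' Estimates stationary moments of the total protein and mRNA counts from
#' time-averages (weighting states by their waiting times) over a stationary
#' window, averaged across replicates; standard errors come from the
#' replicate-to-replicate scatter. The Fano factor `var/mean` of the
#' stationary protein count is the package's intrinsic-noise measure.
#'
#' @inheritParams ssa_simulate
#' @return Object of class `nar_moments`: list with `mean_P`, `var_P`,
#'   `fano_P`, `mean_M`, `fano_M`, per-allele protein means `mean_p`,
#'   standard errors `se_mean_P`, `se_fano_P`, and `n_replicates`.
#' @examples
#' \donttest{
#' stationary_moments(homozygote(10), default_params(),
#'                    ssa_config(n_replicates = 4, sample_window = 100))
#' }
#' @export
stationary_moments <- function(genotype, params, config = ssa_config()) {
  n <- genotype$ploidy
  init <- ssa_initial_counts(genotype, params)
  seeds <- derive_seeds(config$seed, config$n_replicates)
  rep_stats <- vapply(seeds, function(s)
    .ssa_moments_cpp(init$m, init$p, genotype$K, genotype$h,
                     params$beta_b, params$beta_r, params$alpha,
                     params$delta_m, params$delta_p,
                     config$burn_in, config$sample_window, s),
    numeric(9))
  mean_P <- rep_stats[1, ]; var_P <- rep_stats[2, ]
  mean_M <- rep_stats[3, ]; var_M <- rep_stats[4, ]
  half1 <- rep_stats[5, ]
  fano_P <- var_P / mean_P
  fano_M <- var_M / mean_M
  nrep <- config$n_replicates
  se <- function(x) if (nrep > 1) sd(x) / sqrt(nrep) else NA_real_
  # stationarity diagnostic: first-half vs full-window mean drift
  if (nrep > 1) {
    drift <- mean(half1) - mean(mean_P)
    if (is.finite(se(mean_P)) && se(mean_P) > 0 &&
        abs(drift) > 3 * se(mean_P) * sqrt(2))
      warning("possible non-stationarity: burn-in mean drift exceeds 3 SE",
              call. = FALSE)
  }
  structure(list(mean_P = mean(mean_P), var_P = mean(var_P),
                 fano_P = mean(fano_P), mean_M = mean(mean_M),
                 fano_M = mean(fano_M),
                 mean_p = rowMeans(rep_stats[7 + seq_len(n), , drop = FALSE]),
                 mean_m = rowMeans(rep_stats[5 + seq_len(n), , drop = FALSE]),
                 se_mean_P = se(mean_P), se_fano_P = se(fano_P),
                 se_fano_M = se(fano_M),
                 n_replicates = nrep),
            class = "nar_moments")
}

#' @export
print.nar_moments <- function(x, ...) {
  cat(sprintf(paste0("<nar_moments> mean_P = %.4g (SE %.2g), fano_P = %.4g ",
                     "(SE %.2g), fano_M = %.4g [%d replicates]\n"),
              x$mean_P, x$se_mean_P, x$fano_P, x$se_fano_P, x$fano_M,
              x$n_replicates))
  invisible(x)
}

#' Noise change of mutation carriers relative to the resident homozygote
#'
#' Percentage change in the stationary protein Fano factor of the
#' heterozygote `(K_res, K_res * exp(-delta_eps))` and of the mutant
#' homozygote, relative to the resident homozygote, across resident binding
#' strengths (and optionally Hill coefficients). Noise under-dominance
#' appears as resident binding strengths where the heterozygote's noise
#' increases while the mutant homozygote's decreases.
#'
#' @param K_res_axis resident dissociation constants.
#' @param delta_eps mutation effect size in kT (default 1, within the
#'   empirically typical 1-3 kT range).
#' @param params an [model_params()].
#' @param h_values Hill coefficients to scan (default 1).
#' @param config an [ssa_config()].
#' @return data.frame with columns `h`, `K_res`, `fano_res`, `pct_het`,
#'   `pct_hom`, `se_pct_het`, `se_pct_hom`.
#' @export
noise_change_grid <- function(K_res_axis, delta_eps = 1, params,
                              h_values = 1, config = ssa_config()) {
  stopifnot(length(K_res_axis) > 0)
  cells <- expand.grid(K_res = K_res_axis, h = h_values,
                       KEEP.OUT.ATTRS = FALSE)
  cell_seeds <- derive_seeds(config$seed, 3 * nrow(cells))
  res <- lapply(seq_len(nrow(cells)), function(j) {
    K <- cells$K_res[j]; h <- cells$h[j]
    Km <- K * exp(-delta_eps)
    cfg <- function(s) {
      config$seed <- s
      config
    }
    f_res <- stationary_moments(homozygote(K, h), params,
                                cfg(cell_seeds[3 * j - 2]))
    f_het <- stationary_moments(heterozygote(K, Km, h), params,
                                cfg(cell_seeds[3 * j - 1]))
    f_hom <- stationary_moments(homozygote(Km, h), params,
                                cfg(cell_seeds[3 * j]))
    pct <- function(fc, fr)
      100 * (fc$fano_P - fr$fano_P) / fr$fano_P
    pct_se <- function(fc, fr)
      100 / fr$fano_P *
        sqrt(fc$se_fano_P^2 + (fc$fano_P / fr$fano_P)^2 * fr$se_fano_P^2)
    data.frame(h = h, K_res = K, fano_res = f_res$fano_P,
               pct_het = pct(f_het, f_res), pct_hom = pct(f_hom, f_res),
               se_pct_het = pct_se(f_het, f_res),
               se_pct_hom = pct_se(f_hom, f_res))
  })
  do.call(rbind, res)
}

#' Stochastic response times
#'
#' Ensemble-mean first-passage time of the total protein count back to
#' `theta` times its stationary mean, after reducing mRNA and protein counts
#' to a fraction `gamma` of their stationary means.
#'
#' @inheritParams ssa_simulate
#' @param gamma_values retained fractions in `[0, 1]`.
#' @param theta recovery threshold (fraction of the stationary mean).
#' @return data.frame with columns `gamma`, `mean_time`, `se`,
#'   `n_censored` (replicates that did not recover within
#'   `config$max_time`; a warning reports the censoring fraction if any).
#' @export
stochastic_response_time <- function(genotype, params, config = ssa_config(),
                                     gamma_values = seq(0, 0.8, by = 0.1),
                                     theta = 0.9) {
  stopifnot(all(gamma_values >= 0 & gamma_values <= 1))
  mom <- stationary_moments(genotype, params, config)
  n <- genotype$ploidy
  m_bar <- mom$mean_m; p_bar <- mom$mean_p
  target <- theta * mom$mean_P
  seeds <- derive_seeds(config$seed + 1L, config$n_replicates * length(gamma_values))
  out <- lapply(seq_along(gamma_values), function(gi) {
    g <- gamma_values[gi]
    tt <- vapply(seq_len(config$n_replicates), function(r) {
      s <- seeds[(gi - 1) * config$n_replicates + r]
      .ssa_fpt_cpp(as.integer(round(g * m_bar)), as.integer(round(g * p_bar)),
                   genotype$K, genotype$h, params$beta_b, params$beta_r,
                   params$alpha, params$delta_m, params$delta_p,
                   target, config$max_time, s)
    }, numeric(1))
    cens <- sum(tt < 0)
    tt <- tt[tt >= 0]
    data.frame(gamma = g,
               mean_time = if (length(tt)) mean(tt) else NA_real_,
               se = if (length(tt) > 1) sd(tt) / sqrt(length(tt)) else NA_real_,
               n_censored = cens)
  })
  out <- do.call(rbind, out)
  if (any(out$n_censored > 0))
    warning(sprintf("%.1f%% of first-passage replicates censored at max_time",
                    100 * sum(out$n_censored) /
                      (config$n_replicates * length(gamma_values))),
            call. = FALSE)
  out
}
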