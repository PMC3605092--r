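test_that("propensities implement the birth-death scheme", {
  pr <- test_params()
  g <- homozygote(1)
  a0 <- propensities(c(0, 0), c(0, 0), g, pr)
  expect_length(a0, 8)
  # empty cell: only transcription is possible, at the unrepressed rate
  expect_equal(unname(a0[grepl("transcription", names(a0))]),
               rep(pr$beta_b + pr$beta_r, 2))
  expect_true(all(a0[!grepl("transcription", names(a0))] == 0))
  # half-maximal repression when the protein count sits at K (h = 1)
  gK <- homozygote(40)
  aK <- propensities(c(1, 1), c(20, 20), gK, pr)
  expect_equal(unname(aK["transcription1"]), pr$beta_b + pr$beta_r / 2)
  # consistency across random states: every entry matches its defining rate
  set.seed(9)
  for (i in 1:50) {
    m <- sample(0:20, 2, TRUE); p <- sample(0:500, 2, TRUE)
    a <- propensities(m, p, g, pr)
    expect_true(all(a >= 0))
    expect_equal(unname(a["mrna_decay2"]), pr$delta_m * m[2])
    expect_equal(unname(a["translation1"]), pr$alpha * m[1])
    expect_equal(sum(a), sum(pr$beta_b + pr$beta_r *
                               repression(sum(p), g$K, g$h)) +
                   pr$delta_m * sum(m) + pr$alpha * sum(m) +
                   pr$delta_p * sum(p))
  }
  expect_error(propensities(c(-1, 0), c(0, 0), g, pr), "non-negative")
})

test_that("trajectories are reproducible and seed-sensitive", {
  pr <- test_params()
  g <- homozygote(3)
  cfg <- ssa_config(seed = 123, n_replicates = 1)
  t1 <- ssa_simulate(g, pr, cfg, sample_times = seq(0, 5, 0.05))
  t2 <- ssa_simulate(g, pr, cfg, sample_times = seq(0, 5, 0.05))
  expect_identical(t1, t2)
  t3 <- ssa_simulate(g, pr, ssa_config(seed = 124), seq(0, 5, 0.05))
  expect_false(identical(t1$P, t3$P))
})

test_that("unregulated mRNA is Poisson: mean beta_b/delta_m and Fano 1", {
  # beta_r = 0 decouples transcription from protein: a pure birth-death
  pr0 <- model_params(beta_b = 40, beta_r = 0, alpha = 100, delta_m = 10,
                      delta_p = 1)
  cfg <- ssa_config(seed = 2, n_replicates = 6, burn_in = 10,
                    sample_window = 150)
  mom <- stationary_moments(haploid(1), pr0, cfg)
  expect_equal(mom$mean_M, pr0$beta_b / pr0$delta_m, tolerance = 0.05)
  expect_lt(abs(mom$fano_M - 1), 3 * max(mom$se_fano_M, 0.01))
})

test_that("stationary protein statistics match closed forms and the ODE mean", {
  pr <- test_params()
  # two-stage unregulated gene: Fano = 1 + alpha/(delta_m + delta_p)
  cfg <- ssa_config(seed = 4, n_replicates = 6, burn_in = 20,
                    sample_window = 400)
  mom <- stationary_moments(homozygote(1e12), pr, cfg)
  fano_theory <- 1 + pr$alpha / (pr$delta_m + pr$delta_p)
  expect_lt(abs(mom$fano_P - fano_theory) / fano_theory, 0.05)
  expect_lt(abs(mom$fano_M - 1), 3 * max(mom$se_fano_M, 0.01))
  # mean tracks the deterministic equilibrium (high-copy regime)
  K_opt <- test_K_opt()
  g <- homozygote(30 * K_opt)
  mom2 <- stationary_moments(g, pr, ssa_config(seed = 5, n_replicates = 6,
                                               sample_window = 300))
  expect_lt(abs(mom2$mean_P - equilibrium_total_protein(g, pr)),
            3 * mom2$se_mean_P + 0.02 * mom2$mean_P)
})

test_that("negative autoregulation reduces protein noise at matched mean", {
  pr <- test_params()
  K_opt <- test_K_opt()
  g <- homozygote(K_opt)
  cfg <- ssa_config(seed = 6, n_replicates = 6, burn_in = 20,
                    sample_window = 400)
  mom_nar <- stationary_moments(g, pr, cfg)
  # an unregulated gene with the same mean expression
  P_eq <- equilibrium_total_protein(g, pr)
  beta_c <- P_eq * pr$delta_m * pr$delta_p / (2 * pr$alpha)
  pr_c <- model_params(beta_c, 1e-12, pr$alpha, pr$delta_m, pr$delta_p)
  mom_c <- stationary_moments(homozygote(1), pr_c, cfg)
  expect_lt(mom_nar$fano_P, mom_c$fano_P - 3 * (mom_nar$se_fano_P +
                                                  mom_c$se_fano_P))
})

test_that("linear-noise moments agree with the exact simulator", {
  pr <- test_params()
  K_opt <- test_K_opt()
  cfg <- ssa_config(seed = 8, n_replicates = 8, burn_in = 20,
                    sample_window = 500)
  for (g in list(homozygote(10 * K_opt), heterozygote(10 * K_opt, K_opt))) {
    lna <- lna_moments(g, pr)
    mom <- stationary_moments(g, pr, cfg)
    # means differ by the finite-copy-number bias of the deterministic
    # equilibrium (a few percent at these counts)
    expect_lt(abs(mom$mean_P - lna$mean_P) / lna$mean_P, 0.05)
    # LNA carries an O(1/P_eq) bias; require agreement within 10%
    expect_lt(abs(mom$fano_P - lna$fano_P) / lna$fano_P, 0.10)
  }
  # exact for the unregulated gene
  lna0 <- lna_moments(homozygote(1e12), pr)
  expect_equal(lna0$fano_P, 1 + pr$alpha / (pr$delta_m + pr$delta_p),
               tolerance = 1e-8)
  expect_equal(lna0$fano_M, 1, tolerance = 1e-8)
})

test_that("noise change is null for null mutations", {
  pr <- test_params()
  K_opt <- test_K_opt()
  cfg <- ssa_config(seed = 10, n_replicates = 6, sample_window = 200)
  g0 <- suppressWarnings(
    noise_change_grid(3 * K_opt, delta_eps = 0, pr, config = cfg))
  expect_lt(abs(g0$pct_het), 3 * g0$se_pct_het)
  expect_lt(abs(g0$pct_hom), 3 * g0$se_pct_hom)
  expect_true(g0$se_pct_het > 0 && g0$se_pct_hom > 0)
})

test_that("noise under-dominance has its thresholds ordered and separated", {
  pr <- test_params()
  ls <- cached("noise_landscape", noise_selection_landscape(pr))
  # the noise optimum coincides with the small-perturbation optimum
  expect_equal(ls$K_noise_opt, test_K_opt(), tolerance = 0.05)
  # heterozygote threshold is weaker (larger K) than the homozygote one
  expect_gt(ls$K_het_threshold, ls$K_hom_threshold)
  # under-dominance window: mutations deleterious in heterozygotes but
  # beneficial in homozygotes between the thresholds
  K_mid <- sqrt(ls$K_het_threshold * ls$K_hom_threshold)
  fr <- lna_moments(homozygote(K_mid), pr)$fano_P
  fh <- lna_moments(heterozygote(K_mid, K_mid * exp(-1)), pr)$fano_P
  fm <- lna_moments(homozygote(K_mid * exp(-1)), pr)$fano_P
  expect_gt(fh, fr)
  expect_lt(fm, fr)
})

test_that("stochastic recovery matches the deterministic limit and is instant in-band", {
  pr <- test_params()
  K_opt <- test_K_opt()
  g <- homozygote(30 * K_opt)  # weak binding: monotone, high-copy recovery
  cfg <- ssa_config(seed = 12, n_replicates = 24, burn_in = 20,
                    sample_window = 150, max_time = 200)
  rt <- stochastic_response_time(g, pr, cfg, gamma_values = c(0, 0.95))
  expect_equal(rt$mean_time[rt$gamma == 0.95], 0, tolerance = 1e-9)
  t_det <- response_time(g, pr)
  expect_lt(abs(rt$mean_time[rt$gamma == 0] - t_det) / t_det, 0.10)
})

test_that("faster protein degradation shortens recovery at matched equilibrium", {
  pr1 <- default_params(delta_p = 1)
  pr2 <- default_params(delta_p = 2)  # same unregulated equilibrium count
  K_opt <- test_K_opt()
  g <- homozygote(10 * K_opt)
  cfg <- ssa_config(seed = 14, n_replicates = 16, burn_in = 20,
                    sample_window = 100, max_time = 200)
  rt1 <- stochastic_response_time(g, pr1, cfg, gamma_values = 0)
  rt2 <- stochastic_response_time(g, pr2, cfg, gamma_values = 0)
  expect_lt(rt2$mean_time, rt1$mean_time)
})
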