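test_that("the reduced model is exact at fixed points", {
  pr <- test_params()
  for (g in list(homozygote(1), heterozygote(20, 0.5), haploid(3, h = 2))) {
    red <- qss_reduce(pr, g)
    expect_equal(reduced_equilibrium(red)$P,
                 equilibrium_total_protein(g, pr), tolerance = 1e-10)
    expect_equal(reduced_equilibrium(red)$p, equilibrium_state(g, pr)$p,
                 tolerance = 1e-10)
  }
})

test_that("reduced response times approximate the full model under timescale separation", {
  g <- homozygote(3)
  pr100 <- default_params(delta_m = 100)
  t_full <- response_time(g, pr100)
  t_red <- reduced_response_time(qss_reduce(pr100, g))
  expect_lt(abs(t_red - t_full) / t_full, 0.05)
  # separation violated: the reduction warns
  pr1 <- default_params(delta_m = 1)
  expect_warning(qss_reduce(pr1, g), "timescale separation")
})

test_that("homozygote relaxation rate matches limits and a finite-difference Jacobian", {
  pr <- test_params()
  # beta_r -> 0: unregulated relaxation at -delta_p
  pr0 <- model_params(beta_b = 25, beta_r = 1e-12, alpha = 100,
                      delta_m = 10, delta_p = 1)
  red0 <- qss_reduce(pr0, homozygote(1))
  expect_equal(lyapunov_homozygote(1, 1, red0), -pr0$delta_p,
               tolerance = 1e-9)
  red <- qss_reduce(pr, homozygote(1))
  set.seed(3)
  for (i in 1:8) {
    K <- 10^runif(1, -1.5, 2.5); h <- sample(c(1, 2, 4), 1)
    r <- diplonar:::reduced_with(red, K, h)
    eq <- reduced_equilibrium(r)
    J <- fd_reduced_jacobian(r, eq$p)
    expect_equal(lyapunov_homozygote(K, h, red), total_mode_eigenvalue(J),
                 tolerance = 1e-6)
  }
  # |lambda| is maximised at K_opt over a log grid
  K_opt <- test_K_opt()
  lams <- vapply(K_opt * 10^seq(-2, 2, length.out = 21), function(K)
    abs(lyapunov_homozygote(K, 1, red)), numeric(1))
  expect_equal(which.max(lams), 11L)
})

test_that("heterozygote relaxation rate matches eigen-decomposition and decay fits", {
  pr <- test_params()
  red <- qss_reduce(pr, homozygote(1))
  expect_equal(lyapunov_heterozygote(3, 1, 3, 1, red),
               lyapunov_homozygote(3, 1, red), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:8) {
    K1 <- 10^runif(1, -1, 2); K2 <- K1 * exp(-runif(1, 0.2, 3))
    r <- diplonar:::reduced_with(red, c(K1, K2), 1)
    eq <- reduced_equilibrium(r)
    lam <- lyapunov_heterozygote(K1, 1, K2, 1, red)
    # linear-algebra oracle: analytic Jacobian, numerically eigen-decomposed
    fp <- diplonar:::repression_deriv(eq$P, c(K1, K2), 1)
    J <- red$c * matrix(c(fp[1], fp[1], fp[2], fp[2]), 2, byrow = TRUE) -
      diag(red$delta_p, 2)
    expect_equal(lam, total_mode_eigenvalue(J), tolerance = 1e-10)
    # the other eigenvalue is the allelic-difference mode at exactly -delta_p
    expect_equal(sort(eigen(J, only.values = TRUE)$values),
                 sort(c(-red$delta_p, lam)), tolerance = 1e-10)
  }
  # dynamical oracle: decay-rate regression of a 1% perturbation
  K1 <- 20; K2 <- 20 * exp(-1)
  r <- diplonar:::reduced_with(red, c(K1, K2), 1)
  eq <- reduced_equilibrium(r)
  tr <- integrate_reduced(r, seq(0, 2, by = 0.01), p0 = 0.99 * eq$p)
  keep <- tr$time > 0.2 & abs(tr$P - eq$P) > 1e-8 * eq$P
  fit <- lm(log(abs(tr$P - eq$P))[keep] ~ tr$time[keep])
  expect_equal(unname(coef(fit)[2]), lyapunov_heterozygote(K1, 1, K2, 1, red),
               tolerance = 0.02)
})

test_that("the under-dominance decomposition behaves as a divergence penalty", {
  pr <- test_params()
  red <- qss_reduce(pr, homozygote(1))
  d0 <- decompose_heterozygote(5, 5, 1, red)
  expect_equal(d0$delta_sq, 0)
  expect_equal(d0$correction, 0, tolerance = 1e-12)
  d <- decompose_heterozygote(10, 10 * exp(-1.5), 1, red)
  expect_gt(d$delta_sq, 0)
  expect_gt(d$correction, 0)  # heterozygote slower than the matched homozygote
  # correction grows with allelic divergence at fixed geometric mean
  Kg <- 10
  corr <- vapply(c(0.25, 0.5, 1, 2), function(s)
    decompose_heterozygote(Kg * exp(s), Kg * exp(-s), 1, red)$correction,
    numeric(1))
  expect_true(all(diff(corr) > 0))
  expect_error(decompose_heterozygote(1, 2, c(1, 2), red), "shared")
})

test_that("decomposition identity reconstructs the heterozygote rate exactly", {
  pr <- test_params()
  set.seed(17)
  for (i in 1:100) {
    prs <- default_params(P_unregulated = 10^runif(1, 2, 4),
                          b = 10^runif(1, -4, -1),
                          alpha = 10^runif(1, 1, 2.5),
                          delta_m = 10^runif(1, 0.7, 2))
    red <- qss_reduce(prs, homozygote(1))
    K1 <- 10^runif(1, -2, 2) * red$c / 500
    K2 <- if (i %% 10 == 0) K1 else K1 * exp(-runif(1, 0.05, 4))
    h <- sample(c(1, 2, 4), 1)
    d <- decompose_heterozygote(K1, K2, h, red)
    expect_gte(d$correction, 0)
    # on magnitudes: |lambda_het| = |lambda_hom_matched| - correction
    expect_lt(abs(abs(d$lambda_het) -
                    (abs(d$lambda_hom_matched) - d$correction)), 1e-10)
    expect_equal(d$lambda_het,
                 lyapunov_heterozygote(K1, h, K2, h, red), tolerance = 1e-12)
    if (K1 == K2) expect_equal(d$correction, 0, tolerance = 1e-12)
  }
})

test_that("optimal binding strength satisfies the h=1 stationarity condition", {
  pr <- test_params()
  red <- qss_reduce(pr, homozygote(1))
  P_opt <- optimal_equilibrium_protein(red, 1)
  K_opt <- optimal_Kd(red, 1)
  # calculus oracle: at the h=1 optimum, P_eq/K = sqrt(1 + 1/b)
  expect_equal(P_opt / K_opt, sqrt(1 + 1 / red$b), tolerance = 1e-6)
  # interior optimum
  P_min <- 2 * red$c * red$b / red$delta_p
  P_max <- 2 * red$c * (red$b + 1) / red$delta_p
  expect_gt(P_opt, P_min); expect_lt(P_opt, P_max)
  # definition: the equilibrium at K_opt is P_opt
  expect_equal(reduced_equilibrium(diplonar:::reduced_with(red, K_opt, 1))$P,
               P_opt, tolerance = 1e-8)
  # invariance under a rescaling of time units (all rates scaled together)
  pr_s <- model_params(3 * pr$beta_b, 3 * pr$beta_r, 3 * pr$alpha,
                       3 * pr$delta_m, 3 * pr$delta_p)
  red_s <- qss_reduce(pr_s, homozygote(1))
  expect_equal(optimal_Kd(red_s, 1), K_opt, tolerance = 1e-6)
  expect_equal(optimal_equilibrium_protein(red_s, 1), P_opt,
               tolerance = 1e-6)
})

test_that("optimal binding shifts consistently with the background rate", {
  for (b in c(1e-3, 1e-2)) {
    red <- qss_reduce(default_params(b = b), homozygote(1))
    K_opt <- optimal_Kd(red, 1)
    P_opt <- optimal_equilibrium_protein(red, 1)
    expect_equal(P_opt / K_opt, sqrt(1 + 1 / b), tolerance = 1e-6)
  }
  # larger background weakens the optimal binding (larger K_opt)
  expect_gt(optimal_Kd(qss_reduce(default_params(b = 1e-2), homozygote(1)), 1),
            optimal_Kd(qss_reduce(default_params(b = 1e-3), homozygote(1)), 1))
})

test_that("relaxation eigenvalues never fall below the unregulated rate", {
  pr <- test_params()
  red <- qss_reduce(pr, homozygote(1))
  set.seed(23)
  for (i in 1:50) {
    K1 <- 10^runif(1, -2, 3); K2 <- K1 * exp(-runif(1, 0, 4))
    h <- sample(c(1, 2, 4), 1)
    expect_lte(lyapunov_homozygote(K1, h, red),
               -red$delta_p * (1 - 1e-12))
    expect_lte(lyapunov_heterozygote(K1, h, K2, h, red),
               -red$delta_p * (1 - 1e-12))
  }
})

test_that("eigenvalue ordering marks under-dominant cells algebraically", {
  pr <- test_params()
  red <- qss_reduce(pr, homozygote(1))
  K_opt <- test_K_opt()
  # cells where the heterozygote is slower than the resident while the
  # mutant homozygote is faster
  cells <- list(c(10, 2), c(30, 2.5), c(100, 3))
  for (cell in cells) {
    K_res <- cell[1] * K_opt; K_mut <- K_res * exp(-cell[2])
    l_het <- abs(lyapunov_heterozygote(K_res, 1, K_mut, 1, red))
    l_res <- abs(lyapunov_homozygote(K_res, 1, red))
    l_mut <- abs(lyapunov_homozygote(K_mut, 1, red))
    expect_lt(l_het, l_res)
    expect_lt(l_res, l_mut)
  }
})

test_that("full-model spectra contain the reduced eigenvalues as slow modes", {
  g <- heterozygote(20, 20 * exp(-1))
  pr_fast <- default_params(delta_m = 1000)
  ev <- full_model_eigenvalues(g, pr_fast)
  expect_length(ev, 4)
  red <- qss_reduce(pr_fast, g)
  lam <- lyapunov_heterozygote(g$K[1], 1, g$K[2], 1, red)
  # slow modes ~ reduced eigenvalues (-delta_p and lambda), fast ~ -delta_m
  expect_equal(ev[1], -pr_fast$delta_p, tolerance = 1e-2)
  expect_equal(ev[2], lam, tolerance = 1e-2)
  expect_lt(ev[3], -0.9 * pr_fast$delta_m)
})
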