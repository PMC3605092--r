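test_that("recovery is instantaneous when the perturbation stays in the band", {
  pr <- test_params()
  g <- homozygote(1)
  expect_identical(response_time(g, pr, perturbation(gamma = 0.95)), 0)
  expect_identical(response_time(g, pr, perturbation(gamma = 0.9)), 0)
  expect_identical(unname(allele_response_times(g, pr,
                                                perturbation(gamma = 0.92))),
                   c(0, 0, 0))
})

test_that("unregulated recovery matches the closed-form linear cascade", {
  # beta_r = 0 makes the model a linear two-stage cascade solvable by hand
  pr0 <- model_params(beta_b = 25, beta_r = 0, alpha = 100, delta_m = 10,
                      delta_p = 1)
  for (theta in c(0.9, 0.99)) {
    t_num <- response_time(homozygote(1), pr0, perturbation(0, theta))
    t_oracle <- linear_cascade_response_time(pr0, theta)
    expect_equal(t_num, t_oracle, tolerance = 1e-6)
  }
  # also under different rate scales
  pr1 <- model_params(beta_b = 4, beta_r = 0, alpha = 20, delta_m = 7,
                      delta_p = 0.5)
  expect_equal(response_time(haploid(1), pr1, perturbation(0, 0.9)),
               linear_cascade_response_time(pr1, 0.9), tolerance = 1e-6)
})

test_that("compiled integrator agrees with the deSolve reference path", {
  pr <- test_params()
  K_opt <- test_K_opt()
  cases <- list(homozygote(K_opt), homozygote(0.01 * K_opt),
                heterozygote(10 * K_opt, K_opt),
                homozygote(3 * K_opt, h = 2),
                heterozygote(20 * K_opt, 2 * K_opt, h = c(1, 2)))
  for (g in cases) {
    expect_equal(response_time(g, pr),
                 response_time_ref(g, pr, dt = 5e-4), tolerance = 1e-4)
  }
})

test_that("the directly optimised binding strength is an interior minimum", {
  pr <- test_params()
  dopt <- cached("direct_opt", response_time_optimal_K(pr))
  K_opt <- test_K_opt()
  expect_gt(dopt$K, 1e-4 * K_opt)
  expect_lt(dopt$K, K_opt)  # large perturbations favour stronger binding
  for (f in c(1 / 3, 3)) {
    expect_lt(dopt$time, response_time(homozygote(dopt$K * f), pr))
  }
})

test_that("per-allele recovery shows the heterozygote cross-talk signature", {
  pr <- test_params()
  K_opt <- test_K_opt()
  K_res <- 10 * K_opt
  K_mut <- K_res * exp(-1)
  hom <- allele_response_times(homozygote(K_res), pr)
  expect_equal(hom[["allele1"]], hom[["allele2"]], tolerance = 1e-8)
  expect_equal(hom[["allele1"]], hom[["total"]], tolerance = 1e-6)
  het <- allele_response_times(heterozygote(K_res, K_mut), pr)
  # resident allele slower in the heterozygote than in the resident homozygote
  expect_gt(het[["allele1"]], hom[["allele1"]])
  # the stronger-binding (mutant) allele recovers faster than the resident
  # baseline
  expect_lt(het[["allele2"]], hom[["allele1"]])
})

test_that("invasibility grids are symmetric, zero on the diagonal and show under-dominance", {
  pr <- test_params()
  K_opt <- test_K_opt()
  # allele order within a heterozygote is irrelevant
  expect_equal(response_time(heterozygote(10, 1), pr),
               response_time(heterozygote(1, 10), pr), tolerance = 1e-9)
  g0 <- invasibility_grid(c(K_opt, 10 * K_opt), c(0, 1), pr)
  zero <- g0[g0$delta_eps == 0, ]
  expect_true(all(abs(zero$delta_t_het) < 1e-9))
  expect_true(all(abs(zero$delta_t_hom) < 1e-9))
  expect_true(all(zero$favoured_het & zero$favoured_hom))
  # weak resident binding: small mutations favoured in the heterozygote;
  # large ones disfavoured (under-dominance) while favoured as homozygotes
  gw <- invasibility_grid(30 * K_opt, c(0.2, 3), pr)
  expect_true(gw$favoured_het[gw$delta_eps == 0.2])
  expect_false(gw$favoured_het[gw$delta_eps == 3])
  expect_true(gw$favoured_hom[gw$delta_eps == 3])
})

test_that("mutant homozygotes are favoured down to the direct optimum and not beyond", {
  pr <- test_params()
  dopt <- cached("direct_opt", response_time_optimal_K(pr))
  # resident above the optimum: strengthening is favoured as homozygote
  g <- invasibility_grid(dopt$K * 50, c(0.5, 1), pr, mode = "mutant_homozygote")
  expect_true(all(g$favoured_hom))
  # resident at the optimum: any further strengthening overshoots
  g2 <- invasibility_grid(dopt$K, c(0.5, 1, 2), pr, mode = "mutant_homozygote")
  expect_true(all(!g2$favoured_hom))
})

test_that("Hill-coefficient mutations are neutral when identical and can be under-dominant", {
  pr <- test_params()
  K_opt <- test_K_opt()
  same <- hill_mutation_scan(c(K_opt, 10 * K_opt), 1, 1, pr)
  expect_equal(same$ratio, rep(1, 2), tolerance = 1e-9)
  expect_error(hill_mutation_scan(K_opt, h_res = 2, h_mut = 1, pr), "required")
  sc <- hill_mutation_scan(K_opt * c(1e-3, 3e-3, 1, 1e3), 1, 2, pr)
  # weak binding: steeper repression speeds the response (ratio <= 1)
  expect_lt(sc$ratio[sc$K == K_opt * 1e3], 1 + 1e-9)
  # very strong binding (past the direct optimum): steepening slows recovery
  expect_gt(max(sc$ratio), 1)
})

test_that("perturbation scans are monotone for weak regulation and show the strong-NAR burst", {
  pr <- test_params()
  # weak binding: recovery is essentially the linear cascade, and retaining
  # more of the equilibrium can only shorten it
  gw <- homozygote(300 * test_K_opt())
  scw <- perturbation_scan(gw, pr, gamma_values = seq(0, 1, by = 0.1))
  expect_true(all(diff(scw$time) <= 1e-9))
  expect_equal(scw$time[scw$gamma == 0], response_time(gw, pr))
  expect_identical(scw$time[scw$gamma >= 0.9], rep(0, 2))
  # strong binding: full knock-down recovers *faster* than a partial one,
  # because at low protein the promoter is derepressed and transcribes at
  # its maximal rate, while intermediate levels are already repressed
  g <- homozygote(test_K_opt())
  sc <- perturbation_scan(g, pr, gamma_values = c(0, 0.3))
  expect_lt(sc$time[sc$gamma == 0], sc$time[sc$gamma == 0.3])
  expect_equal(sc$time[sc$gamma == 0], response_time(g, pr))
})

test_that("non-recovery within the horizon raises an informative error", {
  pr <- test_params()
  expect_error(response_time(homozygote(1), pr, horizon = 0.05),
               "horizon")
})
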