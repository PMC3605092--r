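test_that("site dissociation constants follow the mismatch energy model", {
  s <- binding_site(eps = c(1, 2, 0.5), K0 = 1000)
  expect_equal(site_Kd(s), 1000)  # minimum affinity: nothing matched
  s1 <- binding_site(c(1, 2, 0.5), matched = c(TRUE, FALSE, FALSE), K0 = 1000)
  expect_equal(site_Kd(s1), 1000 * exp(-1))
  full <- binding_site(c(1, 2, 0.5), matched = rep(TRUE, 3), K0 = 1000)
  expect_equal(site_Kd(full), 1000 * exp(-3.5))
  # adding a match never weakens binding
  set.seed(2)
  for (i in 1:20) {
    L <- sample(5:15, 1)
    eps <- runif(L, 0.05, 3)
    matched <- runif(L) < 0.5
    K_before <- site_Kd(binding_site(eps, matched, 100))
    unm <- which(!matched)
    if (length(unm)) {
      j <- unm[sample.int(length(unm), 1)]
      matched[j] <- TRUE
      expect_lte(site_Kd(binding_site(eps, matched, 100)), K_before)
    }
  }
  expect_error(binding_site(c(1, -1), K0 = 1), "positive")
})

test_that("site sampling honours the reachability exclusion rule", {
  K_opt <- 1
  # generous energies and length: exp(30) >> 1000, never excluded
  cfg_ok <- evolution_config(eps_bounds = c(0.99, 1.01), K0_factor = 1000,
                             length_distribution = data.frame(length = 30,
                                                              weight = 1))
  set.seed(1)
  s <- sample_site(cfg_ok, K_opt)
  expect_identical(attr(s, "n_excluded"), 0L)
  expect_identical(s$L, 30L)
  expect_true(all(!s$matched))
  expect_equal(site_Kd(s), 1000 * K_opt)
  # tiny energies: the fully matched site stays weaker than K_opt
  cfg_bad <- evolution_config(eps_bounds = c(0.005, 0.01), K0_factor = 1000,
                              length_distribution = data.frame(length = 5,
                                                               weight = 1))
  set.seed(1)
  expect_error(sample_site(cfg_bad, K_opt), "exclusion rate")
  # reproducibility of the rejection-sampling stream
  cfg <- evolution_config(seed = 5)
  set.seed(99); sA <- sample_site(cfg, K_opt)
  set.seed(99); sB <- sample_site(cfg, K_opt)
  expect_identical(sA$eps, sB$eps)
})

test_that("adaptive walks accept only non-slower mutants and descend in K", {
  pr <- test_params()
  cfg <- evolution_config(length_distribution = data.frame(length = 8,
                                                           weight = 1))
  K_opt <- test_K_opt()
  set.seed(31)
  site <- sample_site(cfg, K_opt)
  for (pl in c(1L, 2L)) {
    set.seed(42)
    w <- adaptive_walk(site, cfg, pr, ploidy = pl)
    expect_true(w$terminated_by %in% c("no_improving_flip", "all_optimal"))
    expect_length(w$trajectory, w$n_fixed)
    expect_true(all(diff(c(site_Kd(site), w$trajectory)) < 0))
    # audit: recompute every accepted step's fitness test
    K_res <- site_Kd(site)
    for (j in seq_len(w$n_fixed)) {
      K_mut <- w$trajectory[j]
      expect_equal(K_mut, K_res * exp(-w$accepted_eps[j]), tolerance = 1e-12)
      res_g <- if (pl == 1L) haploid(K_res) else homozygote(K_res)
      car_g <- if (pl == 1L) haploid(K_mut) else heterozygote(K_res, K_mut)
      t_res <- response_time(res_g, pr, cfg$pert)
      t_car <- response_time(car_g, pr, cfg$pert)
      expect_lte(t_car, t_res * (1 + 1e-6))
      K_res <- K_mut
    }
  }
})

test_that("under-dominance blocks a single large-effect flip in diploids", {
  pr <- test_params()
  K_opt <- test_K_opt()
  # resident near K_opt with one remaining large-effect position
  eps <- c(rep(1, 7), 3)
  K0 <- 2 * K_opt * exp(7)  # after matching the 1-kT positions, K = 2*K_opt
  site <- binding_site(eps, matched = c(rep(TRUE, 7), FALSE), K0 = K0)
  cfg <- evolution_config()
  set.seed(3)
  w_dip <- adaptive_walk(site, cfg, pr, ploidy = 2L)
  expect_identical(w_dip$n_fixed, 0L)
  expect_identical(w_dip$terminated_by, "no_improving_flip")
  # the same flip is accepted by the direct heterozygote comparison's inverse:
  # as a homozygote the mutant is faster, so a haploid fixes it
  set.seed(3)
  w_hap <- adaptive_walk(site, cfg, pr, ploidy = 1L)
  expect_identical(w_hap$n_fixed, 1L)
  # direct check of the two comparisons
  K_res <- site_Kd(site); K_mut <- K_res * exp(-3)
  expect_gt(response_time(heterozygote(K_res, K_mut), pr, cfg$pert),
            response_time(homozygote(K_res), pr, cfg$pert))
  expect_lte(response_time(haploid(K_mut), pr, cfg$pert),
             response_time(haploid(K_res), pr, cfg$pert))
})

test_that("haploid walks with small-effect mutations approach the selection optimum", {
  pr <- test_params()
  # plentiful small steps let the walk fine-tune binding strength
  cfg <- evolution_config(eps_bounds = c(0.1, 0.2),
                          length_distribution = data.frame(length = 90,
                                                           weight = 1))
  # optimum of the selection criterion actually used (gamma = 0 protocol)
  dopt_hap <- cached("direct_opt_hap", {
    K_ref <- test_K_opt()
    obj <- function(lk) response_time(haploid(exp(lk)), pr, cfg$pert)
    op <- optimize(obj, log(K_ref * c(1e-4, 1e2)), tol = 1e-6)
    exp(op$minimum)
  })
  set.seed(8)
  for (i in 1:2) {
    site <- sample_site(cfg, test_K_opt())
    w <- adaptive_walk(site, cfg, pr, ploidy = 1L)
    expect_lt(abs(log(w$final_K / dopt_hap)), log(3))
  }
})

test_that("paired ensembles expose the diploid constraint", {
  pr <- test_params()
  cfg <- evolution_config(n_replicates = 20, seed = 77)
  ens <- cached("small_ensemble", evolve_ensemble(cfg, pr))
  res <- ens$results
  expect_identical(nrow(res), 40L)
  expect_true(all(res$final_K > 0))
  # haploids evolve stronger binding than diploids
  gm <- ens$summary$geometric_mean_K
  expect_lt(gm[["1"]], gm[["2"]])
  expect_gt(ens$summary$ratio_diploid_haploid, 1)
  # a larger share of haploid walks ends near strong binding
  dopt_hap <- cached("direct_opt_hap", {
    obj <- function(lk) response_time(haploid(exp(lk)), pr, cfg$pert)
    exp(optimize(obj, log(test_K_opt() * c(1e-4, 1e2)), tol = 1e-6)$minimum)
  })
  near <- function(pl) mean(abs(log(res$final_K[res$ploidy == pl] /
                                      (dopt_hap * pl))) < log(3))
  expect_gt(near(1), near(2))
})

test_that("a single-replicate ensemble reduces to one adaptive walk", {
  pr <- test_params()
  cfg <- evolution_config(n_replicates = 1, seed = 13)
  ens <- evolve_ensemble(cfg, pr, ploidies = 2L)
  seeds <- derive_seeds(13, 2)
  set.seed(seeds[1])
  site <- sample_site(cfg, ens$K_opt)
  set.seed(seeds[2])
  w <- adaptive_walk(site, cfg, pr, ploidy = 2L)
  expect_equal(ens$results$final_K, w$final_K)
  expect_equal(ens$results$n_fixed, w$n_fixed)
})

test_that("the heterozygote step, not diploidy itself, is the constraint", {
  pr <- test_params()
  # with homozygote evaluation, a diploid walk makes exactly the decisions
  # of a haploid whose transcription rates are doubled
  pr2 <- model_params(2 * pr$beta_b, 2 * pr$beta_r, pr$alpha, pr$delta_m,
                      pr$delta_p)
  cfg <- evolution_config(length_distribution = data.frame(length = 10,
                                                           weight = 1))
  set.seed(21)
  for (i in 1:3) {
    site <- sample_site(cfg, test_K_opt())
    set.seed(100 + i)
    w_dip <- adaptive_walk(site, cfg, pr, ploidy = 2L,
                           diploid_eval = "homozygote")
    set.seed(100 + i)
    w_hap <- adaptive_walk(site, cfg, pr2, ploidy = 1L)
    expect_equal(w_dip$final_K, w_hap$final_K, tolerance = 1e-12)
    expect_identical(w_dip$n_fixed, w_hap$n_fixed)
  }
})
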