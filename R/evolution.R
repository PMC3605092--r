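#' Transcription-factor binding site under the mismatch energy model
#'
#' A binding site of `L` nucleotide positions, each either matched to the
#' optimal base or not. A matched position `i` contributes its energy
#' `eps[i]` (in kT) to the total binding energy `E`; mismatched positions
#' contribute nothing. The dissociation constant follows the thermodynamic
#' relation `K = K0 * exp(-E)`, where `K0` is the dissociation constant of
#' the fully mismatched (minimum-affinity) site.
#'
#' @param eps per-position energy contributions in kT (> 0).
#' @param matched logical vector of matches (default: all mismatched).
#' @param K0 dissociation constant of the all-mismatched site (> 0).
#' @return An object of class `nar_site`.
#' @examples
#' s <- binding_site(eps = c(1, 2, 0.5), K0 = 1000)
#' site_Kd(s)                                 # K0: nothing matched
#' site_Kd(binding_site(c(1, 2, 0.5), matched = c(TRUE, FALSE, FALSE), 1000))
#' @export
binding_site <- function(eps, matched = rep(FALSE, length(eps)), K0) {
  if (length(eps) < 1 || any(!is.finite(eps)) || any(eps <= 0))
    stop("'eps' must be positive energies (kT), length >= 1", call. = FALSE)
  if (length(matched) != length(eps) || !is.logical(matched))
    stop("'matched' must be a logical vector matching 'eps'", call. = FALSE)
  if (!is.numeric(K0) || K0 <= 0)
    stop("'K0' must be positive", call. = FALSE)
  structure(list(L = length(eps), eps = as.numeric(eps), matched = matched,
                 K0 = K0),
            class = "nar_site")
}

#' @describeIn binding_site dissociation constant of the site,
#'   `K0 * exp(-sum(eps[matched]))`.
#' @param site an `nar_site`.
#' @export
site_Kd <- function(site) {
  stopifnot(inherits(site, "nar_site"))
  site$K0 * exp(-sum(site$eps[site$matched]))
}

#' @export
print.nar_site <- function(x, ...) {
  cat(sprintf("<nar_site> L = %d, %d/%d matched, E = %.3f kT, K = %.4g\n",
              x$L, sum(x$matched), x$L, sum(x$eps[x$matched]), site_Kd(x)))
  invisible(x)
}

#' Binding-site length distribution
#'
#' Discrete stand-in for the empirical length distribution of eukaryotic
#' transcription-factor binding motifs: support 5-22 nucleotides with mode
#' near 10 and mean 10 (a truncated shifted Poisson). A user-supplied
#' empirical histogram (data.frame with columns `length` and `weight`) may
#' be used instead anywhere a length distribution is accepted.
#'
#' @return data.frame with columns `length` and `weight` (normalised).
#' @examples
#' ld <- site_length_distribution()
#' sum(ld$length * ld$weight)  # close to 10
#' @export
site_length_distribution <- function() {
  len <- 5:22
  w <- stats::dpois(len - 5L, lambda = 5)
  data.frame(length = len, weight = w / sum(w))
}

#' Configuration of binding-site evolution runs
#'
#' @param n_replicates number of replicate adaptive walks per ploidy.
#' @param seed master seed.
#' @param eps_bounds bounds of the uniform per-position energy distribution
#'   (kT). The default (0.05, 3) covers the empirically estimated 1-3 kT
#'   range and lets small-effect mutations occur frequently.
#' @param K0_factor all-mismatched dissociation constant, as a multiple of
#'   the optimal binding strength `K_opt` (default 1000: effectively
#'   unregulated).
#' @param length_distribution data.frame with columns `length`, `weight`
#'   (default [site_length_distribution()]).
#' @param pert fitness-evaluation perturbation (default gamma = 0,
#'   theta = 0.9).
#' @param tie_tol relative tolerance of the less-than-or-equal acceptance
#'   rule: accept if `t_mut <= t_res * (1 + tie_tol)`.
#' @return An object of class `nar_evolution_config`.
#' @export
evolution_config <- function(n_replicates = 200L, seed = 1L,
                             eps_bounds = c(0.05, 3),
                             K0_factor = 1000,
                             length_distribution = site_length_distribution(),
                             pert = perturbation(gamma = 0, theta = 0.9),
                             tie_tol = 1e-9) {
  if (n_replicates < 1) stop("'n_replicates' must be >= 1", call. = FALSE)
  if (length(eps_bounds) != 2 || eps_bounds[1] <= 0 ||
      eps_bounds[2] <= eps_bounds[1])
    stop("'eps_bounds' must satisfy 0 < lo < hi", call. = FALSE)
  if (!all(c("length", "weight") %in% names(length_distribution)))
    stop("'length_distribution' needs columns 'length' and 'weight'",
         call. = FALSE)
  structure(list(n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), eps_bounds = eps_bounds,
                 K0_factor = K0_factor,
                 length_distribution = length_distribution,
                 pert = pert, tie_tol = tie_tol),
            class = "nar_evolution_config")
}

#' Sample a binding site for an evolutionary run
#'
#' Draws a site length from the configured length distribution and i.i.d.
#' uniform per-position energies, starting fully mismatched at
#' `K0 = K0_factor * K_opt`. Sites whose *fully matched* sequence is still
#' weaker than the optimal binding strength (`K0 * exp(-sum(eps)) > K_opt`)
#' can never reach the fastest-response regime and are excluded and
#' redrawn, with the number of exclusions recorded in attribute
#' `n_excluded`. Consumes the current R RNG stream (seed with `set.seed()`
#' for reproducibility).
#'
#' @param config an [evolution_config()].
#' @param K_opt the optimal dissociation constant used for site placement
#'   and the exclusion rule.
#' @return An `nar_site` with attribute `n_excluded`.
#' @export
sample_site <- function(config, K_opt) {
  ld <- config$length_distribution
  K0 <- config$K0_factor * K_opt
  excl <- 0L
  repeat {
    L <- ld$length[sample.int(nrow(ld), 1L, prob = ld$weight)]
    eps <- runif(L, config$eps_bounds[1], config$eps_bounds[2])
    if (K0 * exp(-sum(eps)) <= K_opt) break
    excl <- excl + 1L
    if (excl >= 200L && excl / (excl + 1L) > 0.99)
      stop("binding-site exclusion rate exceeds 99%; the configured ",
           "energies cannot reach the optimal binding strength",
           call. = FALSE)
  }
  site <- binding_site(eps, K0 = K0)
  attr(site, "n_excluded") <- excl
  site
}

#' Adaptive walk of binding-site evolution
#'
#' Sequential fixation of single mismatch-to-match substitutions under
#' selection for response time. At each step a uniformly random mismatched
#' position is proposed; the mutant site's dissociation constant is
#' `K_res * exp(-eps[i])`. The mutant fixes if its response time is at most
#' the resident's: haploid mutants are evaluated as haploids, diploid
#' mutants in the heterozygote state against the resident homozygote (each
#' accepted mutant then becomes the new homozygous resident). A proposal
#' that fails is not re-proposed against the same resident; rejection marks
#' are cleared after every acceptance, since a new background can revalue
#' previously rejected flips. The walk ends when every remaining flip fails
#' (`"no_improving_flip"`) or all positions are matched (`"all_optimal"`).
#' Back-mutations are never proposed.
#'
#' @param site an `nar_site` (typically from [sample_site()]).
#' @param config an [evolution_config()].
#' @param params an [model_params()].
#' @param ploidy 1 (haploid) or 2 (diploid) evaluation.
#' @param diploid_eval how diploid mutants are evaluated: in the
#'   `"heterozygote"` state (the default and the biologically relevant
#'   case — new mutations arise in heterozygotes) or as `"homozygote"`
#'   mutants. The homozygote mode removes allelic cross-talk from the
#'   fitness test and is used to verify that the heterozygote step is the
#'   constraint: with it, a diploid walk makes exactly the decisions of a
#'   haploid with doubled transcription rates.
#' @return An object of class `nar_walk`: list with `final_K`, `n_fixed`,
#'   `trajectory` (K after each fixation), `accepted_eps`,
#'   `terminated_by`, `ploidy`, `L`.
#' @export
adaptive_walk <- function(site, config, params, ploidy = 2L,
                          diploid_eval = c("heterozygote", "homozygote")) {
  stopifnot(inherits(site, "nar_site"), ploidy %in% c(1L, 2L))
  diploid_eval <- match.arg(diploid_eval)
  make_res <- function(K) if (ploidy == 1L) haploid(K) else homozygote(K)
  make_car <- function(K_res, K_mut)
    if (ploidy == 1L) haploid(K_mut)
    else if (diploid_eval == "heterozygote") heterozygote(K_res, K_mut)
    else homozygote(K_mut)
  K <- site_Kd(site)
  t_res <- response_time(make_res(K), params, config$pert)
  matched <- site$matched
  rejected <- rep(FALSE, site$L)
  traj <- numeric(0)
  acc_eps <- numeric(0)
  repeat {
    cand <- which(!matched & !rejected)
    if (!length(cand)) {
      term <- if (all(matched)) "all_optimal" else "no_improving_flip"
      break
    }
    i <- if (length(cand) == 1L) cand else sample(cand, 1L)
    K_mut <- K * exp(-site$eps[i])
    t_mut <- response_time(make_car(K, K_mut), params, config$pert)
    if (t_mut <= t_res * (1 + config$tie_tol)) {
      matched[i] <- TRUE
      rejected[] <- FALSE
      K <- K_mut
      traj <- c(traj, K)
      acc_eps <- c(acc_eps, site$eps[i])
      t_res <- response_time(make_res(K), params, config$pert)
    } else {
      rejected[i] <- TRUE
    }
  }
  structure(list(final_K = K, n_fixed = length(traj), trajectory = traj,
                 accepted_eps = acc_eps, terminated_by = term,
                 ploidy = ploidy, L = site$L),
            class = "nar_walk")
}

#' @export
print.nar_walk <- function(x, ...) {
  cat(sprintf("<nar_walk> ploidy %d, L = %d: %d fixations, final K = %.4g (%s)\n",
              x$ploidy, x$L, x$n_fixed, x$final_K, x$terminated_by))
  invisible(x)
}

#' Paired ensembles of binding-site evolution
#'
#' Runs `n_replicates` adaptive walks for each requested ploidy in a paired
#' design: each replicate draws one site and one proposal-order seed, shared
#' by the haploid and diploid walks, so ploidy is the only difference
#' between the paired runs. Summaries report per-ploidy geometric means of
#' the final dissociation constants and the diploid/haploid ratio — the
#' package's measure of how strongly heterozygote under-dominance constrains
#' the binding strength diploids can evolve.
#'
#' @param config an [evolution_config()].
#' @param params an [model_params()].
#' @param ploidies ploidies to run (default `c(1, 2)`).
#' @return An object of class `nar_ensemble`: list with `results` (one row
#'   per walk: `replicate`, `ploidy`, `L`, `final_K`, `n_fixed`,
#'   `terminated_by`), `summary` (per-ploidy geometric means and, when both
#'   ploidies are present, `ratio_diploid_haploid`), `K_opt` and
#'   `n_excluded`.
#' @examples
#' \donttest{
#' ens <- evolve_ensemble(evolution_config(n_replicates = 5), default_params())
#' ens$summary
#' }
#' @export
evolve_ensemble <- function(config, params, ploidies = c(1L, 2L)) {
  red <- qss_reduce(params, homozygote(1))
  K_opt <- optimal_Kd(red, h = 1)
  seeds <- derive_seeds(config$seed, 2L * config$n_replicates)
  n_excluded <- 0L
  rows <- list()
  for (r in seq_len(config$n_replicates)) {
    set.seed(seeds[2L * r - 1L])
    site <- sample_site(config, K_opt)
    n_excluded <- n_excluded + attr(site, "n_excluded")
    for (pl in ploidies) {
      set.seed(seeds[2L * r])  # shared proposal order across ploidies
      w <- adaptive_walk(site, config, params, ploidy = as.integer(pl))
      rows[[length(rows) + 1L]] <-
        data.frame(replicate = r, ploidy = as.integer(pl), L = site$L,
                   final_K = w$final_K, n_fixed = w$n_fixed,
                   terminated_by = w$terminated_by)
    }
  }
  results <- do.call(rbind, rows)
  gm <- vapply(split(results$final_K, results$ploidy),
               function(x) exp(mean(log(x))), numeric(1))
  summary <- list(geometric_mean_K = gm,
                  geometric_mean_K_over_Kopt = gm / K_opt)
  if (all(c("1", "2") %in% names(gm)))
    summary$ratio_diploid_haploid <- unname(gm["2"] / gm["1"])
  structure(list(results = results, summary = summary, K_opt = K_opt,
                 n_excluded = n_excluded),
            class = "nar_ensemble")
}

#' @export
print.nar_ensemble <- function(x, ...) {
  cat("<nar_ensemble>", nrow(x$results), "walks; geometric-mean final K:\n")
  print(signif(x$summary$geometric_mean_K, 4))
  if (!is.null(x$summary$ratio_diploid_haploid))
    cat(sprintf("diploid/haploid ratio = %.3g (K_opt = %.4g)\n",
                x$summary$ratio_diploid_haploid, x$K_opt))
  invisible(x)
}
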