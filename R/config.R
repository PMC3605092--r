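#' Load an experiment configuration
#'
#' Reads a YAML (or JSON) configuration file, validates it against the
#' documented schema and fills unspecified entries with package defaults.
#' Unknown keys are rejected with an error naming the offending key, so
#' typos never silently fall back to defaults.
#'
#' Schema (all blocks optional):
#' \preformatted{
#' seed: 1
#' out_dir: results
#' params:   {beta_b, beta_r, alpha, delta_m, delta_p}
#' genotype: {alleles: [{K, h}, ...], ploidy}
#' perturbation: {gamma, theta, perturb_mrna}
#' grid:     {n_K, n_eps}
#' ssa:      {n_replicates, burn_in, sample_window, max_time}
#' evolution: {n_replicates, eps_lo, eps_hi, K0_factor}
#' census:   {n_tf, p_neg_auto, p_pos_auto, p_repressor, edges_per_tf}
#' }
#'
#' @param path path to a YAML/JSON file; an empty file yields the
#'   all-defaults configuration.
#' @return Object of class `nar_config`: a named list with the blocks
#'   above, all defaults filled.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("configuration must be a mapping", call. = FALSE)
  validate_config(raw)
}

#' @rdname load_config
#' @param config a (possibly partial) configuration list to validate and
#'   complete; `validate_config()` is the programmatic equivalent of
#'   [load_config()].
#' @export
validate_config <- function(config = list()) {
  defaults <- default_config()
  check_keys <- function(x, ref, where) {
    bad <- setdiff(names(x), names(ref))
    if (length(bad))
      stop("unknown configuration key: '",
           paste0(where, bad[1]), "'", call. = FALSE)
  }
  check_keys(config, defaults, "")
  out <- defaults
  for (blk in names(config)) {
    if (is.list(defaults[[blk]]) && blk != "genotype") {
      check_keys(config[[blk]], defaults[[blk]], paste0(blk, "/"))
      out[[blk]] <- modifyList(defaults[[blk]], config[[blk]])
    } else {
      out[[blk]] <- config[[blk]]
    }
  }
  # constructor validation gives named errors for bad values
  do.call(model_params, out$params)
  config_genotype(out)
  pb <- out$perturbation
  perturbation(pb$gamma, pb$theta, pb$perturb_mrna)
  structure(out, class = "nar_config")
}

default_config <- function() {
  pr <- default_params()
  list(seed = 1L,
       out_dir = "results",
       params = list(beta_b = pr$beta_b, beta_r = pr$beta_r,
                     alpha = pr$alpha, delta_m = pr$delta_m,
                     delta_p = pr$delta_p),
       genotype = list(alleles = list(list(K = 1, h = 1), list(K = 1, h = 1)),
                       ploidy = 2L),
       perturbation = list(gamma = 0, theta = 0.9, perturb_mrna = TRUE),
       grid = list(n_K = 40L, n_eps = 50L),
       ssa = list(n_replicates = 8L, burn_in = 20, sample_window = 300,
                  max_time = 1000),
       evolution = list(n_replicates = 200L, eps_lo = 0.05, eps_hi = 3,
                        K0_factor = 1000),
       census = list(n_tf = 182L, p_neg_auto = 82 / 182, p_pos_auto = 0.05,
                     p_repressor = 138 / 182, edges_per_tf = 2L))
}

config_params <- function(cfg) do.call(model_params, cfg$params)

config_genotype <- function(cfg) {
  g <- cfg$genotype
  K <- vapply(g$alleles, function(a) a$K, numeric(1))
  h <- vapply(g$alleles, function(a) if (is.null(a$h)) 1 else a$h, numeric(1))
  ploidy <- g$ploidy %||% length(g$alleles)
  genotype(K[seq_len(ploidy)], h[seq_len(ploidy)], ploidy = ploidy)
}

#' Save a configuration
#'
#' Writes a configuration back to YAML; `load_config(save_config(x, f))`
#' round-trips semantically.
#'
#' @param config an `nar_config` (or partial list).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 12)
  invisible(path)
}

#' Run a configured experiment stage
#'
#' Dispatches one named analysis stage with settings from a validated
#' configuration, writing tabular results (TSV), summaries (JSON) and a
#' provenance record (configuration echo, seed, package version) to
#' `out_dir`. All randomness derives from `config$seed`, so a repeated run
#' with the same configuration reproduces its outputs.
#'
#' @param config an `nar_config` (see [load_config()]).
#' @param command one of `"response-time"`, `"invasibility"`, `"analyze"`,
#'   `"optimal-kd"`, `"noise"`, `"ssa-response"`, `"evolve"`, `"census"`.
#' @param out_dir output directory (default `config$out_dir`).
#' @return Invisibly, a named list of the files written.
#' @export
run_experiment <- function(config, command, out_dir = config$out_dir) {
  if (!inherits(config, "nar_config")) config <- validate_config(config)
  commands <- c("response-time", "invasibility", "analyze", "optimal-kd",
                "noise", "ssa-response", "evolve", "census")
  if (!command %in% commands)
    stop("unknown command '", command, "'; expected one of: ",
         paste(commands, collapse = ", "), call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config_params(config)
  g <- config_genotype(config)
  pert <- with(config$perturbation, perturbation(gamma, theta, perturb_mrna))
  seed <- config$seed
  files <- list()
  emit_tsv <- function(df, name) {
    f <- file.path(out_dir, paste0(name, ".tsv"))
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[name]] <<- f
  }
  emit_json <- function(x, name) {
    f <- file.path(out_dir, paste0(name, ".json"))
    jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files[[name]] <<- f
  }

  if (command == "response-time") {
    sc <- perturbation_scan(g, params, gamma_values = seq(0, 0.8, by = 0.05),
                            theta = config$perturbation$theta,
                            perturb_mrna = config$perturbation$perturb_mrna)
    emit_tsv(sc, "response_time_scan")
  } else if (command == "invasibility") {
    ax <- default_invasibility_axes(params, config$grid$n_K,
                                    config$grid$n_eps)
    gr <- invasibility_grid(ax$K_res, ax$delta_eps, params, pert)
    emit_tsv(gr, "invasibility_grid")
  } else if (command == "analyze") {
    red <- qss_reduce(params, g)
    if (g$ploidy == 2L && !is_homozygote(g)) {
      if (g$h[1] != g$h[2])
        stop("decomposition requires a shared Hill coefficient",
             call. = FALSE)
      d <- decompose_heterozygote(g$K[1], g$K[2], g$h[1], red)
      emit_json(unclass(d), "decomposition")
    } else {
      emit_json(list(lambda = lyapunov_homozygote(g$K[1], g$h[1], red),
                     P_eq = equilibrium_total_protein(g, params)),
                "analysis")
    }
  } else if (command == "optimal-kd") {
    red <- qss_reduce(params, homozygote(1))
    K_opt <- optimal_Kd(red, h = 1)
    emit_json(list(K_opt = K_opt,
                   P_opt = optimal_equilibrium_protein(red, 1),
                   lambda_opt = lyapunov_homozygote(K_opt, 1, red)),
              "optimal_kd")
  } else if (command == "noise") {
    red <- qss_reduce(params, homozygote(1))
    K_opt <- optimal_Kd(red, h = 1)
    cfg <- do.call(ssa_config, c(list(seed = seed), config$ssa))
    grid <- noise_change_grid(K_opt * 10^seq(-1, 2, length.out = 7),
                              delta_eps = 1, params, config = cfg)
    emit_tsv(grid, "noise_change")
  } else if (command == "ssa-response") {
    cfg <- do.call(ssa_config, c(list(seed = seed), config$ssa))
    rt <- stochastic_response_time(g, params, cfg,
                                   gamma_values = seq(0, 0.8, by = 0.1),
                                   theta = config$perturbation$theta)
    emit_tsv(rt, "stochastic_response_time")
  } else if (command == "evolve") {
    ecfg <- evolution_config(n_replicates = config$evolution$n_replicates,
                             seed = seed,
                             eps_bounds = c(config$evolution$eps_lo,
                                            config$evolution$eps_hi),
                             K0_factor = config$evolution$K0_factor,
                             pert = pert)
    ens <- evolve_ensemble(ecfg, params)
    emit_tsv(ens$results, "evolution_replicates")
    emit_json(c(ens$summary, list(K_opt = ens$K_opt)), "evolution_summary")
  } else if (command == "census") {
    cc <- config$census
    tab <- generate_census_table(cc$n_tf, cc$p_neg_auto, cc$p_pos_auto,
                                 cc$p_repressor, cc$edges_per_tf,
                                 seed = seed)
    emit_tsv(as.data.frame(tab), "census_table")
    emit_json(unclass(census(tab)), "census_summary")
  }

  emit_json(list(command = command, seed = seed,
                 package_version = as.character(packageVersion("diplonar")),
                 config = unclass(config)),
            paste0(command, "_provenance"))
  invisible(files)
}
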