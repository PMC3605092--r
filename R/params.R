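#' Kinetic parameters of the autoregulated gene-expression model
#'
#' Bundles the five kinetic rates of the transcription-translation model.
#' Transcription of each allele proceeds at the background rate `beta_b` plus
#' a regulated increment `beta_r * f(P)`, where `f` is the Hill repression
#' function of the *total* cellular protein concentration `P`, so that the
#' maximum transcription rate is `beta_max = beta_b + beta_r` (attained when
#' repression is absent, `f = 1`) and the minimum is `beta_b` (full
#' repression, `f -> 0`).
#'
#' @param beta_b background transcription rate (mRNA per unit time), > 0.
#' @param beta_r regulated transcription increment (mRNA per unit time), >= 0.
#' @param alpha translation rate per mRNA (protein mRNA^-1 time^-1), > 0.
#' @param delta_m mRNA degradation rate (time^-1), > 0.
#' @param delta_p protein degradation rate (time^-1), > 0.
#'
#' @return An object of class `nar_params` (a named list of the five rates
#'   plus the derived `beta_max`).
#' @seealso [default_params()] for the package's reference parameter set.
#' @examples
#' pr <- model_params(beta_b = 0.05, beta_r = 49.95, alpha = 100,
#'                    delta_m = 10, delta_p = 1)
#' pr$beta_max
#' @export
model_params <- function(beta_b, beta_r, alpha, delta_m, delta_p) {
  vals <- list(beta_b = beta_b, beta_r = beta_r, alpha = alpha,
               delta_m = delta_m, delta_p = delta_p)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (beta_b <= 0 || alpha <= 0 || delta_m <= 0 || delta_p <= 0)
    stop("rates 'beta_b', 'alpha', 'delta_m', 'delta_p' must be strictly positive",
         call. = FALSE)
  if (beta_r < 0)
    stop("'beta_r' must be non-negative", call. = FALSE)
  structure(c(vals, list(beta_max = beta_b + beta_r)), class = "nar_params")
}

#' Reference parameter set
#'
#' The package's reference (dimensionless) parameter set. Time is measured in
#' protein lifetimes (`delta_p = 1`); mRNA turns over ten times faster
#' (`delta_m = 10`), consistent with the timescale separation assumed by the
#' quasi-steady-state analysis; the translation rate `alpha = 100` gives a
#' burst size `alpha/delta_m = 10`, typical for transcription factors. The
#' regulated rate `beta_r` is set so that the *unregulated* diploid
#' equilibrium holds `P_unregulated` protein molecules, and the background
#' rate is `b * beta_r`.
#'
#' @param P_unregulated unregulated diploid equilibrium protein count
#'   (default 1000).
#' @param b ratio of background to regulated transcription rate
#'   (`beta_b / beta_r`, default `1e-3`).
#' @param alpha,delta_m,delta_p overrides for the remaining rates.
#' @return An `nar_params` object.
#' @examples
#' default_params()
#' @export
default_params <- function(P_unregulated = 1000, b = 1e-3,
                           alpha = 100, delta_m = 10, delta_p = 1) {
  beta_max <- P_unregulated * delta_m * delta_p / (2 * alpha)
  beta_r <- beta_max / (1 + b)
  model_params(beta_b = b * beta_r, beta_r = beta_r, alpha = alpha,
               delta_m = delta_m, delta_p = delta_p)
}

#' @export
print.nar_params <- function(x, ...) {
  cat("<nar_params>",
      sprintf("beta_b=%.4g beta_r=%.4g (beta_max=%.4g)", x$beta_b, x$beta_r,
              x$beta_max),
      sprintf("alpha=%.4g delta_m=%.4g delta_p=%.4g", x$alpha, x$delta_m,
              x$delta_p), sep = "\n")
  invisible(x)
}

#' Genotype of an autoregulating gene
#'
#' A genotype is an ordered set of alleles, each characterised by the
#' dissociation constant `K` of its autoregulatory binding site (protein
#' concentration at which the site is half-occupied; smaller `K` means
#' stronger binding) and the Hill coefficient `h` of its repression function.
#' Haploids carry one allele; diploids carry two whose repression both read
#' the shared total protein pool.
#'
#' @param K numeric vector of per-allele dissociation constants (> 0), length
#'   equal to the ploidy.
#' @param h per-allele Hill coefficients (>= 1); recycled to the length of
#'   `K`.
#' @param K_res,K_mut,K1,K2 dissociation constants for the convenience
#'   constructors.
#' @param ploidy number of alleles (1 or 2).
#' @return An object of class `nar_genotype` with fields `K`, `h`, `ploidy`.
#' @examples
#' homozygote(1)              # diploid, two identical alleles
#' heterozygote(10, 10 * exp(-1))
#' haploid(0.5)
#' @export
genotype <- function(K, h = 1, ploidy = length(K)) {
  if (!ploidy %in% c(1L, 2L))
    stop("'ploidy' must be 1 or 2", call. = FALSE)
  K <- rep_len(as.numeric(K), ploidy)
  h <- rep_len(as.numeric(h), ploidy)
  if (any(!is.finite(K)) || any(K <= 0))
    stop("dissociation constants 'K' must be strictly positive", call. = FALSE)
  if (any(!is.finite(h)) || any(h < 1))
    stop("Hill coefficients 'h' must be >= 1", call. = FALSE)
  structure(list(K = K, h = h, ploidy = as.integer(ploidy)),
            class = "nar_genotype")
}

#' @rdname genotype
#' @export
homozygote <- function(K, h = 1) genotype(c(K, K), c(h, h))

#' @rdname genotype
#' @export
heterozygote <- function(K_res, K_mut, h = 1) {
  h <- rep_len(h, 2L)
  genotype(c(K_res, K_mut), h)
}

#' @rdname genotype
#' @export
haploid <- function(K, h = 1) genotype(K, h, ploidy = 1L)

#' @rdname genotype
#' @param g an `nar_genotype`.
#' @export
is_homozygote <- function(g) {
  stopifnot(inherits(g, "nar_genotype"))
  g$ploidy == 2L && g$K[1] == g$K[2] && g$h[1] == g$h[2]
}

#' @export
print.nar_genotype <- function(x, ...) {
  lab <- if (x$ploidy == 1L) "haploid"
         else if (is_homozygote(x)) "diploid homozygote"
         else "diploid heterozygote"
  cat(sprintf("<nar_genotype: %s> K = (%s), h = (%s)\n", lab,
              paste(signif(x$K, 6), collapse = ", "),
              paste(signif(x$h, 4), collapse = ", ")))
  invisible(x)
}

#' System state of the expression model
#'
#' Per-allele mRNA and protein concentrations, with the derived totals
#' `M = sum(m)` and `P = sum(p)`.
#'
#' @param m per-allele mRNA concentrations (non-negative).
#' @param p per-allele protein concentrations (non-negative).
#' @return An object of class `nar_state` with fields `m`, `p`, `M`, `P`.
#' @examples
#' system_state(m = c(5, 5), p = c(500, 500))
#' @export
system_state <- function(m, p) {
  m <- as.numeric(m); p <- as.numeric(p)
  if (length(m) != length(p))
    stop("'m' and 'p' must have equal length", call. = FALSE)
  if (any(m < 0) || any(p < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  structure(list(m = m, p = p, M = sum(m), P = sum(p)), class = "nar_state")
}

# internal: check that a state matches a genotype's ploidy
check_state <- function(state, genotype) {
  if (length(state$m) != genotype$ploidy)
    stop("state dimension does not match ploidy", call. = FALSE)
  invisible(TRUE)
}
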