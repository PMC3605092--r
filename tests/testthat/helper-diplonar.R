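# Shared fixtures and independent oracles for the test suite.

test_params <- function(...) default_params(...)

# cache expensive session-wide quantities
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

test_K_opt <- function(params = test_params()) {
  cached(paste0("K_opt_", signif(params$beta_b, 8)),
         optimal_Kd(qss_reduce(params, homozygote(1)), h = 1))
}

# Oracle: positive root of the cleared-denominator quadratic for the h = 1
# diploid homozygote equilibrium:
#   dm*dp*P^2 + (dm*dp*K - 2*alpha*beta_b)*P - 2*alpha*K*(beta_b + beta_r) = 0
quadratic_equilibrium_h1 <- function(K, params) {
  a <- params$delta_m * params$delta_p
  b <- params$delta_m * params$delta_p * K - 2 * params$alpha * params$beta_b
  cc <- -2 * params$alpha * K * (params$beta_b + params$beta_r)
  (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
}

# Oracle: the unregulated (beta_r = 0) linear cascade solved in closed form.
# From m(0) = p(0) = 0 the total protein follows
#   P(t) = P_eq * [1 - (dm*exp(-dp*t) - dp*exp(-dm*t)) / (dm - dp)],
# which rises monotonically; the settle time is the crossing of theta*P_eq,
# found by root-finding on the closed form.
linear_cascade_response_time <- function(params, theta) {
  dm <- params$delta_m; dp <- params$delta_p
  stopifnot(dm != dp)
  frac <- function(t) 1 - (dm * exp(-dp * t) - dp * exp(-dm * t)) / (dm - dp)
  uniroot(function(t) frac(t) - theta, c(1e-9, 200), tol = 1e-12)$root
}

# finite-difference Jacobian of the reduced system at a protein vector
fd_reduced_jacobian <- function(red, p, dh = 1e-6) {
  n <- length(p)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- dh * max(1, abs(p[j]))
    J[, j] <- (reduced_derivatives(red, p + e) -
                 reduced_derivatives(red, p - e)) / (2 * e[j])
  }
  J
}

# eigenvalue of a 2x2 Jacobian whose mode carries total protein
# (eigenvector with non-zero component sum)
total_mode_eigenvalue <- function(J) {
  ed <- eigen(J)
  sums <- abs(colSums(ed$vectors))
  Re(ed$values[which.max(sums)])
}
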