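# Independent oracles used across the test files.

# Lambda-coalescent merger rate by numerical quadrature of
# integral y^(k-2) (1-y)^(b-k) against the Lambda measure density.
lambda_rate_quad <- function(b, k, density) {
  stats::integrate(function(y) y^(k - 2) * (1 - y)^(b - k) * density(y),
                   0, 1, rel.tol = 1e-10)$value
}

beta_density <- function(alpha) function(y) stats::dbeta(y, 2 - alpha, alpha)

# DS sweep part only (the Kingman atom is added separately)
ds_sweep_density <- function(cc) function(y) cc * y

# two-sided Fisher exact p by explicit enumeration over tables with the
# observed margins (minimum-likelihood rule)
fisher_p_enum <- function(Pn, Ps, Dn, Ds) {
  r1 <- Pn + Ps
  c1 <- Pn + Dn
  N <- Pn + Ps + Dn + Ds
  a_vals <- max(0, c1 - (N - r1)):min(r1, c1)
  probs <- stats::dhyper(a_vals, r1, N - r1, c1)
  p_obs <- stats::dhyper(Pn, r1, N - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# mean pairwise differences by explicit enumeration over haplotype pairs,
# for a list of derived-carrier index sets
theta_pi_enum <- function(derived_sets, n) {
  hap <- matrix(0, n, length(derived_sets))
  for (s in seq_along(derived_sets)) hap[derived_sets[[s]], s] <- 1
  pd <- 0
  for (a in 1:(n - 1)) for (b in (a + 1):n) pd <- pd + sum(hap[a, ] != hap[b, ])
  pd / choose(n, 2)
}

kingman_phi <- function(n) {
  i <- seq_len(n - 1)
  (1 / i) / sum(1 / i)
}
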