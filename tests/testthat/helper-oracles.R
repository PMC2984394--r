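# Independent oracles used across the suite. These deliberately avoid the
# package's own closed forms: the free-substrate oracle solves the binding
# conservation equation by bisection, and the SKM2 oracle solves the
# steady-state balance as an explicit quadratic derived from
# (1 - A)(1 + kappa A) = beta kappa A * O / (1 + O).

bisect_free_substrate <- function(s_tot, e_tot, kd, tol = 1e-13) {
  f <- function(s) s + e_tot * s / (kd + s) - s_tot
  lo <- 0; hi <- s_tot
  if (f(hi) < 0) return(hi)
  while (hi - lo > tol) {
    mid <- 0.5 * (lo + hi)
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  0.5 * (lo + hi)
}

skm2_root <- function(kappa, beta, o_bar) {
  w <- o_bar / (1 + o_bar)
  # kappa A^2 + (1 + beta kappa w - kappa) A - 1 = 0, positive root
  b <- 1 + beta * kappa * w - kappa
  if (b > 0) 2 / (b + sqrt(b^2 + 4 * kappa))
  else (-b + sqrt(b^2 + 4 * kappa)) / (2 * kappa)
}

# SKM1-style parameter set used for the skeleton-model regime analyses:
# identical binding and activity for PHD and FIH (products kcat * tot = 100)
skm1_regime_params <- function(alpha = 0.33) {
  full_params(P_tot = 1, KD_P = 1, kcat_P = 100,
              F_tot = 1, KD_FH = 1, kcat_FH = 100,
              alpha = alpha, A_tot = 0, gamma = 0, epsilon = 1)
}

# promote a plain data frame to a validated repeat collection
validate_fixture <- function(df) fihcomp:::validate_ar_db(df)

small_ar_spec <- function(n = 60) {
  synthetic_ar_spec(n_repeats = n, n_proteins = 12,
                    n_l8n = 20, n_strict = 8, n_asn_non_l8n = 18,
                    n_proteins_l8n = 7, n_proteins_strict = 3)
}
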