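# Reference schemes used throughout the suite: the package's two numerical
# experiments (conformational selection with Kd = 0.11 uM; induced fit with
# Kd = 1/11 uM) and the symmetric elementary scheme.
cs_ref <- function() binding_scheme("CS", k_e = 10, k_r = 100,
                                    k_plus = 100, k_minus = 1)
if_ref <- function() binding_scheme("IF", k_e = 1, k_r = 10,
                                    k_plus = 100, k_minus = 100)
el_ref <- function() binding_scheme("elementary", k_plus = 1, k_minus = 1)

# random strictly positive rate set spanning several decades
random_scheme <- function(mechanism, spread = c(-1.5, 2.5)) {
  r <- 10^stats::runif(4, spread[1], spread[2])
  binding_scheme(mechanism, k_e = r[1], k_r = r[2], k_plus = r[3],
                 k_minus = r[4])
}

# smallest/largest eigenvalue oracle for the relaxation spectrum
eigen_rates <- function(scheme, P0, L0) {
  sort(eigen(-jacobian_at_equilibrium(scheme, P0, L0),
             only.values = TRUE)$values)
}

# discriminant term of the one-step binding isotherm, restated
# independently of the package internals
delta_term_oracle <- function(P0, L0, Kd) {
  sqrt((L0 - P0 + Kd)^2 + 4 * Kd * P0)
}

# closed-form kobs table (no multi-exponential fitting): quick synthetic
# input for the inference module
kobs_table_closed_form <- function(scheme, P0, L0, rel_sigma = 0.02,
                                   seed = 1L) {
  grid <- expand.grid(L0_uM = L0, P0_uM = P0)[, c("P0_uM", "L0_uM")]
  k <- mapply(function(p, l) relaxation_rates(scheme, p, l)$kobs_per_s,
              grid$P0_uM, grid$L0_uM)
  sig <- rel_sigma * k
  withr_seed <- function(seed, n, sd) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    stats::rnorm(n, sd = sd)
  }
  eps <- if (rel_sigma > 0) withr_seed(seed, nrow(grid), sig) else 0
  data.frame(P0_uM = grid$P0_uM, L0_uM = grid$L0_uM,
             kobs_per_s = k + eps, sigma_per_s = pmax(sig, 1e-12))
}
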