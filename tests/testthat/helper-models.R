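# Shared fixtures: reference parameter sets for the incoherent regimes,
# and small independent oracles used to cross-check the implementation.

# incoherent recruitment model: TF enhances Pol recruitment, reduces its
# activity (the nonequilibrium colormap configuration)
incoherent_recruitment_ref <- function(bT = 0.1) {
  neq_recruitment_params(aT = 0.01, aT_p = 0.01, bT = bT, bT_Tp = bT,
                         ap = 0.01, ap_T = 0.1, bp = 0.1, bp_Tp = 0.01,
                         q3 = 1, q4 = 0.01)
}

# incoherent cycle model: TF accelerates initiation, slows termination
incoherent_cycle_ref <- function(bT = 1) {
  cycle_params(k1 = 0.01, k1r = 1, k2 = 0.2, k3 = 0.05,
               aT = 0.1, bT = bT, e2 = 15, e3 = 0.01)
}

# occupancy-modulated multisite cycle (incoherent)
incoherent_multisite_ref <- function() {
  list(k1 = 0.05, k1r = 1,
       mod2 = modulation_params(k0 = 0.2, ksat = 20, s = 1, h = 1),
       mod3 = modulation_params(k0 = 0.05, ksat = 0.0005, s = 0.1, h = 1),
       x = 2)
}

# brute-force mean occupancy: enumerate all 2^N binding configurations,
# weight each by (KT x)^(number bound)
enum_occupancy <- function(N, KT, x) {
  configs <- expand.grid(rep(list(0:1), N))
  nb <- rowSums(configs)
  w <- (KT * x)^nb
  sum(nb * w) / sum(w)
}

expect_rel_equal <- function(actual, expected, tol, floor = 0) {
  keep <- abs(expected) > floor
  expect_lt(max(abs(actual[keep] - expected[keep]) /
                  pmax(abs(expected[keep]), 1e-300)), tol)
}
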