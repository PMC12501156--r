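test_that("the equilibrium closed form has the right limits", {
  p <- eq_recruitment_params(KT = 0.5, Kp = 0.2, omega = 3, epsilon = 2)
  # no TF: basal Pol occupancy Kp/(1+Kp) times q3
  expect_equal(recruitment_rate_equilibrium(p, 0), 0.2 / 1.2)
  # neutral TF: rate constant in x
  pn <- eq_recruitment_params(KT = 0.5, Kp = 0.2, omega = 1, epsilon = 1)
  r <- recruitment_rate_equilibrium(pn, c(0, 0.1, 1, 10, 1000))
  expect_equal(r, rep(0.2 / 1.2, 5))
})

test_that("closed form equals the graph route when the cycle condition holds", {
  set.seed(101)
  for (i in 1:50) {
    KT <- exp(runif(1, log(1e-3), log(10)))
    Kp <- exp(runif(1, log(1e-2), log(1e2)))
    omega <- exp(runif(1, log(1e-2), log(1e2)))
    epsilon <- exp(runif(1, log(1e-2), log(1e2)))
    bT <- exp(runif(1, log(1e-2), log(10)))
    bp <- exp(runif(1, log(1e-2), log(10)))
    bT_Tp <- exp(runif(1, log(1e-2), log(10)))
    # realize (KT, Kp, omega) kinetically; detailed balance then holds
    kin <- neq_recruitment_params(
      aT = KT * bT, aT_p = KT * omega * bT_Tp, bT = bT, bT_Tp = bT_Tp,
      ap = Kp * bp, ap_T = Kp * omega * bp, bp = bp, bp_Tp = bp,
      q3 = 1, q4 = epsilon)
    expect_true(check_cycle_condition(build_recruitment_graph(kin), 1))
    eq <- eq_recruitment_params(KT, Kp, omega, epsilon)
    xg <- c(0, exp(seq(log(1e-2), log(1e3), length.out = 8)))
    expect_rel_equal(recruitment_rate(kin, xg),
                     recruitment_rate_equilibrium(eq, xg), 1e-10)
    # and the kinetic -> equilibrium parameter map recovers the ratios
    pe <- as_equilibrium_params(kin)
    expect_equal(pe$KT, KT, tolerance = 1e-12)
    expect_equal(pe$omega, omega, tolerance = 1e-12)
  }
})

test_that("the direction condition predicts the response sign", {
  expect_equal(direction_sign_equilibrium(
    eq_recruitment_params(1, 1, omega = 3, epsilon = 2)), 1)
  expect_equal(direction_sign_equilibrium(
    eq_recruitment_params(1, 1, omega = 1, epsilon = 1)), 0)
  # incoherent set whose balance tips positive:
  # 0.1*0.2*7 + 1.6 - 1 = 0.74 > 0
  p <- eq_recruitment_params(KT = 1, Kp = 0.1, omega = 0.2, epsilon = 8)
  expect_equal(direction_sign_equilibrium(p), 1)
  # finite differences of the closed form agree at every scale
  xg <- exp(seq(log(1e-3), log(1e3), length.out = 20))
  d <- diff(recruitment_rate_equilibrium(p, xg))
  expect_true(all(d > 0))
})

test_that("direction sign matches the empirical end-to-end fold change", {
  set.seed(111)
  for (p in sample_eq_recruitment(200)) {
    expr <- p$Kp * p$omega * (p$epsilon - 1) + p$epsilon * p$omega - 1
    if (abs(expr) < 1e-6) next
    dF <- recruitment_rate_equilibrium(p, 1e4) -
      recruitment_rate_equilibrium(p, 1e-4)
    expect_equal(direction_sign_equilibrium(p), sign(dF))
  }
})

test_that("regulatory modes follow the omega/epsilon quadrants", {
  expect_equal(regulatory_mode(eq_recruitment_params(1, 1, 2, 3)),
               "coherent_positive")
  expect_equal(regulatory_mode(eq_recruitment_params(1, 1, 0.5, 0.1)),
               "coherent_negative")
  expect_equal(regulatory_mode(eq_recruitment_params(1, 1, 0.5, 3)),
               "incoherent")
  expect_equal(regulatory_mode(eq_recruitment_params(1, 1, 1, 3)),
               "neutral")
})

test_that("the recruitment graph has the documented topology", {
  g <- build_recruitment_graph(incoherent_recruitment_ref())
  expect_equal(length(g$vertices), 4)
  expect_equal(nrow(g$edges), 8)
  expect_equal(unname(g$q[c("3", "4")]), c(1, 0.01))
  # symmetric rates balance the single 4-cycle
  sym <- neq_recruitment_params(aT = 0.1, aT_p = 0.1, bT = 1, bT_Tp = 1,
                                ap = 0.5, ap_T = 0.5, bp = 2, bp_Tp = 2,
                                q3 = 1, q4 = 1)
  cc <- check_cycle_condition(build_recruitment_graph(sym), 3)
  expect_true(cc)
  expect_equal(nrow(attr(cc, "report")), 1)   # exactly one basis cycle
})

test_that("without TF only Pol-state occupancy sets the basal rate", {
  p <- incoherent_recruitment_ref()
  g <- build_recruitment_graph(p)
  P0 <- steady_state_spanning_tree(g, 0)$probabilities
  expect_equal(unname(P0["2"] + P0["4"]), 0)   # TF states empty at x = 0
  expect_equal(recruitment_rate(p, 0), unname(p$q3 * P0["3"]),
               tolerance = 1e-12)
})

test_that("the incoherent configuration is nonmonotonic at intermediate unbinding rates", {
  p <- incoherent_recruitment_ref(bT = 0.1)
  curve <- fold_change_curve(function(x) recruitment_rate(p, x),
                             log_grid(1e-1, 1e3, 50))
  expect_equal(curve$class, "nonmonotonic")
  expect_true(curve$F[1] < max(curve$F) && curve$F[50] < max(curve$F))
})

test_that("single-site equilibrium responses are never nonmonotonic", {
  set.seed(121)
  for (p in sample_eq_recruitment(200)) {
    curve <- fold_change_curve(function(x) recruitment_rate_equilibrium(p, x),
                               log_grid(1e-3, 1e3, 50))
    expect_true(curve$class != "nonmonotonic")
  }
})

test_that("coherent kinetic recruitment responses stay monotone away from equilibrium", {
  set.seed(131)
  for (mode in c("positive", "negative")) {
    for (p in sample_coherent_recruitment(100, mode)) {
      curve <- fold_change_curve(function(x) recruitment_rate(p, x),
                                 log_grid(1e-3, 1e3, 50))
      expect_true(curve$class != "nonmonotonic")
    }
  }
})
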