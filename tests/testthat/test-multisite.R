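test_that("mean occupancy matches the single-site and saturation limits", {
  expect_equal(mean_occupancy(1, KT = 1, x = 1), 0.5)
  expect_equal(mean_occupancy(4, KT = 1, x = 1e12), 4, tolerance = 1e-10)
  expect_equal(mean_occupancy(3, KT = 1, x = 0), 0)
  # closed form N KT x / (1 + KT x)
  expect_equal(mean_occupancy(5, KT = 0.3, x = 2),
               5 * 0.6 / 1.6, tolerance = 1e-12)
})

test_that("mean occupancy equals brute-force configuration enumeration", {
  set.seed(301)
  for (N in 1:6) {
    for (i in 1:20) {
      KT <- exp(runif(1, log(1e-3), log(1e2)))
      x <- exp(runif(1, log(1e-2), log(1e2)))
      expect_equal(mean_occupancy(N, KT, x), enum_occupancy(N, KT, x),
                   tolerance = 1e-12)
    }
  }
})

test_that("mean occupancy increases strictly with x and with N", {
  xg <- log_grid(1e-3, 1e3, 40)
  a <- mean_occupancy(3, KT = 0.1, xg)
  expect_true(all(diff(a) > 0))
  aN <- vapply(1:8, function(N) mean_occupancy(N, KT = 0.1, x = 5),
               numeric(1))
  expect_true(all(diff(aN) > 0))
})

test_that("the saturable modulation interpolates between basal and saturating rates", {
  m <- modulation_params(k0 = 0.2, ksat = 20, s = 1, h = 1)
  expect_equal(modulated_rate(m, 0), 0.2)
  expect_equal(modulated_rate(m, 1), 10.1)     # midpoint at a = s
  a <- seq(0, 50, length.out = 200)
  r <- modulated_rate(m, a)
  expect_true(all(r >= 0.2 & r < 20))
  expect_true(all(diff(r) > 0))
  # repressive modulation mirrors
  md <- modulation_params(k0 = 0.05, ksat = 0.0005, s = 0.1, h = 1)
  rd <- modulated_rate(md, a)
  expect_true(all(rd <= 0.05 & rd > 0.0005))
  expect_true(all(diff(rd) < 0))
})

test_that("the closed-form cycle mRNA matches substitutions and the graph flux", {
  expect_equal(cycle_mrna_closed_form(1, 1, 1, 1), 0.25)
  expect_equal(cycle_mrna_closed_form(2, 0, 2, 2), 2 / 3)  # k/3 at k1r = 0
  # bare irreversible 3-cycle solved on the graph
  g <- rate_graph(c("1", "2", "3"),
                  data.frame(from = c("1", "2", "2", "3"),
                             to = c("2", "1", "3", "1"),
                             rate = c(0.05, 1, 0.20, 0.05)))
  P <- steady_state_spanning_tree(g, 0)$probabilities
  expect_equal(cycle_mrna_closed_form(0.05, 1, 0.20, 0.05),
               unname(0.05 * P["3"]), tolerance = 1e-12)
})

test_that("the occupancy-averaged fold change is exactly 1 at basal input", {
  mech <- incoherent_multisite_ref()
  expect_identical(multisite_response(0, KT = 1, x = 5, mech$k1, mech$k1r,
                                      mech$mod2, mech$mod3), 1)
  expect_identical(multisite_response(3, KT = 1, x = 0, mech$k1, mech$k1r,
                                      mech$mod2, mech$mod3), 1)
})

test_that("affinity tunes the site-number response through all three classes", {
  mech <- incoherent_multisite_ref()
  rm <- regime_map(function(KT) {
    function(N) multisite_response(N, KT, mech$x, mech$k1, mech$k1r,
                                   mech$mod2, mech$mod3)
  }, log_grid(1e-3, 1e2, 12), 0:6, basal = 0,
  outer_name = "KT", inner_name = "N")
  expect_setequal(unique(rm$classes),
                  c("increasing", "nonmonotonic", "decreasing"))
})

test_that("coherent occupancy modulation keeps responses monotone in N and x", {
  set.seed(311)
  for (mode in c("positive", "negative")) {
    for (m in sample_coherent_multisite(100, mode)) {
      FN <- multisite_response(0:6, m$KT, x = 2, m$k1, m$k1r,
                               m$mod2, m$mod3)
      expect_true(
        as.character(classify_monotonicity(FN)) != "nonmonotonic")
      Fx <- multisite_response(3, m$KT, log_grid(1e-3, 1e3, 50),
                               m$k1, m$k1r, m$mod2, m$mod3)
      expect_true(
        as.character(classify_monotonicity(Fx)) != "nonmonotonic")
    }
  }
})

test_that("the explicit multisite graph at N = 1 reproduces the cycle model", {
  p <- incoherent_cycle_ref(bT = 0.5)
  ms <- multisite_cycle_params(p, N = 1)
  xg <- c(0, 0.5, 5, 50)
  expect_rel_equal(multisite_cycle_rate(ms, xg), cycle_rate(p, xg), 1e-10)
})

test_that("the N = 2 graph carries binomial binding statistics", {
  p <- cycle_params(k1 = 0.05, k1r = 1, k2 = 0.2, k3 = 0.05,
                    aT = 0.1, bT = 0.5, e2 = 15, e3 = 0.01)
  g <- build_multisite_cycle_graph(multisite_cycle_params(p, N = 2))
  expect_equal(length(g$vertices), 9)
  ed <- g$edges
  bind01 <- ed[ed$from == "(1,0)" & ed$to == "(1,1)", ]
  bind12 <- ed[ed$from == "(1,1)" & ed$to == "(1,2)", ]
  expect_equal(bind01$x_coeff, 2 * p$aT)   # 2 free sites
  expect_equal(bind12$x_coeff, 1 * p$aT)
  unb10 <- ed[ed$from == "(1,1)" & ed$to == "(1,0)", ]
  unb21 <- ed[ed$from == "(1,2)" & ed$to == "(1,1)", ]
  expect_equal(unb10$rate, p$bT)
  expect_equal(unb21$rate, 2 * p$bT)
})

test_that("with recruitment unregulated, TF-binding subcycles obey detailed balance", {
  p <- cycle_params(k1 = 0.05, k1r = 1, k2 = 0.2, k3 = 0.05,
                    aT = 0.1, bT = 0.5, e1 = 1, e1r = 1, e2 = 15, e3 = 0.01)
  g <- build_multisite_cycle_graph(multisite_cycle_params(p, N = 3))
  # subgraph on states 1 and 2 (the reversible recruitment step) across
  # all binding levels: every cycle there must balance
  keep <- g$vertices[grepl("^\\((1|2),", g$vertices)]
  ed <- g$edges[g$edges$from %in% keep & g$edges$to %in% keep, ]
  sub <- rate_graph(keep, ed)
  expect_true(check_cycle_condition(sub, x = 2))
})
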