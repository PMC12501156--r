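test_that("the default design has the documented combinatorics", {
  tab <- generate_mpra_table(seed = 1)
  # 6 affinities x 6 site counts x 3 orientations x 3 spacings x
  # 3 backgrounds, plus 417 random-DNA controls
  expect_equal(nrow(tab), 6 * 6 * 3 * 3 * 3 + 417)
  expect_equal(sum(tab$is_control), 417)
  expect_setequal(unique(tab$site_count[!tab$is_control]), 1:6)
  expect_setequal(unique(tab$orientation[!tab$is_control]),
                  c("forward", "backward", "tandem"))
  expect_setequal(unique(tab$spacing_bp[!tab$is_control]), c(4, 10, 20))
})

test_that("a noise-free neutral mechanism yields exactly zero activity", {
  neut <- default_mpra_mechanism()
  neut$mod2 <- modulation_params(0.2, 0.2 * (1 + 1e-15), 1, 1)
  neut$mod3 <- modulation_params(0.05, 0.05 * (1 + 1e-15), 0.1, 1)
  tab <- generate_mpra_table(mechanism = neut, sigma_bg = 0, sigma_e = 0,
                             seed = 2)
  expect_equal(max(abs(tab$normalized_activity)), 0, tolerance = 1e-12)
})

test_that("normalization subtracts the control mean and is idempotent", {
  tab <- data.frame(raw_activity = c(0, 2, 3),
                    is_control = c(TRUE, TRUE, FALSE))
  n1 <- normalize_activity(tab)
  expect_equal(n1$normalized_activity, c(-1, 1, 2))
  expect_equal(mean(n1$normalized_activity[n1$is_control]), 0)
  n2 <- normalize_activity(n1)
  expect_identical(n1$normalized_activity, n2$normalized_activity)
  expect_error(normalize_activity(
    data.frame(raw_activity = 1, is_control = FALSE)), "control")
})

test_that("tables are bit-reproducible under a fixed seed", {
  t1 <- generate_mpra_table(seed = 33)
  t2 <- generate_mpra_table(seed = 33)
  expect_identical(t1$raw_activity, t2$raw_activity)
  t3 <- generate_mpra_table(seed = 34)
  expect_false(identical(t1$raw_activity, t3$raw_activity))
})

test_that("group means recover the generating log fold change", {
  tab <- generate_mpra_table(seed = 5, replicates = 2)
  truth <- attr(tab, "truth_logF")
  sig <- sqrt(attr(tab, "sigma_bg")^2 + attr(tab, "sigma_e")^2)
  d <- tab[!tab$is_control, ]
  agg <- stats::aggregate(normalized_activity ~ site_count + affinity_level,
                          d, mean)
  cnt <- stats::aggregate(normalized_activity ~ site_count + affinity_level,
                          d, length)
  for (r in seq_len(nrow(agg))) {
    se <- sig / sqrt(cnt$normalized_activity[r])
    expect_lt(abs(agg$normalized_activity[r] -
                    truth[as.character(agg$site_count[r]),
                          agg$affinity_level[r]]),
              4 * se)
  }
})

test_that("shape fits rank constructed trends correctly", {
  set.seed(61)
  N <- rep(0:6, each = 30)
  up <- fit_shapes(N, 0.3 * N + rnorm(length(N), 0, 0.1))
  best <- function(fits) fits[[which.min(vapply(fits, function(f) f$aic,
                                                numeric(1)))]]$shape
  expect_equal(best(up), "increasing")
  flat <- fit_shapes(N, rnorm(length(N), 2, 0.1))
  expect_equal(best(flat), "flat")
  bellish <- fit_shapes(N, -0.2 * (N - 3)^2 + rnorm(length(N), 0, 0.1))
  expect_equal(best(bellish), "bell")
  dn <- fit_shapes(N, -0.3 * N + rnorm(length(N), 0, 0.1))
  expect_equal(best(dn), "decreasing")
  # fitted values respect the declared constraint
  f <- up[[which(vapply(up, function(f) f$shape, character(1)) ==
                   "increasing")]]
  expect_false(is.unsorted(f$fitted_values))
  expect_error(fit_shapes(rep(1, 10), rnorm(10)), "distinct")
  expect_error(fit_shapes(c(1, 1, 2), rnorm(3)), "2 observations")
})

test_that("a bell-shaped truth is selected in most replicates", {
  # peak at N = 3, amplitude ~3 residual sds, 30 observations per N
  set.seed(71)
  hits <- 0
  R <- 200
  for (i in 1:R) {
    N <- rep(0:6, each = 30)
    mu <- 0.3 - 0.1 * abs(N - 3)
    fits <- fit_shapes(N, mu + rnorm(length(N), 0, 0.1))
    aics <- vapply(fits, function(f) f$aic, numeric(1))
    if (fits[[which.min(aics)]]$shape == "bell") hits <- hits + 1
  }
  expect_gte(hits / R, 0.9)
})

test_that("AIC prefers the true shape over flat increasingly with sample size", {
  set.seed(81)
  win <- vapply(c(10, 30, 100), function(n) {
    hits <- 0
    for (i in 1:50) {
      N <- rep(0:6, each = n)
      fits <- fit_shapes(N, 0.1 * N + rnorm(length(N), 0, 0.3))
      aics <- vapply(fits, function(f) f$aic, numeric(1))
      names(aics) <- vapply(fits, function(f) f$shape, character(1))
      if (aics[["increasing"]] < aics[["flat"]]) hits <- hits + 1
    }
    hits / 50
  }, numeric(1))
  expect_false(is.unsorted(win))
  expect_equal(win[3], 1)
})

test_that("a uniformly activating mechanism is called increasing at every level", {
  mech <- default_mpra_mechanism()
  mech$mod2 <- modulation_params(k0 = 0.2, ksat = 10, s = 1, h = 1)
  mech$mod3 <- modulation_params(k0 = 0.05, ksat = 0.5, s = 1, h = 1)
  truth <- mpra_truth_classes(mechanism = mech)
  expect_true(all(truth == "increasing"))
  tab <- generate_mpra_table(mechanism = mech, seed = 91)
  v <- classify_direction(tab)
  expect_true(all(v$verdict == "increasing"))
})

test_that("the default mechanism's affinity switch is recovered end to end", {
  truth <- mpra_truth_classes()
  expect_equal(unname(truth),
               c("increasing", "increasing", "bell", "bell",
                 "decreasing", "decreasing"))
  hits <- 0
  for (i in 1:20) {
    v <- classify_direction(generate_mpra_table(seed = 500 + i))
    if (all(v$verdict == truth)) hits <- hits + 1
  }
  expect_gte(hits, 18)
  # and the summary flags the activation -> repression switch
  v <- classify_direction(generate_mpra_table(seed = 501))
  expect_true(attr(v, "summary")$switch)
})
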