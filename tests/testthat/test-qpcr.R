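test_that("second-derivative-maximum Cp matches the logistic closed form", {
  for (ps in list(c(25, 1), c(25, 1 / log(1.9)), c(20, 0.8), c(30, 1.5))) {
    c0 <- ps[1]; s <- ps[2]
    crv <- data.frame(cycle = 1:42,
                      fluorescence = 1 / (1 + exp(-(1:42 - c0) / s)))
    expect_equal(call_cp(crv), c0 - s * log(2 + sqrt(3)), tolerance = 0.05)
  }
})

test_that("Cp calling is shift-equivariant and scale-invariant", {
  base <- data.frame(cycle = 1:42,
                     fluorescence = 0.1 + 1 / (1 + exp(-(1:42 - 25))))
  shifted <- data.frame(cycle = 1:42,
                        fluorescence = 0.1 + 1 / (1 + exp(-(1:42 - 27))))
  expect_equal(call_cp(shifted) - call_cp(base), 2, tolerance = 0.02)
  scaled <- base; scaled$fluorescence <- 7.3 * base$fluorescence
  expect_equal(call_cp(scaled), call_cp(base), tolerance = 1e-6)
})

test_that("flat or featureless curves raise a no-amplification error", {
  withr::with_seed(1, {
    expect_error(call_cp(abs(rnorm(42, 1, 0.01))), "no amplification")
  })
  expect_error(call_cp(rep(1, 42)), "no amplification")
  expect_error(call_cp(1:10), "20 cycles")
})

test_that("efficiency estimation recovers planted efficiencies", {
  # exact doubling
  dbl <- data.frame(cycle = 1:42, fluorescence = 2^(1:42 - 30))
  expect_equal(estimate_efficiency(dbl), 2, tolerance = 0.01)
  # logistic with baseline and plateau
  crv <- simulate_amplification_curve(E = 1.9, cp = 24)
  expect_equal(estimate_efficiency(crv), 1.9, tolerance = 0.02)
  # scale invariance
  crv2 <- crv; crv2$fluorescence <- 5 * crv$fluorescence
  expect_equal(estimate_efficiency(crv2), estimate_efficiency(crv),
               tolerance = 1e-9)
  # seeded noisy recovery
  noisy <- simulate_amplification_curve(1.9, 24, noise_sd = 0.005, seed = 4)
  expect_equal(estimate_efficiency(noisy), 1.9, tolerance = 0.05)
})

test_that("mean efficiency over a set of reactions lands on the per-pair value", {
  curves <- lapply(1:12, function(s)
    simulate_amplification_curve(1.78, 23 + (s %% 5), noise_sd = 0.005,
                                 seed = 100 + s))
  expect_equal(mean_efficiency(curves), 1.78, tolerance = 0.02)
})

test_that("relative levels follow the external-standard formula", {
  expect_equal(relative_level(1.9, 20, 1.9, 20), 1.0)
  expect_equal(relative_level(2, 20, 2, 21), 0.5)
  expect_equal(relative_level(1.82, 20, 1.78, 20), 1.56, tolerance = 0.005)
  expect_error(relative_level(2.5, 20, 1.9, 20), "1, 2.1")
})

test_that("relative level is monotone in both Cp arguments", {
  withr::with_seed(42, {
    for (i in 1:50) {
      E1 <- runif(1, 1.5, 2); E2 <- runif(1, 1.5, 2)
      cp <- runif(2, 10, 35); d <- runif(1, 0.1, 5)
      expect_gt(relative_level(E1, cp[1], E2, cp[2]),
                relative_level(E1, cp[1], E2, cp[2] + d))
      expect_lt(relative_level(E1, cp[1], E2, cp[2]),
                relative_level(E1, cp[1] + d, E2, cp[2]))
    }
  })
})

test_that("group summaries report mean and standard error", {
  df <- data.frame(level = c(1, 2, 3), group = "a")
  gs <- group_summary(df)
  expect_equal(gs$mean, 2)
  expect_equal(gs$sem, sd(1:3) / sqrt(3), tolerance = 1e-12)
  expect_equal(round(gs$sem, 3), 0.577)
  same <- data.frame(level = rep(2, 8), group = "a")
  expect_equal(group_summary(same)$sem, 0)
  # realistic group sizes pass through silently
  big <- data.frame(level = rnorm(6 + 10), group = rep(c("a", "b"), c(6, 10)))
  expect_silent(group_summary(big))
})

test_that("whole-table relative quantification joins, averages and flags", {
  cp <- data.frame(
    sample_id = rep(c("s1", "s2"), each = 2),
    group = "normoxia", tissue = "brain",
    gene = rep(c("mw2060", "Ki67"), 2),
    cp1 = c(26.0, 26.1, 26.0, 24.0),
    cp2 = c(26.0, 26.1, 26.0, 25.6))  # s2 Ki67 duplicates discordant
  eff <- data.frame(gene = c("mw2060", "Ki67"), tissue = "brain",
                    E = c(1.82, 1.78))
  lv <- qpcr_relative_levels(cp, eff)
  expect_equal(nrow(lv), 2)
  expect_equal(lv$level[lv$sample_id == "s1"],
               1.82^26 / 1.78^26.1, tolerance = 1e-9)
  expect_false(lv$flagged[lv$sample_id == "s1"])
  expect_true(lv$flagged[lv$sample_id == "s2"])
  expect_error(qpcr_relative_levels(cp, eff, normalizer = "actb"), "absent")
  expect_error(qpcr_relative_levels(cp[cp$gene != "mw2060", ], eff), "absent")
})

test_that("Monte Carlo Dunnett agrees with the multivariate-t reference", {
  mc <- dunnett_critical(rep(8, 6), df = 42, alpha = 0.05, n_mc = 1e5, seed = 3)
  corr <- matrix(0.5, 5, 5); diag(corr) <- 1
  set.seed(2)
  ref <- mvtnorm::qmvt(0.95, tail = "both.tails", df = 42, corr = corr)$quantile
  expect_equal(mc$crit, ref, tolerance = 0.02)
})

test_that("Dunnett test calls extreme separations and honours its seed", {
  withr::with_seed(5, {
    y <- c(rnorm(8, 100), rnorm(40))
    g <- rep(c("normoxia", paste0("grp", 1:5)), each = 8)
  })
  d1 <- dunnett_vs_control(y, g, control = "normoxia", n_mc = 2e4, seed = 1)
  expect_true(all(d1$comparisons$significant))
  expect_lt(d1$anova_p, 1e-10)
  d2 <- dunnett_vs_control(y, g, control = "normoxia", n_mc = 2e4, seed = 1)
  expect_identical(d1$comparisons, d2$comparisons)
  expect_error(dunnett_vs_control(y, g, control = "absent"), "not present")
  expect_error(dunnett_vs_control(c(y, 1), c(g, "tiny"), control = "normoxia"),
               "n >= 2")
})

test_that("Dunnett adjusted p-values match multcomp on shared data", {
  withr::with_seed(11, {
    y <- rnorm(48) + rep(c(0, 0, 1.2, 0, 0, 0), each = 8)
    g <- factor(rep(c("ctrl", paste0("g", 1:5)), each = 8))
  })
  mine <- dunnett_vs_control(y, as.character(g), control = "ctrl",
                             n_mc = 1e5, seed = 2)
  glht_fit <- multcomp::glht(stats::aov(y ~ g),
                             linfct = multcomp::mcp(g = "Dunnett"))
  ref_p <- summary(glht_fit)$test$pvalues
  ord <- match(paste0("g", 1:5), mine$comparisons$group)
  expect_equal(mine$comparisons$p_adj[ord], as.numeric(ref_p),
               tolerance = 0.02)
})
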