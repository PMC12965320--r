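test_that("nested t collapses wells to biological-replicate means", {
  # identical replicate means: t = 0, p = 1
  d <- sim_nested(group_effects = c(0, 0), sd_bio = 0, sd_tech = 0)
  d$value <- rep(c(1, 2, 3), each = 3)[seq_len(nrow(d)) %% 9 + 1]
  d$value <- ave(seq_len(nrow(d)), d$replicate) * 0 +
    rep(rep(c(1, 2, 3), each = 3), 2)
  r <- nested_t(d, "g1", "g2")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # a shift with zero within-replicate variance equals the textbook
  # two-sample t on the replicate means, computed by hand as the oracle
  d2 <- d
  d2$value[d2$condition == "g2"] <- d2$value[d2$condition == "g2"] + 1.5
  r2 <- nested_t(d2, "g1", "g2")
  a <- c(1, 2, 3); b <- a + 1.5
  sp <- sqrt((2 * var(a) + 2 * var(b)) / 4)
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(2 / 3))
  expect_equal(r2$statistic, t_hand)
  expect_equal(r2$df, 4)
  expect_equal(r2$p_value, 2 * pt(-abs(t_hand), 4))

  # degrees of freedom follow biological replicates, not wells
  d3 <- sim_nested(n_bio = 4, n_tech = 7, seed = 3)
  expect_equal(nested_t(d3, "g1", "g2")$df, 6)
})

test_that("nested results are invariant to technical-replicate handling", {
  d <- sim_nested(seed = 11)
  r <- nested_t(d, "g1", "g2")
  # permuting wells within a biological replicate changes nothing
  set.seed(1)
  dp <- d[sample(nrow(d)), ]
  expect_equal(nested_t(dp, "g1", "g2")$statistic, r$statistic)
  # duplicating every technical replicate changes nothing
  expect_equal(nested_t(rbind(d, d), "g1", "g2")$statistic, r$statistic)
  # a biological replicate sitting in both groups is a design violation
  bad <- d; bad$replicate <- sub("^g[12]_", "", bad$replicate)
  expect_error(nested_t(bad, "g1", "g2"), "both groups")
})

test_that("the mixed-model nested t agrees with the means mode", {
  d <- sim_nested(n_bio = 4, n_tech = 6, group_effects = c(0, 4),
                  sd_bio = 0.5, sd_tech = 1, seed = 17)
  rm_ <- nested_t(d, "g1", "g2")
  rl <- nested_t(d, "g1", "g2", mode = "lmm")
  # balanced design: the variance-components fit and the replicate-means
  # t test estimate the same contrast with comparable evidence
  expect_equal(abs(unname(diff(rl$group_means))),
               abs(unname(diff(rm_$group_means))))
  expect_equal(abs(rl$statistic), abs(rm_$statistic), tolerance = 0.15)
  expect_lt(rl$p_value, 0.05)
})

test_that("nested t type-I error is calibrated at the nominal level", {
  set.seed(7)
  alpha <- 0.05
  B <- 2000
  rej <- vapply(seq_len(B), function(i) {
    d <- sim_nested(n_bio = 4, n_tech = 3, sd_bio = 1, sd_tech = 1,
                    seed = 20000 + i)
    nested_t(d, "g1", "g2")$p_value < alpha
  }, logical(1))
  expect_lt(abs(mean(rej) - alpha), 3 * sqrt(alpha * (1 - alpha) / B))
})

test_that("nested ANOVA post hocs follow the declared adjustments", {
  # all groups identical: F ~ 0 and every adjusted p = 1
  d0 <- sim_nested(n_groups = 3, sd_bio = 0, sd_tech = 0,
                   group_effects = c(0, 0, 0))
  d0$value <- rep(1, nrow(d0))
  r0 <- nested_anova(d0, posthoc = "sidak")
  expect_equal(r0$anova$F, 0)
  expect_true(all(r0$comparisons$p_adj == 1))

  # Sidak identity: adjusted = 1 - (1 - p)^m over the declared family
  d <- sim_nested(n_groups = 3, group_effects = c(0, 1, 2), seed = 4)
  rs <- nested_anova(d, posthoc = "sidak")
  expect_equal(rs$comparisons$p_adj,
               pmax(1 - (1 - rs$comparisons$p_raw)^3,
                    rs$comparisons$p_raw))
  # adjusted p never undercuts raw p (dunnett too)
  rd <- nested_anova(d, posthoc = "dunnett", reference = "g1")
  expect_true(all(rd$comparisons$p_adj >= rd$comparisons$p_raw - 1e-12))
  expect_error(nested_anova(d, posthoc = "dunnett"), "reference")

  # two-group Dunnett degenerates to the nested t up to the family
  d2 <- sim_nested(group_effects = c(0, 1), seed = 9)
  rt <- nested_t(d2, "g1", "g2")
  r1 <- nested_anova(d2, posthoc = "dunnett", reference = "g1")
  expect_equal(abs(r1$comparisons$estimate),
               abs(unname(diff(rt$group_means))), tolerance = 1e-8)
  expect_equal(r1$comparisons$p_raw, rt$p_value, tolerance = 1e-6)
  expect_equal(r1$comparisons$p_adj, rt$p_value, tolerance = 1e-3)
})

test_that("paired t handles pairing, degeneracy and beats unpaired power", {
  wells <- data.frame(well = rep(paste0("W", 1:6), 2),
                      population = rep(c("gvb_neg", "gvb_pos"), each = 6),
                      value = c(1:6, 1:6))
  r <- paired_t(wells, "gvb_neg", "gvb_pos")
  expect_equal(r$statistic, 0)
  # constant within-pair difference: infinite t flagged degenerate
  wells2 <- wells
  wells2$value[7:12] <- wells2$value[7:12] + 2
  r2 <- paired_t(wells2, "gvb_neg", "gvb_pos")
  expect_true(is.infinite(r2$statistic))
  expect_true(r2$degenerate)
  # unpaired wells are excluded with a warning
  expect_warning(paired_t(wells[-1, ], "gvb_neg", "gvb_pos"), "unpaired")

  # simulated paired shift: paired test outpowers unpaired at equal n
  set.seed(13)
  hits <- replicate(300, {
    base <- rnorm(6, 10, 2)          # strong shared well effect
    a <- base + rnorm(6, 0, 0.3)
    b <- base + 0.5 + rnorm(6, 0, 0.3)
    d <- data.frame(well = rep(paste0("W", 1:6), 2),
                    population = rep(c("a", "b"), each = 6),
                    value = c(a, b))
    c(paired = paired_t(d, "a", "b")$p_value < 0.05,
      unpaired = t.test(a, b)$p.value < 0.05)
  })
  expect_gt(mean(hits["paired", ]), mean(hits["unpaired", ]))
})

test_that("robust outlier flagging is calibrated and affine-invariant", {
  # a value 100 MADs out is always flagged
  x <- c(rnorm(20), 100)
  expect_true(flag_outliers(x)[21])
  expect_false(any(flag_outliers(x)[1:20]))
  # affine rescaling leaves the flags unchanged
  expect_identical(flag_outliers(x), flag_outliers(5 * x - 3))
  # too few values: no flagging, with a warning
  expect_warning(f <- flag_outliers(c(1, 2, 100)), "fewer than 5")
  expect_false(any(f))
  # clean symmetric samples almost never get flagged at Q = 1%
  set.seed(21)
  any_flag <- replicate(2000, any(flag_outliers(rnorm(10))))
  expect_gte(mean(!any_flag), 0.99)
})
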