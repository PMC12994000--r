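test_that("Fisher Z is the monotone odd atanh with boundary clipping", {
  expect_equal(unclass(fisher_z(0)), 0, ignore_attr = TRUE)
  expect_equal(unclass(fisher_z(0.5)), 0.549306, tolerance = 1e-6,
               ignore_attr = TRUE)
  r <- seq(-0.95, 0.95, by = 0.05)
  z <- fisher_z(r)
  expect_false(is.unsorted(z))
  expect_equal(unclass(fisher_z(-r)), -unclass(fisher_z(r)), ignore_attr = TRUE)
  zc <- fisher_z(c(-1, 1))
  expect_true(all(is.finite(zc)))
  expect_equal(attr(zc, "n_clipped"), 2)
})

test_that("one-sample FWE map matches manual t computation and Bonferroni logic", {
  # hand-computed 5-subject single-voxel case
  x <- c(0.2, 0.5, 0.1, 0.4, 0.3)
  gm <- one_sample_fwe(matrix(x, 5, 1))
  t_manual <- mean(x) / (sd(x) / sqrt(5))
  expect_equal(gm$t, t_manual, tolerance = 1e-10)
  expect_equal(gm$p, 2 * pt(-abs(t_manual), 4), tolerance = 1e-12)

  # strong-effect synthetic maps: t around 48, everything significant
  withr::with_seed(7, maps <- matrix(rnorm(23 * 1000, 1, 0.1), 23, 1000))
  gm2 <- one_sample_fwe(maps)
  expect_equal(mean(gm2$t), 1 / (0.1 / sqrt(23)), tolerance = 0.1)
  expect_true(all(gm2$significant))

  # all-zero maps: flagged, nothing significant
  gm0 <- one_sample_fwe(matrix(0, 5, 10))
  expect_true(all(!gm0$significant))
  expect_true(all(gm0$flagged))

  # Bonferroni never declares more voxels than uncorrected testing
  withr::with_seed(8, nm <- matrix(rnorm(10 * 200, 0.1, 0.5), 10, 200))
  gm3 <- one_sample_fwe(nm)
  expect_lte(sum(gm3$significant), sum(gm3$p < 0.05, na.rm = TRUE))
  expect_error(one_sample_fwe(matrix(0, 2, 4)), "3 subjects")

  # map-level family-wise type-I rate under the global Gaussian null
  fw <- withr::with_seed(88, {
    mean(vapply(1:1000, function(i) {
      any(one_sample_fwe(matrix(rnorm(10 * 100), 10, 100))$significant)
    }, logical(1)))
  })
  expect_lte(fw, 0.05 + 0.02)
})

test_that("two-sample ROI test matches the pooled-variance t-test", {
  x <- c(0.3, 0.5, 0.4); y <- c(0.1, 0.2, 0.15)
  got <- two_sample_roi_test(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)

  same <- two_sample_roi_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  withr::with_seed(9, {
    a <- rnorm(23, 1, 0.1); b <- rnorm(23, 0, 0.1)
  })
  expect_lt(two_sample_roi_test(a, b)$p, 0.001)
  expect_error(two_sample_roi_test(1, c(1, 2)), "at least 2")
})

test_that("repeated-measures ANOVA matches aov and car on a two-factor design", {
  withr::with_seed(10, {
    ns <- 12
    d <- expand.grid(subject = 1:ns, roi = c("r1", "r2", "r3"),
                     model = c("m1", "m2"))
    d$value <- 0.3 + 0.2 * (d$roi == "r2") + 0.1 * (d$model == "m2") +
      0.05 * (d$roi == "r3") * (d$model == "m2") +
      rep(rnorm(ns, 0, 0.1), 6) + rnorm(nrow(d), 0, 0.05)
  })
  res <- rm_anova_gg(d, factors = c("roi", "model"))
  expect_equal(res$effect, c("roi", "model", "roi:model"))

  # uncorrected F values against base aov
  fit <- stats::aov(value ~ roi * model + Error(factor(subject) / (roi * model)),
                    data = d)
  sm <- summary(fit)
  f_aov <- c(sm[["Error: factor(subject):roi"]][[1]]["roi", "F value"],
             sm[["Error: factor(subject):model"]][[1]]["model", "F value"],
             sm[["Error: factor(subject):roi:model"]][[1]]["roi:model", "F value"])
  expect_equal(res$statistic, unname(f_aov), tolerance = 1e-8)

  # Greenhouse-Geisser epsilons against car's multivariate machinery
  wide <- tidyr::pivot_wider(d, names_from = c("roi", "model"), values_from = "value")
  wide <- as.data.frame(wide[order(wide$subject), ])
  mlm <- lm(as.matrix(wide[, -1]) ~ 1)
  idata <- expand.grid(roi = c("r1", "r2", "r3"), model = c("m1", "m2"))
  # column order of the wide matrix: roi varies within model blocks
  idata <- idata[order(idata$model, idata$roi), ]
  av <- car::Anova(mlm, idata = idata, idesign = ~ roi * model, type = 3)
  cs <- summary(av)$pval.adjustments
  expect_equal(res$epsilon[res$effect == "roi"], unname(cs["roi", "GG eps"]),
               tolerance = 1e-8)
  expect_equal(res$epsilon[res$effect == "roi:model"],
               unname(cs["roi:model", "GG eps"]), tolerance = 1e-8)

  # partial eta squared from the sums of squares
  expect_equal(res$partial_eta_sq, res$ss / (res$ss + res$ss_error))
  expect_true(all(res$epsilon > 0 & res$epsilon <= 1))
})

test_that("two-level factors have epsilon exactly 1 and SS partition closes", {
  withr::with_seed(11, {
    d <- expand.grid(subject = 1:8, cond = c("a", "b"))
    d$value <- rnorm(16) + 0.5 * (d$cond == "b")
  })
  res <- rm_anova_gg(d, factors = "cond")
  expect_identical(res$epsilon, 1)

  # balanced partition: SS_total = SS_subject + sum of effect + error SS
  withr::with_seed(12, {
    d2 <- expand.grid(subject = 1:6, f1 = c("x", "y", "z"), f2 = c("p", "q"))
    d2$value <- rnorm(nrow(d2))
  })
  res2 <- rm_anova_gg(d2, factors = c("f1", "f2"))
  yarr <- d2$value
  ss_total <- sum((yarr - mean(yarr))^2)
  m_s <- tapply(d2$value, d2$subject, mean)
  ss_subj <- 6 * sum((m_s - mean(yarr))^2)
  expect_equal(ss_total, ss_subj + sum(res2$ss) + sum(res2$ss_error),
               tolerance = 1e-8)

  d3 <- d2[-1, ]
  expect_error(rm_anova_gg(d3, factors = c("f1", "f2")), "balanced")
})

test_that("contrast tests score within-subject contrasts with Bonferroni", {
  withr::with_seed(13, {
    d <- expand.grid(subject = 1:12, condition = c("c1", "c2", "c3"))
    d$value <- rnorm(36, sd = 0.5) + ifelse(d$condition == "c3", 1, 0)
  })
  one <- contrast_tests(d, list(late_vs_rest = c(c1 = -0.5, c2 = -0.5, c3 = 1)))
  expect_equal(one$p, one$p_adjusted) # single contrast: no correction
  expect_lt(one$p_adjusted, 0.05)

  # k identical contrasts: adjusted p = min(1, k * raw)
  k3 <- contrast_tests(d, list(a = c(-1, 0, 1), b = c(-1, 0, 1), c = c(-1, 0, 1)))
  expect_equal(k3$p_adjusted, pmin(1, k3$p * 3))

  # manual oracle for the contrast t statistic
  wide <- tapply(d$value, list(d$subject, d$condition), mean)
  score <- drop(wide %*% c(-0.5, -0.5, 1))
  expect_equal(one$t, unname(t.test(score)$statistic), tolerance = 1e-12)

  expect_error(contrast_tests(d, list(bad = c(1, 1, 1))), "sum to zero")
})

test_that("normalized confidence intervals follow the subject-centred recipe", {
  withr::with_seed(14, base <- matrix(rnorm(8 * 4), 8, 4))
  data <- base
  ci <- normalized_ci(data)
  # manual computation
  adj <- data - rowMeans(data) + mean(data)
  half <- qt(0.975, 7) * apply(adj, 2, sd) / sqrt(8) * sqrt(4 / 3)
  expect_equal(ci$ci_half_width, unname(half), tolerance = 1e-10)
  expect_equal(ci$mean, unname(colMeans(data)))

  # pure subject offsets: no within-subject variability, CI collapses
  offsets <- matrix(rnorm(8), 8, 4) + matrix(1:4 * 0, 8, 4)
  ci0 <- normalized_ci(offsets)
  expect_lt(max(ci0$ci_half_width), 1e-10)

  # M = 2 conditions: Morey factor sqrt(2)
  two <- base[, 1:2]
  adj2 <- two - rowMeans(two) + mean(two)
  half2 <- qt(0.975, 7) * apply(adj2, 2, sd) / sqrt(8) * sqrt(2)
  expect_equal(normalized_ci(two)$ci_half_width, unname(half2), tolerance = 1e-10)

  expect_error(normalized_ci(base[, 1, drop = FALSE]), "single condition")
})
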