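test_that("log response ratio and its variance follow the formulas", {
  a <- data.frame(mean_inoc = 4, sd_inoc = 1, n_inoc = 4,
                  mean_ctrl = 2, sd_ctrl = 1, n_ctrl = 4)
  e <- compute_lrr(a)
  expect_equal(e$lrr, log(2))
  expect_equal(e$variance, 1 / (4 * 16) + 1 / (4 * 4))
  expect_equal(e$variance, 0.078125)
  # trivial endpoints
  same <- data.frame(mean_inoc = 3, sd_inoc = 0.5, n_inoc = 5,
                     mean_ctrl = 3, sd_ctrl = 0.5, n_ctrl = 5)
  expect_equal(compute_lrr(same)$lrr, 0)
  ee <- data.frame(mean_inoc = exp(1) * 2, sd_inoc = 0.5, n_inoc = 5,
                   mean_ctrl = 2, sd_ctrl = 0.5, n_ctrl = 5)
  expect_equal(compute_lrr(ee)$lrr, 1)
  expect_error(compute_lrr(
    data.frame(mean_inoc = -1, sd_inoc = 1, n_inoc = 3,
               mean_ctrl = 2, sd_ctrl = 1, n_ctrl = 3)), "positive")
})

test_that("the LRR variance is invariant to rescaling biomass units", {
  set.seed(1)
  for (i in 1:20) {
    a <- data.frame(mean_inoc = runif(1, 1, 5), sd_inoc = runif(1, 0.1, 1),
                    n_inoc = sample(3:10, 1), mean_ctrl = runif(1, 1, 5),
                    sd_ctrl = runif(1, 0.1, 1), n_ctrl = sample(3:10, 1))
    k <- runif(1, 0.1, 50)
    b <- a
    b$mean_inoc <- k * a$mean_inoc; b$sd_inoc <- k * a$sd_inoc
    b$mean_ctrl <- k * a$mean_ctrl; b$sd_ctrl <- k * a$sd_ctrl
    expect_equal(compute_lrr(a)$variance, compute_lrr(b)$variance,
                 tolerance = 1e-12)
    expect_equal(compute_lrr(a)$lrr, compute_lrr(b)$lrr, tolerance = 1e-12)
  }
})

test_that("diversity-response ratios use the right reference in each mode", {
  assays <- data.frame(
    study_id = "s1", host_species = "h1", life_history = "early",
    fungal_isolate = c("f1", "f2", "mixture"),
    mean_inoc = c(2, 4, 4), sd_inoc = c(0.5, 0.5, 0.5),
    n_inoc = 5, mean_ctrl = 1, sd_ctrl = 0.2, n_ctrl = 5)
  best <- diversity_lrr(assays, "vs_best_single")
  expect_equal(best$lrr, 0)
  avg <- diversity_lrr(assays, "vs_mean_single")
  expect_equal(avg$lrr, log(4 / 3))
  # multi equal to every single: both modes give zero
  eq <- assays; eq$mean_inoc <- c(4, 4, 4)
  expect_equal(diversity_lrr(eq, "vs_best_single")$lrr, 0)
  expect_equal(diversity_lrr(eq, "vs_mean_single")$lrr, 0)
  # tie on the best mean broken by the smaller variance-of-mean
  tie <- assays
  tie$mean_inoc <- c(4, 4, 4); tie$sd_inoc <- c(0.9, 0.1, 0.5)
  out <- diversity_lrr(tie, "vs_best_single")
  expect_equal(out$variance,
               0.5^2 / (5 * 16) + (0.1^2 / 5) / 16, tolerance = 1e-12)
})

test_that("a single effect with no moderators is returned unchanged", {
  eff <- data.frame(lrr = 0.42, variance = 0.01, study_id = "s1",
                    host_species = "h1")
  m <- fit_meta_reml(eff, ~1, random = character(0))
  expect_equal(unname(m$b), 0.42, tolerance = 1e-10)
})

test_that("identical effects with equal variances give the common value and tau2 = 0", {
  eff <- data.frame(lrr = rep(0.3, 6), variance = 0.02,
                    study_id = paste0("s", 1:6),
                    host_species = paste0("h", 1:6))
  m <- fit_meta_reml(eff, ~1)
  expect_equal(unname(m$b), 0.3, tolerance = 1e-8)
  expect_lt(max(m$tau2), 1e-6)
})

test_that("without random heterogeneity the model is the inverse-variance weighted mean", {
  set.seed(2)
  eff <- data.frame(lrr = rnorm(12, 0.5, 0.1),
                    variance = runif(12, 0.005, 0.05),
                    study_id = paste0("s", 1:12),
                    host_species = paste0("h", 1:12))
  m <- fit_meta_reml(eff, ~1, random = character(0))
  ivw <- sum(eff$lrr / eff$variance) / sum(1 / eff$variance)
  expect_equal(unname(m$b), ivw, tolerance = 1e-8)
})

test_that("the Wald QM test reduces to z-squared and matches metafor", {
  set.seed(3)
  eff <- data.frame(
    lrr = rnorm(30, 0.2, 0.3), variance = runif(30, 0.01, 0.05),
    study_id = sample(paste0("s", 1:3), 30, TRUE),
    host_species = sample(paste0("h", 1:10), 30, TRUE),
    life_history = sample(c("early", "late"), 30, TRUE))
  m <- fit_meta_reml(eff, ~ life_history)
  qm1 <- wald_qm(m, "life_historylate")
  z2 <- (m$b[["life_historylate"]] /
           sqrt(m$vcov["life_historylate", "life_historylate"]))^2
  expect_equal(qm1$QM, unname(z2), tolerance = 1e-10)
  expect_equal(qm1$p, pchisq(z2, 1, lower.tail = FALSE),
               ignore_attr = TRUE, tolerance = 1e-10)
  # cross-check the all-moderator QM against metafor's own statistic
  qma <- wald_qm(m)
  expect_equal(qma$QM, m$fit$QM, tolerance = 1e-6)
  expect_error(wald_qm(m, "nope"), "unknown")
})

test_that("QM over a full factor is invariant to the baseline level", {
  set.seed(4)
  grp <- sample(c("a", "b", "c"), 40, TRUE)
  eff <- data.frame(
    lrr = rnorm(40, ifelse(grp == "b", 0.4, 0), 0.2),
    variance = runif(40, 0.01, 0.03),
    study_id = sample(paste0("s", 1:4), 40, TRUE),
    host_species = sample(paste0("h", 1:12), 40, TRUE),
    grp = grp)
  m1 <- fit_meta_reml(eff, ~ grp)
  eff2 <- eff
  eff2$grp <- factor(eff2$grp, levels = c("c", "a", "b"))
  m2 <- fit_meta_reml(eff2, ~ grp)
  q1 <- wald_qm(m1, grep("^grp", names(m1$b), value = TRUE))
  q2 <- wald_qm(m2, grep("^grp", names(m2$b), value = TRUE))
  expect_equal(q1$QM, q2$QM, tolerance = 1e-6)
})

test_that("marginal means average predictions over a balanced grid", {
  set.seed(5)
  iso <- rep(c("f1", "f2"), each = 20)
  lh <- rep(c("early", "late"), 20)
  eff <- data.frame(
    lrr = 0.2 + 0.3 * (iso == "f2") + 0.1 * (lh == "late") + rnorm(40, 0, 0.1),
    variance = rep(0.01, 40),
    study_id = sample(paste0("s", 1:3), 40, TRUE),
    host_species = sample(paste0("h", 1:8), 40, TRUE),
    fungal_isolate = iso, life_history = lh)
  m <- fit_meta_reml(eff, ~ fungal_isolate + life_history)
  mm <- marginal_means(m, "fungal_isolate")
  # balanced averaging: difference of marginal means is the coefficient
  expect_equal(mm$emmean[mm$fungal_isolate == "f2"] -
                 mm$emmean[mm$fungal_isolate == "f1"],
               m$b[["fungal_isolatef2"]], tolerance = 1e-10)
  # equal-weight average over the focal factor equals the grand prediction
  grand <- mean(mm$emmean)
  xall <- c(1, 0.5, 0.5)  # intercept, half f2, half late
  expect_equal(grand, sum(xall * m$b), tolerance = 1e-10)
  # cross-check against emmeans on the same coefficient vector
  skip_if_not_installed("emmeans")
  rg <- emmeans::qdrg(~ fungal_isolate + life_history, data = eff,
                      coef = m$b, vcov = m$vcov)
  ref <- as.data.frame(emmeans::emmeans(rg, "fungal_isolate"))
  expect_equal(mm$emmean, ref$emmean, tolerance = 1e-8)
  expect_equal(mm$se, ref$SE, tolerance = 1e-8)
})

test_that("intercept-only marginal means are the pooled estimate", {
  eff <- data.frame(lrr = c(0.1, 0.5, 0.3), variance = 0.02,
                    study_id = "s1", host_species = paste0("h", 1:3),
                    life_history = c("early", "late", "early"))
  m <- fit_meta_reml(eff, ~ life_history)
  m0 <- fit_meta_reml(eff, ~1)
  mm0 <- marginal_means(m0, character(0))
  expect_equal(nrow(mm0), 1)
  expect_equal(mm0$emmean, unname(m0$b))
  # unobserved focal cells come back NA
  eff$iso <- c("f1", "f1", "f2")
  m2 <- fit_meta_reml(eff, ~ life_history + iso)
  mm2 <- suppressMessages(marginal_means(m2, c("life_history", "iso")))
  expect_true(is.na(mm2$emmean[mm2$life_history == "late" &
                                 mm2$iso == "f2"]))
})
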