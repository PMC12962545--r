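test_that("the interaction coefficient follows its definition", {
  expect_equal(interaction_coefficient(3, 3, 3, 3), 0)
  expect_equal(interaction_coefficient(2, 1, 1, 2), 2)
  expect_equal(interaction_coefficient(3.1, 2.4, 1.9, 2.2), 1.0)
  set.seed(1)
  for (i in 1:20) {
    f <- runif(4, 0.5, 5)
    expect_equal(interaction_coefficient(f[1], f[2], f[3], f[4]),
                 f[1] - f[2] - f[3] + f[4], tolerance = 1e-12)
  }
})

test_that("pairwise interactions are exact on noiseless designs and flagged degenerate", {
  pairs <- data.frame(species_A = c("A", "A", "B"),
                      species_B = c("B", "C", "C"),
                      design_block = "fb1", I_target = c(2, -1, 0.5))
  cfg <- sim_config(biomass_noise_sd = 0, feedback_reps = 3)
  fb <- simulate_feedback_biomass(pairs, cfg, seed = 1)
  res <- pairwise_interactions(fb)
  expect_equal(nrow(res), 3)
  key <- paste(res$species_A, res$species_B)
  expect_equal(res$I[match(c("A B", "A C", "B C"), key)], c(2, -1, 0.5))
  expect_true(all(res$degenerate))
  expect_true(all(res$se == 0))
})

test_that("the pair t test uses the pooled within-cell variance", {
  pairs <- data.frame(species_A = "A", species_B = "B",
                      design_block = "fb1", I_target = 1.5)
  cfg <- sim_config(biomass_noise_sd = 0.5, feedback_reps = 4)
  res <- pairwise_interactions(simulate_feedback_biomass(pairs, cfg, 3))
  expect_equal(res$df, 16 - 4)
  # se = s_pooled * sqrt(sum 1/n) = s_pooled * 1 here; near sd = 0.5
  expect_equal(res$se, 0.5, tolerance = 0.35)
  expect_equal(res$p, 2 * pt(-abs(res$t), res$df))
  # relabeling the pair leaves I and p unchanged
  fb <- simulate_feedback_biomass(pairs, cfg, 3)
  swap <- fb
  swap$host_species <- chartr("AB", "BA", fb$host_species)
  swap$training_species <- chartr("AB", "BA", fb$training_species)
  res2 <- pairwise_interactions(swap)
  expect_equal(res2$I, res$I)
  expect_equal(res2$p, res$p)
})

test_that("I is invariant to a host-species main effect", {
  pairs <- data.frame(species_A = "A", species_B = "B",
                      design_block = "fb1", I_target = 0.8)
  cfg <- sim_config(biomass_noise_sd = 0.2, feedback_reps = 4)
  fb <- simulate_feedback_biomass(pairs, cfg, 5)
  shifted <- fb
  shifted$biomass[shifted$host_species == "A"] <-
    shifted$biomass[shifted$host_species == "A"] + 3
  expect_equal(pairwise_interactions(shifted)$I,
               pairwise_interactions(fb)$I, tolerance = 1e-12)
})

test_that("missing cells make a pair non-estimable and are reported", {
  pairs <- data.frame(species_A = c("A", "A"), species_B = c("B", "C"),
                      design_block = "fb1", I_target = c(1, 1))
  cfg <- sim_config(biomass_noise_sd = 0.1, feedback_reps = 2)
  fb <- simulate_feedback_biomass(pairs, cfg, 1)
  fb <- fb[!(fb$host_species == "B" & fb$training_species == "C"), ]
  res <- pairwise_interactions(fb)
  expect_false(any(res$species_A == "B" & res$species_B == "C"))
  expect_true(any(grepl("B\\|C", attr(res, "skipped"))))
})

test_that("group feedback tests report t and signed-rank results per class", {
  set.seed(2)
  res <- data.frame(I = rnorm(40, 0.8, 1),
                    pair_class = rep(c("early-early", "early-late"), 20))
  out <- group_feedback_tests(res)
  expect_setequal(out$group, c("overall", "early-early", "early-late"))
  ov <- out[out$group == "overall", ]
  tt <- t.test(res$I)
  expect_equal(ov$t, unname(tt$statistic))
  expect_equal(ov$p_mean, tt$p.value)
  expect_equal(ov$p_median, wilcox.test(res$I)$p.value)
  # constant coefficients: degenerate, not an error
  const <- data.frame(I = rep(1, 5), pair_class = "early-early")
  outc <- group_feedback_tests(const)
  expect_true(all(outc$degenerate))
  expect_equal(outc$mean[1], 1)
})

test_that("group tests have power against a shifted distribution and not against a null", {
  set.seed(3)
  rej_null <- rej_shift <- logical(60)
  for (i in 1:60) {
    null_p <- group_feedback_tests(
      data.frame(I = rnorm(40, 0, 1), pair_class = "x"),
      grouping = NULL)$p_mean
    shift_p <- group_feedback_tests(
      data.frame(I = rnorm(40, 0.5, 1), pair_class = "x"),
      grouping = NULL)$p_mean
    rej_null[i] <- null_p < 0.05
    rej_shift[i] <- shift_p < 0.05
  }
  expect_lt(mean(rej_null), 0.2)
  expect_gt(mean(rej_shift), 0.5)
})

test_that("type III ANOVA matches the balanced-design identity and an additive oracle", {
  set.seed(4)
  d <- expand.grid(lh_host = c("early", "late"),
                   lh_train = c("early", "late"), rep = 1:10)
  # purely additive effects: interaction SS near zero
  d$I <- 1 + (d$lh_host == "late") * 2 + (d$lh_train == "late") * -1 +
    rnorm(40, 0, 0.3)
  out <- anova_lifehistory(d)
  expect_lt(out$F[out$term == "lh_host:lh_train"],
            out$F[out$term == "lh_host"] / 10)
  expect_lt(out$p[out$term == "lh_host"], 1e-6)
  # on balanced data type III equals sequential SS
  seq_ss <- anova(lm(I ~ lh_host * lh_train, data = d))$`Sum Sq`
  expect_equal(out$SS[1:3], seq_ss[1:3], tolerance = 1e-8)
})

test_that("feedback vs phylogenetic distance recovers constructed curvature", {
  set.seed(5)
  hits <- aic_hits <- logical(20)
  for (i in 1:20) {
    d <- runif(40, 0, 2)
    I <- -(d - mean(d))^2 + rnorm(40, 0, 0.2)
    res <- data.frame(I = I, patristic_distance = d)
    fit <- feedback_vs_phylodistance(res)
    qcoef <- fit$quadratic[fit$quadratic$term == "I(patristic_distance^2)", ]
    hits[i] <- qcoef$estimate < 0 && qcoef$p < 0.05
    aic_hits[i] <- fit$aic[["quadratic"]] < fit$aic[["linear"]]
  }
  expect_gt(mean(hits), 0.5)
  expect_gt(mean(aic_hits), 0.5)
})

test_that("duplicating every pair leaves OLS point estimates unchanged", {
  set.seed(6)
  res <- data.frame(I = rnorm(20), patristic_distance = runif(20, 0, 2))
  f1 <- feedback_vs_phylodistance(res)
  f2 <- feedback_vs_phylodistance(rbind(res, res))
  expect_equal(f2$linear$estimate, f1$linear$estimate, tolerance = 1e-10)
  expect_equal(f2$quadratic$estimate, f1$quadratic$estimate,
               tolerance = 1e-10)
  expect_lt(f2$linear$se[2], f1$linear$se[2])
  expect_error(feedback_vs_phylodistance(res[1:4, ]), "at least 5")
})

test_that("dissimilarity regressions guard degenerate predictors and constant responses", {
  set.seed(7)
  res <- data.frame(I = rnorm(30),
                    dissim_species = runif(30),
                    dissim_genetic_f1 = rep(0.4, 30))
  out <- suppressMessages(feedback_vs_dissimilarity(res))
  expect_true(is.na(out$p[out$predictor == "dissim_genetic_f1"]))
  expect_false(is.na(out$p[out$predictor == "dissim_species"]))
  # constant response: R2 exactly zero
  res2 <- data.frame(I = rep(1, 30), dissim_species = runif(30))
  out2 <- feedback_vs_dissimilarity(res2)
  expect_equal(out2$r_squared, 0)
  expect_true(all(out$p_holm >= out$p, na.rm = TRUE))
})

test_that("the predicted-feedback correlation behaves like weighted least squares", {
  acc <- cbind(g1 = c(1, 2, 3, 4, 5, 6, 7) / 10, base = rep(0.2, 7))
  rownames(acc) <- paste0("f", 1:7)
  x <- acc[, "g1"] - acc[, "base"]
  mm <- data.frame(fungus = rep(paste0("f", 1:7), 2),
                   group = rep(c("g1", "base"), each = 7),
                   emmean = c(x + 0.1, rep(0.1, 7)))
  w <- setNames(rep(1, 7), paste0("f", 1:7))
  # y-difference equals x exactly: perfect positive fit
  out <- suppressWarnings(
    predicted_feedback_correlation(mm, acc, w, "g1", "base"))
  expect_equal(out$r_squared, 1, tolerance = 1e-10)
  expect_gt(out$slope, 0)
  # equal weights reduce to ordinary least squares
  set.seed(8)
  mm$emmean[1:7] <- x + rnorm(7, 0, 0.3)
  out2 <- predicted_feedback_correlation(mm, acc, w, "g1", "base")
  y <- mm$emmean[1:7] - mm$emmean[8:14]
  ols <- summary(lm(y ~ x))
  expect_equal(out2$slope, unname(ols$coefficients[2, 1]),
               tolerance = 1e-10)
  expect_equal(out2$r_squared, ols$r.squared, tolerance = 1e-10)
  expect_error(predicted_feedback_correlation(mm[1:3, ], acc, w, "g1",
                                              "base"),
               "at least 3")
})

test_that("conditioned-community dissimilarities attach to the right pairs", {
  gen <- generate_full_dataset(small_sim_config(), tempfile("fbdis"),
                               seed = 31)
  ds <- load_dataset(gen$paths, verbose = FALSE)
  hosts <- gen$hosts
  res <- pairwise_interactions(ds$feedback, hosts = hosts, tree = ds$tree)
  res <- feedback_dissimilarities(res, ds$asv, ds$meta, year = 2)
  expect_true(all(is.finite(res$dissim_species)))
  expect_true(all(res$dissim_species >= 0))
  # pair annotations agree with the host table
  lh <- setNames(hosts$life_history, hosts$species)
  expect_equal(res$pair_class,
               paste(pmin(lh[res$species_A], lh[res$species_B]),
                     pmax(lh[res$species_A], lh[res$species_B]), sep = "-"),
               ignore_attr = TRUE)
  # patristic distances symmetric lookup
  pd <- patristic_distances(ds$tree)
  expect_equal(res$patristic_distance,
               pd[cbind(res$species_A, res$species_B)])
})
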