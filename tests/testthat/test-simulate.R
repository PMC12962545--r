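test_that("simulated trees are ultrametric, unit depth, and seed-stable", {
  cherry <- simulate_tree(2, seed = 5)
  expect_equal(patristic_distances(cherry)[1, 2], 2)
  t1 <- simulate_tree(38, seed = 9)
  t2 <- simulate_tree(38, seed = 9)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  C <- phylo_covariance(simulate_tree(50, seed = 2), scale = FALSE)
  expect_equal(unname(diag(C)), rep(1, 50), tolerance = 1e-8)
  expect_error(simulate_tree(1), "at least 2")
})

test_that("host trait assignment is balanced and covers the group vocabulary", {
  tr <- simulate_tree(38, seed = 3)
  hosts <- assign_host_traits(tr, seed = 4)
  expect_equal(sort(unique(hosts$life_history)), c("early", "late"))
  expect_equal(unname(table(hosts$life_history)), c(19L, 19L),
               ignore_attr = TRUE)
  expect_true(all(hosts$phylo_group %in%
                    c("lilies", "grasses", "legumes", "milkweeds", "mints",
                      "asters")))
  expect_equal(hosts$species, tr$tip.label)
})

test_that("host effects reduce to constants when all variances vanish", {
  tr <- simulate_tree(8, seed = 1)
  hosts <- assign_host_traits(tr, seed = 1)
  cfg <- sim_config(n_host_species = 8, sigma2_phylo = 0,
                    sigma2_species = 0,
                    beta_life_history = rep(0, 7))
  E <- simulate_host_effects(tr, hosts, cfg, seed = 2)
  for (f in seq_len(ncol(E)))
    expect_equal(unname(E[, f]), rep(cfg$baseline_log_fitness[f], 8))
})

test_that("Brownian host effects reproduce the tree covariance", {
  tr <- simulate_tree(10, seed = 11)
  hosts <- assign_host_traits(tr, seed = 11)
  C <- phylo_covariance(tr)
  cfg <- sim_config(n_host_species = 10, sigma2_phylo = 1,
                    sigma2_species = 0, beta_life_history = rep(0, 7),
                    baseline_log_fitness = rep(0, 7))
  draws <- sapply(1:500, function(i)
    simulate_host_effects(tr, hosts, cfg, seed = i)[, 1])
  emp <- cov(t(draws))
  # each entry within 3 Monte-Carlo SEs; for Gaussian products
  # var(x_i x_j) <= C_ii C_jj + C_ij^2 <= 2
  mc_se <- sqrt(2 / 500)
  expect_lt(max(abs(emp - C)), 3.5 * mc_se)
})

test_that("life-history effect shifts the designated fungus by its beta", {
  tr <- simulate_tree(12, seed = 21)
  hosts <- assign_host_traits(tr, seed = 21)
  cfg <- sim_config(n_host_species = 12, sigma2_phylo = 0,
                    sigma2_species = 0.2,
                    beta_life_history = c(1, rep(0, 6)),
                    baseline_log_fitness = rep(0, 7))
  late <- hosts$life_history == "late"
  diffs <- sapply(1:300, function(i) {
    E <- simulate_host_effects(tr, hosts, cfg, seed = i)
    c(mean(E[late, 1]) - mean(E[!late, 1]),
      mean(E[late, 2]) - mean(E[!late, 2]))
  })
  se1 <- sd(diffs[1, ]) / sqrt(300)
  expect_equal(mean(diffs[1, ]), 1, tolerance = 3 * se1 + 1e-8)
  expect_equal(mean(diffs[2, ]), 0, tolerance = 3 * sd(diffs[2, ]) /
                 sqrt(300) + 1e-8)
})

test_that("mycobiome counts follow the softmax of the latent effects", {
  tr <- simulate_tree(2, seed = 31)
  hosts <- assign_host_traits(tr, seed = 31)
  # near-multinomial limit: huge concentration, no legacy reads
  cfg <- sim_config(n_host_species = 2, dirichlet_concentration = 1e7,
                    unassigned_rate = 0, block_sd = 0, year_sd = 0,
                    n_blocks = 100, years = 1,
                    sigma2_phylo = 0, sigma2_species = 0,
                    beta_life_history = rep(0, 7),
                    baseline_log_fitness = rep(0, 7))
  E <- simulate_host_effects(tr, hosts, cfg, seed = 1)
  myco <- simulate_mycobiome_counts(E, hosts, cfg, seed = 2)
  sp <- aggregate_to_species(myco$asv)
  props <- sp$counts / rowSums(sp$counts)
  # equal latent effects: every species near 1/7
  expect_equal(unname(colMeans(props)), rep(1 / 7, 7), tolerance = 0.01)

  # non-equal effects: empirical proportions track softmax(E)
  cfg2 <- sim_config(n_host_species = 2, dirichlet_concentration = 1e7,
                     unassigned_rate = 0, block_sd = 0, year_sd = 0,
                     n_blocks = 100, years = 1, sigma2_phylo = 0.5,
                     sigma2_species = 0.25)
  E2 <- simulate_host_effects(tr, hosts, cfg2, seed = 3)
  myco2 <- simulate_mycobiome_counts(E2, hosts, cfg2, seed = 4)
  sp2 <- aggregate_to_species(myco2$asv)
  for (h in hosts$species) {
    sel <- myco2$meta$host_species == h
    p_emp <- colMeans(sp2$counts[sel, ] / rowSums(sp2$counts[sel, ]))
    p_true <- exp(E2[h, ]) / sum(exp(E2[h, ]))
    expect_equal(unname(p_emp), unname(p_true), tolerance = 0.02)
  }
  # no legacy reads: density proxy is exactly 1 everywhere
  expect_true(all(density_proxy(myco$asv)$proportion == 1))
})

test_that("feedback biomass inverts the interaction coefficient", {
  pairs <- data.frame(species_A = "A", species_B = "B",
                      design_block = "fb1", I_target = 2)
  cfg <- sim_config(biomass_noise_sd = 0, feedback_reps = 2)
  fb <- simulate_feedback_biomass(pairs, cfg, seed = 1)
  cell <- function(h, s) mean(fb$biomass[fb$host_species == h &
                                           fb$training_species == s])
  expect_equal(c(cell("A", "A"), cell("A", "B"), cell("B", "A"),
                 cell("B", "B")), c(10, 9, 9, 10))
  expect_equal(interaction_coefficient(cell("A", "A"), cell("A", "B"),
                                       cell("B", "A"), cell("B", "B")), 2)
  # zero target, zero noise: I exactly zero
  pairs0 <- data.frame(species_A = "A", species_B = "B",
                       design_block = "fb1", I_target = 0)
  fb0 <- simulate_feedback_biomass(pairs0, cfg, seed = 1)
  res0 <- pairwise_interactions(fb0)
  expect_equal(res0$I, 0)
  # infeasible target refused
  expect_error(simulate_feedback_biomass(
    data.frame(species_A = "A", species_B = "B", design_block = "fb1",
               I_target = 25), cfg), "infeasible")
})

test_that("the interaction-coefficient estimator is unbiased under noise", {
  pairs <- data.frame(species_A = "A", species_B = "B",
                      design_block = "fb1", I_target = 1.5)
  cfg <- sim_config(biomass_noise_sd = 0.5, feedback_reps = 4)
  est <- vapply(1:400, function(i)
    pairwise_interactions(simulate_feedback_biomass(pairs, cfg,
                                                    seed = i))$I, 0)
  mc_se <- sd(est) / sqrt(400)
  expect_equal(mean(est), 1.5, tolerance = 3 * mc_se)
  # analytic se: sd * sqrt(4/4) = 0.5; empirical spread within 10%
  expect_equal(sd(est), 0.5, tolerance = 0.05)
})

test_that("growth assays reproduce their prescribed effect sizes", {
  tr <- simulate_tree(4, seed = 41)
  hosts <- assign_host_traits(tr, seed = 41)
  cfg <- sim_config(n_host_species = 4, n_studies = 1, hosts_per_study = 4,
                    assay_n = 8, assay_sd = 1e-8)
  lrr0 <- matrix(0, 7, 4, dimnames = list(cfg$fungal_species, hosts$species))
  a0 <- compute_lrr(simulate_growth_assays(lrr0, hosts, cfg, seed = 1))
  expect_equal(a0$lrr[a0$fungal_isolate != "mixture"],
               rep(0, sum(a0$fungal_isolate != "mixture")),
               tolerance = 1e-6)
  # Monte-Carlo mean of the estimator around the true value
  cfg2 <- sim_config(n_host_species = 4, n_studies = 1, hosts_per_study = 1,
                     assay_n = 8, assay_sd = 0.4, assay_baseline = 2)
  lrr7 <- matrix(0.7, 7, 4, dimnames = dimnames(lrr0))
  ests <- vapply(1:300, function(i) {
    a <- compute_lrr(simulate_growth_assays(lrr7, hosts, cfg2, seed = i))
    mean(a$lrr[a$fungal_isolate != "mixture"])
  }, 0)
  expect_equal(mean(ests), 0.7, tolerance = 3 * sd(ests) / sqrt(300))
})

test_that("generate_full_dataset yields a loadable, clean, reproducible study", {
  d1 <- file.path(tempdir(), "gen1"); d2 <- file.path(tempdir(), "gen2")
  cfg <- small_sim_config()
  g1 <- generate_full_dataset(cfg, d1, seed = 77)
  g2 <- generate_full_dataset(cfg, d2, seed = 77)
  for (nm in names(g1$paths))
    expect_identical(readLines(g1$paths[[nm]]), readLines(g2$paths[[nm]]),
                     label = nm)
  ds <- load_dataset(g1$paths, verbose = FALSE)
  rep <- validate_dataset(ds)
  expect_true(rep$is_clean)
  # ground truth records the generating parameters and per-pair targets
  gt <- read.delim(g1$paths[["ground_truth"]], comment.char = "#")
  expect_true(all(c("sigma2_phylo", "sigma2_species") %in% gt$parameter))
  expect_equal(sum(startsWith(gt$parameter, "I_target.")), nrow(g1$pairs))
  expect_equal(gt$value[gt$parameter == "sigma2_phylo"], cfg$sigma2_phylo)
})
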