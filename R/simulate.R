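# Synthetic-data generator emulating the study design: 38 host species on
# an ultrametric tree, 7 inoculated fungal species carrying 2-15 ASVs each,
# phylogenetically autocorrelated host effects on fungal log relative
# fitness, life-history effects, greenhouse blocks, two years of
# overdispersed sequencing counts, a fully factorial feedback assay with
# prescribed interaction coefficients, and growth-assay summary tables.

# Default inoculated species, in the order their per-species ASV richness
# is listed (2, 4, 8, 12, 9, 4, 15).
.default_fungi <- c(
  "Claroideoglomus_lamellosum", "Claroideoglomus_claroideum",
  "Entrophospora_infrequens", "Funneliformis_mosseae",
  "Racocetra_fulgida", "Cetraspora_pellucida", "Acaulospora_spinosa"
)

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator with defaults that
#' reproduce the study design: 38 host species, 7 fungal species with
#' (2, 4, 8, 12, 9, 4, 15) ASVs, 4 greenhouse blocks, 2 years, 5 factorial
#' feedback subsets, 3 prior growth-assay studies.
#'
#' @param n_host_species number of host plant species (tree tips).
#' @param fungal_species character vector of inoculated species names.
#' @param asvs_per_species integer vector, ASVs per fungal species.
#' @param sigma2_phylo Brownian (phylogenetic) variance of host effects on
#'   fungal log relative fitness.
#' @param sigma2_species i.i.d. host-species effect variance.
#' @param beta_life_history per-fungus additive effect of a late-
#'   successional host on log relative fitness.
#' @param baseline_log_fitness per-fungus baseline log relative fitness
#'   (sets mean relative abundances).
#' @param n_blocks greenhouse blocks (= replicate mesocosms per species).
#' @param years number of growing seasons.
#' @param block_sd,year_sd SDs of block-by-fungus and year-by-fungus
#'   log-fitness effects.
#' @param depth_meanlog,depth_sdlog,depth_min log-normal sequencing-depth
#'   parameters and floor.
#' @param dirichlet_concentration overdispersion of species counts
#'   (multinomial limit as it grows).
#' @param unassigned_rate expected fraction of legacy (unassigned) reads.
#' @param n_unassigned_asvs number of legacy ASV columns.
#' @param genetic_concentration Dirichlet concentration of within-species
#'   ASV profiles around the host-specific profile.
#' @param genetic_responsive indices of fungi whose within-species ASV
#'   profile shifts between host life-history groups.
#' @param genetic_shift log-scale magnitude of that shift.
#' @param feedback_blocks number of fully factorial feedback subsets.
#' @param feedback_reps replicates per host-by-soil cell.
#' @param biomass_base,biomass_noise_sd,biomass_floor feedback biomass mean,
#'   replicate SD, and positivity floor (grams).
#' @param feedback_rule list describing how pairwise targets I are drawn:
#'   `type = "dissimilarity"` (I = intercept + slope * genetic
#'   dissimilarity of fungus `fungus`, plus Normal(0, sd) noise) or
#'   `type = "fixed"` with a `targets` data.frame
#'   (species_A, species_B, I_target).
#' @param n_studies,hosts_per_study,assay_n,assay_baseline,assay_sd
#'   growth-assay design: number of prior studies, host species sampled per
#'   study, replicates per treatment group, control biomass baseline and
#'   within-group SD.
#' @param lrr_base,lrr_late per-fungus true log response ratio at baseline
#'   and its additive shift for late-successional hosts.
#' @param diversity_effect additive true LRR of the mixture inoculum over
#'   the per-host mean single-isolate LRR.
#' @param pseudocount default CLR pseudocount carried into analyses.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(
    n_host_species = 38,
    fungal_species = .default_fungi,
    asvs_per_species = c(2, 4, 8, 12, 9, 4, 15),
    sigma2_phylo = 1.0,
    sigma2_species = 0.25,
    beta_life_history = c(0, 0.5, 0, 0.5, 0.5, 0, 0),
    baseline_log_fitness = c(1.0, 0, 1.5, 0, 0, 0, -1.5),
    n_blocks = 4,
    years = 2,
    block_sd = 0.25,
    year_sd = 0.25,
    depth_meanlog = 9,
    depth_sdlog = 0.4,
    depth_min = 500,
    dirichlet_concentration = 50,
    unassigned_rate = 0.2,
    n_unassigned_asvs = 5,
    genetic_concentration = 100,
    genetic_responsive = c(3, 1),
    genetic_shift = 1.5,
    feedback_blocks = 5,
    feedback_reps = 4,
    biomass_base = 10,
    biomass_noise_sd = 0.5,
    biomass_floor = 0.05,
    feedback_rule = list(type = "dissimilarity", fungus = 3,
                         intercept = 0.3, slope = 0.8, sd = 0.3),
    n_studies = 3,
    hosts_per_study = 12,
    assay_n = 8,
    assay_baseline = 2,
    assay_sd = 0.4,
    lrr_base = rep(0.3, 7),
    lrr_late = c(0.5, 0.2, 0.5, 0.2, 0, 0, 0),
    diversity_effect = 0,
    pseudocount = 1) {
  cfg <- as.list(environment())
  k <- length(cfg$fungal_species)
  if (length(cfg$asvs_per_species) != k)
    stop_mf("asvs_per_species must have one entry per fungal species")
  for (nm in c("beta_life_history", "baseline_log_fitness", "lrr_base",
               "lrr_late"))
    if (length(cfg[[nm]]) != k)
      stop_mf("%s must have one entry per fungal species", nm)
  if (cfg$sigma2_phylo < 0 || cfg$sigma2_species < 0)
    stop_mf("variances must be >= 0")
  if (cfg$dirichlet_concentration <= 0)
    stop_mf("dirichlet_concentration must be > 0")
  if (cfg$unassigned_rate < 0 || cfg$unassigned_rate >= 1)
    stop_mf("unassigned_rate must be in [0, 1)")
  if (cfg$n_host_species < 2) stop_mf("need at least 2 host species")
  structure(cfg, class = "sim_config")
}

#' Simulate a host phylogeny
#'
#' Pure-birth (Yule) ultrametric tree rescaled to unit root-to-tip depth,
#' tips labeled `sp01..spNN`.  Unit depth makes the Brownian variance of
#' simulated host effects comparable across runs.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed.
#' @return An [ape::phylo] object.
#' @export
simulate_tree <- function(n_tips, seed = 1) {
  if (n_tips < 2) stop_mf("need at least 2 tips")
  set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr)[seq_len(n_tips)])
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  tr
}

#' Assign life history and phylogenetic group to hosts
#'
#' Life history (`early`/`late`) is a balanced random assignment;
#' phylogenetic groups are six clusters of the patristic distance matrix
#' (average linkage), labeled with the study's group vocabulary so the
#' clusters are phylogenetically coherent.
#'
#' @param tree an [ape::phylo].
#' @param seed integer seed.
#' @param groups group labels to assign (6 by default).
#' @return A data.frame with `species`, `life_history`, `phylo_group`.
#' @export
assign_host_traits <- function(tree, seed = 1,
                               groups = c("lilies", "grasses", "legumes",
                                          "milkweeds", "mints", "asters")) {
  set.seed(seed)
  n <- length(tree$tip.label)
  lh <- sample(rep(c("early", "late"), length.out = n))
  k <- min(length(groups), n)
  cl <- stats::cutree(stats::hclust(stats::as.dist(patristic_distances(tree)),
                                    method = "average"), k = k)
  data.frame(
    species = tree$tip.label,
    life_history = lh,
    phylo_group = groups[cl[tree$tip.label]],
    stringsAsFactors = FALSE
  )
}

#' Simulate latent host effects on fungal log relative fitness
#'
#' `E[h, f] = b_f + beta_f * late_h + u_f[h] + e_f[h]` with
#' `u_f ~ N(0, sigma2_phylo * C)` (Brownian motion on the tree) and
#' `e_f ~ N(0, sigma2_species * I)`.
#'
#' @param tree host phylogeny.
#' @param hosts host trait table from [assign_host_traits()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A hosts-by-fungi matrix of log relative fitness.
#' @export
simulate_host_effects <- function(tree, hosts, config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  C <- phylo_covariance(tree)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop_mf("phylogenetic covariance is not PSD")
  L <- t(chol(C + diag(1e-10, nrow(C))))
  set.seed(seed)
  n <- nrow(C); k <- length(config$fungal_species)
  late <- as.numeric(hosts$life_history[match(rownames(C),
                                              hosts$species)] == "late")
  E <- matrix(0, n, k, dimnames = list(rownames(C), config$fungal_species))
  for (f in seq_len(k)) {
    u <- sqrt(config$sigma2_phylo) * drop(L %*% rnorm(n))
    e <- rnorm(n, sd = sqrt(config$sigma2_species))
    E[, f] <- config$baseline_log_fitness[f] +
      config$beta_life_history[f] * late + u + e
  }
  E
}

# Within-species base ASV profile: geometrically decreasing abundances.
.asv_base_profile <- function(k) softmax(-0.5 * (seq_len(k) - 1))

#' Simulate the mycobiome observation layer
#'
#' One sample per host-by-block-by-year cell: sequencing depth is
#' log-normal; fungal-species proportions are the softmax of the latent
#' host effects plus block-by-fungus and (year 2 only) year-by-fungus
#' effects, scaled by `1 - unassigned_rate`; species counts are
#' Dirichlet-multinomial; each species' count is then split into its ASVs
#' by a host-dependent within-species profile.  For the designated
#' "genetically responsive" fungi the within-species profile shifts between
#' early and late successional hosts, so that within-species (genetic)
#' dissimilarity carries signal.
#'
#' @param E latent host-by-fungus effect matrix.
#' @param hosts host trait table.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A list with `asv` ([asv_table()]) and `meta` (sample metadata).
#' @export
simulate_mycobiome_counts <- function(E, hosts, config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  fungi <- config$fungal_species
  k <- length(fungi)
  asv_ids <- unlist(lapply(seq_len(k), function(f)
    sprintf("%s_asv%02d", fungi[f], seq_len(config$asvs_per_species[f]))))
  taxonomy <- setNames(rep(fungi, config$asvs_per_species), asv_ids)
  if (config$unassigned_rate > 0) {
    legacy <- sprintf("legacy_asv%02d", seq_len(config$n_unassigned_asvs))
    taxonomy <- c(taxonomy, setNames(rep("unassigned", length(legacy)),
                                     legacy))
    asv_ids <- c(asv_ids, legacy)
  }
  legacy_profile <- .asv_base_profile(config$n_unassigned_asvs)

  block_eff <- matrix(rnorm(config$n_blocks * k, sd = config$block_sd),
                      config$n_blocks, k)
  year_eff <- rbind(rep(0, k),
                    if (config$years > 1)
                      matrix(rnorm((config$years - 1) * k,
                                   sd = config$year_sd),
                             config$years - 1, k))

  base_profiles <- lapply(config$asvs_per_species, .asv_base_profile)
  shift_dir <- lapply(config$asvs_per_species, function(m)
    if (m > 1) seq(-1, 1, length.out = m) else 0)

  n_samp <- nrow(E) * config$n_blocks * config$years
  counts <- matrix(0L, n_samp, length(asv_ids),
                   dimnames = list(NULL, asv_ids))
  meta <- vector("list", n_samp)
  s <- 0L
  for (y in seq_len(config$years)) for (b in seq_len(config$n_blocks))
    for (h in seq_len(nrow(E))) {
      s <- s + 1L
      host <- rownames(E)[h]
      lh <- hosts$life_history[hosts$species == host]
      depth <- max(config$depth_min,
                   round(rlnorm(1, config$depth_meanlog, config$depth_sdlog)))
      p_sp <- softmax(E[h, ] + block_eff[b, ] + year_eff[y, ]) *
        (1 - config$unassigned_rate)
      p_all <- c(p_sp, unassigned = config$unassigned_rate)
      g <- rgamma(length(p_all), shape = config$dirichlet_concentration *
                    p_all)
      if (sum(g) <= 0) g <- p_all
      sp_counts <- drop(rmultinom(1, depth, g / sum(g)))
      names(sp_counts) <- names(p_all)
      row <- integer(length(asv_ids))
      names(row) <- asv_ids
      for (f in seq_len(k)) {
        cf <- sp_counts[f]
        if (cf == 0) next
        m <- config$asvs_per_species[f]
        if (m == 1) {
          row[names(taxonomy)[taxonomy == fungi[f]]] <- cf
          next
        }
        sgn <- if (f %in% config$genetic_responsive)
          (if (lh == "late") 0.5 else -0.5) * config$genetic_shift else 0
        prof <- softmax(log(base_profiles[[f]]) + sgn * shift_dir[[f]])
        q <- rgamma(m, shape = config$genetic_concentration * prof)
        if (sum(q) <= 0) q <- prof
        row[sprintf("%s_asv%02d", fungi[f], seq_len(m))] <-
          drop(rmultinom(1, cf, q / sum(q)))
      }
      if (config$unassigned_rate > 0 && sp_counts[["unassigned"]] > 0)
        row[sprintf("legacy_asv%02d", seq_len(config$n_unassigned_asvs))] <-
          drop(rmultinom(1, sp_counts[["unassigned"]], legacy_profile))
      counts[s, ] <- row
      meta[[s]] <- data.frame(
        sample_id = sprintf("%s_b%d_y%d", host, b, y),
        host_species = host,
        life_history = lh,
        phylo_group = hosts$phylo_group[hosts$species == host],
        block = sprintf("b%d", b),
        year = y, replicate = b,
        stringsAsFactors = FALSE
      )
    }
  meta <- do.call(rbind, meta)
  rownames(counts) <- meta$sample_id
  list(asv = asv_table(counts, taxonomy), meta = meta)
}

#' Default fully factorial feedback pairing
#'
#' Partitions the host species into factorial subsets ("design blocks"),
#' balancing early and late successional species across subsets; every
#' within-subset species pair is a feedback pair.  With 38 species in
#' subsets of sizes 8, 8, 8, 7, 7 this yields 126 pairs.
#'
#' @param hosts host trait table.
#' @param n_design_blocks number of factorial subsets.
#' @param seed integer seed.
#' @return A data.frame with `species_A`, `species_B`, `design_block`.
#' @export
default_feedback_pairs <- function(hosts, n_design_blocks = 5, seed = 1) {
  set.seed(seed)
  # interleave shuffled early and late species, then deal them round-robin:
  # subset sizes differ by at most one and life histories stay balanced
  # (38 species in 5 subsets -> sizes 8, 8, 8, 7, 7 -> 126 pairs)
  by_lh <- split(seq_len(nrow(hosts)), hosts$life_history)
  by_lh <- lapply(by_lh, sample)
  ord <- integer(0)
  while (any(lengths(by_lh) > 0)) {
    for (l in names(by_lh)) {
      if (length(by_lh[[l]])) {
        ord <- c(ord, by_lh[[l]][1])
        by_lh[[l]] <- by_lh[[l]][-1]
      }
    }
  }
  grp <- integer(nrow(hosts))
  grp[ord] <- rep_len(seq_len(n_design_blocks), length(ord))
  rows <- list()
  for (g in seq_len(n_design_blocks)) {
    sp <- sort(hosts$species[grp == g])
    if (length(sp) < 2) next
    for (i in seq_len(length(sp) - 1)) for (j in (i + 1):length(sp))
      rows[[length(rows) + 1L]] <- data.frame(
        species_A = sp[i], species_B = sp[j],
        design_block = sprintf("fb%d", g), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate the feedback biomass table
#'
#' Inverts the interaction-coefficient definition: for each design block,
#' cell means are `mu` on the diagonal (own soil) and `mu - I_AB / 2` for
#' the two off-diagonal host-by-soil cells of pair (A, B) — splitting the
#' prescribed target symmetrically between the two conditioning directions,
#' the minimal assumption since the coefficient constrains only the sum.
#' Replicates add Normal noise, truncated at a small positive floor.
#'
#' @param pairs data.frame with `species_A`, `species_B`, `design_block`,
#'   `I_target`.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A data.frame with `host_species`, `training_species`, `block`,
#'   `replicate`, `biomass`.
#' @export
simulate_feedback_biomass <- function(pairs, config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  mu <- config$biomass_base
  if (any(mu - abs(pairs$I_target) / 2 <= config$biomass_floor))
    stop_mf("infeasible target: need biomass_base - |I|/2 > floor")
  set.seed(seed)
  rows <- list()
  add_cell <- function(host, soil, blk, m) {
    y <- pmax(config$biomass_floor,
              m + rnorm(config$feedback_reps, sd = config$biomass_noise_sd))
    data.frame(host_species = host, training_species = soil, block = blk,
               replicate = seq_len(config$feedback_reps), biomass = y,
               stringsAsFactors = FALSE)
  }
  for (blk in unique(pairs$design_block)) {
    pb <- pairs[pairs$design_block == blk, ]
    sp <- sort(unique(c(pb$species_A, pb$species_B)))
    for (a in sp)
      rows[[length(rows) + 1L]] <- add_cell(a, a, blk, mu)
    for (r in seq_len(nrow(pb))) {
      off <- mu - pb$I_target[r] / 2
      rows[[length(rows) + 1L]] <-
        add_cell(pb$species_A[r], pb$species_B[r], blk, off)
      rows[[length(rows) + 1L]] <-
        add_cell(pb$species_B[r], pb$species_A[r], blk, off)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate growth-assay summary records
#'
#' For each of `n_studies` prior studies, a subset of host species is grown
#' with each fungal isolate and with a sterile control; control replicates
#' are Normal around the study baseline and inoculated replicates around
#' `baseline * exp(true LRR)`.  Per-record summary statistics (means, SDs,
#' n) are returned, plus one `"mixture"` record per (study, host) whose
#' true LRR is the host's mean single-isolate LRR plus `diversity_effect`.
#'
#' @param true_lrr fungus-by-host matrix of true log response ratios.
#' @param hosts host trait table.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A growth-assay data.frame (see [compute_lrr()] for columns).
#' @export
simulate_growth_assays <- function(true_lrr, hosts, config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  fungi <- rownames(true_lrr)
  rows <- list()
  for (s in seq_len(config$n_studies)) {
    hs <- sort(sample(colnames(true_lrr),
                      min(config$hosts_per_study, ncol(true_lrr))))
    for (h in hs) {
      info <- hosts[hosts$species == h, ]
      lrrs <- c(setNames(true_lrr[, h], fungi),
                mixture = mean(true_lrr[, h]) + config$diversity_effect)
      ctrl <- rnorm(config$assay_n, config$assay_baseline, config$assay_sd)
      ctrl <- pmax(ctrl, 0.01)
      for (iso in names(lrrs)) {
        inoc <- rnorm(config$assay_n,
                      config$assay_baseline * exp(lrrs[[iso]]),
                      config$assay_sd)
        inoc <- pmax(inoc, 0.01)
        rows[[length(rows) + 1L]] <- data.frame(
          study_id = sprintf("study%d", s), host_species = h,
          life_history = info$life_history, phylo_group = info$phylo_group,
          fungal_isolate = iso,
          mean_inoc = mean(inoc), sd_inoc = sd(inoc), n_inoc = config$assay_n,
          mean_ctrl = mean(ctrl), sd_ctrl = sd(ctrl), n_ctrl = config$assay_n,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Mean cross-sample genetic dissimilarity of one fungus for each pair,
# from the year-2 samples (the feedback inocula).
.pair_genetic_dissim <- function(pairs, asv, meta, fungus, year,
                                 pseudocount) {
  sel <- meta$year == year
  sub <- asv_table(asv$counts[sel, , drop = FALSE], asv$taxonomy)
  gd <- genetic_dissimilarity(sub, fungus, pseudocount)
  hm <- setNames(canon_species(
    meta$host_species[sel][match(rownames(gd$distance),
                                 meta$sample_id[sel])]),
    rownames(gd$distance))
  vapply(seq_len(nrow(pairs)), function(i) {
    sa <- names(hm)[hm == canon_species(pairs$species_A[i])]
    sb <- names(hm)[hm == canon_species(pairs$species_B[i])]
    if (!length(sa) || !length(sb)) return(NA_real_)
    mean(gd$distance[sa, sb, drop = FALSE])
  }, 0)
}

#' Generate a complete synthetic dataset on disk
#'
#' Runs the full generative chain (tree, host traits, latent effects,
#' mycobiome counts for every host-block-year cell, factorial feedback
#' biomass with targets drawn from the configured rule, growth-assay
#' summaries) and writes the input files the pipeline loads —
#' `counts.tsv`, `taxonomy.tsv`, `metadata.tsv`, `tree.nwk`,
#' `feedback.tsv`, `assays.tsv` — plus `ground_truth.tsv` recording the
#' generating parameters and per-pair targets for recovery tests.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param seed master seed; all stages derive their streams from it.
#' @return Invisibly, a list with the in-memory objects (`tree`, `hosts`,
#'   `E`, `asv`, `meta`, `pairs`, `feedback`, `assays`, `paths`).
#' @export
generate_full_dataset <- function(config = sim_config(), out_dir, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tree <- simulate_tree(config$n_host_species, stage_seed(seed, 1L))
  hosts <- assign_host_traits(tree, stage_seed(seed, 2L))
  E <- simulate_host_effects(tree, hosts, config, stage_seed(seed, 3L))
  myco <- simulate_mycobiome_counts(E, hosts, config, stage_seed(seed, 4L))

  pairs <- default_feedback_pairs(hosts, config$feedback_blocks,
                                  stage_seed(seed, 5L))
  rule <- config$feedback_rule
  if (identical(rule$type, "fixed")) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    idx <- match(key(pairs$species_A, pairs$species_B),
                 key(rule$targets$species_A, rule$targets$species_B))
    pairs$I_target <- rule$targets$I_target[idx]
    if (any(is.na(pairs$I_target)))
      stop_mf("fixed feedback targets missing for some pairs")
  } else {
    d <- .pair_genetic_dissim(pairs, myco$asv, myco$meta,
                              config$fungal_species[rule$fungus],
                              year = config$years, config$pseudocount)
    d[!is.finite(d)] <- mean(d[is.finite(d)])
    set.seed(stage_seed(seed, 6L))
    pairs$I_target <- rule$intercept + rule$slope * (d - mean(d)) +
      rnorm(nrow(pairs), sd = rule$sd)
    # keep every target feasible under the biomass floor
    lim <- 2 * (config$biomass_base - config$biomass_floor) - 1e-6
    pairs$I_target <- pmin(pmax(pairs$I_target, -lim), lim)
  }
  feedback <- simulate_feedback_biomass(pairs, config, stage_seed(seed, 7L))

  true_lrr <- t(vapply(seq_along(config$fungal_species), function(f)
    config$lrr_base[f] + config$lrr_late[f] *
      (hosts$life_history == "late"),
    numeric(nrow(hosts))))
  dimnames(true_lrr) <- list(config$fungal_species, hosts$species)
  assays <- simulate_growth_assays(true_lrr, hosts, config,
                                   stage_seed(seed, 8L))

  paths <- c(
    counts = file.path(out_dir, "counts.tsv"),
    taxonomy = file.path(out_dir, "taxonomy.tsv"),
    metadata = file.path(out_dir, "metadata.tsv"),
    tree = file.path(out_dir, "tree.nwk"),
    feedback = file.path(out_dir, "feedback.tsv"),
    assays = file.path(out_dir, "assays.tsv"),
    ground_truth = file.path(out_dir, "ground_truth.tsv")
  )
  counts_df <- data.frame(sample_id = rownames(myco$asv$counts),
                          myco$asv$counts, check.names = FALSE,
                          stringsAsFactors = FALSE)
  write_tsv(counts_df, paths[["counts"]], seed = seed)
  write_tsv(data.frame(asv_id = names(myco$asv$taxonomy),
                       species = unname(myco$asv$taxonomy),
                       stringsAsFactors = FALSE),
            paths[["taxonomy"]], seed = seed)
  write_tsv(myco$meta, paths[["metadata"]], seed = seed)
  ape::write.tree(tree, paths[["tree"]])
  write_tsv(feedback, paths[["feedback"]], seed = seed)
  write_tsv(assays, paths[["assays"]], seed = seed)
  gt <- data.frame(
    parameter = c("sigma2_phylo", "sigma2_species",
                  paste0("beta_life_history.", config$fungal_species),
                  paste0("lrr_base.", config$fungal_species),
                  paste0("lrr_late.", config$fungal_species),
                  sprintf("I_target.%s|%s", pairs$species_A,
                          pairs$species_B)),
    value = c(config$sigma2_phylo, config$sigma2_species,
              config$beta_life_history, config$lrr_base, config$lrr_late,
              pairs$I_target),
    stringsAsFactors = FALSE
  )
  write_tsv(gt, paths[["ground_truth"]], seed = seed)
  invisible(list(tree = tree, hosts = hosts, E = E, asv = myco$asv,
                 meta = myco$meta, pairs = pairs, feedback = feedback,
                 assays = assays, true_lrr = true_lrr, paths = paths))
}
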