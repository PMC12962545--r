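# End-to-end pipeline: ties the stages together and writes their result
# tables.  Every randomized step derives its stream from the master seed,
# so a seeded run is reproducible file-for-file.

#' Run the analysis pipeline
#'
#' Executes the requested stages in order.  `"simulate"` writes a synthetic
#' dataset under `out_dir/data` and subsequent stages read it; to analyze
#' an existing dataset, omit `"simulate"` and pass `data_paths`.
#'
#' Stages: `composition` (CLR, Aitchison distances, rarefied Shannon
#' diversity, density proxy), `pglmm` (the phylogenetic mixed-model suite),
#' `permanova` (species-level and per-fungus genetic tests per year),
#' `meta` (log-response-ratio effect sizes, moderated REML meta-models,
#' Wald QM tests, marginal means, diversity-response ratios), `feedback`
#' (pairwise interaction coefficients, group tests, pattern regressions,
#' predicted-feedback correlations).
#'
#' @param out_dir output directory.
#' @param stages character vector of stage names; `"all"` expands to every
#'   stage.
#' @param config analysis settings, see [default_config()].
#' @param sim a [sim_config()] used by the `"simulate"` stage.
#' @param data_paths named paths to existing input files (see
#'   [load_dataset()]); ignored when simulating.
#' @param seed master seed (defaults to `config$seed`).
#' @param verbose print progress.
#' @return Invisibly, a list with `results` (named data.frames), `paths`
#'   (written files), and the loaded `dataset`.
#' @export
run_pipeline <- function(out_dir,
                         stages = "all",
                         config = default_config(),
                         sim = sim_config(),
                         data_paths = NULL,
                         seed = config$seed,
                         verbose = TRUE) {
  all_stages <- c("simulate", "composition", "pglmm", "permanova", "meta",
                  "feedback")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop_mf("unknown stages: %s", paste(bad, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()

  if ("simulate" %in% stages) {
    msg(verbose, "stage simulate")
    gen <- generate_full_dataset(sim, file.path(out_dir, "data"), seed)
    data_paths <- gen$paths
  }
  if (is.null(data_paths)) stop_mf("data_paths required when not simulating")
  dataset <- load_dataset(data_paths, verbose = verbose)
  report <- validate_dataset(dataset)
  if (length(report$hosts_not_on_tree))
    stop_mf("hosts absent from the tree: %s",
            paste(report$hosts_not_on_tree, collapse = ", "))

  asv <- dataset$asv
  meta <- dataset$meta[match(rownames(asv$counts),
                             dataset$meta$sample_id), ]
  sp_tab <- aggregate_to_species(asv)
  fungi <- setdiff(colnames(sp_tab$counts), "unassigned")
  inoc <- sp_tab$counts[, fungi, drop = FALSE]
  years <- sort(unique(meta$year))

  if ("composition" %in% stages) {
    msg(verbose, "stage composition")
    keep <- rowSums(inoc) > 0
    clr <- clr_transform(inoc[keep, , drop = FALSE], config$pseudocount)
    results$clr_species <- data.frame(sample_id = rownames(clr), clr,
                                      check.names = FALSE)
    sh <- shannon_rarefied(inoc, depth = config$rarefaction_depth,
                           n_draws = config$rarefaction_draws,
                           seed = stage_seed(seed, 11L))
    results$diversity <- data.frame(sample_id = names(sh), shannon = sh)
    results$density <- density_proxy(asv)
    for (yr in years) {
      sel <- keep & meta$year == yr
      D <- aitchison_distance(clr[rownames(clr) %in%
                                    meta$sample_id[sel], , drop = FALSE])
      results[[sprintf("aitchison_species_y%d", yr)]] <-
        data.frame(sample_id = rownames(D), D, check.names = FALSE)
    }
  }

  if ("pglmm" %in% stages) {
    msg(verbose, "stage pglmm")
    results$pglmm_results <- run_pglmm_suite(
      dataset,
      include_asv_level = isTRUE(config$include_asv_level),
      rarefaction_depth = config$rarefaction_depth,
      rarefaction_draws = config$rarefaction_draws,
      seed = stage_seed(seed, 21L))
  }

  if ("permanova" %in% stages) {
    msg(verbose, "stage permanova")
    rows_sp <- list(); rows_gen <- list()
    for (yr in years) {
      sel <- meta$year == yr & rowSums(inoc) > 0
      clr_y <- clr_transform(inoc[sel, , drop = FALSE], config$pseudocount)
      D <- aitchison_distance(clr_y)
      fac <- meta[sel, c("life_history", "phylo_group")]
      pr <- permanova(D, fac, n_perm = config$n_perm,
                      seed = stage_seed(seed, 40L + yr))
      pr$year <- yr
      rows_sp[[length(rows_sp) + 1L]] <- as.data.frame(pr)
      sub <- asv_table(asv$counts[sel, , drop = FALSE], asv$taxonomy)
      for (f in fungi) {
        gd <- genetic_dissimilarity(sub, f, config$pseudocount)
        ids <- rownames(gd$distance)
        if (length(ids) < 10 || gd$n_asv < 2) next
        fac_f <- meta[match(ids, meta$sample_id),
                      c("life_history", "phylo_group")]
        pg <- tryCatch(
          permanova(gd$distance, fac_f, n_perm = config$n_perm,
                    seed = stage_seed(seed, 60L + yr)),
          error = function(e) NULL)
        if (is.null(pg)) next
        pg$year <- yr; pg$fungus <- f
        rows_gen[[length(rows_gen) + 1L]] <- as.data.frame(pg)
      }
    }
    results$permanova_species <- do.call(rbind, rows_sp)
    if (length(rows_gen))
      results$permanova_genetic <- do.call(rbind, rows_gen)
  }

  meta_mm_group <- NULL; meta_mm_lh <- NULL
  if ("meta" %in% stages && !is.null(dataset$assays)) {
    msg(verbose, "stage meta")
    singles <- dataset$assays[dataset$assays$fungal_isolate != "mixture", ]
    effects <- compute_lrr(singles)
    results$effects <- effects
    m_full <- fit_meta_reml(effects,
                            ~ fungal_isolate * (life_history + phylo_group))
    m_lh <- fit_meta_reml(effects, ~ fungal_isolate * life_history)
    m_pg <- fit_meta_reml(effects, ~ fungal_isolate * phylo_group)
    results$meta_model <- data.frame(
      coefficient = names(m_full$b), b = m_full$b,
      se = sqrt(diag(m_full$vcov)), row.names = NULL)
    qm <- list(full = wald_qm(m_full), life_history = wald_qm(m_lh),
               phylo_group = wald_qm(m_pg))
    results$qm_tests <- data.frame(
      model = names(qm),
      QM = vapply(qm, `[[`, 0, "QM"),
      df = vapply(qm, `[[`, 0, "df"),
      p = vapply(qm, `[[`, 0, "p"), row.names = NULL)
    results$tau2 <- data.frame(component = names(m_full$tau2),
                               tau2 = unname(m_full$tau2))
    mm_lh <- marginal_means(m_lh, c("fungal_isolate", "life_history"))
    mm_pg <- marginal_means(m_pg, c("fungal_isolate", "phylo_group"))
    names(mm_lh)[1:2] <- c("fungus", "group")
    names(mm_pg)[1:2] <- c("fungus", "group")
    results$marginal_means_lifehistory <- mm_lh
    results$marginal_means_group <- mm_pg
    meta_mm_lh <- mm_lh; meta_mm_group <- mm_pg
    div <- rbind(diversity_lrr(dataset$assays, "vs_mean_single"),
                 diversity_lrr(dataset$assays, "vs_best_single"))
    if (!is.null(div) && nrow(div)) {
      results$diversity_lrr <- div
      dsub <- div[div$mode == "vs_mean_single", ]
      if (length(unique(dsub$life_history)) > 1 && nrow(dsub) >= 4) {
        m_div <- fit_meta_reml(dsub, ~ life_history)
        qd <- wald_qm(m_div)
        results$diversity_lrr_test <- data.frame(
          QM = qd$QM, df = qd$df, p = qd$p)
      }
    }
  }

  if ("feedback" %in% stages && !is.null(dataset$feedback)) {
    msg(verbose, "stage feedback")
    hosts <- unique(meta[, c("host_species", "life_history", "phylo_group")])
    names(hosts)[1] <- "species"
    fb <- pairwise_interactions(dataset$feedback, hosts = hosts,
                                tree = dataset$tree)
    lh_map <- setNames(hosts$life_history, canon_species(hosts$species))
    fb$lh_host <- lh_map[canon_species(fb$species_A)]
    fb$lh_train <- lh_map[canon_species(fb$species_B)]
    fb <- feedback_dissimilarities(fb, asv, meta,
                                   year = config$feedback_year,
                                   pseudocount = config$pseudocount)
    results$interaction_coefficients <- fb
    results$feedback_group_tests <- rbind(
      group_feedback_tests(fb, "pair_class"),
      group_feedback_tests(fb, "family_pair")[-1, ])
    results$feedback_anova <- anova_lifehistory(fb)
    fd <- feedback_vs_phylodistance(fb)
    results$feedback_vs_distance <- rbind(
      cbind(model = "linear", fd$linear, aic = fd$aic[["linear"]]),
      cbind(model = "quadratic", fd$quadratic, aic = fd$aic[["quadratic"]]))
    results$feedback_vs_dissimilarity <- feedback_vs_dissimilarity(fb)

    if (!is.null(meta_mm_group)) {
      pf <- list()
      for (yr in years) {
        acc_pg <- fungal_accumulation(asv, meta, "phylo_group", yr,
                                      pseudocount = config$pseudocount)
        baseline <- if ("grasses" %in% colnames(acc_pg$means)) "grasses"
        else colnames(acc_pg$means)[1]
        for (g in setdiff(colnames(acc_pg$means), baseline)) {
          r <- tryCatch(predicted_feedback_correlation(
            meta_mm_group, acc_pg$means, acc_pg$weights, g, baseline),
            error = function(e) NULL)
          if (!is.null(r))
            pf[[length(pf) + 1L]] <- data.frame(
              year = yr, contrast = sprintf("%s_vs_%s", g, baseline),
              slope = r$slope, r_squared = r$r_squared, p = r$p, n = r$n)
        }
        acc_lh <- fungal_accumulation(asv, meta, "life_history", yr,
                                      pseudocount = config$pseudocount)
        r <- tryCatch(predicted_feedback_correlation(
          meta_mm_lh, acc_lh$means, acc_lh$weights, "late", "early"),
          error = function(e) NULL)
        if (!is.null(r))
          pf[[length(pf) + 1L]] <- data.frame(
            year = yr, contrast = "late_vs_early", slope = r$slope,
            r_squared = r$r_squared, p = r$p, n = r$n)
      }
      if (length(pf)) results$predicted_feedback <- do.call(rbind, pf)
    }
  }

  paths <- write_results(results, out_dir, seed = seed)
  invisible(list(results = results, paths = paths, dataset = dataset,
                 validation = report))
}
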