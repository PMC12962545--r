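# Pairwise plant-soil feedback: interaction coefficients with uncertainty,
# group-level location tests, pattern regressions against phylogenetic
# distance and compositional/genetic dissimilarity, and the
# predicted-feedback weighted correlations tying meta-analytic benefits to
# observed fungal accumulation.

#' Pairwise feedback interaction coefficient
#'
#' `I = F_Aa - F_Ab - F_Ba + F_Bb`, where `F_Xs` is the performance
#' (biomass) of plant X grown in soil conditioned by species s (a = soil of
#' A, b = soil of B).  Positive I means the pair experiences positive
#' feedback.  I is symmetric under exchanging both the species labels and
#' the soils.
#'
#' @param F_Aa,F_Ab,F_Ba,F_Bb cell mean biomasses.
#' @return The interaction coefficient (same units as biomass).
#' @export
interaction_coefficient <- function(F_Aa, F_Ab, F_Ba, F_Bb) {
  stopifnot(is.finite(F_Aa), is.finite(F_Ab), is.finite(F_Ba), is.finite(F_Bb))
  F_Aa - F_Ab - F_Ba + F_Bb
}

#' Pairwise interaction coefficients from a factorial feedback design
#'
#' For every unordered pair of species that has all four host-by-soil cells
#' within a design block, computes the interaction coefficient from the
#' cell means, its standard error from the pooled within-cell variance
#' (`se = s_pooled * sqrt(sum 1/n_cell)`, df = N - 4), the t statistic and
#' two-sided p-value.  Pairs whose pooled variance is zero are flagged
#' `degenerate` (se = 0, p = NA).
#'
#' @param design data.frame with columns `host_species`, `training_species`,
#'   `block`, `replicate`, `biomass` (> 0).
#' @param hosts optional data.frame with `species`, `life_history`,
#'   `phylo_group` used to annotate pairs (pair class early-early /
#'   early-late / late-late and family-pair label).
#' @param tree optional [ape::phylo] used to attach patristic distances.
#' @return A data.frame, one row per estimable pair, with columns
#'   `species_A`, `species_B`, `block`, `I`, `se`, `t`, `df`, `p`,
#'   `degenerate`, and annotations where available.  Non-estimable pairs
#'   (missing cells) are listed in the `skipped` attribute.
#' @export
pairwise_interactions <- function(design, hosts = NULL, tree = NULL) {
  req <- c("host_species", "training_species", "block", "biomass")
  miss <- setdiff(req, names(design))
  if (length(miss)) stop_mf("missing columns: %s", paste(miss, collapse = ", "))
  if (any(design$biomass <= 0)) stop_mf("biomass must be positive")
  pd <- if (!is.null(tree)) patristic_distances(tree)
  lh <- if (!is.null(hosts))
    setNames(as.character(hosts$life_history), canon_species(hosts$species))
  fam <- if (!is.null(hosts) && "phylo_group" %in% names(hosts))
    setNames(as.character(hosts$phylo_group), canon_species(hosts$species))

  rows <- list(); skipped <- character(0)
  for (blk in unique(design$block)) {
    d <- design[design$block == blk, ]
    sp <- sort(unique(c(d$host_species, d$training_species)))
    if (length(sp) < 2) next
    for (i in seq_len(length(sp) - 1)) for (j in (i + 1):length(sp)) {
      A <- sp[i]; B <- sp[j]
      cells <- list(
        Aa = d$biomass[d$host_species == A & d$training_species == A],
        Ab = d$biomass[d$host_species == A & d$training_species == B],
        Ba = d$biomass[d$host_species == B & d$training_species == A],
        Bb = d$biomass[d$host_species == B & d$training_species == B]
      )
      ns <- lengths(cells)
      if (any(ns == 0)) {
        skipped <- c(skipped, sprintf("%s|%s|block=%s (missing %s)", A, B, blk,
                                      paste(names(cells)[ns == 0],
                                            collapse = ",")))
        next
      }
      means <- vapply(cells, mean, 0)
      I <- interaction_coefficient(means["Aa"], means["Ab"],
                                   means["Ba"], means["Bb"])
      N <- sum(ns)
      ss_within <- sum(vapply(cells, function(v) sum((v - mean(v))^2), 0))
      df <- N - 4L
      s2 <- if (df > 0) ss_within / df else NA_real_
      se <- if (df > 0) sqrt(s2 * sum(1 / ns)) else NA_real_
      degen <- is.na(se) || se == 0
      tval <- if (!degen) I / se else NA_real_
      pval <- if (!degen) 2 * pt(-abs(tval), df) else NA_real_
      cA <- canon_species(A); cB <- canon_species(B)
      pair_class <- if (!is.null(lh)) {
        cls <- sort(c(lh[cA], lh[cB]))
        paste(cls, collapse = "-")
      } else NA_character_
      family_pair <- if (!is.null(fam))
        paste(sort(c(fam[cA], fam[cB])), collapse = "-") else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        species_A = A, species_B = B, block = blk,
        I = unname(I), se = se, t = tval, df = df, p = pval,
        degenerate = degen, pair_class = pair_class,
        family_pair = family_pair,
        patristic_distance = if (!is.null(pd) && cA %in% rownames(pd) &&
                                 cB %in% rownames(pd)) pd[cA, cB]
        else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_mf("no estimable pairs in the design")
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Group-level tests of feedback location
#'
#' Per group of interaction coefficients (plus "overall"), a one-sample t
#' test of the mean against zero and a Wilcoxon signed-rank test for the
#' median against zero.  Groups with zero variance are reported as
#' degenerate with the common sign; groups below `min_n` are skipped.
#'
#' @param results output of [pairwise_interactions()].
#' @param grouping column name to group by (default `"pair_class"`); use
#'   `NULL` for the overall test only.
#' @param min_n minimum coefficients per tested group (default 3).
#' @return A data.frame with one row per group: `group`, `n`, `mean`, `t`,
#'   `df`, `p_mean`, `median`, `p_median`, `degenerate`.
#' @export
group_feedback_tests <- function(results, grouping = "pair_class", min_n = 3) {
  one <- function(x, label) {
    if (length(x) < min_n) {
      message(sprintf("group '%s' skipped (n = %d < %d)", label, length(x),
                      min_n))
      return(NULL)
    }
    if (var(x) == 0) {
      return(data.frame(group = label, n = length(x), mean = mean(x),
                        t = NA_real_, df = NA_real_, p_mean = NA_real_,
                        median = median(x), p_median = NA_real_,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    tt <- t.test(x, mu = 0)
    wt <- suppressWarnings(wilcox.test(x, mu = 0))
    data.frame(group = label, n = length(x), mean = mean(x),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_mean = tt$p.value, median = median(x),
               p_median = wt$p.value, degenerate = FALSE,
               stringsAsFactors = FALSE)
  }
  rows <- list(one(results$I, "overall"))
  if (!is.null(grouping)) {
    for (g in sort(unique(results[[grouping]])))
      rows <- c(rows, list(one(results$I[results[[grouping]] == g], g)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Type III ANOVA of feedback on life-history factors
#'
#' Tests the effect of the two species' life histories (and their
#' interaction) on the interaction coefficient with marginal (Type III)
#' sums of squares under sum-to-zero contrasts.
#'
#' @param results data.frame with the response column and two life-history
#'   factor columns.
#' @param response response column name (default `"I"`).
#' @param factors character(2): the host and training life-history columns.
#' @return A data.frame with `term`, `SS`, `df`, `F`, `p`.
#' @export
anova_lifehistory <- function(results, response = "I",
                              factors = c("lh_host", "lh_train")) {
  miss <- setdiff(c(response, factors), names(results))
  if (length(miss)) stop_mf("missing columns: %s", paste(miss, collapse = ", "))
  d <- results[, c(response, factors)]
  names(d) <- c(".y", ".f1", ".f2")
  d$.f1 <- factor(d$.f1); d$.f2 <- factor(d$.f2)
  if (nlevels(d$.f1) < 2 || nlevels(d$.f2) < 2)
    stop_mf("both factors need at least 2 levels")
  # drop inestimable terms (empty cells or collinear factors) from the top
  forms <- list(full = .y ~ .f1 * .f2, additive = .y ~ .f1 + .f2,
                single = .y ~ .f1)
  if (any(table(d$.f1, d$.f2) == 0)) forms$full <- NULL
  fit <- NULL
  for (nm in names(forms)) {
    cand <- lm(forms[[nm]], data = d,
               contrasts = list(.f1 = "contr.sum", .f2 = "contr.sum")[
                 intersect(c(".f1", ".f2"), all.vars(forms[[nm]]))])
    if (!anyNA(coef(cand))) {
      fit <- cand
      if (nm != "full")
        message("anova_lifehistory: inestimable terms dropped (",
                nm, " model fitted)")
      break
    }
  }
  if (is.null(fit)) stop_mf("life-history design is degenerate")
  a <- car::Anova(fit, type = 3)
  lbl <- c(.f1 = factors[1], .f2 = factors[2],
           `.f1:.f2` = paste(factors, collapse = ":"),
           Residuals = "Residuals")
  keep <- rownames(a) != "(Intercept)"
  out <- data.frame(
    term = unname(lbl[rownames(a)[keep]]),
    SS = a$`Sum Sq`[keep], df = a$Df[keep], F = a$`F value`[keep],
    p = a$`Pr(>F)`[keep], stringsAsFactors = FALSE
  )
  for (tm in setdiff(unname(lbl[1:3]), out$term))
    out <- rbind(out, data.frame(term = tm, SS = NA, df = NA, F = NA,
                                 p = NA))
  rownames(out) <- NULL
  out
}

#' Feedback versus phylogenetic distance
#'
#' Ordinary least-squares fits of the interaction coefficient on patristic
#' distance, linear and quadratic, with coefficient t tests and AIC
#' comparison.
#'
#' @param results output of [pairwise_interactions()] with
#'   `patristic_distance` attached.
#' @return A list with `linear` and `quadratic` coefficient tables
#'   (estimate, se, t, p), `aic` (named, both models), and `best`.
#' @export
feedback_vs_phylodistance <- function(results) {
  d <- results[is.finite(results$patristic_distance) & is.finite(results$I), ]
  if (nrow(d) < 5) stop_mf("need at least 5 pairs with distances")
  lin <- lm(I ~ patristic_distance, data = d)
  quad <- lm(I ~ patristic_distance + I(patristic_distance^2), data = d)
  ct <- function(fit) {
    s <- summary(fit)$coefficients
    data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
               t = s[, 3], p = s[, 4], row.names = NULL,
               stringsAsFactors = FALSE)
  }
  aics <- c(linear = AIC(lin), quadratic = AIC(quad))
  list(linear = ct(lin), quadratic = ct(quad), aic = aics,
       best = names(aics)[which.min(aics)])
}

#' Feedback versus compositional dissimilarity
#'
#' Regresses the interaction coefficient on each supplied dissimilarity
#' predictor (species-level Aitchison and per-fungus genetic Aitchison),
#' reporting R-squared, the overall F and its p-value per predictor, plus a
#' Holm-adjusted p column across predictors.  Constant predictors are
#' refused (reported with `NA` and a note).
#'
#' @param results data.frame containing `I` and the predictor columns.
#' @param predictors character vector of predictor column names; defaults
#'   to all columns starting with `"dissim"`.
#' @return A data.frame with one row per predictor: `predictor`, `n`,
#'   `slope`, `r_squared`, `F`, `df1`, `df2`, `p`, `p_holm`.
#' @export
feedback_vs_dissimilarity <- function(results, predictors = NULL) {
  if (is.null(predictors))
    predictors <- grep("^dissim", names(results), value = TRUE)
  if (!length(predictors)) stop_mf("no dissimilarity predictors found")
  rows <- list()
  for (pr in predictors) {
    x <- results[[pr]]; y <- results$I
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || var(x[ok]) == 0) {
      message(sprintf("predictor '%s' degenerate (constant or too few values)",
                      pr))
      rows[[pr]] <- data.frame(predictor = pr, n = sum(ok), slope = NA_real_,
                               r_squared = NA_real_, F = NA_real_,
                               df1 = NA_real_, df2 = NA_real_, p = NA_real_,
                               stringsAsFactors = FALSE)
      next
    }
    if (var(y[ok]) == 0) {
      # constant response: nothing to explain
      rows[[pr]] <- data.frame(predictor = pr, n = sum(ok), slope = 0,
                               r_squared = 0, F = 0, df1 = 1,
                               df2 = sum(ok) - 2, p = NA_real_,
                               stringsAsFactors = FALSE)
      next
    }
    fit <- lm(y[ok] ~ x[ok])
    s <- summary(fit)
    rows[[pr]] <- data.frame(
      predictor = pr, n = sum(ok), slope = unname(coef(fit)[2]),
      r_squared = s$r.squared, F = unname(s$fstatistic[1]),
      df1 = unname(s$fstatistic[2]), df2 = unname(s$fstatistic[3]),
      p = pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
             lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$p_holm <- p.adjust(out$p, method = "holm")
  rownames(out) <- NULL
  out
}

#' Attach conditioned-community dissimilarities to feedback pairs
#'
#' For each species pair, the species-level Aitchison dissimilarity and the
#' per-fungus genetic Aitchison dissimilarity between the two conditioned
#' communities, computed as the mean distance over all cross pairs of the
#' two training species' mesocosm samples in the chosen year (year 2 soils
#' were the feedback inocula).
#'
#' @param results output of [pairwise_interactions()].
#' @param asv an [asv_table()] at ASV resolution.
#' @param meta sample metadata with `sample_id`, `host_species`, `year`.
#' @param year which year's communities to use (default 2).
#' @param pseudocount passed to [clr_transform()].
#' @return `results` with columns `dissim_species` and one
#'   `dissim_genetic_<fungus>` per fungal species.
#' @export
feedback_dissimilarities <- function(results, asv, meta, year = 2,
                                     pseudocount = 1) {
  stopifnot(inherits(asv, "asv_table"))
  meta <- meta[match(rownames(asv$counts), meta$sample_id), ]
  sel <- meta$year == year
  sp_tab <- aggregate_to_species(asv)
  fungi <- setdiff(colnames(sp_tab$counts), "unassigned")
  sp_counts <- sp_tab$counts[sel, fungi, drop = FALSE]
  keep <- rowSums(sp_counts) > 0
  D_sp <- aitchison_distance(clr_transform(sp_counts[keep, , drop = FALSE],
                                           pseudocount))
  host_of <- setNames(canon_species(meta$host_species[sel][keep]),
                      rownames(sp_counts)[keep])

  mean_cross <- function(D, hosts_map, A, B) {
    sa <- names(hosts_map)[hosts_map == A & names(hosts_map) %in% rownames(D)]
    sb <- names(hosts_map)[hosts_map == B & names(hosts_map) %in% rownames(D)]
    if (!length(sa) || !length(sb)) return(NA_real_)
    mean(D[sa, sb, drop = FALSE])
  }

  gen <- list()
  sub_asv <- asv_table(asv$counts[sel, , drop = FALSE], asv$taxonomy)
  for (f in fungi) {
    gd <- genetic_dissimilarity(sub_asv, f, pseudocount)
    hm <- setNames(canon_species(
      meta$host_species[sel][match(rownames(gd$distance),
                                   meta$sample_id[sel])]),
      rownames(gd$distance))
    gen[[f]] <- list(D = gd$distance, hosts = hm)
  }

  results$dissim_species <- NA_real_
  for (f in fungi)
    results[[paste0("dissim_genetic_", f)]] <- NA_real_
  for (i in seq_len(nrow(results))) {
    A <- canon_species(results$species_A[i])
    B <- canon_species(results$species_B[i])
    results$dissim_species[i] <- mean_cross(D_sp, host_of, A, B)
    for (f in fungi)
      results[[paste0("dissim_genetic_", f)]][i] <-
        mean_cross(gen[[f]]$D, gen[[f]]$hosts, A, B)
  }
  results
}

#' Mean fungal accumulation per host grouping
#'
#' Per-fungus mean abundance within each level of a host grouping (CLR
#' scale by default, relative abundance optionally) for a given year, plus
#' the grand-mean relative abundance of each fungus (the weights used by
#' [predicted_feedback_correlation()]).
#'
#' @param asv an [asv_table()].
#' @param meta sample metadata with `sample_id`, `year`, and the grouping
#'   column.
#' @param group_var metadata column defining host groups (e.g.,
#'   `"phylo_group"` or `"life_history"`).
#' @param year which year's samples to use.
#' @param scale `"clr"` (default) or `"relative"`.
#' @param pseudocount passed to [clr_transform()].
#' @return A list with `means` (fungus x group matrix) and `weights`
#'   (named grand-mean relative abundances).
#' @export
fungal_accumulation <- function(asv, meta, group_var, year,
                                scale = c("clr", "relative"),
                                pseudocount = 1) {
  scale <- match.arg(scale)
  stopifnot(inherits(asv, "asv_table"))
  meta <- meta[match(rownames(asv$counts), meta$sample_id), ]
  sel <- meta$year == year
  sp_tab <- aggregate_to_species(asv)
  fungi <- setdiff(colnames(sp_tab$counts), "unassigned")
  counts <- sp_tab$counts[sel, fungi, drop = FALSE]
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  grp <- factor(meta[[group_var]][sel][keep])
  rel <- counts / rowSums(counts)
  vals <- if (scale == "clr") clr_transform(counts, pseudocount) else rel
  means <- t(vapply(fungi, function(f)
    tapply(vals[, f], grp, mean), numeric(nlevels(grp))))
  dimnames(means) <- list(fungi, levels(grp))
  list(means = means, weights = colMeans(rel))
}

#' Predicted-feedback weighted correlation
#'
#' Tests whether the fungi that accumulate on a host group are also the
#' fungi that benefit that group: for a contrast of group `g` against a
#' baseline, correlates per-fungus differential accumulation
#' (`x_f = mean abundance in g - in baseline`) with the differential
#' meta-analytic benefit (`y_f = marginal-mean LRR in g - in baseline`),
#' by least squares weighted by each fungus' overall relative abundance.
#' A positive slope predicts positive feedback between the groups.
#'
#' @param mm data.frame of marginal means with columns `fungus`, `group`,
#'   `emmean` (e.g., reshaped from [marginal_means()]).
#' @param accumulation fungus-by-group matrix of mean accumulation (see
#'   [fungal_accumulation()]).
#' @param weights named per-fungus weights (overall relative abundance).
#' @param group,baseline the two group levels contrasted.
#' @return A list with `slope`, `r_squared` (weighted), `p`, `n`.
#' @export
predicted_feedback_correlation <- function(mm, accumulation, weights,
                                           group, baseline) {
  fungi <- intersect(rownames(accumulation), unique(mm$fungus))
  x <- accumulation[fungi, group] - accumulation[fungi, baseline]
  yg <- mm$emmean[match(paste(fungi, group),
                        paste(mm$fungus, mm$group))]
  yb <- mm$emmean[match(paste(fungi, baseline),
                        paste(mm$fungus, mm$group))]
  y <- yg - yb
  w <- weights[fungi]
  ok <- is.finite(x) & is.finite(y) & is.finite(w) & w > 0
  if (sum(ok) < 3) stop_mf("need at least 3 fungi with both axes defined")
  fit <- lm(y[ok] ~ x[ok], weights = w[ok])
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), r_squared = s$r.squared,
       p = s$coefficients[2, 4], n = sum(ok))
}
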