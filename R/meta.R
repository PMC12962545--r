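# Log-response-ratio effect sizes and the multilevel random-effects
# meta-regression used to characterize what each fungal isolate does for
# hosts of each phylogenetic group and life history.

#' Log response ratio and its sampling variance
#'
#' For each growth-assay record, the mycorrhizal responsiveness
#' `LRR = ln(mean_inoc / mean_ctrl)` and its sampling variance
#' `var = SD_inoc^2 / (n_inoc * mean_inoc^2) + SD_ctrl^2 / (n_ctrl * mean_ctrl^2)`.
#'
#' @param assays data.frame of growth-assay summaries with columns
#'   `mean_inoc`, `sd_inoc`, `n_inoc`, `mean_ctrl`, `sd_ctrl`, `n_ctrl`
#'   (plus any identifier columns, which are carried through).
#' @return The input data.frame with `lrr` and `variance` columns appended.
#' @export
compute_lrr <- function(assays) {
  req <- c("mean_inoc", "sd_inoc", "n_inoc", "mean_ctrl", "sd_ctrl", "n_ctrl")
  miss <- setdiff(req, names(assays))
  if (length(miss)) stop_mf("missing columns: %s", paste(miss, collapse = ", "))
  if (any(assays$mean_inoc <= 0) || any(assays$mean_ctrl <= 0))
    stop_mf("group means must be positive (log response undefined otherwise)")
  if (any(assays$n_inoc < 2) || any(assays$n_ctrl < 2))
    stop_mf("group sizes must be >= 2")
  if (any(assays$sd_inoc < 0) || any(assays$sd_ctrl < 0))
    stop_mf("standard deviations must be >= 0")
  assays$lrr <- log(assays$mean_inoc / assays$mean_ctrl)
  assays$variance <-
    assays$sd_inoc^2 / (assays$n_inoc * assays$mean_inoc^2) +
    assays$sd_ctrl^2 / (assays$n_ctrl * assays$mean_ctrl^2)
  assays
}

#' Diversity-response log response ratios
#'
#' Effect of multi-species versus single-species inoculation: per study and
#' plant species, `lrr = ln(mean_multi / x_ref)` where the reference is the
#' mean of all single-isolate means (`mode = "vs_mean_single"`) or the mean
#' of the single most beneficial isolate (`mode = "vs_best_single"`; ties on
#' the mean broken by the smaller sampling variance).  Variances follow the
#' delta-method analog of the standard LRR variance, with the reference
#' term `Var(x_ref) / x_ref^2`.
#'
#' @param assays growth-assay data.frame; rows with
#'   `fungal_isolate == "mixture"` are the multi-species inoculations.
#' @param mode `"vs_mean_single"` or `"vs_best_single"`.
#' @return A data.frame with one row per (study, host species) having both
#'   a mixture record and at least two single-isolate records.
#' @export
diversity_lrr <- function(assays, mode = c("vs_mean_single", "vs_best_single")) {
  mode <- match.arg(mode)
  out <- list()
  for (key in unique(paste(assays$study_id, assays$host_species, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- assays[assays$study_id == parts[1] &
                    assays$host_species == parts[2], ]
    multi <- sub[sub$fungal_isolate == "mixture", ]
    singles <- sub[sub$fungal_isolate != "mixture", ]
    if (nrow(multi) != 1 || nrow(singles) < 2) {
      message(sprintf("diversity_lrr: skipping %s / %s (%d mixture, %d singles)",
                      parts[1], parts[2], nrow(multi), nrow(singles)))
      next
    }
    var_of_mean <- singles$sd_inoc^2 / singles$n_inoc
    if (mode == "vs_mean_single") {
      x_ref <- mean(singles$mean_inoc)
      var_ref <- sum(var_of_mean) / nrow(singles)^2
    } else {
      best <- which(singles$mean_inoc == max(singles$mean_inoc))
      if (length(best) > 1) best <- best[which.min(var_of_mean[best])]
      x_ref <- singles$mean_inoc[best]
      var_ref <- var_of_mean[best]
    }
    out[[length(out) + 1L]] <- data.frame(
      study_id = parts[1], host_species = parts[2],
      life_history = multi$life_history[1],
      mode = mode,
      lrr = log(multi$mean_inoc / x_ref),
      variance = multi$sd_inoc^2 / (multi$n_inoc * multi$mean_inoc^2) +
        var_ref / x_ref^2,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Multilevel random-effects meta-regression
#'
#' Fits `lrr_i = x_i' b + u_study + u_species + e_i` with known sampling
#' variances `e_i ~ N(0, variance_i)` and crossed random intercepts for
#' study and plant host species, by REML (via [metafor::rma.mv()]).
#' Moderator columns that are aliased (rank deficient after expansion) are
#' dropped and reported.
#'
#' @param effects data.frame with `lrr`, `variance`, `study_id`,
#'   `host_species`, and any moderator columns.
#' @param moderators one-sided formula over columns of `effects`
#'   (default `~ 1`).
#' @param random character subset of `c("study", "species")`.
#' @return An object of class `meta_model`: list with `b`, `vcov`, `tau2`,
#'   `dropped`, `fit` (the rma.mv object), `formula`, `data`.
#' @export
fit_meta_reml <- function(effects, moderators = ~1,
                          random = c("study", "species")) {
  if (nrow(effects) < 2 && !identical(deparse(moderators), "~1"))
    stop_mf("need at least 2 effects for a moderated model")
  for (nm in all.vars(moderators))
    if (!is.numeric(effects[[nm]])) effects[[nm]] <- factor(effects[[nm]])
  X <- model.matrix(moderators, data = effects)
  q <- qr(X)
  kept <- sort(q$pivot[seq_len(q$rank)])
  dropped <- colnames(X)[setdiff(seq_len(ncol(X)), kept)]
  if (length(dropped))
    message("fit_meta_reml: dropping aliased columns: ",
            paste(dropped, collapse = ", "))
  Xk <- X[, kept, drop = FALSE]
  rand <- list()
  if ("study" %in% random) rand <- c(rand, list(~ 1 | study_id))
  if ("species" %in% random) rand <- c(rand, list(~ 1 | host_species))
  has_int <- "(Intercept)" %in% colnames(Xk)
  mods_arg <- Xk[, setdiff(colnames(Xk), "(Intercept)"), drop = FALSE]
  if (nrow(effects) == 1 && has_int && ncol(mods_arg) == 0) {
    # a single effect: no heterogeneity estimable, estimate is the effect
    return(structure(list(
      b = c(`(Intercept)` = effects$lrr),
      vcov = matrix(effects$variance, 1, 1,
                    dimnames = list("(Intercept)", "(Intercept)")),
      tau2 = setNames(rep(0, length(random)), random), dropped = dropped,
      fit = NULL, formula = moderators, data = effects
    ), class = "meta_model"))
  }
  args <- list(yi = effects$lrr, V = effects$variance,
               intercept = has_int, data = effects, method = "REML")
  if (ncol(mods_arg)) args$mods <- mods_arg
  if (length(rand)) args$random <- rand
  fit <- do.call(metafor::rma.mv, args)
  b <- drop(fit$beta)
  names(b) <- c(if (has_int) "(Intercept)",
                setdiff(colnames(Xk), "(Intercept)"))
  V <- as.matrix(vcov(fit))
  dimnames(V) <- list(names(b), names(b))
  tau2 <- if (length(rand)) setNames(fit$sigma2, random) else numeric(0)
  structure(list(
    b = b, vcov = V, tau2 = tau2, dropped = dropped, fit = fit,
    formula = moderators, data = effects
  ), class = "meta_model")
}

#' @export
print.meta_model <- function(x, ...) {
  cat("meta_model (REML)\n")
  if (length(x$tau2)) {
    cat("tau2:\n"); print(round(x$tau2, 6))
  }
  print(data.frame(b = x$b, se = sqrt(diag(x$vcov))))
  if (length(x$dropped))
    cat("aliased (dropped):", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Wald QM test of a coefficient subset
#'
#' `QM = b_s' Cov(b_s)^{-1} b_s`, referred to a chi-squared distribution
#' with `df = |s|`.
#'
#' @param model a `meta_model`.
#' @param subset coefficient names (or indices); default: all non-intercept
#'   coefficients.
#' @return A list with `QM`, `df`, `p`.
#' @export
wald_qm <- function(model, subset = NULL) {
  stopifnot(inherits(model, "meta_model"))
  nm <- names(model$b)
  if (is.null(subset)) subset <- setdiff(nm, "(Intercept)")
  if (is.numeric(subset)) subset <- nm[subset]
  bad <- setdiff(subset, nm)
  if (length(bad)) stop_mf("unknown coefficients: %s", paste(bad, collapse = ", "))
  bs <- model$b[subset]
  Vs <- model$vcov[subset, subset, drop = FALSE]
  Vi <- tryCatch(solve(Vs), error = function(e)
    stop_mf("singular covariance for the requested subset"))
  qm <- drop(t(bs) %*% Vi %*% bs)
  list(QM = qm, df = length(subset),
       p = pchisq(qm, df = length(subset), lower.tail = FALSE))
}

#' Estimated marginal means from a meta-model
#'
#' Predictions for each combination of the focal factors, averaged with
#' equal weight over a balanced reference grid of the remaining factors in
#' the moderator formula, with delta-method standard errors.  Focal
#' combinations never observed in the data (aliased cells) are returned as
#' `NA` with a note.
#'
#' @param model a `meta_model`.
#' @param focal character vector of factor names in the moderator formula.
#' @return A data.frame with the focal levels, `emmean`, `se`, and
#'   `estimable`.
#' @export
marginal_means <- function(model, focal) {
  stopifnot(inherits(model, "meta_model"))
  vars <- all.vars(model$formula)
  bad <- setdiff(focal, vars)
  if (length(bad)) stop_mf("focal factors not in the model: %s",
                           paste(bad, collapse = ", "))
  data <- model$data
  lev <- lapply(vars, function(v)
    if (is.factor(data[[v]])) levels(data[[v]]) else
      if (is.numeric(data[[v]])) mean(data[[v]]) else unique(data[[v]]))
  names(lev) <- vars
  focal_grid <- if (length(focal))
    expand.grid(lev[focal], stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE)
  else data.frame(row.names = 1)
  others <- setdiff(vars, focal)
  other_grid <- if (length(others))
    expand.grid(lev[others], stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE)
  else data.frame(row.names = 1)

  seen <- if (length(focal))
    unique(do.call(paste, c(lapply(focal, function(v)
      as.character(data[[v]])), sep = "\r")))
  out <- focal_grid
  out$emmean <- NA_real_; out$se <- NA_real_; out$estimable <- FALSE
  for (i in seq_len(nrow(focal_grid))) {
    key <- paste(unlist(lapply(focal_grid[i, , drop = FALSE], as.character)),
                 collapse = "\r")
    if (length(focal) && !(key %in% seen)) {
      message("marginal_means: focal cell not observed, left NA: ", key)
      next
    }
    grid <- other_grid
    for (v in focal) grid[[v]] <- focal_grid[i, v]
    for (v in vars)
      if (is.factor(data[[v]]))
        grid[[v]] <- factor(grid[[v]], levels = levels(data[[v]]))
    Xg <- model.matrix(model$formula, data = grid)
    Xg <- Xg[, names(model$b), drop = FALSE]
    xbar <- colMeans(Xg)
    out$emmean[i] <- sum(xbar * model$b)
    out$se[i] <- sqrt(drop(t(xbar) %*% model$vcov %*% xbar))
    out$estimable[i] <- TRUE
  }
  out
}
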