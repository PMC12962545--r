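# Phylogenetic linear mixed models: REML estimation with arbitrary known
# covariance structures, GLS fixed effects with Wald tests, a boundary
# likelihood-ratio test for the phylogenetic variance component, and
# phylogenetic heritability.
#
# Model: y = X beta + sum_k u_k + e, with cov(u_k) = sigma2_k * S_k for
# known sample-level PSD structure matrices S_k (e.g., Z C Z' for the
# phylogenetic effect) and e ~ N(0, sigma2_e I).  The restricted likelihood
# is profiled over the residual variance and maximized over the variance
# ratios gamma_k = sigma2_k / sigma2_e on the log scale.

# Profiled negative restricted log-likelihood (up to a constant) and the
# ingredients needed to reconstruct estimates at the optimum.
.reml_eval <- function(log_gamma, y, X, S_list) {
  n <- length(y); p <- ncol(X)
  V0 <- diag(n)
  for (k in seq_along(S_list)) V0 <- V0 + exp(log_gamma[k]) * S_list[[k]]
  R <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(R)) return(list(value = 1e10))
  ldV <- 2 * sum(log(diag(R)))
  Xs <- forwardsolve(t(R), X)
  ys <- forwardsolve(t(R), y)
  XtVX <- crossprod(Xs)
  cf <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(cf)) return(list(value = 1e10))
  ldX <- 2 * sum(log(diag(cf)))
  beta <- backsolve(cf, forwardsolve(t(cf), crossprod(Xs, ys)))
  resid <- ys - Xs %*% beta
  rss <- sum(resid^2)
  if (rss <= 0) return(list(value = 1e10))
  list(
    value = 0.5 * (ldV + ldX + (n - p) * log(rss)),
    beta = drop(beta), rss = rss, XtVX = XtVX, ldV = ldV, ldX = ldX
  )
}

#' Fit a linear mixed model with known covariance structures by REML
#'
#' Estimates variance components for a set of known sample-level covariance
#' structures (for a phylogenetic effect, `Z %*% C %*% t(Z)` with `C` from
#' [phylo_covariance()]; for i.i.d. group effects, `Z %*% t(Z)`) plus an
#' i.i.d. residual, by restricted maximum likelihood.  Optimization is on
#' the log variance-ratio scale with multiple starting points; fixed effects
#' are the GLS solution at the estimated variances, with Wald z tests.
#'
#' Structures that are numerically proportional to one another (e.g.,
#' phylogeny on a star tree versus species identity) make the individual
#' components non-identifiable; such pairs are detected and reported in
#' `$collinear`, and the summed component remains well estimated.
#'
#' @param y numeric response vector (finite).
#' @param X fixed-effect design matrix (or a data.frame/vector coerced via
#'   `cbind(1, ...)` is *not* done — pass a full design matrix including the
#'   intercept column).
#' @param structures named list of n-by-n PSD matrices, one per variance
#'   component besides the residual.
#' @param n_restarts number of additional randomized starting points.
#' @param seed seed for the randomized restarts.
#' @return An object of class `pglmm_fit` with elements `beta`, `se`, `z`,
#'   `p_fixed`, `sigma2` (named, including `resid`), `loglik` (full REML
#'   log-likelihood), `converged`, `collinear`, `n`, `p`, `vcov_beta`.
#' @export
fit_pglmm <- function(y, X, structures = list(), n_restarts = 3, seed = 1) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  if (any(!is.finite(y))) stop_mf("response contains non-finite values")
  if (nrow(X) != n) stop_mf("X and y dimensions disagree")
  if (n <= p) stop_mf("need more observations than fixed effects")
  K <- length(structures)
  if (K > 0 && is.null(names(structures)))
    stop_mf("structures must be a named list")
  for (S in structures) {
    if (!isTRUE(all.equal(dim(S), c(n, n))))
      stop_mf("each structure must be n x n")
  }

  # detect numerically proportional structure pairs (non-identifiable split)
  collinear <- list()
  if (K >= 2) {
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      Si <- structures[[i]]; Sj <- structures[[j]]
      cs <- sum(Si * Sj) / sqrt(sum(Si^2) * sum(Sj^2))
      if (cs > 1 - 1e-8)
        collinear[[length(collinear) + 1L]] <-
          c(names(structures)[i], names(structures)[j])
    }
  }

  if (K == 0) {
    fit <- lm.fit(X, y)
    s2 <- sum(fit$residuals^2) / (n - p)
    XtXi <- chol2inv(chol(crossprod(X)))
    se <- sqrt(diag(XtXi) * s2)
    beta <- fit$coefficients
    ll <- -0.5 * ((n - p) * (log(2 * pi) + log(s2) + 1) +
                    2 * sum(log(abs(diag(qr.R(qr(X)))))))
    z <- beta / se
    return(structure(list(
      beta = beta, se = se, z = z,
      p_fixed = 2 * pnorm(-abs(z)),
      sigma2 = c(resid = s2), loglik = ll, converged = TRUE,
      collinear = collinear, n = n, p = p,
      vcov_beta = XtXi * s2, structure_names = character(0)
    ), class = "pglmm_fit"))
  }

  obj <- function(lg) .reml_eval(lg, y, X, structures)$value
  lower <- rep(-25, K); upper <- rep(12, K)
  starts <- list(rep(0, K), rep(-4, K))
  set.seed(stage_seed(seed, 17L))
  for (r in seq_len(n_restarts))
    starts[[length(starts) + 1L]] <- runif(K, -6, 2)

  best <- NULL
  conv <- FALSE
  for (st in starts) {
    op <- tryCatch(
      optim(st, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$value < best$value - 1e-10) {
      best <- op
      conv <- op$convergence == 0
    }
  }
  if (is.null(best)) stop_mf("REML optimization failed from every start")

  ev <- .reml_eval(best$par, y, X, structures)
  gamma <- exp(best$par)
  s2e <- ev$rss / (n - p)
  sigma2 <- c(gamma * s2e, resid = s2e)
  names(sigma2) <- c(names(structures), "resid")
  # components driven to the lower bound are zero for all practical purposes
  sigma2[seq_len(K)][gamma < 1.5e-11] <- 0
  vcov_beta <- chol2inv(chol(ev$XtVX)) * s2e
  se <- sqrt(diag(vcov_beta))
  beta <- ev$beta
  names(beta) <- names(se) <- colnames(X)
  ll <- -0.5 * ((n - p) * (log(2 * pi) + log(s2e) + 1) + ev$ldV + ev$ldX)
  z <- beta / se
  structure(list(
    beta = beta, se = se, z = z, p_fixed = 2 * pnorm(-abs(z)),
    sigma2 = sigma2, loglik = ll, converged = conv,
    collinear = collinear, n = n, p = p, vcov_beta = vcov_beta,
    structure_names = names(structures)
  ), class = "pglmm_fit")
}

#' @export
print.pglmm_fit <- function(x, ...) {
  cat(sprintf("pglmm_fit (n = %d, REML logLik = %.3f%s)\n", x$n, x$loglik,
              if (x$converged) "" else ", NOT CONVERGED"))
  cat("variance components:\n")
  print(round(x$sigma2, 6))
  cat("fixed effects:\n")
  print(data.frame(beta = x$beta, se = x$se, z = x$z, p = x$p_fixed))
  if (length(x$collinear))
    cat("note: non-identifiable structure pairs:",
        paste(vapply(x$collinear, paste, "", collapse = " ~ "),
              collapse = ", "),
        "- individual components arbitrary, their sum is estimable\n")
  invisible(x)
}

#' Boundary likelihood-ratio test for a variance component
#'
#' Compares a full REML fit against the fit without the phylogenetic
#' component (same fixed-effect design).  Because the null value lies on
#' the boundary of the parameter space, the statistic is referred to a
#' 50:50 mixture of a point mass at 0 and a chi-squared with 1 df:
#' `p = 0.5 * P(chisq_1 >= Lambda)`.
#'
#' @param full,reduced `pglmm_fit` objects with identical fixed designs;
#'   `reduced` omits exactly the tested component.
#' @return A list with `lambda` and `p`.
#' @export
lrt_phylo <- function(full, reduced) {
  stopifnot(inherits(full, "pglmm_fit"), inherits(reduced, "pglmm_fit"))
  if (full$n != reduced$n || full$p != reduced$p)
    stop_mf("full and reduced fits must share the same fixed design")
  lambda <- max(0, 2 * (full$loglik - reduced$loglik))
  list(lambda = lambda, p = 0.5 * pchisq(lambda, df = 1, lower.tail = FALSE))
}

#' Phylogenetic heritability
#'
#' Proportion of the among-host-species variance attributable to the
#' phylogeny: `H2 = sigma2_phylo / (sigma2_phylo + sigma2_species)`.
#'
#' @param fit a `pglmm_fit` with components named `phylo` and `species`.
#' @return A number in `[0, 1]`, or `NA` with a warning when both
#'   components are zero.
#' @export
phylo_heritability <- function(fit) {
  stopifnot(inherits(fit, "pglmm_fit"))
  s_a <- fit$sigma2[["phylo"]]
  s_s <- fit$sigma2[["species"]]
  tot <- s_a + s_s
  if (tot <= 0) {
    warning("both between-species components are zero; heritability undefined")
    return(NA_real_)
  }
  s_a / tot
}

# Build sample-level structure matrices for the standard model:
# phylogeny (on C), species identity, block.
.pglmm_structures <- function(host, block, C) {
  host <- canon_species(host)
  missing <- setdiff(unique(host), rownames(C))
  if (length(missing))
    stop_mf("hosts absent from covariance matrix: %s",
            paste(missing, collapse = ", "))
  Zs <- outer(host, rownames(C), `==`) * 1
  Zb <- outer(block, unique(block), `==`) * 1
  list(
    phylo = Zs %*% C %*% t(Zs),
    species = tcrossprod(Zs),
    block = tcrossprod(Zb)
  )
}

#' Run the full phylogenetic mixed-model suite on a dataset
#'
#' For each year separately, fits the standard model (fixed effects:
#' intercept, life history, log sequencing depth; random structures:
#' phylogeny, host species identity, greenhouse block) to a battery of
#' responses: the logit relative abundance of each fungal species among
#' inoculated reads, rarefied Shannon diversity, the logit density proxy,
#' and optionally each species' individual ASVs in order of decreasing
#' overall abundance.  Each response also gets the reduced fit without the
#' phylogenetic structure for the boundary likelihood-ratio test, and
#' phylogenetic heritability.
#'
#' @param dataset list with elements `asv` ([asv_table()]), `meta`
#'   (sample metadata data.frame with `sample_id`, `host_species`,
#'   `life_history`, `block`, `year`), and `tree` ([ape::phylo]).
#' @param include_asv_level also fit per-ASV responses (default `TRUE`).
#' @param max_asv_rank cap on ASV abundance rank fitted per species
#'   (default `Inf`, i.e., all).
#' @param rarefaction_depth,rarefaction_draws passed to [shannon_rarefied()].
#' @param min_n responses with fewer non-missing samples are skipped.
#' @param seed master seed.
#' @return A data.frame, one row per (response, year).
#' @export
run_pglmm_suite <- function(dataset, include_asv_level = TRUE,
                            max_asv_rank = Inf, rarefaction_depth = 100,
                            rarefaction_draws = 100, min_n = 10, seed = 1) {
  asv <- dataset$asv; meta <- dataset$meta; tree <- dataset$tree
  stopifnot(inherits(asv, "asv_table"), inherits(tree, "phylo"))
  C <- phylo_covariance(tree)
  meta <- meta[match(rownames(asv$counts), meta$sample_id), ]
  species_tab <- aggregate_to_species(asv)
  fungi <- setdiff(colnames(species_tab$counts), "unassigned")
  inoc_counts <- species_tab$counts[, fungi, drop = FALSE]
  inoc_total <- rowSums(inoc_counts)
  dens <- density_proxy(asv)

  rows <- list()
  for (yr in sort(unique(meta$year))) {
    sel <- which(meta$year == yr & inoc_total > 0)
    m <- meta[sel, ]
    tot <- inoc_total[sel]
    eps <- 1 / (2 * tot)
    X <- cbind(`(Intercept)` = 1,
               life_history_late = as.numeric(m$life_history == "late"),
               log_depth = log(tot))
    S_full <- .pglmm_structures(m$host_species, m$block, C)
    S_red <- S_full[c("species", "block")]

    responses <- list()
    for (f in fungi) {
      responses[[f]] <- list(
        y = logit(clamp_prop(inoc_counts[sel, f] / tot, eps)),
        level = "species", fungus = f, rank = NA_integer_)
    }
    sh <- shannon_rarefied(inoc_counts[sel, , drop = FALSE],
                           depth = rarefaction_depth,
                           n_draws = rarefaction_draws,
                           seed = stage_seed(seed, 31L + yr))
    responses[["shannon_diversity"]] <-
      list(y = sh, level = "diversity", fungus = NA_character_,
           rank = NA_integer_)
    responses[["density"]] <-
      list(y = dens$logit[sel], level = "density", fungus = NA_character_,
           rank = NA_integer_)

    if (include_asv_level) {
      for (f in fungi) {
        f_asvs <- names(asv$taxonomy)[asv$taxonomy == f]
        ord <- order(colSums(asv$counts[, f_asvs, drop = FALSE]),
                     decreasing = TRUE)
        f_asvs <- f_asvs[ord]
        for (r in seq_len(min(length(f_asvs), max_asv_rank))) {
          a <- f_asvs[r]
          responses[[paste0("asv:", a)]] <- list(
            y = logit(clamp_prop(asv$counts[sel, a] / tot, eps)),
            level = "asv", fungus = f, rank = r)
        }
      }
    }

    for (nm in names(responses)) {
      rs <- responses[[nm]]
      keep <- is.finite(rs$y)
      if (sum(keep) < min_n) {
        message(sprintf("skipping response '%s' year %s: %d usable samples",
                        nm, yr, sum(keep)))
        next
      }
      yk <- rs$y[keep]
      Xk <- X[keep, , drop = FALSE]
      Sf <- lapply(S_full, function(S) S[keep, keep, drop = FALSE])
      Sr <- lapply(S_red, function(S) S[keep, keep, drop = FALSE])
      fit <- fit_pglmm(yk, Xk, Sf, seed = stage_seed(seed, 101L))
      red <- fit_pglmm(yk, Xk, Sr, seed = stage_seed(seed, 102L))
      lrt <- lrt_phylo(fit, red)
      h2 <- suppressWarnings(phylo_heritability(fit))
      rows[[length(rows) + 1L]] <- data.frame(
        response = nm, level = rs$level, fungus = rs$fungus,
        asv_rank = rs$rank, year = yr,
        beta_lifehistory = fit$beta[["life_history_late"]],
        se_lifehistory = fit$se[["life_history_late"]],
        p_lifehistory = fit$p_fixed[["life_history_late"]],
        sigma2_phylo = fit$sigma2[["phylo"]],
        sigma2_species = fit$sigma2[["species"]],
        sigma2_block = fit$sigma2[["block"]],
        sigma2_resid = fit$sigma2[["resid"]],
        LRT_lambda = lrt$lambda, LRT_p_phylo = lrt$p,
        H2_P = h2, converged = fit$converged, n = sum(keep),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
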