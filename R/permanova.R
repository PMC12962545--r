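# Permutational multivariate ANOVA on a distance matrix: sequential
# (Type I) sums of squares from the Gower-centered inner-product matrix,
# pseudo-F statistics, and permutation p-values under random relabeling.

#' Permutational multivariate ANOVA (PerMANOVA)
#'
#' Partitions the total sum of squared distances among samples into
#' sequential contributions of an ordered list of factors (plus, optionally,
#' their interactions) and tests each term's pseudo-F against the
#' permutation distribution obtained by randomly relabeling samples.
#'
#' The distance matrix is Gower-centered, `G = -1/2 J D^2 J` with
#' `J = I - 11'/n`, so that the total sum of squares satisfies
#' `tr(G) = sum_{i<j} d_ij^2 / n`; term sums of squares are differences in
#' `tr(H G)` between nested hat matrices as terms are added in order.
#'
#' @param D symmetric distance matrix (e.g., [aitchison_distance()]).
#' @param factors data.frame of sample factors, rows aligned with `D`.
#' @param formula model formula over columns of `factors`; defaults to the
#'   sequential sum of all columns plus all two-way interactions when
#'   `interactions = TRUE`.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed for the permutation stream.
#' @param interactions include two-way interactions when no formula given.
#' @return An object of class `permanova_result`: a data.frame with one row
#'   per term plus Residual and Total (`df`, `SS`, `F`, `R2`, `p`), with
#'   attributes `n_perm` and `seed`.
#' @export
permanova <- function(D, factors, formula = NULL, n_perm = 999, seed = 1,
                      interactions = TRUE) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop_mf("distance matrix must be symmetric")
  if (n_perm < 99) stop_mf("n_perm must be >= 99")
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  if (nrow(factors) != n) stop_mf("factors and D have different sizes")
  for (nm in names(factors)) {
    factors[[nm]] <- factor(factors[[nm]])
    if (nlevels(factors[[nm]]) < 2)
      stop_mf("factor '%s' has a single level", nm)
  }

  if (is.null(formula)) {
    main <- names(factors)
    terms_chr <- main
    if (interactions && length(main) >= 2) {
      for (i in seq_len(length(main) - 1)) for (j in (i + 1):length(main))
        terms_chr <- c(terms_chr, paste(main[i], main[j], sep = ":"))
    }
  } else {
    terms_chr <- attr(terms(formula), "term.labels")
  }

  # drop interaction terms whose factor crossing has empty cells
  keep <- vapply(terms_chr, function(tc) {
    parts <- strsplit(tc, ":", fixed = TRUE)[[1]]
    if (length(parts) == 1) return(TRUE)
    tab <- table(factors[parts])
    if (any(tab == 0)) {
      warning(sprintf(
        "interaction term '%s' dropped: empty cells in the crossing", tc))
      return(FALSE)
    }
    TRUE
  }, logical(1))
  terms_chr <- terms_chr[keep]

  G <- gower_center(D)
  ss_total <- sum(diag(G))

  # nested sequence of hat matrices, intercept first
  designs <- vector("list", length(terms_chr))
  form <- "~ 1"
  for (k in seq_along(terms_chr)) {
    form <- paste(form, "+", terms_chr[k])
    designs[[k]] <- model.matrix(as.formula(form), data = factors)
  }
  hats <- lapply(designs, function(X) {
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    tcrossprod(Q)
  })
  dfs <- diff(c(1, vapply(designs, function(X) qr(X)$rank, 0L)))
  df_resid <- n - qr(designs[[length(designs)]])$rank
  if (df_resid < 1) stop_mf("no residual degrees of freedom")

  stat_fun <- function(Gp) {
    tr <- vapply(hats, function(H) sum(H * Gp), 0)
    ss_seq <- diff(c(0, tr))
    ss_res <- sum(diag(Gp)) - tr[length(tr)]
    f <- (ss_seq / dfs) / (ss_res / df_resid)
    list(ss = ss_seq, ss_res = ss_res, f = f)
  }

  obs <- stat_fun(G)
  set.seed(seed)
  exceed <- numeric(length(terms_chr))
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    Fp <- stat_fun(G[idx, idx])$f
    exceed <- exceed + (Fp >= obs$f - 1e-12)
  }
  pvals <- (1 + exceed) / (1 + n_perm)

  ss_all <- c(obs$ss, obs$ss_res, ss_total)
  res <- data.frame(
    term = c(terms_chr, "Residual", "Total"),
    df = c(dfs, df_resid, n - 1),
    SS = ss_all,
    F = c(obs$f, NA, NA),
    # no variation at all: nothing explained by anything
    R2 = if (ss_total > 0) ss_all / ss_total else rep(0, length(ss_all)),
    p = c(pvals, NA, NA),
    stringsAsFactors = FALSE
  )
  structure(res, class = c("permanova_result", "data.frame"),
            n_perm = n_perm, seed = seed)
}

#' Gower-center a distance matrix
#'
#' `G = -1/2 J D^2 J`, the inner-product matrix whose trace equals the
#' total sum of squares `sum_{i<j} d_ij^2 / n`.
#'
#' @param D symmetric distance matrix.
#' @return The centered inner-product matrix.
#' @export
gower_center <- function(D) {
  D <- as.matrix(D)
  A <- -0.5 * D^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PerMANOVA (%d permutations, seed %d)\n",
              attr(x, "n_perm"), attr(x, "seed")))
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}
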