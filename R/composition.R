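# Compositional and diversity statistics on ASV count tables: species
# aggregation, CLR transform, Aitchison distances (community-level and
# within-species "genetic"), rarefied Shannon diversity, and the
# inoculated-read density proxy with its Poisson-GLM validation.

#' Construct an ASV count table
#'
#' Bundles a samples-by-ASVs matrix of read counts with an ASV-to-species
#' taxonomy map.  ASVs mapped to `"unassigned"` represent reads not assigned
#' to any inoculated fungal species (legacy DNA); they are retained for the
#' density proxy but excluded from species-level community analyses.
#'
#' @param counts integer matrix, samples in rows, ASVs in columns, with
#'   dimnames.
#' @param taxonomy named character vector mapping each ASV id to a fungal
#'   species name or `"unassigned"`.
#' @return An object of class `asv_table`.
#' @export
asv_table <- function(counts, taxonomy) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_mf("counts matrix must have sample and ASV dimnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_mf("counts must be non-negative integers")
  if (anyDuplicated(names(taxonomy)))
    stop_mf("duplicated ASV ids in taxonomy")
  missing <- setdiff(colnames(counts), names(taxonomy))
  if (length(missing))
    stop_mf("ASVs missing from taxonomy: %s", paste(missing, collapse = ", "))
  structure(
    list(counts = counts, taxonomy = taxonomy[colnames(counts)]),
    class = "asv_table"
  )
}

#' @export
print.asv_table <- function(x, ...) {
  sp <- setdiff(unique(x$taxonomy), "unassigned")
  cat(sprintf("asv_table: %d samples x %d ASVs (%d fungal species%s)\n",
              nrow(x$counts), ncol(x$counts), length(sp),
              if ("unassigned" %in% x$taxonomy) " + unassigned" else ""))
  invisible(x)
}

#' Aggregate ASV counts to fungal species
#'
#' Sums, per sample, all ASVs assigned to the same fungal species.
#' `"unassigned"` reads are kept as their own feature so that the density
#' proxy remains computable downstream; species-level analyses should drop
#' that column.
#'
#' @param x an [asv_table()].
#' @return An `asv_table` whose features are fungal species (taxonomy maps
#'   each species to itself).
#' @export
aggregate_to_species <- function(x) {
  stopifnot(inherits(x, "asv_table"))
  sp <- factor(x$taxonomy, levels = unique(x$taxonomy))
  agg <- t(rowsum(t(x$counts), group = sp))
  colnames(agg) <- levels(sp)
  asv_table(agg, setNames(levels(sp), levels(sp)))
}

#' Centered log-ratio (CLR) transform
#'
#' `CLR(x)_i = ln(x_i + c) - mean_j ln(x_j + c)` per sample (row).  Rows of
#' the result sum to zero.  Exact scale invariance (x and k*x mapping to the
#' same point) holds at `pseudocount = 0` on strictly positive counts; with
#' a pseudocount it is approximate for low counts.
#'
#' @param counts numeric matrix, samples in rows, features in columns.
#' @param pseudocount non-negative offset added before taking logs
#'   (default 1).  With `pseudocount = 0` all counts must be positive.
#' @return A real matrix of the same shape; rows sum to 0.
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (pseudocount < 0) stop_mf("pseudocount must be >= 0")
  zero_rows <- rowSums(counts) == 0
  if (any(zero_rows))
    stop_mf("all-zero rows cannot form a composition: %s",
            paste(rownames(counts)[zero_rows] %||%
                    which(zero_rows), collapse = ", "))
  if (pseudocount == 0 && any(counts <= 0))
    stop_mf("pseudocount = 0 requires strictly positive counts")
  lx <- log(counts + pseudocount)
  lx - rowMeans(lx)
}

#' Aitchison distance matrix
#'
#' Euclidean distances between CLR-transformed rows.
#'
#' @param clr a CLR matrix as returned by [clr_transform()].
#' @return A symmetric distance matrix with zero diagonal and row/col names
#'   from `clr`.
#' @export
aitchison_distance <- function(clr) {
  if (any(!is.finite(clr))) stop_mf("CLR matrix must be finite")
  as.matrix(dist(clr, method = "euclidean"))
}

#' Within-species ("genetic") Aitchison dissimilarity
#'
#' Aitchison distances restricted to the ASVs of one focal fungal species,
#' describing turnover in the genetic composition of that species between
#' samples.  Samples with zero total reads for the focal species carry no
#' information about its internal composition and are excluded (listed in
#' the result) rather than imputed.  A species represented by a single ASV
#' has a degenerate one-part composition: all pairwise distances are 0.
#'
#' @param x an [asv_table()] at ASV resolution.
#' @param species focal fungal species name present in the taxonomy.
#' @param pseudocount passed to [clr_transform()].
#' @return A list with elements `distance` (matrix over retained samples),
#'   `excluded` (character vector of dropped sample ids) and `n_asv`.
#' @export
genetic_dissimilarity <- function(x, species, pseudocount = 1) {
  stopifnot(inherits(x, "asv_table"))
  asvs <- names(x$taxonomy)[x$taxonomy == species]
  if (!length(asvs)) stop_mf("no ASVs assigned to species '%s'", species)
  sub <- x$counts[, asvs, drop = FALSE]
  keep <- rowSums(sub) > 0
  excluded <- rownames(sub)[!keep]
  sub <- sub[keep, , drop = FALSE]
  if (nrow(sub) < 2) {
    d <- matrix(0, nrow(sub), nrow(sub),
                dimnames = list(rownames(sub), rownames(sub)))
    return(list(distance = d, excluded = excluded, n_asv = length(asvs)))
  }
  if (length(asvs) == 1L) {
    # one-part composition: identically zero distances among retained samples
    d <- matrix(0, nrow(sub), nrow(sub),
                dimnames = list(rownames(sub), rownames(sub)))
  } else {
    d <- aitchison_distance(clr_transform(sub, pseudocount))
  }
  list(distance = d, excluded = excluded, n_asv = length(asvs))
}

#' Rarefied Shannon diversity
#'
#' Shannon's H (natural log) computed on subsamples of a fixed number of
#' reads drawn without replacement, averaged over `n_draws` rarefactions.
#' Samples whose total count is below the rarefaction depth are returned as
#' `NA` (flagged, not imputed).
#'
#' @param counts numeric matrix of counts, samples in rows, features
#'   (typically fungal species) in columns.
#' @param depth rarefaction depth in reads (default 100).
#' @param n_draws number of rarefaction draws averaged (default 100).
#' @param seed integer seed for the subsampling stream.
#' @return Named numeric vector of mean rarefied H per sample (nats).
#' @export
shannon_rarefied <- function(counts, depth = 100, n_draws = 100, seed = 1) {
  counts <- as.matrix(counts)
  if (depth < 1) stop_mf("rarefaction depth must be >= 1")
  if (n_draws < 1) stop_mf("n_draws must be >= 1")
  set.seed(seed)
  totals <- rowSums(counts)
  out <- rep(NA_real_, nrow(counts))
  names(out) <- rownames(counts)
  for (i in seq_len(nrow(counts))) {
    if (totals[i] < depth) next
    reads <- rep.int(seq_len(ncol(counts)), counts[i, ])
    h <- numeric(n_draws)
    for (k in seq_len(n_draws)) {
      sub <- sample(reads, depth)
      p <- tabulate(sub, nbins = ncol(counts)) / depth
      p <- p[p > 0]
      h[k] <- -sum(p * log(p))
    }
    out[i] <- mean(h)
  }
  out
}

#' Inoculated-read density proxy
#'
#' Per-sample proportion of reads assigned to the inoculated fungal species
#' (everything not `"unassigned"`), used as a proxy for AM fungal density,
#' together with its empirical logit.  The proportion is clamped into
#' `[eps, 1 - eps]` with `eps = 1 / (2 * depth)` before the logit.
#'
#' @param x an [asv_table()].
#' @return A data.frame with columns `sample_id`, `depth`, `proportion`,
#'   `logit`.
#' @export
density_proxy <- function(x) {
  stopifnot(inherits(x, "asv_table"))
  total <- rowSums(x$counts)
  if (any(total <= 0)) stop_mf("samples with zero depth: %s",
                               paste(names(total)[total <= 0], collapse = ", "))
  inoc <- rowSums(x$counts[, x$taxonomy != "unassigned", drop = FALSE])
  p_raw <- inoc / total
  eps <- 1 / (2 * total)
  p <- clamp_prop(p_raw, eps)
  data.frame(
    sample_id = rownames(x$counts),
    depth = unname(total),
    proportion = unname(p_raw),
    logit = unname(logit(p)),
    stringsAsFactors = FALSE
  )
}

#' Validate the density proxy against spore counts
#'
#' Fits a Poisson generalized linear model (log link) of spore counts on the
#' density proxy by iteratively reweighted least squares and reports the
#' slope, its Wald p-value, and McFadden's pseudo-R-squared
#' `1 - ll_model / ll_null`.
#'
#' @param proxy numeric vector of density-proxy values.
#' @param spore_counts non-negative integer vector of the same length.
#' @param max_iter,tol IRLS iteration controls.
#' @return A list with `slope`, `se`, `p`, `pseudo_r2`, `coefficients`,
#'   `converged`.
#' @export
validate_density_proxy <- function(proxy, spore_counts,
                                   max_iter = 50, tol = 1e-10) {
  y <- spore_counts
  if (length(proxy) != length(y)) stop_mf("proxy and spore_counts differ in length")
  ok <- complete.cases(proxy, y)
  proxy <- proxy[ok]; y <- y[ok]
  if (length(y) < 3) stop_mf("need at least 3 paired observations")
  if (any(y < 0) || any(y != round(y)))
    stop_mf("spore counts must be non-negative integers")
  X <- cbind(1, proxy)
  beta <- c(log(mean(y) + 0.5), 0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    XtW <- t(X * mu)
    beta_new <- solve(XtW %*% X, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- drop(beta_new); converged <- TRUE; break
    }
    beta <- drop(beta_new)
  }
  mu <- exp(drop(X %*% beta))
  cov_beta <- solve(t(X * mu) %*% X)
  se <- sqrt(diag(cov_beta))
  zstat <- beta[2] / se[2]
  ll <- function(m) sum(y * log(m) - m - lgamma(y + 1))
  ll_model <- ll(mu)
  ll_null <- ll(rep(mean(y), length(y)))
  pseudo_r2 <- if (abs(ll_null) < 1e-12) 0 else 1 - ll_model / ll_null
  list(
    slope = unname(beta[2]),
    se = unname(se[2]),
    p = 2 * pnorm(-abs(zstat)),
    pseudo_r2 = max(0, min(1, pseudo_r2)),
    coefficients = setNames(beta, c("(Intercept)", "proxy")),
    converged = converged
  )
}
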