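# Shared fixtures, built in code.

# Three-taxon tree with hand-computable path lengths.
tiny_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# Star tree: all tips attached at the root with equal branch lengths.
star_tree <- function(n = 6) {
  ape::read.tree(text = paste0(
    "(", paste(sprintf("t%d:1", seq_len(n)), collapse = ","), ");"))
}

# Small ASV table: two fungal species (X: 2 ASVs, Y: 1 ASV) plus legacy reads.
tiny_asv <- function() {
  counts <- matrix(
    c(3L, 4L, 5L, 2L,
      10L, 0L, 6L, 4L),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("s1", "s2"), c("x1", "x2", "y1", "u1")))
  asv_table(counts, c(x1 = "X", x2 = "X", y1 = "Y", u1 = "unassigned"))
}

# Balanced one-way random-effects data for REML/ANOVA oracles.
one_way_data <- function(g = 6, r = 5, sigma_a = 2, sigma_e = 1, seed = 1) {
  set.seed(seed)
  a <- rnorm(g, sd = sigma_a)
  grp <- rep(seq_len(g), each = r)
  y <- a[grp] + rnorm(g * r, sd = sigma_e)
  list(y = y, grp = factor(grp))
}

# Sample-level structure matrix for a grouping factor.
group_structure <- function(grp) {
  Z <- outer(grp, sort(unique(grp)), `==`) * 1
  tcrossprod(Z)
}

logit_oracle <- function(p) log(p / (1 - p))

.pglmm_structures_test <- function(host, block, C)
  mycofeedback:::.pglmm_structures(host, block, C)

clamp_prop_test <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

# Small complete synthetic study used by several integration tests.
small_sim_config <- function(...) {
  sim_config(n_host_species = 10, feedback_blocks = 2, n_studies = 2,
             hosts_per_study = 6, ...)
}
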