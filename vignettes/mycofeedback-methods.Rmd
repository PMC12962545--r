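---
title: "Models and methods behind mycofeedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mycofeedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mycofeedback)
```

# The scientific question

Arbuscular mycorrhizal (AM) fungal communities differentiate on their host
plants: relative growth rates of fungal species, and of genotypes within
fungal species, depend on the host. Two host axes are candidates for
structuring that differentiation — the host phylogeny (related plants
cultivating similar symbiont communities, "phylosymbiosis") and the host's
successional life history (early, fast-growing versus late, conservative
species). Whether symbiont differentiation then feeds back on plant
performance is the coadaptation question: positive plant–soil feedback means
plants do better with symbiont communities conditioned by themselves or by
similar hosts.

`mycofeedback` implements the full chain of analyses for this design: ASV
count tables from mesocosms of many host species are summarized
compositionally; host-phylogeny and life-history effects are tested with
phylogenetic linear mixed models and PerMANOVA; growth benefits of the
fungal isolates are summarized meta-analytically; and a factorial
soil-conditioning experiment yields pairwise feedback coefficients whose
structure is tested against phylogenetic distance and compositional change.

# Compositional layer

Counts are compositional: only relative information is meaningful. The
pipeline works on the centered log-ratio (CLR) scale,
$\mathrm{clr}(x)_i = \ln(x_i + c) - \frac{1}{S}\sum_j \ln(x_j + c)$, with a
pseudocount $c$ (default 1; all zero-free oracle checks run at $c = 0$,
where CLR is exactly scale-invariant). The **Aitchison distance** is the
Euclidean distance between CLR rows. Two resolutions are used:

* *species-level*: ASVs summed within each inoculated fungal species
  (reads not assigned to an inoculated species are kept as an
  `"unassigned"` feature for the density proxy and excluded from community
  analyses);
* *within-species ("genetic")*: distances computed on each fungal species'
  own ASVs only. Samples with zero reads of the focal species are excluded
  rather than imputed — a pseudocount-only composition would otherwise
  dominate the within-species space. A species with a single ASV has a
  degenerate one-part composition and identically zero distances.

**Shannon diversity** is computed on reads rarefied to 100 (the assay's
depth floor is well above this), averaged over 100 draws without
replacement; averaging rather than a single rarefaction stabilizes the
estimate, and the draw count is configurable. **Fungal density** has no
direct measurement in sequencing data; the proportion of reads assigned to
inoculated species is used as a proxy (the background is sterilized soil,
so unassigned reads are legacy DNA and roughly constant), logit-transformed
with the empirical clamp $\varepsilon = 1/(2\,\mathrm{depth})$. The proxy
can be validated against spore counts with a Poisson log-link GLM (fitted
by IRLS) reporting the Wald slope test and McFadden's pseudo-$R^2$.

# Phylogenetic mixed models

For each response $y$ (per-species logit relative abundance, diversity,
logit density; each year separately) the model is

$$y = X\beta + u_\mathrm{phylo} + u_\mathrm{species} + u_\mathrm{block} +
\varepsilon,$$

with $u_\mathrm{phylo} \sim N(0, \sigma^2_a\, Z C Z^\top)$ where $C$ is the
Brownian-motion covariance implied by the host tree (shared root-to-MRCA
path lengths), $u_\mathrm{species} \sim N(0, \sigma^2_s Z Z^\top)$ an
i.i.d. host-species effect, a greenhouse-block intercept, and i.i.d.
residuals. $C$ is rescaled to mean diagonal 1 so $\sigma^2_a$ lives on the
response scale and is comparable across trees; non-ultrametric trees are
accepted as-is (the covariance is well defined either way). Fixed effects
are the intercept, host life history, and log sequencing depth — total
depth is a continuous nuisance covariate of the compositional responses and
is statistically coherent as a fixed effect (an option exists to model it
as a random quantile intercept instead of dropping it).

Estimation is REML with the residual variance profiled out and the
variance *ratios* optimized on the log scale (bounded quasi-Newton, two
deterministic plus three randomized starts). Components driven to the
lower bound ($\gamma < 10^{-10}$ or so) are reported as zero. The fixed
effects are the GLS solution at the estimated variances with Wald z tests.

Two derived quantities:

* **phylogenetic signal test**: likelihood-ratio statistic between the full
  fit and the fit without the phylogenetic structure. Since
  $\sigma^2_a = 0$ sits on the boundary, the statistic is referred to the
  50:50 mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$, i.e.
  $p = 0.5\,P(\chi^2_1 \ge \Lambda)$ — the standard, mildly conservative
  choice for a single variance component;
* **phylogenetic heritability**
  $H_P^2 = \hat\sigma^2_a / (\hat\sigma^2_a + \hat\sigma^2_s)$, the share
  of among-host-species variance attributable to the phylogeny, undefined
  (returned `NA`) when both components are zero.

On a star phylogeny $ZCZ^\top$ and $ZZ^\top$ coincide and the two
components are not separately identifiable; the fit detects numerically
proportional structures, flags them, and the *summed* component remains
well estimated. ASV-level responses are fitted in order of decreasing
overall abundance, with no multiple-testing correction across ASVs by
default (a deliberate reporting choice; correct downstream if desired).

# PerMANOVA

Community-level tests use the permutational multivariate ANOVA on Aitchison
distances: the distance matrix is Gower-centered
($G = -\tfrac12 J D^2 J$), sums of squares are sequential (Type I) traces
of nested hat-matrix projections — the community default for this analysis
— with pseudo-$F$ per term and $p$-values from random relabeling of samples
(999 permutations by default, $p \ge 1/(n_\mathrm{perm}+1)$). The Gower
identity $\mathrm{tr}(G) = \sum_{i<j} d_{ij}^2 / n$ ties the partition to
the raw distances. Interaction terms whose factor crossing has empty cells
are dropped with a warning. In the univariate Euclidean case the
pseudo-$F$ reduces exactly to the classical ANOVA $F$ — one of the
package's cross-checks (the other is agreement with `vegan::adonis2`).

# Meta-analysis of growth assays

Each growth-assay record (study × host species × fungal isolate) yields a
log response ratio and its sampling variance:

$$\mathrm{LRR} = \ln\!\frac{\bar x_\mathrm{inoc}}{\bar x_\mathrm{ctrl}},
\qquad
\sigma^2 = \frac{SD^2_\mathrm{inoc}}{n_\mathrm{inoc}\,\bar x^2_\mathrm{inoc}}
         + \frac{SD^2_\mathrm{ctrl}}{n_\mathrm{ctrl}\,\bar x^2_\mathrm{ctrl}}.$$

These feed a multilevel random-effects meta-regression (REML, via
`metafor::rma.mv`) with crossed random intercepts for study and host
species and moderators for isolate, life history, phylogenetic group and
their interactions; aliased moderator columns (cells absent from the
sparse assay designs) are dropped and reported, not penalized. Wald QM
tests summarize moderator blocks; marginal means are predictions averaged
with equal weight over a balanced grid of the non-focal factors
(delta-method SEs), matching the usual estimated-marginal-means convention
(cross-checked against `emmeans`). Diversity-response ratios compare the
mixture inoculum against the mean single isolate or the best single
isolate (ties on the mean broken by the smaller sampling variance); the
reference's variance enters by the delta method as
$\mathrm{Var}(\bar x_\mathrm{ref})/\bar x_\mathrm{ref}^2$, since the exact
analogue is not pinned down by convention.

# Feedback

The two-species feedback statistic is the interaction coefficient

$$I = F_{A\alpha} - F_{A\beta} - F_{B\alpha} + F_{B\beta},$$

cell means of biomass of hosts $A, B$ in soils conditioned by $A$
($\alpha$) and $B$ ($\beta$). $I > 0$ is positive feedback. Its standard
error uses the pooled within-cell variance of the pair's own 2×2 design,
$\mathrm{se} = s_p \sqrt{\sum_\mathrm{cells} 1/n}$ on $N - 4$ df — the
canonical t test of the interaction contrast; pairs with zero pooled
variance are flagged degenerate rather than given a p-value. $I$ is
symmetric in the pair and invariant to host main effects (adding a
constant to one host's biomasses cancels), both asserted in tests.

Pattern analyses: one-sample t and Wilcoxon signed-rank tests of mean and
median feedback per pair class (early–early / early–late / late–late, and
family pairs); Type III ANOVA of $I$ on the two species' life histories
under sum-to-zero contrasts (inestimable terms are dropped from the top and
reported `NA`); linear and quadratic OLS of $I$ on patristic distance with
AIC comparison; and OLS of $I$ on each compositional dissimilarity —
species-level Aitchison and per-fungus genetic Aitchison between the two
conditioned communities. A pair's conditioned-community dissimilarity is
the mean cross distance between the two training species' year-2 mesocosm
samples (year-2 soils were the feedback inocula). Per-fungus regressions
are reported uncorrected, as is conventional for this design, with a
Holm-adjusted column alongside.

The predicted-feedback correlation links the two halves: for a host-group
contrast, per-fungus differential accumulation (mean CLR abundance in the
group minus baseline; CLR is the analysis scale, relative abundance
available by switch) is correlated with the differential meta-analytic
benefit (marginal-mean LRR difference), weighted by each fungus' overall
relative abundance. With seven fungal species these tests have seven
points; the null calibration check in the test suite runs at exactly
$n = 7$ for that reason.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream stage is exercised.

* **Tree**: pure-birth (Yule) tree over 38 tips, rescaled to unit
  root-to-tip depth so $\sigma^2_a$ is comparable across runs; tips
  `sp01..sp38`. Life history is a balanced random assignment; the six
  phylogenetic groups are average-linkage clusters of the patristic matrix,
  so they are clade-coherent.
* **Latent host effects**: per fungus,
  $E = b_f + \beta_f\,[\mathrm{late}] + u_f + e_f$ with
  $u_f \sim N(0, \sigma^2_a C)$ (default $\sigma^2_a = 1$),
  $e_f \sim N(0, \sigma^2_s I)$ (default $0.25$), baseline log fitnesses
  chosen so the most abundant fungi mirror the empirical ranking
  (*E. infrequens*, then *Cl. lamellosum*, with *A. spinosa* rare), and
  late-successional boosts on *Cl. claroideum*, *F. mosseae* and
  *R. fulgida*.
* **Counts**: one sample per host × block (4) × year (2); depth
  log-normal (median ≈ 8100, floored at 500, inside the assay's observed
  range); species proportions are the softmax of $E$ plus block- and
  year-by-fungus effects, scaled by $1 - 0.2$ for a 20% legacy
  (unassigned) read fraction; counts are Dirichlet-multinomial
  (concentration 50 — visibly overdispersed, with the multinomial limit
  available for oracle checks). Species counts are split into the
  (2, 4, 8, 12, 9, 4, 15) ASVs per species by a geometric base profile
  with per-sample Dirichlet wobble; for the two designated "genetically
  responsive" fungi (*E. infrequens*, *Cl. lamellosum*) the within-species
  profile shifts between early and late hosts, so genetic dissimilarity
  carries real signal.
* **Feedback biomass**: 5 fully factorial subsets of the 38 species
  (8, 8, 8, 7, 7 — 126 pairs, matching the degrees of freedom of the
  reported class-wise tests), 4 replicates per host-by-soil cell. Cell
  means invert the interaction coefficient with the symmetric split
  $F_{A\alpha} = F_{B\beta} = \mu$,
  $F_{A\beta} = F_{B\alpha} = \mu - I/2$ (the definition constrains only
  the sum, so the even split is the minimal assumption). Default targets
  are drawn as $I = 0.3 + 0.8\,(d_g - \bar d_g) + N(0, 0.3^2)$ from the
  centered genetic dissimilarity $d_g$ of *E. infrequens* — positive mean
  feedback driven by within-species genetic change, the pattern the
  feedback stage is designed to detect — truncated only at physical
  feasibility ($\mu - |I|/2$ above the biomass floor).
* **Growth assays**: 3 studies of 12 host species each; control replicates
  Normal around a 2 g baseline (SD 0.4, $n = 8$), inoculated replicates
  around $\mathrm{baseline} \times e^{\mathrm{LRR}}$, with true LRRs of
  0.3 plus late-successional boosts on *E. infrequens*, *Cl. lamellosum*
  (0.5) and the two *Claroideoglomus*/*F. mosseae* (0.2) — deliberately
  *not* the fungi that accumulate on late hosts, so the predicted-feedback
  correlation across life history leans negative, as a coadaptation-free
  configuration would. A `"mixture"` record per host supports the
  diversity-response ratios.

What the generator does **not** emulate: serial-passage dynamics between
years (year 2 is a re-draw around $E$ plus a year main effect — the year
effect size is a free parameter, as no empirical magnitude is available),
spatial structure, reads lost to chimeras or non-homologous placement, and
any mechanistic nuclear-segregation model of within-species change. Tests
passing on these data show the estimators recover the generating structure;
they do not certify behavior under real-data pathologies outside that
structure.

# Numerical choices and degenerate inputs

* REML optimization: profiled residual variance; log-ratio scale; bounds
  $e^{-25}$–$e^{12}$; components at the lower bound reported as 0;
  convergence taken from the best of the multiple starts.
* Collinear covariance structures (Frobenius cosine $> 1 - 10^{-8}$) are
  flagged; individual components are then arbitrary but their sum is
  estimable.
* All-zero count rows are refused by the CLR (no composition to form);
  zero counts with $c = 0$ likewise.
* Permutation p-values use the add-one convention
  $(1 + \#\{F^* \ge F\})/(1 + n_\mathrm{perm})$.
* Constant regression inputs: a constant response gives $R^2 = 0$ exactly;
  a constant predictor is refused and reported `NA`.
* Every randomized stage derives its stream from one master seed by fixed
  offsets (`stage_seed`), making the full pipeline reproducible
  file-for-file.

# Problem sizes used in the checks

The test suite exercises the estimators at the study's own scale where the
criterion concerns it (38 tips × 4 blocks × 2 years for parameter
recovery; 126 feedback pairs) and at reduced scale where only calibration
is at stake (null rejection rates at 20–50 samples, 200 replicates;
headline-pattern reconstruction at 16 hosts × 2 blocks over 20 replicates).
Parameter recovery for $\sigma^2_a$ is assessed on the CLR abundance of the
focal fungus: single-species logits contain the softmax's shared
log-denominator, which adds host-structured variance from the other six
fungi and inflates the apparent phylogenetic component by roughly 40% under
the defaults, whereas the CLR response cancels that denominator and is
centered on the generating value. The reporting suite nevertheless fits
the logit responses, as that is the convention for univariate relative
abundance models; its $\sigma^2_a$ should be read as phylogenetic structure
of the *observed* logit abundance, not of the latent fitness alone.

# Known limitations

* The PGLMM is Gaussian-only; counts enter through transformed
  proportions, not through a GLMM likelihood.
* The boundary LRT mixture is asymptotic and mildly conservative at these
  sample sizes (the null-calibration test allows rejection up to 0.08 at
  nominal 0.05).
* Genetic dissimilarities for rare fungi rest on few retained samples and
  are noisy; fungi with a single ASV are degenerate by construction.
* The pairwise feedback significance uses per-pair pooled variances;
  a global mixed model over all pairs would share information but is a
  different estimand.
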