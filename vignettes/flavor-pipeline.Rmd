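---
title: "From consumer panels to sweetness-enhancing volatiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From consumer panels to sweetness-enhancing volatiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Perceived sweetness of fresh fruit is driven only partly by sugars. Volatile
compounds reaching the retronasal tract during chewing can raise sweetness
and liking at sugar concentrations held fixed, which makes them attractive
breeding targets: volatiles occur at concentrations three to six orders of
magnitude below sugars, so increasing them carries almost no agronomic cost.
`flavoromics` implements the full inference chain needed to find such
volatiles from a multi-year study design: bounded-scale consumer-panel
ratings, multi-batch chemical quantification of sugars, acids and volatiles,
and (optionally) genotypes for mapping the loci that control the selected
compounds.

The package has two faces. Applied to real tables, it is an analysis
pipeline. Applied to its own synthetic-data generator, it is a calibration
instrument: every statistical step can be checked against a registry of
planted effects, and the test suite does exactly that.

# The model chain

## Panelist-adjusted sample means

Ratings arrive in sessions: each fruit sample is tasted by the roughly 100
consumers of its session, on the bidirectional hedonic scale $[-100, 100]$
(liking, texture liking) or the intensity scale $[0, 100]$ (sweetness,
sourness, flavor intensity). Consumers differ systematically in scale use, so
for every attribute we fit

$$ y_{ij} = \mu_{s(i)} + b_j + \varepsilon_{ij}, \qquad
   b_j \sim N(0, \sigma_b^2), \; \varepsilon_{ij} \sim N(0, \sigma_e^2), $$

with sample as a fixed effect and panelist as a random intercept, estimated
by REML (`lme4` behind `fit_panelist_adjusted_means()`). The fixed-effect
estimates are the adjusted (least-squares) sample means. The suite checks the
REML variance ratio against a grid-search profiled-likelihood oracle and the
balanced-design identity that panelist offsets cancel. Samples rated by one
panelist only are flagged and given inflated standard errors. Sessions are
treated as independent blocks; no session fixed effect is fitted — with
samples nested in sessions the two are confounded, and the panelist term
absorbs the session-level scale drift that is identifiable.

For large simulation studies the package deliberately uses plain per-sample
means (`method = "raw"`): with $\approx 100$ raters per sample the panelist
adjustment moves a mean by $O(\sigma_b/\sqrt{100}) \approx 1$ rating unit,
negligible against the between-sample spread, at about a hundredth of the
cost. The mixed-model path remains the default for real analyses.

## Per-period autoscaling and merging

Chemical quantification performed in different periods (different operators,
different calibrations) carries batch offsets. Each compound is z-scored
within each period (sample SD, $n-1$ denominator), which maps all periods to
mean 0, SD 1 and makes effects comparable across batches; this is also why
planted effects in the generator are expressed per SD of abundance — they
are invariant to batch structure by construction. Undetected values are
explicit missing values, never zeros: they are excluded from the mean/SD,
and compounds constant or nearly absent within a period are dropped from
that period with a warning. The merged analysis keeps the compounds present
in every period (`merge_periods(mode = "common")`); remaining sporadic
missing values are imputed with the period-minimum z-score, a
below-detection-limit convention (`impute_scaled()`, with a period-mean
alternative). Both behaviors exist because the handling of
absent-in-a-period compounds is a genuinely open choice; selection always
uses the drop-per-period rule.

## Correlations, network, cluster support

All pairs of merged compounds and sensory means are Pearson-correlated with
two-sided t p-values and both Benjamini-Hochberg and Bonferroni columns;
counting significant pairs defaults to BH-adjusted $p < 0.01$. The
association network keeps Bonferroni-significant edges (default
$\alpha = 0.05$, configurable — family-wise control is used here purely to
keep the edge set sparse) weighted by $|r|$; node importance is authority
centrality. On an undirected graph the principal eigenvector of $A^\top A$
coincides with the eigenvector centrality of $A$, so the implementation
power-iterates on the spectrally shifted adjacency $A + cI$ per connected
component: the shift leaves eigenvectors untouched but makes the top
eigenvalue strictly dominant, which matters on bipartite-like components
where iterating on $A^\top A$ is start-dependent. Scores are max-normalized
to 1 globally; singleton components get 0.

Hierarchical clustering of variables uses Ward linkage on $1 - r$
dissimilarity (`ward.D`, the legacy behavior of the named method; Euclidean
distance available). Cluster confidence comes from multiscale bootstrap:
bootstrap sample sizes $m = \lceil rn \rceil$ over a grid of scale factors
$r \in \{0.5, \dots, 1.4\}$ (ten values; the grid must bracket 1, otherwise
the signed-distance/curvature decomposition below is ill-posed), 1000
replicates per scale by default. BP is the appearance frequency of a cluster
at $r = 1$. For AU, the probit-transformed support
$\psi_r = \Phi^{-1}(1 - \mathrm{BP}_r)$ is regressed on
$(\sqrt r, 1/\sqrt r)$ by weighted least squares with binomial weights,
giving signed distance $v$ and curvature $c$, and
$\mathrm{AU} = 1 - \Phi(v - c)$. Degenerate counts are clamped to
$[0.5, n_{boot} - 0.5]$ inside the fit; clusters appearing in all or no
replicates at every scale get AU 1 or 0 directly. The suite verifies BP by
enumeration over stored replicates and checks the $AU \ge BP$ relation for
mid-support clusters, where positive curvature makes the bootstrap
probability conservatively biased.

## PLS, VIP and the consensus selection

The headline procedure regresses a sensory response (sweetness or liking) on
the period's autoscaled compounds plus texture liking, one model per period,
with classical NIPALS at $A = 3$ components (fixed by default; in this
small-$n$, large-$p$ regime three components consistently minimized
cross-validated error, and the value is configurable). Per component $a$,
the explained response sum of squares is $SS_a = q_a^2 \, t_a^\top t_a$, and
Wold's variable importance in projection is

$$ VIP_j = \sqrt{ p \; \frac{\sum_a SS_a \,(w_{ja}/\lVert w_a\rVert)^2}
                        {\sum_a SS_a} }, \qquad \sum_j VIP_j^2 = p . $$

The identity is asserted to $10^{-6}$ on every fitted model, and the NIPALS
path is cross-checked against an eigen-decomposition implementation and an
established PLS package to $10^{-8}$ or better. The response is centered and
standardized within period before fitting; VIP is invariant to this, and it
makes y-loadings comparable across periods.

A volatile is a *consensus* candidate when its VIP exceeds 1.0 in at least
two of the three periods; a period where the compound was undetected casts
no vote. Texture liking enters the predictor block but is never a candidate,
and sugars/acids are reported but not selectable. Each candidate then faces
the sugar-independence test: OLS of the response on the volatile plus total
sugars (glucose + fructose + sucrose, summed raw and z-scored within
period), a two-sided t-test on the volatile slope, Bonferroni-corrected over
the candidates actually tested — not over all volatiles; the smaller family
is the honest one because only consensus candidates reach this stage.
Volatiles nearly collinear with sugars ($|r| > 0.999$) are flagged
non-identifiable rather than tested.

## The predictive benchmark

Six learners — OLS (`glm`), a Gaussian-prior linear model evaluated at its
posterior mode (`bayes_glm`, a closed-form ridge solution), componentwise L2
boosting (step 0.1, stop grid 50/100/200), LASSO (`glmnet` path), our NIPALS
PLS (1-5 components), and a random forest (`ranger`, 200 trees, mtry grid
$p/6, p/3, 2p/3$) — are compared under nested cross-validation: per
iteration one 90/10 split, 5-fold tuning inside the 90%, refit on the full
90%, scored on the 10%; 100 iterations; all learners see identical splits,
and the split indices are hashed so the pairing is testable. The baseline is
OLS on exactly sucrose, glucose, fructose, malic and citric acid; extra
columns in its input are excluded by construction.

$R^2$ is reported as $1 - SS_{res}/SS_{tot}$ on the evaluation fold by
default, with `r2_method = "cor"` (squared observed-predicted correlation)
as an alternative. The distinction matters: on 15-sample test folds the
sum-of-squares form is pulled down by roughly 0.1 through the fold-to-fold
variability of its denominator, while the squared correlation estimates a
planted variance fraction without that bias — the suite's
planted-fraction recovery check therefore uses the correlation form, and the
null-calibration check (pure-noise response must score at chance) uses the
sum-of-squares form, whose null expectation is below zero.

## Genetics

Ester-like phenotypes are first normalized by Box-Cox with $\lambda$
maximizing the profile log-likelihood over $[-2, 2]$ (Brent; checked against
a 0.001-step grid and an established implementation). The single-marker scan
is OLS of phenotype on additive dosage 0/1/2 per marker — variance explained
equals the squared dosage-phenotype correlation, an identity the suite
asserts — with BH control across markers, monomorphic markers skipped, and
missing dosages dropped casewise. This is deliberately the reported
single-marker analysis, not a kinship-corrected mixed model: no pedigree
structure is simulated, so a kinship term would be decoration. PCA
(`prcomp`) omits any variable containing a missing value, the standard
treatment for SNP matrices; chemical PCA autoscales first. Genotype-class
summaries use Tukey HSD at $\alpha = 0.05$ with a compact-letter display.

# What the synthetic generator emulates

One `sim_config()` seed determines everything through named substreams, so
adding a generator never shifts another's draws. Defaults are the study
conditions the pipeline is designed for:

* **Design**: 148 samples over three periods sized 54/49/45; sessions of 3-5
  samples (balanced chunking, so period remainders never create an
  undersized session); ~100 panelists per session, each rating every sample
  of their session on all five attributes.
* **Ratings**: sample true mean + panelist intercept (SD 10) + noise (SD
  15), clipped to the scale; the realized clipping fraction is attached so
  users can confirm it stays small (about 2-3% at defaults).
* **Chemistry**: log-normal abundances; per-compound period offsets (SD 0.5
  log units); latent pathway factors generating correlated ester/aldehyde
  clusters; idiosyncratic log-SDs in [0.4, 1.2], so the most variable
  volatiles span far more than the 70-fold range the design anticipates;
  glucose and fructose share a latent sugar factor (autoscaled correlation
  ~0.9); measurement noise shrinks with the number of technical replicates
  (3 by default — the within-sample replicate structure is exposed as a
  parameter rather than asserted).
* **Planted effects**: total sugars carry 0.40 of sample-level sweetness
  variance and 0.30 of liking; three enhancer volatiles carry 0.10 of
  sweetness and 0.08 of liking each; texture 0.20 of liking; a soil
  temperature covariate enters sweetness and liking with a small negative
  fraction (0.05). These fractions were fixed at design time from the
  anchor values the pipeline targets (a sugars-only baseline near
  $R^2 = 0.4$; selected enhancers correlating 0.3-0.5 with sweetness) and a
  power calculation confirming that effects of that size are detectable by
  the consensus-plus-t-test procedure at $n = 148$; they are conditions,
  not tuning knobs.
* **Identifiability choices**: effects act on the per-period autoscaled
  abundance, so they are batch-invariant; enhancers are drawn from volatiles
  *outside* the pathway clusters, because a clustered "decoy" genuinely
  carries a sugar-independent partial effect through its correlated
  enhancer, which would make false positives ill-defined; the sample-level
  residual of each attribute is orthogonalized in-sample against the
  registered drivers, so joint OLS of the noise-free means on the drivers
  returns the registered slopes exactly (to $10^{-6}$), giving the recovery
  tests an exact target instead of an $O(1/\sqrt n)$ one.
* **Genetics**: markers under Hardy-Weinberg; one causal marker whose
  additive effect is scaled analytically ($2p(1-p)a^2$ against a known
  log-normal noise variance) to explain exactly the configured fraction —
  0.15 by default — of phenotypic variance at the configured allele
  frequency.

What it does **not** emulate: panelist demographics or serving order, GC
peak shapes and retention behavior, the dense correlation structure of a
real volatilome (the synthetic correlation matrix is much sparser than a
real one, so absolute counts of significant correlations are not
comparable), genotype-by-environment interaction, kinship among genotyped
individuals, or any relation between the chemical samples and the genotyped
population (the phenotype set is generated separately). Passing recovery
tests therefore demonstrate that the *procedures* are correct and calibrated
under the stated model, not that real data meet that model.

# Numerical choices and degenerate inputs

* Sample SD everywhere uses the $n-1$ denominator; autoscaling is idempotent
  to $10^{-9}$.
* NIPALS needs no inner iteration for a univariate response; deflation of
  both blocks keeps scores orthogonal to $10^{-8}$, and `ncomp` above the
  rank of centered X is refused.
* Power iteration: deterministic start, convergence $10^{-10}$ in the
  max-norm, shift $c = 0.5\max_i \sum_j A_{ij}$.
* Correlation-based dissimilarities from bootstrap resamples that produce a
  constant column are set to the maximal dissimilarity 2.
* Box-Cox treats $|\lambda| < 10^{-12}$ as the log branch.
* Pairs with fewer than 5 complete observations are excluded from the
  correlation table (logged); samples with a single rater keep their mean
  but with inflated SE; constant attributes give missing correlations, not
  zeros; a constant response refuses PLS; degenerate (constant) evaluation
  folds flag the benchmark iteration and are excluded from aggregation.
* All randomness flows from one seed through `substream_seed()` (a small
  multiplicative hash kept below $2^{31}-1$), so every stage is reproducible
  in isolation.

# Problem sizes used by the checks

The test suite runs the full 148-sample design where the design itself is
under test (variance-component recovery, the 59-volatile intersection,
planted-fraction recovery, 50-replicate enhancer/QTL recovery studies,
100-iteration noise-level benchmark of all six learners) and scaled-down
fixtures (24-40 samples, 6-12 variables) where only correctness of an
operation is at stake. These sizes are the package's choices for keeping the
checks sharp and the suite pleasant to run; all of them are plain arguments.

# Known limitations

* The pipeline treats one population at a time in the genetics module and
  offers no meta-analysis across crosses.
* The sugar-independence test conditions on total sugars only; a volatile
  correlated with an *unmeasured* sweetness driver would still be flagged.
* AU values inherit the usual small-sample caveats of the multiscale fit
  when BP is near 0 or 1 at every scale.
* The benchmark's hyperparameter grids are compact by design; they bracket
  the useful range at $n \approx 150$, but a much larger study would want
  wider grids.
* The `bayes_glm` learner fixes its prior scale rather than estimating it;
  it is a regularized linear reference point, not a full Bayesian treatment.
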