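---
title: "Models and methods in senespat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in senespat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

senespat studies aging and cellular senescence in laminar tissue profiled
with barcode-capture spatial transcriptomics (spots on a grid, each mixing
2–10 cells) and single-nucleus RNA-seq. This vignette is the package's own
account of its models: what is assumed, which knobs matter, and what the
synthetic-data tests do and do not establish about real data.

## The spatial expression model

Each gene is modelled independently. A spot $s$ with count $y_s$ follows a
zero-inflated Poisson,

$$y_s \sim \mathrm{ZIP}(\lambda_s, \theta), \qquad
\log \lambda_s = \beta_{a(s),\,g(s)} + \psi_s + \varepsilon_s,$$

where $\theta$ is the probability of a technical dropout (a structural
zero), $a(s)$ is the spot's anatomical annotation region (AAR: cortical
layers L1–L6 or white matter) and $g(s)$ the donor's age group. $\beta$ is
the characteristic expression rate in natural-log counts/spot — the
quantity all downstream differential expression works on. $\psi$ captures
spatial autocorrelation: it carries an intrinsic conditional autoregressive
(ICAR) prior on the rook-adjacency spot graph, restricted within each
array, with scale $\tau$ and a sum-to-zero constraint per array so it
cannot absorb the intercept. $\varepsilon_s \sim N(0, \sigma)$ is
spot-level overdispersion.

The hierarchy on $\beta$ is one level deep: group-level rates are drawn
around a shared AAR-level mean, $\beta_{a,g} \sim N(\mu_a,
\sigma_\beta^2)$ with $\mu_a \sim N(0, 2^2)$. One level keeps the model
identifiable at the scale of a desk-sized cohort while still pooling
information across groups within a layer. $\sigma_\beta$ is a fixed model
constant (default 0.5), not a hyperparameter: fixing it makes the induced
prior of any group contrast $\Delta = \beta_{a,g_1} - \beta_{a,g_2}$
exactly $N(0, 2\sigma_\beta^2)$, which the Savage-Dickey Bayes factor
needs in closed form. $\tau$ and $\sigma$ get half-Normal(0, 1)
hyperpriors; $\theta$ is per-gene with a Beta(1, 2) prior (dropout is a
property of capture efficiency, which varies by gene). Sexes are pooled
when forming age-group contrasts.

### Inference backends

* **`backend = "mcmc"`** — an adaptive Metropolis-within-Gibbs sampler.
  The ZIP mixture is augmented with latent dropout indicators, giving
  conjugate Beta updates for $\theta$ and restricting the Poisson
  likelihood to "active" spots. $\beta$ cells update by vectorised
  elementwise Metropolis; $\mu_a$ is conjugate normal. The ICAR field
  updates colour class by colour class (the spot graph is vertex-coloured,
  so all spots of one colour have no mutual edges and can be proposed
  simultaneously), followed by per-array recentring. Proposal scales adapt
  during warm-up toward standard acceptance targets. Convergence is
  monitored by split-$\hat R$ on every $\beta$ chain; a fit beyond
  tolerance is returned flagged, never silently.
* **`backend = "vi"`** — a maximum a posteriori fit with a Laplace
  Gaussian approximation, collapsing $\psi$ and $\varepsilon$. Because the
  collapsed model makes spots within an (AAR, group) cell exchangeable,
  the likelihood reduces to per-cell sufficient statistics and a fit costs
  milliseconds. This is the backend the power study loops over, and the
  right choice whenever the data were generated (or filtered) without
  strong spot-level structure. Its credible intervals are calibrated when
  the collapsed model is correct; with strong spatial structure they are
  optimistic, and the MCMC backend should be used.

### Differential expression

Evidence for a nonzero contrast uses the Savage-Dickey density ratio
$\mathrm{BF} = p(0\,|\,\mathrm{prior}) / p(0\,|\,\mathrm{posterior})$: the
prior density at zero is the $N(0, 2\sigma_\beta^2)$ value, the posterior
density at zero is a Gaussian kernel density estimate over the contrast
draws with Silverman's bandwidth. The KDE choice (rather than a Dirac
approximation) is robust to skewed posteriors; its known cost is a few
percent of bias when zero sits far in the posterior's tail, which is
irrelevant at decision thresholds. Bayes factors are clipped to
$[10^{-6}, 10^6]$ so overwhelming evidence never becomes an infinity. A
gene×layer is called at BF > 3 **and** $|\log_2\mathrm{FC}| > 1$, with
reporting tiers at BF > 10 and BF > 30; $\log_2\mathrm{FC} = \Delta /
\ln 2$ since $\beta$ is natural-log scale (the Poisson GLM convention).

## Filters

Genes flagged mitochondrial, lncRNA or pseudogene are removed, then genes
detected in fewer than 0.67% of spots (the detection level of *CDKN2A*,
the least-expressed gene the senescence analyses need). Spots need ≥ 100
UMIs over the retained genes (inclusive at 100: "fewer than 100" are
discarded), a valid AAR, and at least one surviving neighbour — neighbour
pruning iterates to a fixpoint because removing a spot can isolate its
neighbours, and an isolated spot would make the ICAR precision singular.
Nuclei QC is strict at both bounds (> 500 UMIs, < 5% mitochondrial
fraction), after which mitochondrial genes are dropped and per-nucleus
totals refreshed; a nucleus sitting within 5% of the UMI bound can
therefore fall below it on a hypothetical second pass — the filters are
idempotent away from that knife edge.

## Coexpression modules and submodules

Gene–gene Pearson correlations are computed over all spots pooled (the
per-spot expression matrix is typically the model's posterior mean
$\lambda$; normalised counts work for quick analyses). Each gene links to
its $k = 10$ most-correlated partners; the undirected union of those lists
is the graph, with edge weights equal to the correlation floored at zero.
Leiden clustering (modularity objective) partitions it. The resolution
defaults are 2 for spatial modules and 1 for cell-type submodules, and
resolution must be read **relative to graph size**: at 13k genes
resolution 2 yields modules of hundreds of genes, while on a 200-gene toy
it over-partitions — the planted-recovery tests therefore run at
resolution 1. Modules under 50 genes are discarded and their genes marked
unassigned. Submodules re-correlate each module's genes over
depth-normalised (10k counts, log1p) nuclei expression and re-cluster,
namespaced `M<i>.<j>`.

Module scores clip each member gene at its 99th percentile across spots
(type-7, linear interpolation — stated because clipping depends on the
convention), z-scale it, and average over members, removing basal
expression differences. Age testing averages per array and layer to
independent batch estimates and applies Welch's *t* with
Benjamini-Hochberg correction across the whole family of
(module × layer × comparison) tests in a run.

## Senescence hallmark scoring and positivity

Nucleus-level module scores subtract bin-matched controls: all genes
involved are binned into 24 average-expression bins (a common default;
exposed as `n_bins`), and each set gene draws up to 100 controls from its
bin **within a fixed 2,000-gene control set** sampled once per run from
genes outside every hallmark list. Keeping the control set fixed makes
scores comparable across the 10 hallmark lists; bin-matching within it
honours the expression-matching idea. Empty bins fall back to the whole
control set, with a log.

Positivity thresholds are the 95th percentile (type-7) of the **young**
group's scores, computed separately per broad class and hallmark (class
pooling would let the most abundant class set every threshold); a nucleus
is positive when its score is strictly above its stratum's threshold, so
by construction ~5% of young nuclei are positive, less tie effects.
Strata under 20 young nuclei yield undefined thresholds and missing
positivity. The multi-hallmark burden counts the 7 individual hallmarks
only; "3+ hallmarks" flags nuclei positive for at least three.
Age-group differences in positivity are tested with the mixed-effects
logistic model below using batch as the random effect, with a one-sided
difference-of-proportions *t* statistic on donor-level fractions reported
for display.

## Composition and nuclei statistics

**Mixed-effects association (MASC-style).** Cluster membership is
regressed on age group and sex with random intercepts for donor and batch.
The per-nucleus Bernoulli data are aggregated to binomial counts per
(donor, batch, sex, group) cell — the likelihood is identical and the fit
is an order of magnitude faster. Significance is a likelihood-ratio test
dropping the age term; separation (a cluster absent or universal in one
group) returns a flagged infinite/zero odds ratio instead of an error, and
degenerate data that defeat the mixed fit fall back to a fixed-effects
logistic with a log message.

**Pseudobulk differential expression.** Deliberately simple: per-donor
summed counts within a broad class, log2-CPM, ordinary least squares on
age in years with sex and batch covariates, BH correction. Precision
weights (voom-style) are intentionally dropped — pseudobulking already
collapses the nucleus-level mean-variance relationship, and the weighting
machinery is not this package's contribution. Genes must be expressed in
≥ 30 nuclei and detected in ≥ 75% of young or of old donors (middle
donors do not enter the detection rule). Effects are reported as log2FC
over the young-to-old mean age span. A design where batch is confounded
with age errors out, naming the columns.

**Markers and deconvolution.** Marker selection pseudobulks per (class,
donor) — classes need ≥ 10 cells in ≥ 2 donors — normalises to 10k,
log-transforms, rank-tests each gene (Wilcoxon, BH within class) against
all other classes, gates at mean natural-log fold change > 1.25 and
adjusted p < 0.05, discards the global top 1% of genes by dispersion
(variance/mean within class, averaged across classes), and balances lists
by truncation. Spot composition is then a non-negative least-squares fit
of each spot's normalised marker expression onto the per-class mean
profiles, renormalised to sum to 1. This NNLS step is a deliberately
transparent stand-in for probabilistic deconvolution models: it preserves
the interface (spots × classes composition matrix) and suffices for the
composition tests, which use donor-by-layer averages and Wilcoxon
rank-sum with BH.

## Neighborhood decile enrichment

Per-spot gene-set scores (normalised expression, set mean minus a
2,000-gene control mean) are cut into global deciles — cut points are
type-7 quantiles over **all** spots pooled across age groups, so decile
labels are comparable between groups. For a group of spots, the observed
count of adjacent pairs with labels $\{i, j\}$ is compared to a null in
which labels are permuted independently within each array (arrays are
batches; permutation preserves each array's label multiset).
$z = (O - \bar O_{\mathrm{perm}}) / s_{\mathrm{perm}}$ with the sample
(n−1) standard deviation; cells with zero permutation variance are
flagged undefined rather than divided through. Pair counting is unordered
and the matrices symmetric.

## The power study

The power study asks: at a given expression level and fold change, how
often does the BF > 3 rule detect the difference? Levels follow the
field's working values — LOW 0.025, MEDIUM 0.6, HIGH 10 mean counts/spot
(the 20th, 90th and 99.9th percentiles of cortical spatial expression).
A level is interpreted as the ZIP **mean**, so the Poisson rate is
level/(1−θ); θ defaults to 0.1 and is a documented free parameter that
can be set from `mle_zip()` of a pilot dataset. Each replicate simulates
a control and a comparison group of square arrays (default 15×15 spots
across the 7 AAR bands — far smaller than a real capture array, which is
what makes the study desk-sized), fits the model with the variational
backend, and computes per-AAR Bayes factors plus a pooled "overall"
contrast (the mean of per-AAR differences, whose induced prior scale is
$\sqrt{2/7}\,\sigma_\beta$). Detection requires BF > 3 with the correct
sign; power is the detected fraction with a Wilson interval, and
non-converged replicates leave the denominator with a log. At reduced
array size a single AAR band holds ~30–45 spots, so per-AAR power is not
comparable to full-size arrays; the pooled contrast is the scaled-down
analogue and is the quantity the acceptance checks report. Power is
monotone in fold change and arrays/group, and LOW trails MEDIUM at
matched designs because dropout dominates.

## The synthetic-data generator

The generator is first-class, tested code. It emulates: ZIP counts with
AAR×group characteristic rates on square arrays with horizontal layer
bands (L1 at the top through white matter, mimicking cortical
lamination); spatial autocorrelation (white noise smoothed twice over the
rook neighbourhood and rescaled — a cheap stand-in for a proper CAR draw
that produces fields with realistic short-range correlation); iid spot
noise; planted coexpression programs and fold changes; a matched nuclei
cohort with per-class marker programs, lognormal depths, batch structure,
alternating sexes, and planted senescent subpopulations over-expressing
hallmark genes. Defaults are desk-scale (a few donors per group, 10–15
spot grids, hundreds to a few thousand genes) so the full suite runs in
minutes on one CPU.

What it does **not** emulate: the hexagonal capture lattice (a square
rook grid stands in; every consumer takes adjacency as input, so the
lattice choice is isolated), negative-binomial overdispersion beyond the
lognormal spot/depth effects, ambient RNA, doublets, segmentation errors,
or realistic gene-gene correlation beyond the planted programs. Passing
tests therefore demonstrate the *procedures* are correct and calibrated
under their stated model — not that the model captures every property of
real tissue.

## Numerical conventions and degenerate inputs

Percentiles are type-7 throughout (clipping, thresholds, deciles). All
generators and stochastic steps are deterministic given their seed, and
restore the caller's RNG state. Zero-variance genes correlate at 0 (with
a log); constant genes contribute 0 to module scores; all-zero spots get
a flagged uniform composition; constant score fields collapse to decile 1
with a degeneracy flag; all-zero count vectors leave λ unidentified
(flagged) with θ = 1 in the MLE, and prior-dominated in the Bayesian fit.
Ties in rank tests are mid-ranked. The Laplace covariance adds a small
ridge if the numerical Hessian is near-singular.

## Known limitations

Single-chain split-$\hat R$ is a weaker diagnostic than multi-chain
$\hat R$; genes are fitted independently, so users wanting stronger
assurance can refit flagged genes with more draws. The variational
backend understates uncertainty under strong spatial structure. The
Savage-Dickey KDE is biased by a few percent when the posterior is far
from zero (where the call is unambiguous anyway). The NNLS deconvolution
is a linear stand-in and should not be interpreted as a generative model
of spot composition.
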