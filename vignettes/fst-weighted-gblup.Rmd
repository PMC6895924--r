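---
title: "FST-prioritized SNP weighting in genomic relationship matrices"
author: "fstGBLUP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FST-prioritized SNP weighting in genomic relationship matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Genomic selection predicts breeding values of young, unphenotyped animals
from a genomic relationship matrix (GRM) estimated from SNP markers.
Beyond a moderate marker density the GRM stops changing: additive
relationships are already well estimated, and adding markers — up to
sequence density — buys essentially no accuracy. The premise of this
package is that the matrix can still be improved, not by adding markers but
by *reweighting* them so that the matrix measures genetic similarity at the
loci that matter for the trait rather than genome-average relatedness.

The prioritization signal is Wright's fixation index. A trait under
(artificial) selection drags allele frequencies at and around its QTL; the
same logic applies *within* a generation when its phenotypic extremes are
treated as two subpopulations. Animals in the lowest and highest tails of
the training-generation phenotype differ in allele frequency mostly at loci
linked to QTL, so a per-locus FST contrast between the tails ranks markers
by trait relevance without ever fitting marker effects.

## The model and the estimators

**Tail FST (Nei).** The training generation is split at the 5% and 95%
phenotype quantiles into a low tail S1, a middle S0, and a high tail S2.
With subpopulation frequencies $p_{S_1}, p_{S_2}$, tail sizes $n_{S_1},
n_{S_2}$, and the pooled-tail frequency $p$:

$$
H_T = 2pq, \qquad
H_S = \frac{n_{S_1} H_{S_1} + n_{S_2} H_{S_2}}{n_{S_1}+n_{S_2}}, \qquad
F_{ST} = \frac{H_T - H_S}{H_T},
$$

with $H_{S_i} = 2 p_{S_i} q_{S_i}$. $F_{ST}\in[0,1]$ by concavity of
$2pq$; loci monomorphic in the pooled tails are assigned 0 so they can
never be prioritized. Whether $H_T$ should use pooled-tail or
whole-generation frequencies is genuinely open; we use pooled tails
(consistent with the size-weighted $H_S$ and with S0 being excluded from
the scan) — `fst_scores()` accepts any genotype set, so the alternative is
available by passing the full generation as both tails' host matrix.

**Relative weights.** Scores become relative weights
$w_i = F_{ST,i} / \sum_j F_{ST,j} \times N$, which sum to the panel size
$N$ (mean weight 1). Group-budget scenarios assign $x\%$ of the total
weight to the top-$k$ SNPs and $(100-x)\%$ to the remainder; within each
group the budget is spread equally by default. A budget scenario fixes
only how much total weight each group carries, not how it is distributed
inside a group; equal within-group spreading is the simplest choice
consistent with the score-proportional scheme being its own separate
scenario, and `within = "fst"` implements the alternative.

**Weighted GRM.** With dosages $M$, centering $Z = M - 2P$, and weights
$w$:

$$
G = \frac{Z\,\mathrm{diag}(w)\,Z'}{2\sum_i w_i p_i q_i}.
$$

All-ones weights give exactly VanRaden's first method. We normalize by the
*weighted* heterozygosity sum (the unweighted alternative is a plain
argument change): this keeps the expected diagonal near 1 under any budget
and makes $G$ invariant to rescaling all weights by a constant, which the
tests assert. Centering frequencies default to the analyzed
(training + validation) individuals; base-generation frequencies can be
supplied instead.

**GBLUP / AI-REML.** The animal model is $y = Xb + u + e$ with
$u \sim N(0, G\sigma_u^2)$, $e \sim N(0, I\sigma_e^2)$, intercept-only $X$
by default (the simulated trait has only an overall mean). Variance
components maximize the restricted likelihood via average-information
updates; whenever the AI proposal leaves $[10^{-8}\,\mathrm{var}(y),\,
10\,\mathrm{var}(y)]$ an EM-flavoured step
$\theta_i + \theta_i^2(y'PA_iPy - \mathrm{tr}(PA_i))/n$ is taken instead.
The training block of $G$ is eigendecomposed once, making each iteration
$O(n)$. Convergence requires relative parameter changes below $10^{-8}$
and a score norm below $10^{-6}$ (components pinned at the variance floor
are exempt — a boundary optimum is an optimum); non-convergence after 50
iterations is flagged, not raised. The reported deviance uses the
convention $-2\log L_R = \log|V| + \log|X'V^{-1}X| + y'Py +
(n-p)\log 2\pi$, so only differences between fits on the same data are
meaningful across software.

Before inversion $G$ is blended as $0.99\,G + 0.01\,I$ (argument `blend`):
weighted or top-only panels can make $G$ singular, and the blend keeps the
model well posed with negligible effect on estimates.

Breeding values for *all* individuals in $G$ — including unphenotyped
validation animals — come from the BLUP identity
$\hat u = \sigma_u^2\,G[\cdot,\mathrm{train}]\,V^{-1}(y - X\hat b)$. This
is algebraically identical to solving the joint mixed-model equations over
training plus validation, but needs one eigendecomposition instead of a
dense inverse of the full $G$; a unit test checks equality with a dense
MME solve to $10^{-8}$.

**Evaluation.** Accuracy is the correlation between true and predicted
breeding values in the validation generation; dispersion bias is the OLS
regression of GEBV on TBV (slope 1 = no shrinkage bias).

## What the simulator emulates

`simulate_population()` stands in for a large forward-in-time breeding
simulation:

* a randomly mated **historical population** (default 120 generations of
  200, then expansion through 400/800/1600) with all loci initialized at
  frequency 0.5 and recurrent mutation at $10^{-5}$ — drift against
  recombination builds linkage disequilibrium, after which the expansion
  freezes it;
* a **base population** founded by 100 males and 1500 females (the 1:15
  sex ratio of large cattle designs) sampled from the last historical
  generation; G0 is bred by random mating;
* seven **selected generations** (G1–G7) of 3000 offspring each, one
  progeny per mating, 50% male births; each generation the bottom 50% of
  the sire pool and 20% of the dam pool are replaced by the top-ranking
  candidates;
* a fully additive trait: 100 QTL placed on the same equidistant locus
  grid as the 20,000 SNPs (so positions never coincide), effect
  magnitudes i.i.d. Gamma(0.4, scale 0.15) with random sign, QTL never
  genotyped.

Parent ranking uses a pedigree-index EBV, $h^2(y - \bar y_{gen}) +
\tfrac12(\mathrm{EBV}_{sire} + \mathrm{EBV}_{dam})$ — a cheap BLUP
surrogate that produces sustained directional selection without a
mixed-model solve per generation; `selection = "phenotype"` and
`"random"` are available (the latter turns the design into a drift
control, used in the tests).

**Heritability scaling.** The genetic variance realized by 100 Gamma draws
is random, so all QTL effects are rescaled by one common factor to make
the founder TBV variance exactly $h^2 V_p = 0.3$, and
$\sigma_e = \sqrt{(1-h^2)V_p} = \sqrt{0.7}$. Scaling effects (rather than
only the residual) is the only way to satisfy both the heritability and
the phenotypic-variance target simultaneously; the realized base-generation
$h^2$ then fluctuates around 0.30 only through sampling (verified at
$\pm 0.05$ over five replicates in the acceptance suite).

**What the defaults do not reproduce.** The reduced scale (2 chromosomes
× 100 cM, 20K SNPs, 3000 animals/generation) preserves the full-scale
design's *ratios* — markers:QTL (200:1), top-k:panel (5%),
training and validation sampling fractions (2/3 and 1/3 of a generation),
sire:dam ratio — but not its absolute sizes. Consequences: founder
adjacent-marker $r^2$ comes out near 0.2 rather than the 0.3 of the
full-scale design (drift LD at desk-scale effective population size);
absolute accuracies are higher (~0.8 vs ~0.7) because relationships are
stronger in a small population; and relationship histograms have more
mass in the outer bins. Directional conclusions — weighted-top
prioritization increases training–validation genomic similarity and
accuracy, shrinkage slope < 1, deviance favours weighted matrices — are
scale-stable and are what the tests assert. Real-data features the
generator does not attempt: genotyping error, missing genotypes,
non-additive gene action, sex chromosomes, overlapping-generation
phenotyping, population admixture.

## Numerical choices

* Haplotypes are stored as 1-byte raw matrices; Gram matrices accumulate
  over column chunks — a full default-scale replicate peaks below ~2 GB.
* Crossovers: Poisson count per chromosome (mean = map length in Morgans),
  uniform placement, no interference; loci sit on an equidistant grid so
  crossover positions map to locus indices directly.
* Tail partition uses order statistics with ties broken by ascending id,
  giving exact tail counts $\lfloor q n\rfloor$ deterministically; a
  zero-variance phenotype vector is rejected as degenerate.
* Monomorphic loci: retained and flagged in genotypes, FST 0, dropped
  (with a message) from relationship panels.
* Histogram bins are left-open/right-closed around the conventional cuts
  ±0.05/±0.03/±0.01.
* REML starts from $\sigma_u^2 = \sigma_e^2 = \mathrm{var}(y)/2$;
  variances are floored at $10^{-8}\mathrm{var}(y)$.
* Replicate $r$ of a study is seeded as
  `(base_seed %% 2e6) * 1000 + r`, so any replicate can be reproduced in
  isolation.

## Problem sizes used by the test and acceptance runs

Unit tests run on miniature designs (hundreds of loci, tens to hundreds of
animals). The acceptance suite uses the default reduced design: five
base-generation replicates for calibration; a 2000-animal,
3000-marker kinship for REML recovery (ten replicates); five full
replicates of the scenario study for the headline accuracy comparison
(scenarios equal, (100,0), top-FST); and one full replicate across all
nine scenarios for the shrinkage-direction check. These sizes were chosen
so the whole study runs on a single CPU in minutes while keeping the
design ratios above.

## Known limitations

* The FST scan assumes biallelic dosages and two tails; Weir–Cockerham or
  Hudson estimators, multi-allelic loci and window smoothing are out of
  scope.
* Weights are computed once from the training tails — no iterative
  reweighting from estimated marker variances.
* The REML fitter handles one genomic random effect plus residual;
  multi-trait models, repeated records and single-step (pedigree +
  genomic) evaluation are not provided.
* Absolute deviances are comparable only within this package's constant
  convention.
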