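---
title: "Inferring selection on mitochondrial haplotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring selection on mitochondrial haplotypes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitosel)
```

## The problem

Replicated experimental evolution offers a direct test of whether
mitochondrial DNA variation is selectively neutral. The setting `mitosel`
addresses is a seed-beetle style design: three mitochondrial haplotypes
(BRA, CAL, YEM) seeded at exactly equal frequencies (1/3 each) into
replicate populations on each of three nuclear genetic backgrounds, evolved
under two thermal regimes (a warm regime for 36 generations, a cold one for
23, reflecting the temperature dependence of generation time), with
end-point haplotype frequencies read out by pool sequencing and lifetime
reproductive success assayed early and late. The full factorial design is
3 nuclear backgrounds x 2 thermal regimes x 2 maternal-line replicates x 2
technical replicates = 24 lines; the default realized design drops one
warm-regime line (23 lines), mirroring a line lost during culturing. The
evolving line is the unit of replication throughout: drift is expected to
be substantial for mtDNA and is absorbed into the residual of every test.

## The selection model

Because mtDNA is effectively haploid and maternally inherited, haplotype
frequencies follow the haploid selection recursion

$$p_i(t+1) = \frac{p_i(t)\,W_i}{\sum_j p_j(t)\,W_j},$$

with $W_i$ the per-generation relative fitness of haplotype $i$. With
constant $W$ the recursion has the closed form
$f_i(t) = f_i(0) W_i^t / \sum_j f_j(0) W_j^t$, which `simulate_wf_trajectory()`
reproduces in deterministic mode and which serves as the oracle for the
estimator. `relative_fitness()` inverts it: given end-point frequencies
after $t$ generations,

$$r_i = \left(\frac{f_i(t)}{f_i(0)}\right)^{1/t}, \qquad
  W_i = \frac{r_i}{\sum_j f_j(0)\, r_j}.$$

The recursion as printed is a one-generation update and does not by itself
say how to treat end-point data; we adopt the per-generation geometric
solution because it solves the iterated recursion exactly and puts $W$ on a
per-generation scale (deviations of order 0.01 for this design), and we
normalize so that initial mean fitness is 1 ($\sum_j f_j(0) W_j = 1$),
which makes $W$ invariant to rescaling of the fitness vector. A
`one_step` mode (ratios not taken to the $1/t$ power) is kept for
sensitivity analysis; it ignores $t$ entirely and is not the default.
A haplotype at frequency zero yields $W = 0$ with a warning rather than an
error — loss is a real outcome of drift. The average per-generation
frequency change $\Delta f_i = (f_i(t) - 1/3)/t$ is reported alongside;
from a uniform start it ranks haplotypes identically to $W$.

## Pool-seq frequency estimation and the gene bias filter

Haplotype frequencies are estimated from reads that map uniquely, without
mismatch, to exactly one of the three mitogenomes, summarized as counts per
sample x protein-coding gene x haplotype. Control samples constructed to
contain each haplotype at exactly 1/3 calibrate the procedure: per gene and
control sample, a goodness-of-fit chi-square (df 2) tests the observed
counts against the known expectation, p-values are Benjamini–Hochberg
adjusted across the 13 genes within each control sample, and a gene is
retained only when its adjusted Q exceeds 0.05 in *every* control sample —
a gene significant in any control is treated as mapping-biased and dropped
rather than corrected. Two conventions here are ours, since "FDR" alone
does not pin them down: BH as the FDR procedure, and adjustment within
control samples (13 tests each) rather than across the pooled 39; the
within-sample choice keeps each control's calibration self-contained and
marginally more conservative through the all-samples retention rule.

The frequency estimate is the unweighted mean over retained genes of the
per-gene read proportions (renormalized against floating-point drift) —
mean of proportions rather than pooled counts, so a high-coverage gene
cannot dominate, at the price of a slightly higher variance than
coverage-weighting would give. `gene_consistency()` reports the mean
across-sample correlation of per-gene estimates as the diagnostic a
practitioner would eyeball before trusting the mean.

## Compositional ANOVA

Per-line fitnesses sum to a constant ($\sum_h f_h(0) W_h = 1$), so the
lines x 3 fitness matrix has rank 2 and an omnibus test on the raw columns
would be degenerate. `fitness_pca()` performs PCA on the correlation matrix;
the third eigenvalue is numerically zero and the first two components carry
100% of the variance. Each component's sign is fixed by making its
largest-magnitude loading positive, so results are invariant (up to that
convention) to haplotype column order.

The two PC scores per line are treated as the non-focal within-subject
responses of a repeated-measures layout with the line as subject.
`rm_anova()` computes the focal between-subjects tests — thermal regime,
nuclear background, and their interaction — on the per-line mean of the two
responses, the standard between-subjects stratum of an RM-ANOVA; on the
realized 23-line design this gives the expected error df of
$23 - 6 = 17$. Type III sums of squares with sum-to-zero coding are used
because the lost line unbalances the design (on balanced designs Type III
and sequential SS agree exactly, which the tests verify). The
within-subjects stratum is non-focal and not reported.

`permutation_test()` supplies distribution-free p-values: whole lines are
reassigned to treatments uniformly at random (unrestricted across both
factors, since nothing in the design ties a line to a regime under the
null; a `strata` argument allows restricted schemes), the Type III F is
recomputed each time, and $p_{rand} = (1 + \#\{F^* \ge F\})/(n_{perm}+1)$.
When the design admits no more distinct assignments of responses to cells
than `n_perm`, the test enumerates all of them and is exact. The
permutations run on an internal QR-projection engine that reproduces
`car::Anova` type III F values to numerical precision (cross-checked in the
test suite) at a tiny fraction of the cost, which is what makes 9,999
permutations — and the null-calibration simulations in the tests —
inexpensive. `per_haplotype_anova()` fits the same two-way fixed-effects
model to each haplotype's fitness separately; the three models are
correlated by construction and are follow-ups, not an omnibus test.

## Linking frequency change to reproductive fitness

Lifetime reproductive success (LRS) is the lifetime number of fertile eggs
in a competitive assay. Female assays house two focal females against one
focal male in male assays, so female counts are divided by two before any
averaging. For each mtDNA-mix line and sex, relative fitness at assay
generation $g \in \{3, 33\}$ is the line's mean adjusted count divided by
that of the CAL pure line (the genotype expected to be fittest; replicate
CAL pure lines are averaged), and $\Delta W = W_{33} - W_3$ is the change
over the experiment.

`pls_first_dimension()` relates the two-column $\Delta W$ block (male,
female) to the three-column $\Delta f$ block. $\Delta f$ is compositional
(zero-sum), which partial least squares tolerates. Both blocks are
mean-centered and scaled to unit variance — the scaling is our choice, made
for scale invariance, as common PLS software defaults do the same — and the
first pair of loadings are the leading singular vectors of the cross-
covariance matrix $X_s^\top Y_s/(n-1)$. The covariation captured by the
first dimension is $d_1^2 / \sum_k d_k^2$ in the singular values; this is a
cross-covariance fraction, one of at least two quantities that could be
called "% covariation explained", and we document it rather than treat any
published figure as a target. `bootstrap_pls()` resamples lines,
re-estimates the dimension, flips any replicate whose loading vector points
against the point estimate (the latent axis is defined only up to joint
sign; without this correction bootstrap summaries mix orientations and
collapse toward zero), and reports bootstrap SEs, $t = $ estimate/SE with
$n - 1$ df, and bias-corrected percentile intervals.

## Mitogenome divergence

`align_and_call()` aligns the three mitogenomes by globally aligning each
to the first (the reference) with affine-gap pairwise alignment and
projecting onto reference coordinates — at the ~1% divergence of
conspecific mitogenomes this reference-anchored merge is effectively
exact, and a `prealigned` path accepts an existing alignment verbatim.
Ungapped columns with two or more states are SNP sites (a three-state
column is one site, matching site-wise reporting); maximal runs of gap
columns with a constant gap pattern are single indel events. Each SNP is
partitioned by which haplotype it separates. `classify_substitutions()`
reconstructs every genome's codon from the alignment, reverse-complements
minus-strand genes, translates under the invertebrate mitochondrial code
(NCBI table 5 — unstated in most reports but forced by the organisms), and
calls a site synonymous only when all observed codons encode the same amino
acid; premature stops are nonsynonymous and flagged. Pairwise nucleotide
diversity $\pi$ is the per-site difference proportion over ungapped
columns, for the whole alignment or protein-coding genes only (both are
provided since published values rarely say which).

## The synthetic-data generator

Because the analysis chain must be testable without sequencing archives,
`simulate_experiment()` generates studies with the structure the analysis
assumes, at the study's own scale, fixed once:

* **Drift population.** Selection update followed by multinomial
  resampling of `n_females = 300` maternal lineages — mtDNA passes only
  through females, and lines were kept near 600 adults, so 300 transmitting
  females is the natural default. The realized and effective maternal
  population sizes were never measured, so this is the one genuinely free
  parameter of the generator; it is configurable and all drift-sensitive
  conclusions in the tests are stated for 300.
* **Planted fitness.** Per-(thermal, nuclear) cell fitness with overall
  rank CAL > BRA > YEM at per-generation means of about 1.010, 0.999 and
  0.991, plus cell deviations: BRA favoured in the cold regime, CAL and YEM
  in the warm, and a small native-background advantage at 35C (mitonuclear
  coadaptation). These magnitudes make selection and drift comparable in
  size, which is precisely the inferential difficulty the chain must cope
  with.
* **Pool-seq.** Two-stage sampling: a pool of 100 individuals drawn from
  the line, then per-gene Poisson read totals (mean 900 per gene, ~12k
  informative reads per sample over 13 genes — the scale implied by 60x
  effective coverage of mismatch-free uniquely mapping reads) allocated
  multinomially with per-gene, per-haplotype bias multipliers. Both stages
  contribute variance; control samples skip the pool stage because control
  pools are assembled, not sampled. Bias factors default to 1 and exist so
  the filter has something to catch.
* **Phenotypes.** Egg counts are log-normal (assay residual SD 0.4 on the
  log scale, ~19 assays per line x sex x generation cell); a mix line's
  log-mean is the composition-weighted mean of per-haplotype effects plus
  line, sex and generation terms, and females carry a log(2) offset undone
  by the halving adjustment.
* **Seeding.** One root seed; per-line streams derived deterministically
  from (seed, line id), so results are independent of iteration order and
  reruns are byte-identical.

What the generator does *not* emulate: real mapping bias structure (ours is
a constant multiplier per gene), heteroplasmy, selection changing over
generations, frequency dependence (constant $W$ is the model's own
assumption), non-log-normal assay tails, or any correlation between a
line's sequencing noise and its phenotype noise. Passing tests therefore
show that the chain recovers what it assumes, at the study's noise scale —
not that those assumptions hold in any particular dataset.

## Numerical choices and power

Degenerate inputs are handled explicitly: constant responses give F = 0 and
permutation p = 1; zero-variance fitness columns are an error naming the
haplotype; genes with zero reads are dropped per sample with a warning and
never retained by the filter; bias-corrected intervals collapse to the
point when the bootstrap distribution is degenerate; bootstrap replicates
with degenerate rank are dropped and counted, with a warning past 10%.
Bias-corrected (BC, not BCa) percentile intervals are used wherever the
bootstrap appears. Permutation and exact-enumeration comparisons use a
relative tolerance of 1e-8 on F to keep ties stable.

A power note from the package's own simulations: with drift at
$N_f = 300$ over 23–36 generations, the standard deviation of a line's
estimated per-generation $W$ is about 0.01 — the same order as the
selection coefficients of interest. Sign recovery of planted effects and
detection of a 0.02-per-generation pairwise contrast are reliable across
experiments; a 0.01 contrast between two haplotypes is detected in well
under half of replicate experiments. Claims about the weaker contrasts in
any single experiment of this size lean heavily on the replication across
lines. Haplotype-loss events compound this: once a declining haplotype is
rare enough to be missed by a pool of 100 individuals, its estimated
frequency is exactly zero, it receives $W = 0$, and the normalization
pushes the two surviving haplotypes' $W$ far above one for that line —
single loss events can therefore reorder the mean fitnesses of haplotypes
whose true per-generation difference is below about 0.01, and the
package's own recovery simulations show the weakest planted ranking
flipping in roughly a fifth of experiments at these settings.

Test and simulation sizes used by the package's checks (chosen to keep a
full run in the low minutes on one core): 1,000 random draws for the
recursion round trip, 200 simulated studies for ranking recovery, 1,000
seeds for null p-value calibration (with 199 permutations each), 500 seeds
for PLS null-interval calibration at 1,000 bootstrap replicates, and 100
seeds for filter calibration and power.

## A worked run

```{r, eval = FALSE}
sim <- simulate_experiment(seed = 1)
res <- run_pipeline(sim$design, sim$counts, sim$controls,
                    config = pipeline_config(n_perm = 9999, n_boot = 9999,
                                             seed = 1))
res$bias$genes_retained     # genes passing the control-sample filter
colMeans(res$fitness$W)     # per-haplotype mean relative fitness
res$rm_anova                # thermal / nuclear / interaction tests
res$permutation             # permutation p-values for the same sources
```

## Known limitations

* Relative fitness is inferred from two time points only; no time-series
  or likelihood treatment of drift plus sequencing noise is attempted, so
  $W$ is an exact inversion of the deterministic recursion, not a
  drift-aware estimate.
* The mixed-model treatment of assay-level LRS (random line regressions)
  is out of scope; only the group means feeding $\Delta W$ are computed.
* The aligner is built for near-identical mitogenomes; diverged inputs
  should come pre-aligned.
* The permutation scheme is unrestricted by default; whether a restricted
  scheme is more appropriate depends on how lines were physically assigned
  to regimes.
* The bootstrap test "loading CI excludes zero" is anticonservative when
  there is truly no X–Y link: loadings are components of unit-norm
  directions, so they are bounded away from zero even under independence,
  and the sign-alignment step concentrates the bootstrap distribution
  around the point estimate. The package's own null simulations (in the
  test suite) find far more than 5% of 95% intervals excluding zero under
  independence at 11 lines. Treat these intervals as uncertainty summaries
  for the loadings, not as a test of whether any association exists; a
  permutation test of the first singular value would be the calibrated
  alternative.
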