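---
title: "Mosaic aneuploidy, abnormal cleavage, and embryo arrest: models and design notes"
author: "mosaicArrest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mosaic aneuploidy, abnormal cleavage, and embryo arrest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicArrest)
```

# Scope

`mosaicArrest` simulates IVF embryo cohorts carrying meiotic and mitotic
(mosaic) aneuploidies, produces the binned low-coverage read counts a
PGT-A platform would report for trophectoderm (TE) biopsies and whole
arrested embryos, calls copy number from fractional read-depth
displacement, classifies event origin, and models the probability of
developmental arrest. This vignette documents the models, the tunable
parameters, the numerical choices, and the places where the design was
genuinely open.

# The displacement model and origin classification

Low-coverage sequencing of a multi-cell sample measures an average: the
expected count in a genomic bin is proportional to the mean copy number
of that bin's chromosome arm across the sampled cells. After dividing by
bin width and by the per-sample median over autosomal bins, a bin ratio
of 1.0 is the disomic expectation and the estimated chromosome copy
number is `2 * trimmed mean` of its bin ratios (10% trimmed at each tail,
which keeps a single CNV- or breakpoint-contaminated bin from dragging a
whole chromosome). Displacement is

$$ d = |\hat c - 2| \times 100 $$

in percent of a full single-copy change. A constitutional (meiotic)
trisomy present in every cell displaces by ~100%; a mosaic event present
in a fraction $f$ of sampled cells displaces by exactly $100f$ in the
noise-free limit — a linearity the test suite checks bin-exactly for all
biopsy compositions up to 10 cells.

Classification applies fixed thresholds to whole-autosome calls:
$d < 30$ is a normal disomy, $30 \le d \le 70$ is mitotic (mosaic),
$d > 70$ is meiotic. Both boundary values are assigned to the mitotic
range; that is a deliberate, documented reading of "the 30–70% range",
and a `1e-6` guard on the comparisons keeps exact boundary fractions
(3 of 10 cells = 30%) from being moved across a threshold by floating-point
rounding. Sex-chromosome and segmental calls are emitted but never
stratified into meiotic/mitotic: their baseline expectations are less
certain (sex must itself be inferred; arms have fewer bins), so they
carry `origin = "not_classified"` and never influence the five-category
assignment.

Two caveats are intrinsic to bulk displacement and are reproduced rather
than hidden by this package:

* a uniform ploidy change (triploidy, tetraploidy) rescales every bin and
  is invisible after median normalization — the simulator's
  scale-invariance test documents this;
* when many autosomes are displaced at once the median baseline itself is
  biased; profiles in which fewer than half the autosomes look disomic
  are flagged `baseline_unreliable`.

Segmental detection works at arm scope: an arm displaced ≥ 30% while its
sibling arm is < 30% yields a segmental call, and a whole-chromosome call
(both arms displaced in the same direction) suppresses segmental calls on
that chromosome. A binary-segmentation step exists for locating sub-arm
changepoints, but detected changepoints are merged up to arm scope — the
minimum reportable segment is one full arm, matching the arm-scale events
the displacement model can support at this coverage.

# The cohort simulator

The generator's defaults are the study conditions the package emulates,
not free dials: 125 patients, ~1.32 cycles per patient (165 cycles in
expectation), maternal age Normal(38.9, 3.5) truncated to [30, 45] years,
and 7.2 normally fertilized zygotes per cycle on average.

**Meiotic channel.** Each embryo carries at least one meiotic error with
probability $\mathrm{logit}^{-1}(\beta_0 + 0.261\,(\text{age} - 38.9))$;
the age slope 0.261 per year is a study condition. Affected chromosomes
are drawn by weights elevated fourfold on chromosomes 15, 16, 19, 21 and
22 (the small/acrocentric excess typical of maternal meiotic error), each
event a whole-chromosome gain or loss. The intercept $\beta_0 = 1.15$ was
calibrated once so the cohort-level category frequencies resemble the
reference tabulation; the count of affected chromosomes is
1 + Poisson(0.6).

**Mitotic channel.** Mitotic aneuploidy is never drawn as a per-embryo
label; it is produced mechanically by a clone-compressed cell-lineage
simulation:

* *normal division* copies each chromosome to both daughters, with a
  reciprocal missegregation probability of 0.0015 per chromosome per
  division (one daughter gains, the other loses — total copy number is
  conserved, a property the tests assert for whole rounds);
* *multipolar division* scatters the replicated chromatid complement
  (2 × copy per chromosome) uniformly over 3–4 poles, producing
  hypodiploid, partially complementary daughter clones;
* *precocious cleavage* is a normal split followed by a premature second
  division (three cells, usually normal karyotypes);
* *reverse* and *failed cleavage* leave a single tetraploid-like cell;
  polyploid cells subsequently divide multipolar with probability 0.9
  per round, which is what converts an invisible 4N state into a
  detectable chaotic mosaic;
* abnormal patterns occur at 26% of first and 9.7% of second divisions
  (study conditions), with pattern weights (multipolar 0.35, precocious
  0.11, reverse 0.27, failed 0.27) chosen so that about 10% of embryos
  show a 1→3 first division.

Growth rounds divide each cell with probability 0.82 scaled by a
fitness factor (0.5 per nullisomic, 0.92 per monosomic, 0.97 per trisomic
autosome, floored at 0.3). These two choices matter more than they look:
bulk sequencing can only see mosaicism when clone proportions are
*unequal*, and both the stochastic growth and the fitness differences are
what drive clones apart. For arrested embryos an additional attrition
step removes each cell with probability 0.45 before the whole embryo is
processed, emulating the cell degeneration that accompanies arrest; this
too unbalances clone proportions and is the main reason simulated
arrested embryos, like real ones, rarely present perfectly balanced
(hence invisible) reciprocal mosaics.

**Outcome model.** Arrest is Bernoulli with
$P = \mathrm{logit}^{-1}(b_0 + b_1 n + b_2 a + u)$, where $n$ is the
number of whole autosomes whose population mean copy deviates by ≥ 0.3
copies from disomy *relative to the median autosomal ploidy* (read depth
is scale-free, so a pure 4N lineage contributes $n = 0$), $a$ indicates
any abnormal first/second division and $u$ is a Normal(0, 0.4) patient
intercept shared across a patient's cycles. The defaults
$b_0 = \mathrm{logit}(0.16)$, $b_1 = 0.75$, $b_2 = 1.0$ were calibrated
once so the marginal arrest frequencies land near 0.16 for euploid
lineages, ≈ 0.36 for meiotic-only embryos, 0.55–0.64 for
mitotic-containing categories, and ≈ 50% blastulation overall. Arrested
embryos receive a stage (early ≤ 10 cells; mid > 10 pre-compaction; late
up to early blastocoel), earlier for more abnormal lineages; blastocysts
receive ICM/TE grades from a shared latent score cut into A–D (shifted
toward D by aneuploidy, reproducing a steep gradient of aneuploidy across
grades) and a biopsy day drawn from day-5/6/7 probabilities whose means
differ by exactly 0.22 days between aneuploid and euploid embryos.

**Sampling and reads.** Blastocysts contribute a TE biopsy of 5–10 cells
taken as a *contiguous window* in lineage order — biopsies are spatially
clustered cells, so clonal sampling is realistic rather than
hypergeometric. Arrested embryos are processed whole. Expected bin counts
are `depth × (width/bin_size) × copy/2` with negative-binomial noise
(overdispersion 0.01 at depth 100 reads per 1-Mb bin); 3.2% of samples
are marked QC-failed and corrupted. The caller independently excludes
samples whose first-order-difference noise score exceeds 0.15 or whose
autosomal median is zero, mirroring exclusion for excessive noise or lack
of DNA.

# What the generator emulates, and what it does not

It emulates: the patient/cycle hierarchy with shared patient effects,
age-dependent meiotic error with chromosome bias, cleavage-driven mosaic
aneuploidy whose biopsy displacement distribution *emerges* from lineage
sampling (it is never imposed), whole-arrested versus TE-biopsy sampling
asymmetry, morphology and biopsy-day consequences, and sequencing QC
failures.

It does not emulate: GC or amplification bias (counts are exchangeable
across bins given copy number, so the caller needs no GC correction — a
hook exists in the normalization step), time-lapse imagery (division
patterns are symbolic), triploidy as a callable state (only as the
scale-invariance negative control), uniparental disomy, or
parent-of-origin. Passing tests therefore demonstrate the *logic* of the
pipeline under the stated noise model, not robustness to platform
artifacts of real libraries. The simulated five-category table is
qualitatively faithful (aneuploidy dominates arrested embryos; mosaic
events concentrate there) but overweights meiotic-only embryos relative
to the reference tabulation; the calibration deliberately prioritized the
arrest-rate structure over matching every cell of that table.

# Statistical machinery

`fisher_exact()` implements the two-sided exact test by probability-mass
ordering (with the conventional `1 + 1e-7` tie guard) and reports the
conditional maximum-likelihood odds ratio — solved from the noncentral
hypergeometric mean equation $E_\psi[A] = a$, which is monotone in
$\psi$ — together with the exact conditional CI (tail probability
$\alpha/2$ at each bound, one-sided at the boundary) and, since
conventions differ, the sample odds ratio $ad/bc$ as well. The test suite
verifies p-values against full enumeration for every 2×2 table with
$N \le 40$ and the conditional MLE against an independent
likelihood-maximization oracle exhaustively to $N \le 20$.

`fit_quasi_glm()` wraps quasi-binomial/quasi-Poisson GLMs (dispersion =
Pearson $\chi^2/\mathrm{df}$, SEs scaled by its square root) and flags
separation instead of returning an unbounded slope. No multiple-testing
correction is applied anywhere; reported p-values are unadjusted, and the
report says so.

`fit_binomial_glmm()` maximizes the marginal likelihood of a
random-intercept binomial GLMM by adaptive Gauss–Hermite quadrature: per
group, a Newton step finds the conditional mode, the integrand is
rescaled by the mode's curvature, and 15 nodes (Golub–Welsch) integrate
it; one node is exactly the Laplace approximation. Fifteen nodes is the
default because the per-group data here are small (a handful of embryos
per patient), where fixed-node quadrature is the regime that needs care;
with more than 50 groups of more than 200 observations the fit falls back
to Laplace with a warning, which in that regime is accurate and much
cheaper. The log-likelihood includes the binomial normalizing constant,
so values are comparable across node counts and against lme4 on Bernoulli
data — the suite checks both, plus CI coverage for known parameters over
200 small replicates (30 patients × 8 embryos).

Average marginal effects are computed on the probability scale by
integrating the inverse-logit response over the *estimated population*
random-effect distribution with the same nodes, differencing categorical
levels against the euploid reference (chosen as baseline to match the
presentation of arrest by category) or averaging the derivative over
observed values for numeric predictors. CIs come from the delta method
over $(\beta, \log\sigma)$, with a parametric option that redraws the
parameter vector from its estimated sampling distribution (1000 seeded
draws) — a fast parametric bootstrap of the estimator rather than a
refit-per-draw bootstrap, which the delta-vs-bootstrap agreement test
justifies at these sample sizes. The biopsy-day model is a REML
`lme4::lmer` fit; for a binary predictor its AME is the fixed coefficient.

# Numerical and design choices

* **Coordinates** are 0-based half-open throughout (BED-compatible). Bins
  tile each *arm*: the bin containing the centromere is truncated and a
  new bin starts at the centromere, so every bin maps to exactly one arm
  and arm-level calls are clean. Consequently the bin count per
  chromosome is the per-arm ceiling sum, e.g. 47 bins for chromosome 21
  at 1 Mb, and a bin size larger than a chromosome gives one bin per arm.
  Chromosome lengths and centromere positions are packaged constants
  (approximate GRCh38); no reference sequence is read. Neither the bin
  size (default 1 Mb) nor the genome build is dictated by the platform
  being emulated — both are explicit package choices.
* **Reproducibility.** All randomness flows from R's global RNG seeded
  once at `simulate_cohort()` entry from `config$seed`; the same seed
  reproduces cohorts, reports and the acceptance JSON byte for byte.
* **Trimmed mean** (10% per tail) for per-chromosome copy; plain means
  would be bin-exact too on the synthetic data, but the trim is the
  robustness hook for CNV/breakpoint bins on real-like data.
* **QC threshold 0.15** on the per-bin first-order-difference noise score
  (clean samples sit near 0.10 at the default depth/overdispersion;
  corrupted ones near 1), so the realized exclusion rate tracks the
  configured 3.2% flag rate.
* **Degenerate inputs.** QC exclusion is a value, not an exception:
  flagged, noisy, or zero-median samples return a `sample_calls` object
  with `qc_pass = FALSE` and a reason. Model blocks in the report that
  are unidentifiable on a degenerate cohort (single-level predictors,
  e.g. an all-euploid null run) are reported as `NULL`.
* **Tie-breaks.** Threshold comparisons carry a `1e-6` displacement
  guard; Fisher p-values use the standard `1 + 1e-7` probability-mass tie
  guard; GLMM convergence is declared by the optimizer with a 200-
  iteration cap and non-convergence is a flagged result.

# Problem sizes used by the checks

The test suite and acceptance script scale the Monte-Carlo work to what
the inference actually needs: one full-size cohort (125 patients, ~1200
embryos) for the end-to-end pattern checks; 50 replicates at 165 and 40
cycles for the meiotic/mitotic age-slope recovery; 200 replicates of 30
patients × 8 embryos for GLMM coverage; exhaustive enumeration to
$N \le 40$ (p-values) and $N \le 20$ (conditional MLEs) for the exact
test. These sizes are the package's own choices and are stated here so
they can be scaled up by anyone wanting tighter Monte-Carlo error.

# Known limitations

Balanced reciprocal mosaics in whole arrested embryos are invisible by
construction, as they are to the bulk assay itself. The caller's
specificity and sensitivity are only as meaningful as the
negative-binomial noise model; platform-specific wave artifacts, GC bias
and amplification dropouts are out of scope. The arrest model is a
single-equation logistic mechanism — adequate for recovering the
association structure it generated, but not a claim about embryonic
biology beyond the parameters stated above. Sex-chromosome segmental
events are not modeled. The quasi-Poisson complexity contrast and the
division-by-arrest odds ratio come out stronger in simulation than in
real cohorts because simulated chaotic lineages affect many chromosomes
at once; both are reported as computed, not tuned.
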