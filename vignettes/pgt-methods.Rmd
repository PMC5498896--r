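---
title: "Models and methods behind pgtqpcr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pgtqpcr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgtqpcr)
```

## The problem

Preimplantation genetic testing of IVF embryos usually relies on microarray
or sequencing workflows that take days and require freezing the embryo.
Because those workflows already whole-genome-amplify (WGA) the DNA of a
single blastomere or a few trophectoderm cells, the same WGA product can
feed much faster PCR assays. `pgtqpcr` implements three such assays and the
statistics needed to judge them against a reference method such as CGH:

1. **Melting-curve sex determination.** SRY (single-copy) and DYS14
   (multicopy, within TSPY) are Y-linked; their amplicons are read as
   present/absent from peaks in the negative first derivative of the
   SYBR-green melt trace, with GAPDH as amplification control. Any Y-marker
   detection suggests a male embryo (the *GSD index*).
2. **Amelogenin fragment-length sex typing.** A 6 bp insertion in intron 1
   of AMELY makes the Y amplicon 110 bp against AMELX's 104 bp; capillary
   electrophoresis peak tables are classified by AMELY presence, by an AMELY
   peak-height cutoff of 23.5 RFU, and by an X/Y height-ratio cutoff of
   21.8.
3. **Delta-Ct trisomy calling.** TTC3 (chromosome 21) and RPL17
   (chromosome 18) are quantified against the copy-neutral reference HSDB.
   An extra chromosome copy raises target dosage and lowers
   $\Delta Ct = Ct_\text{target} - Ct_\text{ref}$; a trisomy is called when
   $\Delta Ct$ falls at or below 3.85 (TTC3, Trisomy 21) or 0.985 (RPL17,
   Trisomy 18).

Because the raw single-embryo measurements behind the published summary
statistics are not public, the package pairs each caller with a synthetic
cohort generator that reproduces the error structure of single-cell WGA
material, so that every stage is testable end to end.

## The synthetic cohort

`simulate_karyotypes()` draws embryo ground truth: sex (default male
fraction 146/328), trisomy 18/21 status (defaults 9/43 and 13/43),
sample-level WGA failure (6/342), and two biologically documented
complications that dominate the sex-assay error budget:

* **Y-loss males** (`p_y_loss_in_males`, default 0.04): cytogenetically male
  embryos carrying no Y material, hence truly negative for SRY, DYS14 and
  AMELY. The default sits between the four CGH-confirmed Y-losses among 146
  males and the five double-negative males implied by the sex-cohort
  contingency table.
* **Y-fragment females** (`p_y_fragment_in_females`, default 0.02): XX-male
  type translocations placing Y material — and hence true Y-marker signal —
  in a cytogenetic female.

`simulate_locus_detections()` applies the per-locus error model: a present
locus drops out with probability ADO, an absent one appears with
probability FA. Defaults are the study rates (SRY 13.5%/0.5%, DYS14
5.2%/3.4%, AMELY 2.0%/6.3%); the GAPDH control fails with probability 8/342
in samples whose WGA succeeded. Under these defaults the analytic
expectation of GSD-index accuracy is about 94.6%, and the simulated value at
n = 5000 is tested to lie within two points of the reported 94.1%.

### Ct model

For target gene $g$ with copy number $c$,

$$\Delta Ct_g = \mu_g - \gamma_g \log_2(c/2) + \varepsilon_g,
  \qquad \varepsilon_g \sim N(0, \sigma_g),$$

with $\gamma_g$ drawn per embryo from $N(\bar\gamma_g, s_{\gamma,g})$. Under
ideal amplification $\gamma = 1$ and a trisomy shifts $\Delta Ct$ by exactly
$-\log_2(3/2) \approx 0.585$ cycles; the observed shifts are 1.4 (TTC3) and
1.7 (RPL17) cycles, i.e. WGA amplifies the dosage difference, so the
calibrated $\bar\gamma$ are $1.38/0.585 \approx 2.36$ and
$1.66/0.585 \approx 2.84$. The per-gene noise SDs equal the diploid-group
SDs (0.56, 0.80 cycles), and TTC3's between-embryo $s_\gamma$ is set so the
Trisomy-21 group SD is exactly the reported 0.99. Two calibration facts
cannot be represented and are knowingly left out: the reported Trisomy-18
RPL17 SD (0.53) is *smaller* than the diploid SD, which no non-negative
dispersion term can produce, and the reported trisomy-group sensitivities
(12/13, 8/9) exceed what any distribution with the reported group means and
SDs implies at the published cutoffs (for Trisomy 21,
$\Phi((3.85-3.39)/0.99) \approx 0.68$). Both are small-sample artefacts of
groups with 9–13 embryos; the tests therefore check simulated sensitivity
against the binormal closed form and simulated specificity against the
published values, which the calibration does imply.

The $\gamma$ draw is untruncated: truncating at zero would shift the
Trisomy-21 mean by ~0.08 cycles off its calibration target, and an
occasional sign-inverted draw mimics the real overlap between groups.

Raw Ct values anchor the reference gene at `ct_ref_base` (23.5 cycles at
15 ng) plus a sample-level WGA offset ($\sigma = 1.2$ cycles) shared by all
genes of a sample — so it cancels from every $\Delta Ct$, an invariance the
tests assert. The three-point standard curve (3.75, 7.5, 15 ng) follows
$Ct(m) = Ct(15) + \beta \log_{10}(m/15)$ with $\beta = -1/\log_{10} 2
\approx -3.32$ cycles/decade at 100% efficiency, plus 0.05 cycles of
per-well technical noise — enough to exercise the QC code while keeping
honest curves essentially always inside the $-3.3 \pm 0.4$ acceptance band,
matching a study that reported no slope failures. The sample offset and
`ct_ref_base` were chosen so raw target Ts cross the 30-cycle exclusion
threshold at roughly the study's observed rate (3 of 43 embryos).

### Melt and electropherogram models

A melt trace is a sum of logistic transitions on a linear baseline,
$F(T) = \sum_g A/(1 + e^{(T - Tm_g)/w}) + c_0 + c_1 T + N(0, \sigma)$, on a
60–95 °C grid in 0.2 °C steps. The negative derivative of one transition
peaks at $Tm$ with height $A/(4w)$, which makes peak calling analytically
checkable. The instrument publishes no reference Tm values, so the per-gene
defaults (GAPDH 87.5, SRY 84.0, DYS14 80.5 °C, consistent with the
amplicons' relative sizes) are deployment configuration. Noise is 0.15 RFU
against a transition amplitude of 100 RFU; at that signal-to-noise ratio
the default peak threshold (5% of the plate-wide maximum derivative) sits
roughly ten noise SDs above the baseline, as on real instrument traces.

Electropherogram peaks are lognormal in height. True alleles draw from
$\text{logN}(\log 300, 0.5)$; false-allele AMELY peaks from
$\text{logN}(\log 15, 0.7)$, i.e. mostly but not always below the 23.5 RFU
cutoff — which is precisely why the height rule rescues most FA females
while the presence rule cannot, the behaviour that motivated the cutoff in
the first place. Fragment sizes jitter by 0.15 bp around 104/110.

What the generator does **not** emulate: mosaicism (trisomy distortion is
carried entirely by $\gamma$), stutter or pull-up artefacts in
electropherograms, multiplexed wells with overlapping melt transitions, and
CGH hybridization itself (truth labels are taken as given). Passing tests
on simulated cohorts therefore demonstrate correctness of the calling and
evaluation machinery under this error model, not clinical performance on
real embryos.

## Numerical and design choices

* **Derivative estimation.** $-dF/dT$ uses degree-2 Savitzky–Golay
  smoothing-differentiation; ends are handled by the filter's one-sided
  fits. The default window is 5 points: the quadratic filter attenuates a
  peak by $\approx \tfrac{\sum j^4}{6\sum j^2} h^2 |F'''|$, which for a
  0.8 °C-wide transition sampled at 0.2 °C is 1.8% at window 5 but 3.5% at
  window 7 — the narrower window keeps the estimator within 2% of the
  analytic peak height while still suppressing instrument-scale noise.
* **Peak prominence** is measured against the lower of the two flanking
  minima; `melt_call()` applies the same threshold to height and
  prominence.
* **Boundary conventions**, which the sources state only as cutoff values:
  AMELY height strictly greater than 23.5 calls male; ratio at or below
  21.8 calls male; $\Delta Ct$ at or below the cutoff calls the trisomy;
  slope QC passes on the closed band $[-3.7, -2.9]$. Each boundary has a
  dedicated test.
* **Ratio denominator floor**: females lacking an AMELY peak get
  $X/\max(Y, 1)$, so the ratio is large but finite.
* **QC semantics**: a GAPDH-negative sample is *no result*, never female; a
  failed standard curve or a raw target Ct above 30 yields *excluded*,
  never a euploid call. Lowering the exclusion threshold can only exclude
  more samples (tested monotonicity).
* **Logistic category model.** Sex is regressed on SRY and DYS14 indicator
  variables by IRLS. With the three observed detection categories the model
  is saturated, so fitted probabilities equal empirical fractions — the
  package reports 4.7% (neither), 57.1% (DYS14 only) and 98.8% (both);
  the unobserved SRY-only cell is a flagged extrapolation. Complete
  separation is reported as an infinite odds ratio, not an error.
* **Diagnostics are written out in full**: Cohen's kappa from marginal
  products, odds ratios with Woolf (log) intervals and Haldane–Anscombe
  correction on demand, Mann–Whitney AUC on midranks with Hanley–McNeil
  standard errors, and Youden-optimal cutoffs searched over midpoints
  between adjacent distinct scores (ties resolved toward higher
  sensitivity, then the lower cutoff). Tests pin each statistic to a
  brute-force oracle (all-pairs AUC, exhaustive cutoff scan) and to
  independent implementations (`wilcox.test`, pROC).
* **Two FA denominators.** The study's printed false-allele rates divide
  spurious detections by *all* analyzed samples (7/204 = 3.4%), while the
  generative FA parameter is a per-absent-locus probability. `ado_fa_rates`
  reports both (`fa` and `fa_noncarrier`); the first reproduces the printed
  arithmetic, the second recovers simulator parameters. Rates are computed
  on control-positive samples only.

## Problem sizes in the test-suite and acceptance runs

The suite exercises the full melt pipeline (trace simulation, derivative
calling, sex classification, evaluation) at n = 5000 embryos, parameter
recovery at n = 10000 detections, Ct-panel calibration at n = 10000, and
the binormal AUC reproduction with the study's group sizes (21 vs 13) over
200 replicates; these sizes give binomial standard errors a few times
smaller than every tolerance they are tested against. `scripts/acceptance.R`
recomputes the category-logistic probabilities from the reconstructed
204-embryo table and the mean Trisomy-21 AUC from the same 200-replicate
design, all seeded from its `--seed` argument.

## Known limitations

* Sex calls are qualitative: sex-chromosome aneuploidies (XXY, X0, XXX,
  XYY) are out of scope, as in the underlying assays.
* The trisomy caller handles chromosomes 18 and 21 only, and double
  aneuploidy is reported as two positive flags without adjudication.
* The simulator's group distributions are normal/lognormal by construction;
  real WGA material shows occasional heavy-tailed failures that here are
  represented only through the sample-level failure and exclusion channels.
* DYS14's multicopy advantage is modelled through its lower ADO rate, not
  an explicit copy-number mechanism.
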