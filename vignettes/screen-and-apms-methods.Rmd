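---
title: "Methods: reporter-screen hit calling and AP-MS interaction scoring"
author: "screenomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reporter-screen hit calling and AP-MS interaction scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenomics)
```

# Overview

`screenomics` implements the analysis side of a dual-omics campaign for
discovering regulators of TLR7-driven IRF5 signalling: an arrayed siRNA
screen read out with a secreted Lucia luciferase reporter (an
ISRE-containing interferon promoter) and a CellTiter-Glo (CTG) viability
counter-screen, and affinity-purification mass spectrometry (AP-MS) of
FLAG-tagged IRF5 scored from spectral counts. This vignette documents
the statistical model behind each stage, the tunable parameters and
their defaults, what the synthetic-data generators do and do not
emulate, and the design decisions taken where the published analysis
left the procedure open.

# Plate quality control

Each 384-well plate carries non-targeting negative controls and a
pathway positive control (siTLR7-like, which suppresses the reporter
several-fold). Assay quality per plate and replicate is summarised by
the Z'-factor

$$Z' = 1 - \frac{3\,(\mathrm{SD}_{pos} + \mathrm{SD}_{neg})}
                {\lvert \mu_{pos} - \mu_{neg} \rvert},$$

with *sample* standard deviations (the HTS-community convention; the
choice of denominator is not dictated by the formula itself). A plate
is analysed only if $Z' > 0.2$, a strict inequality. Two open choices
are exposed as arguments rather than fixed:

* **Metric.** `qcPlates(metric =)` computes Z' on the normalized ratio
  `N = lucia/ctg` by default — the quantity hit calling operates on —
  or on the raw reporter channel (`"raw_lucia"`). Because the two
  channels carry independent multiplicative noise, Z' on N is
  systematically lower than on raw lucia (the ratio accumulates both
  channels' variance); at the generator defaults (5-fold control
  window, 10% per-channel noise) it sits near 0.36 and individual
  plate estimates occasionally dip below the 0.2 gate. This is a
  property of any Z' estimate from finite control wells, which is why
  hit calling tolerates the loss of single plate-replicates (below).
* **Threshold.** Default 0.2, configurable.

Replicate reproducibility is reported as the squared Pearson
correlation of per-well `log2 N` (or z-scores) between every unordered
pair of replicate plate sets, over experimental wells only.

# Normalization, viability gating and z-scores

For every well, `N = lucia / ctg` normalizes reporter output by cell
number, and the viability ratio is the well's CTG signal relative to
the mean CTG of the plate's negative-control wells. Wells losing more
than 30% viability (`ratio < 0.7`, the boundary itself counts as
viable) are excluded from hit statistics: an siRNA that kills cells
depresses the reporter trivially. The published rule states the 30%
exclusion without naming a referent; the negative-control mean is the
natural in-plate baseline and is what this package uses.

Z-scores are computed per plate and per replicate on `log2 N`:

$$z = \frac{\log_2 N - \hat\mu_{plate}}{\hat\sigma_{plate}},$$

where centre and scale are the mean and sample SD of that plate's
*viable experimental* wells. Controls are excluded from the centring
population — they would drag the plate centre toward the control
phenotype — and receive no z-score. A robust variant (median /
1.4826·MAD) is available via `robust = TRUE`. The base of the log is
immaterial: standardization is invariant under affine maps, so log2
versus log10 changes nothing, and log2 is used for interpretability
(one unit = one doubling).

# Primary and secondary hit rules

**Primary (SMARTpool) rule.** A gene is a hit if its z-score is
$\le -2$ (reporter repressed) or $\ge +3$ (reporter activated) in at
least 2 of the 3 replicates, thresholds inclusive. The asymmetry
(−2/+3) follows the rule under which the published primary hit list
was assembled; a symmetric ±2 variant appears elsewhere in the source
methods, and both cutoffs are plain arguments (`zLow`, `zHigh`). Two
deliberate edge policies:

* a gene crossing *both* thresholds in different replicates is never a
  hit — it is reported as `none` with `discordant = TRUE`, since a
  direction-consistent effect is what the rule is after;
* a gene covered by fewer than `minReplicates` QC-passing replicates is
  `callable = FALSE` rather than silently absent.

**Secondary (deconvolution) rule.** Each hit pool's four constituent
duplexes are screened individually. Per duplex the activity ratio is
`N / mean(N of negative controls)`, averaged across replicates. A
duplex passes if its ratio changed by at least 60% **and** lies outside
the negative controls' mean ± 2 SD band **and** the duplex did not cost
more than 30% viability. The 60% and 2·SD conditions are conjoined
because the published criterion presents them as one. A gene is
confirmed when at least two duplexes pass in the same direction;
opposite-direction passes set a `discordant` flag.

# AP-MS interaction scoring

Spectral counts for each prey are compared between replicate bait
purifications and a panel of negative-control purifications (161 runs
in the emulated design). Two statistics are computed:

**Fold change.** `mean(bait counts) / (mean(control counts) + 0.1)`.
The background factor 0.1 is added unconditionally: that is the
simplest reading of "added to the average control counts to prevent
division by zero", it keeps the statistic continuous in the data, and
it changes nothing materially when the control mean is large.

**Per-replicate probability and AvgP.** The published analysis used the
external SAINT program; its semi-supervised mixture internals are out
of scope here. `scoreReplicate()` instead ships a deliberately simple
two-component Poisson posterior behind the same interface: background
rate $\lambda_0 = \max(\overline{ctrl}, 0.1)$, alternative rate
$\lambda_1 = \max(k, f\lambda_0)$ with fold-floor $f = 2$ (so weak
counts cannot shrink the alternative below the null), prior $\pi = 0.1$,
and

$$p = \frac{\pi\,\mathrm{Pois}(k;\lambda_1)}
           {\pi\,\mathrm{Pois}(k;\lambda_1) +
            (1-\pi)\,\mathrm{Pois}(k;\lambda_0)}.$$

Using the observed count as the alternative's rate estimate makes the
score monotone in $k$ and calibrated against the control panel; with
$k = 0$ the posterior can never exceed the prior. The per-replicate
probabilities are averaged arithmetically into **AvgP**, and a prey
passes at `AvgP >= 0.89`, inclusive — the stringent cutoff used for the
final interactome list. $\pi$ and $f$ are documented, configurable
defaults, not fitted quantities; the `scorer =` argument is pluggable
so an external backend can be slotted in, and a crude `fold_only`
squash ($fc/(1+fc)$) is provided for sensitivity analysis. No
spectral-count normalization is applied (counts are used as-is, the
"norm = 0" convention).

**Condition enhancement.** The source analysis labels some interactions
stimulation-enhanced without stating a criterion, so the classifier
here is an explicit package convention, recorded in the output
attributes: presence/absence dominates (passing only under stimulation
is `enhanced`, only in mock `reduced`), otherwise the bait fold-change
ratio decides at 2-fold either way; everything else passing is
`unchanged`, non-passing preys are `na`.

# Synthetic data: what it emulates, what it does not

The generators exist so that every downstream stage is testable with
known ground truth and no instrument data.

`simulateScreen()` draws wells from
`lucia = baseline_lucia × gene_effect × control_effect × viability ×
LogNormal(0, cv)` and `ctg = baseline_ctg × viability × LogNormal(0,
cv)` — multiplicative log-normal noise, independent between channels,
coupled only through the shared viability factor, as in the real assay
where siRNA toxicity depresses both readouts. Defaults are chosen once
to describe a plausible triplicate campaign: 2.5% spiked regulators
split evenly between 4× activation and 0.25× repression of the
reporter, 2% cytotoxic genes losing half their viability, 10% well
noise (`cv_noise = 0.1`, a typical coefficient of variation for
automated luminescence assays), baselines 1000/2000 RLU, and a
positive control at 0.2× (the assay's siTLR7 control suppresses the
reporter more than 3-fold). Controls occupy fixed edge columns (1/23
negative, 2 positive, 24 toxicity). One random stream per generator
call is consumed in documented order — truth sets first, then per
replicate the lucia noise over wells in layout order, then the CTG
noise — so a fixed seed is bit-reproducible.

Deliberately **not** simulated (beyond scope of the published
analysis, which corrects for none of them): spatial edge effects,
plate drift, carry-over, sequence-level off-target effects, and —
importantly — per-gene baseline heterogeneity. Null genes share one
expected baseline, so between-replicate R² on synthetic data is
bounded by the spike-in variance share (≈ 0.5 at the defaults, per the
variance-components prediction tested in the suite) and is *not*
comparable to concordance values reported for real screens, where
genuine gene-to-gene biology dominates the between-well variance.
Passing tests therefore demonstrate correctness of the statistics, not
realism of screen-level concordance.

`simulateApms()` draws independent Poisson counts: true interactors at
`lambda_true = 10` in bait runs, everything else — including all preys
in all control runs — at `lambda_bg = 0.2`, with 2 bait replicates per
condition and 161 controls. Enhanced preys multiply their stimulated
bait rate by `enhancement_factor = 4`; the classifier's cutoff is
2-fold, and a factor of 4 keeps the enhanced class separated from the
Poisson noise of two-replicate fold-change ratios (at a factor of
exactly 2 the classification of a genuinely enhanced prey would be a
coin flip against sampling noise). Peptide-level identification and
protein inference are upstream of this model and not simulated.

# Numerical choices and degenerate inputs

* CSV round trips write numerics as `%.17g`, so write → read is
  bit-exact for finite doubles and write → read → write is
  byte-identical.
* Zero-spread plates (`sd(log2 N) = 0`), equal control means, fewer
  than 2 control values, fewer than 10 usable experimental wells, and
  zero-variance replicates raise errors rather than returning NaN.
* Posterior evaluation is done in log space to survive large counts.
* Tie-breaking in `scoreInteractions()` is total and deterministic:
  AvgP descending, then fold change descending, then prey identifier.
* All threshold comparisons at boundaries follow the published wording:
  hit z-cutoffs and AvgP are inclusive (≤ / ≥), the QC gate is strict
  (> 0.2), the viability boundary 0.7 counts as viable.
* Genes with other than 4 duplexes in a deconvolution set are an error
  in strict mode, a warning otherwise.

# Problem sizes used by the test and acceptance runs

The shipped suites run the screen arm at 960 genes × 3 plates × 3
replicates over 10 seeds (primary recovery, false-call rate, secondary
confirmation of all spiked genes with 4 active duplexes) and the AP-MS
arm at 500 preys × 165 runs over 5 seeds, plus 5 pure-background
matrices of 500 preys for gate calibration. These sizes were chosen so
that each recovery estimate pools a few hundred positive and several
thousand null decisions, which is ample for the coarse rates being
asserted (sensitivity ≥ 0.9, false calls ≤ 1%, AP-MS FDR ≤ 5%,
background pass fraction ≤ 2%) while keeping a full run in seconds.

# Known limitations

* The Poisson-mixture scorer is a stand-in with the same interface and
  qualitative behaviour as established interactome scorers, not a
  numerical replica of any of them; published AvgP values can be
  re-filtered via `reproduceSupplementary()` but are not recomputed.
* The secondary screen's negative-control band uses ratios pooled
  across replicates of a plate; with very few negative wells the SD
  estimate is coarse.
* `reproduceSupplementary()` is column-map-driven by necessity —
  external supplementary tables do not share one schema — and degrades
  to whichever filters its map enables, reporting the rest as skipped.
* Identifier normalization is upper-casing plus a user alias map; no
  online ID mapping is attempted, by design (offline determinism).
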