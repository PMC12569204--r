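---
title: "Models and methods behind epiassay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epiassay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiassay)
```

# Scope

`epiassay` implements two quantitative readouts used to validate
locus-specific DNA demethylation in imprinting-disorder cell models, plus a
synthetic-data generator that emulates both assays with known ground truth:

1. **Methylation fraction from methylation-sensitive digestion qPCR.**
   Genomic DNA is split into three digests: a methylation-sensitive enzyme
   plus a fragmenting control enzyme (HpaII + MseI-type), the
   methylation-insensitive isoschizomer plus the control enzyme
   (MspI + MseI-type), and the control enzyme alone. qPCR across an
   amplicon containing the sensitive site then reports how much template
   survived each digest.
2. **Calcium transient detection.** ROI fluorescence time series from a
   genetically encoded calcium indicator are normalized to
   $\Delta F/F_0$, and discrete activity events are detected with a
   MAD-based dynamic threshold and a difference-pattern peak search,
   yielding per-cell activity rates in events per minute.

This vignette records the models, the tunable parameters, the numerical
conventions, and the design decisions taken where the procedure left
choices open. Everything quantitative stated here is computed by the test
suite or the acceptance script; nothing is quoted from elsewhere.

# The digestion-qPCR dosage model

Let a locus carry $k_m$ methylated and $k_u$ unmethylated copies, so the
latent methylation fraction is $m = k_m / (k_m + k_u)$. A biparental
diploid imprint has $m = 0.5$; a paternal-deletion genotype carrying only
the silenced maternal copy has $m = 1$; complete demethylation of a single
copy gives $m = 0$; maternal uniparental disomy after monoallelic
demethylation gives $m = 0.5$.

**Survival model.** The sensitive enzyme cuts each unmethylated copy
independently with probability $c_s$ (its cut efficiency) and never cuts a
methylated copy, so the template fraction surviving the sensitive digest is

$$ s = m + (1 - m)(1 - c_s), $$

which reduces to $s = m$ under complete digestion ($c_s = 1$). The
insensitive isoschizomer survives $s' = 1 - c_i$ regardless of $m$, and the
control digest leaves $s = 1$. This independent-cutting model is the
minimal one consistent with the assay chemistry, and it makes the
estimator exactly identifiable: relative amplification equals $m$ in the
noiseless, fully digested limit (a property test asserts this for
arbitrary allele configurations).

**Ct model.** With PCR efficiency $E \in (1, 2]$ per cycle, a condition
with surviving fraction $s$ crosses threshold $-\log_E s$ cycles after the
control digest:

$$ \mathrm{Ct} = \mathrm{Ct}_\text{base} - \frac{\log s}{\log E}
   + \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2_\text{Ct}), $$

independently per replicate. $s = 0$ produces the *no-amplification
sentinel* (empty cells in CSV, `NA` internally), never a finite Ct, and
maps to relative amplification $R = 0$ downstream.

**Estimation.** Replicates are summarized by mean Ct *before* forming

$$ R = E^{-(\overline{\mathrm{Ct}}_\text{digest} -
   \overline{\mathrm{Ct}}_\text{control})}, $$

matching conventional $\Delta$Ct practice and avoiding the log-scale bias
of averaging per-replicate ratios (the alternative was a genuinely open
choice; this one is fixed and documented). A standard curve
$R = a \cdot f + b$ is fit by ordinary least squares to calibration
standards of known fraction $f$, and a sample's fraction is recovered by
inverse prediction $(R - b)/a$, clamped to $[0, 1]$ with a `clamped` flag.
Clamping rather than rejecting matters because truly 0% and 100% loci are
routinely measured and noise overshoots the endpoints. The linear form is
adopted because the dosage model is exactly linear; the fitting interface
(`fit_standard_curve()`) is the single place a different form would go.

**Digestion QC.** The insensitive digest's residual amplification measures
incomplete digestion; QC passes when $R_\text{insensitive} \le 0.05$
(boundary inclusive). The 5% default is a package choice — the assay
defines the control's purpose but no numeric cutoff.

**Expression.** `relative_expression_ddct()` implements the comparative
$\Delta\Delta$Ct method (target normalized to a reference gene, then to a
calibrator sample; fold change $E^{-\Delta\Delta Ct}$), exposing the raw
$\Delta$Ct for downstream statistics.

## Parameters and defaults (digestion arm)

| parameter | default | units | why |
|---|---|---|---|
| `cut_efficiency_sensitive` | 1 | probability | 12 h over-digestion aims at completeness |
| `cut_efficiency_insensitive` | 1 | probability | same |
| `pcr_efficiency` | 2 | fold/cycle | perfect doubling; amplicon-specific efficiencies are not stated, so it is configurable |
| `base_ct` | 20 | cycles | typical for 10–100 ng input |
| `noise_sd` | 0.2 | cycles | typical technical-replicate spread |
| `n_replicates` | 3 | — | standard qPCR triplicates |
| calibration fractions | 0, 0.25, 0.5, 0.75, 1 | fraction | the calibration series actually used upstream is not stated; an even 5-point span is a package choice |
| QC `max_residual` | 0.05 | fraction | see above |

## What a green estimator test establishes

At the stated noise (0.2 Ct, 3 replicates, 5-point calibration) a *single*
estimate has a standard deviation of roughly 6 percentage points at 50%
survival, growing to ~13 at 100% (the Ct→ratio map is log-linear, so
absolute noise grows with $R$). Recovery is therefore asserted on averages:
the mean absolute error over 100 seeded repetitions is ≤ 0.05 for true
fractions {0, 0.5, 1}, and the acceptance report quotes the **median** over
50 repetitions of the full pipeline. The median rather than the mean is
deliberate: at the clamped endpoints the estimate distribution is
half-clamped and the mean is biased inward by the very noise the tolerance
absorbs (measured: mean ≈ 94.9% vs median ≈ 99.6% for a true-100%
genotype), while the median is seed-stable and boundary-unbiased.

# The calcium transient detector

Given a raw trace $F$ sampled every `sampling_interval` seconds:

1. **Normalization.** $F_0$ is the lower 5th percentile of the session
   (linear interpolation between order statistics — conventions differ
   across ecosystems, so this one is fixed explicitly and tested against
   the closed form $1 + 0.05 \cdot 99 = 5.95$ for the trace $1..100$), and
   $\Delta F/F_0 = (F - F_0)/F_0$. $F_0 \le 0$ is an error naming the ROI.
2. **Dynamic threshold.** $\theta = \max(2 \cdot \mathrm{MAD}, 0.1)$ with
   the *unscaled* MAD, $\mathrm{median}(|x - \mathrm{median}(x)|)$ — no
   1.4826 normal-consistency factor, because the rule is stated as "2 times
   the MAD", not as a robust SD estimate.
3. **Candidates.** With differences $d_i = x_{i+1} - x_i$, sample $t$ is a
   candidate iff $d_{t-1} > 0$, $d_t \le 0$, $d_{t+1} < 0$: a rise into the
   sample, a non-positive step, then a fall. The anchor is the sample
   between the positive and non-positive differences — the local peak or
   plateau start — because that is where the amplitude-vs-threshold
   comparison is meaningful. The first and last two samples can never be
   candidates; no padding or reflection is applied. The first difference
   must be strictly positive (a plateau of zeros does not start an event).
4. **Filtering.** A candidate survives iff $x_t > \theta$, strictly:
   "exceeds" is read as a strict inequality, so amplitude exactly at
   threshold is rejected.
5. **De-duplication.** Scanning left to right, consecutive events join the
   same group unless the minimum of $x$ strictly *between* them (the event
   samples themselves excluded — an inclusive scan could never merge,
   since both events exceed $\theta$) drops below $\theta$. Each group
   keeps its maximum-amplitude member, earliest on ties; which member of a
   merged group survives was unspecified, and this rule is the package's
   choice.
6. **Activity rate.** Events per minute over the session duration
   (`n_samples * sampling_interval` seconds — durations are in seconds
   with a declared sampling interval, since frames-vs-seconds was left
   open). Cells with zero events carry `included = FALSE` and are meant to
   be excluded from group summaries.

Every `event_set` satisfies two checkable invariants: all amplitudes
strictly exceed the threshold, and between consecutive retained events the
trace dips below it. A brute-force reference implementation (enumerating
every difference triple and every grouping) agrees exactly with the staged
detector on 1000 random traces in the acceptance suite.

## The synthetic calcium world

The generator emulates: a positive baseline; slow monotone photobleaching
(linear loss of up to `drift_amplitude` = 5% of baseline per session,
per-cell loss drawn uniformly); transients with a 2-sample linear rise, a
single-exponential 2 s decay, and amplitudes uniform on 0.4–0.8
$\Delta F/F_0$; Poisson onsets at 2 events/min thinned by a 10-sample
refractory dead time; and white Gaussian noise at 2% of baseline (so
amplitudes are ≥ 20× the noise sd). One global seed drives an independent
RNG substream per cell, so enlarging a session never perturbs existing
cells.

Two generator choices deserve flagging. First, the drift model is
*monotone* bleaching, not an oscillation: a drift that rises above its own
5th percentile by more than the 0.1 threshold floor is indistinguishable
from signal for any detrending-free detector, including this one — an
early sinusoidal drift prototype demonstrated exactly that failure
(precision collapsed to ~0.4), and the paper's algorithm plainly assumes
drift below threshold. Second, refractory thinning is a dead-time process:
it lowers the realized event rate by a factor $1/(1 + \lambda\tau)$, so
the "expected events = rate × duration" property is tested with the
refractory set to zero, while detector recovery is always scored against
the *retained* (thinned) ground truth.

What a green recovery test does **not** establish: performance under
movement artifacts, overlapping ROIs, non-stationary noise, bursting
regimes faster than the refractory spacing, or amplitudes near the
threshold floor. The generator's transients are clean kernels; real
indicator kinetics vary.

## Detection-recovery scoring

`evaluate_detection()` matches detected peaks to true onsets greedily,
earliest-first, one-to-one, within ±3 samples (the 2-sample rise keeps
peak-vs-onset offsets inside that tolerance). Precision is
matched/detected — reported as 0 with a `precision_defined = FALSE` flag
when nothing was detected — and recall is matched/true. On the default
session the detector achieves precision ≈ 0.91 and recall ≈ 0.99; residual
false positives are early-session bleaching baseline plus noise peaks that
clear the 0.1 floor, which is a property of the stated world rather than a
detector defect.

# File formats and orchestration

All tables are UTF-8 CSV with a header row and "." decimals. Ct tables
carry `sample_id, condition, replicate, ct` (empty `ct` = no
amplification; unknown conditions and duplicate replicate keys are errors
naming the row) plus an optional `known_fraction` for calibration
standards. Trace matrices carry one ROI per column, optional leading
`time`/`index` column, ≥ 4 rows, strictly positive finite cells. Sample
indices are 0-based in every *written* output (stated in the column
header) while R objects are 1-based; run configurations are JSON (no YAML
parser is assumed). Every `run_workflow()` call writes a `report.json`
echoing the full parameter set, package version, seed, and accumulated
warnings, so any output row is traceable to its inputs and settings.

# Known limitations

- The estimator is per-amplicon: no per-CpG resolution, no bisulfite or
  nanopore modeling.
- PCR efficiency is assumed shared between digest and control reactions of
  a sample; amplicon-specific efficiencies must be supplied by the user.
- The linear standard curve is assumed, not verified against any external
  calibration equation.
- The detector performs no detrending, deconvolution, or ROI handling;
  traces arrive pre-extracted, and drift above the threshold floor will
  produce false positives by construction.
- Group-level hypothesis testing is out of scope; the pipeline emits
  per-sample and per-cell summaries only.
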