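---
title: "Detecting and correcting transcriptome-wide anomalies in time-series expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and correcting transcriptome-wide anomalies in time-series expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stripeqc)
```

## The problem

Time-series RNA-seq experiments occasionally contain time points whose
transcript levels shift *across the whole transcriptome* relative to their
temporal neighbors — up (high), down (low), or split in both directions
(bimodal). Such shifts are too large and too fast to be transcriptional,
can differ between technical replicates of a single time point, and appear
across species and timescales; they are technical artifacts, here called
STRIPEs after their appearance as vertical stripes on Z-scored heatmaps.
Because their origin within the extraction/library/sequencing/quantification
chain is not understood, they cannot be predicted from run metrics; they can
only be recognized by comparison to replicate or temporally proximate
samples, and then corrected so downstream analyses (periodicity calling
above all) are not biased.

`stripeqc` packages that recognition-and-repair loop: KS-based sequential
detection, three corrections, verification by re-detection, downstream
impact metrics, and a simulator to validate the whole chain against known
ground truth.

## Detection model and assumptions

Let $x_{g,t}$ be the expression of gene $g$ at time $t$ (TPM/FPKM). By
default detection operates on per-gene Z-scores
$z_{g,t} = (x_{g,t} - \bar x_g)/s_g$ with the *population* standard
deviation (divisor $T$); this choice matches the default of the numerical
stacks commonly used for this preprocessing and is stated here because the
two conventions differ at small $T$. Rows with $s_g = 0$ are mapped to zero
(not NaN) and reported; they shift both samples of any KS comparison
identically. A `preprocess = "none"` mode exists for data already on a
common distributional scale.

Two time points are compared with the two-sample Kolmogorov–Smirnov
distance $D = \sup_x |\hat F_i(x) - \hat F_j(x)|$, evaluated exactly over
the pooled sample points, with the asymptotic two-sided p-value
$Q\!\left(D\sqrt{n_1 n_2/(n_1+n_2)}\right)$ clamped to $(0,1]$. At
transcriptome scale ($n$ in the thousands) the asymptotic form is accurate,
and — unlike exact small-sample p-values — well defined under ties, which
quantile-normalized data contain in abundance. An exact p-value is therefore
deliberately not offered.

The sequential detector assumes the series *starts* with a non-STRIPE
point. It compares points 1 and 2; if they agree (metric does not cross the
threshold) it scans forward, comparing each point to the most recent point
labeled non-STRIPE (the anchor). Crossing is strict — STRIPE iff
$D > \tau$ (distance mode) or $p < \tau$ (p-value mode) — so exact equality
is non-STRIPE. If the initial pair disagrees, the assumption is transferred
to the *last* point and the scan runs in reverse; the reverse pass is also
triggered when `max_consecutive` (default 5) consecutive STRIPEs accumulate,
since each additional consecutive STRIPE widens the temporal gap to the
anchor and inflates even biological distances. If both directions exhaust
the budget, detection aborts with an `"stripe_ambiguous"` condition rather
than guessing: the all-by-all `pairwise_distance_matrix()` is the fallback,
at the cost of being confounded by slow biological drift (e.g. recovery
from synchronization), which is why it is not the primary method.

There is no universally correct threshold: all neighbors differ a little
biologically. `suggest_threshold()` therefore computes consecutive-neighbor
distances and flags robust outliers, $|d - \mathrm{med}|/(1.4826\,
\mathrm{MAD}) > 3.5$ — a stated, reproducible stand-in for picking outliers
off a distance-distribution plot by eye. The fence 3.5 is the conventional
robust-z cutoff; the suggestion is advisory and never auto-applied. When
the MAD is zero no outlier can be scored and a warning says so.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.3 (distance) | KS metric cutoff; a tool default, not a universal constant — always inspect `suggest_threshold()` |
| `preprocess` | `"zscore"` | scale on which distributions are compared |
| `max_consecutive` | 5 | consecutive-STRIPE budget before the direction flips |
| `fence` | 3.5 | robust-z cutoff of the threshold advisory |

## Correction methods and verification

*PCHIP interpolation* drops the STRIPE columns and reconstructs each gene
from the remaining (time, value) nodes with the Fritsch–Carlson
shape-preserving cubic Hermite interpolant (zero derivative at interior
extrema, weighted harmonic mean of adjacent secants otherwise, one-sided
shape-preserving ends) — computed by `pracma::pchip` and cross-checked in
the test suite against an independent implementation of the same rule. It
assumes the anomalous samples are uninformative and the neighbors are dense
enough to carry the signal; whatever true biology the STRIPE contained is
lost. Interpolation acts on the raw scale. A STRIPE at the first or last
time point has no bracketing node; such points are constant-filled from the
nearest remaining column with a prominent warning, because a library must
return a complete matrix even where interpolation proper is impossible —
terminal anomalies are better dropped or handled by normalization.

*Quantile normalization* (QN) maps every column onto the per-rank
arithmetic mean of the sorted columns (median available as an option). It
uses the STRIPE data rather than discarding them, but assumes all
distributional variation is technical. Ties receive the mean of the
reference over the tied rank range — the standard expression-array
convention, stated explicitly because it is a genuine free choice; under it
QN preserves within-column ranks and is idempotent.

*Z-score quantile normalization* (ZQN) is QN applied after per-gene
Z-scoring. The order of operations is the only difference from QN, and it
is decisive for bimodal anomalies: a uniform up/down shift leaves
within-column ranks intact, so raw-scale QN undoes it, but a bimodal shift
reshuffles ranks and survives QN — whereas ZQN forces exactly the Z-score
distributions on which the STRIPE definition rests to coincide.

`correct_stripes()` verifies by re-running the detector on the corrected
matrix *at the same threshold*: a STRIPE counts as corrected when it is no
longer detected, residual otherwise. Verification preprocessing follows the
output scale — interpolation and QN outputs are re-Z-scored; ZQN output is
already distribution-matched Z-scores, so re-detection uses
`preprocess = "none"` (re-Z-scoring rows of a rank-matched matrix would
break exactly the property ZQN establishes). The user may override the
interpolation list with an explicit one, e.g. to exclude early time points
whose distribution shift is suspected to be biological (recovery from
synchronization), while the before/after bookkeeping still reports the
detected set.

## The simulator: what it emulates, and what it does not

`simulate_timecourse()` draws, per gene, a log-normal baseline
($\log_2 b_g \sim N(6, 2^2)$, i.e. a median of ~64 TPM with a wide dynamic
range), a uniform phase, a uniform log2 amplitude in $[0.5, 2]$ for the
periodic half of the genes, and i.i.d. Gaussian log2 noise (sd 0.25):

$$\log_2 x_{g,t} = \log_2 b_g + A_g \cos\!\big(2\pi (t - \phi_g)/P\big)
  \,[g\ \text{periodic}] + \varepsilon_{g,t}.$$

The default design — 24 points at 2-unit spacing, period 24, hence 12
points per cycle over two cycles — mirrors a typical mammalian cell-cycle
course and satisfies the 8-plus-points-per-cycle rule of thumb for
periodicity work. Anomalies are injected multiplicatively: the affected
genes in one column are multiplied by $2^{\pm\delta}$ (all minus for low,
all plus for high, an independent fair coin per gene for bimodal — no
gene-class structure). Real anomaly magnitudes are not quantified anywhere,
so $\delta$ is a free parameter; the validation sweep uses
$\delta \in \{0.25, 0.5, 1, 2\}$ with $\delta = 2$ as the clearly-visible
reference case.

The simulator deliberately omits several features of real data: count
noise and the mean–variance relation, correlated gene programs, replicate
and batch covariance, drifting baselines, partial-transcriptome anomalies
(available via `fraction < 1` but not default), and anomalies whose
magnitude varies by gene. Passing the recovery tests therefore shows the
*algorithmic* chain is correct under its stated model — it does not certify
performance on any particular real dataset, where threshold choice and
biological distribution shifts dominate.

## Downstream impact metrics

The built-in periodicity score is a cosinor $R^2$: the fit of
$\beta_0 + \beta_1\cos(2\pi t/P) + \beta_2\sin(2\pi t/P)$ per gene, with
constant genes scored 0 and ties broken by gene ID. It is a transparent
stand-in for dedicated periodicity algorithms, which are out of scope;
external rankings are first-class inputs (`read_ranking()` /
`as_periodicity_ranking()`) wherever a ranking is consumed.

`stripe_alignment_fraction()` reports, over the top-$n$ genes, the fraction
whose expression maximum *or* minimum in the search window falls on a
STRIPE time, next to the uniform single-extremum expectation $k/m$ ($k$
STRIPEs among $m$ window points). Two conventions deserve attention. First,
the window: the default is the first full period, matching the convention
of ordering periodic genes on their first-period peak; a full-series mode
is exposed because nothing forces that restriction. Second, the counting
rule: peak-or-trough alignment roughly *doubles* the single-extremum
expectation on anomaly-free data (the trough sits half a period from the
peak, so about $2k/m$ of genes align by chance). Both numbers are reported
side by side so the mismatch is visible rather than hidden; the
over-representation caused by a real anomaly (several-fold above either
rate) dwarfs the factor-two convention gap.

`sampling_sensitivity()` re-detects on reduced series (leave-one-out or
keep-every-k), reporting omitted points as `"absent"` — never as
non-STRIPE — and recording ambiguous outcomes per subsample instead of
failing.

## Numerical choices, degenerate inputs, problem sizes

- KS distance evaluated at tie-group ends of the pooled sorted sample:
  exact under ties; agrees with a brute-force ECDF oracle to $10^{-12}$.
- Asymptotic p clamped to `(.Machine$double.xmin, 1]`; the Kolmogorov
  series is summed to 101 terms (far past double-precision convergence).
- Strict threshold crossing; equality is non-STRIPE.
- Constant genes: zero Z-scores, flagged, retained.
- QN tie rule as above; reference by arithmetic mean, `ref_fun` pluggable.
- Cosinor $R^2$ clamped to $[0,1]$; zero-variance genes score 0.
- Validation problem sizes: the recovery sweep runs 20 seeds × 3 anomaly
  subtypes at 2000 genes × 24 time points ($\delta = 2$, $\tau_D = 0.3$),
  where detection is error-free; the KS oracle comparison uses 1000 random
  pairs of sizes 2–200. These sizes make the full suite and the
  reproduction script each a couple of minutes of single-CPU work.

## Limitations

Correction minimizes, but does not erase, an anomaly's downstream
footprint; residuals are reported, not bounded. Detection is comparative:
with two samples a STRIPE is undecidable, with three barely decidable, and
confidence grows with replicates and sampling density — the subsampling
tools quantify exactly this. Whether a flagged distribution shift is
technical remains, in the end, a judgment about the experiment: the
detector measures distributional surprise, not causality.
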