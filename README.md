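# stripeqc

Quality control for time-series transcriptomic experiments: detection and
correction of **STRIPEs** — TRanscriptomic Irregular Profile Expression
changes. A STRIPE is a time point (or technical replicate) whose
transcript-level distribution deviates *transcriptome-wide* from its
temporal neighbors for technical, non-biological reasons; on a Z-scored
heatmap it appears as a vertical stripe, and in single-gene line plots as a
spike or trough too fast to be transcriptional. Left uncorrected, STRIPEs
bias downstream analyses — most visibly periodicity calling in cell-cycle
and circadian time courses, where genes whose dynamics happen to "fall in
line" with the false peak/trough become over-represented among the top
periodic genes.

`stripeqc` is for anyone analyzing genes × time expression matrices
(TPM/FPKM, bulk or pseudobulk): it flags anomalous time points, corrects
them, verifies the correction, and quantifies the downstream impact.

## Method

**Detection.** Time points are compared with the two-sample
Kolmogorov–Smirnov statistic on their (by default per-gene Z-scored)
transcript-level distributions,

D = sup_x | F̂_i(x) − F̂_j(x) |,

with the asymptotic two-sided p-value at D·√(n₁n₂/(n₁+n₂)). The sequential
detector first compares time points 1 and 2; if they agree it scans forward,
comparing each point to its *most recent non-STRIPE neighbor* (the anchor)
and labeling it 1 (STRIPE) when D exceeds the user threshold τ, else 0
(making it the new anchor). If the initial pair disagrees — or five
consecutive STRIPEs accumulate — the scan restarts in reverse from the last
time point; if both directions exhaust the budget the result is declared
ambiguous and the all-by-all pairwise KS distance matrix is the fallback
view. A robust advisory picks candidate thresholds by flagging
consecutive-neighbor distances with |d − median|/(1.4826·MAD) > 3.5.

**Correction** (three methods, verified by re-detection at the same τ):

- *PCHIP interpolation* — drop the STRIPE columns and reconstruct them per
  gene with a shape-preserving piecewise cubic Hermite interpolant
  (Fritsch–Carlson derivatives; no overshoot, no use of the anomalous data);
- *quantile normalization* (QN) — force all columns onto the per-rank mean
  reference distribution, on the raw scale;
- *Z-score quantile normalization* (ZQN) — Z-score per gene first, then
  quantile normalize. Only the order of operations differs from QN, but it
  is what removes **bimodal** STRIPEs (half the genes up, half down), which
  survive raw-scale QN because the anomaly reshuffles within-column ranks.

**Downstream impact.** A built-in cosinor score (R² of a fixed-period
single-harmonic fit; external rankings plug in) supports the peak/trough
alignment statistic: among the top-N periodic genes, the fraction whose
first-period extremum lands on a STRIPE time, compared to the uniform
expectation k/m for k STRIPEs among m time points per cycle. Top-N overlap
counts and leave-one-out / keep-every-k subsampling complete the picture.

**Simulator.** `simulate_timecourse()` generates cosine-on-log2 periodic
expression with multiplicative noise and injects low / high / bimodal
STRIPEs of chosen log2 magnitude, returning the ground truth needed to
score detection — the package's built-in test bed.

## Worked example

```r
library(stripeqc)

# 2000 genes, 24 time points (0,2,...,46 h), period 24 h, one bimodal
# anomaly of 2 log2 units injected at t = 12
sim <- simulate_timecourse(simulation_config(seed = 1),
                           stripes = list(stripe_spec(12, "bimodal", 2)))

detect_stripes(sim$matrix, threshold = 0.3)
#> <stripe_calls> 24 time points, 1 STRIPE(s); forward pass, distance threshold 0.3
#>   STRIPE times: 12

correct_stripes(sim$matrix, "qn", threshold = 0.3)
#> <stripe_correction> method = qn
#>   STRIPEs before: 12
#>   corrected:      none
#>   residual:       12

res <- correct_stripes(sim$matrix, "zqn", threshold = 0.3)
res
#> <stripe_correction> method = zqn
#>   STRIPEs before: 12
#>   corrected:      12
#>   residual:       none

stripe_alignment_fraction(sim$matrix, 12, top_n = 500, period = 24)
#> <alignment_report> top 500 genes, first-period window (12 points)
#>   aligned with STRIPE peak/trough: 57.6% (uniform expectation 8.3%)
stripe_alignment_fraction(res$corrected, 12, top_n = 500, period = 24)
#> <alignment_report> top 500 genes, first-period window (12 points)
#>   aligned with STRIPE peak/trough: 2.6% (uniform expectation 8.3%)
```

Reading: the detector finds exactly the injected anomaly; raw-scale QN fails
to remove a bimodal STRIPE (it is re-detected at the same threshold) while
ZQN succeeds; and among the top 500 cosinor-ranked genes the fraction whose
peak or trough sits on the anomaly drops from 57.6% — seven times the 8.3%
uniform expectation for one time point among twelve — to 2.6% after ZQN
correction.

The same pipeline runs from the shell via the installed `exec/stripeqc`
script (`simulate`, `detect`, `matrix`, `suggest`, `normalize`, `correct`,
`evaluate` subcommands); see `stripeqc --help`.

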