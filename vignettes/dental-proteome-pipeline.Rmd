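---
title: "Methods: two-batch label-free differential expression and landmark morphometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-batch label-free differential expression and landmark morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dentproteo)
```

## The analysis model

`dentproteo` analyzes label-free quantification (LFQ) experiments in
which a small number of treatment and control specimens were acquired in
two LC-MS/MS batches. Ionization efficiency differs between runs, so the
two batches are deliberately *not* pooled: each batch is
quality-filtered on its own, and only proteins detected in both batches
(the combined group, CG) enter downstream interpretation. Within a
batch, every treatment specimen is compared against every control
specimen — with 2+2 specimens per batch that is 4 comparisons per batch
and 8 in total — and a protein is promoted to the combined significant
set (CGSig) only if it shows at least one significant comparison in
*each* batch and is missing in at most one of the 8 comparisons. The
two-batch agreement requirement is the design's replication safeguard:
with so few specimens per batch, a single-batch signal is too easily an
artifact of one run.

### Abundance ratios, censoring, significance

For a comparison (T over C) the protein-level statistic is the
normalized abundance ratio $r = a_T / a_C$, reported as $\log_2 r$
clamped to $[-3.32, 3.32]$. The sentinel $3.32 = \log_2 10$ is read as a
10-fold cap: ratios beyond it (including those arising from
effectively-zero denominators) carry no reliable magnitude, only a
direction, and are flagged `censored`. Normalization rescales every
specimen to the median per-specimen total abundance; it cancels in no
way downstream (ratios between specimens change by the ratio of scale
factors), and a specimen with no observed values at all is rejected
rather than silently scaled.

The per-comparison p-value is a reconstruction — quantification
software rarely documents its test — and is stated openly as such: a
two-sided one-sample t-test of the peptide-level
$\log_2(\text{T}/\text{C})$ ratios against 0. Peptides missing on either
side are excluded; fewer than 2 usable peptide ratios gives a missing
p-value. Degenerate inputs follow a fixed convention: all peptide ratios
exactly at the null gives $p = 1$; all equal to the same non-null
constant gives a missing p (a variance of zero carries no evidence
scale), never a division-by-zero. Multiplicity is handled per
comparison with Benjamini–Hochberg across proteins (`"bonferroni"` and
`"none"` are available); the missingness rule for CGSig pools the count
across both batches' 8 comparisons.

### Fold-change summaries

The per-protein summary averages the *uncensored* significant log2
ratios. Censored values still contribute to the up/down tallies
(`n_up`, `n_down`, `n_censored`) but not to the mean — a ±3.32 sentinel
would otherwise dominate it with a fabricated magnitude. The editorial
rule "don't print a mean that is close to 0 or that one outlier could
flip" is made deterministic: the mean is withheld when the uncensored
significant set is empty, when $|\bar{x}| < \varepsilon$ (default
$\varepsilon = 0.3$, i.e. below a ~1.23-fold change), or when any
leave-one-out mean changes sign. Withheld records report `xU/yD` and
take their direction from the majority vote (ties are `Mixed`).
$\varepsilon$ is a tunable parameter with no canonical value; 0.3 sits
below every fold change the motivating analysis chose to print and
above its blank-average rows' plausible means.

### Over-representation analysis

Enrichment of a query of $n$ proteins (CGSig) in a pathway of $K$
members against an organism-wide background of $N$ entities uses the
exact hypergeometric upper tail
$P(X \ge x) = \sum_{j \ge x} \binom{K}{j}\binom{N-K}{n-j} / \binom{N}{n}$,
accumulated from log-binomial coefficients so that backgrounds up to
$10^7$ pose no overflow risk. Only over-representation is tested, there
is no cross-pathway correction by default (significance is declared at
raw entities $p \le 0.05$, with an optional BH switch), and significant
pathways are ranked by the *entity ratio* $K/N$, descending, with ties
broken by smaller p then pathway id. Ranking by entity ratio is a
deliberate oddity inherited from the published convention: it orders by
pathway size relative to the proteome, not by surprise, so a large
pathway with a modest p-value can out-rank a tiny pathway with an
extreme one.

The background $N$ is rarely published. `infer_background()` recovers it
from printed (K, 4-decimal entity ratio) pairs: every pair constrains
$N$ to an interval via half-ULP rounding bounds, and the returned
integer minimizes $\sum (\mathrm{round}(K/N, 4) - r)^2$. Because
4-decimal rounding leaves a plateau of exactly-fitting integers (the
bundled 34-row reference table admits all of $[11015, 11023]$), ties
are broken by the continuous objective $\sum (K/N - r)^2$, which has a
unique minimizer; the package's default background constant is 11017,
inside that plateau. Residual differences between computed and printed
p-values at the third decimal reflect the original web service's
identifier-to-entity mapping (its effective per-pathway query size can
differ from $n$), and are documented rather than absorbed.

### Landmark phenotypes

Skull length is the Euclidean distance between two labelled landmarks.
Crown footprint area is the area of the planar convex hull of 25
outline landmarks: the points are centered, projected onto the plane of
their two dominant principal axes, hulled (`grDevices::chull`), and
measured with the shoelace formula. The projection choice makes "area"
well-defined for landmarks digitized in 3D: the quantity is the 2D
footprint in mm², invariant under rigid motions (the principal axes
rotate with the data), and a 3D hull would instead yield a surface or
volume. Configurations whose second principal extent is below $10^{-9}$
of the first are rejected as collinear. Group comparisons use Welch's
unequal-variance t-test with Welch–Satterthwaite degrees of freedom
reported unrounded; the default alternative is one-sided,
control − treatment > 0, matching the prediction that protein
restriction shrinks phenotypes, so an *increase* under treatment shows
up as a large one-sided p, not as significance.

## The synthetic generator

`generate_quant_experiment()` emulates the statistical structure that
matters for validating the selection rules, with defaults frozen to the
emulated study design:

| parameter | default | meaning |
|---|---|---|
| `n_proteins` | 2400 | protein universe |
| `detect_prob_g1/g2` | 0.92 / 0.67 | per-batch detection; expected ~2200/~1600 detected, ~1500 shared |
| `n_treatment/n_control` | 2 / 2 | specimens per arm per batch |
| `frac_de` | 0.05 | planted differential proteins |
| `effect_range` | [1, 2.5] | planted \|log2 effect\|, random sign |
| `baseline_mean/sd` | 23 / 2 | log2 baseline abundance (log-normal intensities) |
| `n_peptides_range` | 2–12 | peptides per protein (the t-test's replicates) |
| `peptide_offset_sd` | 1 | per-peptide ionization offset (log2) |
| `peptide_noise_sd` | 0.4 | per-observation log2 noise |
| `mnar_threshold/slope` | 19 / 1 | dropout: `plogis(slope * (threshold − log2 abundance))` |
| `frac_fail_*` | 0.02 each | records constructed to fail each QC filter |
| `ratio_cap` | 3.32 | censoring bound |

Dropout is logistic in log2 abundance — missing *not* at random —
because censored sentinels and missing comparisons in real LFQ data are
concentrated at low intensity; the threshold sits about two standard
deviations below the mean baseline so overall missingness stays in the
realistic few-percent range while low-abundance proteins are visibly
depleted. A planted protein is guaranteed to surface in at least one
batch so that ground-truth bookkeeping never dangles. Synthetic pathway
sizes default to 15–500, the conventional gene-set size window for
over-representation testing (very small sets make the hypergeometric
tail uninformative, very large ones are background-like).

What the generator does *not* emulate: retention-time or spectral
artifacts, correlated peptide noise within a protein, shared peptides
across proteins, batch effects beyond detection depth, and litter or
sex structure in the quantitative signal. Passing tests therefore
demonstrate that the selection machinery is correct under the stated
model, not that the model captures every pathology of real LFQ data.

The landmark generator places skull endpoints exactly
`base + effect` mm apart in a random 3D orientation and jitters each
endpoint with isotropic noise of per-coordinate sd
`skull_noise_sd`/√2, so the measured length has sd ≈ `skull_noise_sd`;
molar sets are a planar 25-gon (2:1 ellipse) rescaled to the exact
per-specimen target area, then rigidly rotated and translated — with
zero noise the recovered hull area equals the configured one to 1e-9
regardless of orientation, which is the package's rotation-invariance
oracle. Defaults reproduce the motivating experiment's group means
(skull 19.03/19.20 mm, crown 1.022/1.034 mm²) and the noise levels
implied by its Welch statistics.

## Numerical and testing choices

* **Uniformity diagnostics for discrete tests.** Exact hypergeometric
  p-values are discrete and super-uniform: $P(p \le t) \le t$ with
  equality only at the atoms. A one-sample KS test of raw p-values
  against U(0,1) therefore rejects even when the null is exactly true
  (the statistic picks up pmf-sized steps, ~0.1–0.3 here). The
  package's null-calibration check instead applies KS to the randomized
  probability integral transform
  $u = P(X > x) + U \cdot P(X = x)$, $U \sim \mathrm{U}(0,1)$, which is
  exactly uniform if and only if the null overlap counts follow the
  hypergeometric law — the same hypothesis, correctly calibrated.
* **Determinism.** Every generator is a pure function of its
  configuration including the seed; the pipeline derives stage seeds
  from one top-level seed as `(seed * 1009 + stage) mod (2^31 − 1)`, so
  identical configurations produce byte-identical outputs and
  manifests.
* **Problem sizes in the test suite.** Unit tests run on 150–500
  protein universes; the recovery simulation uses 10 seeds of the
  2000-protein, 5%-planted configuration; the hypergeometric
  implementation is checked against exhaustive enumeration for *every*
  valid (x, K, n, N) with N ≤ 40 and against `stats::phyper` at
  realistic scale; hull areas are checked against an independent
  gift-wrapping implementation on 200 random 25-point sets. These sizes
  give Monte-Carlo standard errors comfortably inside the asserted
  margins while keeping the whole suite under half a minute.
* **Boundary semantics.** QC keeps q = 0.05, 2 peptides and 4 PSMs and
  removes 3 PSMs (the rules are exclusions of "greater than 0.05",
  "fewer than two", "three or fewer"); `select_cgsig` accepts
  `alpha = 1` so the limiting case — selection reduces to the
  missingness rule — is expressible.

## Known limitations

* The per-comparison t-test is a reconstruction; analyses that start
  from vendor-exported per-comparison ratios and adjusted p-values
  should feed those columns directly into `select_cgsig()` and
  `summarize_protein()` rather than recomputing them.
* Missing abundances are never imputed; a protein missing in 2+ of the
  8 comparisons is discarded, which is conservative for low-abundance
  proteins under MNAR dropout.
* Enrichment is identifier-based over-representation only: no pathway
  topology, no reaction counts, and computed p-values can differ from a
  web service's at the third decimal because of its internal
  query-to-entity mapping.
* The crown "area" is a 2D footprint; studies wanting occlusal-surface
  area or 3D hulls need a different estimator.
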