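---
title: "Classifying pain- and itch-responsive DRG neurons: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying pain- and itch-responsive DRG neurons: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drgmodal)
library(dplyr)
```

drgmodal classifies dorsal root ganglion (DRG) sensory neurons as
pain-responsive, itch-responsive, or dual-responsive using two independent
arms of evidence: in vivo two-photon calcium imaging of stimulus-evoked
activity, and single-cell marker-gene expression. This vignette explains the
models and procedures each arm implements, the tunable parameters and their
defaults, what the synthetic generators emulate (and what they do not), and
the numerical choices made where the design was genuinely open.

## The calcium arm

### Model

A recording is a neurons-by-frames fluorescence matrix with stimulus epochs.
Activity is expressed as the fractional fluorescence change

$$\Delta F/F_0 = \frac{F_t - F_0}{F_0} \times 100\%$$

where $F_0$ is each neuron's own baseline, the mean fluorescence over the
first 60 s of its trace. The baseline window must be stimulus-free; the
package rejects recordings whose first epoch starts inside it rather than
silently re-windowing, because a contaminated $F_0$ biases every downstream
call.

A neuron is *activated* by a stimulus when its peak $\Delta F/F_0$ inside the
stimulus's analysis window reaches **20%** (inclusive: a peak of exactly
20.0% counts). The criterion is stated as a threshold on $\Delta F/F_0$
without naming a statistic; we apply it to the *maximum* within the window,
the conventional reading for transient detection, and expose the threshold as
`threshold_pct`.

Analysis windows differ by stimulus kind:

* **Mechanical** epochs (pinch, brush; ~10 s) are scored from onset to offset
  plus a 10 s decay margin (`mech_decay_margin_s`), because GCaMP6s decays
  slowly and a response peaking just after stimulus offset is still a
  response.
* **Chemical** epochs (intraplantar chloroquine or formalin) are scored from
  **60 s after injection** (the injection procedure itself perturbs the
  signal, so the first minute is discarded; `exclusion_s_after_injection`) to
  **11 min after injection** (`observation_s_after_injection = 660`).

Overlap statistics count neurons activated by both of two stimuli, by only
the first, or by only the second; the denominator is their union. Percentages
are rounded half-away-from-zero to one decimal (`round_half_up()`), the
convention under which 198/530 prints as 37.4. Base R's `round()` rounds half
to even and would print 37.3 for some inputs.

Population amplitude comparisons (e.g., dual-responsive vs single-modality
neurons) use a two-sided unpaired Student's *t* test on peak $\Delta F/F_0$
(pooled variance; Welch behind `var_equal = FALSE`), reported as
mean ± SEM with conventional significance stars.

### The synthetic recording generator

`simulate_recording()` emulates GCaMP6s-like stimulus-evoked transients on a
constant baseline with additive i.i.d. Gaussian noise:

$$F(t) = B\left(1 + \sum_e A_e\, k_e(t)\right) + \varepsilon(t),
  \qquad \varepsilon(t) \sim \mathcal N(0, \sigma^2)$$

with $k_e$ a double-exponential kernel
$e^{-s/\tau_d} - e^{-s/\tau_r}$ normalized to peak 1 **on the sampled frame
grid**, so a planted amplitude $A_e$ is realized exactly in the noiseless
limit — this calibration is what makes exact planted-count recovery a testable
contract rather than an approximation.

Defaults, fixed as the package's study conditions:

| parameter | default | rationale |
|---|---|---|
| `frame_rate` | 5 Hz | typical for two-photon population imaging; not a measured fact |
| mechanical kernel | $\tau_r = 0.2$ s, $\tau_d = 1.5$ s | GCaMP6s-like kinetics; the indicator is named but its kinetics are a simulator choice |
| mechanical epochs | 10 s stimuli, 5 min apart | matches the inter-stimulus interval used to avoid sensitization |
| chemical kernel | $\tau_r = 30$ s, $\tau_d = 240$ s, onset delayed 30 s after injection | a sustained, minutes-long response whose peak falls *after* the 1-min exclusion window |
| `noise_sd` | 2 (with baseline 100) | 2% of baseline; low enough for exact class recovery, the regime the recovery contract is stated in |
| planted classes | 198 both / 293 pinch-only / 39 brush-only of 530 | the mechanical-arm population composition |
| amplitudes | both: 80/60%; pinch-only 50%; brush-only 40% | dual-responsive neurons are planted with larger peaks; the amplitude gap is a planted effect, not an emergent one, because only the effect (not a mechanism) is reported |

An optional injection artifact (`artifact_dff`) plants a fast spike a few
seconds after a chemical epoch's onset; it exists purely to exercise the
exclusion rule and is off by default.

What the generator does **not** emulate: shot noise and photobleaching,
motion artifacts (motion correction is upstream of this package's scope),
spike-to-calcium nonlinearity, and correlated network activity. Passing
recovery tests therefore demonstrate the correctness of the thresholding
arithmetic under the stated noise model, not robustness to imaging artifacts.

```{r calcium-example}
sim <- simulate_recording(calcium_sim_config(n_neurons = 530, seed = 1))
calls <- sim$recording |> compute_dff() |> call_responses()
summarize_overlap(calls, "pinch", "brush")
```

## The single-cell arm

### QC

Cells are retained when they have **more than 500 detected genes** and a
**mitochondrial UMI rate below 20%** (both strict inequalities, so a
500-gene or exactly-20% cell is dropped), after which mitochondrial gene rows
(`mt-` prefix) are removed from the expression table. A matrix with no mito
annotation is processed with a warning and mito rates of zero.

### Marker positivity: the top-3 / 5% rule

Single-cell data are zero-inflated enough that mean expression is a poor
summary; the package instead reports the *fraction of positive cells* per
gene. For each gene:

1. the "maximum" expression level is the **mean of the three largest
   per-cell values** (zeros included if fewer than three cells are nonzero);
2. the positivity threshold is **5%** of that maximum (`threshold_frac`);
3. a cell is positive when its expression is **strictly greater** than the
   threshold, so an all-zero gene has fraction 0 rather than 1.

The rule is scale-invariant per gene: rescaling one gene's vector by any
$c > 0$ leaves its calls unchanged. The expression scale only matters through
between-cell depth differences; we compute positivity on depth-normalized
linear expression (counts per 10,000) by default and expose `scale =
"counts"` for raw values, because the original analysis does not state its
scale. One wording ambiguity deserves note: the source method describes the
maximum as an average over the top three *genes*; read literally that is a
category error (a per-gene threshold cannot average across genes), and the
referenced thresholding method and its supplementary illustration make clear
the top three *cells* per gene are meant. The implementation uses cells.

### Classification

With itch markers (*Mrgpra3*, *Nmb*) and pain markers (*Tac1*, *Calca*):

* **itch**: positive for an itch marker, negative for both pain markers;
* **pain**: positive for a pain marker, negative for both itch markers;
* **itch_pain**: positive for at least one of each;
* **unclassified**: negative for all four — excluded from the class
  denominator.

Class percentages are reported over the classified set. Per-marker fractions
can instead be computed over all cells with `positivity()`; both denominators
are available because both views are scientifically meaningful. A known
arithmetic quirk of the reference counts: 405 dual cells of 971 classified is
41.709…%, which rounds to 41.7; the package reports computed values only.

```{r classes-example}
fx <- make_fixture_classes(c(itch_only = 420, pain_only = 146, both = 405))
class_summary(classify_neurons(fx))
```

### Differential expression

`wilcoxon_de()` tests each gene between two cell groups with a two-sided
Wilcoxon rank-sum test on counts-per-10k expression:

* **exact enumeration** of the rank-sum null (over all $\binom{n}{n_A}$
  assignments of the pooled mid-ranks) when both groups have ≤ 8 cells;
* a **tie-corrected normal approximation** (no continuity correction)
  otherwise.

The log2 fold change is $\log_2\!\frac{\bar x_A + \varepsilon}{\bar x_B +
\varepsilon}$ on linear normalized expression with $\varepsilon = 10^{-9}$,
well defined at zero means. A gene *passes* when raw $p < 0.05$, log2FC
$> 0.25$ and the larger detection fraction exceeds 0.1 — deliberately raw-p,
mirroring the filter convention this reimplements; Benjamini–Hochberg
q-values are emitted alongside because the raw-p flag does not control FDR
across thousands of genes, and any error-rate statement should be made on q.
The fold-change filter is positive-only by default (marker semantics);
`two_sided_lfc = TRUE` switches to $|\log_2 FC|$. `positive_markers()` (each
cluster vs the rest, log2FC > 0.1, positive side only) and `condition_deg()`
(contrast between conditions within each neuron class, skipping empty
class-condition cells with a warning) wrap the same test.

Normalization is counts-per-10k with natural `log1p` where a log scale is
needed. The original pipeline used SCTransform; that is a packaged,
version-dependent procedure whose variance model is orthogonal to what is
being tested here, so the standard log-normalization is used and the
divergence is documented rather than hidden.

### The synthetic count generator

`simulate_umi_counts()` draws gene-wise negative-binomial counts with
multiplicative per-cell lognormal library factors and binomial dropout.
Defaults, fixed as study conditions:

* class mix itch-only 0.338 / pain-only 0.117 / both 0.326 / none 0.219 —
  the control-group composition implied by 971 classified of 1242 neurons;
* marker genes: NB mean 50 (size 8) in cells of their class, 0.02 elsewhere —
  markers are modeled as strongly bimodal, which is what makes planted
  prevalence a recoverable quantity under thresholding;
* 2000 genes total, background means lognormal($\ln 0.5$, 1), NB size 2,
  library sdlog 0.3, dropout 0.1 — sized so healthy cells clear the 500-gene
  QC floor (~1000 detected genes) while 5% planted low-quality cells
  (library ×0.1, mito ×10) fail it;
* 25 genes planted up (log2FC 1.5) in CCI and 25 in AEW by default;
  class-restricted effects are supported via the `class` column of
  `condition_effects`.

Not emulated: ambient RNA, doublets, batch effects, and any read-level
structure. The generator gives the QC, thresholding and rank-test machinery
realistic marginals and exact ground truth; it does not certify behavior on
real droplet data.

## Numerical choices and degenerate inputs

* Percent rounding: half-away-from-zero at one decimal everywhere a
  percentage is reported.
* Empty response union: counts are reported with percentages `NA` and a
  `defined = FALSE` flag — never a division by zero.
* SEM of a single neuron: reported as 0 with `sem_defined = FALSE`.
* `gene_positivity()` requires ≥ 3 cells (the top-3 mean is otherwise
  arbitrary); the classifier's internal path zero-pads below 3 cells so that
  degenerate fixtures (a single planted cell) remain classifiable.
* Exact Wilcoxon ties: mid-ranks, with the two-sided p defined as the null
  probability of a rank-sum at least as far from its mean (a $10^{-9}$
  comparison tolerance guards floating-point rank sums).
* Determinism: both generators are pure functions of their config (seed
  included) and restore the caller's RNG state.

## Problem sizes

The shipped tests and the acceptance script run the mechanical arm at its
full 530-neuron population (5 Hz, 400 s), the chemical arm at 232 neurons
(1500 s), prevalence checks at ~1100 post-QC cells, null-calibration at
~2100 genes × 220 cells, and DE recovery at ~500 cells per condition ×
2000 genes — the sizes at which the stated statistical bounds (99% binomial
intervals; sensitivity ≥ 0.9, FDR ≤ 0.1 on q-values) are meaningful.

## Known limitations

* The activated-fraction denominator ("all detectable neurons") cannot be
  derived from response calls; it is an explicit input (`n_detectable`).
* Whether the 20% criterion should bind on peak or sustained signal is an
  interpretation; peak is implemented and exposed.
* The raw-p `passes` flag is reproduced as specified and is anti-conservative
  by construction; use the `q` column for error-controlled gene lists.
* GO/KEGG enrichment, clustering/UMAP, SCTransform and image registration are
  out of scope; cluster labels, when needed, are inputs.
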