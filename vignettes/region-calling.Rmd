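---
title: "Region-based chromatin status calling: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based chromatin status calling: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regioncall)
library(ggplot2)
```

## The problem

Peak callers find high-signal loci with data-dependent boundaries, which
makes region-matched comparison across samples, marks and assays awkward.
When the question is "is mark X present at these promoters, and how strongly,
in each sample?", the natural unit is a *predefined* fixed-width window — for
example promoters as TSS ± 1 kb — and the natural output is a per-window
status with an effect size and a significance measure. `regioncall`
implements exactly that for ChIP-seq, CUT&RUN, CUT&Tag and ATAC-seq
alignments, with or without a matched control, and integrates multiple marks
into discrete chromatin states.

## The model

**Counting.** Each sequenced fragment is reduced to its central genomic
position: proper read pairs are merged into one fragment spanning the outer
mapped coordinates of both mates, single-end reads count as fragments over
their own aligned span, and the midpoint of `[start, end)` is
`start + floor((end - start)/2)`. Fragment midpoints falling inside each
window (half-open, BED coordinates) give the observed count $y_i$. The point
representation makes paired- and single-end libraries with different fragment
lengths directly comparable, at the cost of ignoring fragment extent.

**Global background.** Each chromosome is partitioned into non-overlapping
tiles of the window width $W$ (trailing partial tiles are dropped so every
tile has equal width; tiles overlapping the blacklist are removed whole). The
background rate is the plain mean over the $N$ retained tiles,

$$\lambda_g = \frac{1}{N}\sum_{i=1}^{N} y_i,$$

with zero-count tiles retained — excluding them would inflate the background
of sparse libraries. Overdispersion is captured by a single global Negative
Binomial size parameter $\theta$, estimated by method of moments from the
same tiles: $\hat\theta = \hat\mu^2/(s^2-\hat\mu)$ with the unbiased sample
variance. The closed form is fast and stable on millions of tiles; when
$s^2 \le \hat\mu$ (no overdispersion) or $\hat\theta > 10^6$ the model drops
to its Poisson limit. A single genome-wide $\theta$ per experiment reflects
the view that, without replicates, overdispersion is dominated by library-wide
technical variability; per-region dispersion estimates from one observation
would be meaningless.

**Local modulation.** Regional coverage varies for biological and technical
reasons the global mean cannot see — accessibility, copy-number changes,
mappability. With a matched control, each region's expectation is scaled by

$$m_i = \max\!\left(1, \frac{y_i^{(\mathrm{ctrl})}}{\lambda_g^{(\mathrm{ctrl})}}\right),
\qquad \lambda_{t,i} = m_i\,\lambda_g,$$

so a region with 3× control coverage must beat a 3× background. The floor at
one stops *deflation*: a cold spot in the control never makes the test more
lenient than the global background. Without a control (typical for ATAC-seq)
all $m_i = 1$ and inference is against $\lambda_g$ alone.

**Testing and scoring.** Each region gets a one-sided tail probability

$$p_i = P\!\left(Y \ge y_i \mid Y \sim \mathrm{NB}(\mu = \lambda_{t,i},
\text{size} = \theta)\right),$$

computed via the survival function at $y_i - 1$ (not $1 - F(y_i)$ arithmetic,
which loses precision in the far tail), with the Poisson tail when $\theta$
is infinite. Benjamini–Hochberg adjustment is applied per experiment across
all non-blacklisted regions. Two complementary effect measures accompany the
p-value: the enrichment score

$$s_i = \log_2\frac{y_i + \epsilon}{\lambda_{t,i} + \epsilon}$$

and a z-score standardised by the NB variance,
$z_i = (y_i - \lambda_{t,i})/\sqrt{\lambda_{t,i} + \lambda_{t,i}^2/\theta}$
(Poisson reduction $\sqrt{\lambda_{t,i}}$). A mark is **present** (call 1)
when $s_i > 1.5$ and BH-adjusted $p < 0.25$, both strict; the permissive FDR
threshold suits broad promoter marks, and downstream analyses of comparative
proportions are robust to it. Blacklisted regions carry `NA` through testing.

**States and comparisons.** Two marks over the same windows combine into
four states — `N` (neither), `A` (active mark only), `R` (repressive only),
`B` (bivalent) — with `NA` propagation. Two samples over the same windows
yield per-region deltas ($\Delta s$, $\Delta z$, $\Delta$expression) with the
*second* argument as baseline, so transition labels read
`baseline->target`. No two-sample significance test is attached: the deltas
are descriptive.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `width` (W) | 2000 bp | window width; all regions must match it exactly |
| `tile_width` | `width` | background tile width; equal widths keep $\lambda_g$ commensurable with window counts without rescaling |
| `epsilon` | 1 | score pseudo-count; 1 is conventional for log2 count ratios and fixes $s(0,0)=0$ |
| `score_min` | 1.5 | presence threshold on $s$ (strict `>`) |
| `fdr_max` | 0.25 | presence threshold on BH-adjusted $p$ (strict `<`) |
| `min_mapq` | 0 | MAPQ floor; alignment filtering normally happens upstream |

Choices that were genuinely open, and how they were resolved:

* **Even-length fragments** have no central base; the floor convention
  (`start + len %/% 2`) is deterministic and stays on integer coordinates.
* **Trailing partial tiles are dropped, not clipped**: a per-tile mean over
  unequal widths would be biased low at chromosome ends.
* **A tile with any blacklist overlap is removed whole** — fractional-tile
  bookkeeping buys little at 2-kb resolution.
* **Out-of-bounds regions are dropped with a warning, never clipped**,
  because clipping breaks the fixed-width invariant the test relies on.
* **Target regions are not excluded from background tiles.** With hundreds
  of thousands of tiles, signal windows shift $\lambda_g$ and $\theta$ only
  marginally, and a single tile set keeps the model transparent; strongly
  enriched windows make the background slightly conservative, never
  anti-conservative.
* **The z-score denominator** uses the NB mean–variance relation
  $\mu + \mu^2/\theta$, the standardisation consistent with the test's null.
* **BH is applied per experiment** (per mark), not pooled across marks.
* **Improper pairs are skipped** in paired mode rather than salvaged as
  single-end fragments, keeping the fragment definition uniform.
* **Degenerate expectations**: $\lambda_t = 0$ with $y > 0$ gives $p = 0$, a
  score via $\epsilon$, and `z = NA`.

## What the simulator emulates — and what it does not

`simulation_spec()` + `simulate_dataset()` build fully self-contained toy
datasets: a small genome, non-overlapping fixed-width windows with gene-like
names, uniform background fragments at a stated rate per tile (Poisson, or
gamma-mixed to give genuinely NB tile counts when `overdispersion` is set),
spiked windows whose expected count is `fold × rate`, a control with optional
regional coverage multipliers emulating copy-number bias (applied to the
experiment too via `distort_treatment`, as a real gain would be), and proper
read pairs written through a real BAM writer so the full I/O path is
exercised. All randomness flows from one recorded seed.

The simulator does *not* emulate sequence content, mappability structure,
GC bias, fragment-length signal coupling, or peak shape. Tests passing on it
show the inference machinery is correct under its own model — calibrated
nulls, recovered spike-ins, modulation rescue — not that real chromatin data
satisfy that model.

Validation problem sizes: end-to-end checks run on 500 windows of 2 kb over
a 2.5-Mb three-chromosome genome at background 20 midpoints per tile
(~25k fragments per library); parameter-recovery checks use $10^5$ simulated
tiles over a grid $\mu \in \{2,5,20\} \times \theta \in \{0.5,2,10\}$. At
these sizes the binomial standard error on a 5% null rate is under 1
percentage point and method-of-moments recovery is well inside 1% (rate) and
10% (dispersion).

## Worked example

```{r example, eval = FALSE}
spec <- simulation_spec(c(chr1 = 840000, chr2 = 840000, chr3 = 840000),
                        width = 2000, n_regions = 500,
                        enriched = c(20, 120, 300), fold = 8,
                        background_rate = 20, seed = 7)
fx <- simulate_dataset(spec, tempfile("demo"))

sizes   <- read_chrom_sizes(fx$chrom_sizes)
regions <- read_regions_bed(fx$regions, width = 2000, sizes = sizes)
calls   <- call_regions(regions, fx$experiment, sizes, control = fx$control)

glance(calls)
autoplot(calls)
tidy(attr(calls, "background"))
```

Multi-mark integration and comparison chain the same way:

```{r states, eval = FALSE}
states <- classify_states(active_calls, repressive_calls)
delta  <- compare_samples(recurrent_calls, primary_calls,
                          states_recurrent, states_primary)
autoplot(delta)
```

## Known limitations

* One global $\theta$ per experiment: local overdispersion structure
  (e.g. CNV-heavy genomes without a control) is not modelled.
* Enrichment only: no depletion test, and no significance test on deltas.
* Fixed-width windows only; variable-width region sets must be standardised
  upstream.
* The expression join is by region name; coordinate-based joining is out of
  scope by design (the promoter BED carries the gene identifier).
* Control modulation is undefined for a control with zero genome-wide
  coverage (an error, deliberately).
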