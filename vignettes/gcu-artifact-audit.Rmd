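---
title: "Auditing sequence-context artifacts in direct RNA m5C calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing sequence-context artifacts in direct RNA m5C calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-sample m5C detectors for nanopore direct RNA sequencing emit, for
every cytosine of a reference transcriptome, a *methylated fraction*: the
proportion of covering reads whose current signal was judged consistent with
5-methylcytosine. These fractions are continuous, so "how many sites are
modified" is not directly answerable; instead, practice has been to rank
cytosines by fraction and interpret the most highly ranked ones.

That practice is vulnerable to sequence-context bias. If the detector
over-calls cytosines embedded in a particular local context — regardless of
any true modification — the top of the ranking fills up with that context,
and downstream motif analysis "discovers" a methylation motif that is in fact
a property of the caller. The decisive control is in-vitro-transcribed (IVT)
RNA: IVT RNA contains no modified bases, so any context-specific elevation
that persists in an IVT sample is an artifact of the detection algorithm, not
biology. The context with this behavior in the audited workflow is the 3-mer
GCU (central C).

`gcuaudit` packages that audit as a reusable pipeline:

1. **Site statistics** — aggregate per-read calls to per-cytosine fractions,
   apply strict depth filters, rank, select the top N, extract sequence
   context windows.
2. **Motif discovery** — exhaustive central-3-mer enrichment counting plus a
   ZOOPS EM position-weight-matrix learner with permutation significance.
3. **Context comparison** — stratify fractions by central 3-mer, compare GCU
   against all other central-C contexts (median fold change, two-tailed
   Welch z, Cohen's d), and compare native against IVT samples per context.
4. **Synthetic data** — a seeded generator that plants a context-specific
   false-call bias, so the whole chain can be validated by parameter
   recovery.

## Conventions

* Sequences are handled internally in the DNA alphabet; `U` is accepted on
  input and mapped to `T`. Motifs and k-mers are *reported* in the RNA
  alphabet, so the artifact context prints as `GCU`.
* All coordinates are 0-based transcript positions; strand is always `+`
  (transcriptome space has no strand ambiguity).
* All filters are strict inequalities: `depth > 100` (preset `> 10` for
  shallow samples), `fraction > 0`. A site with depth exactly 100 is
  excluded. Sites with depth 0 have no defined fraction and are rejected at
  I/O time.
* Fraction histograms use half-open bins `[low, low + w)` of width 0.025
  (40 bins over [0, 1]), with the final bin closed so a fraction of exactly
  1.0 is counted. Bin membership is evaluated against the actual bin-edge
  values (`findInterval`), not by division, so values lying exactly on an
  edge land deterministically in the right bin despite binary floating
  point.

## Site selection

`aggregate_fractions()` counts a read as modified when its per-read
probability is at or above `call_threshold` (default 0.5; binary callers emit
exactly 0/1, for which any threshold in (0, 1] is equivalent). Ranking sorts
by fraction descending with deterministic tie-breaks — depth descending, then
transcript and position ascending — so any permutation of the input yields
the identical top-N set.

The context window default is `flank = 5`: 5 reference bases on each side of
the candidate cytosine, an 11-nt window. We read the upstream tool's
"10 bases of context" as 10 bases *surrounding* the site; since conventions
differ, `flank` is a parameter rather than an assertion.

`rank_top_n()` records the lowest fraction among the selected sites. For
well-powered whole-transcriptome samples this floor is high (≥ 0.85); when
it falls below that, the audit summary warns that a top-N analysis is likely
uninformative for the reference at hand (short references simply lack
enough near-1.0 sites) and suggests the all-3-mer stratified mode instead.

## The motif model

The learner implements the ZOOPS (zero-or-one-occurrence-per-sequence)
model: each window either contains one motif site (prior probability
$\lambda$, uniform over offsets) or is pure background. The background is
0-order, estimated from the input windows' letter frequencies
(Laplace-smoothed), and only the given strand is searched. For a window $x$
of length $L$ and motif width $w$ with $m = L - w + 1$ offsets:

$$P(x) = (1-\lambda)\prod_t b_{x_t} + \frac{\lambda}{m} \sum_{j=1}^{m}
  \prod_{t \notin [j, j+w)} b_{x_t} \prod_{k=0}^{w-1} f_{x_{j+k},k}$$

EM alternates a posterior over {no site, site at offset $j$} with
re-estimation of the PWM $f$ (0.1 pseudocount per cell) and $\lambda$.
Because the M-step is pseudocounted, the quantity that is provably
non-decreasing is the *penalized* objective (data log-likelihood plus the
Dirichlet term implied by the pseudocounts); that is what the convergence
check and the monotonicity assertions use, and the raw data log-likelihood
is reported alongside. EM stops when the relative change falls below `tol`
(default 1e-6, `max_iter` 200). Initialization is deterministic: the PWM is
seeded from the most frequent width-$w$ word among the windows
(lexicographically first on ties) and $\lambda_0 = 0.5$, so a seeded run is
bit-reproducible. If $\lambda$ reaches 0 the M-step leaves the PWM
untouched — a fixed point of the model rather than a silent reset to
uniform.

Successive motifs are found after *probabilistic erasure*: each position's
availability is multiplied by one minus its posterior probability of being
covered by earlier motifs' sites, the standard erase-and-repeat device.

### Significance

Analytic E-values are replaced by a permutation null: each replicate
mononucleotide-shuffles every window independently (per-window letter
composition preserved exactly) and re-runs the same EM at the same width;
the per-width p-value is $(1 + \#\{\text{null} \ge \text{obs}\}) / (1 +
n_{\text{shuffles}})$, so the smallest attainable p with the default 100
shuffles is 1/101.

Width selection searches all widths in `[minw, maxw]` (defaults 3–6, so
3-mers and 6-mers compete). Selecting the best of four widths is a multiple
comparison, so the motif's reported `p_empirical` is selection-adjusted by
the min-p (Westfall–Young) construction over the shared shuffle ensemble:
the observed minimum per-width p is referred to the distribution of each
null replicate's own minimum per-width rank. Under an i.i.d.-uniform null
this keeps the rate of spurious `p < 0.05` motifs at its nominal level,
which the test suite checks over 20 seeds.

Two tie-break choices are deliberate: when several widths saturate at the
minimum attainable p (as any strongly planted word does at every width),
the width with the larger null-standardized score — observed log-likelihood
ratio minus null mean, over null SD — wins, and remaining ties go to the
smaller width. Standardization is what lets a planted 6-mer beat its own
3-mer prefix, whose raw score is mechanically smaller; under the null the
choice is immaterial because tied widths are all non-significant.

One shuffle ensemble is computed per `discover_motifs()` call and shared by
all motifs. The null does not involve erasure; since later motifs' observed
scores *are* computed under erasure, their p-values are, if anything,
conservative.

## The comparison statistics

`compare_gcu()` splits central-C sites (full 3-mer context available) into
GCU and non-GCU groups after the strict depth filter and reports:

* group medians and the **median fold change** (GCU / non-GCU) — medians,
  not means, because the fraction distributions are heavily skewed;
* a **two-tailed Welch z test**,
  $z = (\bar{x}_A - \bar{x}_B) / \sqrt{s_A^2/n_A + s_B^2/n_B}$, with
  $p = 2(1 - \Phi(|z|))$ — the normal reference is justified by group sizes
  far above 30 in every intended use; the test treats sites as independent,
  an assumption discussed under limitations;
* **Cohen's d** with the classical pooled standard deviation.

`paired_sample_compare()` applies identical filters to the native and IVT
samples, by default keeping only positions that pass the filters in *both*
(position-matched mode), and reports per-3-mer medians, histograms, the
Kolmogorov–Smirnov statistic between the two fraction samples (a
descriptive distance — native and IVT being indistinguishable at GCU is the
hallmark of the artifact), and the median difference. The KS statistic is
used descriptively, not as a test: methylated fractions are discrete at
finite depth, so KS p-values would be unreliable, and no p-value is
reported for it.

The pipeline verdict in `run_compare_pair()` is `"artifact-consistent"`
exactly when the GCU elevation is significant (positive z, `p < alpha`,
default 0.05) in **both** samples: a "modification" signal present in fully
unmodified IVT RNA cannot be biological. No multiple-testing correction is
applied across 3-mers because a single pre-specified context (GCU) is
tested per sample.

## What the generator emulates — and what it does not

`simulation_config()` defaults define the study conditions used throughout
validation:

| parameter | default | meaning |
|---|---|---|
| `n_transcripts`, `length_mean` | 25, 1500 nt (±20%) | ~37.5 kb of i.i.d. sequence, ≈ 580 GCU sites at GC 0.5 |
| `gc` | 0.5 | P(G) = P(C) = 0.25 |
| `depth_mean`, `depth_model` | 100, Poisson | per-site coverage; negative binomial available for overdispersion |
| `p_base` | 0.1 | per-read false-call probability at unbiased C sites |
| `p_context` | GCU = 0.25 | planted context bias; planted median fold 0.25/0.10 = 2.5 |
| `n_true_sites`, `true_fraction` | 0, 0.9 | optional truly modified sites (native member only in a pair) |

Every read covering a C site is called modified with the site's probability;
calls are binary, mirroring the audited caller's per-site output (a fraction
of binary per-read judgments). An IVT member inherits the same `p_context`
but has no true sites — by construction the planted GCU elevation persists
in the unmodified sample, which is precisely the artifact signature the
pipeline must detect. A truth table records every C site's generating
probability for parameter-recovery checks.

The generator does *not* emulate: transcript-level expression variation
beyond the depth model, alignment or basecalling error, read-length
structure, signal-level (squiggle) behavior, positional autocorrelation of
caller errors along a read, or compositional bias of real transcriptomes.
Passing the recovery tests therefore shows the pipeline correctly measures
a context bias of the planted form at realistic depth and site counts — it
does not show that any particular real dataset is or is not artifact-bearing.

## Validation problem sizes

The test suite validates each statistic against brute-force oracles on
1000+ randomized small inputs (equality to 1e-9), checks EM monotonicity on
every fit it runs, recovers a planted 6-mer word from 50 windows with
occupancy > 0.9 and the minimum attainable p, and confirms null calibration
(no motif at `p < 0.05` on i.i.d. uniform windows in ≥ 90% of 20 seeds,
100 windows each). End-to-end recovery runs 20 seeded native/IVT pairs at
the default conditions above and requires the top central 3-mer to be GCU,
`compare_gcu` to reach `p < 0.01`, and the recovered median fold to fall
within ±0.3 of the planted 2.5 in ≥ 95% of seeds. Recovery comparisons use
the shallow-sample depth preset (`min_depth = 10`): with mean depth 100 the
`> 100` cutoff would discard about half of the simulated sites, and the
planted-fold property is defined at the simulated depth, not conditional on
above-average coverage.

## Known limitations

* The Welch z treats sites as independent; clustered caller errors along a
  transcript would make the reported p optimistic. Group sizes in intended
  use are large enough that the normal reference itself is not the binding
  assumption.
* Permutation resolution is bounded by `n_shuffles`; with the default 100,
  p-values below 0.0099 are not distinguishable.
* The EM learner is a deliberately small ZOOPS engine: no OOPS/ANR models,
  no reverse-complement search, no Markov backgrounds above order 0, no
  analytic E-values. It answers "is the enriched context GCU and is it
  stronger than composition-matched noise", not "what would MEME print".
* The wiggle/bedGraph interop reader accepts only single-base records, the
  shape per-site fraction tracks actually take; interval tracks are
  rejected rather than resampled. Whichever fraction variant the upstream
  caller exported (raw or dampened) is taken at face value and its filename
  recorded.
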