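# gcuaudit

Audit sequence-context bias in per-site 5-methylcytosine (m5C) calls from
nanopore direct RNA sequencing.

Single-sample m5C detectors assign every cytosine of a reference
transcriptome a *methylated fraction* — the proportion of covering reads
called modified. When a detector systematically over-calls cytosines in a
particular sequence context, the most "highly modified" sites and the motifs
enriched around them reflect the caller, not the biology. The decisive
control is in-vitro-transcribed (IVT) RNA, which carries no modifications:
a context-specific elevation that persists in an IVT sample is an artifact.
The context with exactly this behavior in widely used single-sample m5C
calling is the 3-mer **GCU** (central C).

`gcuaudit` is for epitranscriptomics analysts who want to test their own
modification-call tables for this class of artifact, and for methods
developers who need a seeded testbed with a planted, recoverable bias.

## What it computes

* **Site statistics** — per-cytosine methylated fractions aggregated from
  per-read calls; strict depth filters (`depth > 100`, shallow preset
  `> 10`); ranking with deterministic tie-breaks; top-N selection; 11-nt
  sequence-context windows.
* **Motif discovery** — central-3-mer enrichment counts (GCU count vs
  runner-up), and a ZOOPS (zero-or-one-occurrence-per-sequence) EM
  position-weight-matrix learner, widths 3–6, 0-order background, given
  strand only, with mononucleotide-shuffle permutation p-values
  (selection-adjusted across widths).
* **Context comparison** — fractions stratified by central 3-mer
  (histograms at bin width 0.025); GCU vs non-GCU medians, median fold
  change, two-tailed Welch z
  `z = (x̄_A − x̄_B) / sqrt(s²_A/n_A + s²_B/n_B)`, and Cohen's d with pooled
  SD; paired native/IVT comparison with per-context Kolmogorov–Smirnov
  distances and an `"artifact-consistent"` verdict when the GCU elevation
  is significant in both samples.
* **Synthetic data** — seeded transcriptome and per-read call simulation
  with a planted context bias (`p_base = 0.1`, `p_GCU = 0.25`, depth 100 by
  default) and optional true modification sites, for native/IVT pairs.

See `vignettes/gcu-artifact-audit.Rmd` for the model and design details.

## Worked example

Simulate a native/IVT pair with the default planted bias (per-read
false-call probability 0.25 at GCU vs 0.1 elsewhere, so the planted median
fold is 2.5) and 25 true modification sites in the native member only, then
run the audit:

```r
library(gcuaudit)

cfg_native <- simulation_config(n_true_sites = 25L, seed = 101)
cfg_ivt    <- simulation_config(n_true_sites = 0L,  seed = 102)
ref  <- generate_transcriptome(cfg_native)
pair <- simulate_pair(ref, cfg_native, cfg_ivt)
native <- aggregate_fractions(pair$native$calls)
ivt    <- aggregate_fractions(pair$ivt$calls)

ranked  <- rank_top_n(native, n = 1000, min_depth = 10)
windows <- extract_windows(ref, ranked$sites, flank = 5)$windows
count_central_kmers(windows, k = 3)
#> central 3-mer counts over 995 windows
#>   top: GCU (561), ratio to runner-up 14.76
#> GCU UCG GCA ACU CCG ACA CCU UCC ACG UCU
#> 561  38  37  36  32  31  29  29  28  28

compare_gcu(native, ref, min_depth = 10)
#> GCU (n=568) vs non-GCU (n=8832): medians 0.250 vs 0.100 (fold 2.50)
#>   Welch z = 66.200, two-tailed p = 0, Cohen's d = 2.920

compare_gcu(ivt, ref, min_depth = 10)
#> GCU (n=568) vs non-GCU (n=8832): medians 0.253 vs 0.099 (fold 2.56)
#>   Welch z = 79.910, two-tailed p = 0, Cohen's d = 4.855
```

Reading the output: more than half of the top 1,000 sites are GCU-centred
(14.8× the runner-up 3-mer), the GCU median fraction is 2.5-fold the
non-GCU median — recovering the planted ratio — and the same elevation
appears in the IVT sample, which contains no modified bases at all. That
combination is the artifact signature: `run_compare_pair()` renders it as
the verdict `artifact-consistent`.

Real data enter through `read_site_table()` (TSV of per-site fractions),
`read_per_read_table()` (per-read calls), `read_fraction_track()`
(wiggle/bedGraph fraction + coverage tracks), and `read_fasta()` for the
reference. A thin command-line wrapper with the same defaults lives at
`inst/exec/gcuaudit` (subcommands `simulate`, `fractions`, `audit`,
`stratify`, `compare-pair`).

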