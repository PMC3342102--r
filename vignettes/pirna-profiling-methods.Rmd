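---
title: "Profiling transposon piRNAs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling transposon piRNAs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnaprofiler)
```

## The analysis

PIWI-interacting RNAs (piRNAs) are 23–30 nt small RNAs that guide PIWI
proteins to silence transposons in animal gonads. In the silkworm *Bombyx
mori*, the female-limited W chromosome is a source of female-enriched
piRNAs, and profiling ovarian piRNA libraries against a transposon
consensus set is the standard way to ask whether a mutant ovary has lost
specific piRNA populations.

`pirnaprofiler` implements that profiling analysis as a tested pipeline
over tabular (tibble) data:

1. **Trim** — each 36-cycle raw read is scanned for its 3′ adapter,
   tolerating up to 2 substitutions; reads without an adapter are
   discarded; inserts of 23–30 nt (inclusive) are kept.
2. **Map** — inserts are aligned with **zero mismatches**, strand-aware,
   to a genome reference and to a transposon consensus set. All perfect
   hits are reported.
3. **Profile** — the number of distinct reads mapping perfectly to the
   genome is the library's sequencing-depth proxy; per-transposon
   sense/antisense read counts are scaled to reads per million (RPM),
   `rpm = 1e6 * reads / genome_mapped_total`. Two library-level statistics
   summarise piRNA character: the **1U bias** (percentage of
   transposon-mapped reads starting with T) and the **antisense bias**
   (pooled antisense/sense read ratio).
4. **Compare** — per transposon and strand class, a sample library's RPM is
   divided by the wild-type baseline's to give relative expression
   (RE, baseline = 1), classified into three bands (reduced RE < 0.6,
   unchanged 0.6 ≤ RE ≤ 1.6 inclusive, elevated RE > 1.6). Replicates are
   summarised by mean ± sample SD and a percent reduction,
   `100 × (1 − mean RE)`.

The comparison is restricted to transposons whose total RPM in the
baseline library **strictly exceeds** 500 — a transposon at exactly
500 RPM is excluded — so that RE ratios are computed only where the
baseline is well measured.

## The synthetic-data generator

Deposited sequencing libraries are not required: `generate_references()`,
`transposon_models()` and `simulate_library()` produce libraries with
per-read ground truth (source element, strand, true insert, adapter
offset), which makes every stage testable and gives the acceptance checks
known generative parameters to recover.

What the generator emulates:

* **References.** 121 random consensus sequences of 800–2000 nt, each
  embedded verbatim once in an otherwise random 400 kb genome with at
  least 100 nt of background between copies. Verbatim embedding guarantees
  that every consensus-derived read also maps perfectly to the genome, so
  the RPM denominator is well defined.
* **piRNA reads.** A source transposon is chosen proportionally to its
  abundance weight, the strand is antisense with probability
  `antisense_fraction`, the insert length is drawn from a distribution
  peaked at 27 nt (the typical mode of ovarian piRNA lengths), and a
  window of the consensus is sampled. The 5′ base is forced to U/T with
  probability `u_probability` by **resampling the start position** (up to
  50 attempts) rather than editing the base, so the insert remains an
  exact consensus substring and stays perfectly mappable; in the rare case
  no attempt succeeds the first base is substituted, and such a read
  simply fails zero-mismatch mapping.
* **Background reads.** Inserts drawn from genome intervals that do not
  overlap any embedded copy (strand 50/50). They count toward the genome-
  mapped denominator but toward no transposon — as intergenic piRNA-like
  reads do in real libraries.
* **Junk reads.** Random 36-mers rejected-resampled until they contain no
  adapter occurrence within the trimmer's tolerance; they exercise the
  `no_adapter` discard path.
* **Adapter and errors.** The insert is followed by the ligated 3′
  adapter, the read is truncated to the 36-cycle window, and per-base
  substitution errors (default 0) are applied last — so adapter copies can
  carry mismatches, exercising the ≤2-mismatch trimmer.

Bias presets (`pirna_presets()`) encode the published ovarian statistics:
wild type at 1U = 73%, antisense ratio 3.5; the masculinized mutant at
69% and 3.7, with the antisense *fraction* parameterised as `r/(1+r)`.
The `reduced_factor` of 0.6 scales designated families' abundance
weights to emulate the reported ~40% drop of specific female-enriched
piRNAs.

Defaults chosen once, with rationale:

| parameter | default | why |
|---|---|---|
| piRNA / background / junk reads | 200 000 / 20 000 / 5 000 | a realistic small-RNA library scale at which binomial noise on the bias statistics is well below printed precision |
| abundance weights | Zipf, exponent 1.5 | heavy-tailed family abundances; roughly half to two-thirds of 121 families clear 500 RPM, matching the scale of published abundant-family counts |
| insert lengths | weights peaked at 27 nt over 23–30 | ovarian piRNA length mode |
| adapter | fixed 20-mer (`default_adapter()`) | the original kit's adapter is unpublished; any ligated 3′ adapter behaves identically here, and the sequence is configurable |
| cycle length | 36 | the sequencing chemistry the analysis assumes |
| RNG | R Mersenne–Twister, one stream per library seed | byte-identical reruns |

What the generator does **not** emulate: quality-score variation (a
constant placeholder is written), indels, PCR duplicates, ping-pong
(10-nt 5′ overlap) structure, genomic polymorphism between reads and
reference, and sequence similarity *between* transposon families. Passing
tests therefore show that the pipeline's arithmetic and contracts are
right under the stated generative model — not that the biology of a real
library is fully captured. In particular, cross-family multi-mapping,
common for real transposons, is exercised only by targeted unit fixtures,
not by the generator's random consensi.

## Numerical and policy decisions

* **Leftmost adapter match.** When several positions satisfy the mismatch
  bound, the smallest offset wins (the shortest insert) — the standard
  trimming convention. A minimum overlap of 6 nt prevents spurious 1–2 nt
  "adapter" tails; `N` always counts as a mismatch. An adapter at offset 0
  (empty insert) is tallied as `too_short`.
* **Re-trimming is not exactly idempotent.** A random 23–30-mer contains a
  chance ≥6 nt adapter-prefix match with ≤2 mismatches a few percent of
  the time, so re-scanning kept inserts at the short overlap can fire; no
  *complete* adapter occurrence can survive, and the test suite asserts
  that form. This is a property of mismatch-tolerant scanning, not of the
  data.
* **All-hits mapping.** The mapper reports every perfect hit on both
  strands (no best-hit sampling), from a forward-strand 23-mer index plus
  full-length verification; 23 is the minimum query length, so one lookup
  serves all query lengths. Coordinates are 0-based, half-open, reported
  on the reference's forward strand. Reads are collapsed to unique
  sequences before mapping and re-expanded afterwards — provably the same
  result, much faster on deep libraries.
* **Counting policy.** A read counts once per (transposon, strand)
  regardless of how many positions it hits, and counts toward every
  transposon it hits. The genome-mapped denominator counts distinct
  reads, never hits.
* **1U-bias denominator.** Computed over transposon-mapped reads, the
  closest reading of how the statistic is reported for transposon piRNAs;
  the all-kept-reads variant is exposed alongside
  (`one_u_bias_all_reads`) so both denominators can be compared.
* **Antisense bias is pooled.** One scalar per library,
  `sum(antisense) / sum(sense)`; a mean of per-transposon ratios would be
  undefined whenever a family has zero sense reads.
* **Baseline.** A single designated wild-type library by default; when
  several baseline replicates are supplied their mean RPM is used.
* **Replicate spread.** Sample SD (divisor n − 1), appropriate for n = 3
  biological replicates; undefined (NA) below two values.
* **Degenerate statistics are errors or NA, never numbers.** RE with a
  zero baseline is NA; 1U/antisense bias with an empty denominator raise
  errors; the pooled t test returns p = 1 for identical constant groups
  and p = 0 (t = ±Inf) for different constant groups. No multiple-testing
  correction is applied; p values are emitted raw.

## Problem sizes and runtime

The acceptance-scale runs use one wild-type and six mutant libraries of
225 000 reads each (200 000 piRNA + 20 000 background + 5 000 junk)
against 121 consensi in a 400 kb genome; a full
simulate → trim → map → profile pass takes roughly 15 s per library on
one core. Unit and property tests use 4–6 families and 10³–10⁵ reads,
chosen so the binomial convergence checks (3 SD) are meaningful while the
whole suite stays fast.

## A worked miniature

```{r example}
refs <- generate_references(n_transposons = 4, length_range = c(300, 500),
                            genome_length = 6000, seed = 1)
models <- transposon_models(refs, preset = "wt-ovary")
lib <- simulate_library(refs, models,
                        library_config(n_pirna_reads = 4000,
                                       n_background_reads = 400,
                                       n_junk_reads = 100, seed = 2))
trimmed <- trim_and_filter(lib$reads)
trimmed$tallies

mapping <- map_library(trimmed$trimmed,
                       build_index(c(genome = refs$genome)),
                       build_index(refs$transposons))
wt <- profile_library(trimmed, mapping, library_id = "wt")
glance(wt)
```

The recovered 1U bias and antisense bias estimate the preset's 0.73 and
3.5/4.5 to binomial accuracy at this depth; `tidy(wt)` holds the
per-transposon RPM table, and `autoplot(wt)` plots sense versus antisense
abundance. A mutant-versus-wild-type comparison chains the same pieces:

```{r compare}
kg_models <- scale_abundance(transposon_models(refs, preset = "kg-ovary"),
                             "TE002", 0.6)
kg_lib <- simulate_library(refs, kg_models,
                           library_config(n_pirna_reads = 4000,
                                          n_background_reads = 400,
                                          n_junk_reads = 100, seed = 3))
kg_trim <- trim_and_filter(kg_lib$reads)
kg <- profile_library(kg_trim,
                      map_library(kg_trim$trimmed,
                                  build_index(c(genome = refs$genome)),
                                  build_index(refs$transposons)),
                      library_id = "kg")
comparison <- compare_profiles(kg, wt,
                               transposon_ids = filter_abundant(wt, 500))
summarize_comparison(comparison)
```

`run_pipeline()` (or the `pirna-profiler` script in `exec/`) wraps the
same steps with a YAML configuration, fixed on-disk layout and a JSON
manifest whose TSV outputs are byte-identical across reruns.

## Known limitations

* Exact (zero-mismatch) mapping only: reads carrying sequencing errors or
  polymorphisms relative to the reference simply fail to map, exactly as
  the no-mismatch policy dictates; there is no mismatch-tolerant rescue.
* The mapper's index holds every reference k-mer in memory — appropriate
  for transposon consensus sets and the compact simulated genome, not for
  chromosome-scale mammalian references.
* `two_sample_t()` is provided for replicate RE comparisons as a
  convenience; the original significance criterion for piRNA reductions is
  not specified beyond replicate spread, so no particular test is asserted
  by the pipeline itself.
* Band boundaries (0.6, 1.6) and the 500 RPM filter are conventions of
  the published heat-map presentation, exposed as parameters rather than
  hard-coded truths.
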