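---
title: "Methods: discordant-pair fusion discovery and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discordant-pair fusion discovery and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fusionsurvey` implements a three-stage computational survey of gene fusions
in paired-end tumor RNA-seq, together with a synthetic-data generator that
makes every stage testable without external data. This vignette is the
package's own account of the methods: the models, the tunable parameters,
the numerical choices, and what the synthetic data do and do not show about
real data.

## The discovery model: discordant read pairs

A fusion transcript joins the leading exons of a 5' partner gene to the
trailing exons of a 3' partner. A paired-end fragment that straddles the
fusion junction produces a *discordant read pair*: two mates that map
uniquely to two different genes. Discovery proceeds as:

1. **Trimming.** Reads are cut to their 5'-most 30 nt
   (`trim_reads(mode = "five_prime_30")`). Shorter reads widen the span
   between the two mates, raising the chance that the junction falls
   between them rather than inside a read.
2. **Exact mapping.** Trimmed pairs are mapped in paired-end mode with no
   mismatch, indel, or splicing inside a read (`map_pairs_exact()`), on
   both strands, via a k-mer index (`k = 17`, chosen so the shortest query
   the pipeline ever produces — a 17-nt trimmed end — is a single-k-mer
   lookup). `N` never matches anything. No insert-size or orientation
   constraint is applied: abnormal inserts and unusual orientations are
   exactly what a rearrangement produces, and filtering them is known to
   delete true positives such as read-through-like junctions.
3. **Discordant collection.** A pair is discordant iff both mates map
   uniquely and their enclosing genes differ (`collect_discordant_pairs()`).
   Multi-mapping mates are retained but flagged, and only unique–unique
   pairs feed candidates; uniqueness is the standard guard against
   repeat-driven false fusions. Per-gene "intra" counts are uniquely mapped
   mates not in a discordant pair — the gene's expression proxy.

### Scoring

With `M` total mapped pairs, `inter` discordant pairs for gene pair (A, B),
and `p_G = max(intra_G, 1) / M` (the floor keeps silent genes from zeroing
the expectation):

* **SPER** `= inter / M * 1e6` — support per million mapped pairs.
* **DASPER** `= SPER − expected/M * 1e6`, where
  `expected = D_tot * p_A p_B / Σ_cand p_X p_Y` and `D_tot` is the total
  discordant count. Highly expressed gene pairs accumulate chance
  discordant pairs in proportion to their expression; DASPER subtracts
  that expectation.
* **RESPER** `= SPER / mean(SPER)` over the sample's candidates — support
  relative to the sample's average candidate.

All three are invariant under proportional scaling of
(`inter`, `intra`, `M`). Candidates are filtered at the conventional strict
cutoffs `DASPER > 1.0`, `RESPER > 1.0` and sorted by RESPER descending
(ties: `inter_reads`, then pair name). Note an arithmetic consequence at
small scale: a sample with a *single* candidate has RESPER exactly 1 and
DASPER 0, so it cannot pass the thresholds; the thresholds presuppose a
background of chance candidates, which tiny synthetic runs may not contain.
Sensitivity checks therefore rank the scored table rather than the
filtered one. The 5'/3' orientation of a reported pair is the majority
mate-1 gene across its fragments, ties broken lexicographically — with an
unstranded library this is close to arbitrary, which is why the geometry
label, not the orientation, carries the interpretation.

Pair geometry (`classify_fusion_type()`): different contigs → `inter`;
adjacent (no annotated gene between) and same strand → `read-through`;
adjacent, opposite strands → `cis`; otherwise `intra`. Read-through
candidates are scored, not auto-excluded: genuine oncogenic fusions can be
read-through-like.

## The exclusion ledger

Top candidates are triaged by explicit, ordered rules (`apply_ledger()`):

1. **Known fusion** → set aside (validates the survey; not followed up).
2. **Amplicon association** → excluded. Exome coverage in 10-kb windows,
   normalized by the genome-wide median window depth
   (`estimate_copy_number()`), flags windows at ≥ 3-fold; a candidate is
   amplicon-associated if either gene ± 1 Mb touches such a window
   (`flag_amplicon()`). The 3.0 default splits the situations the rule
   must separate — high-level (6–12-fold) amplification treated as
   exclusionary versus mild (< 2-fold) gains that are tolerated — and is
   configurable.
3. **Misannotation** → excluded. An adjacent same-strand pair joined by a
   single annotated transcript (a *joining-transcript table* shipped with
   the annotation, standing in for EST evidence, since live EST lookup is
   out of scope) is one gene mis-split in the annotation, not a fusion.
4. **Off-frame** → excluded (`check_frame()`, below).
5. **No junction reads** → excluded: a real fusion transcript must yield
   splice-junction-spanning reads.

The rules partition the input; a candidate triggering several rules is
excluded under whichever order, with the first rule in the stated order
reported as the reason. `gbm_survey_example()` runs the bundled top-20
candidate table from a published glioblastoma survey through these rules
as a worked example.

### Reading frame

A junction is in frame when the summed 5'-side CDS length modulo 3
complements the start phase of the first 3'-side CDS interval
(`(len5 mod 3) == (3 − phase3) mod 3`, GFF phase convention). Equivalently,
conceptual translation of the fused CDS reaches the 3' CDS end without a
premature stop — the property the test suite verifies by direct translation
on engineered toy fusions. Only in-frame fusions preserve the 3' partner's
named domains (e.g. transmembrane and kinase domains of a receptor
kinase); `check_frame()` reports the retained domains only when in frame.

## Breakpoint evidence

For a retained candidate, `run_validation()` assembles four lines of
evidence against a two-gene reference (each partner's span ± 1 kb,
`build_pair_reference()`):

* **Coverage discontinuity.** Mean per-exon depth; the first inter-exon
  boundary where one side is ≥ `min_depth` (default 5) and the other falls
  below `side / ratio` (default 10) marks the suspected break intron. The
  defaults demand an order-of-magnitude step that is visually unmistakable
  in a coverage plot; promoter-swap fusions, which over-express the fused
  portion, produce exactly that.
* **Chimeric splice-junction reads.** Untrimmed reads are split-mapped
  (`map_single_spliced()`, ≤ 2 exact segments, annotated splice sites
  preferred, unannotated gaps ≥ 20 nt, smallest gap wins ties); a read
  counts when its segments meet the 5' junction exon end and the 3'
  junction exon start with ≥ `min_overhang` (default 8) exact bases each
  side. No minimum is standard in the field; 8 nt makes a chance exact
  8-mer match (~6 × 10⁻⁵ per position) negligible at these reference
  sizes. Reads whose junction overhang happens to be homologous to the
  other gene are *not* discarded — the corresponding "small homology"
  filter is known to remove true positives.
* **DNA-level fusion-point reads.** Each original 76-nt read is trimmed to
  its two 17-nt ends (`dual_17`), mapped exactly as a pair, and retained
  iff (1) the ends hit the two different genes, (2) either end lies
  *wholly inside* a suspected break intron, and (3) neither end touches a
  repeat-masked interval. Containment in (2) is deliberate: a spliced
  exon–exon junction read whose end extends a coincidental base into the
  intron would otherwise masquerade as DNA-level evidence, and because all
  such reads agree on the exon boundary they would outvote the true
  fusion-point reads.
* **Breakpoint resolution and micro-homology.** Each candidate read is
  decomposed into its longest exact prefix in the 5' gene and longest
  exact suffix in the 3' gene; the overlap of the two maximal extensions
  *is* the micro-homology `h`, and the two break intervals of width `h`
  each contain the true break. Per-read calls are aggregated by majority
  (ties → widest interval, the conservative report of ambiguity). A call
  needs ≥ `min_support` reads (default 2 — one read is an anecdote, two
  independent fragments are not; configurable).

Somatic status: a call is somatic iff tumor-derived support exists and
matched normal-exome support is zero. When junction reads exist but no
fusion-point read survives, the DNA/RNA level is reported as
`"undetermined"` — the honest verdict when the genomic fusion point is
not covered (deep intronic breaks are captured by exome reads only when
the break lies fortuitously close to a captured exon).

## Expression consequences

* **RPKM**: `1e9 · c_g / (L_g · N)` with `L_g` the summed exon length.
* **Outlier samples** (`detect_outlier_samples()`): value above background
  (default 1.0 RPKM; for array data use a cohort quantile, e.g. the 95th
  percentile, since "above background" has no absolute meaning there) and
  above `median + 5·MAD`, with the MAD floored at `0.1·median + 1e-8` so a
  cohort of near-zero values — the typical silent-receptor situation —
  remains callable.
* **Signature derivation** (`derive_signature()`): treated profile versus
  the mean of controls on linear scale; a gene enters at ratio ≥ 2 (up) or
  ≤ 1/2 (down), boundaries inclusive; both directions are kept because the
  activity template is directional. Named genes (e.g. the receptor whose
  activation the signature represents) are excluded last, so the template
  measures downstream activity, not receptor expression itself. Linear
  ratios were chosen over log2 differences; with the inclusive 2-fold
  boundary the two differ only for genes exactly at the cutoff.
* **Activity scoring** (`score_activity()`): each signature gene is
  z-scored across the cohort; a sample's activity is the cosine between
  its z-vector over the signature genes and the ±1 direction vector —
  exactly bounded in [−1, 1], with > 0 read as relative activation. This
  is the nearest-template score reduced to its cosine core; the published
  template method adds resampling significance, which is available as an
  optional permutation p-value (`score_activity_significance()`, 1000
  shuffles, off by default) but is not part of the activity definition.
  Because of the per-gene z-scoring, the score is invariant under any
  per-gene affine transform applied uniformly to all samples.

## The synthetic-data generator as study conditions

`make_reference()` lays alternating-strand multi-exon genes (default 8
genes × 4 exons, exons 150–300 nt, introns 300–600 nt) on one contig, all
exons coding with cumulative phases. `apply_fusion()` plants a DNA-level
join as an extra tumor contig (the wild-type contigs are retained —
a heterozygous somatic event), choosing break positions inside the
requested introns such that exactly `h` bases immediately 5' of both
breaks are identical and the flanking bases differ, so the planted
micro-homology is exactly `h`.

`simulate_rnaseq()` draws fragments from transcripts in proportion to
expression weights, with a pre-mRNA fraction (default 0.01: junction reads
in the hundreds imply intronic fusion-point reads in the single digits, a
roughly 1% unspliced fraction) and normal insert sizes (200 ± 20 nt)
truncated to the 76-nt read length; the library is unstranded (mates
swapped with probability ½). Base errors default to 0 because the mapping
contract forbids mismatches; the error-rate knob exists to measure
sensitivity loss, not as a default condition. `simulate_exome()` draws
fragments wholly inside exon ± flank windows (default flank 100 nt), and
the matched normal uses the wild-type genome whenever the fusion is
somatic. `simulate_dataset()` defaults encode the promoter-swap situation
the survey targets: fused gene weight 20, wild-type 3' partner 0.05,
all other genes 1 — a strongly over-expressed fusion over a silent
receptor, which is what makes the coverage discontinuity and outlier
expression detectable.

What the generator does **not** emulate: sequencing error and quality
variation, PCR duplicates, mappability structure of a real genome (repeats
exist only as planted decoy masks), alternative splicing, multiple
simultaneous rearrangements, and library-preparation biases. Passing tests
therefore demonstrate the correctness of the algorithms under their stated
assumptions — exact reads from a known genome — not robustness to
real-data noise; on real data the exact-matching contract makes the
pipeline conservative (errors cost sensitivity, not specificity).

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; conversions
  happen only at I/O boundaries (GTF 1-based inclusive, BED/bedGraph
  0-based half-open). A single convention kills off-by-one drift.
* The k-mer index stores every position; duplicate k-mers keep all
  positions, and candidate hits are verified by full substring equality,
  so the index is exact, never heuristic.
* Splice-aware mapping tries both orientations and prefers annotated
  junctions; among unannotated decompositions the smallest reference gap
  wins, with the maximal-prefix split reported.
* Zero-coverage contigs, empty candidate tables, empty FASTQ files, and
  all-zero depth vectors are all legal inputs and produce empty (not
  erroneous) outputs; an all-zero exome coverage track is an error
  ("insufficient coverage") because folds are undefined.
* Determinism: every generator routes randomness through a private RNG
  stream seeded from its config and restores the caller's RNG state;
  identical config + seed gives byte-identical output files.

## Problem sizes

The test suite and the acceptance script run on references of 4–8 genes
(~15–25 kb), 400–1500 read pairs per sample, 20-kb mapping-oracle genomes
with 200–500 planted pairs across up to 20 seeds, micro-homology recovery
at h ∈ {0, 1, 2, 5} with ~15× junction depth, and 100-sample × 200-gene
expression cohorts. These sizes were chosen so that brute-force oracles
(naive substring search, per-base coverage counting, direct translation)
remain feasible cross-checks for every stage.

## Known limitations

* Discovery assumes the two partners are distinct annotated genes;
  intergenic breakpoints and intra-genic rearrangements are out of scope.
* Fusion construction and validation assume '+'-strand partners in the
  synthetic genome; the analysis stages themselves are strand-aware.
* The thresholds' behavior at single-candidate scale (RESPER ≡ 1) means
  the filtered table understates sensitivity on tiny cohorts; use the
  scored table for ranking.
* The signature-derivation fold cutoff operates on linear-scale profiles;
  array data preprocessed to log scale must be unlogged first.
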