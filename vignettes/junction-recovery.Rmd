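---
title: "Recovering transposon insertion sites from junction reads"
author: "tradiskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering transposon insertion sites from junction reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tradiskit)
```

## The model

A TraDIS library is a pool of mutants, each carrying one transposon
insertion. After fragmentation, adapter ligation and junction-specific
PCR, Read 1 of a junction fragment is deterministic up to the insertion
point:

```
balancer (3-6 nt, variable) | anchor (20 nt) | mosaic end (19 nt) | genome
```

The balancer staggers cluster phasing on the sequencer; the anchor is the
transposon-internal priming site of the first PCR; the 19-nt Tn5 mosaic
end (ME) is the last transposon sequence before genomic DNA. The
insertion site is therefore the first genomic base after the ME, and the
number of *unique* such coordinates — unique insertion sites (UIS) — is
the number of unique mutants sampled by sequencing.

Recovery proceeds in three steps, each with a small number of tunable
parameters.

### Two-round trimming

Round 1 searches the first `round1_window` = 37 bases of Read 1 (maximum
balancer 6 + pattern 29 + 2 slack for indels) for the 29-nt pattern
`anchor + ME[1:9]`, tolerating up to `floor(round1_error_rate * 29)`
errors — 2 at the 10% default. Two error models are available:

* `edit` (default): unit-cost substitutions and indels, scored by
  semi-global alignment of the whole pattern against the read prefix
  (read bases before and after the match are free). This mirrors
  adapter-trimming tools whose error rate counts indels.
* `hamming`: contiguous placement, substitutions only — strictly never
  more permissive than `edit` at the same budget (a property the test
  suite checks).

Everything up to the end of the match is removed, which deletes the
balancer implicitly; no separate balancer step exists. Ties between
equally good matches are broken by fewest errors, then smallest match
end. One consequence worth knowing: under edit distance a substitution in
the *last* pattern base admits an equal-cost alignment ending one base
earlier, so the tie-break shifts the cut leftward and round 2 then fails;
such reads are dropped rather than mis-trimmed, trading a small amount of
yield for coordinate exactness.

Round 2 requires the read to start with the exact remaining 10-nt ME
(`TAAGAGACAG`), removed with no mismatch allowed, and reads shorter than
`min_remaining_len` = 20 after trimming (a mappability floor) are
dropped. Mates of dropped reads are discarded to keep files paired.

The *usable read fraction* is kept pairs over raw input pairs (the raw
denominator is a deliberate choice; no basecalling-QC pre-filter is
assumed). Because round 2 is exact, a per-base error rate `e` removes
roughly a fraction `1 - (1 - e)^10` of genuine junction reads: at
`e = 0.001` the expected usable fraction of an 80%-junction library is
about 0.79, while at `e = 0.005` it drops to about 0.76. Usable fraction
tracks the library's junction content only up to this error-dependent
survival factor.

### Dual-orientation mapping

Instead of tracking strand flags, the reference is doubled: every
chromosome is indexed forward (`chr1`) and reverse-complemented
(`chr1_rc`), and all reported alignments are forward-orientation hits on
one oriented entry. This reproduces the observable behaviour of mapping
against a two-orientation FASTA and keeping FLAG = 0 records, and it
makes the junction key a plain (entry, leftmost coordinate) pair.

The built-in mapper is seed-and-extend: exact k-mer seeds (k = 21 —
long enough that random 21-mer collisions are absent in the simulated
genome sizes, short enough that reads with up to ~2% substitutions retain
an intact seed), ungapped extension over the full read, Hamming scoring
with budget `floor(0.05 * read_len)`, and a unique-best rule: if the best
placement is not strictly better than the second best the read is
discarded rather than risk inflating UIS with ambiguous coordinates.
Extension is ungapped because the substitution-only error model makes
gapped placements superfluous and the junction definition uses only the
leftmost coordinate. External alignments can be supplied as SAM text
(`read_sam_alignments()` + `filter_forward()`), in which case only the
mandatory columns are interpreted.

### Junction calling

Forward alignments are de-duplicated by (oriented entry, 1-based leftmost
coordinate); group sizes are the junction counts and the number of
alignments entering the caller is the CPM denominator (counts per million
*mapped* reads, taken after the orientation filter). Putative junctions
with CPM below `cpm_min` = 1 are flagged out; the rule is implemented as
"keep CPM >= 1" — i.e. the strict complement of removing `< 1` — so a
junction sitting exactly at 1 CPM survives. With read depth equalised by
`subsample_pairs()` (default 5,000,000 pairs, drawn uniformly without
replacement, order-preserving and seeded) UIS counts are comparable
across strains and conditions; `compare_conditions()` reports each
condition's mean UIS as a percentage of a reference condition, with the
± half-range across duplicate replicates.

Junction identity deliberately lives in oriented-entry space: a forward
junction at `chr1:100` and a reverse junction projecting to the same
genomic base are distinct mutants (the transposon points in opposite
directions) and are counted separately. `rc_to_fwd_pos()` and
`project_truth()` translate to forward coordinates for interpretation.

## What the simulator emulates — and what it does not

`simulate_library()` draws a uniform-random genome (50% GC), `n`
distinct insertion sites at least one read length from contig ends, with
uniform position, equal-probability orientation, and i.i.d. log-normal
clone abundances (`abundance_sigma`, default 1 — a one-parameter skew
standing in for clonal expansion during recovery and selection; CV =
sqrt(exp(sigma^2) - 1) ≈ 1.31 at the default). Read pairs are junction
fragments with probability `junction_fraction` (default 0.8, the usable
proportion a well-behaved hybrid library produces) and plain genomic
fragments otherwise; fragment lengths are uniform on 300–400 bp
(sonication range), reads are 150 bp, and each base is substituted
independently at `base_error_rate` (default 0.001, a typical modern
basecall error). Read 2 is the reverse complement of the fragment's
distal end — entirely genomic at these fragment sizes — and is used only
to verify mate synchronisation; mapping consumes Read 1 alone. At contig
edges the fragment is clamped to the sequence end rather than resampled,
a simplification that can shorten Read 2 near boundaries.

Deliberately not modelled: PCR duplicates, GC bias, quality-score error
profiles (qualities are constant Q40 and never used), indel sequencing
errors, the 9-bp target-site duplication of real Tn5 insertions
(invisible to a leftmost-coordinate caller), and adapter read-through.
Non-junction pairs are pure genomic carryover; real libraries may also
contain adapter artefacts. Passing recovery tests on these simulations
therefore demonstrates the correctness of the trimming/mapping/calling
logic and its coordinate bookkeeping — not robustness to every artefact
of real sequencers, which is what the mismatch budgets and the CPM filter
are there to absorb.

## Numerical and design choices

* Round-1 error budget `floor(0.10 * 29) = 2`, matching the standard
  adapter-trimmer convention for a 10% error rate.
* Edit-mode is the default error model because the tools this workflow
  descends from count indels in their error rate; `hamming` is provided
  for substitution-only analyses.
* The CPM denominator is the post-filter alignment count. Passing a
  different total to `junction_table()` reproduces the alternative
  (pre-filter) reading if desired.
* Degenerate inputs are defined, not errors: zero input pairs give a
  usable fraction of 0; an empty junction table classifies to zero UIS;
  an empty called set has precision 1 by convention and recall 0.
* Subsampling is implemented as a sorted uniform index sample, which is
  distributionally identical to single-pass reservoir sampling and
  order-preserving; with fewer pairs than the target it returns
  everything with a warning.
* One run seed is fanned out to stages as seed + stage ordinal, so stages
  are independently reproducible and a full rerun is byte-identical.
* The synthetic KAN2 cassette (1221 bp) reproduces only what downstream
  steps can see: the read-side terminus `anchor + ME`, the opposite
  terminus starting with the reverse-complemented ME (where the
  amplification primers anneal), and a seeded 50%-GC filler with no
  homopolymer above 6. It is labelled synthetic throughout.
* The transposome molar-ratio calculator exposes the DNA concentration
  and volume-ratio terms instead of fixing them: with 400 ng of the
  1221-bp cassette at 100 ng/µL mixed 1:2 with 1 µM Tn5 it gives ≈ 15.9:1
  Tn5:transposon, and since a complete transposome needs 2 Tn5 per
  transposon, at most ≈ 13% of Tn5 can reside in complete complexes.

```{r molar}
mix <- transposome_mix(dna_mass_ng = 400, cassette_len_bp = 1221,
                       dna_conc_ng_per_ul = 100, tn5_conc_uM = 1,
                       volume_ratio_tn5_to_dna = 2)
r <- molar_ratio(mix)
c(ratio = r, complete_fraction = complete_transposome_fraction(r))
```

## Problem sizes used in validation

The test suite validates the kernels against independent oracles — a
vectorised dynamic-programming aligner for trimming, and an exhaustive
`Biostrings::matchPattern` scan for mapping — on 10,000 and 5,000 reads
respectively, and runs end-to-end recovery on a 200 kb genome with 1,000
insertion sites and 2,000,000 read pairs at 0.5% base error, sizes chosen
so the whole suite runs comfortably on a laptop while keeping per-site
expected coverage (~1,500×) in the regime where the 1-CPM filter is the
binding detection limit. At that scale precision and recall against
truth are 1.00 for sites above the detection floor.

## Limitations

* The built-in mapper is ungapped and single-threaded; for real bacterial
  genomes with repeats or indel-rich data, map externally and ingest SAM.
* SAM ingest is text-only and minimal (mandatory columns + `NM`); BAM is
  out of scope.
* No gene-level essentiality statistics (insertion-index models,
  condition comparisons beyond relative UIS percentages) are provided.
* Junction calling assumes substitution-dominated errors; indel errors in
  the genomic part shift leftmost coordinates by design of the upstream
  tools, not of this caller.

```{r session, echo = FALSE}
sessionInfo()
```
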