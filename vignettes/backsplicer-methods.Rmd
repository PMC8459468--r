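---
title: "Seed-anchored circRNA annotation and quantification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-anchored circRNA annotation and quantification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(backsplicer)
```

## The problem

Circular RNAs (circRNAs) arise when a downstream splice donor joins an
upstream splice acceptor, producing a covalently closed transcript whose
only sequence-level signature is the backsplice junction. Detection
pipelines that call circRNAs from chimeric alignments disagree
substantially with one another and carry many false positives, and their
sensitivity degrades as reads get shorter. `backsplicer` addresses both
problems with a two-phase design:

1. **Annotation** — candidate junctions from any number of upstream
   pipelines are merged into one coordinate-keyed catalog, re-annotated
   against an exon model, and validated experimentally by RNase R
   resistance, yielding a per-tissue *true list*.
2. **Quantification** — junction-spanning reads are counted against
   small junction-centred reference windows with an exact seed rule, so
   counting power is nearly independent of read length and of the
   pipelines used for discovery.

## Boundary scoring and transcript choice

Most circRNAs use annotated splice sites. Each candidate `[start, end)`
is scored against every transcript overlapping it on the same strand:
**2** if `start` coincides with an exon start *and* `end` with an exon
end of that transcript, **1** if exactly one boundary matches, **0**
otherwise. The best-fit transcript is the score maximiser. When several
transcripts tie, we pick the lexicographically smallest
`transcript_id`: a random choice among ties is equally defensible
biologically, but a deterministic rule makes every downstream artifact
reproducible, so the random tie-break is available only behind
`random_tiebreak = TRUE` with an explicit seed. All internal
coordinates are 0-based half-open; GTF (1-based closed) and per-pipeline
candidate dialects are converted only at the I/O boundary, which keeps
off-by-one reconciliation in exactly one place.

Merging defaults to exact coordinate identity after dialect
normalization. Upstream pipelines occasionally disagree by a base or
two; `tolerance` clusters candidates whose boundaries each differ by at
most that many bases (single linkage), represented by the member with
the widest pipeline support. The default is 0 because silently fusing
distinct junctions is the worse failure mode.

## Reference windows

Only reads that *contain* the backsplice junction are informative, so
instead of indexing full circle sequences we index a junction-centred
window: the last `k` and first `k` bases of the circle with
`k = min(W, circle length)`, junction offset recorded. `W` defaults to
70 bases — the read length of the libraries the method targets — and
should be at least the read length in use. For circles shorter than
`W` the window is a rotated copy of the whole circle ("rolling"
construction) and still contains exactly one junction copy. Counting
semantics are identical to a full-circle index because a countable read
must span the junction anyway.

For a candidate whose boundary score is at least 1 the circle sequence
is the spliced concatenation of the best-fit transcript's exon chain
clipped to the candidate; for score-0 candidates it is the unspliced
genomic span. For score-1 candidates the annotation does not pin the
internal structure; we splice with the best-fit chain and record the
choice in the reference metadata, since the unspliced alternative would
make junction windows of exon-boundary-inconsistent candidates
systematically intron-contaminated.

The linear comparison references join the circle to its closest
annotated neighbour exons *within the chosen transcript*:
`linear_left` = upstream exon + first `k` circle bases, `linear_right`
= last `k` circle bases + downstream exon. These carry the host gene's
canonical splice junctions — the RNase R-*sensitive* junctions against
which resistance is judged. A circle at a transcript terminus simply
lacks that side's reference; we deliberately do not fall back to other
transcripts, which would mix host models.

## The seed rule and exclusion

A read supports a junction iff it has an ungapped placement on the
window covering at least `j` bases on each side of the junction, with
the `2j` seed bases centred on the junction matching **exactly** and at
most `m` mismatches elsewhere in the read. Defaults: `j = 5` (a
10-base exact seed across the backsplice) and `m = 2`. `N` counts as a
mismatch wherever it occurs, in read or reference, so it can never
contribute to a seed. Matching is ungapped throughout: at desk scale
the exact definition is preferable to emulating a gapped aligner, and
junction evidence never requires indel alignment. The `m` allowance is
our choice (recorded in run metadata); it absorbs sequencing error
without letting the seed degrade.

Every read supporting a circular junction is then tested against the
linear world: if the full read has an ungapped end-to-end placement
with at most `m` mismatches anywhere in the genome (either strand) or
in the spliced transcriptome, it is discarded. The search is exact, by
pigeonhole k-mer seeding: a read of length `L` is split into `m + 1`
disjoint blocks of `floor(L / (m + 1))` bases; any qualifying placement
contains at least one exact block, so exact block hits enumerate every
candidate placement, each verified base by base. This makes the
exclusion filter provably equivalent to exhaustive search (the test
suite asserts this against a sliding-window oracle on random
instances).

Counting is fragment-level: paired mates hitting the same junction
contribute one count, and the counted (fragment, junction) multiset is
asserted duplicate-free after every run. A fragment matching more than
one distinct circRNA for the same junction kind is discarded as
ambiguous rather than fractionally assigned — conservative, and every
discard is auditable in the evidence report. The library size used for
normalization is the number of reads with any ungapped placement
(genome, transcriptome, or junction reference), the closest exact
analogue of "aligned reads" in an aligner-based workflow.

## RNase R classification

RNase R degrades linear RNA and spares circles. For one sample we take
a mock and a treated library, normalize each junction count to counts
per million aligned reads (CPM), and form the treated/mock ratio for
every junction with mock count at least `min_mock` (default 1). The
ratio could equally be computed on raw counts (`normalized = FALSE`);
CPM is the default because library sizes after RNase R differ
drastically from mock, and the package's own normalization statement
for downstream analysis is per-aligned-read.

The classification threshold is drawn from the data rather than fixed:
the cutoff `c` names the fraction of *linear* junction ratios (the host
genes' canonical junctions, pooled over `linear_left` and
`linear_right`) to declare RNase R-sensitive, and the threshold `tau`
is the nearest-rank upper quantile — the `ceiling(c * n)`-th smallest
of `n` linear ratios. This convention makes the contract exact and
testable: exactly `ceiling(c * n)` linear ratios fall at or below
`tau` for every sample and cutoff. A candidate is **true** iff its
ratio is strictly greater than `tau`; ties go false, which is
conservative and reversible by rescue. A fixed fold-change mode
(`fold_cutoff = 5`) is provided for comparison with the common
5-fold-enrichment practice, which tends to discard genuine but lowly
enriched circles. The choice of `c` itself is left to the user (0.90
by default); `cutoff_sweep()` and the expression-strata diagnostic
exist to support that choice, on the heuristic that well-expressed
candidates reported by many pipelines should survive it.

Across tissues of one species, a circle may fail the cutoff in one
tissue purely for coverage reasons. `collapse_rescue()` re-annotates
any false call whose key is true in another tissue (or in an external
validated list) as *rescued*, with provenance. Rescue only ever grows
the true list.

## The synthetic-data generator

The generator exists so that every stage can be validated on data with
known truth. It emulates: a random genome with single-transcript genes
of 2–8 exons (150–300 bases) separated by introns (60–150 bases) and
intergenic gaps; planted exon-boundary-aligned true circles; decoy
junctions that are boundary-shifted by 1–10 bases or intergenic,
standing in statistically for pipeline artifacts (their reads are
depleted by the simulated RNase R like linear reads); junction-spanning
reads with uniform start positions keeping at least 5 bases on each
side of the junction; and linear reads drawn uniformly from host-gene
transcripts. RNase R treatment is Bernoulli thinning of the mock read
pool: survival 0.9 for circular reads, 0.05 for decoy/linear reads.
Each eligible gene hosts at most one planted junction so that
ambiguity, which the counter deliberately discards, does not confound
recovery checks.

The default study — 120 genes, 50 circles, 50 decoys, 70-base
single-end reads, 64 junction reads per junction, 100 linear reads per
host gene — is the condition under which the end-to-end recovery
properties are asserted: at cutoff 0.90, sensitivity at least 0.95 and
decoy false-positive rate at most 0.10. The serial-dilution design
(`set_halving = TRUE`, 7 sets, 640 junction reads per circle in set 1)
plants half the circular reads of each set in the next, and recovered
totals must keep consecutive ratios in [0.4, 0.6] wherever expected
counts are at least 100. Validation problem sizes elsewhere in the test
suite are smaller (tens of genes, tens of reads per junction), chosen
as the smallest instances that still exercise every code path.

One generator rule deserves emphasis: a drawn junction read whose
junction overhang is so short that the whole read also has an
end-to-end linear placement within the default mismatch allowance is
redrawn. Such a read is not valid circular evidence — the exclusion
filter would (correctly) remove it — so planting it would make exact
recovery of the truth ledger impossible by construction, not by defect.
The redraw guarantees the invariant *planted = recovered* at
survival 1 for the default matching parameters.

What the generator does **not** emulate: sequencing errors and quality
scores (qualities are written as constant `I` and never used), PCR
duplicates, expression heterogeneity between circles, multi-transcript
genes, alternative circle isoforms sharing a backsplice, and the
specific artifact spectra of real detection pipelines. Passing tests
therefore demonstrate the correctness of the algorithms under their
stated model, not field performance on real libraries.

## Numerical and degenerate-input conventions

* Nearest-rank (upper) quantiles everywhere a quantile is taken
  (threshold, expression terciles); ties at the threshold classify
  false.
* Expression terciles with a degenerate spread (all values equal)
  assign every record to `mid`.
* Empty libraries quantify to all-zero counts with a warning; an empty
  reference list writes valid empty FASTA files.
* The DE-matrix read filter is interpreted as *total across the
  matrix* (`filter = "total"`, default 2 reads), switchable to a
  per-sample interpretation; the filter is defined on raw counts, so it
  commutes with normalization.
* The Welch test in `total_circ_load()` degrades to `NA` statistics
  with a warning when a group has zero variance instead of failing the
  whole computation.
* Fragments are keyed by read id with the `/1`/`/2` mate suffix
  stripped; duplicate (id, mate) pairs are fatal.

## Known limitations

* Alternative internal-exon isoforms of one backsplice junction are not
  resolved; they would require a different experimental design, and the
  junction window counts them as one species.
* Ungapped matching means a read with a true indel near the junction is
  not counted.
* The linear transcriptome used for exclusion is exactly the annotation
  supplied; unannotated linear transcripts can leak reads past the
  exclusion filter, which is why the genome placement check runs as
  well.
* `merge_candidates()` with a large tolerance can chain-merge distinct
  junctions via single linkage; the default tolerance of 0 avoids this
  entirely.

## A worked run

```{r, eval = FALSE}
res <- run_pipeline(sim_config(seed = 1), cutoff = 0.9)
res$performance
glance(res$classification)
autoplot(res$classification)
```
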