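---
title: "Detecting intermediate-size indels from soft-clipped reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting intermediate-size indels from soft-clipped reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(clipindel)
```

## The signal and the model

Short-read aligners handle an intermediate-size indel (50 bp–10 kb) by
refusing to: a read crossing the breakpoint is aligned on its longer
anchor and the rest is soft-clipped; a read falling wholly inside a long
insertion is left unmapped while its mate anchors in the flank.
`clipindel` models an indel as a pair of breakpoint clusters:

* a **FWD** cluster at reference coordinate $p_f$: reads anchored
  upstream, clipped sequence extending rightward — for a deletion the
  clips carry sequence from *beyond* the deleted span; for an insertion,
  the insertion's prefix;
* a **BWD** cluster at $p_b$: reads anchored downstream, clipped
  leftward — the mirror image.

A deletion of length $L$ satisfies $p_b - p_f = L$; an insertion leaves
$p_b \approx p_f$. Both clips sample the same *variant haplotype*
around the event, which is why the pipeline can reconstruct it by pure
consensus: per cluster, clips are breakpoint-anchored, multiple-aligned
and majority-voted into a consensus fragment; the FWD and BWD fragments
(each extended with its anchoring reference context) are two overlapping
windows on that haplotype and are merged through their overlap. Aligning
the merged consensus $C$ against the reference window $R$ (±5,000 bp
around $p_f$) with an alignment that is *global in* $C$ and *local in*
$R$ exposes the event directly: a run of $L$ reference-only columns is a
deletion of length $L$, a run of consensus-only columns an insertion.

## Scoring: why gap-extend 0

The glocal DP uses match $+5$, mismatch $-20$, gap-open $-20$,
gap-extend $0$ (affine: a gap run of length $k$ costs
$\text{open} + k\cdot\text{ext}$). The zero extension cost is the load-
bearing choice: a 10 kb deletion then costs one gap-open — the same as a
single mismatch penalty — so event size does not compete with alignment
score. The large mismatch penalty keeps the flanks pinned. The match
reward is not derivable from the published penalties-only description;
+5 is a conventional DNA match score and only relative magnitudes
matter here. Traceback ties prefer diagonal, then gap-in-target, then
gap-in-query, and the leftmost equal-scoring target window is reported —
consequently calls are emitted in their *leftmost* score-equivalent
placement, the usual VCF normalisation convention, which can shift a
reported position a few bases left of the planted one when flanking
bases repeat.

The same engine provides three border configurations: glocal (free
target prefix and suffix) for consensus-to-reference comparison and for
floating sequences in the star alignment; start-anchored (no free
leading border) for clip-to-centre alignment, since clips share the
breakpoint by construction; and dovetail (free first-sequence prefix,
free second-sequence suffix) for joining FWD/BWD fragments, tried in
both orders. A purely query-global alignment cannot represent the
general suffix–prefix relation between the two extended fragments —
neither contains the other — which is why the join step is an overlap
alignment rather than a literal glocal call.

## Consensus building

Within a cluster the clips are anchored (left ends for FWD; BWD is
reversed first, so the code path is one-sided) and star-aligned: the
longest *clip* is the centre — never a rescued unmapped read, whose
flank overhang would break the anchoring — and insertions relative to
the centre are stacked left-aligned under "once a gap, always a gap".
Per column the most frequent base wins; ties break by summed base
quality, then lexicographically. Two deliberate choices differ from the
most literal reading of the design:

* **End gaps do not vote.** Clip lengths are roughly uniform, so at any
  tail column about half the rows have simply ended. Counting that
  padding as "gap" deletes every column beyond the *median* clip length
  and caps the consensus reach at ~half a read — which silently removes
  all insertions longer than ~60% of the read length. The gap-majority
  rule is therefore evaluated only over rows whose coverage spans the
  column; a column is deleted when *spanning* rows vote gap by strict
  majority (a real deletion signal), and low-depth tail columns survive
  with depth 1–2, where the 90%-identity join check absorbs their
  errors.
* **Join identity is measured over aligned columns.** With gap-extend 0
  the DP may bridge a few tail errors with a long zero-cost gap;
  counting those gap columns in the identity denominator rejected true
  joins. The overlap requirement (≥ 20 columns) is likewise counted on
  aligned columns.

Rescued unmapped reads join the cluster MSA in floating mode and extend
the consensus tail into insertion interiors. Unattached unmapped reads
go to a greedy k-mer assembler (canonical k-mers, seed = most frequent
unused, extend by highest-count neighbour, stop below count 2, default
$k = 25$, contigs ≥ 2k kept); a contig replaces a consensus fragment
that aligns into it at ≥ 90% identity, extending the fragment's reach.
This assembler inherits the documented failure mode of greedy
single-k assembly: insertions whose sequence repeats flanking sequence
at scale ≥ k share k-mers with the flank, so the extension walk aborts
or chimerises and such insertions are mostly missed — the acceptance
suite asserts exactly this contrast rather than hiding it.

## Genotypes and depth

"Supporting depth" is the number of distinct evidence reads (clipped +
rescued) behind the joined consensus, and the ≥ 10 filter applies to it;
reference support is counted as mapped reads crossing the breakpoint
with ≥ 20 bp on both sides and no clip boundary within 3 bp. The
genotype rule — hom iff VAF ≥ 0.8 (boundary inclusive) — is this
package's choice; the original description reports genotypes without
stating a rule. Both thresholds are exposed in `caller_config()`.

## The simulator and what a green test establishes

`sim_config()` defaults encode the published benchmark world at desk
scale: 10 kb bins (10 of them rather than 100 — same per-size structure,
minutes instead of hours), one planted event per bin centred with ±25%
jitter, sizes 100–1,000 bp at 100 bp steps, paired-end 150 bp reads at
100×, outer distance $\mathcal{N}(500, 50^2)$, base error 0.02 and
haplotype point-mutation rate 0.001 (75 bp/200×/0.005 are the other
published grid points). Qualities are a constant Phred 35 and errors are
drawn independently of them, as wgsim does; the mean-quality filter
therefore passes clips exactly as it does on real data. Insertion
sequences are i.i.d. uniform ACGT, or copies of the upstream flank in
`repeat_flank` mode.

`analytic_map()` replaces the aligner: every read's true origin is
known, so full-match, soft-clip and unmapped records can be emitted
exactly. One emulation detail matters: before emitting a clip (and for
reads inside a flank-copy insertion) the read is tested for a
full-length contiguous reference match at ≤ 10% mismatches and mapped
fully when it passes — a real aligner prefers the contiguous placement,
and without this the analytic mapper would leak breakpoint information
no aligner has. This is precisely what removes the BWD cluster of a
tandem-duplication-like insertion and reproduces the repeat-flank
failure end-to-end.

What a green end-to-end test does *not* establish: performance on real
libraries (non-uniform coverage, quality ramps, indel sequencing errors,
PCR duplicates, repetitive genomes — the toy reference is i.i.d. random,
which understates clustering ambiguity), multi-haplotype genotype
calibration (events are planted homozygously), or behaviour of the
BWA path (`detect_indels()` accepts any coordinate-sorted SAM/BAM, but
only the analytic mapper is exercised in CI).

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; 1-based conversion
  happens only in `write_vcf()`.
* Cluster linkage is single-linkage chaining (≤ 3 bp to the previous
  member), so a chain can span > 3 bp overall; `linkage = "span"` bounds
  the total span instead. Representative breakpoint = lower median.
* Rescued reads attach within `insert_sd` (50 bp) of a cluster, not
  3 bp: the mate-distance estimate is soft.
* `estimate_unmapped_breakpoints()` approximates the anchor's reference
  span by the read length when the mate CIGAR is unavailable; negative
  estimates clamp to 0 with a warning.
* Truncated BAMs are rejected by the BGZF end-of-file marker check
  (htslib prints but does not raise; silent zero-record reads are worse
  than an error).
* Overlapping candidate pairs are resolved greedily by descending join
  score, ties by leftmost coordinate; duplicate calls from overlapping
  consensus pairs are deduplicated keeping the deepest.
* `compute_metrics()` reports NaN with a warning on zero denominators;
  table parity uses half-up rounding to 2 decimals. One cell of the
  shipped validation table (NA18948/ScanIndel F-measure, printed 0.39)
  is inconsistent with its own printed precision 0.70 and recall 0.35,
  whose harmonic mean is 0.47; the package asserts the formula value.

## Known limitations

Insertions longer than the combined reach of the two consensus
fragments (roughly `2 × (read_length − anchor_min)` plus whatever
assembly contributes) cannot be fully reconstructed; repeat-of-flank
insertions are missed or mis-placed by design of greedy assembly and of
alignment ambiguity (a tandem duplication's insertion point is only
defined up to the repeat). Translocations, inversions, discordant-pair-
only signals and split alignments via SA tags are out of scope, as are
somatic calling, multi-sample VCFs and CRAM input.
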