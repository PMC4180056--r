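---
title: "Novel sequence discovery: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Novel sequence discovery: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(novasm)
```

## The problem and the model

A de novo assembly of an individual genome contains sequence the reference
assembly lacks — insertions segregating in the population, sequence the
reference build simply misses, and (in practice) contamination. `novasm`
identifies these *novel sequences* by aligning the assembly to the
reference and reporting what cannot be aligned, under the field's
operational definition: at least 100 bp, under 90% identity to the
reference, not a known repeat.

Because assembly and reference are ~99% identical, exact k-mer matches are
a sufficient alignment currency. The model is deliberately gap-free at the
block level: an aligned region is a chain of exact k-mer matches mapping
to a single reference locus (a maximal unique match, MUM), optionally
extended base-by-base. Insertions and deletions between assembly and
reference simply terminate blocks; they are represented by adjacent blocks
on different diagonals, not by gapped edit scripts. This is the right
economy for the task: the object of interest is the *unaligned remainder*,
not a base-perfect alignment.

### Phase 1 — indexing

Each chromosome gets a hash table from k-mer code to ascending positions,
where the code is the base-4 positional value with `A,C,G,T → 0,1,2,3`
(a bijection on N-free k-mers; the mapping itself is an arbitrary fixed
choice). Windows containing N are not indexed — indexing them would
manufacture false seeds from ambiguity. Tables are built in one rolling
pass and stored one chromosome per file, which bounds memory by the
largest chromosome plus the largest query.

### Phase 2 — chromosome assignment with gapped seeds

Scanning every k-mer of every contig against every chromosome is wasteful
when the goal is only to shortlist a target chromosome and orientation.
Instead, seeds are sampled with a fixed gap `g` between consecutive seeds
*on both query and reference*, in `m` offset sets with period `k + g`,
realized by loading only reference positions divisible by
`δ = (k + g)/m`. Multiple offset sets matter: an indel in the query
shifts which seed phase can anchor an alignment, so single-set sampling
would miss a fraction of true alignments.

A chain starts at the first query base whose seed has indexed positions
and grows by intersecting the surviving reference-start set with the next
seed's positions shifted by `k + g`. Most of a mammalian genome is unique
at 25 bp, so intersections collapse to a single locus after a few seeds.
A chain is kept when it is unique and spans at least `min_mum_len`.
Scanning restarts after each chain, so each query base is examined at
most once per orientation — the phase is linear in assembly size.

Chance matches produce spurious regions far from the true locus. Within
one (chromosome, orientation) the longest region anchors the alignment
and regions whose reference start lies more than `D` from the anchor's
are discarded. `D = 10^6` comfortably exceeds the size of almost all
structural variants while still rejecting cross-arm noise; results are
insensitive over 10^5–10^7.

The per-query score for a slot is the total aligned bases after pruning.
Across the `2 × n_chroms` slots, chance scores are approximately
Gaussian; the true target is a right outlier. With `μ, σ` the mean and
population standard deviation over all slots, a slot is assigned iff
`σ > 0` and `(s − μ)/σ ≥ z_crit = 2.326` (one-sided p = 0.01). Three
choices here were genuinely open and are fixed as follows:

* **All slots enter `μ/σ`, including the candidate.** The leave-one-out
  variant is available (`leave_one_out = TRUE`) but the inclusive form is
  the simpler reading and differs negligibly at 48 slots.
* **Population (divide-by-n) standard deviation.** Any consistent choice
  works; dividing by n is the maximum-likelihood Gaussian fit.
* **`z_crit` is the fixed quantile 2.326**, overridable; only the p-value
  threshold is canonical.

Note a structural consequence of the outlier test: a one-hot score vector
over `2n` slots has `z = sqrt(2n − 1)`, so with fewer than ~4
chromosomes nothing can pass at p = 0.01. The test presumes a
chromosome-scale reference; toy references in tests use ≥ 6 sequences.

Queries shorter than `min_mum_len` cannot produce a retainable region and
are routed directly to the unassigned group without scanning.

### Phase 3 — full-density alignment

Assigned queries are re-aligned to their assigned targets using *all*
indexed k-mers (the index is loaded unfiltered; within a chain
consecutive seeds are `k` apart). Raw chains are extended base-by-base in
both directions while query and reference agree (N never matches),
stopping at the first mismatch — extension is exact-match only; "as far
as possible" under a mismatch-tolerant scheme would need a scoring model
the block representation deliberately avoids. The phase-3 minimum block
length is `2k` (24 bp by default): far below the assignment threshold for
sensitivity, above `k` so isolated chance seed hits cannot survive. It is
applied **after** extension, which makes the emitted blocks exactly the
maximal unique exact matches of that minimum length (the acceptance suite
checks this equivalence against a brute-force enumerator).

Overlaps on the query are resolved by length priority; equal lengths are
ordered by a seeded shuffle, and one `rng_seed` governs every random
tie-break in a run (recorded in the run log). Per query the best target
by aligned bases wins, ties broken by chromosome order with forward
before reverse.

The four groups are processed as: aligned ≤ half the query length →
misassigned, re-aligned against all `2 × n_chroms` targets together with
the unassigned group; then maximal unaligned runs longer than
`fp_cutoff = 2500` bp are excised as false-positive novel candidates —
the signature of a chimeric join, where an assembler fused regions of two
chromosomes — and re-aligned against all targets; recovered blocks merge
back into the owning query. The cutoff is data-dependent (it reflects the
size of chimeric fragments in real assemblies) and therefore exposed.

### Candidates and post-filters

The complement of the final blocks, clipped of N runs and filtered at
`min_novel_len = 100`, forms the candidate set. Every candidate records
its originating sequence and its nearest flanking block as an anchor
(chromosome, reference coordinate, side; `unplaced` when the query never
aligned). Filtering is interval subtraction in original-candidate-local
coordinates: BLAST tabular hits are subtracted only at identity ≥ 90%
(below that the hit is itself evidence the sequence diverges enough to be
novel), RepeatMasker intervals always, contaminant masks always with a
per-source removal tally. After each subtraction the 100 bp floor is
re-applied. Keying masks by the *original* candidate id and frame makes
subtraction idempotent and keeps a filter trail whose removals, plus
surviving and refilter-dropped bases, account for every input base
exactly. BLAST and RepeatMasker themselves are never executed — only
their outputs are parsed — and the e-value/identity gates (1e-5 is not
applied by default; identity 90%) are exposed configuration, not
validated constants.

### Viewer

Candidates are drawn in ascending order of originating-sequence length
(ties by candidate id, so the layout is stable), each occupying width
proportional to its bases, with dashed guides at configurable percentiles
(deciles by default) of the origin-length rank. Each comparison set is a
row whose bar height is that candidate's coverage fraction — the bar
height convention is our resolution of an underdescribed display choice;
per-candidate coverage is the quantity the filters already compute, so
the plot and the filters share one source of truth. Runs of candidates
with no coverage in any row stand out as empty columns, which is how
contaminant blocks (e.g. viral sequence among short contigs) are spotted.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `k` | 12 | bp | 8–16 sensible; multiples of 3 preferred (codon structure); 12 balances table size and specificity |
| `gap` | 84 | bp | with `min_mum_len = 200`, about the largest gap that still lets ~3 seeds span a minimum match; divisible by `sets` |
| `sets` | 6 | — | gives `δ = (12+84)/6 = 16`, inside the recommended 10–20 |
| `min_mum_len` | 200 | bp | must exceed 25 (genome uniqueness scale); small enough to assign short contigs |
| `prune_dist` | 1e6 | bp | covers structural-variant scale; results insensitive over 1e5–1e7 |
| `z_crit` | 2.326 | — | one-sided normal quantile, p = 0.01 |
| `min_block_len` | 2k | bp | phase-3 floor, applied post-extension |
| `fp_cutoff` | 2500 | bp | chimeric-fragment scale; data-dependent, exposed |
| `min_novel_len` | 100 | bp | the operational definition of a novel sequence |
| `identity_ceiling` | 90 | % | the operational identity bound |

The advisory three-seed condition `3k + 2g ≤ min_mum_len` is violated by
two bases at the defaults (204 vs 200); this mirrors the recommended
practice of preferring a `gap` divisible by `sets`, and is surfaced as a
construction-time warning rather than an error because two-seed chains
still require uniqueness and the minimum span.

## The simulator: what it emulates and what it does not

`sim_config()` defaults state the testing world once: a 10-chromosome
reference of 50–200 kb, ~60 contigs of 0.5–5 kb, 1% substitutions, sparse
indels (5e-4 per base, ≤ 10 bp), 50 novel insertions of 100–2000 bp, two
3-copy repeat families, occasional N gaps, 5% chimeric and 5% contaminant
contigs. Insertions are uniform random sequence rejection-sampled so that
*neither strand shares a 2k-mer with the reference*; the check runs at 2k
(= the phase-3 block floor), not k, because isolated shared 12-mers are
statistically unavoidable against a megabase reference (tens are expected
per 2 kb insertion) yet cannot seed a reportable block. Insertion
boundary bases are chosen to differ from their flanking contig bases, so
the implanted interval is exactly the unalignable run and the 100 bp
boundary behaves sharply. Insertions are placed with ≥ 200 bp flanks.

The simulator does **not** emulate read-level error profiles, assembler
mis-joins other than clean two-segment chimeras, polymorphic repeat
expansion, or reference gaps. A green test therefore establishes that the
algorithm recovers what its model can represent under realistic mutation
load — not that it matches any particular genome-scale result.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally and in BED; 1-based
  inclusive in FASTA headers and human-readable reports.
* Ambiguity codes other than N are normalized to N on ingest (the index
  skips them regardless); `U` becomes `T`; anything else is an error.
* Reverse-strand matching reverse-complements the *query*, never the
  index; orientation symmetry is then exact by construction.
* Anchor ties (equal-longest regions) break to the smallest reference
  start; pruning distance is measured between reference starts.
* `σ = 0` (all slots equal, e.g. an all-N query) → unassigned.
* An all-N excised false-positive run is not re-scanned.
* Chromosomes shorter than k produce an empty index with a warning;
  empty candidate sets lay out as an empty plot with a warning.
* Saved index files carry magic bytes + version; a version or k mismatch
  on load is an error, as is refiltering an already-filtered index with
  an incompatible δ.

## Known limitations

* Uniqueness is judged on the chained (whole-seed) span; a region whose
  chain prefix is repeated but whose full extension is unique is
  conservatively discarded. Rare in practice, and conservative in the
  right direction for novelty calling.
* After a discarded chain the scan restarts past it ("each base once"),
  so a true alignment overlapping a rejected repeat chain can be missed
  in phase 2; phase 3's density and the four-group routing compensate.
* Candidates are not merged across queries and are not re-placed on the
  reference beyond flank anchoring.
* The non-consecutive-seed geometry assumes indels are rare relative to
  `k + g`; assemblies with dense indels would need a smaller `gap`.
* YAML configuration is not supported offline; JSON and flat `key=value`
  files are.
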