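# novasm — novel sequence discovery in de novo genome assemblies

`novasm` finds **novel sequences**: stretches of DNA present in an
individual's de novo whole-genome assembly but absent from the reference
genome. Operationally a novel sequence is at least 100 bp long, has less
than 90% identity to the reference, and is not a known repeat. The package
is aimed at genome analysts who have a contig/scaffold assembly and a
chromosome-level reference and want the unalignable remainder, with
coordinates, provenance and post-filtering — without running a
general-purpose aligner pipeline.

## The method

Alignment proceeds in three phases over per-chromosome k-mer hash indexes
(`h(w) = Σ d(w_i) · 4^(k−1−i)` with `d(A,C,G,T) = 0,1,2,3`):

1. **Indexing.** Every N-free k-mer window of each chromosome is mapped to
   its ascending positions; one index per chromosome, built in a single
   rolling pass and persistable to disk.
2. **Chromosome assignment** (gapped seeds). Only seed positions divisible
   by `δ = (k + g) / m` are loaded — `m` offset seed sets with period
   `k + g`. Each query is scanned once per orientation; a candidate region
   grows by intersecting reference-position lists of successive seeds
   (`k + g` apart on query and reference) until the match is unique, and
   is kept if its span reaches the minimum MUM length. Regions further
   than `D` (default 10⁶ bp) from the longest region (the anchor) are
   pruned as spurious. Each query keeps one alignment score — total
   aligned bases — per (chromosome, orientation) slot (48 slots for a
   24-chromosome reference). Chance scores are modelled as Gaussian: a
   slot is assigned iff `(s − μ)/σ ≥ 2.326` (one-sided p = 0.01) over the
   per-query score vector.
3. **Query alignment** (full density). Four groups — assigned, unassigned,
   misassigned (aligned ≤ half their length), and false-positive
   candidates (unaligned runs > 2.5 kb, typically chimeric joins, excised
   and re-aligned genome-wide) — are aligned with *all* indexed k-mers,
   extended base-by-base to the first mismatch, overlap-resolved by length
   priority (seeded random ties), and reduced to the best-scoring target.

Final unaligned runs ≥ 100 bp (N runs clipped) become novel candidates.
Parsed BLAST tabular hits (identity ≥ 90%) and RepeatMasker annotations
are subtracted, a contamination screen tallies removals per source
organism, and a viewer renders candidates sorted by originating-sequence
length with per-comparison-set coverage tracks — blocks of uncovered
candidates are the visual signature of contamination.

A seeded simulator (`simulate_genome()`) generates reference + assembly
fixtures with exact ground truth (substitutions, indels, N gaps, repeat
families, chimeric contigs, contaminant contigs, and novel insertions
verified k-mer-disjoint from the reference), so the whole pipeline is
testable offline.

## Worked example

```r
library(novasm)
sim <- simulate_genome(sim_config(seed = 42, n_chroms = 5,
                                  chrom_lengths = rep(60e3, 5),
                                  n_contigs = 25, novel_insertion_count = 10))
cfg <- pipeline_config(rng_seed = 42)   # k=12, g=84, m=6, min MUM 200, D=1e6
res <- run_pipeline(sim$reference, sim$assembly, cfg)
```

prints (package-generated output):

```
queries: 22 assigned / 1 unassigned / 2 misassigned
aligned 59168 of 76034 bases (77.8%)
11 novel candidates, 14271 bases
      candidate_id query_id start  end anchor_chrom anchor_side
1 ctg003:1550-2308   ctg003  1549 2308         chr5        left
2  ctg007:956-2348   ctg007   955 2348         chr4        left
```

22 of 25 contigs get a chromosome+orientation from the outlier test; the
unassigned/misassigned ones are contaminant or chimeric contigs that are
re-aligned genome-wide. The 11 candidates are the implanted insertions
(compare `sim$truth$novel`: ctg003 truth interval [1549, 2274)) plus
contaminant contig sequence; bases aligned + candidate + filtered always
equal total assembly bases exactly. Candidate ids are
`<contig>:<1-based start>-<end>`; internal coordinates (the `start`/`end`
columns and all BED output) are 0-based half-open.

## Command line

```sh
Rscript -e 'novasm::novasm_cli()' simulate --seed 3 --out fixtures/
Rscript -e 'novasm::novasm_cli()' run-all --ref fixtures/reference.fasta \
        --asm fixtures/assembly.fasta --out run/ --seed 11
Rscript -e 'novasm::novasm_cli()' stats --asm fixtures/assembly.fasta
```

Subcommands: `stats`, `split`, `index`, `assign`, `run-all`, `filter`,
`view`, `simulate`; options may come from `--config file.json` or flat
`key=value` files. `index` writes one binary index file per chromosome
(magic bytes, version, k, delta, chromosome id, per-code position arrays)
into the output directory. Exit codes: 0 ok, 1 user error, 2 internal.

## Scope

No base-level CIGAR output, no affine-gap dynamic programming, no
FASTQ/read-level handling, no assembly construction, and BLAST/
RepeatMasker are *parsed*, never executed. See
`vignettes/novel-sequence-discovery.Rmd` for the model, parameter
rationale and limitations.
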