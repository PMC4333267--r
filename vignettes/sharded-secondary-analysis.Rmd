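---
title: "Deterministic sharded secondary analysis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic sharded secondary analysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shardseq)
```

## The problem

The post-alignment half of short-read secondary analysis — duplicate
removal, base-quality recalibration and genotyping — is not
embarrassingly parallel. Duplicate marking needs the whole read set
(duplicate mates can map anywhere), recalibration needs genome-wide
covariate counts, and variants near an interval edge need reads that
overlap the edge. Naive scatter/gather over genomic intervals therefore
either merges everything at costly synchronization points or silently
changes results depending on how the work was cut.

`shardseq` implements a balanced parallelization of this stage that is
*deterministic in the strong sense*: for fixed input, every output file
is byte-identical whatever the shard count `M` or worker count. Three
devices make this possible:

1. **Fixed-boundary subregions with overlap buffers.** The genome is
   cut into `M` near-equal intervals (never spanning a chromosome);
   each carries a buffer, 3 kb by default, on both sides that is used
   only at variant-calling time.
2. **An artificial-chromosome destination (`chrI`).** A read pair
   whose two 5' ends do not fall inside the same subregion — boundary
   spanners and interchromosomal pairs alike — is routed whole to a
   dedicated file, deduplicated there as a unit, and only then are its
   individual reads redistributed to the subregions holding their own
   coordinates.
3. **Covariate merge before recalibration.** Mismatch covariate tables
   are built per shard, summed bin-wise into one sample-wide table, and
   that single table drives recalibration of every shard.

## Why per-shard deduplication is exact

Duplicate marking groups templates by *external coordinates*: the
(chromosome, unclipped 5' position, strand) triples of the two mates,
canonically ordered, plus a library tag. Routing uses precisely those
coordinates: both 5' ends inside one subregion's fixed boundaries send
the pair there, anything else goes to `chrI`. Hence two templates with
equal duplicate keys have equal mate coordinates and receive the same
destination — every duplicate class arrives intact at exactly one
place (closure). Each destination resolves its classes with the same
deterministic survivor rule, so the union of survivors is identical,
record for record, to genome-wide serial deduplication. The test suite
asserts this equivalence on hundreds of randomized fixtures against an
independently written hash-group-and-pick oracle.

The survivor of a class is the pair with the highest mapping quality,
implemented as the larger sum of the two mates' MAPQs because a pair's
"mapping quality" is otherwise undefined when mates disagree; ties fall
to the lexicographically smallest template name so that no ordering of
the input can change a byte. The wider ecosystem convention (sum of
base qualities at or above Q15) is available as
`survivor = "baseq_sum"`. Removal is the default; `mark_only` sets the
0x400 flag instead.

Redistributed `chrI` reads appear in a subregion as lone mates of
mapped pairs; they carry no duplicate key there (their class was
already resolved) and thus are never re-deduplicated. Templates with a
genuinely unmapped mate are deduplicated single-end on the mapped
mate's triple, with a sentinel keeping single-end keys disjoint from
pair keys. Fully unmapped templates pass through untouched.

## The recalibration model

The covariate model bins every aligned (`M`/`=`/`X`) base of a mapped
primary read by **reported quality**, **machine cycle** (1-based
position in the stored read, negated for second-of-pair mates) and
**dinucleotide context** (preceding + current read base; a sentinel bin
for the first base or a non-ACGT predecessor). Insertions and clips
consume no reference and are skipped, as are `N` bases on either side.
Tables merge by bin-wise addition — exactly, with the empty table as
identity — so per-shard tables summed equal the whole-genome table,
which is what entitles every shard's recalibration instance to
genome-wide evidence. No downsampling is performed anywhere.

The recalibrated quality of a bin is a Laplace-smoothed empirical
Phred,

    Q = round(-10 * log10((mismatches + 1) / (observations + 2))),

clamped to `[2, 60]`. The floor and cap avoid Phred 0/1 pathologies and
unbounded scores on large mismatch-free bins; an empty bin maps to Q3.
This transform is a declared stand-in: the upstream ecosystem's
hierarchical delta decomposition is not reproduced, because the
contribution under test is the *merge-then-apply* parallelization, not
the per-bin model. Bases whose bin is absent from the table keep their
reported quality, and all query bases (clipped ones included) are
transformed, so the result depends only on the read and the global
table — never on the shard.

## Variant calling and buffer reconciliation

The bundled caller is deliberately simple plumbing — a position-wise
pileup over the *buffered* window, with evidence drawn from the shard
and its same-chromosome neighbours' reads overlapping the window. A
SNP is emitted where the leading non-reference base reaches
`min_alt_frac` (default 0.2) of depth at `min_depth` (default 8) or
more; `hom_frac` (default 0.8) separates hom from het. Indels come
from CIGAR `I`/`D` evidence, leftmost-anchored at the aligned base to
the left of the event, with VCF-style anchored alleles and the same
thresholds against anchor depth. QUAL is a deterministic binomial-tail
proxy, `-10*log10 P[Binomial(depth, 0.01) >= alt_count]`. The defaults
are arbitrary but fixed; the acceptance fixtures use error-free reads
where thresholds are not load-bearing. Production callers can be
substituted behind the calling stage without touching the graph.

A variant inside a buffer is called twice — by its owner and by the
neighbour whose buffer covers it. Reconciliation keeps a call iff the
fixed boundaries of its *provenance* shard contain its POS (boundaries
are inclusive; a multi-base variant belongs to the shard containing
its anchor, the only unambiguous single location). The owner's record
survives verbatim, including its QUAL, even if the neighbour's buffer
evidence produced a slightly different score. Identical-site,
different-allele calls are distinct variants and all survive.

## The task graph

`plan_tasks()` lays out split (per input) → merge (per destination) →
chrI dedup → redistribute → per-shard dedup → realign (a pass-through
hook; local realignment is out of scope) → covariate build → covariate
merge → recalibrate → call → finalize. Exactly three joins serialize
the graph: the chrI merge, the covariate merge and the final VCF
concatenation. Every task erases scheduling nondeterminism by
canonically sorting (C-locale, full-record key) before writing, which
is the entire determinism argument for `workers > 1`:
`parallel::mclapply` only changes *when* tasks run, never what any
task writes. Splitting is one task per *input* (each pass writes all
of that input's per-destination fragments, preserving the
`inputs x destinations` file layout while reading each input once)
rather than one task per (input, destination) pair — same layout,
`M`-fold less input I/O. `M` defaults to twice the worker count, a
documented load-balancing heuristic. `--emit-scripts` writes one shell script per
task for external schedulers instead of executing; cluster submission
itself is environment, not algorithm.

Resume (`resume = TRUE`) skips tasks whose completion markers exist,
after checking a config digest so a changed configuration forces a
clean re-run. The worker count is excluded from the digest — it must
not invalidate results it cannot change.

## The synthetic world

The generator emulates a typical human resequencing run at desk scale,
and its defaults are the stated world of the tests: uniform-random
A/C/G/T references; 100 bp paired-end reads at 30x coverage; insert
sizes Normal(300, 30) truncated below at the read length; a 15%
PCR-duplicate fraction (duplicates share external coordinates and
CIGARs but get fresh names, errors and MAPQs, and a `du:Z:` tag naming
their original); 5% of pairs re-paired across chromosomes; 5%
soft-clipped read ends that preserve the unclipped 5' coordinate; a
10^-3 substitution error rate; and homozygous spiked SNPs/indels
(indels 1–6 bp, left-normalized by construction) with a truth VCF.
When a partition plan is supplied, at least one SNP lands within the
overlap of every interior boundary, so buffer reconciliation is always
exercised. Reads are emitted pre-aligned to their true origin with
MAPQ 60 by default; alignment itself is upstream of this package's
input boundary.

What the generator does *not* emulate — and hence what a green test
does not establish — includes quality decay by cycle and other
platform error profiles, indel sequencing errors (the caller's indel
path is exercised only through true spiked indels), GC or mappability
coverage bias, optical-duplicate tile geometry, and heterozygous
variation. The equivalence and determinism claims do not depend on any
of these; the caller's accuracy numbers would.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout and stored as doubles,
  so multi-gigabase chromosomes stay exact (doubles are exact
  integers far beyond 2^31).
* All string ordering uses C-locale radix sorts; no output depends on
  the session locale.
* The intervals file stores buffered windows with a `#overlap=` header
  comment; fixed boundaries are reconstructed from the tiling
  invariant (first fixed start is 1, last fixed end is the chromosome
  length, interior edges are buffer-stripped). Pathological files
  whose every edge is clipped are rejected as ambiguous rather than
  guessed at.
* Empty destinations produce header-only files and empty tables, which
  merge as identities; an empty call set writes a header-only VCF.
* `round()` half-even behaviour is irrelevant to the empirical-Phred
  examples asserted (none sit on .5), and QUAL is rounded to one
  decimal purely for stable formatting.

## Known limitations

Single-sample, SNP+short-indel calling only; no realignment, no VQSR,
no structural variants (the retained `chrI` file is kept precisely so
downstream SV tooling has the boundary-spanning evidence). SAM text
only — adequate at desk scale, not a BAM replacement. The recalibration
transform is the declared stand-in above, so its outputs are not
numerically comparable to production BQSR tables.
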