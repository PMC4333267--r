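Package: shardseq
Title: Deterministic Sharded Parallelization of NGS Secondary Analysis
Version: 0.1.0
Authors@R:
    person("shardseq", "developers", email = "shardseq@example.org",
           role = c("aut", "cre"))
Description: Balanced, deterministic parallelization of the post-alignment
    steps of short-read secondary analysis. The genome is divided into
    equal-size subregions with fixed boundaries and overlap buffers; read
    pairs whose mates fall in different subregions are routed through a
    dedicated inter/intrachromosomal ("chrI") file so that duplicate-pair
    removal performed per shard is exactly equivalent to duplicate removal
    on a single genome-wide file. Base-quality covariate tables are built
    per shard and merged so recalibration sees genome-wide counts, and
    variants called in overlap buffers are reconciled by fixed-boundary
    ownership. Includes a seeded simulator of references, aligned
    paired-end reads and spiked truth variants used to test every stage,
    and a pipeline driver whose outputs are byte-identical regardless of
    shard count or worker count.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table (>= 1.14),
    jsonlite,
    parallel,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
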