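test_that("everything is reproducible from the seed", {
  spec <- sim_spec(seed = 5, chrom_lengths = c(c1 = 20000, c2 = 10000),
                   coverage = 4)
  a <- simulate_dataset(spec)
  b <- simulate_dataset(spec)
  expect_identical(a$reference, b$reference)
  expect_identical(as.data.frame(a$variants), as.data.frame(b$variants))
  expect_identical(as.data.frame(a$records), as.data.frame(b$records))
  c <- simulate_dataset(sim_spec(seed = 6,
                                 chrom_lengths = spec$chrom_lengths,
                                 coverage = 4))
  expect_false(identical(a$reference, c$reference))
})

test_that("reference has the requested geometry and balanced GC", {
  spec <- sim_spec(seed = 2, chrom_lengths = c(a = 100000, b = 50000))
  ref <- generate_reference(spec)
  expect_equal(unname(nchar(ref)), c(100000, 50000))
  expect_equal(index_from_reference(ref)$length, c(100000, 50000))
  gc <- sum(strsplit(ref[["a"]], "")[[1]] %in% c("G", "C")) / 100000
  expect_lt(abs(gc - 0.5), 0.02)   # ~6 sigma binomial bound
})

test_that("spiked variants alter exactly their own positions", {
  spec <- sim_spec(seed = 3, chrom_lengths = c(z = 30000), n_snps = 12,
                   n_indels = 0)
  ref <- generate_reference(spec)
  sp <- spike_variants(ref, spec)
  expect_equal(nrow(sp$variants), 12L)
  hap <- strsplit(sp$haplotype[["z"]], "")[[1]]
  raw <- strsplit(ref[["z"]], "")[[1]]
  diffs <- which(hap != raw)
  expect_setequal(diffs, sp$variants$pos)
  # zero variants: haplotype equals reference
  spec0 <- sim_spec(seed = 3, chrom_lengths = c(z = 30000), n_snps = 0,
                    n_indels = 0)
  sp0 <- spike_variants(ref, spec0)
  expect_identical(sp0$haplotype, ref)
  expect_equal(nrow(sp0$variants), 0L)
})

test_that("indels are anchored, short and left-normalized", {
  spec <- sim_spec(seed = 4, chrom_lengths = c(z = 50000), n_snps = 0,
                   n_indels = 25)
  ref <- generate_reference(spec)
  v <- spike_variants(ref, spec)$variants
  expect_equal(nrow(v), 25L)
  expect_true(all(substr(v$ref, 1, 1) == substr(v$alt, 1, 1)))
  expect_true(all(abs(nchar(v$ref) - nchar(v$alt)) %in% 1:6))
  last <- function(s) substr(s, nchar(s), nchar(s))
  expect_true(all(last(v$ref) != last(v$alt)))  # cannot shift left
  # REF matches the reference sequence at its anchor
  for (i in seq_len(nrow(v))) {
    expect_equal(substr(ref[["z"]], v$pos[i],
                        v$pos[i] + nchar(v$ref[i]) - 1), v$ref[i])
  }
})

test_that("a plan makes every interior boundary buffer carry a SNP", {
  spec <- sim_spec(seed = 8, chrom_lengths = c(a = 60000, b = 30000),
                   n_snps = 5, n_indels = 0)
  ref <- generate_reference(spec)
  plan <- partition_genome(index_from_reference(ref), 6, overlap = 3000)
  v <- spike_variants(ref, spec, plan = plan)$variants
  sub <- plan$subregions
  lens <- spec$chrom_lengths
  interior <- sub[sub$end < lens[sub$chrom], ]
  for (i in seq_len(nrow(interior))) {
    b <- interior$end[i]
    hit <- v$chrom == interior$chrom[i] & abs(v$pos - b) <= 3000
    expect_true(any(hit))
  }
})

test_that("truth VCF round-trips through the VCF codec", {
  spec <- sim_spec(seed = 9, chrom_lengths = c(a = 20000), n_snps = 6,
                   n_indels = 3)
  ref <- generate_reference(spec)
  v <- spike_variants(ref, spec)$variants
  tf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, index_from_reference(ref), tf)
  back <- read_vcf(tf)
  expect_equal(back$pos, v$pos)
  expect_equal(back$ref, v$ref)
  expect_equal(back$alt, v$alt)
  expect_true(all(back$genotype == "hom"))
})

test_that("duplicate emission matches the requested rate and is tagged", {
  spec <- sim_spec(seed = 10, chrom_lengths = c(a = 60000, b = 40000),
                   coverage = 20, dup_rate = 0.2, error_rate = 0.001)
  ref <- generate_reference(spec)
  rec <- simulate_reads(ref, NULL, spec)
  n_pairs_total <- length(unique(rec$qname))
  n_dup <- attr(rec, "n_duplicate_pairs")
  frac <- n_dup / n_pairs_total
  expect_lt(abs(frac - 0.2), 0.02)
  # every duplicate's du: tag names an original with an equal key
  keys <- duplicate_keys(rec)
  dup_rows <- rec[grepl("^du:Z:", rec$tags)]
  pairing <- unique(data.frame(q = dup_rows$qname,
                               o = sub("^du:Z:", "", dup_rows$tags)))
  km <- keys$key[match(pairing$q, keys$qname)]
  ko <- keys$key[match(pairing$o, keys$qname)]
  expect_gt(nrow(pairing), 0)
  expect_equal(km, ko)
})

test_that("with zero duplication, key collisions stay near the birthday bound", {
  spec <- sim_spec(seed = 12, chrom_lengths = c(a = 100000),
                   coverage = 10, dup_rate = 0, clip_rate = 0)
  ref <- generate_reference(spec)
  rec <- simulate_reads(ref, NULL, spec)
  keys <- duplicate_keys(rec)
  n <- nrow(keys)
  collisions <- n - length(unique(keys$key))
  # pairs land on ~100000 x insert-sd grid; a loose 10x expected bound
  expect_lt(collisions, max(10, 0.01 * n))
})

test_that("interchromosomal rate feeds the chrI destination", {
  spec <- sim_spec(seed = 13, chrom_lengths = c(a = 60000, b = 40000),
                   coverage = 15, interchrom_rate = 0.05, dup_rate = 0)
  ref <- generate_reference(spec)
  rec <- simulate_reads(ref, NULL, spec)
  plan <- partition_genome(index_from_reference(ref), 4, overlap = 3000)
  dest <- route_records(rec, plan)
  frac <- length(unique(rec$qname[dest == -1L])) /
    length(unique(rec$qname))
  expect_gte(frac, 0.045)   # boundary spanners only add to it
  inter <- rec[rec$rname != rec$rnext & rec$rnext != "*"]
  expect_gt(nrow(inter), 0)
})

test_that("simulated records are well-formed SAM", {
  fix <- small_fixture(14, coverage = 3, clip_rate = 0.3)
  rec <- fix$records
  expect_true(all(nchar(rec$seq) == nchar(rec$qual)))
  st_q <- vapply(rec$cigar, cigar_query_len, numeric(1))
  expect_equal(unname(st_q), nchar(rec$seq))
  expect_true(all(rec$pos >= 1))
  # exactly one first-of-pair and one second-of-pair per template
  per <- tapply(rec$flag, rec$qname, function(f) {
    sum(is_first_of_pair(f)) == 1 && sum(is_second_of_pair(f)) == 1
  })
  expect_true(all(per))
  # clipped reads exist and keep their mates' pairing info
  expect_gt(sum(grepl("S", rec$cigar)), 0)
})
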