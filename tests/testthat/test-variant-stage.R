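# deterministic stack of single-end reads over a toy reference
stack_reads <- function(ref, n_ref, n_alt, pos, width = 20,
                        altify = function(s, at) {
  substr(s, at, at) <- if (substr(s, at, at) == "A") "C" else "A"
  s
}) {
  start <- pos - 5
  base <- substr(ref[[1]], start, start + width - 1)
  alt <- altify(base, 6)
  reads <- c(rep(base, n_ref), rep(alt, n_alt))
  sam_records(sprintf("r%03d", seq_along(reads)), 0x42L, "chr1", start,
              60L, sprintf("%dM", width), "*", 0, 0, reads,
              strrep("I", width))
}

toy_window <- function(len = 4000) {
  set.seed(9)
  ref <- c(chr1 = paste(sample(c("A", "C", "G", "T"), len, TRUE),
                        collapse = ""))
  plan <- partition_genome(genome_index("chr1", len), M = 1)
  list(ref = ref, window = plan$subregions[1], plan = plan)
}

test_that("pileup caller applies depth, fraction and genotype thresholds", {
  tw <- toy_window()
  # 30 reads, 15 alt: het above min_alt_frac
  r <- stack_reads(tw$ref, 15, 15, pos = 100)
  calls <- pileup_call(tw$window, r, tw$ref)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, 100)
  expect_equal(calls$genotype, "het")
  expect_equal(calls$depth, 30)
  # all-alt: hom
  r2 <- stack_reads(tw$ref, 0, 30, pos = 200)
  expect_equal(pileup_call(tw$window, r2, tw$ref)$genotype, "hom")
  # zero alt reads anywhere: no calls
  r3 <- stack_reads(tw$ref, 30, 0, pos = 300)
  expect_equal(nrow(pileup_call(tw$window, r3, tw$ref)), 0L)
  # below min_depth: silent
  r4 <- stack_reads(tw$ref, 3, 4, pos = 400)
  expect_equal(nrow(pileup_call(tw$window, r4, tw$ref)), 0L)
  # fraction below min_alt_frac: silent
  r5 <- stack_reads(tw$ref, 28, 2, pos = 500)
  expect_equal(nrow(pileup_call(tw$window, r5, tw$ref)), 0L)
})

test_that("indel calls are leftmost-anchored with VCF-style alleles", {
  tw <- toy_window()
  width <- 20
  start <- 95
  base <- substr(tw$ref[[1]], start, start + width - 1)
  # deletion of 3 bases after query position 6 (anchor ref pos 100)
  delseq <- paste0(substr(base, 1, 6),
                   substr(tw$ref[[1]], start + 9, start + width + 2))
  del <- sam_records(sprintf("d%02d", 1:12), 0x42L, "chr1", start, 60L,
                     "6M3D14M", "*", 0, 0, delseq, strrep("I", width))
  calls <- pileup_call(tw$window, del, tw$ref)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, 100)
  expect_equal(calls$ref, substr(tw$ref[[1]], 100, 103))
  expect_equal(calls$alt, substr(tw$ref[[1]], 100, 100))
  expect_equal(calls$genotype, "hom")
  # insertion of AC after anchor 200
  start2 <- 195
  ins <- paste0(substr(tw$ref[[1]], start2, start2 + 5), "AC",
                substr(tw$ref[[1]], start2 + 6, start2 + width - 3))
  insr <- sam_records(sprintf("i%02d", 1:12), 0x42L, "chr1", start2, 60L,
                      "6M2I12M", "*", 0, 0, ins, strrep("I", width))
  calls2 <- pileup_call(tw$window, insr, tw$ref)
  expect_equal(calls2$pos, 200)
  expect_equal(calls2$alt, paste0(substr(tw$ref[[1]], 200, 200), "AC"))
})

test_that("subregion assignment is inclusive at fixed boundaries", {
  plan <- partition_genome(genome_index("chr1", 100), M = 2)  # cut at 50
  calls <- data.table::data.table(chrom = "chr1", pos = c(50, 51, 25, 75))
  expect_equal(assign_subregion(calls, plan), c(0L, 1L, 0L, 1L))
  # exhaustive check at every toy boundary for several M
  for (M in 2:6) {
    p <- partition_genome(genome_index("chr1", 120), M = M)
    ends <- p$subregions$end
    inner <- ends[-length(ends)]
    cc <- data.table::data.table(chrom = "chr1",
                                 pos = c(inner, inner + 1))
    own <- assign_subregion(cc, p)
    left <- own[seq_along(inner)]
    right <- own[seq_along(inner) + length(inner)]
    expect_equal(right, left + 1L)
    expect_equal(p$subregions$end[left + 1L], inner)
  }
})

test_that("reconciliation keeps exactly the owner's copy", {
  plan <- partition_genome(genome_index("chr1", 10000), M = 2,
                           overlap = 3000)   # boundary at 5000
  call_at <- function(pos, prov, qual = 50) data.table::data.table(
    chrom = "chr1", pos = pos, ref = "A", alt = "T", qual = qual,
    genotype = "hom", depth = 30, subregion_index = prov)
  both <- rbind(call_at(4800, 0L, qual = 50),
                call_at(4800, 1L, qual = 47),   # buffer-zone duplicate
                call_at(200, 0L), call_at(9800, 1L))
  out <- reconcile_boundary_variants(both, plan)
  expect_equal(nrow(out), 3L)
  expect_equal(out$pos, c(200, 4800, 9800))
  # the owner's record survives verbatim (its qual, not the neighbour's)
  expect_equal(out$qual[out$pos == 4800], 50)
  expect_equal(anyDuplicated(out[, c("chrom", "pos", "ref", "alt")]), 0L)
})

test_that("VCF writing round-trips and rejects unsorted input", {
  genome <- genome_index(c("chr1", "chr2"), c(10000, 5000))
  calls <- data.table::data.table(
    chrom = c("chr1", "chr1", "chr2"), pos = c(17, 500, 40),
    ref = c("A", "CTT", "G"), alt = c("T", "C", "GAA"),
    qual = c(57.1, 99, 12.5), genotype = c("het", "hom", "hom"),
    depth = c(31, 28, 9))
  tf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, genome, tf)
  lines <- readLines(tf)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  expect_true(any(grepl("##contig=<ID=chr1,length=10000>", lines,
                        fixed = TRUE)))
  back <- read_vcf(tf)
  expect_equal(as.data.frame(back), as.data.frame(calls))
  expect_error(write_vcf(calls[c(2, 1, 3)], genome, tf),
               "must be sorted")
  # empty call set: header-only file round-trips to zero rows
  write_vcf(calls[0], genome, tf)
  expect_equal(nrow(read_vcf(tf)), 0L)
})

test_that("concatenation of fragments equals writing the merged list", {
  genome <- genome_index("chr1", 10000)
  plan <- partition_genome(genome, M = 2)
  c1 <- data.table::data.table(chrom = "chr1", pos = 100, ref = "A",
                               alt = "G", qual = 50, genotype = "hom",
                               depth = 20)
  c2 <- data.table::data.table(chrom = "chr1", pos = 8000, ref = "T",
                               alt = "C", qual = 44.5, genotype = "het",
                               depth = 18)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  fm <- withr::local_tempfile(); fc <- withr::local_tempfile()
  write_vcf(c1, genome, f1)
  write_vcf(c2, genome, f2)
  concat_vcf(c(f1, f2), fc)
  write_vcf(rbind(c1, c2), genome, fm)
  expect_identical(readLines(fc), readLines(fm))
})

test_that("spiked SNPs in error-free data are all called", {
  fix <- small_fixture(81, coverage = 30, error_rate = 0, dup_rate = 0,
                       interchrom_rate = 0, clip_rate = 0,
                       lens = c(chrA = 20000), n_snps = 8, n_indels = 2,
                       boundary_enrich = 0, M = 2)
  dd <- deduplicate_serial(fix$records, genome = fix$genome)
  calls <- list()
  for (k in fix$plan$subregions$index) {
    w <- fix$plan$subregions[fix$plan$subregions$index == k, ]
    calls[[k + 1]] <- pileup_call(w, dd, fix$reference)
  }
  final <- reconcile_boundary_variants(data.table::rbindlist(calls),
                                       fix$plan)
  got <- paste(final$chrom, final$pos, final$ref, final$alt)
  want <- paste(fix$variants$chrom, fix$variants$pos, fix$variants$ref,
                fix$variants$alt)
  expect_true(all(want %in% got))
  expect_true(all(final$genotype == "hom"))
})
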