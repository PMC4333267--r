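write_fixture_inputs <- function(seed, dir, n_inputs = 1L, ...) {
  fix <- small_fixture(seed, ...)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref_path <- file.path(dir, "ref.fa")
  write_reference(fix$reference, ref_path)
  n <- nrow(fix$records)
  cut <- ceiling(seq(0, n, length.out = n_inputs + 1L))
  paths <- character(n_inputs)
  for (i in seq_len(n_inputs)) {
    rows <- (cut[i] + 1L):cut[i + 1L]
    paths[i] <- file.path(dir, sprintf("in%d.sam", i))
    write_sam(fix$records[rows], paths[i], genome = fix$genome)
  }
  list(fix = fix, reference = ref_path, inputs = paths)
}

test_that("config validation enumerates every problem at once", {
  err <- tryCatch(
    pipeline_config(reference = 42, inputs = character(0),
                    workdir = "w", output_dir = "o", M = 0,
                    min_alt_frac = 7),
    error = function(e) conditionMessage(e))
  expect_match(err, "'M' must be")
  expect_match(err, "'reference' must be")
  expect_match(err, "'inputs' is empty")
  expect_match(err, "'min_alt_frac' must lie")
  # M defaults to twice the worker count
  cfg <- pipeline_config(reference = c(chr1 = "ACGT"),
                         inputs = list(data.frame()),
                         workdir = "w", output_dir = "o", workers = 3)
  expect_equal(cfg$M, 6L)
})

test_that("task graph has the documented fan-out and barriers", {
  cfg <- pipeline_config(reference = c(chr1 = strrep("ACGT", 100)),
                         inputs = list(1, 2), workdir = "w",
                         output_dir = "o", M = 4)
  plan <- partition_genome(genome_index("chr1", 400), 4)
  g <- plan_tasks(cfg, plan, n_inputs = 2L)
  expect_equal(sum(g$stage == "split"), 2L)           # one per input
  expect_equal(sum(g$stage == "merge"), 5L)           # 4 subregions + chrI
  expect_equal(sum(g$stage == "call"), 4L)
  expect_equal(g$id[g$barrier], c("merge:chrI", "covmerge", "finalize"))
  # barriers are exactly the tasks that join a whole fan-out level
  n_deps <- lengths(g$deps)
  wide <- g$id[n_deps >= 4L & g$stage != "merge"]
  expect_setequal(wide, c("covmerge", "finalize"))
  # identical configs give identical graphs
  g2 <- plan_tasks(cfg, plan, n_inputs = 2L)
  expect_identical(g, g2)
  # M = 1 degenerates to a serial chain per chromosome
  g1 <- plan_tasks(cfg, partition_genome(genome_index("chr1", 400), 1),
                   n_inputs = 1L)
  expect_equal(sum(g1$stage == "call"), 1L)
})

test_that("pipeline outputs are byte-identical across worker counts", {
  dir <- withr::local_tempdir()
  fx <- write_fixture_inputs(91, dir, n_inputs = 2L, coverage = 8,
                             lens = c(chrA = 20000, chrB = 12000),
                             n_snps = 6, n_indels = 2)
  outs <- list()
  for (W in c(1L, 2L)) {
    wd <- file.path(dir, sprintf("wd%d", W))
    od <- file.path(dir, sprintf("od%d", W))
    cfg <- pipeline_config(reference = fx$reference, inputs = fx$inputs,
                           workdir = wd, output_dir = od, M = 3L,
                           workers = W)
    run_pipeline(cfg)
    outs[[as.character(W)]] <- vapply(
      c("variants.vcf", "recalibrated.sam", "covariates.tsv",
        "chrI.sam", "metrics.txt"),
      function(f) unname(tools::md5sum(file.path(od, f))), "")
  }
  expect_identical(outs[["1"]], outs[["2"]])
  # the run report log exists and is JSON-lines
  log <- readLines(file.path(dir, "wd1", "log.jsonl"))
  expect_true(all(grepl("^\\{", log)))
  parsed <- lapply(log, jsonlite::fromJSON)
  expect_true(any(vapply(parsed, function(x) x$task == "finalize",
                         logical(1))))
})

test_that("record conservation holds through split/merge/redistribute", {
  dir <- withr::local_tempdir()
  fx <- write_fixture_inputs(92, dir, coverage = 6, dup_rate = 0.2,
                             interchrom_rate = 0.08,
                             boundary_enrich = 0.15)
  wd <- file.path(dir, "wd"); od <- file.path(dir, "od")
  cfg <- pipeline_config(reference = fx$reference, inputs = fx$inputs,
                         workdir = wd, output_dir = od, M = 4L)
  run_pipeline(cfg)
  n_in <- nrow(fx$fix$records)
  serial <- deduplicate_serial(fx$fix$records, genome = fx$fix$genome)
  out <- read_sam(file.path(od, "recalibrated.sam"))
  expect_equal(nrow(out), nrow(serial))
  expect_lt(nrow(out), n_in)   # duplicates actually removed
  # and the retained record set equals serial dedup (coordinates/quals
  # aside from recalibrated qual strings)
  expect_identical(sort(out$qname), sort(serial$qname))
})

test_that("a failing task aborts with the subregion named", {
  dir <- withr::local_tempdir()
  fx <- write_fixture_inputs(93, dir, coverage = 2,
                             lens = c(chrA = 15000))
  wd <- file.path(dir, "wd"); od <- file.path(dir, "od")
  cfg <- pipeline_config(reference = fx$reference, inputs = fx$inputs,
                         workdir = wd, output_dir = od, M = 2L)
  run_pipeline(cfg)
  # corrupt one subregion's intermediate and force its re-run
  writeLines("not\tsam", file.path(wd, "withchrI", "s00001.sam"))
  unlink(list.files(file.path(wd, "manifest"),
                    pattern = "^(dedup_s00001|realign_s00001)",
                    full.names = TRUE))
  cfg_resume <- pipeline_config(reference = fx$reference,
                                inputs = fx$inputs, workdir = wd,
                                output_dir = od, M = 2L, resume = TRUE)
  plan <- partition_genome(genome_index("chrA", 15000), 2L)
  graph <- plan_tasks(cfg_resume, plan, 1L)
  expect_error(execute(graph, cfg_resume, plan), "dedup:s00001")
})

test_that("resume skips completed tasks and reproduces outputs", {
  dir <- withr::local_tempdir()
  fx <- write_fixture_inputs(94, dir, coverage = 5,
                             lens = c(chrA = 15000), n_snps = 4,
                             n_indels = 1)
  wd <- file.path(dir, "wd"); od <- file.path(dir, "od")
  cfg <- pipeline_config(reference = fx$reference, inputs = fx$inputs,
                         workdir = wd, output_dir = od, M = 2L)
  run_pipeline(cfg)
  h1 <- tools::md5sum(file.path(od, "variants.vcf"))
  before <- file.mtime(file.path(wd, "merged", "s00000.sam"))
  cfg_resume <- pipeline_config(reference = fx$reference,
                                inputs = fx$inputs, workdir = wd,
                                output_dir = od, M = 2L, resume = TRUE)
  res <- run_pipeline(cfg_resume)
  expect_equal(length(res$task_summaries), 0L)  # everything skipped
  expect_identical(tools::md5sum(file.path(od, "variants.vcf")), h1)
  expect_equal(file.mtime(file.path(wd, "merged", "s00000.sam")), before)
  # a changed config invalidates the markers and reruns
  cfg_changed <- pipeline_config(reference = fx$reference,
                                 inputs = fx$inputs, workdir = wd,
                                 output_dir = od, M = 2L, resume = TRUE,
                                 min_depth = 9L)
  res2 <- run_pipeline(cfg_changed)
  expect_gt(length(res2$task_summaries), 0L)
})

test_that("emitted scripts cover the graph in topological order", {
  dir <- withr::local_tempdir()
  fx <- write_fixture_inputs(95, dir, coverage = 2,
                             lens = c(chrA = 15000))
  cfg <- pipeline_config(reference = fx$reference, inputs = fx$inputs,
                         workdir = file.path(dir, "wd"),
                         output_dir = file.path(dir, "od"), M = 2L)
  sdir <- file.path(dir, "scripts")
  write_pipeline_scripts(cfg, sdir)
  files <- list.files(sdir)
  expect_true("run_all.sh" %in% files)
  expect_true("config.json" %in% files)
  expect_true(all(c("split_0.sh", "merge_chrI.sh", "dedup_chrI.sh",
                    "covmerge.sh", "finalize.sh") %in% files))
  runall <- readLines(file.path(sdir, "run_all.sh"))
  pos_of <- function(f) grep(f, runall, fixed = TRUE)
  expect_lt(pos_of("split_0.sh"), pos_of("merge_chrI.sh"))
  expect_lt(pos_of("merge_chrI.sh"), pos_of("dedup_chrI.sh"))
  expect_lt(pos_of("covmerge.sh"), pos_of("finalize.sh"))
})

test_that("the CLI partitions, simulates and validates", {
  dir <- withr::local_tempdir()
  idx_path <- file.path(dir, "g.fai")
  write_genome_index(genome_index("chr1", 100000), idx_path)
  out <- file.path(dir, "iv.list")
  code <- shardseq_main(c("partition", "--reference-index", idx_path,
                          "--subregions", "4", "--overlap", "500",
                          "--out", out))
  expect_equal(code, 0L)
  plan <- read_intervals(out, genome_index("chr1", 100000))
  expect_equal(nrow(plan$subregions), 4L)
  expect_equal(shardseq_main(c("partition", "--subregions", "2")), 2L)
  simdir <- file.path(dir, "sim")
  code2 <- shardseq_main(c("simulate", "--seed", "3", "--chroms",
                           "20000,10000", "--coverage", "3", "--snps",
                           "5", "--indels", "1", "--out", simdir))
  expect_equal(code2, 0L)
  expect_true(file.exists(file.path(simdir, "reads.sam")))
  expect_true(file.exists(file.path(simdir, "truth.vcf")))
  expect_equal(shardseq_main("frobnicate"), 2L)
})
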