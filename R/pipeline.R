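#' Pipeline configuration
#'
#' Validates and freezes everything a run depends on. Validation
#' collects *all* problems before failing so a bad config is fixed in
#' one pass. When `M` is not given it defaults to `2 * workers`, a
#' load-balancing heuristic (more shards than workers keeps every
#' worker busy as shard runtimes vary).
#'
#' @param reference reference genome: FASTA path or named character
#'   vector of sequences.
#' @param inputs aligned inputs: character vector of SAM paths, or a
#'   list of records data.tables (in-memory use).
#' @param workdir working directory for intermediate files.
#' @param output_dir directory for final outputs.
#' @param M subregion count; default `2 * workers`.
#' @param overlap buffer size in bp (default 3000).
#' @param workers maximum concurrent tasks (default 1).
#' @param survivor duplicate survivor rule, see [select_survivor()].
#' @param mark_only mark duplicates (SAM 0x400) instead of removing.
#' @param skip_recalibration pass reads through the recalibration
#'   stage unchanged.
#' @param min_depth,min_alt_frac,hom_frac,error_rate caller thresholds,
#'   see [pileup_call()].
#' @param resume skip tasks whose completion markers exist (and whose
#'   config is unchanged).
#' @param sample sample name in the final VCF.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(reference, inputs, workdir, output_dir,
                            M = NULL, overlap = 3000, workers = 1L,
                            survivor = c("mapq_sum", "baseq_sum"),
                            mark_only = FALSE,
                            skip_recalibration = FALSE,
                            min_depth = 8L, min_alt_frac = 0.2,
                            hom_frac = 0.8, error_rate = 0.01,
                            resume = FALSE, sample = "sample") {
  survivor <- match.arg(survivor)
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  if (!is.numeric(workers) || length(workers) != 1L || workers < 1) {
    note("'workers' must be a positive integer")
    workers <- 1L
  }
  if (is.null(M)) M <- 2L * as.integer(workers)
  if (!is.numeric(M) || length(M) != 1L || M < 1 || M != floor(M)) {
    note("'M' must be a positive integer")
  }
  if (!is.numeric(overlap) || overlap < 0) {
    note("'overlap' must be non-negative")
  }
  if (is.character(reference)) {
    if (length(reference) == 1L && file.exists(reference)) {
      # a FASTA path
    } else if (is.null(names(reference))) {
      note("'reference' must be an existing FASTA path or a named vector")
    }
  } else {
    note("'reference' must be a FASTA path or named character vector")
  }
  if (is.character(inputs)) {
    miss <- inputs[!file.exists(inputs)]
    if (length(inputs) == 0L) note("'inputs' is empty")
    for (m in miss) note(sprintf("input file does not exist: %s", m))
  } else if (is.list(inputs)) {
    if (length(inputs) == 0L) note("'inputs' is empty")
  } else {
    note("'inputs' must be SAM paths or a list of record tables")
  }
  for (nm in c("min_alt_frac", "hom_frac", "error_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1) {
      note(sprintf("'%s' must lie in [0, 1]", nm))
    }
  }
  if (length(problems)) {
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(list(
    reference = reference, inputs = inputs, workdir = workdir,
    output_dir = output_dir, M = as.integer(M), overlap = overlap,
    workers = as.integer(workers), survivor = survivor,
    mark_only = isTRUE(mark_only),
    skip_recalibration = isTRUE(skip_recalibration),
    min_depth = min_depth, min_alt_frac = min_alt_frac,
    hom_frac = hom_frac, error_rate = error_rate,
    resume = isTRUE(resume), sample = sample), class = "pipeline_config")
}

STAGE_ORDER <- c("split", "merge", "chrI_dedup", "redistribute",
                 "subregion_dedup", "realign", "covariate_build",
                 "covariate_merge", "recalibrate", "call", "finalize")

#' Plan the task graph of a pipeline run
#'
#' Builds the full stage/fan-out structure: per-input split tasks,
#' per-destination merges (subregions plus `chrI`), the `chrI`
#' deduplication, per-subregion redistribute/dedup/realign/covariate/
#' recalibrate/call tasks, and the three synchronization barriers —
#' the `chrI` merge (all inputs join), the covariate merge (all
#' subregions join) and the final VCF concatenation. Identical configs
#' yield identical graphs.
#'
#' @param config a [pipeline_config()].
#' @param plan a [partition_genome()] plan.
#' @param n_inputs number of aligned inputs.
#' @return A data.table: `id`, `stage`, `subregion`, `input`,
#'   `deps` (list column of prerequisite ids), `barrier`.
#' @export
plan_tasks <- function(config, plan, n_inputs) {
  subs <- plan$subregions$index
  sname <- dest_name(subs)
  splits <- sprintf("split:%d", seq_len(n_inputs) - 1L)
  rows <- list()
  add <- function(id, stage, subregion = NA_integer_,
                  input = NA_integer_, deps = character(0),
                  barrier = FALSE) {
    rows[[length(rows) + 1L]] <<- data.table::data.table(
      id = id, stage = stage, subregion = subregion, input = input,
      deps = list(deps), barrier = barrier)
  }
  for (i in seq_len(n_inputs)) {
    add(splits[i], "split", input = i - 1L)
  }
  for (k in seq_along(subs)) {
    add(sprintf("merge:%s", sname[k]), "merge", subregion = subs[k],
        deps = splits)
  }
  add("merge:chrI", "merge", deps = splits, barrier = TRUE)
  add("dedup:chrI", "chrI_dedup", deps = "merge:chrI")
  for (k in seq_along(subs)) {
    add(sprintf("redistribute:%s", sname[k]), "redistribute",
        subregion = subs[k],
        deps = c("dedup:chrI", sprintf("merge:%s", sname[k])))
    add(sprintf("dedup:%s", sname[k]), "subregion_dedup",
        subregion = subs[k], deps = sprintf("redistribute:%s", sname[k]))
    add(sprintf("realign:%s", sname[k]), "realign", subregion = subs[k],
        deps = sprintf("dedup:%s", sname[k]))
    add(sprintf("covar:%s", sname[k]), "covariate_build",
        subregion = subs[k], deps = sprintf("realign:%s", sname[k]))
  }
  add("covmerge", "covariate_merge",
      deps = sprintf("covar:%s", sname), barrier = TRUE)
  for (k in seq_along(subs)) {
    add(sprintf("recal:%s", sname[k]), "recalibrate", subregion = subs[k],
        deps = "covmerge")
  }
  sub <- plan$subregions
  for (k in seq_along(subs)) {
    neigh <- sub$index[sub$chrom == sub$chrom[k] &
                         abs(sub$index - sub$index[k]) <= 1L]
    add(sprintf("call:%s", sname[k]), "call", subregion = subs[k],
        deps = sprintf("recal:%s", dest_name(neigh)))
  }
  add("finalize", "finalize",
      deps = c(sprintf("call:%s", sname), "dedup:chrI"), barrier = TRUE)
  graph <- data.table::rbindlist(rows)
  graph[, stage := factor(stage, levels = STAGE_ORDER)]
  data.table::setorderv(graph, c("stage", "id"))
  graph[, stage := as.character(stage)]
  graph[]
}

pipeline_paths <- function(config) {
  w <- config$workdir
  o <- config$output_dir
  list(workdir = w, output = o,
       dedup_chrI = file.path(w, "dedup", "chrI.sam"),
       chrI_copy = file.path(o, "chrI.sam"),
       covariates = file.path(o, "covariates.tsv"),
       vcf = file.path(o, "variants.vcf"),
       recalibrated = file.path(o, "recalibrated.sam"),
       metrics = file.path(o, "metrics.txt"),
       log = file.path(w, "log.jsonl"))
}

load_pipeline_reference <- function(config) {
  if (is.character(config$reference) && length(config$reference) == 1L &&
      is.null(names(config$reference))) {
    read_reference(config$reference)
  } else {
    config$reference
  }
}

load_input_records <- function(config, i) {
  if (is.character(config$inputs)) {
    read_sam(config$inputs[i])
  } else {
    config$inputs[[i]]
  }
}

withchrI_path <- function(w, k) {
  file.path(w, "withchrI", sprintf("%s.sam", dest_name(k)))
}
stage_path <- function(w, stage, k, ext = "sam") {
  file.path(w, stage, sprintf("%s.%s", dest_name(k), ext))
}

#' Execute a single pipeline task
#'
#' Stateless per-task runner: reads its inputs from the working
#' directory (or the config), writes its outputs, and returns a small
#' summary list. [execute()] schedules these; they can also be invoked
#' from scripts emitted by [write_pipeline_scripts()].
#'
#' @param config a [pipeline_config()].
#' @param plan a [partition_genome()] plan.
#' @param task task id as in [plan_tasks()].
#' @param state internal shared-state list (`genome`, `reference`,
#'   `n_inputs`); rebuilt from `config` when omitted.
#' @return A list with at least `task` and `n` (records or bins
#'   touched).
#' @export
run_pipeline_task <- function(config, plan, task, state = NULL) {
  if (is.null(state)) {
    reference <- load_pipeline_reference(config)
    state <- list(reference = reference,
                  genome = index_from_reference(reference),
                  n_inputs = length(config$inputs))
  }
  w <- config$workdir
  genome <- state$genome
  parts <- strsplit(task, ":", fixed = TRUE)[[1]]
  stagekey <- parts[1]
  arg <- if (length(parts) > 1L) parts[2] else NA_character_

  if (stagekey == "split") {
    i <- as.integer(arg)
    recs <- load_input_records(config, i + 1L)
    man <- split_alignment_file(recs, plan, i, w, genome)
    jsonlite::write_json(man, file.path(w, "split",
                                        sprintf("manifest_%03d.json", i)),
                         digits = NA)
    return(list(task = task, n = nrow(recs)))
  }
  read_split_manifests <- function() {
    files <- sort(list.files(file.path(w, "split"),
                             pattern = "^manifest_.*\\.json$",
                             full.names = TRUE))
    data.table::rbindlist(lapply(files, function(f) {
      data.table::as.data.table(jsonlite::read_json(f, simplifyVector = TRUE))
    }))
  }
  if (stagekey == "merge") {
    d <- if (arg == "chrI") -1L else as.integer(sub("^s", "", arg))
    merge_by_destination(read_split_manifests(), d, w, genome)
    return(list(task = task, n = NA_integer_))
  }
  if (task == "dedup:chrI") {
    recs <- read_sam(merged_path(w, -1L))
    dd <- deduplicate_serial(recs, survivor = config$survivor,
                             mark_only = config$mark_only,
                             genome = genome)
    dir.create(file.path(w, "dedup"), recursive = TRUE,
               showWarnings = FALSE)
    write_sam(dd, file.path(w, "dedup", "chrI.sam"), genome = genome)
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    # retained copy: boundary-spanning/interchromosomal evidence for
    # downstream structural-variant review
    file.copy(file.path(w, "dedup", "chrI.sam"),
              file.path(config$output_dir, "chrI.sam"), overwrite = TRUE)
    m <- attr(dd, "dedup_metrics")
    jsonlite::write_json(m, file.path(w, "dedup", "chrI.metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    return(list(task = task, n = nrow(dd)))
  }
  k <- if (!is.na(arg) && grepl("^s[0-9]+$", arg)) {
    as.integer(sub("^s", "", arg))
  } else NA_integer_
  if (stagekey == "redistribute") {
    chrI <- read_sam(file.path(w, "dedup", "chrI.sam"))
    rd <- redistribute_chrI(chrI, plan)
    own <- read_sam(merged_path(w, k))
    extra <- rd$placed[rd$placed$.dest == k, !".dest"]
    dir.create(file.path(w, "withchrI"), recursive = TRUE,
               showWarnings = FALSE)
    out <- sort_records(rbind(own, extra), genome)
    write_sam(out, withchrI_path(w, k), genome = genome)
    return(list(task = task, n = nrow(out)))
  }
  if (stagekey == "dedup") {
    recs <- read_sam(withchrI_path(w, k))
    dd <- deduplicate_serial(recs, survivor = config$survivor,
                             mark_only = config$mark_only,
                             genome = genome)
    dir.create(file.path(w, "dedup"), recursive = TRUE,
               showWarnings = FALSE)
    write_sam(dd, stage_path(w, "dedup", k), genome = genome)
    jsonlite::write_json(attr(dd, "dedup_metrics"),
                         stage_path(w, "dedup", k, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    return(list(task = task, n = nrow(dd)))
  }
  if (stagekey == "realign") {
    # pass-through hook: local indel realignment is outside this
    # package's scope; the stage exists so a realigner can be plugged
    # in without reshaping the graph
    dir.create(file.path(w, "realign"), recursive = TRUE,
               showWarnings = FALSE)
    file.copy(stage_path(w, "dedup", k), stage_path(w, "realign", k),
              overwrite = TRUE)
    return(list(task = task, n = NA_integer_))
  }
  if (stagekey == "covar") {
    recs <- read_sam(stage_path(w, "realign", k))
    tab <- build_covariate_table(recs, state$reference)
    dir.create(file.path(w, "covar"), recursive = TRUE,
               showWarnings = FALSE)
    write_covariate_table(tab, stage_path(w, "covar", k, "tsv"))
    return(list(task = task, n = nrow(tab)))
  }
  if (task == "covmerge") {
    tabs <- lapply(plan$subregions$index, function(kk) {
      read_covariate_table(stage_path(w, "covar", kk, "tsv"))
    })
    merged <- merge_covariate_tables(tabs)
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_covariate_table(merged,
                          file.path(config$output_dir, "covariates.tsv"))
    return(list(task = task, n = nrow(merged)))
  }
  if (stagekey == "recal") {
    recs <- read_sam(stage_path(w, "realign", k))
    out <- if (config$skip_recalibration) {
      recs
    } else {
      tab <- read_covariate_table(
        file.path(config$output_dir, "covariates.tsv"))
      apply_recalibration(recs, tab)
    }
    dir.create(file.path(w, "recal"), recursive = TRUE,
               showWarnings = FALSE)
    write_sam(out, stage_path(w, "recal", k), genome = genome)
    return(list(task = task, n = nrow(out)))
  }
  if (stagekey == "call") {
    sub <- plan$subregions
    wrow <- sub[sub$index == k, ]
    neigh <- sub$index[sub$chrom == wrow$chrom & abs(sub$index - k) <= 1L]
    evidence <- data.table::rbindlist(lapply(neigh, function(kk) {
      read_sam(stage_path(w, "recal", kk))
    }))
    if (nrow(evidence)) {
      st <- cigar_stats(evidence$cigar)
      mapped <- !is_unmapped(evidence$flag)
      evidence <- evidence[mapped & evidence$rname == wrow$chrom &
                             evidence$pos <= wrow$buffered_end &
                             evidence$pos + st$ref_span - 1 >=
                               wrow$buffered_start]
    }
    calls <- pileup_call(wrow, evidence, state$reference,
                         min_depth = config$min_depth,
                         min_alt_frac = config$min_alt_frac,
                         hom_frac = config$hom_frac,
                         error_rate = config$error_rate)
    dir.create(file.path(w, "vcf"), recursive = TRUE, showWarnings = FALSE)
    write_vcf(calls, genome, stage_path(w, "vcf", k, "vcf"),
              sample = config$sample)
    return(list(task = task, n = nrow(calls)))
  }
  if (task == "finalize") {
    subs <- plan$subregions$index
    calls <- data.table::rbindlist(lapply(subs, function(kk) {
      cc <- read_vcf(stage_path(w, "vcf", kk, "vcf"))
      if (nrow(cc)) cc[, subregion_index := kk]
      else cc[, subregion_index := integer(0)]
      cc
    }))
    final <- reconcile_boundary_variants(calls, plan)
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_vcf(final[, !"subregion_index"], genome,
              file.path(config$output_dir, "variants.vcf"),
              sample = config$sample)
    # genome-wide recalibrated alignment (re-sorted: a subregion may
    # own reverse reads whose leftmost position precedes its start)
    recs <- data.table::rbindlist(lapply(subs, function(kk) {
      read_sam(stage_path(w, "recal", kk))
    }))
    chrI <- read_sam(file.path(w, "dedup", "chrI.sam"))
    unplaced <- chrI[is_unmapped(chrI$flag)]
    merged <- sort_records(rbind(recs, unplaced), genome)
    write_sam(merged, file.path(config$output_dir, "recalibrated.sam"),
              genome = genome)
    met <- c(
      sprintf("subregions\t%d", length(subs)),
      sprintf("overlap\t%s", format_bp(plan$overlap)),
      sprintf("records_out\t%d", nrow(merged)),
      sprintf("variants\t%d", nrow(final)))
    writeLines(met, file.path(config$output_dir, "metrics.txt"))
    return(list(task = task, n = nrow(final)))
  }
  stop("unknown task: ", task, call. = FALSE)
}

#' Execute a planned task graph
#'
#' Runs stages in dependency order; tasks within a stage touch
#' distinct subregions and run concurrently under
#' `parallel::mclapply` when `workers > 1`. Every task erases
#' scheduling nondeterminism with a canonical sort before writing, so
#' all outputs are byte-identical for any worker count. A structured
#' JSON-lines log (no timestamps — logs are part of the deterministic
#' surface) records per-task record counts in task order.
#'
#' @param graph output of [plan_tasks()].
#' @param config a [pipeline_config()].
#' @param plan a [partition_genome()] plan.
#' @return Invisible list of per-task summaries.
#' @export
execute <- function(graph, config, plan) {
  reference <- load_pipeline_reference(config)
  state <- list(reference = reference,
                genome = index_from_reference(reference),
                n_inputs = length(config$inputs))
  w <- config$workdir
  dir.create(file.path(w, "manifest"), recursive = TRUE,
             showWarnings = FALSE)
  cfg_hash <- config_hash(config)
  hash_file <- file.path(w, "manifest", "config.md5")
  stale <- !file.exists(hash_file) ||
    !identical(readLines(hash_file, warn = FALSE), cfg_hash)
  if (stale && config$resume) {
    unlink(list.files(file.path(w, "manifest"), pattern = "\\.done$",
                      full.names = TRUE))
  }
  writeLines(cfg_hash, hash_file)
  done_marker <- function(id) {
    file.path(w, "manifest", paste0(gsub(":", "_", id), ".done"))
  }
  logcon <- file(file.path(w, "log.jsonl"),
                 if (config$resume && !stale) "a" else "w")
  on.exit(close(logcon))
  results <- list()
  for (st in STAGE_ORDER) {
    ids <- graph$id[graph$stage == st]
    if (length(ids) == 0L) next
    skip <- if (config$resume && !stale) {
      file.exists(vapply(ids, done_marker, ""))
    } else {
      rep(FALSE, length(ids))
    }
    todo <- ids[!skip]
    runner <- function(id) {
      run_pipeline_task(config, plan, id, state = state)
    }
    res <- if (config$workers > 1L && length(todo) > 1L) {
      parallel::mclapply(todo, function(id) {
        tryCatch(runner(id), error = function(e) {
          structure(list(task = id, error = conditionMessage(e)),
                    class = "shardseq_task_error")
        })
      }, mc.cores = config$workers)
    } else {
      lapply(todo, function(id) {
        tryCatch(runner(id), error = function(e) {
          structure(list(task = id, error = conditionMessage(e)),
                    class = "shardseq_task_error")
        })
      })
    }
    bad <- vapply(res, inherits, TRUE, what = "shardseq_task_error") |
      vapply(res, inherits, TRUE, what = "try-error")
    if (any(bad)) {
      i <- which(bad)[1]
      msg <- if (inherits(res[[i]], "shardseq_task_error")) {
        res[[i]]$error
      } else {
        as.character(res[[i]])
      }
      stop(sprintf("task failure in stage '%s', task '%s': %s",
                   st, todo[i], msg), call. = FALSE)
    }
    for (r in res) {
      writeLines(jsonlite::toJSON(
        list(task = r$task, stage = st, status = "done", n = r$n),
        auto_unbox = TRUE, null = "null", digits = NA), logcon)
      file.create(done_marker(r$task))
    }
    results <- c(results, res)
  }
  invisible(results)
}

config_hash <- function(config) {
  cfg <- config
  cfg$resume <- NULL
  cfg$workers <- NULL   # worker count must not invalidate resume
  if (is.list(cfg$inputs) && !is.character(cfg$inputs)) {
    cfg$inputs <- sprintf("<in-memory:%d>", lengths(cfg$inputs))
  }
  if (!is.null(names(cfg$reference))) {
    cfg$reference <- sprintf("<in-memory:%d>", length(cfg$reference))
  }
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the complete pipeline
#'
#' Partition, split, merge, chrI-first deduplication, redistribution,
#' per-subregion deduplication, covariate build/merge, recalibration,
#' buffered-window calling, boundary reconciliation, concatenation.
#' Final outputs under `output_dir`: `variants.vcf`,
#' `recalibrated.sam`, `covariates.tsv`, `chrI.sam` (retained copy),
#' `metrics.txt`. All of them are byte-identical across worker counts;
#' `variants.vcf`, `recalibrated.sam` and `covariates.tsv` are also
#' byte-identical across subregion counts `M`.
#'
#' @param config a [pipeline_config()].
#' @return A list: `paths`, `plan`, `graph`, `task_summaries`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  reference <- load_pipeline_reference(config)
  genome <- index_from_reference(reference)
  plan <- partition_genome(genome, config$M, overlap = config$overlap)
  graph <- plan_tasks(config, plan, length(config$inputs))
  res <- execute(graph, config, plan)
  list(paths = pipeline_paths(config), plan = plan, graph = graph,
       task_summaries = res)
}

#' Emit per-task shell scripts without executing
#'
#' Writes one shell script per task plus a `run_all.sh` that invokes
#' them in topological order — the hook for users driving the graph
#' with an external scheduler (a cluster engine is environment, not
#' algorithm, so nothing here submits jobs). Requires a path-based
#' config (file inputs and a FASTA reference).
#'
#' @param config a [pipeline_config()].
#' @param dir directory for the scripts.
#' @return The directory, invisibly.
#' @export
write_pipeline_scripts <- function(config, dir) {
  if (!is.character(config$inputs) ||
      !(is.character(config$reference) &&
          is.null(names(config$reference)))) {
    stop("emitting scripts requires file-based inputs and reference",
         call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA)
  reference <- load_pipeline_reference(config)
  plan <- partition_genome(index_from_reference(reference), config$M,
                           overlap = config$overlap)
  graph <- plan_tasks(config, plan, length(config$inputs))
  script_of <- function(id) paste0(gsub(":", "_", id), ".sh")
  for (i in seq_len(nrow(graph))) {
    id <- graph$id[i]
    lines <- c("#!/bin/sh", "set -e",
               sprintf("Rscript -e 'shardseq::run_config_task(\"%s\", \"%s\")'",
                       normalizePath(cfg_path), id))
    writeLines(lines, file.path(dir, script_of(id)))
  }
  writeLines(c("#!/bin/sh", "set -e",
               sprintf("sh %s", file.path(dir, script_of(graph$id)))),
             file.path(dir, "run_all.sh"))
  invisible(dir)
}

#' Run one task from a serialized config (script entry point)
#'
#' @param config_path path to the JSON config written by
#'   [write_pipeline_scripts()].
#' @param task task id.
#' @return The task summary, invisibly.
#' @export
run_config_task <- function(config_path, task) {
  raw <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  config <- do.call(pipeline_config, raw[setdiff(names(raw), character(0))])
  reference <- load_pipeline_reference(config)
  genome <- index_from_reference(reference)
  plan <- partition_genome(genome, config$M, overlap = config$overlap)
  invisible(run_pipeline_task(config, plan, task))
}
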