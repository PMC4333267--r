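#' Select the surviving template of a duplicate group
#'
#' Among templates sharing a duplicate key, the survivor is the one
#' with the highest mapping quality, interpreted for a pair as the sum
#' of the two mates' MAPQ values (a pair's mapping quality is otherwise
#' undefined when the mates disagree). Ties are broken by the
#' lexicographically smallest qname, which makes the choice — and hence
#' every downstream byte — independent of grouping or arrival order.
#' `survivor = "baseq_sum"` switches to the Picard-style score (sum of
#' base qualities >= 15) for interoperability.
#'
#' @param group records data.table holding the records of one duplicate
#'   group (all templates share one duplicate key).
#' @param survivor `"mapq_sum"` (default) or `"baseq_sum"`.
#' @return The records of the surviving template.
#' @export
select_survivor <- function(group, survivor = c("mapq_sum", "baseq_sum")) {
  survivor <- match.arg(survivor)
  keys <- duplicate_keys(group)
  keys <- keys[!is.na(keys$key)]
  if (nrow(keys) == 0L) {
    stop("group holds no keyed templates", call. = FALSE)
  }
  if (length(unique(keys$key)) != 1L) {
    stop("group members do not share a single duplicate key", call. = FALSE)
  }
  q <- surviving_qnames(keys, survivor)
  group[group$qname == q]
}

# keys: output of duplicate_keys() restricted to non-NA keys.
# Returns the surviving qname per key (C-locale deterministic).
surviving_qnames <- function(keys, survivor) {
  sc <- if (survivor == "mapq_sum") keys$mapq_sum else keys$baseq_sum
  k <- data.table::data.table(dupkey = keys$key, qname = keys$qname,
                              score = sc)
  data.table::setorderv(k, c("dupkey", "score", "qname"),
                        order = c(1L, -1L, 1L))
  k[!duplicated(k$dupkey)]$qname
}

#' Genome-wide (serial) duplicate removal
#'
#' The oracle form of deduplication: groups every template of the
#' complete record set by duplicate key and reduces each group to its
#' survivor. By default non-survivors are removed outright; with
#' `mark_only = TRUE` they are kept and their SAM duplicate flag
#' (0x400) is set on every record of the template. Templates without a
#' key (fully unmapped, or dedup-exempt lone mates) pass through
#' untouched.
#'
#' @param records complete records data.table.
#' @param survivor survivor rule, see [select_survivor()].
#' @param mark_only set the duplicate flag instead of removing.
#' @param genome optional [genome_index()] fixing the canonical sort.
#' @param library library tag for [duplicate_keys()].
#' @return Canonically sorted records; attribute `"dedup_metrics"`
#'   carries a list with `templates`, `keyed`, `groups` and
#'   `duplicates` counts.
#' @export
deduplicate_serial <- function(records,
                               survivor = c("mapq_sum", "baseq_sum"),
                               mark_only = FALSE, genome = NULL,
                               library = "lib") {
  survivor <- match.arg(survivor)
  keys <- duplicate_keys(records, library = library)
  keyed <- keys[!is.na(keys$key)]
  surv <- surviving_qnames(keyed, survivor)
  dup_q <- setdiff(keyed$qname, surv)
  if (mark_only) {
    out <- data.table::copy(records)
    hit <- out$qname %in% dup_q
    out[hit, flag := bitwOr(flag, FLAG_DUPLICATE)]
  } else {
    out <- records[!(records$qname %in% dup_q)]
  }
  out <- sort_records(out, genome)
  data.table::setattr(out, "dedup_metrics", list(
    templates = nrow(keys), keyed = nrow(keyed),
    groups = length(unique(keyed$key)), duplicates = length(dup_q)))
  out
}

#' Sharded (parallel) duplicate removal
#'
#' The production form: records are routed per [route_records()]; the
#' `chrI` destination (boundary-spanning and interchromosomal pairs) is
#' deduplicated first as a single unit, its surviving reads are
#' redistributed to the subregions containing their own 5' positions,
#' and each subregion is then deduplicated independently (optionally
#' across worker processes). Redistributed lone mates carry no
#' duplicate key inside a subregion, so they are never re-deduplicated.
#'
#' The multiset of retained records equals [deduplicate_serial()] of
#' the same input exactly, for every subregion count and worker count:
#' duplicate classes are closed under routing (equal keys imply equal
#' coordinates imply equal destination), so every group is resolved
#' whole in exactly one place, under the same deterministic survivor
#' rule.
#'
#' @inheritParams deduplicate_serial
#' @param plan a [partition_genome()] plan.
#' @param workers worker processes for per-subregion deduplication
#'   (`parallel::mclapply`; 1 = serial execution).
#' @return Canonically sorted records, identical to the serial result.
#' @export
deduplicate_parallel <- function(records, plan, workers = 1L,
                                 survivor = c("mapq_sum", "baseq_sum"),
                                 mark_only = FALSE, genome = NULL,
                                 library = "lib") {
  survivor <- match.arg(survivor)
  dest <- route_records(records, plan)
  chrI <- deduplicate_serial(records[dest == -1L], survivor = survivor,
                             mark_only = mark_only, genome = genome,
                             library = library)
  rd <- redistribute_chrI(chrI, plan)
  subs <- sort(unique(dest[dest >= 0L]))
  subs <- sort(unique(c(subs, rd$placed$.dest)))
  work <- lapply(subs, function(k) {
    extra <- rd$placed[rd$placed$.dest == k, !".dest"]
    rbind(records[dest == k], extra)
  })
  run_one <- function(recs) {
    deduplicate_serial(recs, survivor = survivor, mark_only = mark_only,
                       genome = genome, library = library)
  }
  deduped <- if (workers > 1L && length(work) > 1L) {
    res <- parallel::mclapply(work, run_one, mc.cores = workers)
    err <- vapply(res, inherits, TRUE, what = "try-error")
    if (any(err)) {
      stop("worker failure in subregion ", subs[which(err)[1]],
           call. = FALSE)
    }
    res
  } else {
    lapply(work, run_one)
  }
  out <- data.table::rbindlist(c(deduped, list(rd$unplaced)))
  sort_records(out, genome)
}
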