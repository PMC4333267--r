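#' Simulation specification
#'
#' The stated world of the synthetic fixtures: a small multi-chromosome
#' genome sequenced as 100 bp paired-end reads at 30x coverage with a
#' normal insert-size distribution (300 +/- 30 bp), a PCR-duplicate
#' rate of 15%, 5% interchromosomal re-pairing, 5% soft-clipping and a
#' low substitution error rate — a desk-scale emulation of a typical
#' short-read whole-genome run. Every draw is reproducible from
#' `seed`; the reference, variant and read stages use `seed`,
#' `seed + 1` and `seed + 2` respectively.
#'
#' @param seed integer RNG seed (< 2^31 - 3).
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param coverage mean fold coverage.
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd insert-size (outer fragment length)
#'   normal distribution parameters, bp.
#' @param dup_rate expected fraction of emitted pairs that are PCR
#'   duplicates of another emitted pair, in `[0, 1)`.
#' @param interchrom_rate fraction of pairs re-paired across
#'   chromosomes, in `[0, 1)`.
#' @param boundary_enrich fraction of pairs deliberately placed to
#'   straddle a fixed subregion boundary (requires a plan at
#'   simulation time).
#' @param clip_rate fraction of reads given a soft-clipped end.
#' @param error_rate per-base substitution sequencing-error rate.
#' @param n_snps,n_indels numbers of spiked true variants.
#' @param base_quality reported Phred quality of every base.
#' @param mapq_choices integer vector MAPQ values are drawn from.
#' @return An object of class `sim_spec` (a validated list).
#' @export
sim_spec <- function(seed = 1L,
                     chrom_lengths = c(chr1 = 100000, chr2 = 50000),
                     coverage = 30, read_length = 100L,
                     insert_mean = 300, insert_sd = 30,
                     dup_rate = 0.15, interchrom_rate = 0.05,
                     boundary_enrich = 0, clip_rate = 0.05,
                     error_rate = 0.001, n_snps = 50L, n_indels = 10L,
                     base_quality = 30L, mapq_choices = 60L) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("'chrom_lengths' must be named", call. = FALSE)
  }
  rates <- c(dup_rate = dup_rate, interchrom_rate = interchrom_rate,
             boundary_enrich = boundary_enrich, clip_rate = clip_rate,
             error_rate = error_rate)
  if (any(rates < 0 | rates >= 1)) {
    stop("rates must lie in [0, 1)", call. = FALSE)
  }
  if (coverage <= 0) stop("'coverage' must be positive", call. = FALSE)
  if (read_length > min(chrom_lengths)) {
    stop("'read_length' exceeds the shortest chromosome", call. = FALSE)
  }
  if (insert_mean < read_length) {
    stop("'insert_mean' must be >= 'read_length'", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), chrom_lengths = chrom_lengths,
    coverage = coverage, read_length = as.integer(read_length),
    insert_mean = insert_mean, insert_sd = insert_sd,
    dup_rate = dup_rate, interchrom_rate = interchrom_rate,
    boundary_enrich = boundary_enrich, clip_rate = clip_rate,
    error_rate = error_rate, n_snps = as.integer(n_snps),
    n_indels = as.integer(n_indels),
    base_quality = as.integer(base_quality),
    mapq_choices = as.integer(mapq_choices)), class = "sim_spec")
}

#' Generate a uniform-random reference genome
#'
#' @param spec a [sim_spec()].
#' @return Named character vector of A/C/G/T sequences, byte-identical
#'   for identical seeds.
#' @export
generate_reference <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  vapply(spec$chrom_lengths, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, "")
}

#' Spike truth variants into a reference
#'
#' Places `n_snps` homozygous SNPs and `n_indels` homozygous indels
#' (1-6 bp, left-normalized by construction) at mutually distant
#' positions. When a partition plan is supplied, at least one SNP is
#' placed within `overlap` bp of every interior fixed boundary, so the
#' buffer-zone reconciliation path is always exercised.
#'
#' @param reference named character vector of chromosome sequences.
#' @param spec a [sim_spec()].
#' @param plan optional [partition_genome()] plan for boundary-aware
#'   placement.
#' @return A list: `variants` (truth calls data.table: `chrom`, `pos`,
#'   `ref`, `alt`, `qual` = NA, `genotype` = "hom", `depth` = NA),
#'   `haplotype` (the mutated sequences).
#' @export
spike_variants <- function(reference, spec, plan = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed + 1L)
  genome <- index_from_reference(reference)
  min_gap <- 15L + 6L
  taken <- lapply(reference, function(x) numeric(0))
  vars <- list()

  free_pos <- function(chrom, lo, hi) {
    len <- nchar(reference[[chrom]])
    lo <- max(lo, 2L)                    # keep an anchor base to the left
    hi <- min(hi, len - 8L)
    for (try in 1:1000) {
      p <- if (hi <= lo) lo else lo + floor(stats::runif(1) * (hi - lo + 1))
      if (all(abs(taken[[chrom]] - p) >= min_gap)) return(p)
    }
    stop("infeasible variant placement on ", chrom, call. = FALSE)
  }
  add_snp <- function(chrom, pos) {
    refb <- substring(reference[[chrom]], pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
    taken[[chrom]] <<- c(taken[[chrom]], pos)
    vars[[length(vars) + 1L]] <<- data.table::data.table(
      chrom = chrom, pos = pos, ref = refb, alt = alt)
  }

  # boundary-adjacent SNPs first
  n_boundary <- 0L
  if (!is.null(plan) && spec$n_snps > 0L) {
    sub <- plan$subregions
    len_of <- genome$length[match(sub$chrom, genome$name)]
    interior <- which(sub$end < len_of)
    ov <- max(plan$overlap, 1)
    for (i in interior) {
      b <- sub$end[i]
      p <- free_pos(sub$chrom[i], b - ov + 1, b + ov)
      add_snp(sub$chrom[i], p)
      n_boundary <- n_boundary + 1L
    }
  }
  # remaining random SNPs
  chroms <- names(reference)
  for (j in seq_len(max(0L, spec$n_snps - n_boundary))) {
    cn <- sample(chroms, 1L, prob = nchar(reference))
    add_snp(cn, free_pos(cn, 2L, nchar(reference[[cn]])))
  }
  # indels
  for (j in seq_len(spec$n_indels)) {
    cn <- sample(chroms, 1L, prob = nchar(reference))
    placed <- FALSE
    for (try in 1:1000) {
      p <- free_pos(cn, 2L, nchar(reference[[cn]]))
      l <- sample(1:6, 1L)
      anchor <- substring(reference[[cn]], p, p)
      if (stats::runif(1) < 0.5) {       # deletion of [p+1, p+l]
        refal <- substring(reference[[cn]], p, p + l)
        altal <- anchor
      } else {                           # insertion after p
        insseq <- paste(sample(c("A", "C", "G", "T"), l, TRUE),
                        collapse = "")
        refal <- anchor
        altal <- paste0(anchor, insseq)
      }
      # left-normalized iff the representation cannot shift left, i.e.
      # the final REF and ALT bases differ
      if (substring(refal, nchar(refal), nchar(refal)) !=
          substring(altal, nchar(altal), nchar(altal))) {
        taken[[cn]] <- c(taken[[cn]], p)
        vars[[length(vars) + 1L]] <- data.table::data.table(
          chrom = cn, pos = p, ref = refal, alt = altal)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("infeasible indel placement", call. = FALSE)
  }

  variants <- if (length(vars)) data.table::rbindlist(vars) else {
    data.table::data.table(chrom = character(), pos = numeric(),
                           ref = character(), alt = character())
  }
  variants[, `:=`(qual = NA_real_, genotype = "hom", depth = NA_real_)]
  variants <- variants[order(match(variants$chrom, genome$name),
                             variants$pos, method = "radix")]
  list(variants = variants[], haplotype = apply_variants(reference, variants))
}

#' Apply variants to reference sequences
#'
#' @param reference named character vector.
#' @param variants truth calls data.table (`chrom`, `pos`, `ref`,
#'   `alt` in the anchored VCF convention).
#' @return Named character vector of mutated sequences.
#' @export
apply_variants <- function(reference, variants) {
  out <- reference
  for (cn in names(reference)) {
    v <- variants[variants$chrom == cn, ]
    if (nrow(v) == 0L) next
    v <- v[order(v$pos), ]
    pieces <- character(0)
    cursor <- 1
    s <- reference[[cn]]
    for (i in seq_len(nrow(v))) {
      pieces <- c(pieces, substring(s, cursor, v$pos[i] - 1), v$alt[i])
      cursor <- v$pos[i] + nchar(v$ref[i])
    }
    pieces <- c(pieces, substring(s, cursor, nchar(s)))
    out[[cn]] <- paste(pieces, collapse = "")
  }
  out
}

# Extract a read of rl query bases starting at reference position s,
# applying the chromosome's truth variants; returns seq/cigar.
extract_read <- function(refstr, vars, s, rl) {
  near <- vars[vars$pos >= s - 7 & vars$pos <= s + rl + 7, ]
  if (nrow(near) == 0L) {
    return(list(seq = substring(refstr, s, s + rl - 1),
                cigar = sprintf("%dM", rl)))
  }
  snps <- near[nchar(near$ref) == 1L & nchar(near$alt) == 1L, ]
  inds <- near[nchar(near$ref) != nchar(near$alt), ]
  if (nrow(inds) == 0L) {
    seq <- substring(refstr, s, s + rl - 1)
    hit <- snps[snps$pos >= s & snps$pos <= s + rl - 1, ]
    if (nrow(hit)) {
      ch <- strsplit(seq, "")[[1]]
      ch[hit$pos - s + 1] <- hit$alt
      seq <- paste(ch, collapse = "")
    }
    return(list(seq = seq, cigar = sprintf("%dM", rl)))
  }
  # general walker: consume reference from s, emitting query bases
  inds <- inds[order(inds$pos), ]
  ops <- character(0); lens <- numeric(0)
  outch <- character(0)
  p <- s; q <- 0
  emit <- function(op, l) {
    n <- length(ops)
    if (n > 0 && ops[n] == op) {
      lens[n] <<- lens[n] + l
    } else {
      ops <<- c(ops, op); lens <<- c(lens, l)
    }
  }
  snp_sub <- function(chars, from) {
    hit <- snps[snps$pos >= from & snps$pos < from + length(chars), ]
    if (nrow(hit)) chars[hit$pos - from + 1] <- hit$alt
    chars
  }
  while (q < rl) {
    nxt <- inds[inds$pos >= p, ]
    if (nrow(nxt) == 0L || nxt$pos[1] > p + (rl - q) - 1) {
      m <- rl - q
      ch <- snp_sub(strsplit(substring(refstr, p, p + m - 1), "")[[1]], p)
      outch <- c(outch, ch); emit("M", m); q <- q + m; p <- p + m
      break
    }
    a <- nxt$pos[1]
    m <- a - p + 1                       # M run through the anchor base
    ch <- snp_sub(strsplit(substring(refstr, p, a), "")[[1]], p)
    outch <- c(outch, ch); emit("M", m); q <- q + m; p <- a + 1
    if (q >= rl) break
    if (nchar(nxt$alt[1]) > nchar(nxt$ref[1])) {   # insertion
      insseq <- substring(nxt$alt[1], 2)
      k <- min(nchar(insseq), rl - q)
      outch <- c(outch, strsplit(substring(insseq, 1, k), "")[[1]])
      emit("I", k); q <- q + k
    } else {                                       # deletion
      dl <- nchar(nxt$ref[1]) - 1
      emit("D", dl); p <- p + dl
    }
  }
  # a read cannot end in a deletion
  if (ops[length(ops)] == "D") {
    ops <- ops[-length(ops)]; lens <- lens[-length(lens)]
  }
  list(seq = paste(outch, collapse = ""),
       cigar = paste0(lens, ops, collapse = ""))
}

#' Simulate aligned paired-end reads
#'
#' Emits SAM-style records pre-aligned to their true origin (alignment
#' itself is outside this package's input boundary): proper FR pairs
#' with normal insert sizes, a controlled fraction of PCR-duplicate
#' pairs (identical external coordinates, fresh names, errors and
#' MAPQs, tagged `du:Z:<original qname>`), a controlled fraction of
#' interchromosomally re-paired mates, optional enrichment of pairs
#' straddling fixed subregion boundaries, soft-clipped read ends (the
#' unclipped 5' coordinate is preserved), and uniform substitution
#' errors. Sequencing errors are substitutions only; the caller's
#' indel path is exercised through spiked true indels.
#'
#' @param reference named character vector of chromosome sequences
#'   (the unmutated reference; truth variants are woven in per read).
#' @param variants truth calls data.table from [spike_variants()]
#'   (may be empty).
#' @param spec a [sim_spec()].
#' @param plan optional [partition_genome()] plan, required when
#'   `boundary_enrich > 0`.
#' @return Canonically sorted records data.table; attribute
#'   `"n_duplicate_pairs"` records the number of duplicate pairs
#'   emitted.
#' @export
simulate_reads <- function(reference, variants = NULL, spec,
                           plan = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  if (is.null(variants)) {
    variants <- data.table::data.table(chrom = character(),
                                       pos = numeric(), ref = character(),
                                       alt = character())
  }
  set.seed(spec$seed + 2L)
  genome <- index_from_reference(reference)
  rl <- spec$read_length
  lens <- spec$chrom_lengths[genome$name]
  n_pairs <- ceiling(spec$coverage * sum(lens) / (2 * rl))

  chrom1 <- sample(genome$name, n_pairs, replace = TRUE,
                   prob = lens / sum(lens))
  ins <- round(stats::rnorm(n_pairs, spec$insert_mean, spec$insert_sd))
  ins <- pmax(rl, pmin(ins, lens[chrom1]))
  start <- 1 + floor(stats::runif(n_pairs) * (lens[chrom1] - ins + 1))

  # boundary-straddling enrichment
  if (spec$boundary_enrich > 0) {
    if (is.null(plan)) {
      stop("'plan' required when boundary_enrich > 0", call. = FALSE)
    }
    sub <- plan$subregions
    nb <- round(spec$boundary_enrich * n_pairs)
    if (nb > 0) {
      pick <- seq_len(nb)
      for (i in pick) {
        bnds <- sub$end[sub$chrom == chrom1[i] &
                          sub$end < lens[chrom1[i]]]
        if (length(bnds) == 0L) next
        b <- bnds[1 + (i %% length(bnds))]
        s <- b - floor(ins[i] / 2)
        start[i] <- min(max(1, s), lens[chrom1[i]] - ins[i] + 1)
      }
    }
  }

  chrom2 <- chrom1
  start2 <- start + ins - rl
  proper <- rep(TRUE, n_pairs)
  # interchromosomal re-pairing
  ni <- round(spec$interchrom_rate * n_pairs)
  if (ni > 0 && nrow(genome) > 1L) {
    pick <- sample(n_pairs, ni)
    for (i in pick) {
      other <- sample(setdiff(genome$name, chrom1[i]), 1L)
      chrom2[i] <- other
      start2[i] <- 1 + floor(stats::runif(1) * (lens[other] - rl + 1))
      proper[i] <- FALSE
    }
  }

  vlist <- split(variants, factor(variants$chrom, levels = genome$name))
  # vectorized extraction: reads far from every variant are plain
  # substrings; only variant-proximal reads go through the walker
  pull_all <- function(chroms, starts) {
    n <- length(starts)
    seqs <- character(n)
    cigars <- rep(sprintf("%dM", rl), n)
    out_start <- starts
    for (cn in unique(chroms)) {
      sel <- which(chroms == cn)
      v <- vlist[[cn]]
      s <- starts[sel]
      dels <- v[nchar(v$ref) > nchar(v$alt), ]
      for (i in seq_len(nrow(dels))) {     # shift starts out of deletions
        dl <- nchar(dels$ref[i]) - 1
        inside <- s > dels$pos[i] & s <= dels$pos[i] + dl
        s[inside] <- dels$pos[i] + dl + 1
      }
      s <- pmin(s, nchar(reference[[cn]]) - rl + 1)
      near <- rep(FALSE, length(s))
      for (p in v$pos) near <- near | (p >= s - 7 & p <= s + rl + 7)
      plain <- sel[!near]
      seqs[plain] <- substring(reference[[cn]], s[!near],
                               s[!near] + rl - 1)
      out_start[plain] <- s[!near]
      for (j in which(near)) {
        ex <- extract_read(reference[[cn]], v, s[j], rl)
        seqs[sel[j]] <- ex$seq
        cigars[sel[j]] <- ex$cigar
        out_start[sel[j]] <- s[j]
      }
    }
    list(start = out_start, seq = seqs, cigar = cigars)
  }
  e1 <- pull_all(chrom1, start)
  e2 <- pull_all(chrom2, start2)
  m1 <- lapply(seq_len(n_pairs), function(i) {
    list(start = e1$start[i], seq = e1$seq[i], cigar = e1$cigar[i])
  })
  m2 <- lapply(seq_len(n_pairs), function(i) {
    list(start = e2$start[i], seq = e2$seq[i], cigar = e2$cigar[i])
  })

  # soft clips on pure-M reads: leading for forward mates, trailing for
  # reverse mates; the unclipped 5' coordinate is unchanged
  clip1 <- stats::runif(n_pairs) < spec$clip_rate
  clip2 <- stats::runif(n_pairs) < spec$clip_rate
  klen <- function() sample(3:15, 1L)
  for (i in which(clip1)) {
    if (m1[[i]]$cigar != sprintf("%dM", rl)) next
    k <- klen()
    m1[[i]]$cigar <- sprintf("%dS%dM", k, rl - k)
    m1[[i]]$start <- m1[[i]]$start + k
    substr(m1[[i]]$seq, 1, k) <- paste(
      sample(c("A", "C", "G", "T"), k, TRUE), collapse = "")
  }
  for (i in which(clip2)) {
    if (m2[[i]]$cigar != sprintf("%dM", rl)) next
    k <- klen()
    m2[[i]]$cigar <- sprintf("%dM%dS", rl - k, k)
    substr(m2[[i]]$seq, rl - k + 1, rl) <- paste(
      sample(c("A", "C", "G", "T"), k, TRUE), collapse = "")
  }

  pairs <- data.table::data.table(
    origin = seq_len(n_pairs),
    qname = sprintf("r%06d", seq_len(n_pairs)),
    chrom1 = chrom1, pos1 = vapply(m1, `[[`, 0, "start"),
    cigar1 = vapply(m1, `[[`, "", "cigar"),
    seq1 = vapply(m1, `[[`, "", "seq"),
    chrom2 = chrom2, pos2 = vapply(m2, `[[`, 0, "start"),
    cigar2 = vapply(m2, `[[`, "", "cigar"),
    seq2 = vapply(m2, `[[`, "", "seq"),
    proper = proper, dup_of = "")

  # PCR duplicates: identical coordinates and CIGARs, fresh everything.
  # dup_rate is the expected duplicate fraction of *emitted* pairs, so
  # n_dup/(n_pairs + n_dup) ~ dup_rate.
  n_dup <- stats::rbinom(1L, n_pairs,
                         spec$dup_rate / (1 - spec$dup_rate))
  if (n_dup > 0) {
    orig <- sample(n_pairs, n_dup, replace = TRUE)
    dups <- pairs[orig]
    dups[, `:=`(qname = sprintf("d%06d", seq_len(n_dup)),
                dup_of = pairs$qname[orig])]
    pairs <- rbind(pairs, dups)
  }

  n_tot <- nrow(pairs)
  err_sub <- function(seqs) {
    nerr <- stats::rbinom(length(seqs), rl, spec$error_rate)
    for (i in which(nerr > 0)) {
      at <- sample(rl, nerr[i])
      ch <- strsplit(seqs[i], "")[[1]]
      ch[at] <- vapply(ch[at], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, "")
      seqs[i] <- paste(ch, collapse = "")
    }
    seqs
  }
  pairs[, seq1 := err_sub(seq1)]
  pairs[, seq2 := err_sub(seq2)]
  mapq1 <- sample(spec$mapq_choices, n_tot, replace = TRUE)
  mapq2 <- sample(spec$mapq_choices, n_tot, replace = TRUE)

  qualstr <- strrep(intToUtf8(spec$base_quality + 33L), rl)
  f1 <- ifelse(pairs$proper, 0x63L, 0x61L)   # paired(,proper),mate-rev,first
  f2 <- ifelse(pairs$proper, 0x93L, 0x91L)   # paired(,proper),rev,second
  tlen1 <- ifelse(pairs$chrom1 == pairs$chrom2,
                  pairs$pos2 + rl - pairs$pos1, 0)
  tags <- ifelse(nzchar(pairs$dup_of),
                 sprintf("du:Z:%s", pairs$dup_of), "")
  r1 <- sam_records(pairs$qname, f1, pairs$chrom1, pairs$pos1, mapq1,
                    pairs$cigar1, pairs$chrom2, pairs$pos2, tlen1,
                    pairs$seq1, qualstr, tags)
  r2 <- sam_records(pairs$qname, f2, pairs$chrom2, pairs$pos2, mapq2,
                    pairs$cigar2, pairs$chrom1, pairs$pos1, -tlen1,
                    pairs$seq2, qualstr, tags)
  out <- sort_records(rbind(r1, r2), genome)
  data.table::setattr(out, "header", sam_header(genome))
  data.table::setattr(out, "n_duplicate_pairs", n_dup)
  out
}

#' Generate a complete synthetic dataset
#'
#' Reference, spiked truth variants and aligned reads from one spec,
#' optionally written to disk (`reference.fa`, `genome.fai`,
#' `reads.sam`, `truth.vcf`, `spec.json`).
#'
#' @param spec a [sim_spec()].
#' @param plan optional [partition_genome()] plan for boundary-aware
#'   variant placement and pair enrichment.
#' @param dir optional output directory.
#' @return A list: `reference`, `genome` (index), `variants`,
#'   `records`, `spec`, and (when written) `paths`.
#' @export
simulate_dataset <- function(spec, plan = NULL, dir = NULL) {
  reference <- generate_reference(spec)
  genome <- index_from_reference(reference)
  spiked <- spike_variants(reference, spec, plan = plan)
  records <- simulate_reads(reference, spiked$variants, spec, plan = plan)
  out <- list(reference = reference, genome = genome,
              variants = spiked$variants, records = records, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      reference = file.path(dir, "reference.fa"),
      index = file.path(dir, "genome.fai"),
      reads = file.path(dir, "reads.sam"),
      truth = file.path(dir, "truth.vcf"),
      spec = file.path(dir, "spec.json"))
    write_reference(reference, paths$reference)
    write_genome_index(genome, paths$index)
    write_sam(records, paths$reads, genome = genome)
    write_vcf(spiked$variants, genome, paths$truth)
    jsonlite::write_json(unclass(spec), paths$spec, auto_unbox = TRUE,
                         digits = NA)
    out$paths <- paths
  }
  out
}
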