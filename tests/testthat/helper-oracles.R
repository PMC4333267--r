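# Independent oracles and fixture builders. Everything here is written
# as plainly as possible and must stay independent of the package
# internals it checks.

# -- per-base CIGAR walker -------------------------------------------------
# Assigns every query base (clips included) a virtual reference
# position by walking the CIGAR one base at a time: clipped bases
# continue the reference coordinate beyond the alignment. The unclipped
# 5' coordinate is then simply the virtual position of the first query
# base (forward strand) or of the last query base (reverse strand).
oracle_unclipped5 <- function(pos, cigar, reverse) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.numeric(sub(".$", "", ops))
  kinds <- sub("^[0-9]+", "", ops)
  vpos <- numeric(0)   # ref position per base; NA for clipped/inserted
  r <- pos
  for (i in seq_along(kinds)) {
    k <- kinds[i]
    for (b in seq_len(lens[i])) {
      if (k %in% c("M", "=", "X")) {
        vpos <- c(vpos, r); r <- r + 1
      } else if (k %in% c("S", "H", "I")) {
        vpos <- c(vpos, NA)
      } else if (k %in% c("D", "N")) {
        r <- r + 1
      }
    }
  }
  aligned <- which(!is.na(vpos))
  if (!reverse) {
    first <- aligned[1]
    vpos[first] - (first - 1)            # extend left over clipped bases
  } else {
    last <- aligned[length(aligned)]
    vpos[last] + (length(vpos) - last)   # extend right over clipped bases
  }
}

# random valid CIGAR for a given query length budget
random_cigar <- function() {
  parts <- character(0)
  if (runif(1) < 0.4) parts <- c(parts, sprintf("%dS", sample(1:10, 1)))
  nblocks <- sample(1:3, 1)
  for (b in seq_len(nblocks)) {
    parts <- c(parts, sprintf("%dM", sample(5:40, 1)))
    if (b < nblocks) {
      parts <- c(parts, if (runif(1) < 0.5) {
        sprintf("%dI", sample(1:5, 1))
      } else {
        sprintf("%dD", sample(1:5, 1))
      })
    }
  }
  if (runif(1) < 0.4) parts <- c(parts, sprintf("%dS", sample(1:10, 1)))
  if (runif(1) < 0.1) parts <- c(parts, sprintf("%dH", sample(1:5, 1)))
  paste(parts, collapse = "")
}

cigar_query_len <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.numeric(sub(".$", "", ops))
  kinds <- sub("^[0-9]+", "", ops)
  sum(lens[kinds %in% c("M", "I", "S", "=", "X")])
}

# -- brute-force duplicate-removal oracle ----------------------------------
# Hash-group-and-pick, one template at a time, no vectorization.
oracle_dedup_qnames <- function(records) {
  df <- as.data.frame(records)
  prim <- df[bitwAnd(df$flag, 0x900) == 0, ]
  groups <- split(prim, prim$qname)
  keyed <- list()
  for (qn in names(groups)) {
    g <- groups[[qn]]
    mapped <- g[bitwAnd(g$flag, 0x4) == 0, ]
    if (nrow(mapped) == 0) next
    triples <- character(0)
    for (i in seq_len(nrow(mapped))) {
      rev <- bitwAnd(mapped$flag[i], 0x10) != 0
      p5 <- oracle_unclipped5(mapped$pos[i], mapped$cigar[i], rev)
      triples <- c(triples, sprintf("%s:%.0f:%s", mapped$rname[i], p5,
                                    if (rev) "-" else "+"))
    }
    if (length(triples) == 2) {
      key <- paste(sort(triples), collapse = "|")
    } else if (nrow(g) == 2 || bitwAnd(mapped$flag[1], 0x8) != 0 ||
               bitwAnd(mapped$flag[1], 0x1) == 0) {
      key <- paste(triples, "*", sep = "|")
    } else {
      next  # lone mate of a mapped pair: exempt
    }
    score <- sum(g$mapq[bitwAnd(g$flag, 0x4) == 0])
    keyed[[length(keyed) + 1]] <- list(qname = qn, key = key,
                                       score = score)
  }
  bykey <- split(keyed, vapply(keyed, `[[`, "", "key"))
  losers <- character(0)
  for (grp in bykey) {
    scores <- vapply(grp, function(x) x$score, numeric(1))
    qn <- vapply(grp, `[[`, "", "qname")
    best <- qn[scores == max(scores)]
    surv <- sort(best)[1]
    losers <- c(losers, setdiff(qn, surv))
  }
  survivors <- setdiff(unique(df$qname), losers)
  survivors
}

# -- naive covariate recount oracle ----------------------------------------
oracle_covariates <- function(records, reference) {
  df <- as.data.frame(records)
  df <- df[bitwAnd(df$flag, 0x904) == 0 & df$seq != "*" & df$qual != "*", ]
  acc <- new.env()
  bump <- function(key, mm) {
    cur <- if (!is.null(acc[[key]])) acc[[key]] else c(0, 0)
    acc[[key]] <- cur + c(1, mm)
  }
  for (i in seq_len(nrow(df))) {
    ops <- regmatches(df$cigar[i],
                      gregexpr("[0-9]+[MIDNSHP=X]", df$cigar[i]))[[1]]
    lens <- as.numeric(sub(".$", "", ops))
    kinds <- sub("^[0-9]+", "", ops)
    r <- df$pos[i]; q <- 0
    second <- bitwAnd(df$flag[i], 0x80) != 0
    for (j in seq_along(kinds)) {
      k <- kinds[j]
      if (k %in% c("M", "=", "X")) {
        for (b in seq_len(lens[j])) {
          q <- q + 1
          base <- substr(df$seq[i], q, q)
          refb <- substr(reference[[df$rname[i]]], r, r)
          qv <- utf8ToInt(substr(df$qual[i], q, q)) - 33
          prev <- if (q > 1) substr(df$seq[i], q - 1, q - 1) else "-"
          ctx <- if (q == 1 || !(prev %in% c("A", "C", "G", "T"))) {
            "--"
          } else {
            paste0(prev, base)
          }
          cyc <- if (second) -q else q
          if (base != "N" && refb != "N") {
            bump(paste(qv, cyc, ctx, sep = "\r"),
                 as.integer(base != refb))
          }
          r <- r + 1
        }
      } else if (k %in% c("D", "N")) {
        r <- r + lens[j]
      } else if (k %in% c("I", "S")) {
        q <- q + lens[j]
      }
    }
  }
  keys <- ls(acc)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    reported_q = as.integer(vapply(parts, `[[`, "", 1)),
    cycle = as.integer(vapply(parts, `[[`, "", 2)),
    context = vapply(parts, `[[`, "", 3),
    observations = vapply(keys, function(k) acc[[k]][1], numeric(1)),
    mismatches = vapply(keys, function(k) acc[[k]][2], numeric(1)),
    row.names = NULL)
  out[order(out$reported_q, out$cycle, out$context, method = "radix"), ]
}

# -- builders --------------------------------------------------------------
rec1 <- function(qname = "q", flag = 0L, rname = "chr1", pos = 1,
                 mapq = 60L, cigar = "10M", rnext = "*", pnext = 0,
                 tlen = 0, seq = NULL, qual = NULL) {
  ql <- cigar_query_len(cigar)
  if (is.null(seq)) seq <- strrep("A", ql)
  if (is.null(qual)) qual <- strrep("?", ql)
  sam_records(qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen,
              seq, qual)
}

# a mapped FR pair with controllable coordinates / cigars / mapqs
make_pair <- function(qname, chrom1, pos1, chrom2, pos2, cigar1 = "100M",
                      cigar2 = "100M", mapq1 = 60L, mapq2 = 60L,
                      qual = strrep("?", 100)) {
  rl1 <- cigar_query_len(cigar1)
  rl2 <- cigar_query_len(cigar2)
  rbind(
    sam_records(qname, 0x63L, chrom1, pos1, mapq1, cigar1, chrom2, pos2,
                0, strrep("A", rl1), substr(strrep(qual, 4), 1, rl1)),
    sam_records(qname, 0x93L, chrom2, pos2, mapq2, cigar2, chrom1, pos1,
                0, strrep("C", rl2), substr(strrep(qual, 4), 1, rl2)))
}

records_signature <- function(records) {
  df <- as.data.frame(records)
  sort(do.call(paste, c(df, sep = "\t")))
}

small_fixture <- function(seed, dup_rate = 0.2, interchrom_rate = 0.05,
                          clip_rate = 0.1, coverage = 10,
                          lens = c(chrA = 30000, chrB = 20000),
                          n_snps = 10L, n_indels = 3L,
                          boundary_enrich = 0.1, M = 4L,
                          error_rate = 0.001,
                          mapq_choices = c(20L, 40L, 60L)) {
  spec <- sim_spec(seed = seed, chrom_lengths = lens, coverage = coverage,
                   dup_rate = dup_rate, interchrom_rate = interchrom_rate,
                   clip_rate = clip_rate, boundary_enrich = boundary_enrich,
                   error_rate = error_rate, n_snps = n_snps,
                   n_indels = n_indels, mapq_choices = mapq_choices)
  genome <- genome_index(names(lens), lens)
  plan <- partition_genome(genome, M, overlap = 3000)
  ref <- generate_reference(spec)
  spiked <- spike_variants(ref, spec, plan = plan)
  records <- simulate_reads(ref, spiked$variants, spec, plan = plan)
  list(spec = spec, genome = genome, plan = plan, reference = ref,
       variants = spiked$variants, records = records)
}
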