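#' Mapping decision parameters
#'
#' The real-time decision statistic is a weighted sum of three normalized
#' ratios computed from the current chain set: `r1` compares the primary
#' mapping quality to a "sufficiently high" reference quality
#' (`mapq_ref = 30`), `r2` compares the best chain's quality to the mean
#' quality of all chains and `r3` compares the best chain score to the
#' mean score of all chains.  `r2`/`r3` are capped at `cap2`/`cap3` and
#' rescaled to `[0, 1]`; a single chain saturates both.  The read is
#' mapped as soon as `w_sum = sum(r_i * w_i) > tau`.
#'
#' @param mapq_ref Reference mapping quality (default 30).
#' @param weights Length-3 non-negative weights for `(r1, r2, r3)`;
#'   normalized to sum 1.
#' @param tau Decision threshold.
#' @param cap2,cap3 Ratio caps for `r2` and `r3`.
#' @return A `decision_params` list.
#' @export
decision_params <- function(mapq_ref = 30, weights = c(0.4, 0.3, 0.3),
                            tau = 0.55, cap2 = 5, cap3 = 5) {
  stopifnot(length(weights) == 3L, all(weights >= 0), sum(weights) > 0,
            mapq_ref > 0, cap2 > 0, cap3 > 0)
  structure(list(mapq_ref = mapq_ref, weights = weights / sum(weights),
                 tau = tau, cap2 = cap2, cap3 = cap3),
            class = "decision_params")
}

#' Signal chunking parameters
#'
#' @param chunk_samples Samples delivered per chunk (default 4000, about
#'   one second of DNA sequencing at a 4 kHz sampling rate).
#' @param max_chunks Give up and report the read unmapped after this many
#'   chunks.
#' @param samples_per_base Sampling rate divided by translocation speed;
#'   the default 4000/450 matches R9.4 DNA conditions.
#' @return A `chunk_params` list.
#' @export
chunk_params <- function(chunk_samples = 4000L, max_chunks = 30L,
                         samples_per_base = 4000 / 450) {
  stopifnot(chunk_samples > 0, max_chunks >= 1, samples_per_base > 0)
  structure(list(chunk_samples = as.integer(chunk_samples),
                 max_chunks = as.integer(max_chunks),
                 samples_per_base = samples_per_base),
            class = "chunk_params")
}

#' Query-side frequency filter
#'
#' Removes seeds whose hash occurs more than `max_query_occ` times among
#' the query's own seeds (0 disables the filter), before any hash-table
#' lookup is made.
#'
#' @param seeds `data.frame(pos, hash)`.
#' @param max_query_occ Occurrence threshold.
#' @return Filtered `data.frame`.
#' @export
query_frequency_filter <- function(seeds, max_query_occ) {
  if (max_query_occ <= 0L || !nrow(seeds)) return(seeds)
  occ <- table(seeds$hash)
  keep <- occ[as.character(seeds$hash)] <= max_query_occ
  seeds[as.vector(keep), , drop = FALSE]
}

#' Weighted mapping decision
#'
#' Computes the decision statistic of [decision_params()] on the current
#' chain set.  With no chains the decision is `continue` with
#' `w_sum = 0`; with a single chain `r2 = r3 = 1`.
#'
#' @param chains Chains with `mapq` set ([mapping_quality()]).
#' @param dp A [decision_params()] object.
#' @return `list(decision = "map"|"continue", w_sum, ratios)`.
#' @export
weighted_decision <- function(chains, dp = decision_params()) {
  if (!length(chains)) {
    return(list(decision = "continue", w_sum = 0, ratios = c(0, 0, 0)))
  }
  mapqs <- vapply(chains, `[[`, 0L, "mapq")
  scores <- vapply(chains, `[[`, 0, "score")
  best_q <- mapqs[1L]
  best_s <- scores[1L]
  r1 <- min(1, best_q / dp$mapq_ref)
  if (length(chains) == 1L) {
    r2 <- 1
    r3 <- 1
  } else {
    mean_q <- mean(mapqs)
    r2 <- if (mean_q > 0) min(dp$cap2, best_q / mean_q) / dp$cap2 else 0
    mean_s <- mean(scores)
    r3 <- if (mean_s > 0) min(dp$cap3, best_s / mean_s) / dp$cap3 else 0
  }
  r <- c(r1, r2, r3)
  w_sum <- sum(r * dp$weights)
  list(decision = if (w_sum > dp$tau) "map" else "continue",
       w_sum = w_sum, ratios = r)
}

# One empty mapping record row (shared schema for mapped/unmapped).
paf_record <- function(qname, qlen = 0L, qstart = 0L, qend = 0L,
                       strand = "*", tname = "*", tlen = 0L, tstart = 0L,
                       tend = 0L, nmatch = 0L, blocklen = 0L, mapq = 0L,
                       chunks = 0L, events = 0L, w_sum = 0,
                       decision = "unmapped_max_chunks") {
  data.frame(qname = qname, qlen = as.integer(qlen),
             qstart = as.integer(qstart), qend = as.integer(qend),
             strand = strand, tname = tname, tlen = as.integer(tlen),
             tstart = as.integer(tstart), tend = as.integer(tend),
             nmatch = as.integer(nmatch), blocklen = as.integer(blocklen),
             mapq = as.integer(mapq), chunks = as.integer(chunks),
             events = as.integer(events), w_sum = w_sum,
             decision = decision, stringsAsFactors = FALSE)
}

#' Map one raw read against a reference index
#'
#' The real-time loop: consume the read chunk by chunk, segment the new
#' samples, re-normalize all event levels seen so far, regenerate query
#' seeds, apply the query-side frequency filter, look seeds up in the
#' index, chain the anchors per contig/strand, score mapping quality and
#' apply the weighted decision.  The loop stops at the first chunk whose
#' decision is `map` (emitting the best chain as a PAF row) or after
#' `max_chunks` chunks / end of signal (emitting an unmapped row).
#'
#' Query coordinates are events; PAF base coordinates use the estimate
#' `events_per_base = events_seen / bases_consumed` with
#' `bases_consumed = samples_consumed / samples_per_base`.
#'
#' @param read A [raw_read()].
#' @param index A `ref_index` from [build_index()].
#' @param segp,ckp,chp,dcp Segmentation, chunking, chaining and decision
#'   parameters.
#' @param max_query_occ Query-side frequency threshold (0 = off).
#' @return One-row `data.frame`: the 12 mandatory PAF fields plus decision
#'   metadata (`chunks`, `events`, `w_sum`, `decision`).
#' @export
map_read <- function(read, index, segp = seg_params(), ckp = chunk_params(),
                     chp = chain_params(), dcp = decision_params(),
                     max_query_occ = 5L) {
  stopifnot(inherits(read, "raw_read"), inherits(index, "ref_index"))
  qp <- index$params$qp
  sp <- index$params$sp
  st <- segment_state(segp)
  n <- length(read$samples)
  n_chunks <- min(ckp$max_chunks, ceiling(n / ckp$chunk_samples))
  levels <- numeric(0)
  consumed <- 0L
  res <- NULL
  for (ci in seq_len(max(n_chunks, 1L))) {
    lo <- (ci - 1L) * ckp$chunk_samples + 1L
    hi <- min(ci * ckp$chunk_samples, n)
    if (lo <= hi) {
      ev <- extend_events(st, read$samples[lo:hi])
      if (ci == n_chunks) ev <- rbind(ev, finalize_events(st))
      levels <- c(levels, ev$level)
      consumed <- hi
    }
    if (length(levels) < sp$e + 1L) next
    if (sqrt(mean((levels - mean(levels))^2)) <= 0) next
    norm <- normalize_levels(levels)
    seeds <- seeds_from_events(norm, qp, sp)
    seeds <- query_frequency_filter(seeds, max_query_occ)
    chains <- collect_chains(seeds, index, chp)
    dec <- weighted_decision(chains, dcp)
    if (dec$decision == "map") {
      res <- emit_mapping(read, index, chains[[1L]], ckp, ci, consumed,
                          length(levels), dec$w_sum)
      break
    }
  }
  if (is.null(res)) {
    if (!length(levels)) {
      warning("read '", read$read_id, "' produced no usable events")
    }
    qlen <- max(1L, round(consumed / ckp$samples_per_base))
    res <- paf_record(read$read_id, qlen = qlen,
                      chunks = if (n_chunks) n_chunks else 0L,
                      events = length(levels), w_sum = 0,
                      decision = "unmapped_max_chunks")
  }
  res
}

# Look query seeds up in the index and chain per contig/strand group.
collect_chains <- function(seeds, index, chp) {
  if (!nrow(seeds)) return(list())
  q <- data.table(hash = seeds$hash, y = seeds$pos)
  hits <- index$table[q, on = "hash", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(hits)) return(list())
  e <- index$params$sp$e
  chains <- list()
  for (grp in split(hits, by = c("contig", "strand"))) {
    setorder(grp, pos, y)
    anch <- data.frame(x = grp$pos, y = grp$y, w = e)
    cc <- chain_anchors(anch, chp)
    for (ch in cc) {
      ch$contig <- grp$contig[1L]
      ch$strand <- grp$strand[1L]
      chains[[length(chains) + 1L]] <- ch
    }
  }
  chains <- chains[order(-vapply(chains, `[[`, 0, "score"))]
  mapping_quality(chains)
}

# Turn the winning chain into a PAF row (base coordinates).
emit_mapping <- function(read, index, chain, ckp, chunks, consumed,
                         n_events, w_sum) {
  k <- index$params$k
  tlen <- index$contigs$length[chain$contig]
  n_levels <- tlen - k + 1L
  if (chain$strand == "+") {
    tstart <- chain$ref_start
    tend <- (chain$ref_end - 1L) + k
  } else {
    # postings are in reverse-complement k-mer coordinates; flip back
    tstart <- tlen - k - (chain$ref_end - 1L)
    tend <- tlen - chain$ref_start
  }
  tstart <- max(0L, as.integer(tstart))
  tend <- min(tlen, as.integer(tend))
  qlen <- max(1L, round(consumed / ckp$samples_per_base))
  epb <- n_events / (consumed / ckp$samples_per_base)
  qstart <- max(0L, as.integer(round(chain$query_start / epb)))
  qend <- min(qlen, as.integer(round(chain$query_end / epb)))
  if (qend <= qstart) qend <- min(qlen, qstart + 1L)
  blocklen <- max(tend - tstart, qend - qstart)
  paf_record(read$read_id, qlen = qlen, qstart = qstart, qend = qend,
             strand = chain$strand,
             tname = index$contigs$name[chain$contig], tlen = tlen,
             tstart = tstart, tend = tend,
             nmatch = min(as.integer(round(chain$score)), blocklen),
             blocklen = blocklen, mapq = chain$mapq, chunks = chunks,
             events = n_events, w_sum = w_sum, decision = "mapped")
}

#' Map a set of reads
#'
#' @param reads List of [raw_read()] objects.
#' @param index A `ref_index`.
#' @param ... Passed to [map_read()].
#' @param verbose Log a per-read decision summary to stderr.
#' @return `data.frame` of mapping records, one row per read.
#' @export
map_reads <- function(reads, index, ..., verbose = FALSE) {
  out <- lapply(reads, function(rd) {
    rec <- map_read(rd, index, ...)
    if (verbose) {
      message(sprintf("%s\t%s\t%s:%d-%d\tchunks=%d\tw_sum=%.3f",
                      rec$qname, rec$decision, rec$tname, rec$tstart,
                      rec$tend, rec$chunks, rec$w_sum))
    }
    rec
  })
  do.call(rbind, out)
}

#' Bases processed before the mapping decision
#'
#' Sequencing-cost accounting: every read (mapped or not) consumed
#' `chunks * chunk_samples / samples_per_base` bases' worth of signal
#' before its decision was made.
#'
#' @param records Mapping records ([map_reads()]).
#' @param ckp The [chunk_params()] used for mapping.
#' @return Numeric vector of base counts, one per record.
#' @export
bases_before_decision <- function(records, ckp = chunk_params()) {
  records$chunks * ckp$chunk_samples / ckp$samples_per_base
}

#' Write mapping records as PAF
#'
#' Twelve mandatory tab-separated columns plus SAM-style typed tags
#' (`ch:i` chunks, `ev:i` events, `ws:f` decision statistic, `dc:Z`
#' decision).
#'
#' @param records `data.frame` from [map_reads()] (or [read_paf()]).
#' @param path Output path or `""` for stdout.
#' @export
write_paf <- function(records, path) {
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\tch:i:%d\tev:i:%d\tws:f:%g\tdc:Z:%s",
                   records$qname, records$qlen, records$qstart, records$qend,
                   records$strand, records$tname, records$tlen,
                   records$tstart, records$tend, records$nmatch,
                   records$blocklen, records$mapq, records$chunks,
                   records$events, records$w_sum, records$decision)
  if (identical(path, "")) cat(lines, sep = "\n") else writeLines(lines, path)
  invisible(path)
}

#' Read a PAF file
#'
#' Parses the 12 mandatory columns and the typed tags written by
#' [write_paf()]; unknown tags are ignored, malformed lines are skipped
#' with a warning.
#'
#' @param path PAF path.
#' @return `data.frame` in the [map_reads()] schema.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  kept <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L) {
      warning("skipping malformed PAF line with ", length(f), " columns")
      next
    }
    tags <- f[-seq_len(12L)]
    tagval <- function(key, default) {
      hit <- tags[startsWith(tags, key)]
      if (!length(hit)) return(default)
      sub(key, "", hit[1L], fixed = TRUE)
    }
    kept <- kept + 1L
    out[[kept]] <- paf_record(
      f[1L], qlen = as.integer(f[2L]), qstart = as.integer(f[3L]),
      qend = as.integer(f[4L]), strand = f[5L], tname = f[6L],
      tlen = as.integer(f[7L]), tstart = as.integer(f[8L]),
      tend = as.integer(f[9L]), nmatch = as.integer(f[10L]),
      blocklen = as.integer(f[11L]), mapq = as.integer(f[12L]),
      chunks = as.integer(tagval("ch:i:", "0")),
      events = as.integer(tagval("ev:i:", "0")),
      w_sum = as.numeric(tagval("ws:f:", "0")),
      decision = tagval("dc:Z:", if (f[6L] == "*") "unmapped_max_chunks"
                        else "mapped"))
  }
  do.call(rbind, out[seq_len(kept)])
}
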