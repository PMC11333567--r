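#' Minimizer sketching parameters
#'
#' @param w_min Window size in consecutive seeds (>= 1).
#' @param enabled Whether minimizer selection is applied.
#' @return A `minimizer_params` list.
#' @export
minimizer_params <- function(w_min = 5L, enabled = FALSE) {
  stopifnot(w_min >= 1)
  structure(list(w_min = as.integer(w_min), enabled = isTRUE(enabled)),
            class = "minimizer_params")
}

#' Select minimizers from a seed list
#'
#' A seed is retained iff its hash is the minimum of at least one window
#' of `w_min` consecutive seeds, ties broken by leftmost position.  The
#' retained list is sorted by position and deduplicated.  With `w_min = 1`
#' the input is returned unchanged.
#'
#' @param seeds `data.frame(pos, hash)` in position order.
#' @param w_min Window size.
#' @return Sublist of `seeds`.
#' @export
select_minimizers <- function(seeds, w_min) {
  stopifnot(w_min >= 1)
  m <- nrow(seeds)
  if (w_min == 1L || m <= w_min) {
    if (m && m <= w_min && w_min > 1L) {
      # fewer seeds than one window: treat the whole list as one window
      i <- which.min(seeds$hash)
      return(seeds[i, , drop = FALSE])
    }
    return(seeds)
  }
  # embed() lists window elements latest-first; flip to original order so
  # ties.method = "first" implements the leftmost tie-break.
  M <- stats::embed(seeds$hash, w_min)[, w_min:1, drop = FALSE]
  off <- max.col(-M, ties.method = "first")
  idx <- sort(unique(seq_len(m - w_min + 1L) + off - 1L))
  seeds[idx, , drop = FALSE]
}

#' Read a FASTA file into a named character vector
#'
#' Multi-contig, wrapped lines, case-insensitive (sequences are
#' upper-cased).  Thin wrapper over `Biostrings::readDNAStringSet()`.
#'
#' @param path FASTA path.
#' @return Named character vector of contig sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a named character vector as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Build the reference index
#'
#' Translates every contig (both strands) into expected current levels
#' with the pore model, z-score normalizes them with *global* reference
#' statistics (stored in the index so queries can be compared against it),
#' quantizes and packs seeds, optionally sketches them with minimizers,
#' and inserts postings into a hash table.  Hashes occurring more than
#' `max_ref_occ` times are finally removed when `max_ref_occ > 0`
#' (reference-side frequency filter).
#'
#' Postings carry the 0-based end-anchored event position on the strand
#' they came from: forward-strand positions are indices into the contig's
#' k-mer array; reverse-strand positions are indices into the reverse
#' complement's k-mer array (converted to forward base coordinates when
#' mappings are reported).
#'
#' @param ref FASTA path or named character vector of contigs.
#' @param model A [pore_model()].
#' @param qp,sp,mp Quantization, seed and minimizer parameters.
#' @param max_ref_occ Reference frequency threshold (0 = filter off).
#' @return A `ref_index` object.
#' @export
build_index <- function(ref, model, qp = quant_params(), sp = seed_params(),
                        mp = minimizer_params(), max_ref_occ = 0L) {
  if (is.character(ref) && length(ref) == 1L && file.exists(ref)) {
    ref <- read_fasta(ref)
  }
  if (!length(ref)) stop("empty reference")
  if (is.null(names(ref)) || any(!nzchar(names(ref)))) {
    stop("reference contigs must be named")
  }
  k <- model$k
  min_len <- k + sp$e - 1L
  keep <- nchar(ref) >= min_len
  if (!all(keep)) {
    warning("skipping ", sum(!keep), " contig(s) shorter than k + e - 1 = ",
            min_len)
    ref <- ref[keep]
  }
  if (!length(ref)) stop("no contig long enough to index")

  # per contig/strand level segments, then global normalization statistics
  segs <- list()
  for (ci in seq_along(ref)) {
    for (strand in c("+", "-")) {
      ss <- sequence_to_levels(ref[[ci]], model,
                               if (strand == "+") "forward" else "reverse")
      for (sg in ss) {
        if (length(sg$levels) < sp$e) next
        segs[[length(segs) + 1L]] <- list(contig = ci, strand = strand,
                                          start = sg$start, levels = sg$levels)
      }
    }
  }
  if (!length(segs)) stop("reference produced no usable level segments")
  all_levels <- unlist(lapply(segs, `[[`, "levels"), use.names = FALSE)
  mu <- mean(all_levels)
  sigma <- sqrt(mean((all_levels - mu)^2))
  if (sigma <= 0) {
    # degenerate (e.g. homopolymer) reference: indexable, but only the
    # frequency filter can make its seeds useful
    warning("reference levels are constant; using unit normalization scale")
    sigma <- 1
  }

  tabs <- lapply(segs, function(sg) {
    sd0 <- seeds_from_events((sg$levels - mu) / sigma, qp, sp)
    if (mp$enabled) sd0 <- select_minimizers(sd0, mp$w_min)
    if (!nrow(sd0)) return(NULL)
    data.table(hash = sd0$hash, contig = as.integer(sg$contig),
               pos = as.integer(sd0$pos + sg$start),
               strand = sg$strand)
  })
  table <- rbindlist(tabs)
  if (max_ref_occ > 0L) {
    cnt <- table[, .N, by = hash]
    table <- table[!cnt[N > max_ref_occ], on = "hash"]
  }
  setkey(table, hash)
  structure(list(
    table = table,
    contigs = data.frame(name = names(ref), length = nchar(ref),
                         row.names = NULL, stringsAsFactors = FALSE),
    params = list(k = k, qp = qp, sp = sp, mp = mp,
                  max_ref_occ = as.integer(max_ref_occ)),
    level_stats = c(mean = mu, sd = sigma),
    version = 1L), class = "ref_index")
}

#' Automatic reference frequency cap
#'
#' Smallest threshold `T` such that at least `keep_frac` of distinct
#' hashes have no more than `T` postings (minimap2-style top-fraction
#' rule).
#'
#' @param index A `ref_index` (unfiltered).
#' @param keep_frac Fraction of distinct hashes to keep (default 0.998).
#' @return Integer threshold.
#' @export
auto_freq_cap <- function(index, keep_frac = 0.998) {
  cnt <- index$table[, .N, by = hash]$N
  as.integer(stats::quantile(cnt, keep_frac, type = 1L))
}

#' @export
print.ref_index <- function(x, ...) {
  cat("ref_index:", nrow(x$contigs), "contig(s),",
      format(sum(x$contigs$length), big.mark = ","), "bp,",
      format(nrow(x$table), big.mark = ","), "postings,",
      format(length(unique(x$table$hash)), big.mark = ","),
      "distinct hashes\n")
  invisible(x)
}

INDEX_MAGIC <- "squigglemap-index"

#' Save / load a reference index
#'
#' Versioned RDS archive with a magic tag; [load_index()] refuses files
#' that are not squigglemap indexes or that carry a different version.
#'
#' @param index A `ref_index`.
#' @param path File path.
#' @return `load_index` returns the `ref_index`.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "ref_index"))
  saveRDS(list(magic = INDEX_MAGIC, version = index$version, index = index),
          path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read index file '", path,
                                           "': ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$magic, INDEX_MAGIC)) {
    stop("not a squigglemap index: ", path)
  }
  if (!identical(obj$version, 1L)) {
    stop("unsupported index version: ", obj$version)
  }
  obj$index
}
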