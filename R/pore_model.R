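#' Load a k-mer pore model
#'
#' Reads the tab-separated k-mer model table used to translate reference
#' bases into expected current levels.  Rows are
#' `kmer<TAB>level_mean<TAB>level_stdv`; a header row and `#`-prefixed
#' comment lines are skipped.  The k-mer length `k` is inferred from the
#' first key and the table must contain all `4^k` k-mers over `{A,C,G,T}`
#' exactly once.
#'
#' @param path Path to the model TSV.
#' @return A `pore_model` object: list with `k`, `kmers` (lexicographic
#'   order), `level_mean` and `level_stdv` (numeric vectors aligned with
#'   `kmers`).
#' @examples
#' path <- system.file("extdata", "example_model_k2_synthetic.tsv",
#'                     package = "squigglemap")
#' model <- load_pore_model(path)
#' model$k
#' @export
load_pore_model <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("pore model file has no data rows: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3)) stop("pore model rows must have >= 3 tab-separated columns")
  km <- toupper(vapply(parts, `[[`, "", 1L))
  # tolerate a header row ("kmer  level_mean  level_stdv")
  if (grepl("[^ACGT]", km[1L])) {
    parts <- parts[-1L]; km <- km[-1L]
    if (!length(km)) stop("pore model file has no data rows: ", path)
  }
  mean <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  stdv <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(mean) || anyNA(stdv)) stop("non-numeric level in pore model")
  k <- nchar(km[1L])
  if (any(nchar(km) != k)) stop("pore model k-mers have inconsistent lengths")
  if (any(grepl("[^ACGT]", km))) stop("pore model k-mers must be over {A,C,G,T}")
  if (anyDuplicated(km)) stop("duplicate k-mer in pore model: ", km[anyDuplicated(km)])
  if (length(km) != 4^k) {
    stop("pore model incomplete: expected ", 4^k, " ", k, "-mers, got ", length(km))
  }
  if (any(stdv <= 0)) stop("level_stdv must be > 0 for all k-mers")
  ord <- order(km)
  new_pore_model(k, km[ord], mean[ord], stdv[ord])
}

new_pore_model <- function(k, kmers, level_mean, level_stdv) {
  structure(list(k = as.integer(k), kmers = kmers,
                 level_mean = level_mean, level_stdv = level_stdv),
            class = "pore_model")
}

#' Write a pore model TSV
#'
#' @param model A `pore_model`.
#' @param path Output path.
#' @export
write_pore_model <- function(model, path) {
  stopifnot(inherits(model, "pore_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#kmer\tlevel_mean\tlevel_stdv", con)
  writeLines(sprintf("%s\t%.6f\t%.6f", model$kmers,
                     model$level_mean, model$level_stdv), con)
  invisible(path)
}

#' Generate a synthetic pore model
#'
#' Builds a complete, reproducible k-mer model for testing and simulation:
#' level means are drawn from a normal distribution on a picoampere-like
#' scale and level standard deviations uniformly from `stdv_range`.  This is
#' a synthetic stand-in for a flow-cell-calibrated model; any conforming TSV
#' can be used instead via [load_pore_model()].
#'
#' @param k K-mer length (default 6).
#' @param level_centre,level_spread Mean and SD of the level-mean
#'   distribution, in model units (defaults 90 and 8, roughly the R9.4
#'   current scale).
#' @param stdv_range Range of per-k-mer level SDs (default `c(1.5, 3)`).
#' @param seed RNG seed; the model is fully determined by its arguments.
#' @return A `pore_model`.
#' @export
synthetic_pore_model <- function(k = 6L, level_centre = 90, level_spread = 8,
                                 stdv_range = c(1.5, 3), seed = 7L) {
  stopifnot(k >= 1, level_spread > 0, all(stdv_range > 0))
  n <- 4^k
  kmers <- kmer_strings(k)
  with_seed(seed, {
    new_pore_model(k, kmers,
                   rnorm(n, level_centre, level_spread),
                   runif(n, stdv_range[1L], stdv_range[2L]))
  })
}

# All 4^k k-mers in lexicographic (A<C<G<T) order.
kmer_strings <- function(k) {
  b <- c("A", "C", "G", "T")
  out <- b
  if (k > 1) for (i in 2:k) out <- paste0(rep(out, each = 4L), b)
  out
}

# Integer codes (A=0,C=1,G=2,T=3, NA otherwise) for a sequence string.
base_codes <- function(seq) {
  raw <- utf8ToInt(toupper(seq))
  code <- rep(NA_real_, length(raw))
  code[raw == utf8ToInt("A")] <- 0
  code[raw == utf8ToInt("C")] <- 1
  code[raw == utf8ToInt("G")] <- 2
  code[raw == utf8ToInt("T")] <- 3
  code
}

#' Translate a nucleotide sequence into expected current levels
#'
#' Maps every k-mer of `seq` (or of its reverse complement, reported in the
#' reverse complement's own 5'->3' order) to the model's expected level
#' mean.  Positions containing `N` produce no level and split the output
#' into segments; segment start offsets are reported in the coordinate
#' frame of the oriented sequence's k-mer array (0-based).
#'
#' @param seq Nucleotide string over `{A,C,G,T,N}`.
#' @param model A `pore_model`.
#' @param strand `"forward"` or `"reverse"`.
#' @return List of segments, each `list(start = <0-based k-mer index>,
#'   levels = <numeric>)`.  A sequence shorter than `k` yields an empty
#'   list with a warning.
#' @export
sequence_to_levels <- function(seq, model, strand = c("forward", "reverse")) {
  stopifnot(inherits(model, "pore_model"))
  strand <- match.arg(strand)
  if (strand == "reverse") seq <- revcomp(seq)
  k <- model$k
  L <- nchar(seq)
  if (L < k) {
    warning("sequence shorter than k = ", k, "; no levels produced")
    return(list())
  }
  code <- base_codes(seq)
  nwin <- L - k + 1L
  kc <- numeric(nwin)
  for (j in seq_len(k)) kc <- kc * 4 + code[j:(nwin + j - 1L)]
  lv <- model$level_mean[kc + 1]  # NA windows (contain N) stay NA
  ok <- !is.na(kc)
  if (!any(ok)) return(list())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- which(r$values)
  lapply(segs, function(i) {
    list(start = starts[i] - 1L, levels = lv[starts[i]:ends[i]])
  })
}
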