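#' Construct an in-memory raw read
#'
#' `samples` are stored in converted (picoampere) units; on disk SLOW5
#' stores integer DAC values, converted as
#' `pA = (raw + offset) * range / digitisation`.  With the default
#' `digitisation = range = 1` and `offset = 0` the conversion is the
#' identity.
#'
#' @param read_id Read identifier.
#' @param samples Numeric vector of current samples (converted units).
#' @param sampling_rate Samples per second (Hz).
#' @param digitisation,offset,range Conversion attributes (see above).
#' @return A `raw_read` object.
#' @export
raw_read <- function(read_id, samples, sampling_rate = 4000,
                     digitisation = 1, offset = 0, range = 1) {
  stopifnot(is.character(read_id), length(read_id) == 1L,
            sampling_rate > 0, digitisation > 0, range > 0)
  structure(list(read_id = read_id, samples = as.numeric(samples),
                 sampling_rate = as.numeric(sampling_rate),
                 digitisation = as.numeric(digitisation),
                 offset = as.numeric(offset), range = as.numeric(range)),
            class = "raw_read")
}

# Snap converted samples onto the integer DAC grid defined by the
# conversion attributes, so write/read round-trips are exact.
digitise_samples <- function(pA, digitisation, offset, range) {
  raw <- round(pA * digitisation / range - offset)
  (raw + offset) * range / digitisation
}

slow5_columns <- c("read_id", "read_group", "digitisation", "offset",
                   "range", "sampling_rate", "len_raw_signal", "raw_signal")

#' Read raw signals from an ASCII SLOW5 file
#'
#' Parses the tab-separated ASCII dialect of SLOW5.  The signal column is
#' comma-separated integers; values are converted to picoamperes with each
#' record's `digitisation`/`offset`/`range` attributes.  Records with a
#' column-count mismatch or an empty signal field are skipped with a
#' warning; iteration continues.
#'
#' @param path Path to a `.slow5` file.
#' @return List of [raw_read()] objects in file order.
#' @export
read_slow5 <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "#slow5_version")) {
    stop("not a SLOW5 ASCII file (missing #slow5_version header): ", path)
  }
  hdr_idx <- which(startsWith(lines, "#read_id"))
  if (!length(hdr_idx)) stop("SLOW5 file has no column header line")
  hdr_idx <- hdr_idx[1L]
  cols <- strsplit(sub("^#", "", lines[hdr_idx]), "\t", fixed = TRUE)[[1L]]
  need <- match(slow5_columns, cols)
  if (anyNA(need)) stop("SLOW5 header missing columns: ",
                        paste(slow5_columns[is.na(need)], collapse = ", "))
  body <- lines[-seq_len(hdr_idx)]
  body <- body[nzchar(body) & !startsWith(body, "#") & !startsWith(body, "@")]
  out <- vector("list", length(body))
  kept <- 0L
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(cols)) {
      warning("skipping SLOW5 record with ", length(f), " columns (expected ",
              length(cols), ")")
      next
    }
    f <- f[need]
    sig <- f[8L]
    if (!nzchar(sig)) {
      warning("skipping SLOW5 record '", f[1L], "' with empty signal")
      next
    }
    raw <- as.numeric(strsplit(sig, ",", fixed = TRUE)[[1L]])
    dig <- as.numeric(f[3L]); off <- as.numeric(f[4L]); rng <- as.numeric(f[5L])
    kept <- kept + 1L
    out[[kept]] <- raw_read(f[1L], (raw + off) * rng / dig,
                            sampling_rate = as.numeric(f[6L]),
                            digitisation = dig, offset = off, range = rng)
  }
  out[seq_len(kept)]
}

#' Write raw signals to an ASCII SLOW5 file
#'
#' Converted samples are mapped back to integer DAC values with each read's
#' conversion attributes; samples produced by the package's simulator lie
#' exactly on that grid, so a write/read round trip reproduces them.
#'
#' @param reads List of [raw_read()] objects.
#' @param path Output path.
#' @export
write_slow5 <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#slow5_version\t2.0",
               "#num_read_groups\t1",
               paste0("#", paste(slow5_columns, collapse = "\t"))), con)
  for (rd in reads) {
    stopifnot(inherits(rd, "raw_read"))
    raw <- round(rd$samples * rd$digitisation / rd$range - rd$offset)
    writeLines(paste(rd$read_id, 0L,
                     format(rd$digitisation, scientific = FALSE),
                     format(rd$offset, scientific = FALSE),
                     format(rd$range, scientific = FALSE),
                     format(rd$sampling_rate, scientific = FALSE),
                     length(raw),
                     paste(format(raw, scientific = FALSE, trim = TRUE),
                           collapse = ","),
                     sep = "\t"), con)
  }
  invisible(path)
}
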