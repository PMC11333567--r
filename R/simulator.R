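#' Squiggle simulator parameters
#'
#' Defaults emulate a DNA run on an R9.4-like pore: 450 bases/s
#' translocation, 4 kHz sampling (so a mean dwell of ~8.9 samples per
#' k-mer step), per-step dwell drawn from a rounded Gamma with coefficient
#' of variation `dwell_dispersion`, Gaussian current noise scaled from the
#' pore model's per-k-mer level SD, and a per-read affine distortion
#' (scale `a ~ N(1, per_read_scale_sd)`, shift `b ~ N(0,
#' per_read_shift_sd)` in model units).
#'
#' @param n_reads Number of reads.
#' @param read_len_mean,read_len_min Read length distribution (bases);
#'   lengths are Gamma(shape = 3) with the given mean, floored at the
#'   minimum.
#' @param bases_per_second Translocation speed.
#' @param sampling_rate Signal sampling rate, Hz.
#' @param dwell_dispersion CV of per-step dwell (0 = constant dwell).
#' @param noise_sd_scale Multiplier on the model `level_stdv` for sample
#'   noise (0 = noiseless).
#' @param per_read_shift_sd,per_read_scale_sd Per-read affine distortion.
#' @param rng_seed Seed; the output is fully determined by it.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_reads = 200L, read_len_mean = 1000L,
                       read_len_min = 200L, bases_per_second = 450,
                       sampling_rate = 4000, dwell_dispersion = 0.25,
                       noise_sd_scale = 1.0, per_read_shift_sd = 1.0,
                       per_read_scale_sd = 0.02, rng_seed = 1L) {
  stopifnot(n_reads >= 1, read_len_min >= 1, read_len_mean >= read_len_min,
            bases_per_second > 0, sampling_rate > 0, dwell_dispersion >= 0,
            noise_sd_scale >= 0, per_read_shift_sd >= 0,
            per_read_scale_sd >= 0)
  structure(list(n_reads = as.integer(n_reads),
                 read_len_mean = as.integer(read_len_mean),
                 read_len_min = as.integer(read_len_min),
                 bases_per_second = bases_per_second,
                 sampling_rate = sampling_rate,
                 dwell_dispersion = dwell_dispersion,
                 noise_sd_scale = noise_sd_scale,
                 per_read_shift_sd = per_read_shift_sd,
                 per_read_scale_sd = per_read_scale_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_params")
}

#' Simulate raw nanopore reads with ground truth
#'
#' Draws read origins uniformly from the reference (contigs weighted by
#' length, strand fair-coin), translates each read's oriented sequence to
#' expected levels with the pore model, expands levels by the dwell model,
#' adds Gaussian noise and the per-read affine distortion, and snaps
#' samples onto the SLOW5 integer grid.  Ground truth is returned as PAF
#' records (and optionally written alongside the SLOW5 file).
#'
#' @param ref FASTA path or named character vector of contigs (no `N`s).
#' @param model A [pore_model()].
#' @param sp A [sim_params()] object.
#' @param out_slow5,out_truth Optional output paths for the SLOW5 file and
#'   truth PAF.
#' @return `list(reads = <list of raw_read>, truth = <PAF data.frame>)`.
#' @export
simulate_reads <- function(ref, model, sp = sim_params(),
                           out_slow5 = NULL, out_truth = NULL) {
  if (is.character(ref) && length(ref) == 1L && file.exists(ref)) {
    ref <- read_fasta(ref)
  }
  stopifnot(length(ref) > 0, !is.null(names(ref)))
  if (any(grepl("N", ref, fixed = TRUE))) {
    stop("simulate_reads requires an N-free reference")
  }
  k <- model$k
  clen <- nchar(ref)
  mu_dwell <- sp$sampling_rate / sp$bases_per_second
  reads <- vector("list", sp$n_reads)
  truth <- vector("list", sp$n_reads)
  with_seed(sp$rng_seed, {
    for (i in seq_len(sp$n_reads)) {
      len <- max(sp$read_len_min,
                 round(rgamma(1L, shape = 3, scale = sp$read_len_mean / 3)))
      ci <- start <- NA
      for (try in seq_len(100L)) {
        ci <- sample.int(length(ref), 1L, prob = clen)
        if (clen[ci] >= len) {
          start <- sample.int(clen[ci] - len + 1L, 1L) - 1L  # 0-based
          break
        }
      }
      if (is.na(start)) stop("no contig can hold a read of length ", len)
      strand <- if (runif(1L) < 0.5) "+" else "-"
      seq <- substr(ref[[ci]], start + 1L, start + len)
      if (strand == "-") seq <- revcomp(seq)
      segs <- sequence_to_levels(seq, model, "forward")
      lv <- segs[[1L]]$levels
      idx <- match(substring(seq, seq_len(len - k + 1L),
                             seq_len(len - k + 1L) + k - 1L), model$kmers)
      stdv <- model$level_stdv[idx]
      dwell <- if (sp$dwell_dispersion > 0) {
        shape <- 1 / sp$dwell_dispersion^2
        pmax(1L, as.integer(round(rgamma(length(lv), shape = shape,
                                         scale = mu_dwell / shape))))
      } else rep(as.integer(round(mu_dwell)), length(lv))
      a <- if (sp$per_read_scale_sd > 0) rnorm(1L, 1, sp$per_read_scale_sd) else 1
      b <- if (sp$per_read_shift_sd > 0) rnorm(1L, 0, sp$per_read_shift_sd) else 0
      samples <- rep(a * lv + b, dwell)
      if (sp$noise_sd_scale > 0) {
        samples <- samples + rnorm(length(samples), 0,
                                   sp$noise_sd_scale * rep(stdv, dwell))
      }
      rid <- sprintf("sim_%04d", i)
      rd <- raw_read(rid, samples, sampling_rate = sp$sampling_rate,
                     digitisation = 8192, offset = 0, range = 1443)
      rd$samples <- digitise_samples(rd$samples, rd$digitisation, rd$offset,
                                     rd$range)
      reads[[i]] <- rd
      truth[[i]] <- paf_record(rid, qlen = len, qstart = 0L, qend = len,
                               strand = strand, tname = names(ref)[ci],
                               tlen = clen[ci], tstart = start,
                               tend = start + len, nmatch = len,
                               blocklen = len, mapq = 60L,
                               decision = "mapped")
    }
  })
  truth <- do.call(rbind, truth)
  if (!is.null(out_slow5)) write_slow5(reads, out_slow5)
  if (!is.null(out_truth)) write_paf(truth, out_truth)
  list(reads = reads, truth = truth)
}

#' Generate a random reference genome
#'
#' Uniform ACGT contigs, reproducible from `seed`.
#'
#' @param lengths Named integer vector of contig lengths.
#' @param seed RNG seed.
#' @return Named character vector of contig sequences.
#' @export
random_genome <- function(lengths = c(chr1 = 60000L, chr2 = 40000L),
                          seed = 11L) {
  stopifnot(!is.null(names(lengths)), all(lengths > 0))
  with_seed(seed, {
    vapply(lengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, "")
  })
}
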