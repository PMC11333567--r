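#' Segmentation parameters
#'
#' Controls the two-window t-statistic event detector.  A boundary is
#' placed where the Welch t-statistic between the `w` samples on either
#' side is a local maximum exceeding that window's threshold; peaks from
#' the short and long windows are pooled and non-maximum suppression keeps
#' the strongest peak within `w_short` samples.  Events shorter than
#' `min_dwell` samples are merged into a neighbour (stutter suppression).
#'
#' @param w_short,w_long Short/long window sizes, samples.
#' @param t_short,t_long Peak thresholds for the two windows.
#' @param peak_height_min Absolute floor on the t-statistic of any peak.
#' @param min_dwell Minimum event length in samples; shorter events merge.
#' @param max_events_per_chunk Advisory cap carried in the configuration
#'   (0 = unlimited); the detector itself does not truncate.
#' @return A `seg_params` list.
#' @export
seg_params <- function(w_short = 4L, w_long = 16L, t_short = 4.5,
                       t_long = 3.0, peak_height_min = 0.2,
                       min_dwell = 3L, max_events_per_chunk = 0L) {
  stopifnot(w_short > 0, w_long > w_short, t_short > 0, t_long > 0,
            min_dwell >= 1)
  structure(list(w_short = as.integer(w_short), w_long = as.integer(w_long),
                 t_short = t_short, t_long = t_long,
                 peak_height_min = peak_height_min,
                 min_dwell = as.integer(min_dwell),
                 max_events_per_chunk = as.integer(max_events_per_chunk)),
            class = "seg_params")
}

# Welch t-statistic for a split after sample b (1-based), windows of w on
# each side.  Returns a length-(n-1) vector, 0 where the window does not fit.
tstat_array <- function(x, w) {
  n <- length(x)
  out <- numeric(max(n - 1L, 0L))
  if (n < 2L * w) return(out)
  S <- c(0, cumsum(x))
  Q <- c(0, cumsum(x * x))
  b <- w:(n - w)
  m1 <- (S[b + 1L] - S[b - w + 1L]) / w
  m2 <- (S[b + w + 1L] - S[b + 1L]) / w
  v1 <- pmax((Q[b + 1L] - Q[b - w + 1L]) / w - m1^2, 0)
  v2 <- pmax((Q[b + w + 1L] - Q[b + 1L]) / w - m2^2, 0)
  out[b] <- abs(m1 - m2) / sqrt(pmax((v1 + v2) / w, 1e-12))
  out
}

# Local maxima of t exceeding thr; leftmost element of a plateau wins.
peak_positions <- function(t, thr) {
  n <- length(t)
  if (!n) return(integer(0))
  left <- c(-Inf, t[-n])
  right <- c(t[-1L], -Inf)
  which(t >= thr & t > left & t >= right)
}

#' Detect events in a raw sample vector
#'
#' Single-shot event segmentation: pooled short/long-window t-statistic
#' peaks with non-maximum suppression, followed by a short-event merge
#' pass.  Event levels are the arithmetic means of their (un-normalized)
#' samples.
#'
#' @param samples Numeric vector of raw samples.
#' @param params A [seg_params()] object.
#' @return `data.frame(level, start_sample, end_sample)` with 0-based,
#'   half-open sample intervals tiling the input.  Fewer than `w_long`
#'   samples yield zero rows.
#' @export
detect_events <- function(samples, params = seg_params()) {
  empty <- data.frame(level = numeric(0), start_sample = integer(0),
                      end_sample = integer(0))
  n <- length(samples)
  if (n < params$w_long) return(empty)
  bounds <- event_boundaries(samples, params)
  bounds <- merge_short_events(bounds, n, params$min_dwell)
  starts <- c(0L, bounds)
  ends <- c(bounds, n)
  S <- c(0, cumsum(samples))
  data.frame(level = (S[ends + 1L] - S[starts + 1L]) / (ends - starts),
             start_sample = starts, end_sample = ends)
}

# Pooled candidate peaks from both windows + NMS.  Returns sorted 0-based
# boundary positions (split before sample index b).
event_boundaries <- function(samples, params) {
  cand_pos <- integer(0)
  cand_str <- numeric(0)
  for (cfg in list(c(params$w_short, params$t_short),
                   c(params$w_long, params$t_long))) {
    t <- tstat_array(samples, cfg[1L])
    thr <- max(cfg[2L], params$peak_height_min)
    p <- peak_positions(t, thr)
    cand_pos <- c(cand_pos, p)
    cand_str <- c(cand_str, t[p] / cfg[2L])
  }
  if (!length(cand_pos)) return(integer(0))
  ord <- order(-cand_str, cand_pos)
  cand_pos <- cand_pos[ord]
  keep <- logical(length(cand_pos))
  acc <- integer(0)
  for (i in seq_along(cand_pos)) {
    if (!length(acc) || min(abs(acc - cand_pos[i])) > params$w_short) {
      keep[i] <- TRUE
      acc <- c(acc, cand_pos[i])
    }
  }
  sort(unique(cand_pos[keep]))
}

# Left-to-right merge of events shorter than min_dwell into a neighbour
# (previous when one exists).  Deterministic single policy so streaming and
# single-shot segmentation agree.
merge_short_events <- function(bounds, n, min_dwell) {
  repeat {
    lens <- diff(c(0L, bounds, n))
    short <- which(lens < min_dwell)
    if (!length(short) || length(lens) == 1L) return(bounds)
    i <- short[1L]
    bounds <- bounds[-(if (i == 1L) 1L else i - 1L)]
  }
}

#' Z-score normalize event levels
#'
#' Centres and scales to population mean 0 / SD 1.  Affine-invariant:
#' `normalize_levels(a*x + b)` equals `normalize_levels(x)` for `a > 0`.
#'
#' @param levels Numeric vector, length >= 2, non-constant.
#' @return Normalized vector of the same length and order.
#' @export
normalize_levels <- function(levels) {
  if (length(levels) < 2L) stop("need >= 2 levels to normalize")
  m <- mean(levels)
  s <- sqrt(mean((levels - m)^2))
  if (s <= 0) stop("zero variance: levels cannot be normalized")
  (levels - m) / s
}

#' Streaming segmentation state
#'
#' Carries the samples seen so far for one read plus a count of events
#' already emitted.  [extend_events()] re-detects over all accumulated
#' samples and emits only events whose boundaries can no longer change
#' when more signal arrives; [finalize_events()] flushes the rest.
#'
#' @param params A [seg_params()] object.
#' @return A `segment_state` environment.
#' @export
segment_state <- function(params = seg_params()) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$samples <- numeric(0)
  st$emitted <- 0L
  class(st) <- "segment_state"
  st
}

#' Feed a chunk of samples to a streaming segmenter
#'
#' Concatenating the events emitted over all chunks plus
#' [finalize_events()] reproduces [detect_events()] on the concatenated
#' samples exactly: a detected event is withheld until no future sample
#' can move its boundaries (its end lies well clear of the stream end and
#' it is not one of the last two events, which a trailing boundary or
#' short-event merge could still alter).
#'
#' @param state A [segment_state()].
#' @param new_samples Numeric vector (may be empty).
#' @return `data.frame` of newly closed events (as [detect_events()]).
#' @export
extend_events <- function(state, new_samples) {
  stopifnot(inherits(state, "segment_state"))
  state$samples <- c(state$samples, as.numeric(new_samples))
  ev <- detect_events(state$samples, state$params)
  m <- nrow(ev)
  if (m <= 2L) return(ev[0L, ])
  # Guard band: new samples can only create t-stat peaks within w_long of
  # the stream end, but a cascade of non-maximum-suppression flips can walk
  # a few w_short radii further left, so hold back a generous margin.
  hold <- state$params$w_long + 8L * state$params$w_short
  stable <- which(ev$end_sample <= length(state$samples) - hold)
  stable <- stable[stable <= m - 2L]
  last_ok <- if (length(stable)) max(stable) else 0L
  if (last_ok <= state$emitted) return(ev[0L, ])
  out <- ev[(state$emitted + 1L):last_ok, , drop = FALSE]
  state$emitted <- last_ok
  out
}

#' Flush the remaining events of a streaming segmenter
#'
#' @param state A [segment_state()].
#' @return `data.frame` of all not-yet-emitted events.
#' @export
finalize_events <- function(state) {
  stopifnot(inherits(state, "segment_state"))
  ev <- detect_events(state$samples, state$params)
  if (state$emitted >= nrow(ev)) return(ev[0L, ])
  out <- ev[(state$emitted + 1L):nrow(ev), , drop = FALSE]
  state$emitted <- nrow(ev)
  out
}
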