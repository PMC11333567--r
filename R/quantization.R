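#' Adaptive quantization parameters
#'
#' Normalized event levels are quantized into the integer range `[0, n]`
#' with a bifurcated scheme: a high-resolution *fine range*
#' `[f_min, f_max]` (where most normalized values fall) gets a fraction
#' `f_r` of the resolution, and the flanking *coarse ranges* share the
#' rest at low resolution `c_r = (1 - f_r) * 0.5`.  `c_r` is always
#' derived, never user-set.
#'
#' @param n Top of the quantized range `[0, n]`.
#' @param f_r Fine-range resolution fraction, in (0, 1).
#' @param f_min,f_max Fine-range boundaries in normalized (z-score) units.
#' @return A `quant_params` list; `bits_per_value = ceil(log2(n + 1))`.
#' @export
quant_params <- function(n = 15L, f_r = 0.8, f_min = -2, f_max = 2) {
  stopifnot(n >= 1, f_r > 0, f_r < 1, f_min < f_max)
  structure(list(n = as.integer(n), f_r = f_r, f_min = f_min, f_max = f_max,
                 c_r = (1 - f_r) * 0.5,
                 bits_per_value = as.integer(ceiling(log2(n + 1)))),
            class = "quant_params")
}

#' Quantize normalized signal levels
#'
#' Piecewise map from a normalized level `s` to an integer bucket:
#' \deqn{q(s) = \lfloor n f_r (s - f_{min})/(f_{max} - f_{min}) \rfloor}
#' inside the fine range, \eqn{\lfloor n (f_r + c_r s) \rfloor} below it
#' and \eqn{\lfloor n (f_r + c_r + c_r s) \rfloor} above it.  The raw
#' piecewise value can leave `[0, n]` for large `|s|` (and the coarse
#' branches can overlap the fine branch's output range); results are
#' clamped into `[0, n]`.  Vectorized over `s`.
#'
#' @param s Numeric vector of normalized levels (finite).
#' @param p A [quant_params()] object.
#' @return Integer vector in `[0, n]`.
#' @export
quantize <- function(s, p = quant_params()) {
  n <- p$n
  q <- numeric(length(s))
  fine <- s >= p$f_min & s <= p$f_max
  lo <- s < p$f_min
  hi <- s > p$f_max
  q[fine] <- floor(n * p$f_r * (s[fine] - p$f_min) / (p$f_max - p$f_min))
  q[lo] <- floor(n * (p$f_r + p$c_r * s[lo]))
  q[hi] <- floor(n * (p$f_r + p$c_r + p$c_r * s[hi]))
  as.integer(pmin(pmax(q, 0), n))
}

#' Seed-packing parameters
#'
#' A seed is built from `e` consecutive quantized event levels packed
#' big-endian into one integer (first event in the most significant bits),
#' optionally scrambled by an invertible affine mixer so that hash order is
#' decorrelated from level order (which matters for minimizer sketching).
#' Hashes are held in doubles, exact up to 2^53, so
#' `e * bits_per_value <= 52` is required.
#'
#' @param e Events packed per seed.
#' @param bits_per_value Bits per quantized value (from [quant_params()]).
#' @param mix Apply the invertible mixer (default `TRUE`).
#' @return A `seed_params` list.
#' @export
seed_params <- function(e = 5L, bits_per_value = quant_params()$bits_per_value,
                        mix = TRUE) {
  stopifnot(e >= 1, bits_per_value >= 1, e * bits_per_value <= 52)
  structure(list(e = as.integer(e), bits_per_value = as.integer(bits_per_value),
                 mix = isTRUE(mix), bits_total = as.integer(e * bits_per_value)),
            class = "seed_params")
}

# Invertible affine hash mixer modulo 2^bits: h -> (A*h + C) mod 2^bits,
# A odd (< 2^26 so products stay exact in doubles via a 26-bit split).
MIX_A <- 41943611   # odd
MIX_C <- 2654435769
mix_hash <- function(h, bits) {
  m <- 2^bits
  if (bits <= 26) return((MIX_A * h + MIX_C) %% m)
  h1 <- floor(h / 2^26)
  h0 <- h - h1 * 2^26
  t1 <- (MIX_A * h1) %% 2^(bits - 26)
  lo <- (MIX_A * h0 + MIX_C) %% m  # keep partial sums < 2^53 (exact doubles)
  (t1 * 2^26 + lo) %% m
}

#' Pack quantized values into a seed hash
#'
#' @param q_values Integer vector of length `e`, each in
#'   `[0, 2^bits_per_value)`.
#' @param sp A [seed_params()] object.
#' @return A single hash value (numeric, exact integer < 2^52).
#' @export
pack_seed <- function(q_values, sp = seed_params()) {
  if (length(q_values) != sp$e) stop("expected ", sp$e, " quantized values")
  if (any(q_values < 0) || any(q_values >= 2^sp$bits_per_value)) {
    stop("quantized value out of range [0, 2^bits_per_value)")
  }
  h <- 0
  for (q in q_values) h <- h * 2^sp$bits_per_value + q
  if (sp$mix) h <- mix_hash(h, sp$bits_total)
  h
}

#' Seeds from a vector of normalized event levels
#'
#' Quantizes the levels and emits one packed hash per sliding window of
#' `e` consecutive values.  Seed positions are end-anchored: the position
#' is the 0-based index of the window's last event, so an anchor with span
#' `w` covers events `[pos - w + 1, pos]`.
#'
#' @param levels Normalized numeric levels.
#' @param qp,sp [quant_params()] / [seed_params()] objects.
#' @return `data.frame(pos, hash)` with `length(levels) - e + 1` rows
#'   (zero rows when the input is shorter than `e`).
#' @export
seeds_from_events <- function(levels, qp = quant_params(), sp = seed_params()) {
  L <- length(levels)
  if (L < sp$e) return(data.frame(pos = integer(0), hash = numeric(0)))
  q <- quantize(levels, qp)
  nw <- L - sp$e + 1L
  h <- numeric(nw)
  base <- 2^sp$bits_per_value
  for (j in seq_len(sp$e)) h <- h * base + q[j:(nw + j - 1L)]
  if (sp$mix) h <- mix_hash(h, sp$bits_total)
  data.frame(pos = (sp$e - 1L):(L - 1L), hash = h)
}
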