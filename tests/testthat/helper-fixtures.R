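# Shared fixtures, built in code at test time.

fixture_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_pore_model(6)
    cache
  }
})

# Tiny complete model with distinct integer-ish levels, handy for exact maths.
tiny_model <- function(k = 2L) {
  km <- squigglemap:::kmer_strings(k)
  squigglemap:::new_pore_model(k, km,
                               level_mean = seq(80, 120,
                                                length.out = length(km)),
                               level_stdv = rep(2, length(km)))
}

write_model_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(rows, path)
  path
}

# Independent re-statement of the adaptive quantization formula, written
# branch by branch without reusing package internals.
quantize_oracle <- function(s, n, f_r, f_min, f_max) {
  c_r <- (1 - f_r) * 0.5
  raw <- if (s >= f_min && s <= f_max) {
    floor(n * (f_r * (s - f_min) / (f_max - f_min)))
  } else if (s < f_min) {
    floor(n * (f_r + c_r * s))
  } else {
    floor(n * (f_r + c_r + c_r * s))
  }
  min(max(raw, 0), n)
}

# Exhaustive chaining oracle: best score over all colinear anchor
# subsequences under the gap-penalty recurrence, by brute-force recursion.
brute_best_chain <- function(anchors) {
  n <- nrow(anchors)
  gamma <- function(l, w) if (l == 0) 0 else 0.01 * w * abs(l) + 0.5 * log2(abs(l))
  best <- -Inf
  extend <- function(last, score) {
    best <<- max(best, score)
    for (i in seq_len(n)) {
      if (anchors$x[i] > anchors$x[last] && anchors$y[i] > anchors$y[last]) {
        dx <- anchors$x[i] - anchors$x[last]
        dy <- anchors$y[i] - anchors$y[last]
        a <- min(min(dy, dx), anchors$w[i])
        extend(i, score + a - gamma(dy - dx, anchors$w[i]))
      }
    }
  }
  for (i in seq_len(n)) extend(i, anchors$w[i])
  best
}

# Random anchor sets sorted the way chain_anchors expects.
random_anchors <- function(n, span = 6L, coord_max = 60L) {
  a <- data.frame(x = sample.int(coord_max, n, replace = TRUE),
                  y = sample.int(coord_max, n, replace = TRUE),
                  w = span)
  a <- unique(a)
  a[order(a$x, a$y), , drop = FALSE]
}

# Chain stubs for decision/mapq tests.
chain_stub <- function(score, n_anchors = 10L, mapq = NA_integer_) {
  list(anchors = seq_len(n_anchors), score = score, n_anchors = n_anchors,
       ref_start = 0L, ref_end = 10L, query_start = 0L, query_end = 10L,
       mapq = mapq, is_primary = FALSE)
}
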