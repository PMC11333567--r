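#' Chaining parameters
#'
#' Bounds and heuristics for the anchor-chaining dynamic program.
#' `max_gap` limits the distance between successive anchors on both axes,
#' `max_iter` caps how many predecessors are scanned per anchor and
#' `max_skip` stops the scan after that many consecutive non-improving
#' candidates (both are performance heuristics; disable by setting them
#' very large).  Chains scoring below `min_score` or holding fewer than
#' `min_anchors` anchors are dropped.
#'
#' @param max_gap,max_skip,max_iter,min_score,min_anchors See above; all
#'   positive.
#' @return A `chain_params` list.
#' @export
chain_params <- function(max_gap = 2000L, max_skip = 25L, max_iter = 5000L,
                         min_score = 25, min_anchors = 4L) {
  stopifnot(max_gap > 0, max_skip > 0, max_iter > 0, min_score > 0,
            min_anchors > 0)
  structure(list(max_gap = as.integer(max_gap), max_skip = as.integer(max_skip),
                 max_iter = as.integer(max_iter), min_score = min_score,
                 min_anchors = as.integer(min_anchors)),
            class = "chain_params")
}

#' Gap penalty for chaining
#'
#' `gamma_c(l) = 0.01 * w * |l| + 0.5 * log2(|l|)`, with the value at the
#' log singularity pinned to `gamma_c(0) = 0`: a zero gap costs nothing.
#'
#' @param l Gap length (difference of query and reference gaps); any sign.
#' @param w Anchor span.
#' @return Penalty (vectorized over `l`).
#' @export
gap_penalty <- function(l, w) {
  a <- abs(l)
  ifelse(a == 0, 0, 0.01 * w * a + 0.5 * log2(pmax(a, 1)))
}

#' Chain anchors with a gap-penalty dynamic program
#'
#' Anchors are seed matches `(x, y, w)`: reference end, query end and span,
#' all on one strand, sorted by `(x, y)`.  The chain score of anchor `i` is
#' `f(i) = max(max_j {f(j) + alpha(j,i) - beta(j,i)}, w_i)` over admissible
#' predecessors `j` (`x_j < x_i`, `y_j < y_i`, both gaps at most
#' `max_gap`), where `alpha(j,i) = min(min(y_i - y_j, x_i - x_j), w_i)` is
#' the matching-region length and `beta(j,i)` is [gap_penalty()] of
#' `l = (y_i - y_j) - (x_i - x_j)`.  Chains are recovered by backtracking
#' best predecessors from high-scoring anchors; each anchor joins at most
#' one reported chain.
#'
#' @param anchors `data.frame(x, y, w)` sorted by `(x, y)`, single strand.
#' @param cp A [chain_params()] object.
#' @return List of chains sorted by decreasing score; each chain is a list
#'   with `anchors` (row indices into the input), `score`, `n_anchors`,
#'   `ref_start`, `ref_end`, `query_start`, `query_end` (half-open,
#'   event coordinates).
#' @export
chain_anchors <- function(anchors, cp = chain_params()) {
  n <- nrow(anchors)
  if (!n) return(list())
  x <- as.numeric(anchors$x); y <- as.numeric(anchors$y)
  w <- as.numeric(anchors$w)
  if (is.unsorted(x) ||
      any(diff(x) == 0 & diff(y) < 0)) stop("anchors must be sorted by (x, y)")
  f <- w
  pred <- integer(n)
  for (i in seq_len(n)[-1L]) {
    jlo <- findInterval(x[i] - cp$max_gap - 0.5, x) + 1L
    jlo <- max(jlo, i - cp$max_iter)
    if (jlo > i - 1L) next
    js <- (i - 1L):jlo                       # near -> far
    ok <- x[js] < x[i] & y[js] < y[i] & (y[i] - y[js]) <= cp$max_gap
    if (!any(ok)) next
    js <- js[ok]
    dx <- x[i] - x[js]; dy <- y[i] - y[js]
    sc <- f[js] + pmin(pmin(dy, dx), w[i]) - gap_penalty(dy - dx, w[i])
    # max_skip heuristic: stop scanning after a long run of non-improvements
    if (length(sc) > cp$max_skip) {
      run <- cummax(c(-Inf, head(cummax(sc), -1)))
      improving <- sc > run
      bad_run <- cumsum(!improving) - cummax(cumsum(!improving) * improving)
      cut <- which(bad_run > cp$max_skip)
      if (length(cut)) { sc <- sc[seq_len(cut[1L])]; js <- js[seq_len(cut[1L])] }
    }
    best <- which.max(sc)
    if (sc[best] > f[i]) {
      f[i] <- sc[best]
      pred[i] <- js[best]
    }
  }
  backtrack_chains(anchors, f, pred, cp)
}

# Greedy one-to-one assignment of anchors to chains, best score first.
backtrack_chains <- function(anchors, f, pred, cp) {
  n <- length(f)
  used <- logical(n)
  chains <- list()
  for (i in order(-f)) {
    if (used[i]) next
    path <- integer(0)
    j <- i
    base <- 0
    while (j != 0L && !used[j]) {
      path <- c(path, j)
      used[j] <- TRUE
      j <- pred[j]
    }
    if (j != 0L) base <- f[j]   # truncated at an anchor already claimed
    score <- f[i] - base
    path <- rev(path)
    if (length(path) < cp$min_anchors || score < cp$min_score) next
    xs <- anchors$x[path]; ys <- anchors$y[path]; ws <- anchors$w[path]
    chains[[length(chains) + 1L]] <- list(
      anchors = path, score = score, n_anchors = length(path),
      ref_start = xs[1L] - ws[1L] + 1L, ref_end = xs[length(path)] + 1L,
      query_start = ys[1L] - ws[1L] + 1L, query_end = ys[length(path)] + 1L,
      mapq = NA_integer_, is_primary = FALSE)
  }
  chains[order(-vapply(chains, `[[`, 0, "score"))]
}

#' Assign mapping qualities to chains
#'
#' minimap2-style quality for the primary (best-scoring) chain:
#' `mapq = clamp(round(40 * (1 - f2/f1) * min(1, m/10) * ln(f1)), 0, 60)`
#' with `f1`/`f2` the best and second-best chain scores (`f2 = 0` when
#' there is a single chain) and `m` the anchor count of the best chain.
#' Non-primary chains get `mapq = 0`.
#'
#' @param chains List of chains from [chain_anchors()] (sorted by
#'   decreasing score).
#' @return The chains with `mapq` and `is_primary` set.
#' @export
mapping_quality <- function(chains) {
  if (!length(chains)) return(chains)
  f1 <- chains[[1L]]$score
  f2 <- if (length(chains) >= 2L) chains[[2L]]$score else 0
  m <- chains[[1L]]$n_anchors
  raw <- 40 * (1 - f2 / f1) * min(1, m / 10) * log(max(f1, 1))
  chains[[1L]]$mapq <- as.integer(min(60, max(0, round(raw))))
  chains[[1L]]$is_primary <- TRUE
  for (i in seq_along(chains)[-1L]) {
    chains[[i]]$mapq <- 0L
    chains[[i]]$is_primary <- FALSE
  }
  chains
}
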