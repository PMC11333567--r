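#' Compare mapping output against ground truth
#'
#' pafstats-style scoring.  A test mapping is a true positive iff it hits
#' the same target name on the same strand and its target interval
#' overlaps the truth interval within `tol` bases (the intervals may miss
#' each other by up to `tol`).  Test-mapped reads that are wrong or absent
#' from the truth are false positives; truth-mapped reads without a true
#' positive are false negatives (a wrongly mapped read therefore counts
#' once as FP and once as FN).  Reads unmapped in both are ignored.
#'
#' `precision = TP/(TP+FP)` (0 when nothing is mapped),
#' `recall = TP/(TP+FN)`, `f1 = 2PR/(P+R)` (0 when `P+R = 0`).
#'
#' @param test,truth Mapping `data.frame`s ([map_reads()] / [read_paf()]);
#'   truth has at most one row per read id.
#' @param tol Overlap tolerance in bases.
#' @return `list(tp, fp, fn, precision, recall, f1)` of class
#'   `eval_result`.
#' @export
compare_paf <- function(test, truth, tol = 100L) {
  if (anyDuplicated(truth$qname)) stop("truth must have <= 1 row per read")
  if (anyDuplicated(test$qname)) {
    warning("duplicate test rows; keeping the best-mapq row per read")
    test <- test[order(test$qname, -test$mapq), , drop = FALSE]
    test <- test[!duplicated(test$qname), , drop = FALSE]
  }
  truth_mapped <- truth[truth$tname != "*", , drop = FALSE]
  test_mapped <- test[test$tname != "*", , drop = FALSE]
  i <- match(test_mapped$qname, truth_mapped$qname)
  has_truth <- !is.na(i)
  tr <- truth_mapped[i[has_truth], , drop = FALSE]
  tm <- test_mapped[has_truth, , drop = FALSE]
  overlap <- pmin(tm$tend, tr$tend) - pmax(tm$tstart, tr$tstart)
  correct <- tm$tname == tr$tname & tm$strand == tr$strand & overlap > -tol
  tp_reads <- tm$qname[correct]
  tp <- length(tp_reads)
  fp <- nrow(test_mapped) - tp
  fn <- nrow(truth_mapped) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d FN=%d  P=%.4f R=%.4f F1=%.4f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Relative abundance estimate and its distance to truth
#'
#' Estimates per-genome abundance as the fraction of mapped *reads* (not
#' bases) assigned to each genome, then reports the Euclidean distance to
#' the ground-truth fraction vector.
#'
#' @param test Mapping `data.frame`.
#' @param genome_of_contig Named character vector: contig name -> genome
#'   name; every mapped contig must be covered.
#' @param truth_fractions Named numeric vector of true per-genome
#'   fractions (defines the genome set; should sum to 1).
#' @return `list(fractions, euclidean_distance)` of class
#'   `abundance_result`.
#' @export
relative_abundance <- function(test, genome_of_contig, truth_fractions) {
  mapped <- test[test$tname != "*", , drop = FALSE]
  if (!nrow(mapped)) stop("no mapped reads: relative abundance undefined")
  g <- genome_of_contig[mapped$tname]
  if (anyNA(g)) {
    stop("contig(s) without a genome assignment: ",
         paste(unique(mapped$tname[is.na(g)]), collapse = ", "))
  }
  genomes <- names(truth_fractions)
  counts <- table(factor(g, levels = genomes))
  fractions <- as.numeric(counts) / nrow(mapped)
  names(fractions) <- genomes
  structure(list(fractions = fractions,
                 euclidean_distance =
                   sqrt(sum((fractions - truth_fractions)^2))),
            class = "abundance_result")
}
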