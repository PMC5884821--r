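#' Match indel calls against a truth set
#'
#' A call matches a truth record iff same chromosome and svtype, absolute
#' position difference <= `pos_tol` and absolute length difference <=
#' `len_tol * truth length`. Matching is one-to-one and greedy by call
#' position; the nearest unmatched truth record wins, ties to the smaller
#' coordinate. In `genotype_strict` mode a matched pair only counts as a
#' true positive when the genotypes agree (true positives defined as
#' correctly predicted genotypes).
#'
#' @param calls data.frame with `chrom`, `pos1`, `svtype`, `length` (and
#'   `genotype` for strict mode).
#' @param truth data.frame with the same columns (see [read_truth()]).
#' @param pos_tol position tolerance in bp (default 10).
#' @param len_tol length tolerance as a fraction of the truth length
#'   (default 0.1).
#' @param genotype_strict require genotype equality for TP.
#' @return list of class `evaluation_counts`: `TP`, `FP`, `FN`,
#'   `matched_truth` (row indices into `truth`, NA for unmatched calls).
#' @export
match_calls <- function(calls, truth, pos_tol = 10, len_tol = 0.1,
                        genotype_strict = FALSE) {
  if (pos_tol < 0 || len_tol < 0) stop("tolerances must be non-negative")
  nc <- nrow(calls); nt <- nrow(truth)
  taken <- logical(nt)
  matched <- rep.int(NA_integer_, nc)
  tp <- 0L
  if (nc > 0L) {
    ord <- order(calls$chrom, calls$pos1)
    for (i in ord) {
      cand <- which(!taken &
                      truth$chrom == calls$chrom[i] &
                      truth$svtype == calls$svtype[i] &
                      abs(truth$pos1 - calls$pos1[i]) <= pos_tol &
                      abs(truth$length - calls$length[i]) <=
                        len_tol * truth$length)
      if (length(cand) == 0L) next
      d <- abs(truth$pos1[cand] - calls$pos1[i])
      best <- cand[d == min(d)]
      best <- best[which.min(truth$pos1[best])]
      taken[best] <- TRUE
      matched[i] <- best
      gt_ok <- !genotype_strict ||
        identical(calls$genotype[i], truth$genotype[best])
      if (gt_ok) tp <- tp + 1L
    }
  }
  structure(list(TP = tp, FP = nc - sum(!is.na(matched)),
                 FN = nt - sum(taken), matched_truth = matched),
            class = "evaluation_counts")
}

#' Precision, recall and F-measure from TP/FP/FN counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `f_measure = 2 * precision * recall / (precision + recall)`
#' (the harmonic mean). Undefined metrics (zero denominator) are reported
#' as `NaN` with a warning.
#'
#' @param counts list or `evaluation_counts` with `TP`, `FP`, `FN`.
#' @return list of class `indel_metrics`: `precision`, `recall`,
#'   `f_measure` at full precision, plus `rounded` (half-up to 2
#'   decimals).
#' @export
compute_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("precision undefined (TP + FP == 0)"); NaN
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("recall undefined (TP + FN == 0)"); NaN
  }
  f <- if (is.nan(precision) || is.nan(recall) || precision + recall == 0)
    NaN else 2 * precision * recall / (precision + recall)
  structure(list(precision = precision, recall = recall, f_measure = f,
                 rounded = c(precision = round_half_up(precision),
                             recall = round_half_up(recall),
                             f_measure = round_half_up(f))),
            class = "indel_metrics")
}

#' Round half away from zero
#'
#' Matches the rounding convention of the published benchmark tables
#' (0.005 -> 0.01), unlike base R's round-half-even.
#'
#' @param x numeric.
#' @param digits decimal places (default 2).
#' @export
round_half_up <- function(x, digits = 2) {
  ifelse(is.nan(x), NaN, floor(abs(x) * 10^digits + 0.5) / 10^digits * sign(x))
}

#' Published validation counts (HapMap benchmark)
#'
#' TP/FP/FN counts from the Sanger/PacBio validation of four callers on
#' HapMap samples NA18943, NA18948 and NA12878, as printed in the original
#' benchmarking study, together with the printed precision/recall/
#' F-measure for parity checks. Competitor rows are included only as
#' metric arithmetic inputs.
#'
#' @return data.frame: `sample`, `method`, `genotype_calls`, `examined`,
#'   `tp`, `fp`, `fn`, `reported_precision`, `reported_recall`,
#'   `reported_f`.
#' @export
validation_counts <- function() {
  path <- system.file("extdata", "validation_counts.tsv",
                      package = "clipindel", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Score calls against truth and summarise
#'
#' @inheritParams match_calls
#' @param size_bin bin width for the per-size recall table (default 100).
#' @return list: `counts` (`evaluation_counts`), `metrics`
#'   (`indel_metrics`), `per_size` (data.frame `size`, `n_truth`,
#'   `n_recovered`, `recall`).
#' @export
evaluate_calls <- function(calls, truth, pos_tol = 10, len_tol = 0.1,
                           genotype_strict = FALSE, size_bin = 100) {
  counts <- match_calls(calls, truth, pos_tol, len_tol, genotype_strict)
  metrics <- suppressWarnings(compute_metrics(counts))
  bins <- size_bin * ceiling(truth$length / size_bin)
  rec <- tabulate(factor(bins[unique(stats::na.omit(counts$matched_truth))],
                         levels = sort(unique(bins))),
                  nbins = length(unique(bins)))
  tot <- as.integer(table(factor(bins, levels = sort(unique(bins)))))
  per_size <- data.frame(size = sort(unique(bins)), n_truth = tot,
                         n_recovered = rec, recall = rec / tot)
  list(counts = counts, metrics = metrics, per_size = per_size)
}
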