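#' Classify reads for indel evidence
#'
#' Reads are classified into `HQ_SOFTCLIPPED` (mapped, not duplicate,
#' mapping quality > 20, and at least one soft-clip segment of length > 5
#' whose mean base quality > 20), `UNMAPPED_WITH_MATE` (read unmapped,
#' mate mapped), `DISCARDED` (duplicates; unmapped with unmapped mate) or
#' `MAPPED` (everything else). All three quality thresholds are strict
#' inequalities.
#'
#' @param reads data.frame as returned by [read_alignments()].
#' @param min_mapq strict lower bound on mapping quality (default 20).
#' @param min_clip_len strict lower bound on soft-clip length (default 5).
#' @param min_clip_meanq strict lower bound on the arithmetic mean Phred
#'   quality of the clipped bases (default 20).
#' @param use_duplicates keep duplicate-marked reads (default FALSE).
#' @return character vector, one class per read.
#' @export
classify_reads <- function(reads, min_mapq = 20, min_clip_len = 5,
                           min_clip_meanq = 20, use_duplicates = FALSE) {
  n <- nrow(reads)
  cls <- rep.int("MAPPED", n)
  dup <- reads$is_dup & !use_duplicates
  cls[dup] <- "DISCARDED"
  cls[reads$is_unmapped & reads$mate_unmapped] <- "DISCARDED"
  cls[!dup & reads$is_unmapped & !reads$mate_unmapped] <- "UNMAPPED_WITH_MATE"
  cand <- which(!dup & !reads$is_unmapped & reads$mapq > min_mapq &
                grepl("S", reads$cigar, fixed = TRUE))
  if (length(cand)) {
    cl <- .clip_lens(reads$cigar[cand])
    ok <- vapply(seq_along(cand), function(k) {
      i <- cand[k]
      q <- reads$qual[i]
      rl <- nchar(reads$seq[i])
      pass <- FALSE
      if (cl$lead[k] > min_clip_len &&
          .mean_phred(substr(q, 1L, cl$lead[k])) > min_clip_meanq)
        pass <- TRUE
      if (!pass && cl$trail[k] > min_clip_len &&
          .mean_phred(substr(q, rl - cl$trail[k] + 1L, rl)) > min_clip_meanq)
        pass <- TRUE
      pass
    }, logical(1))
    cls[cand[ok]] <- "HQ_SOFTCLIPPED"
  }
  cls
}

#' @rdname classify_reads
#' @param read single-row data.frame.
#' @export
classify_read <- function(read, ...) classify_reads(read, ...)[1]

.mean_phred <- function(qual) mean(utf8ToInt(qual)) - 33

#' Extract clipped fragments from high-quality soft-clipped reads
#'
#' Each passing soft-clip segment yields one fragment. A trailing clip
#' (`...xM yS`) gives orientation `FWD` with `breakpoint0 = pos0 +`
#' reference-consumed length of the aligned part; a leading clip
#' (`yS xM...`) gives orientation `BWD` with `breakpoint0 = pos0`. Clip
#' segments failing the length/quality filters are dropped individually; a
#' read clipped on both ends can yield two fragments.
#'
#' @inheritParams classify_reads
#' @param reads data.frame of reads; rows not classified `HQ_SOFTCLIPPED`
#'   are an error (call on the classified subset).
#' @return data.frame of fragments: `chrom`, `breakpoint0`, `orientation`
#'   (`FWD`/`BWD`), `seq`, `qual`, `mean_qual`, `qname`, `mapq`.
#' @export
extract_clips <- function(reads, min_mapq = 20, min_clip_len = 5,
                          min_clip_meanq = 20) {
  cls <- classify_reads(reads, min_mapq, min_clip_len, min_clip_meanq)
  if (any(cls != "HQ_SOFTCLIPPED"))
    stop("extract_clips expects only HQ_SOFTCLIPPED reads")
  if (nrow(reads) == 0L) return(.empty_frags())
  cl <- .clip_lens(reads$cigar)
  span <- cigar_ref_span(reads$cigar)
  out <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    rl <- nchar(reads$seq[i])
    rows <- list()
    if (cl$lead[i] > min_clip_len) {
      q <- substr(reads$qual[i], 1L, cl$lead[i])
      if (.mean_phred(q) > min_clip_meanq)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = reads$chrom[i], breakpoint0 = reads$pos0[i],
          orientation = "BWD",
          seq = substr(reads$seq[i], 1L, cl$lead[i]), qual = q,
          mean_qual = .mean_phred(q), qname = reads$qname[i],
          mapq = reads$mapq[i], stringsAsFactors = FALSE)
    }
    if (cl$trail[i] > min_clip_len) {
      q <- substr(reads$qual[i], rl - cl$trail[i] + 1L, rl)
      if (.mean_phred(q) > min_clip_meanq)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = reads$chrom[i], breakpoint0 = reads$pos0[i] + span[i],
          orientation = "FWD",
          seq = substr(reads$seq[i], rl - cl$trail[i] + 1L, rl), qual = q,
          mean_qual = .mean_phred(q), qname = reads$qname[i],
          mapq = reads$mapq[i], stringsAsFactors = FALSE)
    }
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) .empty_frags() else res
}

.empty_frags <- function() {
  data.frame(chrom = character(), breakpoint0 = integer(),
             orientation = character(), seq = character(),
             qual = character(), mean_qual = numeric(),
             qname = character(), mapq = integer(),
             stringsAsFactors = FALSE)
}

#' Estimate breakpoints for unmapped reads with mapped mates
#'
#' The mapped mate anchors the pair: a forward-strand anchor places the
#' unmapped read downstream (`est_breakpoint0 = anchor_pos0 + insert_mean -
#' read_length`, orientation `FWD`); a reverse-strand anchor places it
#' upstream (`est_breakpoint0 = anchor_pos0 - insert_mean + read_length +
#' anchor_ref_span`, orientation `BWD`). The stored sequence is put on the
#' reference forward strand (reverse-complemented when the anchor is
#' forward, since the unmapped mate was then sequenced from the reverse
#' strand). Negative estimates are clamped to 0 with a warning.
#'
#' @param reads data.frame rows classified `UNMAPPED_WITH_MATE`. The
#'   anchor strand is taken from the mate-reverse flag (0x20).
#' @param insert_mean,insert_sd outer-distance mean/sd of the library
#'   (defaults 500/50).
#' @param anchor_ref_span reference span of the anchor alignment; defaults
#'   to the read length (mate CIGAR is not in the unmapped record).
#' @return data.frame: `chrom`, `est_breakpoint0`, `est_orientation`,
#'   `seq` (forward strand), `qual`, `qname`, `anchor_pos0`.
#' @export
estimate_unmapped_breakpoints <- function(reads, insert_mean = 500,
                                          insert_sd = 50,
                                          anchor_ref_span = NULL) {
  if (nrow(reads) == 0L)
    return(data.frame(chrom = character(), est_breakpoint0 = integer(),
                      est_orientation = character(), seq = character(),
                      qual = character(), qname = character(),
                      anchor_pos0 = integer(), stringsAsFactors = FALSE))
  if (any(reads$mate_unmapped)) stop("mate unmapped: no anchor to estimate from")
  rl <- nchar(reads$seq)
  span <- if (is.null(anchor_ref_span)) rl else rep_len(anchor_ref_span, nrow(reads))
  anchor_rev <- bitwAnd(reads$flag, 32L) > 0L
  # SAM places an unmapped read at its mate's coordinates
  anchor_pos0 <- ifelse(is.na(reads$mate_pos0) | reads$mate_pos0 < 0,
                        reads$pos0, reads$mate_pos0)
  est <- ifelse(anchor_rev,
                anchor_pos0 - insert_mean + rl + span,
                anchor_pos0 + insert_mean - rl)
  if (any(est < 0)) {
    warning("negative estimated breakpoint(s) clamped to 0")
    est[est < 0] <- 0
  }
  orient <- ifelse(anchor_rev, "BWD", "FWD")
  seqs <- reads$seq
  quals <- reads$qual
  flip <- !anchor_rev  # forward anchor -> unmapped mate sequenced reverse
  if (any(flip)) {
    seqs[flip] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[flip])))
    quals[flip] <- vapply(quals[flip], function(q)
      intToUtf8(rev(utf8ToInt(q))), character(1), USE.NAMES = FALSE)
  }
  chrom <- ifelse(is.na(reads$chrom), reads$mate_chrom, reads$chrom)
  data.frame(chrom = chrom, est_breakpoint0 = as.integer(round(est)),
             est_orientation = orient, seq = seqs, qual = quals,
             qname = reads$qname, anchor_pos0 = as.integer(anchor_pos0),
             stringsAsFactors = FALSE)
}
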