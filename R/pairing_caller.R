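#' Scoring parameters for the glocal aligner
#'
#' Mismatch and gap-open penalties dominate the match reward so that long
#' indels open a single cheap gap instead of accumulating mismatches; a
#' gap-extension of 0 makes a 10 kb deletion cost one gap-open, which is
#' what makes intermediate-size events detectable at all.
#'
#' @param match match score (default +5).
#' @param mismatch mismatch penalty, negative (default -20).
#' @param gap_open gap-open penalty, non-positive (default -20).
#' @param gap_extend per-base gap-extension penalty, non-positive
#'   (default 0).
#' @return list of class `glocal_params`.
#' @export
glocal_params <- function(match = 5L, mismatch = -20L, gap_open = -20L,
                          gap_extend = 0L) {
  if (mismatch >= 0) stop("mismatch must be negative")
  if (gap_open > 0 || gap_extend > 0)
    stop("gap penalties must be non-positive")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "glocal_params")
}

#' Global-in-query, local-in-target ("glocal") alignment
#'
#' Affine-gap dynamic programming: the entire query must align; leading
#' and trailing target sequence is free, so the best-scoring target window
#' is found. A gap run of length k costs `gap_open + k * gap_extend`.
#' Traceback ties prefer diagonal, then up (gap in target), then left
#' (gap in query); among equal-scoring windows the leftmost is returned.
#'
#' @param query,target nonempty nucleotide strings.
#' @param params [glocal_params()].
#' @return list: `score`, `q_aln`, `t_aln` (gapped strings of the covered
#'   region), `t_start`/`t_end` (0-based half-open target window).
#' @export
glocal_align <- function(query, target, params = glocal_params()) {
  if (!nzchar(query) || !nzchar(target)) stop("empty sequence")
  r <- align_engine_cpp(toupper(query), toupper(target),
                        params$match, params$mismatch,
                        params$gap_open, params$gap_extend,
                        FALSE, TRUE)
  r[c("score", "q_aln", "t_aln", "t_start", "t_end")]
}

# dovetail: suffix of `first` aligned to prefix of `second` (free `first`
# prefix, free `second` suffix); used by join_pair
overlap_align <- function(first, second, params = glocal_params()) {
  if (!nzchar(first) || !nzchar(second)) stop("empty sequence")
  align_engine_cpp(toupper(first), toupper(second),
                   params$match, params$mismatch,
                   params$gap_open, params$gap_extend,
                   TRUE, FALSE)
}

# start-anchored: both sequences share their first position (no free
# leading border), target tail free; used for breakpoint-anchored clips
# in the star MSA
anchor_align <- function(query, target, params = glocal_params()) {
  if (!nzchar(query) || !nzchar(target)) stop("empty sequence")
  align_engine_cpp(toupper(query), toupper(target),
                   params$match, params$mismatch,
                   params$gap_open, params$gap_extend,
                   FALSE, FALSE)
}

#' Pair forward and backward consensus fragments
#'
#' Candidate pairs are (FWD f, BWD b) with `-overlap_slack <=
#' b$breakpoint0 - f$breakpoint0 <= max_span`: deletions separate the two
#' breakpoints by up to the maximum deletion size, insertions leave them
#' near-coincident (the slack absorbs clustering jitter). A fragment may
#' appear in several candidate pairs; [detect_indels()] later keeps a
#' best-scoring disjoint set.
#'
#' @param fwd,bwd lists of `consensus_fragment`s on one chromosome.
#' @param max_span maximum breakpoint separation (default 10000, the
#'   maximum deletion size).
#' @param overlap_slack allowed negative separation (default 200).
#' @return list of `list(fwd = , bwd = )` pairs.
#' @export
pair_clusters <- function(fwd, bwd, max_span = 10000L, overlap_slack = 200L) {
  out <- list()
  for (f in fwd) for (b in bwd) {
    if (!identical(f$chrom, b$chrom)) stop("fragments from different chromosomes")
    d <- b$breakpoint0 - f$breakpoint0
    if (d >= -overlap_slack && d <= max_span)
      out[[length(out) + 1L]] <- list(fwd = f, bwd = b)
  }
  out
}

#' Join a FWD/BWD consensus-fragment pair into a consensus sequence
#'
#' Each fragment is extended with its anchoring reference context (the
#' mapped side of its cluster): `E_f = ref[f$bp - ctx, f$bp) + f$seq`,
#' `E_b = b$seq + ref[b$bp, b$bp + ctx)`. Both are windows on the variant
#' haplotype around the event, so one's suffix overlaps the other's
#' prefix; the dovetail alignment is tried in both orders and the better
#' score kept. The pair joins when the overlap spans at least
#' `min_overlap` columns at `min_identity` identity; the merged sequence
#' takes the first sequence's bases through the overlap.
#'
#' @param f,b `consensus_fragment`s (FWD, BWD).
#' @param ref FASTA path or `DNAStringSet`.
#' @param params [glocal_params()].
#' @param ctx anchoring reference context in bp (default 150, one read
#'   length).
#' @param min_overlap minimum overlap columns (default 20).
#' @param min_identity minimum overlap identity (default 0.9).
#' @return list of class `consensus_sequence` (`chrom`, `seq`, `fwd`,
#'   `bwd`, `depth`, `score`, `junction_offset`) or `NULL`.
#' @export
join_pair <- function(f, b, ref, params = glocal_params(), ctx = 150L,
                      min_overlap = 20L, min_identity = 0.9) {
  ref <- load_reference(ref)
  clen <- length(ref[[f$chrom]])
  up0 <- max(0L, f$breakpoint0 - ctx)
  ef <- paste0(ref_slice(ref, f$chrom, up0, f$breakpoint0), f$seq)
  dn1 <- min(clen, b$breakpoint0 + ctx)
  eb <- paste0(b$seq, ref_slice(ref, b$chrom, b$breakpoint0, dn1))
  cand <- list(list(first = eb, second = ef, order = "bf"),
               list(first = ef, second = eb, order = "fb"))
  best <- NULL
  for (cc in cand) {
    al <- overlap_align(cc$first, cc$second, params)
    if (is.null(best) || al$score > best$al$score)
      best <- list(al = al, first = cc$first, second = cc$second,
                   order = cc$order)
  }
  al <- best$al
  qa <- .chars(al$q_aln); ta <- .chars(al$t_aln)
  aligned <- qa != "-" & ta != "-"  # identity over aligned columns: the
  ov <- sum(aligned)                # zero-cost long gaps the scoring allows
  if (ov < min_overlap) return(NULL)  # must not dilute it
  ident <- sum(qa[aligned] == ta[aligned]) / ov
  if (ident < min_identity) return(NULL)
  merged <- paste0(best$first, substr(best$second, al$t_end + 1L,
                                      nchar(best$second)))
  junction <- if (best$order == "bf") nchar(b$seq) else f$breakpoint0 - up0
  structure(list(chrom = f$chrom, seq = merged, fwd = f, bwd = b,
                 depth = f$n_reads + b$n_reads, score = al$score,
                 overlap = ov, identity = ident,
                 junction_offset = junction),
            class = "consensus_sequence")
}

#' Extract indel calls from a consensus sequence
#'
#' The consensus sequence (query, global) is aligned to the reference
#' window (target, local). Each run of query-gap columns of total length L
#' is a candidate deletion; each run of target-gap columns a candidate
#' insertion. Candidates survive iff `min_size <= L <= max_size` and the
#' supporting depth is at least `min_depth`.
#'
#' @param cs `consensus_sequence` from [join_pair()] (any list with
#'   `chrom`, `seq`, `depth` works).
#' @param window `reference_window` from [fetch_reference_window()].
#' @param params [glocal_params()].
#' @param min_size,max_size event size bounds in bp (defaults 50 / 10000).
#' @param min_depth minimum supporting read depth (default 10, inclusive).
#' @param n_span reference-spanning read count at the breakpoint for
#'   genotyping (default 0, i.e. hom in the absence of spanning evidence).
#' @param flank expected window flank; a differing window triggers a
#'   warning, not an error.
#' @param hom_vaf hom genotype threshold (see [genotype_call()]).
#' @return data.frame of calls: `chrom`, `pos1` (1-based base before the
#'   event), `svtype`, `length`, `alt_seq`, `ref_span`, `depth`,
#'   `genotype`, `breakpoint_fwd`, `breakpoint_bwd`.
#' @export
call_indels <- function(cs, window, params = glocal_params(),
                        min_size = 50L, max_size = 10000L, min_depth = 10L,
                        n_span = 0L, flank = 5000L, hom_vaf = 0.8) {
  if (!is.null(window$flank) && window$flank != flank)
    warning("window flank (", window$flank, ") differs from configured (",
            flank, ")")
  al <- glocal_align(cs$seq, window$seq, params)
  qa <- .chars(al$q_aln); ta <- .chars(al$t_aln)
  refpos <- window$start0 + al$t_start  # 0-based ref cursor
  calls <- list()
  i <- 1L
  while (i <= length(qa)) {
    if (qa[i] == "-") {            # deletion: target consumed, no query
      j <- i
      while (j < length(qa) && qa[j + 1L] == "-") j <- j + 1L
      L <- j - i + 1L
      if (L >= min_size && L <= max_size && cs$depth >= min_depth) {
        gt <- genotype_call(cs$depth, n_span, hom_vaf)
        calls[[length(calls) + 1L]] <- data.frame(
          chrom = cs$chrom, pos1 = refpos, svtype = "DEL", length = L,
          alt_seq = "", ref_span = paste(ta[i:j], collapse = ""),
          depth = cs$depth, genotype = gt,
          breakpoint_fwd = if (!is.null(cs$fwd)) cs$fwd$breakpoint0 else refpos,
          breakpoint_bwd = if (!is.null(cs$bwd)) cs$bwd$breakpoint0 else refpos + L,
          stringsAsFactors = FALSE)
      }
      refpos <- refpos + L
      i <- j + 1L
    } else if (ta[i] == "-") {     # insertion: query consumed, no target
      j <- i
      while (j < length(qa) && ta[j + 1L] == "-") j <- j + 1L
      L <- j - i + 1L
      if (L >= min_size && L <= max_size && cs$depth >= min_depth) {
        gt <- genotype_call(cs$depth, n_span, hom_vaf)
        calls[[length(calls) + 1L]] <- data.frame(
          chrom = cs$chrom, pos1 = refpos, svtype = "INS", length = L,
          alt_seq = paste(qa[i:j], collapse = ""), ref_span = "",
          depth = cs$depth, genotype = gt,
          breakpoint_fwd = if (!is.null(cs$fwd)) cs$fwd$breakpoint0 else refpos,
          breakpoint_bwd = if (!is.null(cs$bwd)) cs$bwd$breakpoint0 else refpos,
          stringsAsFactors = FALSE)
      }
      i <- j + 1L
    } else {
      refpos <- refpos + 1L
      i <- i + 1L
    }
  }
  if (length(calls) == 0L) return(.empty_calls())
  do.call(rbind, calls)
}

.empty_calls <- function() {
  data.frame(chrom = character(), pos1 = integer(), svtype = character(),
             length = integer(), alt_seq = character(),
             ref_span = character(), depth = integer(),
             genotype = character(), breakpoint_fwd = integer(),
             breakpoint_bwd = integer(), stringsAsFactors = FALSE)
}

#' Genotype a call from variant and reference-spanning read counts
#'
#' Variant allele fraction `v = n_variant / (n_variant + n_spanning)`;
#' `hom` iff `v >= hom_vaf` (default 0.8, boundary inclusive), else
#' `het`. Spanning reads are mapped reads crossing the breakpoint with at
#' least 20 bp on both sides and no clip at it (see
#' [count_spanning_reads()]).
#'
#' @param n_variant_support variant-supporting read count (>= 1).
#' @param n_reference_spanning reference-spanning read count.
#' @param hom_vaf hom threshold on the variant allele fraction.
#' @return `"het"` or `"hom"`.
#' @export
genotype_call <- function(n_variant_support, n_reference_spanning,
                          hom_vaf = 0.8) {
  if (n_variant_support + n_reference_spanning == 0)
    stop("no reads to genotype from")
  if (n_variant_support < 1) stop("n_variant_support must be >= 1")
  v <- n_variant_support / (n_variant_support + n_reference_spanning)
  if (v >= hom_vaf) "hom" else "het"
}

#' Count reference-spanning reads at a breakpoint
#'
#' Mapped, non-duplicate reads whose aligned span covers
#' `[bp0 - margin, bp0 + margin)` without a clip boundary within 3 bp of
#' the breakpoint.
#'
#' @param reads alignment data.frame ([read_alignments()]).
#' @param chrom,bp0 breakpoint (0-based).
#' @param margin required anchored bases on each side (default 20).
#' @return integer count.
#' @export
count_spanning_reads <- function(reads, chrom, bp0, margin = 20L) {
  r <- reads[!reads$is_unmapped & !reads$is_dup & reads$chrom == chrom, ,
             drop = FALSE]
  if (nrow(r) == 0L) return(0L)
  span <- cigar_ref_span(r$cigar)
  covers <- r$pos0 <= bp0 - margin & r$pos0 + span >= bp0 + margin
  if (!any(covers)) return(0L)
  r <- r[covers, , drop = FALSE]
  cl <- .clip_lens(r$cigar)
  span <- span[covers]
  clip_at_bp <- (cl$lead > 0L & abs(r$pos0 - bp0) <= 3L) |
                (cl$trail > 0L & abs(r$pos0 + span - bp0) <= 3L)
  sum(!clip_at_bp)
}
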