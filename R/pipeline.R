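#' Caller configuration
#'
#' All tunable knobs of the detection pipeline in one list. Defaults are
#' the published operating point: strict mapping-quality/clip filters
#' (>20/>5/>20), 3 bp breakpoint clustering, a +/- 5,000 bp reference
#' window, event sizes 50-10,000 bp, and a supporting depth of at least
#' 10 reads.
#'
#' @param min_mapq,min_clip_len,min_clip_meanq strict read filters.
#' @param cluster_tol breakpoint clustering tolerance (bp).
#' @param linkage `"chain"` or `"span"` (see [cluster_fragments()]).
#' @param insert_mean,insert_sd paired-end outer-distance model.
#' @param rescue_tol attachment tolerance for rescued unmapped reads;
#'   defaults to `insert_sd`.
#' @param msa_mode,mafft_bin consensus MSA backend (see [msa()]).
#' @param k,min_kmer_count greedy assembly parameters.
#' @param min_members minimum cluster members for a consensus.
#' @param params [glocal_params()].
#' @param ctx anchoring reference context for [join_pair()] (bp).
#' @param min_join_overlap,min_join_identity join acceptance thresholds.
#' @param max_span,overlap_slack candidate pairing bounds (bp).
#' @param flank reference-window flank (bp).
#' @param min_size,max_size,min_depth call filters.
#' @param hom_vaf hom genotype threshold on variant allele fraction.
#' @param use_duplicates keep duplicate-marked reads.
#' @return named list of class `caller_config`.
#' @export
caller_config <- function(min_mapq = 20, min_clip_len = 5,
                          min_clip_meanq = 20, cluster_tol = 3L,
                          linkage = "chain", insert_mean = 500,
                          insert_sd = 50, rescue_tol = insert_sd,
                          msa_mode = "internal", mafft_bin = "mafft",
                          k = 25L, min_kmer_count = 2L, min_members = 2L,
                          params = glocal_params(), ctx = 150L,
                          min_join_overlap = 20L, min_join_identity = 0.9,
                          max_span = 10000L, overlap_slack = 200L,
                          flank = 5000L, min_size = 50L, max_size = 10000L,
                          min_depth = 10L, hom_vaf = 0.8,
                          use_duplicates = FALSE) {
  structure(as.list(environment()), class = "caller_config")
}

#' Detect intermediate-size indels from mapped reads
#'
#' Runs the full pipeline: classification, clip extraction, breakpoint
#' clustering, unmapped-mate rescue, per-cluster consensus, greedy k-mer
#' assembly of unattached unmapped reads (a contig replaces a consensus
#' fragment that is a >=90%-identity substring of it), forward/backward
#' pairing, dovetail joining, glocal comparison against the reference
#' window, and size/depth/genotype filtering.
#'
#' @param alignments SAM/BAM path or a data.frame from
#'   [read_alignments()].
#' @param ref FASTA path or `DNAStringSet`.
#' @param config [caller_config()].
#' @param region optional region for the alignment reader.
#' @return data.frame of calls (see [call_indels()]), sorted by
#'   (chrom, pos1).
#' @export
detect_indels <- function(alignments, ref, config = caller_config(),
                          region = NULL) {
  reads <- if (is.character(alignments))
    read_alignments(alignments, region) else alignments
  ref <- load_reference(ref)
  cfg <- config
  all_calls <- list()
  chroms <- unique(reads$chrom[!reads$is_unmapped & !is.na(reads$chrom)])
  for (chrom in chroms) {
    on_chr <- (!reads$is_unmapped & reads$chrom == chrom) |
      (reads$is_unmapped & !reads$mate_unmapped &
         (!is.na(reads$mate_chrom) & reads$mate_chrom == chrom |
            !is.na(reads$chrom) & reads$chrom == chrom))
    r <- reads[on_chr & !is.na(on_chr), , drop = FALSE]
    cls <- classify_reads(r, cfg$min_mapq, cfg$min_clip_len,
                          cfg$min_clip_meanq, cfg$use_duplicates)
    frags <- extract_clips(r[cls == "HQ_SOFTCLIPPED", , drop = FALSE],
                           cfg$min_mapq, cfg$min_clip_len,
                           cfg$min_clip_meanq)
    um <- r[cls == "UNMAPPED_WITH_MATE", , drop = FALSE]
    rescued <- estimate_unmapped_breakpoints(um, cfg$insert_mean,
                                             cfg$insert_sd)
    clusters <- cluster_fragments(frags, cfg$cluster_tol, cfg$linkage)
    att <- attach_unmapped(clusters, rescued, cfg$rescue_tol)
    cons <- Filter(Negate(is.null),
                   lapply(att$clusters, build_consensus,
                          min_members = cfg$min_members,
                          mode = cfg$msa_mode, mafft_bin = cfg$mafft_bin))
    contigs <- assemble_unmapped(att$pooled$seq, cfg$k, cfg$min_kmer_count)
    if (length(contigs))
      cons <- lapply(cons, .maybe_replace_with_contig, contigs = contigs,
                     params = cfg$params)
    fwd <- Filter(function(x) x$orientation == "FWD", cons)
    bwd <- Filter(function(x) x$orientation == "BWD", cons)
    for (i in seq_along(fwd)) fwd[[i]]$id <- i
    for (i in seq_along(bwd)) bwd[[i]]$id <- i
    pairs <- pair_clusters(fwd, bwd, cfg$max_span, cfg$overlap_slack)
    joined <- Filter(Negate(is.null),
                     lapply(pairs, function(p)
                       join_pair(p$fwd, p$bwd, ref, cfg$params, cfg$ctx,
                                 cfg$min_join_overlap,
                                 cfg$min_join_identity)))
    if (length(joined) == 0L) next
    # greedy best-scoring disjoint set: descending join score, ties leftmost
    sc <- vapply(joined, `[[`, numeric(1), "score")
    lt <- vapply(joined, function(j) j$fwd$breakpoint0, integer(1))
    joined <- joined[order(-sc, lt)]
    used_f <- used_b <- logical(0)
    chosen <- list()
    for (j in joined) {
      fu <- paste0("f", j$fwd$id); bu <- paste0("b", j$bwd$id)
      if (fu %in% names(used_f) || bu %in% names(used_b)) next
      used_f[fu] <- TRUE; used_b[bu] <- TRUE
      chosen[[length(chosen) + 1L]] <- j
    }
    for (cs in chosen) {
      win <- fetch_reference_window(ref, chrom, cs$fwd$breakpoint0,
                                    cfg$flank)
      n_span <- count_spanning_reads(r, chrom, cs$fwd$breakpoint0)
      calls <- call_indels(cs, win, cfg$params, cfg$min_size, cfg$max_size,
                           cfg$min_depth, n_span = n_span,
                           flank = cfg$flank, hom_vaf = cfg$hom_vaf)
      if (nrow(calls)) all_calls[[length(all_calls) + 1L]] <- calls
    }
  }
  if (length(all_calls) == 0L) return(.empty_calls())
  calls <- do.call(rbind, all_calls)
  # dedupe identical events from overlapping consensus pairs
  key <- paste(calls$chrom, calls$pos1, calls$svtype, calls$length)
  calls <- calls[order(key, -calls$depth), , drop = FALSE]
  calls <- calls[!duplicated(paste(calls$chrom, calls$pos1, calls$svtype,
                                   calls$length)), , drop = FALSE]
  calls <- calls[order(calls$chrom, calls$pos1), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

# a contig replaces a consensus fragment when the fragment aligns into the
# contig (either strand) at >=90% identity; the replacement keeps the
# fragment's anchored end and extends in its clip direction
.maybe_replace_with_contig <- function(frag, contigs, params,
                                       min_identity = 0.9) {
  for (ct in contigs) {
    for (cseq in c(ct$seq, as.character(Biostrings::reverseComplement(
           Biostrings::DNAString(ct$seq))))) {
      if (nchar(cseq) <= nchar(frag$seq)) next
      al <- tryCatch(glocal_align(frag$seq, cseq, params),
                     error = function(e) NULL)
      if (is.null(al)) next
      qa <- .chars(al$q_aln); ta <- .chars(al$t_aln)
      ident <- sum(qa == ta & qa != "-") / nchar(frag$seq)
      if (ident < min_identity) next
      new_seq <- if (frag$orientation == "FWD")
        substr(cseq, al$t_start + 1L, nchar(cseq))
      else substr(cseq, 1L, al$t_end)
      if (nchar(new_seq) > nchar(frag$seq)) {
        frag$seq <- new_seq
        frag$depth_per_col <- rep.int(frag$depth, nchar(new_seq))
        return(frag)
      }
    }
  }
  frag
}
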