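#' Simulation configuration
#'
#' Defaults reproduce the published benchmark world at desk scale: 10 kb
#' bins with one planted event each, event sizes 100-1,000 bp at 100 bp
#' intervals, paired-end reads of 150 bp at 100x coverage, outer distance
#' 500 +/- 50 bp, per-base substitution error 0.02 and haplotype point
#' mutation rate 0.001 (the published grid also uses 75 bp reads, 200x and
#' 0.005). The default 10 bins are a scale-down of the published 100-bin
#' runs with the same per-size structure.
#'
#' @param n_bins number of bins, one planted event each (default 10).
#' @param bin_size bin size in bp (default 10000); must exceed
#'   `max(indel_sizes) + 2 * read_length`.
#' @param indel_sizes event sizes, recycled over bins.
#' @param n_ins,n_del counts of insertions/deletions (recycled over bins;
#'   default half and half).
#' @param mutation_rate haplotype point-mutation rate per base.
#' @param read_length read length in bp.
#' @param coverage fold coverage.
#' @param base_error per-base sequencing substitution rate.
#' @param outer_distance,outer_sd fragment outer-distance model (bp).
#' @param repeat_flank if TRUE insertion sequences copy the adjacent
#'   upstream flank (tandem-duplication-like) instead of being random.
#' @param anchor_min minimum matching bases for the analytic mapper to
#'   anchor a clipped read (default 20).
#' @param ref_length reference length; default `n_bins * bin_size`.
#' @param seed optional RNG seed (< 2^31) consumed by [plant_indels()] and
#'   [simulate_reads()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_bins = 10L, bin_size = 10000L,
                       indel_sizes = seq(100L, 1000L, by = 100L),
                       n_ins = 5L, n_del = 5L, mutation_rate = 0.001,
                       read_length = 150L, coverage = 100,
                       base_error = 0.02, outer_distance = 500L,
                       outer_sd = 50L, repeat_flank = FALSE,
                       anchor_min = 20L, ref_length = NULL, seed = NULL) {
  if (is.null(ref_length)) ref_length <- n_bins * bin_size
  if (bin_size <= max(indel_sizes) + 2L * read_length)
    stop("bin_size must exceed max(indel_sizes) + 2 * read_length")
  rates <- c(mutation_rate, base_error)
  if (any(rates < 0 | rates >= 1)) stop("rates must be in [0, 1)")
  structure(as.list(environment())[c(
    "n_bins", "bin_size", "indel_sizes", "n_ins", "n_del", "mutation_rate",
    "read_length", "coverage", "base_error", "outer_distance", "outer_sd",
    "repeat_flank", "anchor_min", "ref_length", "seed")],
    class = "sim_config")
}

#' Generate a random reference genome
#'
#' @param length genome length in bp.
#' @param chrom chromosome name.
#' @return `DNAStringSet` with one chromosome of i.i.d. uniform ACGT.
#' @export
random_genome <- function(length, chrom = "sim1") {
  s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
             collapse = "")
  setNames(Biostrings::DNAStringSet(s), chrom)
}

#' Plant indels into a reference genome
#'
#' One event per bin, centred with +/- 25% of `bin_size` jitter; insertion
#' sequences are i.i.d. uniform ACGT, or copies of the adjacent upstream
#' flank in `repeat_flank` mode (to reproduce the repetitive-insertion
#' assembly failure mode). Returns the mutated genome plus the truth table
#' and the mutated-to-reference coordinate segments the analytic mapper
#' uses.
#'
#' @param ref reference (`DNAStringSet`, FASTA path) or NULL to generate a
#'   random genome of `cfg$ref_length`.
#' @param cfg [sim_config()].
#' @return list of class `planted_genome`: `ref` (DNAStringSet), `chrom`,
#'   `genome` (mutated haplotype string), `truth` (data.frame `chrom`,
#'   `pos1`, `svtype`, `length`, `sequence`), `events`, `segments`.
#' @export
plant_indels <- function(ref = NULL, cfg = sim_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.null(ref)) ref <- random_genome(cfg$ref_length)
  ref <- load_reference(ref)
  chrom <- names(ref)[1]
  glen <- length(ref[[chrom]])
  if (glen < cfg$n_bins * cfg$bin_size)
    stop("reference shorter than n_bins * bin_size: overlapping bins requested")
  refstr <- toupper(as.character(ref[[chrom]]))
  types <- rep_len(rep(c("DEL", "INS"), c(cfg$n_del, cfg$n_ins)), cfg$n_bins)
  sizes <- rep_len(cfg$indel_sizes, cfg$n_bins)
  margin <- max(cfg$indel_sizes) / 2 + cfg$read_length
  p0 <- integer(cfg$n_bins)
  for (i in seq_len(cfg$n_bins)) {
    lo <- (i - 1L) * cfg$bin_size
    center <- lo + cfg$bin_size %/% 2L
    jit <- round(runif(1, -0.25, 0.25) * cfg$bin_size)
    p0[i] <- as.integer(min(max(center + jit, lo + margin),
                            lo + cfg$bin_size - margin))
  }
  seqs <- character(cfg$n_bins)
  for (i in seq_len(cfg$n_bins)) {
    L <- sizes[i]
    if (types[i] == "DEL") {
      seqs[i] <- substr(refstr, p0[i] + 1L, p0[i] + L)
    } else if (cfg$repeat_flank) {
      seqs[i] <- substr(refstr, p0[i] - L + 1L, p0[i])
    } else {
      seqs[i] <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                       collapse = "")
    }
  }
  events <- data.frame(chrom = chrom, p0 = p0, svtype = types,
                       length = sizes, sequence = seqs,
                       src_start0 = ifelse(types == "INS" & cfg$repeat_flank,
                                           p0 - sizes, NA_integer_),
                       stringsAsFactors = FALSE)
  events <- events[order(events$p0), , drop = FALSE]
  # splice mutated genome and build the mut<->ref segment map
  pieces <- character(0)
  segs <- list()
  cur_ref <- 0L; off <- 0L
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    pieces <- c(pieces, substr(refstr, cur_ref + 1L, e$p0))
    segs[[length(segs) + 1L]] <- data.frame(
      mut_start0 = cur_ref + off, mut_end0 = e$p0 + off,
      type = "collinear", ref_start0 = cur_ref,
      src_start0 = NA_integer_, stringsAsFactors = FALSE)
    if (e$svtype == "DEL") {
      cur_ref <- e$p0 + e$length
      off <- off - e$length
    } else {
      pieces <- c(pieces, e$sequence)
      segs[[length(segs) + 1L]] <- data.frame(
        mut_start0 = e$p0 + off, mut_end0 = e$p0 + off + e$length,
        type = "inserted", ref_start0 = NA_integer_,
        src_start0 = e$src_start0, stringsAsFactors = FALSE)
      cur_ref <- e$p0
      off <- off + e$length
    }
  }
  pieces <- c(pieces, substr(refstr, cur_ref + 1L, glen))
  segs[[length(segs) + 1L]] <- data.frame(
    mut_start0 = cur_ref + off, mut_end0 = glen + off, type = "collinear",
    ref_start0 = cur_ref, src_start0 = NA_integer_, stringsAsFactors = FALSE)
  genome <- paste(pieces, collapse = "")
  truth <- data.frame(chrom = chrom, pos1 = events$p0, svtype = events$svtype,
                      length = events$length, sequence = events$sequence,
                      stringsAsFactors = FALSE)
  structure(list(ref = ref, chrom = chrom, genome = genome, truth = truth,
                 events = events, segments = do.call(rbind, segs)),
            class = "planted_genome")
}

#' Simulate paired-end reads from a planted genome
#'
#' wgsim-style: haplotype point mutations are applied once to the mutated
#' genome, fragments are drawn with Normal(outer_distance, outer_sd) outer
#' distance, inward-facing read pairs are cut from the fragment ends, and
#' per-base substitution errors are added at `base_error` (independently
#' of the constant Phred 35 quality string, as wgsim does). The number of
#' pairs is `floor(coverage * genome_length / (2 * read_length))`.
#'
#' @param sim `planted_genome` from [plant_indels()].
#' @param cfg [sim_config()].
#' @return list of class `sim_reads`: `reads` (data.frame `qname`, `mate`,
#'   `mut_start0`, `is_reverse`, `fwd_seq` — forward-strand sequence with
#'   errors —, `qual`), `chrom`, `read_length`.
#' @export
simulate_reads <- function(sim, cfg = sim_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1L)
  rl <- cfg$read_length
  if (rl > cfg$outer_distance) stop("read_length exceeds outer_distance")
  genome <- sim$genome
  glen <- nchar(genome)
  bases <- c("A", "C", "G", "T")
  # haplotype SNVs
  nsnv <- rbinom(1L, glen, cfg$mutation_rate)
  if (nsnv > 0L) {
    pos <- sample.int(glen, nsnv)
    old <- substring(genome, pos, pos)
    new <- vapply(old, function(b) sample(setdiff(bases, b), 1L),
                  character(1), USE.NAMES = FALSE)
    for (i in seq_len(nsnv))
      substr(genome, pos[i], pos[i]) <- new[i]
  }
  n_pairs <- floor(cfg$coverage * glen / (2 * rl))
  frag <- pmin(pmax(round(rnorm(n_pairs, cfg$outer_distance, cfg$outer_sd)),
                    rl), glen)
  s <- floor(runif(n_pairs) * (glen - frag + 1))
  s1 <- s; s2 <- s + frag - rl
  starts <- c(rbind(s1, s2))  # interleaved pair rows
  mates <- rep(c(1L, 2L), n_pairs)
  qn <- rep(sprintf("p%06d", seq_len(n_pairs)), each = 2L)
  seqs <- substring(genome, starts + 1L, starts + rl)
  # sequencing errors (substitutions only)
  nerr <- rbinom(length(seqs), rl, cfg$base_error)
  for (i in which(nerr > 0L)) {
    pos <- sample.int(rl, nerr[i])
    for (p in pos) {
      b <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, b), 1L)
    }
  }
  structure(list(
    reads = data.frame(qname = qn, mate = mates,
                       mut_start0 = as.integer(starts),
                       is_reverse = mates == 2L, fwd_seq = seqs,
                       qual = strrep("D", rl), stringsAsFactors = FALSE),
    chrom = sim$chrom, read_length = rl), class = "sim_reads")
}

#' Write simulated reads as paired FASTQ
#'
#' Mate-2 reads are reverse-complemented to sequencing orientation.
#'
#' @param simreads `sim_reads` from [simulate_reads()].
#' @param prefix output prefix; writes `<prefix>_1.fq` and `<prefix>_2.fq`.
#' @return character vector of the two paths, invisibly.
#' @export
write_fastq <- function(simreads, prefix) {
  r <- simreads$reads
  out <- c(paste0(prefix, "_1.fq"), paste0(prefix, "_2.fq"))
  for (m in 1:2) {
    rm <- r[r$mate == m, , drop = FALSE]
    seqs <- rm$fwd_seq
    if (m == 2L)
      seqs <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs)))
    writeLines(paste0("@", rm$qname, "/", m, "\n", seqs, "\n+\n", rm$qual),
               out[m])
  }
  invisible(out)
}

#' Analytically map simulated reads (aligner stand-in)
#'
#' Emits the SAM records a soft-clipping aligner would produce, using the
#' simulation bookkeeping instead of alignment: reads entirely within
#' unaltered sequence get full-match CIGARs; reads crossing a planted
#' breakpoint are anchored on their longest reference-collinear run (at
#' least `cfg$anchor_min` bases) and soft-clipped on the other side; reads
#' entirely inside a long insertion are emitted unmapped with their mapped
#' mate's coordinates. Mimicking a real aligner's preference for
#' contiguous matches, any candidate clip (and any read inside a
#' flank-copy insertion) is first tested for a full-length contiguous
#' reference match with <=10% mismatches and mapped fully when it passes —
#' this is what removes the backward-clip signal of
#' tandem-duplication-like insertions.
#'
#' @param simreads `sim_reads` from [simulate_reads()].
#' @param sim `planted_genome` from [plant_indels()].
#' @param cfg [sim_config()].
#' @return data.frame of SAM fields (`qname`, `flag`, `rname`, `pos1`,
#'   `mapq`, `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual`),
#'   coordinate-sorted.
#' @export
analytic_map <- function(simreads, sim, cfg = sim_config()) {
  need <- c("qname", "mate", "mut_start0", "is_reverse", "fwd_seq", "qual")
  if (!all(need %in% names(simreads$reads)))
    stop("reads lack simulation bookkeeping")
  r <- simreads$reads
  rl <- simreads$read_length
  segs <- sim$segments
  refstr <- toupper(as.character(sim$ref[[sim$chrom]]))
  reflen <- nchar(refstr)
  n <- nrow(r)
  mapped <- logical(n); pos0 <- rep.int(NA_integer_, n)
  cigar <- rep.int("*", n)

  mismatch_frac <- function(a, b) {
    if (nchar(a) != nchar(b) || nchar(a) == 0L) return(1)
    mean(charToRaw(a) != charToRaw(b))
  }
  try_full <- function(seq, p) {
    if (is.na(p) || p < 0L || p + rl > reflen) return(FALSE)
    mismatch_frac(seq, substr(refstr, p + 1L, p + rl)) <= 0.1
  }

  seg_idx <- findInterval(r$mut_start0, segs$mut_start0)
  seg_idx_end <- findInterval(r$mut_start0 + rl - 1L, segs$mut_start0)
  for (i in seq_len(n)) {
    s <- r$mut_start0[i]; e <- s + rl
    i1 <- seg_idx[i]; i2 <- seg_idx_end[i]
    if (i1 == i2 && segs$type[i1] == "collinear") {
      mapped[i] <- TRUE
      pos0[i] <- segs$ref_start0[i1] + (s - segs$mut_start0[i1])
      cigar[i] <- paste0(rl, "M")
      next
    }
    if (i1 == i2) {  # wholly inside an inserted segment
      pf <- segs$src_start0[i1]
      if (!is.na(pf) && try_full(r$fwd_seq[i], pf + (s - segs$mut_start0[i1]))) {
        mapped[i] <- TRUE
        pos0[i] <- pf + (s - segs$mut_start0[i1])
        cigar[i] <- paste0(rl, "M")
      }
      next
    }
    # crossing: collect reference-collinear runs
    best_len <- 0L; best <- NULL
    for (k in i1:i2) {
      if (segs$type[k] != "collinear") next
      a <- max(s, segs$mut_start0[k]); b <- min(e, segs$mut_end0[k])
      if (b - a > best_len) {
        best_len <- b - a
        best <- list(read_off = a - s,
                     ref_start = segs$ref_start0[k] + (a - segs$mut_start0[k]),
                     len = b - a)
      }
    }
    if (is.null(best) || best$len < cfg$anchor_min) {
      # try contiguous rescue through an adjacent flank-copy insertion
      for (k in i1:i2) {
        if (segs$type[k] != "inserted" || is.na(segs$src_start0[k])) next
        a <- max(s, segs$mut_start0[k])
        pf <- segs$src_start0[k] + (a - segs$mut_start0[k]) - (a - s)
        if (try_full(r$fwd_seq[i], pf)) {
          mapped[i] <- TRUE; pos0[i] <- pf; cigar[i] <- paste0(rl, "M")
          break
        }
      }
      next
    }
    p_full <- best$ref_start - best$read_off
    if (try_full(r$fwd_seq[i], p_full)) {
      mapped[i] <- TRUE; pos0[i] <- p_full; cigar[i] <- paste0(rl, "M")
      next
    }
    nleft <- best$read_off
    nright <- rl - nleft - best$len
    mapped[i] <- TRUE
    pos0[i] <- best$ref_start
    cigar[i] <- paste0(if (nleft > 0L) paste0(nleft, "S") else "",
                       best$len, "M",
                       if (nright > 0L) paste0(nright, "S") else "")
  }

  # pair bookkeeping: rows interleaved, mate of row i is i+1 / i-1
  flag <- rep.int(1L, n)
  flag <- flag + ifelse(r$mate == 1L, 64L, 128L)
  flag[!mapped] <- flag[!mapped] + 4L
  midx <- ifelse(seq_len(n) %% 2L == 1L, seq_len(n) + 1L, seq_len(n) - 1L)
  mate_mapped <- mapped[midx]
  flag[!mate_mapped] <- flag[!mate_mapped] + 8L
  flag[mapped & r$is_reverse] <- flag[mapped & r$is_reverse] + 16L
  mate_rev <- r$is_reverse[midx]
  flag[mate_mapped & mate_rev] <- flag[mate_mapped & mate_rev] + 32L

  out_pos0 <- ifelse(mapped, pos0, ifelse(mate_mapped, pos0[midx], NA))
  rname <- ifelse(is.na(out_pos0), "*", sim$chrom)
  pnext <- ifelse(mapped[midx], pos0[midx] + 1L,
                  ifelse(mapped, pos0 + 1L, 0L))
  pnext[is.na(pnext)] <- 0L
  rnext <- ifelse(pnext > 0L, "=", "*")
  tlen <- integer(n)
  both <- mapped & mate_mapped
  span_self <- ifelse(mapped, cigar_ref_span(cigar), 0L)
  lo <- pmin(out_pos0, pos0[midx])
  hi <- pmax(out_pos0 + span_self, pos0[midx] + span_self[midx])
  t <- ifelse(both, hi - lo, 0L)
  left_of_pair <- out_pos0 < pos0[midx] |
    (out_pos0 == pos0[midx] & r$mate == 1L)
  tlen[both] <- ifelse(left_of_pair[both], t[both], -t[both])

  seqout <- r$fwd_seq
  unm_rev <- !mapped & r$is_reverse
  if (any(unm_rev))
    seqout[unm_rev] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqout[unm_rev])))
  sam <- data.frame(qname = r$qname, flag = flag, rname = rname,
                    pos1 = as.integer(ifelse(is.na(out_pos0), 0L, out_pos0 + 1L)),
                    mapq = ifelse(mapped, 60L, 0L), cigar = cigar,
                    rnext = rnext, pnext = as.integer(pnext),
                    tlen = as.integer(tlen), seq = seqout, qual = r$qual,
                    stringsAsFactors = FALSE)
  sam[order(sam$rname == "*", sam$pos1, sam$qname, sam$flag), , drop = FALSE]
}

#' Write SAM records to a file
#'
#' @param sam data.frame from [analytic_map()].
#' @param ref `DNAStringSet` (for the `@SQ` header).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sam, ref, path) {
  ref <- load_reference(ref)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(ref), "\tLN:", Biostrings::width(ref)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  sam$qname, sam$flag, sam$rname, sam$pos1, sam$mapq,
                  sam$cigar, sam$rnext, sam$pnext, sam$tlen, sam$seq,
                  sam$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate a full benchmark data set
#'
#' Convenience wrapper: plants indels, simulates reads, analytically maps
#' them, and (optionally) writes `ref.fa`, `truth.tsv`, `reads_1.fq`,
#' `reads_2.fq` and `mapped.sam` to a directory.
#'
#' @param cfg [sim_config()].
#' @param out_dir optional output directory.
#' @param ref optional reference (default: random genome).
#' @return list: `sim` (`planted_genome`), `simreads`, `sam` (data.frame),
#'   and `paths` when `out_dir` is given.
#' @export
simulate_dataset <- function(cfg = sim_config(), out_dir = NULL, ref = NULL) {
  sim <- plant_indels(ref, cfg)
  simreads <- simulate_reads(sim, cfg)
  sam <- analytic_map(simreads, sim, cfg)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(out_dir, "ref.fa")
    Biostrings::writeXStringSet(sim$ref, fa)
    write_truth(sim$truth, file.path(out_dir, "truth.tsv"))
    write_fastq(simreads, file.path(out_dir, "reads"))
    write_sam(sam, sim$ref, file.path(out_dir, "mapped.sam"))
    paths <- list(ref = fa, truth = file.path(out_dir, "truth.tsv"),
                  sam = file.path(out_dir, "mapped.sam"))
  }
  list(sim = sim, simreads = simreads, sam = sam, paths = paths)
}
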