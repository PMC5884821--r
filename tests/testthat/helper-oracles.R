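# Independent oracles and fixture builders, kept deliberately naive.

# Needleman-Wunsch global alignment score with affine gaps
# (gap run of length k costs open + k * ext), plain R, no traceback.
nw_score <- function(q, t, match = 5, mismatch = -20, open = -20, ext = 0) {
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  n <- length(qc); m <- length(tc)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in query (consumes target)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in target (consumes query)
  M[1, 1] <- 0
  for (j in seq_len(m)) X[1, j + 1] <- open + j * ext
  for (i in seq_len(n)) Y[i + 1, 1] <- open + i * ext
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (qc[i] == tc[j]) match else mismatch
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i + 1, j] + open + ext, X[i + 1, j] + ext,
                           Y[i + 1, j] + open + ext)
    Y[i + 1, j + 1] <- max(M[i, j + 1] + open + ext, Y[i, j + 1] + ext,
                           X[i, j + 1] + open + ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# brute-force glocal score: full NW against every target window
# (including the empty window, where the whole query is one gap run)
brute_glocal <- function(q, t, match = 5, mismatch = -20, open = -20,
                         ext = 0) {
  m <- nchar(t)
  best <- open + nchar(q) * ext  # empty window
  for (a in seq_len(m)) for (b in a:m) {
    w <- substr(t, a, b)
    best <- max(best, nw_score(q, w, match, mismatch, open, ext))
  }
  best
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# single aligned-read row in the read_alignments() data.frame layout
make_read <- function(qname = "r1", chrom = "sim1", pos0 = 1000L,
                      mapq = 60L, cigar = "100M", seq = NULL, qual = NULL,
                      flag = 0L, is_unmapped = FALSE, mate_unmapped = FALSE,
                      is_reverse = FALSE, is_dup = FALSE,
                      mate_chrom = chrom, mate_pos0 = pos0 + 300L,
                      tlen = 450L, qlen = NULL) {
  if (is.null(qlen)) qlen <- max(clipindel::cigar_query_len(cigar), 100L)
  if (is.null(seq)) seq <- random_seq(qlen)
  if (is.null(qual)) qual <- strrep("D", nchar(seq))  # Phred 35
  data.frame(qname = qname, flag = flag, chrom = chrom, pos0 = pos0,
             mapq = mapq, cigar = cigar, seq = seq, qual = qual,
             is_unmapped = is_unmapped, mate_unmapped = mate_unmapped,
             is_reverse = is_reverse, is_dup = is_dup,
             mate_chrom = mate_chrom, mate_pos0 = mate_pos0, tlen = tlen,
             stringsAsFactors = FALSE)
}

# quality string with a given mean Phred
qual_str <- function(n, phred) strrep(intToUtf8(phred + 33), n)

# convert an analytic_map() SAM data.frame to the read_alignments() layout
# without the Rsamtools round trip (fast path for simulation tests)
sam_as_reads <- function(s) {
  data.frame(qname = s$qname, flag = s$flag,
             chrom = ifelse(s$rname == "*", NA, s$rname),
             pos0 = s$pos1 - 1L, mapq = s$mapq, cigar = s$cigar,
             seq = s$seq, qual = s$qual,
             is_unmapped = bitwAnd(s$flag, 4L) > 0,
             mate_unmapped = bitwAnd(s$flag, 8L) > 0,
             is_reverse = bitwAnd(s$flag, 16L) > 0, is_dup = FALSE,
             mate_chrom = ifelse(s$rnext == "=", s$rname, NA),
             mate_pos0 = s$pnext - 1L, tlen = s$tlen,
             stringsAsFactors = FALSE)
}

# a clip cluster fixture: n copies of `true_seq` (FWD orientation) with
# optional per-sequence mutations, as a cluster list
make_cluster <- function(true_seq, n, orientation = "FWD", chrom = "sim1",
                         breakpoint0 = 500L, mutate = 0) {
  seqs <- vapply(seq_len(n), function(i) {
    s <- true_seq
    if (mutate > 0) {
      k <- rbinom(1, nchar(s), mutate)
      if (k > 0) for (p in sample.int(nchar(s), k)) {
        b <- substr(s, p, p)
        substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }
    }
    s
  }, character(1))
  members <- data.frame(chrom = chrom, breakpoint0 = breakpoint0,
                        orientation = orientation, seq = seqs,
                        qual = strrep("D", nchar(seqs)),
                        mean_qual = 35, qname = paste0("m", seq_len(n)),
                        mapq = 60L, stringsAsFactors = FALSE)
  list(chrom = chrom, orientation = orientation, breakpoint0 = breakpoint0,
       members = members,
       rescued = data.frame(chrom = character(), est_breakpoint0 = integer(),
                            est_orientation = character(), seq = character(),
                            qual = character(), qname = character(),
                            anchor_pos0 = integer(), stringsAsFactors = FALSE),
       support = n)
}

# error-free reads tiling a sequence at a given step (for assembly tests)
tiling_reads <- function(s, read_len = 50L, step = 5L) {
  starts <- seq(1L, max(1L, nchar(s) - read_len + 1L), by = step)
  substring(s, starts, pmin(starts + read_len - 1L, nchar(s)))
}
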