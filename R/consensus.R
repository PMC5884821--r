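#' Multiple sequence alignment of clipped fragments
#'
#' `mode = "internal"` (default) computes a star alignment: the longest
#' sequence is the centre, every other sequence is aligned to it with the
#' package's glocal DP, and pairwise alignments are merged under "once a
#' gap, always a gap" (insertions relative to the centre are stacked
#' left-aligned). `mode = "external"` shells out to a MAFFT-compatible
#' executable (`mafft --nuc --ep 0.0 --op 1 --genafpair --maxiterate
#' 1000`) and parses its FASTA output.
#'
#' @param seqs character vector of at least 2 nucleotide strings.
#' @param quals optional parallel vector of Phred+33 quality strings.
#' @param mode `"internal"` or `"external"`.
#' @param mafft_bin MAFFT executable for the external mode.
#' @param anchored internal mode only: drop columns preceding the centre's
#'   first position (sequences share an anchored left end, e.g. clips at a
#'   breakpoint after orientation normalisation).
#' @param n_anchor number of leading sequences eligible to be the centre
#'   in anchored mode.
#' @return list: `aln` — character matrix (rows = input sequences, single
#'   characters, `-` for gaps); `qual` — numeric matrix of Phred scores
#'   (NA at gaps).
#' @export
msa <- function(seqs, quals = NULL, mode = c("internal", "external"),
                mafft_bin = "mafft", anchored = FALSE,
                n_anchor = length(seqs)) {
  mode <- match.arg(mode)
  if (length(seqs) < 2L) stop("msa needs at least 2 sequences")
  if (is.null(quals)) quals <- vapply(nchar(seqs), function(n)
    strrep("I", n), character(1))
  if (mode == "external") return(.msa_external(seqs, quals, mafft_bin))
  .msa_star(seqs, quals, anchored, n_anchor)
}

.msa_star <- function(seqs, quals, anchored = FALSE,
                      n_anchor = length(seqs)) {
  n <- length(seqs)
  # in anchored mode the centre must itself be breakpoint-anchored (a clip
  # member, rows 1..n_anchor), never a rescued read with flank overhang
  ci <- which.max(nchar(seqs[seq_len(n_anchor)]))
  center <- seqs[ci]
  Lc <- nchar(center)
  # per row: base[p] over centre positions 1..Lc, ins[[p]] after position p
  base <- matrix("-", nrow = n, ncol = Lc)
  qbase <- matrix(NA_real_, nrow = n, ncol = Lc)
  ins <- vector("list", n)
  qins <- vector("list", n)
  for (r in seq_len(n)) {
    ins[[r]] <- vector("list", Lc + 1L)
    qins[[r]] <- vector("list", Lc + 1L)
  }
  base[ci, ] <- .chars(center)
  qbase[ci, ] <- utf8ToInt(quals[ci]) - 33
  for (r in setdiff(seq_len(n), ci)) {
    # clips share the breakpoint with the centre: their starts are pinned
    # (anchored rows); rescued reads may overhang and float in the centre
    al <- if (anchored && r <= n_anchor) anchor_align(seqs[r], center)
          else glocal_align(seqs[r], center)
    qa <- .chars(al$q_aln); ta <- .chars(al$t_aln)
    qq <- utf8ToInt(quals[r]) - 33
    tpos <- al$t_start  # centre position after which we currently sit
    qpos <- 0L
    for (col in seq_along(qa)) {
      if (ta[col] != "-") {
        tpos <- tpos + 1L
        if (qa[col] != "-") {
          qpos <- qpos + 1L
          base[r, tpos] <- qa[col]
          qbase[r, tpos] <- qq[qpos]
        }
      } else {
        qpos <- qpos + 1L
        ins[[r]][[tpos + 1L]] <- c(ins[[r]][[tpos + 1L]], qa[col])
        qins[[r]][[tpos + 1L]] <- c(qins[[r]][[tpos + 1L]], qq[qpos])
      }
    }
  }
  # assemble columns: [ins after 0][base 1][ins after 1]...[base Lc][ins after Lc]
  cols <- list(); qcols <- list()
  add_ins <- function(p) {
    w <- max(vapply(seq_len(n), function(r) length(ins[[r]][[p + 1L]]),
                    integer(1)))
    if (w == 0L) return()
    for (k in seq_len(w)) {
      cc <- rep.int("-", n); qc <- rep.int(NA_real_, n)
      for (r in seq_len(n)) {
        v <- ins[[r]][[p + 1L]]
        if (length(v) >= k) { cc[r] <- v[k]; qc[r] <- qins[[r]][[p + 1L]][k] }
      }
      cols[[length(cols) + 1L]] <<- cc
      qcols[[length(qcols) + 1L]] <<- qc
    }
  }
  if (!anchored) add_ins(0L)  # anchored: overhang before the breakpoint is cut
  for (p in seq_len(Lc)) {
    cols[[length(cols) + 1L]] <- base[, p]
    qcols[[length(qcols) + 1L]] <- qbase[, p]
    add_ins(p)
  }
  list(aln = do.call(cbind, cols), qual = do.call(cbind, qcols))
}

.msa_external <- function(seqs, quals, mafft_bin) {
  if (Sys.which(mafft_bin) == "")
    stop("MAFFT executable '", mafft_bin,
         "' not found; use mode = \"internal\"")
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa))
  writeLines(paste0(">s", seq_along(seqs), "\n", seqs), fa)
  out <- suppressWarnings(system2(
    mafft_bin,
    c("--nuc", "--ep", "0.0", "--op", "1", "--genafpair",
      "--maxiterate", "1000", "--quiet", fa),
    stdout = TRUE, stderr = FALSE))
  if (length(out) == 0L) stop("MAFFT produced no output")
  outfa <- tempfile(fileext = ".fa")
  on.exit(unlink(outfa), add = TRUE)
  writeLines(out, outfa)
  dss <- Biostrings::readBStringSet(outfa, format = "fasta")
  dss <- dss[match(paste0("s", seq_along(seqs)), names(dss))]
  rows <- toupper(as.character(dss))
  aln <- do.call(rbind, lapply(rows, .chars))
  qual <- matrix(NA_real_, nrow = nrow(aln), ncol = ncol(aln))
  for (r in seq_along(seqs)) {
    qq <- utf8ToInt(quals[r]) - 33
    nz <- which(aln[r, ] != "-")
    qual[r, nz] <- qq[seq_along(nz)]
  }
  list(aln = aln, qual = qual)
}

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Build a consensus fragment from a breakpoint cluster
#'
#' Member (and rescued) sequences are anchored at the breakpoint — FWD
#' clips share their left end, BWD clips their right end (handled by
#' reversing before alignment) — and multiple-aligned. Per column the
#' consensus base is the most frequent non-gap base; ties break by larger
#' summed base quality, then lexicographically. Columns where the gap is
#' the strict majority are deleted.
#'
#' @param cluster one cluster from [cluster_fragments()] /
#'   [attach_unmapped()].
#' @param min_members minimum sequences to attempt a consensus (default 2).
#' @param min_len minimum consensus length (default 6).
#' @param mode,mafft_bin forwarded to [msa()].
#' @return list of class `consensus_fragment` (`chrom`, `orientation`,
#'   `breakpoint0`, `seq`, `depth_per_col`, `depth` = max column support,
#'   `n_reads`, `qnames`) or `NULL` when the cluster cannot support one.
#' @export
build_consensus <- function(cluster, min_members = 2L, min_len = 6L,
                            mode = "internal", mafft_bin = "mafft") {
  seqs <- c(cluster$members$seq, cluster$rescued$seq)
  quals <- c(cluster$members$qual, cluster$rescued$qual)
  qnames <- c(cluster$members$qname, cluster$rescued$qname)
  if (length(seqs) < min_members) return(NULL)
  rev_mode <- identical(cluster$orientation, "BWD")
  if (rev_mode) {
    seqs <- vapply(seqs, .str_rev, character(1), USE.NAMES = FALSE)
    quals <- vapply(quals, .str_rev, character(1), USE.NAMES = FALSE)
  }
  m <- msa(seqs, quals, mode = mode, mafft_bin = mafft_bin,
           anchored = (mode == "internal"),
           n_anchor = max(1L, nrow(cluster$members)))
  cons <- .vote_consensus(m$aln, m$qual)
  if (rev_mode) {
    cons$seq <- .str_rev(cons$seq)
    cons$depth_per_col <- rev(cons$depth_per_col)
  }
  if (nchar(cons$seq) < min_len) return(NULL)
  structure(list(chrom = cluster$chrom, orientation = cluster$orientation,
                 breakpoint0 = cluster$breakpoint0, seq = cons$seq,
                 depth_per_col = cons$depth_per_col,
                 depth = max(cons$depth_per_col),
                 n_reads = length(seqs), qnames = qnames),
            class = "consensus_fragment")
}

.str_rev <- function(s) paste(rev(.chars(s)), collapse = "")

# End gaps (alignment padding before a row's first / after its last base)
# do not vote: a short fragment is silent, not evidence for a deletion.
# Only rows whose coverage spans a column count toward the gap majority.
.vote_consensus <- function(aln, qual) {
  keep_chars <- character(0)
  depths <- integer(0)
  bases <- c("A", "C", "G", "T")
  nongap <- aln %in% bases
  dim(nongap) <- dim(aln)
  first <- apply(nongap, 1L, function(z) if (any(z)) which(z)[1] else Inf)
  last <- apply(nongap, 1L, function(z) if (any(z)) max(which(z)) else -Inf)
  for (col in seq_len(ncol(aln))) {
    voting <- first <= col & last >= col
    if (!any(voting)) next
    v <- aln[voting, col]
    is_base <- v %in% bases
    n_gap <- sum(!is_base)
    if (n_gap > length(v) / 2) next  # gap strict majority: column deleted
    cnt <- vapply(bases, function(b) sum(v == b), integer(1))
    top <- which(cnt == max(cnt))
    if (length(top) > 1L) {
      qv <- qual[voting, col]
      qs <- vapply(top, function(t)
        sum(qv[v == bases[t]], na.rm = TRUE), numeric(1))
      top <- top[qs == max(qs)]
      top <- top[1L]  # lexicographic (bases are sorted)
    }
    keep_chars <- c(keep_chars, bases[top])
    depths <- c(depths, sum(is_base))
  }
  list(seq = paste(keep_chars, collapse = ""), depth_per_col = depths)
}

#' Greedy k-mer assembly of unmapped reads
#'
#' Inchworm-style: count all k-mers on canonical strand, seed with the
#' most frequent unused k-mer, extend one base at a time in both
#' directions choosing the highest-count overlapping k-mer, stop when the
#' best count drops below `min_kmer_count` or the extension k-mer was
#' already used; repeat until no seed remains. Contigs shorter than `2k`
#' are dropped. This reproduces the known failure mode on insertions whose
#' sequence repeats flanking sequence at scale >= k: shared k-mers make
#' extension ambiguous and contigs fragment or chimerise.
#'
#' @param seqs character vector of read sequences.
#' @param k odd k-mer size (default 25).
#' @param min_kmer_count minimum k-mer multiplicity to seed/extend
#'   (default 2).
#' @return list of contigs sorted by descending supporting-read count,
#'   each a list (`seq`, `kmer_size`, `n_reads`).
#' @export
assemble_unmapped <- function(seqs, k = 25L, min_kmer_count = 2L) {
  if (length(seqs) == 0L) return(list())
  if (k %% 2L == 0L) stop("k must be odd")
  seqs <- toupper(seqs)
  seqs <- seqs[nchar(seqs) >= k]
  if (length(seqs) == 0L) return(list())
  read_kmers <- lapply(seqs, function(s) {
    nk <- nchar(s) - k + 1L
    unique(.canonical(substring(s, seq_len(nk), seq_len(nk) + k - 1L)))
  })
  counts <- table(unlist(lapply(seqs, function(s) {
    nk <- nchar(s) - k + 1L
    .canonical(substring(s, seq_len(nk), seq_len(nk) + k - 1L))
  })))
  cnt <- setNames(as.integer(counts), names(counts))
  cnt <- cnt[order(-cnt, names(cnt))]  # deterministic seed order
  used <- new.env(hash = TRUE, parent = emptyenv())
  get_count <- function(km) {
    v <- cnt[.canonical(km)]
    if (is.na(v)) 0L else v
  }
  is_used <- function(km) !is.null(used[[.canonical(km)]])
  mark <- function(km) assign(.canonical(km), TRUE, envir = used)
  contigs <- list()
  bases <- c("A", "C", "G", "T")
  repeat {
    avail <- names(cnt)[cnt >= min_kmer_count]
    avail <- avail[!vapply(avail, function(x) !is.null(used[[x]]), logical(1))]
    if (length(avail) == 0L) break
    seed <- avail[which.max(cnt[avail])]  # names sorted: ties lexicographic
    mark(seed)
    contig <- seed
    repeat {  # extend right
      suf <- substr(contig, nchar(contig) - k + 2L, nchar(contig))
      cand <- paste0(suf, bases)
      sc <- vapply(cand, get_count, integer(1))
      ok <- sc >= min_kmer_count & !vapply(cand, is_used, logical(1))
      if (!any(ok)) break
      best <- which(ok)[which.max(sc[ok])]
      contig <- paste0(contig, bases[best])
      mark(cand[best])
    }
    repeat {  # extend left
      pre <- substr(contig, 1L, k - 1L)
      cand <- paste0(bases, pre)
      sc <- vapply(cand, get_count, integer(1))
      ok <- sc >= min_kmer_count & !vapply(cand, is_used, logical(1))
      if (!any(ok)) break
      best <- which(ok)[which.max(sc[ok])]
      contig <- paste0(bases[best], contig)
      mark(cand[best])
    }
    if (nchar(contig) >= 2L * k) {
      nkc <- nchar(contig) - k + 1L
      ckm <- unique(.canonical(
        substring(contig, seq_len(nkc), seq_len(nkc) + k - 1L)))
      n_reads <- sum(vapply(read_kmers, function(rk) any(rk %in% ckm),
                            logical(1)))
      contigs[[length(contigs) + 1L]] <-
        list(seq = contig, kmer_size = as.integer(k), n_reads = n_reads)
    }
  }
  if (length(contigs) > 1L) {
    ord <- order(vapply(contigs, `[[`, integer(1), "n_reads"),
                 decreasing = TRUE)
    contigs <- contigs[ord]
  }
  contigs
}

.canonical <- function(kmers) {
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  ifelse(kmers <= rc, kmers, rc)
}
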