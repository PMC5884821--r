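#' Load a reference genome
#'
#' Accepts a FASTA path or an existing `Biostrings::DNAStringSet` and
#' returns a `DNAStringSet` whose names are truncated at the first
#' whitespace (SAM-style chromosome names).
#'
#' @param ref FASTA file path or `DNAStringSet`.
#' @return `DNAStringSet`.
#' @export
load_reference <- function(ref) {
  if (methods::is(ref, "DNAStringSet")) return(ref)
  if (is.character(ref) && length(ref) == 1L) {
    if (!file.exists(ref)) stop("reference FASTA not found: ", ref)
    dss <- Biostrings::readDNAStringSet(ref)
    names(dss) <- sub("\\s.*$", "", names(dss))
    return(dss)
  }
  stop("ref must be a FASTA path or a DNAStringSet")
}

# 0-based half-open slice, upper-cased character string
ref_slice <- function(ref, chrom, start0, end0) {
  ref <- load_reference(ref)
  if (!chrom %in% names(ref)) stop("unknown chromosome: ", chrom)
  toupper(as.character(Biostrings::subseq(ref[[chrom]], start0 + 1L, end0)))
}

#' Read alignments from SAM/BAM
#'
#' Thin wrapper over Rsamtools. A `.sam` input is converted to a sorted,
#' indexed temporary BAM first. Duplicate-marked reads are flagged, not
#' dropped (exclusion happens in clip extraction).
#'
#' @param path SAM or BAM file.
#' @param region optional `"chrom"` or `"chrom:start-end"` (1-based,
#'   inclusive); requires an index.
#' @return data.frame, one row per record, in coordinate order: `qname`,
#'   `flag`, `chrom`, `pos0` (0-based leftmost), `mapq`, `cigar`, `seq`,
#'   `qual` (Phred+33 string), `is_unmapped`, `mate_unmapped`,
#'   `is_reverse`, `is_dup`, `mate_chrom`, `mate_pos0`, `tlen`.
#' @export
read_alignments <- function(path, region = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.bam$", path, ignore.case = TRUE)) .check_bgzf_eof(path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = TRUE)
  }
  which <- NULL
  if (!is.null(region)) {
    idx <- paste0(bam, ".bai")
    if (!file.exists(idx) && !file.exists(sub("\\.bam$", ".bai", bam)))
      stop("region query requires a BAM index (.bai) for ", bam)
    m <- regmatches(region,
                    regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
    if (length(m) == 0L) stop("malformed region: ", region)
    chrom <- m[2]
    if (m[3] == "") {
      hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
      if (!chrom %in% names(hdr)) stop("unknown chromosome: ", chrom)
      which <- GenomicRanges::GRanges(chrom,
                IRanges::IRanges(1L, unname(hdr[chrom])))
    } else {
      which <- GenomicRanges::GRanges(chrom,
                IRanges::IRanges(as.integer(m[4]), as.integer(m[5])))
    }
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
            "mrnm", "mpos", "isize", "seq", "qual")
  param <- if (is.null(which)) Rsamtools::ScanBamParam(what = what)
           else Rsamtools::ScanBamParam(what = what, which = which)
  res <- Rsamtools::scanBam(bam, param = param)
  r <- res[[1]]
  flag <- r$flag
  data.frame(
    qname = r$qname,
    flag = flag,
    chrom = as.character(r$rname),
    pos0 = as.integer(r$pos) - 1L,
    mapq = as.integer(r$mapq),
    cigar = ifelse(is.na(r$cigar), "*", r$cigar),
    seq = as.character(r$seq),
    qual = as.character(r$qual),
    is_unmapped = bitwAnd(flag, 4L) > 0L,
    mate_unmapped = bitwAnd(flag, 8L) > 0L,
    is_reverse = bitwAnd(flag, 16L) > 0L,
    is_dup = bitwAnd(flag, 1024L) > 0L,
    mate_chrom = as.character(r$mrnm),
    mate_pos0 = as.integer(r$mpos) - 1L,
    tlen = as.integer(r$isize),
    stringsAsFactors = FALSE)
}

#' Fetch a reference window around a breakpoint
#'
#' @param ref FASTA path or `DNAStringSet`.
#' @param chrom chromosome name.
#' @param breakpoint0 0-based breakpoint coordinate.
#' @param flank flank size in bp on each side (default 5000, the window the
#'   consensus sequence is compared against).
#' @return list of class `reference_window`: `chrom`, `start0`, `end0`
#'   (0-based half-open, clipped to the chromosome), `seq` (upper case),
#'   `flank`.
#' @export
fetch_reference_window <- function(ref, chrom, breakpoint0, flank = 5000L) {
  ref <- load_reference(ref)
  if (!chrom %in% names(ref)) stop("unknown chromosome: ", chrom)
  len <- length(ref[[chrom]])
  start0 <- max(0L, as.integer(breakpoint0 - flank))
  end0 <- min(len, as.integer(breakpoint0 + flank))
  structure(list(chrom = chrom, start0 = start0, end0 = end0,
                 seq = ref_slice(ref, chrom, start0, end0),
                 flank = as.integer(flank)),
            class = "reference_window")
}

#' Write indel calls to VCF 4.2
#'
#' Deletions are encoded as REF = anchor base + deleted span, ALT = anchor
#' base; insertions as REF = anchor base, ALT = anchor base + inserted
#' sequence. INFO carries SVTYPE, SVLEN (negative for deletions) and END;
#' the single FORMAT field is GT (het -> 0/1, hom -> 1/1).
#'
#' @param calls data.frame as returned by [call_indels()]/[detect_indels()]
#'   (columns `chrom`, `pos1`, `svtype`, `length`, `alt_seq`, `ref_span`,
#'   `depth`, `genotype`), sorted by (chrom, pos1).
#' @param ref FASTA path or `DNAStringSet` (for anchor bases and contigs).
#' @param out output path.
#' @param sample sample name for the genotype column.
#' @return `out`, invisibly.
#' @export
write_vcf <- function(calls, ref, out, sample = "SAMPLE") {
  ref <- load_reference(ref)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=clipindel",
    paste0("##contig=<ID=", names(ref), ",length=",
           Biostrings::width(ref), ">"),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Signed length of the event\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the event\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Variant-supporting read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  lines <- hdr
  if (nrow(calls) > 0) {
    o <- order(calls$chrom, calls$pos1)
    calls <- calls[o, , drop = FALSE]
    recs <- vapply(seq_len(nrow(calls)), function(i) {
      x <- calls[i, ]
      if (!x$chrom %in% names(ref)) stop("unknown chromosome: ", x$chrom)
      clen <- length(ref[[x$chrom]])
      if (x$pos1 < 1 || x$pos1 > clen) stop("call position outside reference")
      anchor <- ref_slice(ref, x$chrom, x$pos1 - 1L, x$pos1)
      if (x$svtype == "DEL") {
        if (x$pos1 + x$length > clen) stop("call position outside reference")
        refa <- paste0(anchor, ref_slice(ref, x$chrom, x$pos1, x$pos1 + x$length))
        alta <- anchor
        svlen <- -x$length
        end <- x$pos1 + x$length
      } else {
        refa <- anchor
        alta <- paste0(anchor, x$alt_seq)
        svlen <- x$length
        end <- x$pos1
      }
      gt <- if (identical(x$genotype, "hom")) "1/1" else "0/1"
      paste(x$chrom, x$pos1, ".", refa, alta, ".", "PASS",
            sprintf("SVTYPE=%s;SVLEN=%d;END=%d;DP=%d",
                    x$svtype, svlen, end, as.integer(x$depth)),
            "GT", gt, sep = "\t")
    }, character(1))
    lines <- c(lines, recs)
  }
  writeLines(lines, out)
  invisible(out)
}

#' Read or write a truth/indel list (TSV)
#'
#' Tabular indel lists use columns `chrom`, `pos1`, `svtype`, `length`,
#' `sequence`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("truth file not found: ", path)
  tr <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos1", "svtype", "length", "sequence")
  if (!all(need %in% names(tr)))
    stop("truth TSV must have columns: ", paste(need, collapse = ", "))
  tr
}

#' @rdname read_truth
#' @param truth data.frame with the columns above.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# htslib writes a fixed 28-byte empty BGZF block at the end of every BAM;
# its absence means the file was truncated (samtools quickcheck's test)
.check_bgzf_eof <- function(path) {
  eof_magic <- as.raw(c(0x1f, 0x8b, 0x08, 0x04, 0x00, 0x00, 0x00, 0x00,
                        0x00, 0xff, 0x06, 0x00, 0x42, 0x43, 0x02, 0x00,
                        0x1b, 0x00, 0x03, 0x00, 0x00, 0x00, 0x00, 0x00,
                        0x00, 0x00, 0x00, 0x00))
  sz <- file.size(path)
  if (sz < 28) stop("truncated BAM (too small): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, sz - 28)
  tail28 <- readBin(con, "raw", 28L)
  if (!identical(tail28, eof_magic))
    stop("truncated BAM (missing BGZF EOF marker): ", path)
  invisible(TRUE)
}
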