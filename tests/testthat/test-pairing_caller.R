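test_that("glocal_align reproduces the worked examples", {
  a <- glocal_align("ACGTACGT", "ACGTACGT")
  expect_equal(a$score, 40L)  # 8 x match(+5), no gaps
  expect_equal(a$q_aln, a$t_aln)

  b <- glocal_align("ACGT", "TTTTACGTTTTT")
  expect_equal(b$score, 20L)
  expect_equal(c(b$t_start, b$t_end), c(4L, 8L))

  # 11-base target insertion relative to the query: one query gap,
  # score = 8*5 - 20 - 11*0
  d <- glocal_align("ACGTACGT", "ACGTTTTTTTTTTTTACGT")
  expect_equal(d$score, 20L)
  expect_equal(sum(strsplit(d$q_aln, "")[[1]] == "-"), 11L)

  expect_error(glocal_align("", "ACGT"), "empty")
  expect_error(glocal_align("ACGT", ""), "empty")
})

test_that("glocal scores equal the brute-force window oracle (random pairs)", {
  set.seed(61)
  for (i in 1:120) {
    q <- random_seq(sample(1:12, 1))
    t <- random_seq(sample(1:12, 1))
    expect_equal(glocal_align(q, t)$score, brute_glocal(q, t),
                 info = paste(q, t))
  }
  # second scoring scheme exercises gap extension
  p <- glocal_params(match = 3L, mismatch = -4L, gap_open = -6L,
                     gap_extend = -1L)
  for (i in 1:60) {
    q <- random_seq(sample(1:10, 1))
    t <- random_seq(sample(1:10, 1))
    expect_equal(glocal_align(q, t, p)$score,
                 brute_glocal(q, t, 3, -4, -6, -1), info = paste(q, t))
  }
})

test_that("glocal score is symmetric under reverse complement", {
  set.seed(62)
  for (i in 1:40) {
    q <- random_seq(sample(4:40, 1))
    t <- random_seq(sample(10:80, 1))
    expect_equal(glocal_align(q, t)$score,
                 glocal_align(revcomp(q), revcomp(t))$score)
  }
})

test_that("pair_clusters applies the span window", {
  mk <- function(bp, ori) structure(
    list(chrom = "sim1", orientation = ori, breakpoint0 = bp,
         seq = random_seq(40), depth_per_col = rep(12L, 40), depth = 12L,
         n_reads = 12L), class = "consensus_fragment")
  f <- mk(1000L, "FWD")
  expect_length(pair_clusters(list(f), list(mk(1060L, "BWD"))), 1L)
  expect_length(pair_clusters(list(f), list(mk(1002L, "BWD"))), 1L)
  expect_length(pair_clusters(list(f), list(mk(20000L, "BWD"))), 0L)
  expect_length(pair_clusters(list(f), list(mk(700L, "BWD"))), 0L)
  bx <- mk(1060L, "BWD"); bx$chrom <- "x"
  expect_error(pair_clusters(list(f), list(bx)), "chromosomes")
})

ref_join <- local({ set.seed(63); random_genome(30000L) })

test_that("join_pair merges overlapping fragments and rejects weak overlaps", {
  g <- toupper(as.character(ref_join[[1]]))
  # deletion of 300 bp at [10000, 10300): FWD clip carries post-deletion
  # sequence, BWD clip pre-deletion sequence
  fwd_seq <- substr(g, 10301, 10380)  # 80 bp after the deleted span
  bwd_seq <- substr(g, 9921, 10000)   # 80 bp before it
  mkf <- function(seq, bp, ori, n = 12L) structure(
    list(chrom = "sim1", orientation = ori, breakpoint0 = bp, seq = seq,
         depth_per_col = rep(n, nchar(seq)), depth = n, n_reads = n),
    class = "consensus_fragment")
  f <- mkf(fwd_seq, 10000L, "FWD")
  b <- mkf(bwd_seq, 10300L, "BWD")
  cs <- join_pair(f, b, ref_join)
  expect_s3_class(cs, "consensus_sequence")
  expect_gte(cs$identity, 0.99)
  expect_equal(cs$depth, 24L)
  # the merged sequence spans the junction: upstream flank + downstream
  junction <- paste0(substr(g, 9991, 10000), substr(g, 10301, 10310))
  expect_true(grepl(junction, cs$seq, fixed = TRUE))

  # a clean 20 bp suffix/prefix overlap joins; the same overlap at 80%
  # identity does not (ctx = 0 isolates the overlap itself)
  set.seed(65)
  ovl <- random_seq(20)
  f4 <- mkf(paste0(random_seq(100), ovl), 20000L, "FWD")
  b4 <- mkf(paste0(ovl, random_seq(100)), 20000L, "BWD")
  expect_s3_class(join_pair(f4, b4, ref_join, ctx = 0L),
                  "consensus_sequence")
  ov_bad <- strsplit(ovl, "")[[1]]
  pos <- sample(20, 4)
  ov_bad[pos] <- vapply(ov_bad[pos], function(bse)
    sample(setdiff(c("A", "C", "G", "T"), bse), 1), character(1))
  b5 <- mkf(paste0(paste(ov_bad, collapse = ""), random_seq(100)),
            20000L, "BWD")
  expect_null(join_pair(f4, b5, ref_join, ctx = 0L))

  # no overlap >= 20 aligned columns -> none
  f3 <- mkf(random_seq(15), 25000L, "FWD")
  b3 <- mkf(random_seq(15), 25004L, "BWD")
  expect_null(suppressWarnings(join_pair(f3, b3, ref_join,
                                         min_overlap = 200L)))
})

test_that("call_indels extracts size- and depth-filtered events", {
  g <- toupper(as.character(ref_join[[1]]))
  win <- fetch_reference_window(ref_join, "sim1", 10000L, 5000L)
  # consensus = window with 60 bp excised at [10000, 10060)
  cs <- list(chrom = "sim1",
             seq = paste0(substr(g, 9501, 10000), substr(g, 10061, 10500)),
             depth = 12L)
  calls <- call_indels(cs, win)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$svtype, "DEL")
  expect_equal(calls$length, 60L)
  expect_equal(calls$pos1, 10000L)
  expect_equal(calls$ref_span, substr(g, 10001, 10060))
  expect_equal(calls$genotype, "hom")

  # 49 bp excised: below the 50 bp bound -> no call
  cs49 <- list(chrom = "sim1",
               seq = paste0(substr(g, 9501, 10000), substr(g, 10050, 10500)),
               depth = 12L)
  expect_equal(nrow(call_indels(cs49, win)), 0L)

  # depth 9 -> no call (>=10 strict bound)
  cs9 <- cs; cs9$depth <- 9L
  expect_equal(nrow(call_indels(cs9, win)), 0L)
  cs10 <- cs; cs10$depth <- 10L
  expect_equal(nrow(call_indels(cs10, win)), 1L)

  # insertions: 70 bp novel sequence between two window halves
  ins <- random_seq(70)
  csi <- list(chrom = "sim1",
              seq = paste0(substr(g, 9501, 10000), ins,
                           substr(g, 10001, 10500)),
              depth = 15L)
  ci <- call_indels(csi, win)
  expect_equal(ci$svtype, "INS")
  expect_equal(ci$length, 70L)
  expect_equal(nchar(ci$alt_seq), 70L)

  # mismatched flank warns
  expect_warning(call_indels(cs, fetch_reference_window(ref_join, "sim1",
                                                        10000L, 4000L)),
                 "flank")
})

test_that("planted deletions round-trip through call_indels (property)", {
  set.seed(64)
  g <- toupper(as.character(ref_join[[1]]))
  for (i in 1:50) {
    L <- sample(50:5000, 1)
    bp <- sample(8000:12000, 1)
    win <- fetch_reference_window(ref_join, "sim1", bp, 5000L)
    keepL <- sample(200:450, 1); keepR <- sample(200:450, 1)
    cs <- list(chrom = "sim1",
               seq = paste0(substr(g, bp - keepL + 1, bp),
                            substr(g, bp + L + 1,
                                   min(bp + L + keepR, nchar(g)))),
               depth = 30L)
    calls <- call_indels(cs, win)
    del <- calls[calls$svtype == "DEL", , drop = FALSE]
    expect_equal(nrow(del), 1L, info = paste(L, bp))
    expect_equal(del$length, L, info = paste(L, bp))
    # the caller reports the leftmost score-equivalent placement; shift
    # the planted coordinate left while flanking bases repeat
    bpn <- bp
    while (bpn > 0 && substr(g, bpn, bpn) == substr(g, bpn + L, bpn + L))
      bpn <- bpn - 1L
    expect_equal(del$pos1, bpn, info = paste(L, bp))
  }
})

test_that("raising the depth threshold never increases the call count", {
  g <- toupper(as.character(ref_join[[1]]))
  win <- fetch_reference_window(ref_join, "sim1", 10000L, 5000L)
  cs <- list(chrom = "sim1",
             seq = paste0(substr(g, 9501, 10000), substr(g, 10101, 10500)),
             depth = 15L)
  n_prev <- Inf
  for (d in seq(10L, 20L, by = 2L)) {
    n <- nrow(call_indels(cs, win, min_depth = d))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("genotype_call applies the VAF 0.8 rule with inclusive boundary", {
  expect_equal(genotype_call(12, 0), "hom")   # v = 1.0
  expect_equal(genotype_call(12, 13), "het")  # v = 0.48
  expect_equal(genotype_call(16, 4), "hom")   # v = 0.80 boundary inclusive
  expect_equal(genotype_call(15, 4), "het")   # v = 0.789...
  expect_error(genotype_call(0, 0), "no reads")
})

test_that("count_spanning_reads requires both-side anchors and no clip", {
  reads <- rbind(
    make_read("a", pos0 = 960L, cigar = "100M", qlen = 100L),   # spans 1000
    make_read("b", pos0 = 985L, cigar = "100M", qlen = 100L),   # 15bp left
    make_read("c", pos0 = 950L, cigar = "50M50S", qlen = 100L), # clip at bp
    make_read("d", pos0 = 500L, cigar = "100M", qlen = 100L))   # far away
  expect_equal(count_spanning_reads(reads, "sim1", 1000L), 1L)
})
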