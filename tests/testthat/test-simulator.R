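test_that("sim_config validates its invariants", {
  expect_error(sim_config(bin_size = 1200L, indel_sizes = 1000L),
               "bin_size")
  expect_error(sim_config(base_error = 1), "rates")
  cfg <- sim_config()
  expect_equal(cfg$outer_distance, 500L)
  expect_equal(cfg$outer_sd, 50L)
  expect_equal(cfg$base_error, 0.02)
  expect_equal(cfg$indel_sizes, seq(100L, 1000L, by = 100L))
})

test_that("plant_indels places one event per bin and conserves sequence", {
  cfg <- sim_config(n_bins = 10L, n_del = 5L, n_ins = 5L, seed = 71L)
  sim <- plant_indels(cfg = cfg)
  expect_equal(nrow(sim$truth), 10L)
  expect_setequal(sim$truth$length, seq(100L, 1000L, by = 100L))
  # deletions shorten, insertions lengthen, by the planted lengths
  delta <- sum(sim$truth$length[sim$truth$svtype == "INS"]) -
    sum(sim$truth$length[sim$truth$svtype == "DEL"])
  expect_equal(nchar(sim$genome), 100000L + delta)
  # deletion sequences equal the excised reference span; flanks intact
  g <- toupper(as.character(sim$ref[[1]]))
  for (i in which(sim$truth$svtype == "DEL")) {
    p <- sim$truth$pos1[i]; L <- sim$truth$length[i]
    expect_equal(sim$truth$sequence[i], substr(g, p + 1L, p + L))
  }
  expect_error(plant_indels(random_genome(5000L),
                            sim_config(n_bins = 10L)), "overlapping bins")
})

test_that("repeat-of-flank insertions copy the upstream flank", {
  cfg <- sim_config(n_bins = 4L, indel_sizes = c(100L, 200L, 300L, 400L),
                    n_del = 0L, n_ins = 4L, repeat_flank = TRUE, seed = 72L)
  sim <- plant_indels(cfg = cfg)
  g <- toupper(as.character(sim$ref[[1]]))
  for (i in seq_len(4L)) {
    p <- sim$truth$pos1[i]; L <- sim$truth$length[i]
    expect_equal(sim$truth$sequence[i], substr(g, p - L + 1L, p))
  }
})

test_that("simulate_reads matches the coverage arithmetic and determinism", {
  cfg <- sim_config(n_bins = 2L, indel_sizes = 100L, n_del = 2L,
                    n_ins = 0L, coverage = 100, read_length = 150L,
                    mutation_rate = 0, base_error = 0, seed = 73L)
  sim <- plant_indels(cfg = cfg)
  sr <- simulate_reads(sim, cfg)
  glen <- nchar(sim$genome)
  expect_equal(nrow(sr$reads), 2L * floor(100 * glen / (2 * 150)))
  # error-free, mutation-free reads are exact substrings of the haplotype
  idx <- sample.int(nrow(sr$reads), 50L)
  for (i in idx) {
    s <- sr$reads$mut_start0[i]
    expect_identical(sr$reads$fwd_seq[i],
                     substr(sim$genome, s + 1L, s + 150L))
  }
  # same seed twice: byte-identical FASTQ
  dir <- withr::local_tempdir()
  write_fastq(simulate_reads(sim, cfg), file.path(dir, "a"))
  write_fastq(simulate_reads(sim, cfg), file.path(dir, "b"))
  expect_identical(readLines(file.path(dir, "a_1.fq")),
                   readLines(file.path(dir, "b_1.fq")))
  expect_identical(readLines(file.path(dir, "a_2.fq")),
                   readLines(file.path(dir, "b_2.fq")))
  cfg_bad <- cfg; cfg_bad$read_length <- 600L
  expect_error(simulate_reads(sim, cfg_bad), "outer_distance")
})

test_that("analytic_map emits aligner-faithful CIGARs", {
  cfg <- sim_config(n_bins = 2L, indel_sizes = c(300L, 600L),
                    n_del = 1L, n_ins = 1L, mutation_rate = 0,
                    base_error = 0, seed = 74L)
  sim <- plant_indels(cfg = cfg)
  del <- sim$events[sim$events$svtype == "DEL", ]
  ins <- sim$events[sim$events$svtype == "INS", ]
  expect_lt(del$p0, ins$p0)  # deletion is in bin 1: its junction is at p0
  rl <- 150L
  mk <- function(qname, mut_start0, mate) data.frame(
    qname = qname, mate = mate, mut_start0 = mut_start0,
    is_reverse = mate == 2L,
    fwd_seq = substr(sim$genome, mut_start0 + 1L, mut_start0 + rl),
    qual = strrep("D", rl), stringsAsFactors = FALSE)
  djunc <- del$p0  # no earlier event, mut coordinate == ref coordinate
  reads <- rbind(mk("p1", djunc - 500L, 1L),  # fully left -> 150M
                 mk("p1", djunc - 90L, 2L))   # 90 before junction -> 90M60S
  sr <- structure(list(reads = reads, chrom = sim$chrom, read_length = rl),
                  class = "sim_reads")
  sam <- analytic_map(sr, sim, cfg)
  expect_setequal(sam$cigar, c("150M", "90M60S"))
  r2 <- sam[sam$cigar == "90M60S", ]
  expect_equal(r2$pos1 - 1L + 90L, del$p0)  # clip at the left breakpoint
  expect_equal(bitwAnd(r2$flag, 16L), 16L)  # mate 2 mapped on reverse strand
})

test_that("reads inside a long insertion are unmapped with mapped mates", {
  cfg <- sim_config(n_bins = 1L, indel_sizes = 600L, n_del = 0L,
                    n_ins = 1L, mutation_rate = 0, base_error = 0,
                    seed = 75L)
  sim <- plant_indels(cfg = cfg)
  seg <- sim$segments
  ins_seg <- seg[seg$type == "inserted", ]
  rl <- 150L
  inside <- ins_seg$mut_start0 + 200L
  reads <- data.frame(
    qname = c("p1", "p1"), mate = c(1L, 2L),
    mut_start0 = c(inside - 400L, inside),
    is_reverse = c(FALSE, TRUE),
    fwd_seq = substring(sim$genome, c(inside - 400L, inside) + 1L,
                        c(inside - 400L, inside) + rl),
    qual = strrep("D", rl), stringsAsFactors = FALSE)
  sam <- analytic_map(structure(list(reads = reads, chrom = sim$chrom,
                                     read_length = rl),
                                class = "sim_reads"), sim, cfg)
  expect_equal(sum(bitwAnd(sam$flag, 4L) > 0L), 1L)
  um <- sam[bitwAnd(sam$flag, 4L) > 0L, ]
  expect_equal(um$cigar, "*")
  expect_equal(um$pos1, sam$pos1[bitwAnd(sam$flag, 4L) == 0L])  # at mate
  expect_error(analytic_map(structure(list(reads = reads[, 1:3],
                                           chrom = sim$chrom,
                                           read_length = rl),
                                      class = "sim_reads"), sim, cfg),
               "bookkeeping")
})

test_that("clip breakpoints equal truth breakpoints for all clipped reads", {
  cfg <- sim_config(n_bins = 4L, indel_sizes = c(100L, 300L, 500L, 700L),
                    n_del = 2L, n_ins = 2L, mutation_rate = 0,
                    base_error = 0, coverage = 30, seed = 76L)
  ds <- simulate_dataset(cfg)
  reads <- sam_as_reads(ds$sam)
  cls <- classify_reads(reads)
  frags <- extract_clips(reads[cls == "HQ_SOFTCLIPPED", , drop = FALSE])
  truth_bps <- sort(unique(c(
    ds$sim$truth$pos1,
    ds$sim$truth$pos1 + ifelse(ds$sim$truth$svtype == "DEL",
                               ds$sim$truth$length, 0L))))
  expect_true(all(frags$breakpoint0 %in% truth_bps))
  expect_true(all(truth_bps %in% frags$breakpoint0))
})

test_that("simulate_dataset writes the full file set", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_bins = 2L, indel_sizes = c(100L, 200L), n_del = 2L,
                    n_ins = 0L, coverage = 20, seed = 77L)
  ds <- simulate_dataset(cfg, out_dir = dir)
  expect_true(all(file.exists(file.path(dir, c(
    "ref.fa", "truth.tsv", "reads_1.fq", "reads_2.fq", "mapped.sam")))))
  tr <- read_truth(file.path(dir, "truth.tsv"))
  expect_equal(tr$length, ds$sim$truth$length)
  r <- read_alignments(file.path(dir, "mapped.sam"))
  expect_equal(nrow(r), nrow(ds$sam))
})
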