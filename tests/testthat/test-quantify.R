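# Junction pseudo-references, overhang-gated counting, normalization.

test_that("pseudo-reference spells donor flank followed by acceptor flank", {
  seq <- withr::with_seed(5, paste(sample(c("A", "C", "G", "T"), 3000,
                                          replace = TRUE), collapse = ""))
  gm <- structure(list(chroms = list(chr1 = seq)), class = "genome_model")
  call <- data.frame(circ_id = "c", chrom = "chr1", start = 1000L,
                     end = 2000L, strand = "+", stringsAsFactors = FALSE)
  ref <- build_junction_reference(call, gm, flank = 20L)
  expect_identical(ref$seq,
                   paste0(substring(seq, 1981, 2000), # genome[1980:2000)
                          substring(seq, 1001, 1020))) # genome[1000:1020)
  expect_equal(ref$flank, 20L)
  expect_equal(nchar(ref$seq), 40L)

  # minus strand equals the reverse complement of the plus construction
  call$strand <- "-"
  refm <- build_junction_reference(call, gm, flank = 20L)
  expect_identical(refm$seq, circnet:::revcomp(ref$seq))
})

test_that("flanks truncate symmetrically at chromosome edges", {
  seq <- strrep("ACGT", 100) # 400 nt
  gm <- structure(list(chroms = list(chr1 = seq)), class = "genome_model")
  call <- data.frame(circ_id = "edge", chrom = "chr1", start = 10L,
                     end = 390L, strand = "+", stringsAsFactors = FALSE)
  expect_warning(ref <- build_junction_reference(call, gm, flank = 50L),
                 "truncated")
  expect_equal(ref$flank, 10L)
  expect_equal(nchar(ref$seq), 20L)
})

test_that("junction counting honors the 6 nt overhang rule inclusively", {
  ref <- withr::with_seed(6, data.frame(
    circ_id = "c1",
    seq = paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                collapse = ""),
    flank = 75L, stringsAsFactors = FALSE))
  read_at <- function(s, len) substring(ref$seq, s + 1, s + len)
  # 6 nt left of center, crossing: counted (boundary inclusive)
  expect_equal(as.vector(count_junction_reads(ref, read_at(69, 81))), 1L)
  # exactly 6 on the right
  expect_equal(as.vector(count_junction_reads(ref, read_at(0, 81))), 1L)
  # 5 nt on one side: not counted
  expect_equal(as.vector(count_junction_reads(ref, read_at(70, 80))), 0L)
  expect_equal(as.vector(count_junction_reads(ref, read_at(0, 80))), 0L)
  # reverse-complemented read still counts
  rc <- circnet:::revcomp(read_at(60, 30))
  expect_equal(as.vector(count_junction_reads(ref, rc)), 1L)
  # non-matching read does not
  expect_equal(as.vector(count_junction_reads(ref, strrep("A", 30))), 0L)
})

test_that("lowering min_overhang never decreases counts (monotonicity)", {
  tp <- tiny_planted(seed = 61)
  sim <- simulate_split_alignments(tp$genome, tp$circs, seed = 62,
                                   n_background = 30, frac_short = 0.3)
  pl <- tp$circs[tp$circs$callable, ]
  refs <- suppressWarnings(build_junction_reference(
    data.frame(circ_id = pl$circ_id, chrom = pl$chrom, start = pl$start,
               end = pl$end, strand = pl$strand, stringsAsFactors = FALSE),
    tp$genome, flank = 150L))
  c6 <- count_junction_reads(refs, sim$reads$seq, min_overhang = 6L)
  c3 <- count_junction_reads(refs, sim$reads$seq, min_overhang = 3L)
  c20 <- count_junction_reads(refs, sim$reads$seq, min_overhang = 20L)
  expect_true(all(c3 >= c6))
  expect_true(all(c6 >= c20))
  # counting is idempotent
  expect_identical(c6, count_junction_reads(refs, sim$reads$seq))
})

test_that("synthetic counts equal truth depth minus sub-overhang reads", {
  tp <- tiny_planted(seed = 63)
  sim <- simulate_split_alignments(tp$genome, tp$circs, seed = 64,
                                   n_background = 30, frac_short = 0.2)
  pl <- tp$circs[tp$circs$callable, ]
  refs <- suppressWarnings(build_junction_reference(
    data.frame(circ_id = pl$circ_id, chrom = pl$chrom, start = pl$start,
               end = pl$end, strand = pl$strand, stringsAsFactors = FALSE),
    tp$genome, flank = 150L))
  counts <- count_junction_reads(refs, sim$reads$seq)
  short <- table(sim$reads$circ_id[sim$reads$sub_overhang])
  for (i in seq_len(nrow(pl))) {
    n_short <- if (pl$circ_id[i] %in% names(short))
      as.integer(short[pl$circ_id[i]]) else 0L
    expect_equal(unname(counts[pl$circ_id[i], 1]), pl$depth[i] - n_short)
    # the sub-overhang reads are flagged in the truth
    expect_equal(n_short, round(0.2 * pl$depth[i]))
  }
})

test_that("RPM and RPKM follow their definitions and scale invariance", {
  counts <- matrix(c(10, 0, 40, 90), 2,
                   dimnames = list(c("f1", "f2"), c("s1", "s2")))
  rpm <- normalize_expression(counts, lib_sizes = c(1e6, 2e6))
  expect_equal(rpm["f1", "s1"], 10)
  expect_equal(rpm["f2", "s2"], 45)
  expect_equal(rpm["f2", "s1"], 0) # zero count -> zero normalized
  rpkm <- normalize_expression(counts, lib_sizes = c(1e6, 2e6),
                               lengths = c(500, 2000), method = "rpkm")
  expect_equal(rpkm["f1", "s1"], 20)
  expect_equal(rpkm["f2", "s2"], 22.5)
  # doubling counts and library sizes leaves RPM unchanged
  expect_equal(normalize_expression(2 * counts, lib_sizes = 2 * c(1e6, 2e6)),
               rpm)
  # per-sample RPM sums to 1e6 x counted fraction of the library
  lib <- c(2e3, 4e3)
  expect_equal(colSums(normalize_expression(counts, lib_sizes = lib)),
               1e6 * colSums(counts) / lib)
  expect_error(normalize_expression(counts, lib_sizes = c(0, 1)),
               "library size")
})
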