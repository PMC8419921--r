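# Back-splice candidate detection, call filtering, SAM round trip.

seg_row <- function(rid, chrom, start, end, strand, qs, qe) {
  data.frame(read_id = rid, chrom = chrom, start = start, end = end,
             strand = strand, query_start = qs, query_end = qe,
             stringsAsFactors = FALSE)
}

test_that("head-to-tail rules classify constructed segment pairs", {
  # reversed genomic order, 5 kb apart, same chrom/strand -> one candidate
  ok <- rbind(seg_row("r1", "c1", 5000, 5075, "+", 0, 75),
              seg_row("r1", "c1", 100, 175, "+", 75, 150))
  cand <- find_chimeric_candidates(ok)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start, 100)
  expect_equal(cand$end, 5075)
  expect_equal(cand$n_reads, 1)

  cases <- list(
    diff_chrom = rbind(seg_row("r", "c1", 5000, 5075, "+", 0, 75),
                       seg_row("r", "c2", 100, 175, "+", 75, 150)),
    strand_mismatch = rbind(seg_row("r", "c1", 5000, 5075, "+", 0, 75),
                            seg_row("r", "c1", 100, 175, "-", 75, 150)),
    too_far = rbind(seg_row("r", "c1", 1500000, 1500075, "+", 0, 75),
                    seg_row("r", "c1", 100, 175, "+", 75, 150)),
    same_order = rbind(seg_row("r", "c1", 100, 175, "+", 0, 75),
                       seg_row("r", "c1", 5000, 5075, "+", 75, 150)))
  for (reason in names(cases)) {
    cand <- find_chimeric_candidates(cases[[reason]])
    expect_equal(nrow(cand), 0)
    expect_equal(attr(cand, "rejections")$reason, reason)
  }

  # minus strand: ascending genomic order in read order is the back-splice
  mk <- rbind(seg_row("m", "c1", 100, 175, "-", 0, 75),
              seg_row("m", "c1", 5000, 5075, "-", 75, 150))
  cand <- find_chimeric_candidates(mk)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$strand, "-")
  expect_equal(cand$start, 100)
  expect_equal(cand$end, 5075)
})

test_that("candidate detection equals the brute-force pair scan on random inputs", {
  for (s in 1:6) {
    aln <- random_alignments(300, seed = 100 + s)
    cand <- find_chimeric_candidates(aln, merge_tol = 0L)
    oracle <- oracle_candidates(aln)
    got <- sort(unlist(lapply(seq_len(nrow(cand)), function(i)
      paste(strsplit(cand$read_ids[i], ",")[[1]], cand$chrom[i],
            cand$strand[i], cand$start[i], cand$end[i]))))
    want <- sort(vapply(names(oracle$accepted), function(rid)
      paste(rid, paste(oracle$accepted[[rid]], collapse = " ")), ""))
    expect_identical(got, unname(want))
    rej <- attr(cand, "rejections")
    expect_identical(sort(rej$read_id), sort(names(oracle$rejected)))
    expect_identical(rej$reason[order(rej$read_id)],
                     unname(unlist(oracle$rejected[sort(names(oracle$rejected))])))
  }
})

test_that("input order permutation leaves the sorted candidate set unchanged", {
  aln <- random_alignments(200, seed = 42)
  c1 <- find_chimeric_candidates(aln)
  withr::with_seed(1, {
    c2 <- find_chimeric_candidates(aln[sample.int(nrow(aln)), ])
  })
  expect_identical(c1[, c("chrom", "strand", "start", "end", "n_reads",
                          "read_ids")],
                   c2[, c("chrom", "strand", "start", "end", "n_reads",
                          "read_ids")])
})

test_that("malformed segments are skipped with the read logged", {
  aln <- rbind(seg_row("good", "c1", 5000, 5075, "+", 0, 75),
               seg_row("good", "c1", 100, 175, "+", 75, 150),
               seg_row("bad", "c1", 500, 400, "+", 0, 75),
               seg_row("bad", "c1", 100, 175, "+", 75, 150))
  expect_warning(cand <- find_chimeric_candidates(aln), "malformed")
  expect_equal(nrow(cand), 1)
  rej <- attr(cand, "rejections")
  expect_true(any(rej$read_id == "bad" & rej$reason == "malformed"))
})

test_that("call filter applies inclusive boundaries and logs rejections", {
  tp <- tiny_planted(seed = 55)
  model <- splice_model()
  p <- tp$circs[tp$circs$callable, ][1, ]
  cand <- data.frame(chrom = p$chrom, strand = p$strand, start = p$start,
                     end = p$end, n_reads = 2L, read_ids = "a,b",
                     stringsAsFactors = FALSE)
  consensus_total <- select_junction(tp$genome, p$chrom, p$start, p$end,
                                     p$strand, splice_model(scale = 1))$score
  # rescale so the planted junction scores 10.0 (up to rounding in the
  # model arithmetic); the filter must pass at exactly the realized score
  at10 <- splice_model(scale = 10 / consensus_total)
  s10 <- select_junction(tp$genome, p$chrom, p$start, p$end, p$strand,
                         at10)$score
  expect_equal(s10, 10, tolerance = 1e-9)
  calls <- call_circrnas(cand, tp$genome, at10, min_score = s10)
  expect_equal(nrow(calls), 1) # 2 reads, score == threshold: both pass
  expect_equal(calls$junction_reads, 2L)

  just_below <- splice_model(scale = 9.99 / consensus_total)
  calls2 <- call_circrnas(cand, tp$genome, just_below)
  expect_equal(nrow(calls2), 0)
  expect_equal(attr(calls2, "rejections")$reason, "low_score")

  cand1 <- cand; cand1$n_reads <- 1L
  expect_warning(calls3 <- call_circrnas(cand1, tp$genome, at10,
                                         min_reads = 1L), "relaxed")
  expect_equal(nrow(calls3), 1)
  calls4 <- call_circrnas(cand1, tp$genome, at10)
  expect_equal(nrow(calls4), 0)
  expect_equal(attr(calls4, "rejections")$reason, "too_few_reads")
})

test_that("relaxing both filters yields a superset of default calls", {
  tp <- tiny_planted(seed = 71)
  sim <- simulate_split_alignments(tp$genome, tp$circs, seed = 72,
                                   n_background = 20)
  f <- tempfile(fileext = ".sam"); write_sam(sim, f)
  aln <- read_split_alignments(f)
  cand <- find_chimeric_candidates(aln)
  strict <- call_circrnas(cand, tp$genome)
  loose <- suppressWarnings(
    call_circrnas(cand, tp$genome, min_reads = 0L, min_score = -Inf))
  strict_key <- paste(strict$chrom, strict$start, strict$end, strict$strand)
  loose_key <- paste(loose$chrom, loose$start, loose$end, loose$strand)
  expect_true(all(strict_key %in% loose_key))
  expect_gt(nrow(loose), nrow(strict))
})

test_that("SAM round trip reproduces the simulated segments", {
  tp <- tiny_planted(seed = 81)
  sim <- simulate_split_alignments(tp$genome, tp$circs, seed = 82,
                                   n_background = 10)
  f <- tempfile(fileext = ".sam"); write_sam(sim, f)
  aln <- read_split_alignments(f)
  # every junction read of a callable planting appears as two segments
  # flanking its junction
  pl <- tp$circs[tp$circs$callable, ]
  for (i in seq_len(nrow(pl))) {
    p <- pl[i, ]
    rids <- sprintf("%s_r%02d", p$circ_id, seq_len(p$depth))
    seg <- aln[aln$read_id %in% rids, ]
    expect_equal(nrow(seg), 2L * p$depth)
    expect_true(all(seg$chrom == p$chrom))
    expect_true(all(seg$strand == p$strand))
    # implied junction equals the planted coordinates for every read
    cand <- find_chimeric_candidates(seg)
    expect_equal(nrow(cand), 1)
    expect_equal(cand$start, p$start)
    expect_equal(cand$end, p$end)
    expect_equal(cand$n_reads, p$depth)
  }
})

test_that("hard-clipped supplementary records give the same query intervals", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:c1\tLN:10000",
    sprintf("r1\t0\tc1\t5001\t60\t75M75S\t*\t0\t0\t%s\t*",
            strrep("A", 150)),
    sprintf("r1\t2048\tc1\t101\t60\t75H75M\t*\t0\t0\t%s\t*",
            strrep("A", 75))), sam)
  aln <- read_split_alignments(sam)
  expect_equal(aln$query_start, c(0L, 75L))
  expect_equal(aln$query_end, c(75L, 150L))
  cand <- find_chimeric_candidates(aln)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start, 100)
  expect_equal(cand$end, 5075)
})
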