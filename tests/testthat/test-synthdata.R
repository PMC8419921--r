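# Synthetic-data generator: plantings, decoy inventory, expression truth,
# target tables, determinism.

test_that("plantings satisfy the candidate rules; decoys record one violation", {
  tp <- tiny_planted(seed = 41)
  circs <- tp$circs
  true_c <- circs[circs$callable, ]
  expect_equal(nrow(true_c), 8)
  # all three candidate rules hold by construction
  expect_true(all(true_c$end - true_c$start > 0))
  expect_true(all(true_c$end - true_c$start <= 1e6))
  expect_true(all(true_c$strand %in% c("+", "-")))
  # GT..AG on the annotated strand at the chosen donor/acceptor
  for (i in seq_len(nrow(true_c))) {
    p <- true_c[i, ]
    seq <- tp$genome$chroms[[p$chrom]]
    if (p$strand == "+") {
      expect_equal(substring(seq, p$end + 1, p$end + 2), "GT")
      expect_equal(substring(seq, p$start - 1, p$start), "AG")
    } else {
      expect_equal(substring(seq, p$start - 1, p$start), "AC")
      expect_equal(substring(seq, p$end + 1, p$end + 2), "CT")
    }
  }
  dec <- circs[!circs$callable, ]
  expect_equal(nrow(dec), 6)
  expect_setequal(dec$decoy_type,
                  c("diff_chrom", "too_far", "opposite_strand", "same_order",
                    "one_read", "weak_motif"))
  expect_equal(unname(dec$reason[dec$decoy_type == "too_far"]), "too_far")
  expect_true(dec$end[dec$decoy_type == "too_far"] -
              dec$start[dec$decoy_type == "too_far"] > 1e6)
  expect_equal(dec$depth[dec$decoy_type == "one_read"], 1L)
  expect_error(plant_circrnas(generate_genome(tiny_genome_config(), 1),
                              n_true = 500, seed = 1),
               "insufficient exon-pair slots")
})

test_that("simulated SAM output is deterministic and structurally sound", {
  tp <- tiny_planted(seed = 43)
  s1 <- simulate_split_alignments(tp$genome, tp$circs, seed = 9,
                                  n_background = 25)
  s2 <- simulate_split_alignments(tp$genome, tp$circs, seed = 9,
                                  n_background = 25)
  f1 <- tempfile(); f2 <- tempfile()
  write_sam(s1, f1); write_sam(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # depth junction reads per planting, as two-segment records
  p1 <- tp$circs[1, ]
  recs <- s1$sam[startsWith(s1$sam$qname, paste0(p1$circ_id, "_")), ]
  expect_equal(nrow(recs), 2L * p1$depth)
  expect_true(all(table(recs$qname) == 2))
  # zero plantings -> single-segment records only
  s0 <- simulate_split_alignments(tp$genome, tp$circs[0, ], seed = 9,
                                  n_background = 25)
  expect_equal(nrow(s0$sam), 25)
  expect_true(all(table(s0$sam$qname) == 1))
})

test_that("sub-overhang reads are emitted unsplit and flagged in the truth", {
  tp <- tiny_planted(seed = 45)
  sim <- simulate_split_alignments(tp$genome, tp$circs, seed = 10,
                                   n_background = 0, frac_short = 0.2)
  short <- sim$reads[sim$reads$sub_overhang, ]
  expect_gt(nrow(short), 0)
  expect_true(all(short$left_overhang == 5L))
  # present in the SAM as a single clipped record
  recs <- sim$sam[sim$sam$qname %in% short$read_id, ]
  expect_equal(nrow(recs), nrow(short))
  expect_true(all(grepl("S", recs$cigar)))
})

test_that("noiseless expression realizes planted fold changes and correlations", {
  tp <- tiny_planted(seed = 47)
  es <- simulate_expression(tp$truth, noise_sd = 0, seed = 11)
  f <- tp$truth$features
  counts <- do.call(rbind, lapply(es$matrices, `[[`, "counts"))
  rownames(counts) <- unlist(lapply(es$matrices,
                                    function(m) rownames(m$counts)))
  ratio <- log2(rowMeans(counts[, es$groups == "B"]) /
                rowMeans(counts[, es$groups == "A"]))
  expect_equal(unname(ratio[f$feature_id]), f$lfc, tolerance = 1e-12)
  # within-triplet Pearson r on the raw counts is exactly 1 (ceRNA-mRNA)
  # and negative for the miRNA
  for (i in seq_len(nrow(tp$truth$triplets))) {
    t <- tp$truth$triplets[i, ]
    expect_equal(cor(counts[t$cerna_id, ], counts[t$mrna_id, ]), 1,
                 tolerance = 1e-12)
    # the miRNA is exactly anti-collinear on the log scale
    expect_equal(cor(log2(counts[t$cerna_id, ]), log2(counts[t$mirna_id, ])),
                 -1, tolerance = 1e-12)
  }
  # counts are non-negative in all regimes
  es_n <- simulate_expression(tp$truth, seed = 12)
  expect_true(all(do.call(rbind, lapply(es_n$matrices, `[[`, "counts")) >= 0))
  expect_error(simulate_expression(tp$truth, noise_sd = -1), "noise_sd")
})

test_that("target tables equal an exhaustive seed scan and contain planted edges", {
  tp <- tiny_planted(seed = 49)
  tab <- emit_target_tables(tp$genome, tp$truth)
  # planted triplet edges all present
  for (i in seq_len(nrow(tp$truth$triplets))) {
    t <- tp$truth$triplets[i, ]
    expect_true(any(tab$mirna_id == t$mirna_id & tab$target_id == t$cerna_id))
    expect_true(any(tab$mirna_id == t$mirna_id & tab$target_id == t$mrna_id))
  }
  # equals the brute-force sliding-window oracle for a sample of pairs
  f <- tp$truth$features
  mirs <- f$feature_id[f$class == "miRNA"][1:4]
  tgts <- f$feature_id[f$class == "mRNA"][1:5]
  for (m in mirs) {
    mseq <- transcript_seq(tp$genome, m)
    for (tg in tgts) {
      want <- oracle_seed_sites(mseq, transcript_seq(tp$genome, tg))
      got <- tab[tab$mirna_id == m & tab$target_id == tg,
                 c("position", "site_type")]
      expect_equal(got$position, want$position)
      expect_equal(got$site_type, want$site_type)
    }
  }
  # chance seed matches of DE miRNAs have been scrubbed from DE transcripts
  de_mir <- f$feature_id[f$class == "miRNA" & f$lfc != 0]
  de_tgt <- f$feature_id[f$class != "miRNA" & f$lfc != 0]
  planted <- paste(tp$truth$triplets$mirna_id,
                   c(tp$truth$triplets$cerna_id, tp$truth$triplets$mrna_id))
  hits <- tab[tab$mirna_id %in% de_mir & tab$target_id %in% de_tgt, ]
  expect_true(all(paste(hits$mirna_id, hits$target_id) %in% planted))
})

test_that("null-calibration truth produces uniform screening p values", {
  # no planted DE: the p < 0.01 rate matches the nominal level within
  # Monte-Carlo error (pooled over replicate seeds)
  hits <- 0L; total <- 0L
  for (s in 1:8) {
    truth <- null_expression_truth(500, seed = s)
    es <- simulate_expression(truth, seed = 100 + s)
    m <- normalize_expression(es$matrices$mRNA$counts)
    de <- de_screen(m, es$groups)
    hits <- hits + sum(de$p_value < 0.01, na.rm = TRUE)
    total <- total + nrow(de)
  }
  mc_sd <- sqrt(0.01 * 0.99 / total)
  expect_lt(abs(hits / total - 0.01), 3 * mc_sd)
})
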