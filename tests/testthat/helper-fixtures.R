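# Small shared fixtures, built in code. The tiny configuration keeps unit
# tests fast; acceptance tests build the full-size study configuration
# themselves.

tiny_genome_config <- function() {
  genome_config(chrom_lengths = c(chr1 = 3e4, chr2 = 3e4),
                n_mrna = 10, n_lncrna = 5, n_mirna = 8)
}

tiny_expr_config <- function(...) {
  expr_config(n_trip_circ = 2, n_trip_lnc = 2, de_mrna = 2, de_lncrna = 1,
              de_mirna = 2, de_circ = 2, ...)
}

tiny_pipeline_config <- function(seed = 1L, ...) {
  pipeline_config(seed = seed, n_true = 8, n_decoys = 6, n_background = 40,
                  genome = tiny_genome_config(), expr = tiny_expr_config(),
                  ...)
}

# planted tiny genome + circs + truth, deterministic
tiny_planted <- function(seed = 1L) {
  gm <- generate_genome(tiny_genome_config(), seed = seed)
  pl <- plant_circrnas(gm, n_true = 8, n_decoys = 6, seed = seed + 1L)
  et <- plant_expression_truth(pl$genome, pl$circs, tiny_expr_config(),
                               seed = seed + 2L)
  list(genome = et$genome, circs = pl$circs, truth = et$truth)
}

# random split-alignment table: two-segment reads with random geometry,
# used for oracle-equivalence checks
random_alignments <- function(n_reads, seed) {
  withr::with_seed(seed, {
    chroms <- c("c1", "c2")
    rows <- lapply(seq_len(n_reads), function(i) {
      rid <- sprintf("rr%04d", i)
      ch <- sample(chroms, 2, replace = TRUE)
      st <- sample(c("+", "-"), 2, replace = TRUE)
      pos <- sample.int(2e6, 2)
      w <- sample(30:120, 2)
      data.frame(read_id = rid, chrom = ch, start = pos, end = pos + w,
                 strand = st, query_start = c(0L, w[1]),
                 query_end = c(w[1], w[1] + w[2]), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
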