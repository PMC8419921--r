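#!/usr/bin/env Rscript
# Stage 3 — circular-junction quantification and expression normalization.
#
# Builds the junction pseudo-references (donor flank ++ acceptor flank,
# junction at the center), counts junction-spanning reads under the
# >= 6 nt overhang rule, then simulates the paired two-group expression
# matrices for all RNA classes and normalizes them (RPM for miRNA and
# circRNA junctions, RPKM for mRNA/lncRNA).

suppressMessages(library(circnet))
out <- "results"
SEED <- 1L

# deterministic regeneration of the stage-1 objects (same seeds)
gm0 <- generate_genome(genome_config(), seed = SEED)
pl <- plant_circrnas(gm0, n_true = 50, n_decoys = 20, seed = SEED + 1L,
                     depth = 10)
et <- plant_expression_truth(pl$genome, pl$circs, expr_config(),
                             seed = SEED + 2L)
sim <- simulate_split_alignments(et$genome, pl$circs, seed = SEED + 3L,
                                 n_background = 300)
calls <- local({
  aln <- read_split_alignments(file.path(out, "alignments.sam"))
  call_circrnas(find_chimeric_candidates(aln), et$genome)
})

refs <- suppressWarnings(build_junction_reference(calls, et$genome,
                                                  flank = 150L))
jc <- count_junction_reads(refs, sim$reads$seq)
write.table(jc, file.path(out, "junction_counts.tsv"), sep = "\t",
            quote = FALSE, col.names = NA)

truths <- pl$circs[pl$circs$callable, ]
m <- match(paste(calls$chrom, calls$start, calls$end, calls$strand),
           paste(truths$chrom, truths$start, truths$end, truths$strand))
cat(sprintf("junction counts equal planted depth for %d/%d circRNAs\n",
            sum(jc[, 1] == truths$depth[m]), nrow(calls)))

es <- simulate_expression(et$truth, seed = SEED + 4L)
for (cls in names(es$matrices)) {
  cm <- es$matrices[[cls]]
  method <- if (cls %in% c("miRNA", "circRNA")) "rpm" else "rpkm"
  nm <- normalize_expression(cm$counts, lib_sizes = cm$lib_sizes,
                             lengths = cm$lengths, method = method)
  write.table(round(nm, 4), file.path(out, sprintf("norm_%s.tsv", cls)),
              sep = "\t", quote = FALSE, col.names = NA)
  cat(sprintf("%-8s %4d features x %d samples (%s)\n", cls, nrow(nm),
              ncol(nm), toupper(method)))
}
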