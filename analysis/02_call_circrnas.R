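#!/usr/bin/env Rscript
# Stage 2 — back-splice circRNA calling from the simulated alignments.
#
# Reads the SAM written by stage 1, forms head-to-tail candidates (same
# chromosome, <= 1 Mb apart, same strand, reversed order), picks the
# maximum-splice-strength junction per candidate and applies the call
# filter (>= 2 reads, score >= 10). Reports recovery against the planted
# truth and the per-rule rejection tally.

suppressMessages(library(circnet))
out <- "results"

gm <- read_genome(file.path(out, "genome.fa"), file.path(out, "annotation.tsv"))
planted <- read.delim(file.path(out, "planted_circs.tsv"))

aln <- read_split_alignments(file.path(out, "alignments.sam"))
cand <- find_chimeric_candidates(aln)
calls <- call_circrnas(cand, gm)

write_calls_bed(calls, file.path(out, "calls.bed"))
write.table(attr(cand, "rejections"), file.path(out, "read_rejections.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(attr(calls, "rejections"), file.path(out, "call_rejections.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

truths <- planted[planted$callable, ]
ck <- paste(calls$chrom, calls$start, calls$end, calls$strand)
tk <- paste(truths$chrom, truths$start, truths$end, truths$strand)
cat(sprintf("candidates: %d | calls: %d\n", nrow(cand), nrow(calls)))
cat(sprintf("planted junctions recovered at exact coordinates: %d/%d (extras: %d)\n",
            sum(tk %in% ck), nrow(truths), sum(!ck %in% tk)))
cat("read-level rejections by rule:\n")
print(table(attr(cand, "rejections")$reason))
cat("candidate-level rejections:\n")
print(table(attr(calls, "rejections")$reason))
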