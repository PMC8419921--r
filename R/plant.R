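## Plant circRNA back-splice junctions on annotated exon boundaries, plus
## decoys each violating exactly one candidate/call rule. The decoy
## inventory records the reason every decoy must be rejected downstream.

DECOY_TYPES <- c("diff_chrom", "too_far", "opposite_strand", "same_order",
                 "one_read", "weak_motif")
## reason string each decoy must be rejected with, and the stage that logs it
DECOY_REASON <- c(diff_chrom = "diff_chrom", too_far = "too_far",
                  opposite_strand = "strand_mismatch", same_order = "same_order",
                  one_read = "too_few_reads", weak_motif = "low_score")

#' Plant circRNAs (and decoys) on a toy genome
#'
#' True plantings sit on internal exon-boundary pairs of multi-exon genes,
#' so the back-splice donor and acceptor carry full consensus splice
#' windows; each is callable (same chromosome, separation below 1 Mb, same
#' strand, reversed order, `depth` supporting reads, consensus motifs).
#' Decoys cycle through six single-rule violations: `diff_chrom`, `too_far`
#' (> 1 Mb), `opposite_strand`, `same_order`, `one_read` (single supporting
#' read) and `weak_motif` (junction in motif-free sequence). A `too_far`
#' decoy needs more room than the gene-bearing chromosomes offer, so a
#' gene-free random scaffold chromosome is appended to the genome for it
#' (mirroring the unplaced scaffolds of real assemblies).
#'
#' @param gm a `genome_model` from [generate_genome()].
#' @param n_true number of callable plantings.
#' @param n_decoys number of decoys (types cycled in the order above).
#' @param seed integer seed.
#' @param depth junction-read depth per true planting (default 10).
#' @param scaffold_len length of the decoy scaffold chromosome, used only
#'   when a `too_far` decoy is requested (default 1.6 Mb).
#' @return list with `genome` (possibly extended), `circs` (planted circRNA
#'   table: `circ_id`, `chrom`, `start`, `end`, `strand`, `gene_id`,
#'   `exon_from`, `exon_to`, `depth`, `callable`, `decoy_type`, `reason`).
#' @export
plant_circrnas <- function(gm, n_true = 50L, n_decoys = 20L, seed = 1L,
                           depth = 10L, scaffold_len = 1.6e6) {
  stopifnot(inherits(gm, "genome_model"), depth >= 1)
  with_seed(seed, {
    slots <- circ_slots(gm)
    decoy_types <- if (n_decoys > 0)
      DECOY_TYPES[(seq_len(n_decoys) - 1L) %% length(DECOY_TYPES) + 1L]
      else character(0)
    ## slot-consuming entries: true + opposite_strand/same_order/one_read/
    ## weak_motif decoys (diff_chrom and too_far live off-slot)
    n_slot <- n_true + sum(decoy_types %in%
                             c("opposite_strand", "same_order", "one_read",
                               "weak_motif"))
    if (n_slot > nrow(slots))
      stop(sprintf("insufficient exon-pair slots: need %d, have %d",
                   n_slot, nrow(slots)))
    shuffled <- slots[sample.int(nrow(slots)), , drop = FALSE]
    ## weak-motif decoys shift both breakpoints 30 nt inward, so they need
    ## multi-exon slots whose span still accommodates full junction reads
    n_weak <- sum(decoy_types == "weak_motif")
    is_multi <- shuffled$exon_to > shuffled$exon_from
    if (n_weak > sum(is_multi))
      stop("insufficient multi-exon slots for weak-motif decoys")
    weak_rows <- which(is_multi)[seq_len(n_weak)]
    other_rows <- setdiff(seq_len(nrow(shuffled)),
                          weak_rows)[seq_len(n_slot - n_weak)]
    picked <- shuffled[other_rows, , drop = FALSE]
    weak_picked <- shuffled[weak_rows, , drop = FALSE]

    rows <- list(); si <- 0L
    for (i in seq_len(n_true)) {
      si <- si + 1L; s <- picked[si, ]
      rows[[length(rows) + 1L]] <- data.frame(
        circ_id = sprintf("pcirc%03d", i), chrom = s$chrom, start = s$start,
        end = s$end, strand = s$strand, gene_id = s$gene_id,
        exon_from = s$exon_from, exon_to = s$exon_to, depth = depth,
        callable = TRUE, decoy_type = NA_character_, reason = NA_character_,
        stringsAsFactors = FALSE)
    }
    need_scaffold <- any(decoy_types == "too_far")
    if (need_scaffold) {
      gm$chroms <- c(gm$chroms, scaffold = random_dna(scaffold_len))
    }
    for (k in seq_along(decoy_types)) {
      ty <- decoy_types[k]
      id <- sprintf("decoy%02d", k)
      if (ty %in% c("opposite_strand", "same_order", "one_read", "weak_motif")) {
        if (ty == "weak_motif") {
          s <- weak_picked[1, ]; weak_picked <- weak_picked[-1, , drop = FALSE]
        } else {
          si <- si + 1L; s <- picked[si, ]
        }
        start <- s$start; end <- s$end; chrom <- s$chrom; strand <- s$strand
        dep <- if (ty == "one_read") 1L else depth
        if (ty == "weak_motif") {
          ## shift both breakpoints into exon interiors: geometry valid,
          ## motif-free sequence at the junction
          start <- start + 30L; end <- end - 30L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          circ_id = id, chrom = chrom, start = start, end = end,
          strand = strand, gene_id = s$gene_id, exon_from = s$exon_from,
          exon_to = s$exon_to, depth = dep, callable = FALSE,
          decoy_type = ty, reason = unname(DECOY_REASON[ty]),
          stringsAsFactors = FALSE)
      } else if (ty == "diff_chrom") {
        ## segments on two different chromosomes; coordinates stored as
        ## start on chrom A (acceptor side) and end on chrom B (donor side)
        stopifnot(length(gm$chroms) >= 2)
        c2 <- names(gm$chroms)[1:2]
        rows[[length(rows) + 1L]] <- data.frame(
          circ_id = id, chrom = paste(c2, collapse = "|"),
          start = 5000L + 137L * k, end = 7000L + 211L * k, strand = "+",
          gene_id = NA, exon_from = NA, exon_to = NA, depth = depth,
          callable = FALSE, decoy_type = ty,
          reason = unname(DECOY_REASON[ty]), stringsAsFactors = FALSE)
      } else { # too_far
        start <- 1000L + 977L * k
        rows[[length(rows) + 1L]] <- data.frame(
          circ_id = id, chrom = "scaffold", start = start,
          end = start + 1500000L, strand = "+", gene_id = NA,
          exon_from = NA, exon_to = NA, depth = depth, callable = FALSE,
          decoy_type = ty, reason = unname(DECOY_REASON[ty]),
          stringsAsFactors = FALSE)
      }
    }
    circs <- do.call(rbind, rows)
    list(genome = gm, circs = circs)
  })
}

## enumerate internal exon-boundary pairs usable as back-splice junctions:
## for a gene with k exons, genomic exons i <= j with i, j in 2..(k-1)
## (both boundaries internal on either strand); one slot per (gene, i, j)
circ_slots <- function(gm) {
  out <- list()
  for (gid in unique(gm$exons$gene_id)) {
    e <- gm$exons[gm$exons$gene_id == gid, ]
    k <- nrow(e)
    if (k < 3) next
    for (i in 2:(k - 1)) for (j in i:(k - 1)) {
      out[[length(out) + 1L]] <- data.frame(
        gene_id = gid, chrom = e$chrom[1], strand = e$strand[1],
        start = e$start[i], end = e$end[j], exon_from = i, exon_to = j,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), exon_from = integer(),
                      exon_to = integer()))
  do.call(rbind, out)
}
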