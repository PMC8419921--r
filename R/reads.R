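## Simulate split-alignment read evidence for planted circRNAs and decoys.
## Junction reads are emitted as two partial alignments of one read
## (primary + supplementary SAM records sharing QNAME); linear background
## reads and sub-overhang junction reads are single-segment records.

#' Simulate split-alignment reads for planted circRNAs
#'
#' For every planting, emits `depth` reads whose sequence crosses the
#' back-splice junction: the donor-side flank is followed by the
#' acceptor-side flank, so the two partial alignments appear in reverse
#' genomic order (strand-aware). Decoys emit reads realizing their single
#' rule violation. A configurable fraction of each true planting's reads
#' carries a 5 nt overhang: too short to satisfy the junction-count rule,
#' and emitted as a single clipped alignment (an aligner would not split on
#' 5 nt).
#'
#' @param gm `genome_model` (as returned inside [plant_circrnas()]).
#' @param circs planted circRNA table from [plant_circrnas()].
#' @param read_len read length in nt (default 150).
#' @param seed integer seed.
#' @param n_background number of linear single-segment background reads.
#' @param frac_short fraction of each callable planting's reads emitted with
#'   a 5 nt overhang (default 0).
#' @param min_overhang_sim minimum simulated overhang for compliant junction
#'   reads (default 20 nt).
#' @return list with `alignments` (a `split_alignments` data frame),
#'   `sam` (SAM record table for [write_sam()]), and `reads`
#'   (`read_id`, `circ_id`, `seq`, `left_overhang`, `sub_overhang`).
#' @export
simulate_split_alignments <- function(gm, circs, read_len = 150L, seed = 1L,
                                      n_background = 300L, frac_short = 0,
                                      min_overhang_sim = 20L) {
  stopifnot(read_len >= 2 * min_overhang_sim)
  if (min_overhang_sim < 6)
    stop("min_overhang_sim below the junction-count overhang rule")
  with_seed(seed, {
    sam <- list(); reads <- list(); aln <- list()
    emit <- function(rec) sam[[length(sam) + 1L]] <<- rec
    for (i in seq_len(nrow(circs))) {
      p <- circs[i, ]
      ty <- if (is.na(p$decoy_type)) "true" else p$decoy_type
      n_short <- if (ty == "true") round(frac_short * p$depth) else 0L
      n_full <- p$depth - n_short
      ## cap overhangs at the circle span so reads stay within one lap of
      ## the junction on either side; span - 1 because an overhang equal to
      ## the span would collapse the two segments onto one start position
      span <- if (ty %in% c("true", "one_read", "weak_motif"))
        abs(p$end - p$start) else read_len + 1L
      hi <- min(read_len - min_overhang_sim, span - 1L)
      lo <- max(min_overhang_sim, read_len - hi)
      if (lo > hi) stop("overhang profile incompatible with read length ",
                        "for ", p$circ_id, " (span ", span, ")")
      Ls <- sample(seq(lo, hi), n_full, replace = TRUE)
      for (r in seq_len(n_full)) {
        rid <- sprintf("%s_r%02d", p$circ_id, r)
        L <- Ls[r]; R <- read_len - L
        recs <- junction_read(gm, p, ty, rid, L, R, read_len)
        for (rec in recs$sam) sam[[length(sam) + 1L]] <- rec
        reads[[length(reads) + 1L]] <- list(
          read_id = rid, circ_id = p$circ_id, seq = recs$seq,
          left_overhang = L, sub_overhang = FALSE)
      }
      for (r in seq_len(n_short)) {
        rid <- sprintf("%s_s%02d", p$circ_id, r)
        L <- 5L; R <- read_len - L
        rd <- junction_read_seq(gm, p, L, R)
        ## aligner keeps the long acceptor-side block, clips the 5 nt
        if (p$strand == "+") {
          rec <- sam_rec(rid, 0L, p$chrom, p$start + 1L,
                         sprintf("%dS%dM", L, R), rd)
        } else {
          rec <- sam_rec(rid, 16L, p$chrom, p$end - R + 1L,
                         sprintf("%dM%dS", R, L), revcomp(rd))
        }
        sam[[length(sam) + 1L]] <- rec
        reads[[length(reads) + 1L]] <- list(
          read_id = rid, circ_id = p$circ_id, seq = rd,
          left_overhang = L, sub_overhang = TRUE)
      }
    }
    ## linear background reads: contiguous genomic fragments
    gene_chroms <- names(gm$chroms)[!names(gm$chroms) %in% "scaffold"]
    for (b in seq_len(n_background)) {
      rid <- sprintf("bg%04d", b)
      chrom <- sample(gene_chroms, 1)
      pos <- sample.int(nchar(gm$chroms[[chrom]]) - read_len, 1) - 1L
      minus <- runif(1) < 0.5
      frag <- subseq0(gm$chroms[[chrom]], pos, pos + read_len)
      rd <- if (minus) revcomp(frag) else frag
      sam[[length(sam) + 1L]] <- sam_rec(rid, if (minus) 16L else 0L, chrom,
                                         pos + 1L, sprintf("%dM", read_len),
                                         frag)
      reads[[length(reads) + 1L]] <- list(
        read_id = rid, circ_id = NA_character_, seq = rd,
        left_overhang = NA_integer_, sub_overhang = FALSE)
    }
    sam <- bind_rows_fast(sam)
    reads <- bind_rows_fast(reads)
    list(sam = sam, reads = reads, chrom_lengths = nchar(gm$chroms))
  })
}

## full junction-crossing read sequence (original read orientation)
junction_read_seq <- function(gm, p, L, R) {
  seq <- gm$chroms[[p$chrom]]
  if (p$strand == "+") {
    paste0(subseq0(seq, p$end - L, p$end), subseq0(seq, p$start, p$start + R))
  } else {
    paste0(revcomp(subseq0(seq, p$start, p$start + L)),
           revcomp(subseq0(seq, p$end - R, p$end)))
  }
}

## SAM record pair (primary + supplementary) for one junction-type read
junction_read <- function(gm, p, ty, rid, L, R, read_len) {
  if (ty %in% c("true", "one_read", "weak_motif")) {
    rd <- junction_read_seq(gm, p, L, R)
    if (p$strand == "+") {
      r1 <- sam_rec(rid, 0L, p$chrom, p$end - L + 1L,
                    sprintf("%dM%dS", L, R), rd)
      r2 <- sam_rec(rid, 2048L, p$chrom, p$start + 1L,
                    sprintf("%dS%dM", L, R), rd)
    } else {
      rc <- revcomp(rd)
      r1 <- sam_rec(rid, 16L, p$chrom, p$start + 1L,
                    sprintf("%dS%dM", R, L), rc)
      r2 <- sam_rec(rid, 2048L + 16L, p$chrom, p$end - R + 1L,
                    sprintf("%dM%dS", R, L), rc)
    }
    return(list(sam = list(r1, r2), seq = rd))
  }
  seq1 <- gm$chroms[[strsplit(p$chrom, "|", fixed = TRUE)[[1]][1]]]
  if (ty == "too_far") {
    ## valid reversed geometry, separation > 1 Mb
    rd <- paste0(subseq0(seq1, p$end - L, p$end),
                 subseq0(seq1, p$start, p$start + R))
    r1 <- sam_rec(rid, 0L, "scaffold", p$end - L + 1L,
                  sprintf("%dM%dS", L, R), rd)
    r2 <- sam_rec(rid, 2048L, "scaffold", p$start + 1L,
                  sprintf("%dS%dM", L, R), rd)
    return(list(sam = list(r1, r2), seq = rd))
  }
  if (ty == "diff_chrom") {
    cs <- strsplit(p$chrom, "|", fixed = TRUE)[[1]]
    sA <- gm$chroms[[cs[1]]]; sB <- gm$chroms[[cs[2]]]
    rd <- paste0(subseq0(sB, p$end - L, p$end),
                 subseq0(sA, p$start, p$start + R))
    r1 <- sam_rec(rid, 0L, cs[2], p$end - L + 1L, sprintf("%dM%dS", L, R), rd)
    r2 <- sam_rec(rid, 2048L, cs[1], p$start + 1L, sprintf("%dS%dM", L, R), rd)
    return(list(sam = list(r1, r2), seq = rd))
  }
  if (ty == "opposite_strand") {
    ## donor-side segment on "+", acceptor-side reported on "-"
    rd <- junction_read_seq(gm, p, L, R)
    r1 <- sam_rec(rid, 0L, p$chrom, p$end - L + 1L,
                  sprintf("%dM%dS", L, R), rd)
    r2 <- sam_rec(rid, 2048L + 16L, p$chrom, p$start + 1L,
                  sprintf("%dM%dS", R, L), revcomp(rd))
    return(list(sam = list(r1, r2), seq = rd))
  }
  if (ty == "same_order") {
    ## a linear splice-junction read: transcript-adjacent exon ends in
    ## forward transcript order (never reversed)
    e <- gm$exons[gm$exons$gene_id == p$gene_id, ]
    j <- p$exon_to
    if (p$strand == "+") {
      rd <- paste0(subseq0(seq1, e$end[j] - L, e$end[j]),
                   subseq0(seq1, e$start[j + 1], e$start[j + 1] + R))
      r1 <- sam_rec(rid, 0L, p$chrom, e$end[j] - L + 1L,
                    sprintf("%dM%dS", L, R), rd)
      r2 <- sam_rec(rid, 2048L, p$chrom, e$start[j + 1] + 1L,
                    sprintf("%dS%dM", L, R), rd)
    } else {
      rd <- paste0(revcomp(subseq0(seq1, e$start[j + 1], e$start[j + 1] + L)),
                   revcomp(subseq0(seq1, e$end[j] - R, e$end[j])))
      rc <- revcomp(rd)
      r1 <- sam_rec(rid, 16L, p$chrom, e$start[j + 1] + 1L,
                    sprintf("%dS%dM", R, L), rc)
      r2 <- sam_rec(rid, 2048L + 16L, p$chrom, e$end[j] - R + 1L,
                    sprintf("%dM%dS", R, L), rc)
    }
    return(list(sam = list(r1, r2), seq = rd))
  }
  stop("unknown planting type: ", ty)
}

sam_rec <- function(qname, flag, rname, pos1, cigar, seq) {
  list(qname = qname, flag = flag, rname = rname, pos = pos1,
       mapq = 60L, cigar = cigar, seq = seq)
}

## bind a list of sam_rec()/read-row lists into a data frame
bind_rows_fast <- function(rows) {
  cols <- names(rows[[1]])
  out <- lapply(cols, function(cn)
    unlist(lapply(rows, `[[`, cn), use.names = FALSE))
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Write simulated alignments as SAM
#'
#' Header carries `@SQ` lines for every chromosome; records are written in
#' the stable simulation order, with constant Q30 base qualities.
#'
#' @param sim output of [simulate_split_alignments()] (or any list with
#'   `sam` records and `chrom_lengths`).
#' @param path output SAM path.
#' @return invisibly, `path`.
#' @export
write_sam <- function(sim, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sim$chrom_lengths),
                   as.integer(sim$chrom_lengths)))
  s <- sim$sam
  recs <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  s$qname, s$flag, s$rname, s$pos, s$mapq, s$cigar, s$seq,
                  strrep("?", nchar(s$seq)))
  writeLines(c(hdr, recs), path)
  invisible(path)
}
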