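## Back-splice circRNA identification from chimeric split alignments.
##
## A read supports a head-to-tail (back-splice) junction when two of its
## partial alignments map (i) to the same chromosome no more than `max_sep`
## apart, (ii) on the same strand, (iii) in reverse genomic order relative
## to their order in the read (strand-aware: on "-" the transcript runs
## right-to-left, so "reverse order" means ascending genomic coordinates).

#' Read split alignments from a SAM/BAM file
#'
#' Parses primary and supplementary records sharing a QNAME into per-read
#' partial-alignment segments. Query coordinates are reported in original
#' read orientation (reverse-strand records are flipped using the clip
#' structure), genomic coordinates as 0-based half-open intervals.
#' Unmapped and secondary records are dropped; records with malformed
#' CIGARs (zero reference span) are skipped with a warning.
#'
#' @param path SAM or BAM file.
#' @return data frame of class `split_alignments`: `read_id`, `chrom`,
#'   `start`, `end`, `strand`, `query_start`, `query_end`.
#' @export
read_split_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else bam <- path
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "strand", "seq"))
  r <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(r$pos) & !bitwAnd(r$flag, 256L) # mapped, not secondary
  qname <- r$qname[keep]; flag <- r$flag[keep]
  chrom <- as.character(r$rname)[keep]; pos <- r$pos[keep]
  cigar <- r$cigar[keep]; seqlen <- Biostrings::width(r$seq)[keep]

  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  bad <- refw <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with zero reference span skipped")
    qname <- qname[!bad]; flag <- flag[!bad]; chrom <- chrom[!bad]
    pos <- pos[!bad]; cigar <- cigar[!bad]; seqlen <- seqlen[!bad]
    refw <- refw[!bad]
  }
  ## query interval in stored (possibly reverse-complemented) orientation:
  ## leading/trailing soft and hard clips delimit the aligned query block
  total <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cigar, before.hard.clipping = TRUE)
  clip1 <- function(cig, pat, extract) {
    has <- grepl(pat, cig)
    out <- integer(length(cig))
    out[has] <- as.integer(sub(extract, "\\1", cig[has], perl = TRUE))
    out
  }
  clip_len <- function(cig, lead) {
    if (lead) {
      h <- clip1(cig, "^\\d+H", "^(\\d+)H.*$")
      cig <- sub("^\\d+H", "", cig)
      h + clip1(cig, "^\\d+S", "^(\\d+)S.*$")
    } else {
      h <- clip1(cig, "\\d+H$", "^.*?(\\d+)H$")
      cig <- sub("\\d+H$", "", cig)
      h + clip1(cig, "\\d+S$", "^.*?(\\d+)S$")
    }
  }
  qstart <- clip_len(cigar, lead = TRUE)
  qend <- total - clip_len(cigar, lead = FALSE)
  minus <- bitwAnd(flag, 16L) > 0
  ostart <- ifelse(minus, total - qend, qstart)
  oend <- ifelse(minus, total - qstart, qend)

  out <- data.frame(read_id = qname, chrom = chrom, start = pos - 1L,
                    end = pos - 1L + refw,
                    strand = ifelse(minus, "-", "+"),
                    query_start = as.integer(ostart),
                    query_end = as.integer(oend),
                    stringsAsFactors = FALSE)
  class(out) <- c("split_alignments", class(out))
  out
}

## evaluate one ordered segment pair (a before b in the read, scalar
## fields); returns the implied junction or the first violated rule
pair_junction <- function(chrom_a, start_a, end_a, strand_a,
                          chrom_b, start_b, end_b, strand_b, max_sep) {
  if (chrom_a != chrom_b) return(list(reason = "diff_chrom"))
  if (strand_a != strand_b) return(list(reason = "strand_mismatch"))
  if (strand_a == "+") {
    donor <- end_a; acceptor <- start_b
    start <- acceptor; end <- donor
    reversed <- start_b < start_a
  } else {
    donor <- start_a; acceptor <- end_b
    start <- donor; end <- acceptor
    reversed <- start_b > start_a
  }
  sep <- end - start
  if (abs(start_b - start_a) > max_sep || sep > max_sep)
    return(list(reason = "too_far"))
  if (!reversed || sep <= 0) return(list(reason = "same_order"))
  list(chrom = chrom_a, strand = strand_a, start = start, end = end)
}

#' Detect back-splice candidates from split alignments
#'
#' Applies the three head-to-tail rules (same chromosome, separation no more
#' than `max_sep`, same strand, reversed order) to every ordered segment
#' pair of every multi-segment read, and aggregates reads whose implied
#' breakpoints agree within `merge_tol` nt into one candidate. Per-read
#' rejections are tallied by the first violated rule and attached as
#' attribute `"rejections"` (`read_id`, `reason`).
#'
#' @param aln `split_alignments` data frame (any row order).
#' @param max_sep maximum genomic separation in nt (default 1e6).
#' @param merge_tol breakpoint agreement tolerance in nt when pooling reads
#'   into a candidate (default 5).
#' @return data frame of class `backsplice_candidates`: `chrom`, `strand`,
#'   `start`, `end` (modal implied breakpoints), `n_reads`, `read_ids`
#'   (comma-separated), sorted by (chrom, start, end).
#' @export
find_chimeric_candidates <- function(aln, max_sep = 1e6, merge_tol = 5L) {
  stopifnot(is.data.frame(aln))
  bad <- aln$end <= aln$start
  skipped <- character(0)
  if (any(bad)) {
    skipped <- unique(aln$read_id[bad])
    warning("malformed segment(s) (end <= start); skipping read(s): ",
            paste(skipped, collapse = ", "))
    aln <- aln[!(aln$read_id %in% skipped), , drop = FALSE]
  }
  v_chrom <- aln$chrom; v_start <- aln$start; v_end <- aln$end
  v_strand <- aln$strand; v_qs <- aln$query_start
  idx <- split(seq_len(nrow(aln)), aln$read_id)
  j_read <- character(0); j_chrom <- character(0); j_strand <- character(0)
  j_start <- integer(0); j_end <- integer(0)
  r_read <- character(0); r_reason <- character(0)
  for (rid in names(idx)) {
    ii <- idx[[rid]]
    if (length(ii) < 2) next
    ii <- ii[order(v_qs[ii])]
    found <- NULL; first_reason <- NULL
    for (i in seq_len(length(ii) - 1)) {
      for (j in seq(i + 1, length(ii))) {
        a <- ii[i]; b <- ii[j]
        res <- pair_junction(
          v_chrom[a], v_start[a], v_end[a], v_strand[a],
          v_chrom[b], v_start[b], v_end[b], v_strand[b], max_sep)
        if (is.null(res$reason)) { found <- res; break }
        if (is.null(first_reason)) first_reason <- res$reason
      }
      if (!is.null(found)) break
    }
    if (!is.null(found)) {
      j_read <- c(j_read, rid); j_chrom <- c(j_chrom, found$chrom)
      j_strand <- c(j_strand, found$strand)
      j_start <- c(j_start, found$start); j_end <- c(j_end, found$end)
    } else {
      r_read <- c(r_read, rid); r_reason <- c(r_reason, first_reason)
    }
  }
  juncs <- if (length(j_read))
    list(data.frame(read_id = j_read, chrom = j_chrom, strand = j_strand,
                    start = j_start, end = j_end, stringsAsFactors = FALSE))
  else list()
  rejections <- data.frame(read_id = r_read, reason = r_reason,
                           stringsAsFactors = FALSE)
  if (length(skipped))
    rejections <- rbind(rejections,
                        data.frame(read_id = skipped, reason = "malformed"))

  if (!length(juncs)) {
    out <- data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      n_reads = integer(), read_ids = character())
  } else {
    jt <- do.call(rbind, juncs)
    jt <- df_sort(jt, c("chrom", "strand", "start", "end"))
    ## greedy clustering: same chrom/strand, start and end within merge_tol
    ## of the cluster seed
    key <- paste(jt$chrom, jt$strand)
    cl <- integer(nrow(jt)); nc <- 0L
    seed_s <- numeric(0); seed_e <- numeric(0); seed_k <- character(0)
    for (i in seq_len(nrow(jt))) {
      hit <- which(seed_k == key[i] &
                   abs(seed_s - jt$start[i]) <= merge_tol &
                   abs(seed_e - jt$end[i]) <= merge_tol)
      if (length(hit)) cl[i] <- hit[1]
      else {
        nc <- nc + 1L; cl[i] <- nc
        seed_s[nc] <- jt$start[i]; seed_e[nc] <- jt$end[i]; seed_k[nc] <- key[i]
      }
    }
    out <- do.call(rbind, lapply(split(jt, cl), function(g) {
      mode1 <- function(x) as.integer(names(sort(table(x), decreasing = TRUE))[1])
      data.frame(chrom = g$chrom[1], strand = g$strand[1],
                 start = mode1(g$start), end = mode1(g$end),
                 n_reads = nrow(g),
                 read_ids = paste(sort(unique(g$read_id)), collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    out <- df_sort(out, c("chrom", "start", "end", "strand"))
  }
  attr(out, "rejections") <- rejections
  class(out) <- c("backsplice_candidates", class(out))
  out
}

#' Call circRNAs from back-splice candidates
#'
#' For each candidate, selects the maximum-splice-strength donor/acceptor
#' pair near the implied breakpoints ([select_junction()]) and emits a call
#' when the junction is supported by at least `min_reads` reads and the
#' splicing score is greater than or equal to `min_score` (both boundaries
#' inclusive). Candidates failing a filter are recorded in attribute
#' `"rejections"` with reason `too_few_reads` or `low_score`.
#'
#' @param candidates output of [find_chimeric_candidates()].
#' @param gm a `genome_model`.
#' @param model a [splice_model()].
#' @param min_reads minimum junction-spanning reads (default 2).
#' @param min_score minimum donor+acceptor splicing score (default 10).
#' @param radius junction search radius in nt (default 10).
#' @return data frame of class `circ_calls`: `circ_id`, `chrom`, `start`,
#'   `end`, `strand`, `junction_reads`, `splice_score`, `read_ids`, sorted
#'   by (chrom, start).
#' @export
call_circrnas <- function(candidates, gm, model = splice_model(),
                          min_reads = 2L, min_score = 10, radius = 10L) {
  if (min_reads < 2 || min_score <= 0)
    warning("thresholds relaxed below the default call filter ",
            "(min_reads=", min_reads, ", min_score=", min_score, ")")
  n <- nrow(candidates)
  sel <- vector("list", n)
  for (i in seq_len(n))
    sel[[i]] <- select_junction(gm, candidates$chrom[i], candidates$start[i],
                                candidates$end[i], candidates$strand[i],
                                model, radius)
  score <- vapply(sel, `[[`, 0, "score")
  start <- vapply(sel, `[[`, 0, "start")
  end <- vapply(sel, `[[`, 0, "end")
  enough <- candidates$n_reads >= min_reads
  strong <- score >= min_score
  keep <- enough & strong
  rej <- data.frame(
    chrom = candidates$chrom[!keep], start = start[!keep], end = end[!keep],
    strand = candidates$strand[!keep],
    n_reads = candidates$n_reads[!keep], splice_score = score[!keep],
    reason = ifelse(!enough[!keep], "too_few_reads", "low_score"),
    read_ids = candidates$read_ids[!keep], stringsAsFactors = FALSE)
  out <- data.frame(
    chrom = candidates$chrom[keep], start = as.integer(start[keep]),
    end = as.integer(end[keep]), strand = candidates$strand[keep],
    junction_reads = candidates$n_reads[keep], splice_score = score[keep],
    read_ids = candidates$read_ids[keep], stringsAsFactors = FALSE)
  out <- df_sort(out, c("chrom", "start", "end", "strand"))
  out <- cbind(circ_id = sprintf("circ_%s_%d_%d_%s", out$chrom, out$start,
                                 out$end, out$strand), out)
  attr(out, "rejections") <- rej
  class(out) <- c("circ_calls", class(out))
  out
}

#' Write circRNA calls as BED6+2
#'
#' Columns: chrom, start, end, circ_id, junction_reads, strand,
#' splice_score, n_supporting_reads.
#'
#' @param calls `circ_calls` data frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_calls_bed <- function(calls, path) {
  bed <- data.frame(calls$chrom, calls$start, calls$end, calls$circ_id,
                    calls$junction_reads, calls$strand,
                    round(calls$splice_score, 4), calls$junction_reads)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
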