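## Circular-junction pseudo-references and junction-spanning read counting
## under the minimum-overhang rule, plus RPM/RPKM normalization.

#' Build circular-junction pseudo-references
#'
#' For each call, concatenates the donor-side flank (sequence 5' of the
#' back-splice junction on the transcript) with the acceptor-side flank, so
#' the circular junction sits exactly at the center of a 2 x `flank`
#' pseudo-sequence. On "+", this is `genome[end-flank, end)` followed by
#' `genome[start, start+flank)`; minus-strand calls are the reverse
#' complement of that construction. Calls nearer than `flank` to a
#' chromosome edge get symmetrically truncated flanks with a warning.
#'
#' @param calls `circ_calls` data frame (needs `circ_id`, `chrom`, `start`,
#'   `end`, `strand`).
#' @param gm a `genome_model`.
#' @param flank flank length per side in nt (default 150).
#' @return data frame of class `junction_refs`: `circ_id`, `seq`, `flank`
#'   (junction offset = `flank`).
#' @export
build_junction_reference <- function(calls, gm, flank = 150L) {
  stopifnot(flank >= 6)
  n <- nrow(calls)
  seqs <- character(n); flanks <- integer(n)
  for (i in seq_len(n)) {
    chrom <- gm$chroms[[calls$chrom[i]]]
    s <- calls$start[i]; e <- calls$end[i]
    f <- min(flank, s, nchar(chrom) - e, e - s)
    if (f < flank)
      warning(sprintf(
        "flank truncated to %d nt for %s (chromosome edge or short circle)",
        f, calls$circ_id[i]))
    ps <- paste0(subseq0(chrom, e - f, e), subseq0(chrom, s, s + f))
    if (calls$strand[i] == "-") ps <- revcomp(ps)
    seqs[i] <- ps; flanks[i] <- f
  }
  out <- data.frame(circ_id = calls$circ_id, seq = seqs, flank = flanks,
                    stringsAsFactors = FALSE)
  class(out) <- c("junction_refs", class(out))
  out
}

#' Count junction-spanning reads
#'
#' A read increments a circRNA's count iff it matches the pseudo-reference
#' exactly (either orientation) with the match crossing the junction center
#' and at least `min_overhang` matched nt on both sides. Each read counts at
#' most once per circRNA per sample.
#'
#' @param refs [build_junction_reference()] output.
#' @param reads character vector of read sequences for one sample, or a
#'   named list of such vectors (one element per sample).
#' @param min_overhang minimum matched nt on each side of the junction
#'   (default 6, boundary inclusive).
#' @return integer matrix circRNAs x samples.
#' @export
count_junction_reads <- function(refs, reads, min_overhang = 6L) {
  if (!is.list(reads)) reads <- list(sample1 = reads)
  out <- matrix(0L, nrow = nrow(refs), ncol = length(reads),
                dimnames = list(refs$circ_id,
                                names(reads) %||% paste0("sample", seq_along(reads))))
  for (s in seq_along(reads)) {
    rs <- reads[[s]]
    rrs <- revcomp(rs)
    for (i in seq_len(nrow(refs))) {
      center <- refs$flank[i]
      ref <- refs$seq[i]
      n <- 0L
      for (k in seq_along(rs)) {
        hit <- junction_match(ref, rs[k], center, min_overhang) ||
               junction_match(ref, rrs[k], center, min_overhang)
        if (hit) n <- n + 1L
      }
      out[i, s] <- n
    }
  }
  out
}

## does `read` match `ref` exactly somewhere, crossing `center` (0-based)
## with >= min_overhang nt on both sides?
junction_match <- function(ref, read, center, min_overhang) {
  m <- gregexpr(read, ref, fixed = TRUE)[[1]]
  if (m[1] == -1) return(FALSE)
  starts <- as.integer(m) - 1L
  ends <- starts + nchar(read)
  any(starts <= center - min_overhang & ends >= center + min_overhang)
}

#' Normalize a count matrix to RPM or RPKM
#'
#' RPM = count x 1e6 / library size; RPKM additionally divides by feature
#' length in kb. Junction and miRNA counts have no meaningful transcript
#' length and use RPM; mRNA/lncRNA use RPKM.
#'
#' @param counts features x samples count matrix.
#' @param lib_sizes per-sample library sizes (default: column sums).
#' @param lengths feature lengths in nt (required for `method = "rpkm"`).
#' @param method `"rpm"` or `"rpkm"`.
#' @return numeric matrix of normalized values.
#' @export
normalize_expression <- function(counts, lib_sizes = colSums(counts),
                                 lengths = NULL,
                                 method = c("rpm", "rpkm")) {
  method <- match.arg(method)
  if (any(lib_sizes <= 0))
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[lib_sizes <= 0], collapse = ", "))
  rpm <- sweep(counts, 2, lib_sizes, `/`) * 1e6
  if (method == "rpm") return(rpm)
  stopifnot(!is.null(lengths), all(lengths > 0), length(lengths) == nrow(counts))
  sweep(rpm, 1, lengths / 1e3, `/`)
}
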