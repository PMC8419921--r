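## PWM splice-strength model over MaxEntScan-style windows:
## donor  = 9 nt  (3 exonic | GT + 4 intronic)
## acceptor = 23 nt (18 intronic tract + AG | 3 exonic)
## Score of a window is the scaled sum of per-position log2(p/background).

#' Load the splice-site strength model
#'
#' Reads a position-weight-matrix model from a tab-separated file with
#' columns `site` (donor/acceptor), `pos`, `A`, `C`, `G`, `T`. Each row's
#' probabilities must sum to 1. The packaged default model encodes standard
#' human donor/acceptor base composition. An alternative model (e.g. a
#' full maximum-entropy table collapsed to per-position weights) can be
#' supplied through the same file interface.
#'
#' @param path model file; default is the packaged model.
#' @param background background base frequencies (A, C, G, T).
#' @param scale multiplicative factor mapping log-odds to score units. The
#'   default 0.5 is calibrated so that, under the packaged PWM, the
#'   consensus donor+acceptor pair scores about 17 (above the call
#'   threshold of 10) while the maximum score over a +/-10 nt search radius
#'   in random sequence stays several null standard deviations below 10.
#' @return object of class `splice_model` with `donor` and `acceptor`
#'   log-odds weight matrices (positions x ACGT).
#' @export
splice_model <- function(path = system.file("extdata", "splice_pwm.tsv",
                                            package = "circnet"),
                         background = c(A = .25, C = .25, G = .25, T = .25),
                         scale = 0.5) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("site", "pos", "A", "C", "G", "T") %in% names(tab)))
  mk <- function(site) {
    m <- as.matrix(tab[tab$site == site, c("A", "C", "G", "T")])
    stopifnot(all(abs(rowSums(m) - 1) < 1e-9))
    sweep(log2(m), 2, log2(background[colnames(m)]), `-`) * scale
  }
  donor <- mk("donor"); acceptor <- mk("acceptor")
  stopifnot(nrow(donor) == 9, nrow(acceptor) == 23)
  ## consensus GT / AG must be modal at the canonical positions
  stopifnot(which.max(donor[4, ]) == 3, which.max(donor[5, ]) == 4,
            which.max(acceptor[19, ]) == 1, which.max(acceptor[20, ]) == 3)
  structure(list(donor = donor, acceptor = acceptor,
                 background = background, scale = scale),
            class = "splice_model")
}

## score fixed-length windows (character vector) against a log-odds matrix;
## windows containing non-ACGT characters score -Inf
score_windows <- function(windows, lom) {
  w <- nrow(lom)
  n <- length(windows)
  out <- rep(-Inf, n)
  ok <- !is.na(windows) & nchar(windows) == w & !grepl("[^ACGT]", windows)
  if (!any(ok)) return(out)
  chars <- matrix(match(unlist(strsplit(windows[ok], "")), BASES),
                  ncol = w, byrow = TRUE)
  out[ok] <- rowSums(matrix(lom[cbind(as.vector(col(chars)), as.vector(chars))],
                            ncol = w))
  out
}

## donor window at genomic boundary position `pos` (0-based, the exon|intron
## boundary: exon ends at pos on "+", starts at pos on "-")
donor_window <- function(seq, pos, strand) {
  if (strand == "+") {
    s <- pos - DONOR_EXONIC; e <- pos + (9L - DONOR_EXONIC)
    if (s < 0 || e > nchar(seq)) return(NA_character_)
    subseq0(seq, s, e)
  } else {
    s <- pos - (9L - DONOR_EXONIC); e <- pos + DONOR_EXONIC
    if (s < 0 || e > nchar(seq)) return(NA_character_)
    revcomp(subseq0(seq, s, e))
  }
}

## acceptor window at genomic boundary position `pos` (intron|exon boundary:
## exon starts at pos on "+", ends at pos on "-")
acceptor_window <- function(seq, pos, strand) {
  if (strand == "+") {
    s <- pos - ACCEPTOR_INTRONIC; e <- pos + (23L - ACCEPTOR_INTRONIC)
    if (s < 0 || e > nchar(seq)) return(NA_character_)
    subseq0(seq, s, e)
  } else {
    s <- pos - (23L - ACCEPTOR_INTRONIC); e <- pos + ACCEPTOR_INTRONIC
    if (s < 0 || e > nchar(seq)) return(NA_character_)
    revcomp(subseq0(seq, s, e))
  }
}

#' Score a splice donor or acceptor site
#'
#' @param gm a `genome_model`.
#' @param chrom,pos,strand site location: `pos` is the 0-based exon/intron
#'   boundary on the annotated strand.
#' @param model a [splice_model()].
#' @param site `"donor"` or `"acceptor"`.
#' @return numeric score (`-Inf` if the window leaves the chromosome).
#' @export
score_splice_site <- function(gm, chrom, pos, strand, model,
                              site = c("donor", "acceptor")) {
  site <- match.arg(site)
  seq <- gm$chroms[[chrom]]
  win <- if (site == "donor") donor_window(seq, pos, strand)
         else acceptor_window(seq, pos, strand)
  score_windows(win, model[[site]])
}

#' Select the maximum-strength junction for a back-splice candidate
#'
#' Scans donor and acceptor positions within `radius` nt of the breakpoints
#' implied by the supporting reads and returns the pair maximizing
#' donor + acceptor score. Ties are broken by proximity to the implied
#' breakpoints (sum of absolute shifts), then by smaller genomic
#' coordinates. Strand-aware: on "-" the donor lies at the genomic start of
#' the circle and scanning uses reverse-complemented windows.
#'
#' @param gm a `genome_model`.
#' @param chrom,start,end,strand candidate junction: `start`/`end` are the
#'   0-based half-open genomic span implied by the segment breakpoints.
#' @param model a [splice_model()].
#' @param radius search radius in nt around each breakpoint (default 10).
#' @return list with `start`, `end`, `score` (donor + acceptor, `-Inf` if
#'   nothing scorable).
#' @export
select_junction <- function(gm, chrom, start, end, strand, model, radius = 10L) {
  seq <- gm$chroms[[chrom]]
  offs <- seq(-radius, radius)
  if (strand == "+") { # donor at end, acceptor at start
    don_pos <- end + offs; acc_pos <- start + offs
  } else {             # donor at start, acceptor at end
    don_pos <- start + offs; acc_pos <- end + offs
  }
  don_sc <- score_windows(vapply(don_pos, donor_window, "", seq = seq,
                                 strand = strand), model$donor)
  acc_sc <- score_windows(vapply(acc_pos, acceptor_window, "", seq = seq,
                                 strand = strand), model$acceptor)
  if (all(!is.finite(don_sc)) || all(!is.finite(acc_sc)))
    return(list(start = start, end = end, score = -Inf))
  tot <- outer(don_sc, acc_sc, `+`) # rows = donor offset, cols = acceptor
  best <- max(tot)
  hits <- which(tot == best, arr.ind = TRUE)
  shift <- abs(offs[hits[, 1]]) + abs(offs[hits[, 2]])
  hits <- hits[order(shift, acc_pos[hits[, 2]], don_pos[hits[, 1]]), ,
               drop = FALSE]
  d <- don_pos[hits[1, 1]]; a <- acc_pos[hits[1, 2]]
  if (strand == "+") list(start = a, end = d, score = best)
  else list(start = d, end = a, score = best)
}
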