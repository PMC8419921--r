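## Toy genome with annotated multi-exon genes and consensus splice sites.
## Coordinates are 0-based half-open throughout the package; text output
## follows each format's own convention (BED 0-based, GTF-like table 0-based
## half-open with the convention stated in the header).

CONSENSUS_DONOR <- "CAGGTAAGT" # 3 exonic + 6 intronic nt
CONSENSUS_ACCEPTOR <- "TTTTTTTTTTTTTTTTTCAGGCG" # 20 intronic + 3 exonic nt
DONOR_EXONIC <- 3L # nt of the donor window inside the exon
ACCEPTOR_INTRONIC <- 20L # nt of the acceptor window inside the intron

#' Synthetic-genome configuration
#'
#' Parameters of the toy genome the generator emits: chromosome lengths,
#' gene counts per RNA class and exon geometry. Exon and intron length
#' floors keep splice-site windows (9 nt donor, 23 nt acceptor)
#' non-overlapping so every annotated boundary carries a clean consensus
#' motif.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (nt).
#' @param n_mrna,n_lncrna,n_mirna gene counts per RNA class.
#' @param exons_per_gene exon count for mRNA/lncRNA genes (miRNA genes are
#'   single-exon hairpins of `mirna_len` nt).
#' @param exon_len,intron_len length ranges (`c(min, max)`) for exons and
#'   introns of multi-exon genes.
#' @param mirna_len mature miRNA length.
#' @param gene_gap minimum intergenic gap.
#' @return a list of class `synth_genome_config`.
#' @export
genome_config <- function(chrom_lengths = c(chr1 = 1e5, chr2 = 1e5),
                          n_mrna = 60, n_lncrna = 30, n_mirna = 30,
                          exons_per_gene = 4L,
                          exon_len = c(90L, 130L),
                          intron_len = c(40L, 70L),
                          mirna_len = 22L,
                          gene_gap = 60L) {
  stopifnot(all(chrom_lengths > 0), exons_per_gene >= 1,
            exon_len[1] >= 40, intron_len[1] >= 30, mirna_len >= 18)
  structure(
    list(chrom_lengths = chrom_lengths, n_mrna = n_mrna,
         n_lncrna = n_lncrna, n_mirna = n_mirna,
         exons_per_gene = as.integer(exons_per_gene),
         exon_len = as.integer(exon_len), intron_len = as.integer(intron_len),
         mirna_len = as.integer(mirna_len), gene_gap = as.integer(gene_gap)),
    class = "synth_genome_config"
  )
}

#' Generate a toy genome with annotated genes
#'
#' Emits random chromosome sequences and lays out non-overlapping genes of
#' three RNA classes along them. Every internal exon boundary is overwritten
#' with the full consensus donor (`CAGGTAAGT`) or acceptor
#' (pyrimidine tract + `CAG` + 3 exonic nt) window on the annotated strand,
#' so annotated splice sites are GT..AG sites that score maximally under the
#' packaged PWM model.
#'
#' @param config a [genome_config()].
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return an object of class `genome_model`: list with `chroms` (named
#'   character vector of sequences), `genes` and `exons` data frames
#'   (0-based half-open coordinates).
#' @export
generate_genome <- function(config = genome_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_genome_config"))
  with_seed(seed, {
    chroms <- vapply(config$chrom_lengths, function(n) random_dna(n), "")
    names(chroms) <- names(config$chrom_lengths)

    classes <- c(rep("mRNA", config$n_mrna),
                 rep("lncRNA", config$n_lncrna),
                 rep("miRNA", config$n_mirna))
    genes <- list(); exons <- list()
    cursor <- setNames(rep(0L, length(chroms)), names(chroms))
    chrom_i <- 1L
    for (g in seq_along(classes)) {
      cls <- classes[g]
      if (cls == "miRNA") {
        widths <- config$mirna_len
      } else {
        widths <- sample(seq(config$exon_len[1], config$exon_len[2]),
                         config$exons_per_gene, replace = TRUE)
      }
      n_ex <- length(widths)
      gaps <- if (n_ex > 1)
        sample(seq(config$intron_len[1], config$intron_len[2]),
               n_ex - 1, replace = TRUE) else integer(0)
      span <- sum(widths) + sum(gaps)

      ## first chromosome (round-robin from chrom_i) with room
      placed <- FALSE
      for (k in seq_along(chroms)) {
        ci <- ((chrom_i - 1L + k - 1L) %% length(chroms)) + 1L
        start <- cursor[ci] + config$gene_gap
        if (start + span + config$gene_gap <= nchar(chroms[ci])) {
          placed <- TRUE; chrom_i <- ci + 1L; break
        }
      }
      if (!placed) {
        stop(sprintf(
          "chromosome '%s' too short to host gene %d of %d (need %d more nt)",
          names(chroms)[which.max(config$chrom_lengths)], g, length(classes),
          span + 2L * config$gene_gap))
      }
      chrom <- names(chroms)[ci]
      strand <- sample(c("+", "-"), 1)
      starts <- start + cumsum(c(0L, head(widths, -1) + gaps))
      ends <- starts + widths
      gid <- sprintf("%s%03d", c(mRNA = "gene", lncRNA = "lnc", miRNA = "mir")[cls], g)
      genes[[g]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                               rna_class = cls, start = starts[1],
                               end = ends[n_ex], stringsAsFactors = FALSE)
      exons[[g]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                               rna_class = cls, start = starts, end = ends,
                               exon_rank = seq_len(n_ex), stringsAsFactors = FALSE)
      cursor[ci] <- ends[n_ex]
    }
    genes <- do.call(rbind, genes) %||% empty_genes()
    exons <- do.call(rbind, exons) %||% empty_exons()

    gm <- structure(list(chroms = chroms, genes = genes, exons = exons),
                    class = "genome_model")
    write_splice_motifs(gm)
  })
}

empty_genes <- function() {
  data.frame(gene_id = character(), chrom = character(), strand = character(),
             rna_class = character(), start = integer(), end = integer())
}
empty_exons <- function() {
  cbind(empty_genes()[, 1:4], start = integer(), end = integer(),
        exon_rank = integer())
}

## place consensus donor/acceptor windows at every internal exon boundary,
## strand aware: on "-" the motif is the reverse complement on the + text.
write_splice_motifs <- function(gm) {
  ex <- gm$exons
  if (nrow(ex) == 0) return(gm)
  for (gid in unique(ex$gene_id)) {
    e <- ex[ex$gene_id == gid, ]
    k <- nrow(e)
    if (k < 2) next
    chrom <- e$chrom[1]; strand <- e$strand[1]
    seq <- gm$chroms[[chrom]]
    for (r in seq_len(k)) {
      if (strand == "+") {
        if (r < k) # donor after exon r
          seq <- replace0(seq, e$end[r] - DONOR_EXONIC, CONSENSUS_DONOR)
        if (r > 1) # acceptor before exon r
          seq <- replace0(seq, e$start[r] - ACCEPTOR_INTRONIC, CONSENSUS_ACCEPTOR)
      } else {
        if (r > 1) # donor at genomic start of exon r (transcript 5'ss)
          seq <- replace0(seq, e$start[r] - (nchar(CONSENSUS_DONOR) - DONOR_EXONIC),
                          revcomp(CONSENSUS_DONOR))
        if (r < k) # acceptor at genomic end of exon r (transcript 3'ss)
          seq <- replace0(seq, e$end[r] - (nchar(CONSENSUS_ACCEPTOR) - ACCEPTOR_INTRONIC),
                          revcomp(CONSENSUS_ACCEPTOR))
      }
    }
    gm$chroms[[chrom]] <- seq
  }
  gm
}

#' Spliced transcript sequence of a gene
#'
#' Concatenates exon sequences in transcript order (reverse-complemented for
#' minus-strand genes).
#'
#' @param gm a `genome_model`.
#' @param gene_id gene identifier.
#' @return character scalar (DNA).
#' @export
transcript_seq <- function(gm, gene_id) {
  e <- gm$exons[gm$exons$gene_id == gene_id, ]
  if (nrow(e) == 0) stop("unknown gene_id: ", gene_id)
  parts <- subseq0(gm$chroms[[e$chrom[1]]], e$start, e$end)
  s <- paste(parts, collapse = "")
  if (e$strand[1] == "-") revcomp(s) else s
}

## genomic (chrom, pos0, strand) of a transcript offset; used to plant
## seed-match sites inside exons through the genome text
transcript_to_genomic <- function(gm, gene_id, offset) {
  e <- gm$exons[gm$exons$gene_id == gene_id, ]
  widths <- e$end - e$start
  if (e$strand[1] == "-") e <- e[rev(seq_len(nrow(e))), ]
  cum <- cumsum(c(0L, (e$end - e$start)))
  i <- findInterval(offset, cum, rightmost.closed = FALSE)
  if (i < 1 || offset >= cum[length(cum)]) stop("offset outside transcript")
  within <- offset - cum[i]
  if (e$strand[1] == "+") {
    list(chrom = e$chrom[1], pos = e$start[i] + within, strand = "+",
         exon_len = e$end[i] - e$start[i], exon_offset = within)
  } else {
    list(chrom = e$chrom[1], pos = e$end[i] - within - 1L, strand = "-",
         exon_len = e$end[i] - e$start[i], exon_offset = within)
  }
}

#' Write a genome model to FASTA and a GTF-like annotation table
#'
#' @param gm a `genome_model`.
#' @param fasta,annotation output paths; `NULL` skips that file.
#' @return invisibly, the paths written.
#' @export
write_genome <- function(gm, fasta = NULL, annotation = NULL) {
  if (!is.null(fasta)) {
    ss <- Biostrings::DNAStringSet(gm$chroms)
    Biostrings::writeXStringSet(ss, fasta, width = 80L)
  }
  if (!is.null(annotation)) {
    ann <- data.frame(
      chrom = gm$exons$chrom, source = "circnet_synth", feature = "exon",
      start = gm$exons$start, end = gm$exons$end, strand = gm$exons$strand,
      gene_id = gm$exons$gene_id, rna_class = gm$exons$rna_class,
      exon_rank = gm$exons$exon_rank)
    write.table(ann, annotation, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(fasta = fasta, annotation = annotation))
}

#' Read a genome model from FASTA + annotation written by [write_genome()]
#'
#' @param fasta FASTA path.
#' @param annotation annotation TSV path (may be `NULL` for a bare genome).
#' @return a `genome_model`.
#' @export
read_genome <- function(fasta, annotation = NULL) {
  ss <- Biostrings::readDNAStringSet(fasta)
  chroms <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  if (is.null(annotation)) {
    exons <- empty_exons(); genes <- empty_genes()
  } else {
    ann <- read.delim(annotation, stringsAsFactors = FALSE)
    exons <- data.frame(gene_id = ann$gene_id, chrom = ann$chrom,
                        strand = ann$strand, rna_class = ann$rna_class,
                        start = ann$start, end = ann$end,
                        exon_rank = ann$exon_rank)
    first <- !duplicated(exons$gene_id)
    genes <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e)
      data.frame(gene_id = e$gene_id[1], chrom = e$chrom[1],
                 strand = e$strand[1], rna_class = e$rna_class[1],
                 start = min(e$start), end = max(e$end))))
    rownames(genes) <- NULL
  }
  structure(list(chroms = chroms, genes = genes, exons = exons),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosome(s), %d gene(s) (%s)\n",
              length(x$chroms), nrow(x$genes),
              paste(sprintf("%s=%d", names(table(x$genes$rna_class)),
                            table(x$genes$rna_class)), collapse = ", ")))
  invisible(x)
}
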