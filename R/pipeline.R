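## End-to-end orchestration: synthetic data -> circRNA calling -> junction
## quantification -> DE screening -> ceRNA network -> enrichment, with a
## run report and reproducible seeding.

#' Pipeline configuration
#'
#' Collects every stage threshold (defaults exactly as the method's printed
#' cut-offs) plus the synthetic-data generator settings.
#'
#' @param seed master integer seed; stage seeds are derived from it.
#' @param max_sep maximum back-splice segment separation (1 Mb).
#' @param min_reads,min_score circRNA call filter (2 reads, score 10).
#' @param min_overhang junction-count overhang rule (6 nt).
#' @param lfc_cut,p_cut DE screen cut-offs (2, 0.01).
#' @param r_cut,adjp_cut co-expression gate (0.9, 0.1).
#' @param enrich_p_cut enrichment significance threshold (0.05).
#' @param n_per_group samples per group (9 paired patients).
#' @param noise_sd generator log2 noise sd.
#' @param paired use the paired DE test (the generator emulates a paired
#'   pre/post design).
#' @param n_true,n_decoys,depth planted circRNA counts and junction depth.
#' @param read_len read length (150 nt).
#' @param n_background linear background reads.
#' @param frac_short fraction of sub-overhang junction reads.
#' @param mirna_rule triplet miRNA direction rule (see
#'   [assemble_network()]).
#' @param genome a [genome_config()].
#' @param expr an [expr_config()] (its `n_per_group`/`noise_sd` are
#'   overridden by the arguments here).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, max_sep = 1e6, min_reads = 2L,
                            min_score = 10, min_overhang = 6L, lfc_cut = 2,
                            p_cut = 0.01, r_cut = 0.9, adjp_cut = 0.1,
                            enrich_p_cut = 0.05, n_per_group = 9L,
                            noise_sd = 0.5, paired = TRUE,
                            n_true = 50L, n_decoys = 20L, depth = 10L,
                            read_len = 150L, n_background = 300L,
                            frac_short = 0, mirna_rule = "opposite",
                            genome = genome_config(), expr = expr_config()) {
  stopifnot(max_sep > 0, min_overhang > 0, p_cut > 0, r_cut > 0,
            adjp_cut > 0, enrich_p_cut > 0, n_per_group >= 3)
  expr$n_per_group <- as.integer(n_per_group)
  expr$noise_sd <- noise_sd
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic-mode pipeline
#'
#' Stages run in order: genome generation, circRNA planting, read
#' simulation (through a SAM round trip), back-splice candidate detection,
#' junction selection and call filtering, junction quantification,
#' expression simulation, per-class DE screening, target-table emission,
#' co-expression gating, network assembly, and over-representation of each
#' sub-network's mRNA set. Identical config and seed give identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional directory; when given, stage outputs are written
#'   (FASTA, annotation, SAM, BED calls, TSV tables, SIF/GraphML networks,
#'   JSON report).
#' @return list of class `pipeline_result` with all stage objects and a
#'   `report` (per-stage counts, config echo, timings).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c(); tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3); t0 <<- t1
  }
  seed <- as.integer(config$seed)

  ## --- synthetic data -------------------------------------------------
  gm <- generate_genome(config$genome, seed = seed)
  planted <- plant_circrnas(gm, n_true = config$n_true,
                            n_decoys = config$n_decoys, seed = seed + 1L,
                            depth = config$depth)
  gm <- planted$genome
  et <- plant_expression_truth(gm, planted$circs, config$expr,
                               seed = seed + 2L)
  gm <- et$genome; truth <- et$truth
  sim <- simulate_split_alignments(gm, planted$circs,
                                   read_len = config$read_len,
                                   seed = seed + 3L,
                                   n_background = config$n_background,
                                   frac_short = config$frac_short)
  tick("synthdata")

  ## --- circRNA calling (through the SAM round trip) -------------------
  sam_path <- if (is.null(outdir)) tempfile(fileext = ".sam")
    else file.path(outdir, "alignments.sam")
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE,
                                   recursive = TRUE)
  write_sam(sim, sam_path)
  aln <- read_split_alignments(sam_path)
  cand <- find_chimeric_candidates(aln, max_sep = config$max_sep)
  model <- splice_model()
  calls <- call_circrnas(cand, gm, model, min_reads = config$min_reads,
                         min_score = config$min_score)
  tick("circcall")

  ## --- junction quantification ----------------------------------------
  refs <- build_junction_reference(calls, gm, flank = config$read_len)
  jcounts <- count_junction_reads(refs, sim$reads$seq,
                                  min_overhang = config$min_overhang)
  tick("quantify")

  ## --- expression + DE screening --------------------------------------
  expr <- simulate_expression(truth, seed = seed + 4L)
  ## map calls back to planted ids so expression features match call set
  call_key <- paste(calls$chrom, calls$start, calls$end, calls$strand)
  planted_key <- paste(planted$circs$chrom, planted$circs$start,
                       planted$circs$end, planted$circs$strand)
  called_ids <- planted$circs$circ_id[match(call_key, planted_key)]

  de <- list(); norm <- list()
  for (cls in names(expr$matrices)) {
    cm <- expr$matrices[[cls]]
    counts <- cm$counts
    if (cls == "circRNA") # screened on the called set only
      counts <- counts[rownames(counts) %in% called_ids, , drop = FALSE]
    method <- if (cls %in% c("miRNA", "circRNA")) "rpm" else "rpkm"
    nm <- normalize_expression(counts, lib_sizes = cm$lib_sizes,
                               lengths = cm$lengths[rownames(counts)],
                               method = method)
    norm[[cls]] <- nm
    de[[cls]] <- de_screen(nm, expr$groups, test = "welch",
                           paired = config$paired, lfc_cut = config$lfc_cut,
                           p_cut = config$p_cut, rna_class = cls)
  }
  de_all <- do.call(rbind, de)
  rownames(de_all) <- NULL
  de_summary <- summarize_de(de)
  tick("descreen")

  ## --- ceRNA network ---------------------------------------------------
  targets <- emit_target_tables(gm, truth)
  pairs <- candidate_pairs(targets)
  ## gate on log2(normalized + 2^-10): co-expression of abundances is
  ## assessed on the log scale; the small offset only guards zeros
  lnorm <- do.call(rbind, lapply(norm, function(m) log2(m + 2^-10)))
  pairs <- pairs[pairs$x_id %in% rownames(lnorm) &
                 pairs$y_id %in% rownames(lnorm), , drop = FALSE]
  coexp <- if (nrow(pairs))
    correlate_pairs(lnorm, lnorm, pairs, r_cut = config$r_cut,
                    adjp_cut = config$adjp_cut)
  else
    structure(data.frame(x_id = character(), y_id = character(),
                         pearson_r = numeric(), p_value = numeric(),
                         adj_p = numeric(), retained = logical()),
              class = c("coexpression_edges", "data.frame"))
  targets_de <- targets[targets$target_id %in% de_all$feature_id, ,
                        drop = FALSE]
  net <- assemble_network(de_all, targets_de, coexp,
                          mirna_rule = config$mirna_rule)
  tick("cerna")

  ## --- enrichment -------------------------------------------------------
  mrna_universe <- truth$features$feature_id[truth$features$class == "mRNA"]
  up_mrnas <- unique(net$triplets$mrna_id[net$triplets$direction == "up"])
  anno <- simulate_annotation(mrna_universe,
                              planted = if (length(up_mrnas)) up_mrnas else NULL,
                              seed = seed + 5L)
  enrich <- list()
  for (sn in unique(net$triplets$subnetwork)) {
    q <- unique(net$triplets$mrna_id[net$triplets$subnetwork == sn])
    if (length(q))
      enrich[[sn]] <- ora_test(q, anno, mrna_universe,
                               p_cut = config$enrich_p_cut)
  }
  tick("enrich")

  report <- list(
    seed = seed,
    config_hash = config_hash(config),
    n_reads = nrow(sim$reads),
    n_alignment_records = nrow(sim$sam),
    n_candidates = nrow(cand),
    read_rejections = table_to_list(attr(cand, "rejections")$reason),
    n_calls = nrow(calls),
    call_rejections = table_to_list(attr(calls, "rejections")$reason),
    de_summary = de_summary,
    n_pairs_tested = nrow(pairs),
    n_edges_retained = sum(coexp$retained),
    n_triplets = nrow(net$triplets),
    subnetworks = net$subnetworks,
    timings = timings)

  res <- structure(
    list(genome = gm, planted = planted$circs, truth = truth, sim = sim,
         alignments = aln, candidates = cand, calls = calls,
         junction_refs = refs, junction_counts = jcounts, expr = expr,
         normalized = norm, de = de, de_all = de_all, targets = targets,
         coexpression = coexp, network = net, enrichment = enrich,
         annotation = anno, report = report, config = config),
    class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

config_hash <- function(config) {
  flat <- unlist(config[!vapply(config, is.list, TRUE)])
  sub <- unlist(config[vapply(config, is.list, TRUE)])
  x <- paste(c(flat, sub), collapse = "|")
  ## small stable polynomial hash; avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

table_to_list <- function(x) {
  if (!length(x)) return(list())
  as.list(table(x))
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_genome(res$genome, fasta = p("genome.fa"),
               annotation = p("annotation.tsv"))
  write.table(res$planted, p("planted_circs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_calls_bed(res$calls, p("calls.bed"))
  write.table(attr(res$calls, "rejections"), p("call_rejections.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- Biostrings::DNAStringSet(setNames(res$junction_refs$seq,
                                          res$junction_refs$circ_id))
  Biostrings::writeXStringSet(ss, p("junction_refs.fa"), width = 80L)
  write.table(res$junction_counts, p("junction_counts.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  for (cls in names(res$normalized))
    write.table(res$normalized[[cls]],
                p(sprintf("norm_%s.tsv", cls)), sep = "\t", quote = FALSE,
                col.names = NA)
  write.table(res$de_all, p("de_records.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(res$targets, p("target_edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(res$coexpression, p("coexpression_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(res$network$triplets, p("triplets.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(res$network$edges)) {
    export_network(res$network, p("network.sif"))
    export_network(res$network, p("network.graphml"))
  }
  jsonlite::write_json(res$report, p("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("pipeline_result (seed", r$seed, ", config", r$config_hash, ")\n")
  cat(sprintf("  reads %d | candidates %d | calls %d\n", r$n_reads,
              r$n_candidates, r$n_calls))
  cat(sprintf("  pairs tested %d | edges retained %d | triplets %d\n",
              r$n_pairs_tested, r$n_edges_retained, r$n_triplets))
  print(r$de_summary, row.names = FALSE)
  invisible(x)
}
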