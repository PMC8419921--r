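## miRNA seed-match target prediction, Pearson co-expression gating, and
## assembly of direction-stratified circRNA/lncRNA-miRNA-mRNA networks.

#' Predict miRNA targets by canonical seed matching
#'
#' Site definitions (target read 5'->3'; seed = miRNA positions 2-7):
#' `6mer` = Watson-Crick complement of the seed; `7mer-m8` adds pairing at
#' miRNA position 8; `7mer-A1` adds an A opposite miRNA position 1 (the nt
#' 3' of the seed match on the target); `8mer` = both. Every site is
#' reported with its strongest classification and 1-based position of the
#' 6mer core on the target.
#'
#' @param mirnas named character vector of miRNA sequences (>= 8 nt,
#'   RNA or DNA alphabet).
#' @param targets named character vector of target sequences (>= 8 nt).
#' @param target_class named vector of classes (`mRNA`, `lncRNA`,
#'   `circRNA`) per target, recycled if a scalar.
#' @return data frame of class `target_edges`: `mirna_id`, `target_id`,
#'   `target_class`, `site_type`, `position`.
#' @export
predict_targets <- function(mirnas, targets, target_class = NA_character_) {
  mirnas <- toupper(chartr("u", "t", chartr("U", "T", mirnas)))
  targets <- toupper(chartr("u", "t", chartr("U", "T", targets)))
  bad <- grepl("[^ACGT]", c(mirnas, targets))
  if (any(bad))
    stop("non-ACGT/ACGU symbols in sequence(s): ",
         paste(names(c(mirnas, targets))[bad], collapse = ", "))
  if (any(nchar(mirnas) < 8)) stop("miRNA sequences must be >= 8 nt")
  if (any(nchar(targets) < 8)) stop("target sequences must be >= 8 nt")
  if (length(target_class) == 1)
    target_class <- setNames(rep(target_class, length(targets)), names(targets))
  out <- list()
  for (m in names(mirnas)) {
    seed6 <- revcomp(substr(mirnas[m], 2, 7))
    m8 <- complement_base(substr(mirnas[m], 8, 8))
    for (tg in names(targets)) {
      tseq <- targets[tg]
      hits <- gregexpr(seed6, tseq, fixed = TRUE)[[1]]
      if (hits[1] == -1) next
      for (pos in as.integer(hits)) { # 1-based start of the 6mer core
        has_m8 <- pos > 1 && substr(tseq, pos - 1, pos - 1) == m8
        has_a1 <- pos + 6 <= nchar(tseq) &&
          substr(tseq, pos + 6, pos + 6) == "A"
        type <- if (has_m8 && has_a1) "8mer"
          else if (has_m8) "7mer-m8"
          else if (has_a1) "7mer-A1"
          else "6mer"
        out[[length(out) + 1L]] <- data.frame(
          mirna_id = m, target_id = tg,
          target_class = unname(target_class[tg]),
          site_type = type, position = pos, stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(mirna_id = character(), target_id = character(),
               target_class = character(), site_type = character(),
               position = integer())
  class(res) <- c("target_edges", class(res))
  res
}

#' Pearson co-expression gating of candidate pairs
#'
#' Computes Pearson r across all supplied samples for each candidate pair,
#' a two-sided p value from the t transform `t = r sqrt((n-2)/(1-r^2))`,
#' and BH-adjusted p over exactly the tested pair set. An edge is retained
#' iff `r > r_cut` and `adj_p < adjp_cut` (both strict, as printed).
#' Zero-variance vectors are skipped with the reason logged in attribute
#' `"skipped"`.
#'
#' @param mat_x,mat_y features x samples matrices with aligned columns
#'   (may be the same matrix).
#' @param pairs data frame with columns `x_id`, `y_id` (row names of
#'   `mat_x` / `mat_y`).
#' @param r_cut,adjp_cut retention thresholds (defaults 0.9 and 0.1).
#' @return data frame of class `coexpression_edges`: `x_id`, `y_id`,
#'   `pearson_r`, `p_value`, `adj_p`, `retained`.
#' @export
correlate_pairs <- function(mat_x, mat_y, pairs, r_cut = 0.9,
                            adjp_cut = 0.1) {
  stopifnot(ncol(mat_x) == ncol(mat_y))
  n <- ncol(mat_x)
  if (n < 3) stop("need >= 3 paired samples")
  keep <- logical(nrow(pairs)); r <- numeric(nrow(pairs))
  skipped <- list()
  for (i in seq_len(nrow(pairs))) {
    x <- mat_x[pairs$x_id[i], ]; y <- mat_y[pairs$y_id[i], ]
    if (var(x) == 0 || var(y) == 0) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        x_id = pairs$x_id[i], y_id = pairs$y_id[i],
        reason = "zero_variance", stringsAsFactors = FALSE)
      r[i] <- NA; next
    }
    keep[i] <- TRUE
    r[i] <- cor(x, y)
  }
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.xmin))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[!keep] <- NA
  out <- data.frame(x_id = pairs$x_id, y_id = pairs$y_id, pearson_r = r,
                    p_value = p, adj_p = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  out$retained <- !is.na(out$pearson_r) & out$pearson_r > r_cut &
    !is.na(out$adj_p) & out$adj_p < adjp_cut
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(x_id = character(), y_id = character(), reason = character())
  class(out) <- c("coexpression_edges", class(out))
  out
}

#' Assemble the ceRNA regulatory network
#'
#' A triplet (ceRNA, miRNA, mRNA) enters the network iff: the miRNA has a
#' seed-match edge to both the ceRNA and the mRNA; all three are
#' differentially expressed; the ceRNA and mRNA share a DE direction; the
#' miRNA is DE in the opposite direction (ceRNA logic; set
#' `mirna_rule = "any"` to drop the direction requirement); and the
#' ceRNA-mRNA pair passed the co-expression gate. Four sub-networks are
#' emitted: {circRNA, lncRNA} x {up, down}. Triplets excluded solely by the
#' miRNA-direction rule are logged in attribute `"mirna_direction_excluded"`
#' so the permissive alternative stays auditable.
#'
#' @param de combined `de_records` for all classes (one row per feature).
#' @param target_edges [predict_targets()] output (or an externally
#'   supplied table in the same schema).
#' @param coexp_edges [correlate_pairs()] output over ceRNA-mRNA pairs.
#' @param mirna_rule `"opposite"` (default) or `"any"`.
#' @return object of class `cerna_network`: list with `nodes`, `edges`,
#'   `triplets`, `subnetworks` (per-sub-network node composition).
#' @export
assemble_network <- function(de, target_edges, coexp_edges,
                             mirna_rule = c("opposite", "any")) {
  mirna_rule <- match.arg(mirna_rule)
  ids <- unique(c(target_edges$mirna_id, target_edges$target_id))
  missing <- setdiff(ids, de$feature_id)
  if (length(missing))
    stop("feature id(s) in edges but absent from the DE table: ",
         paste(missing, collapse = ", "))
  status <- setNames(de$status, de$feature_id)
  cls <- setNames(de$class, de$feature_id)

  ce_edges <- target_edges[target_edges$target_class %in%
                             c("circRNA", "lncRNA"), , drop = FALSE]
  m_edges <- target_edges[target_edges$target_class == "mRNA", , drop = FALSE]
  coexp_key <- paste(coexp_edges$x_id, coexp_edges$y_id)
  retained <- coexp_edges$retained

  trips <- list(); excluded <- list()
  for (mir in intersect(unique(ce_edges$mirna_id), unique(m_edges$mirna_id))) {
    cerna_ids <- unique(ce_edges$target_id[ce_edges$mirna_id == mir])
    mrna_ids <- unique(m_edges$target_id[m_edges$mirna_id == mir])
    for (ce in cerna_ids) for (mr in mrna_ids) {
      s_ce <- status[ce]; s_mr <- status[mr]; s_mi <- status[mir]
      if (s_ce == "ns" || s_mr == "ns" || s_ce != s_mr) next
      k <- match(paste(ce, mr), coexp_key)
      if (is.na(k)) k <- match(paste(mr, ce), coexp_key)
      if (is.na(k) || !retained[k]) next
      row <- data.frame(
        cerna_id = ce, cerna_class = unname(cls[ce]), mirna_id = mir,
        mrna_id = mr, direction = unname(s_ce),
        pearson_r = coexp_edges$pearson_r[k],
        adj_p = coexp_edges$adj_p[k], stringsAsFactors = FALSE)
      ok_mir <- s_mi != "ns" &&
        (mirna_rule == "any" || s_mi != s_ce)
      if (s_mi == "ns") next # all three members must be DE
      if (ok_mir) trips[[length(trips) + 1L]] <- row
      else excluded[[length(excluded) + 1L]] <- row
    }
  }
  triplets <- if (length(trips)) do.call(rbind, trips) else
    data.frame(cerna_id = character(), cerna_class = character(),
               mirna_id = character(), mrna_id = character(),
               direction = character(), pearson_r = numeric(),
               adj_p = numeric())
  triplets$subnetwork <- if (nrow(triplets))
    paste0(ifelse(triplets$cerna_class == "circRNA", "circ", "lnc"),
           "-", triplets$direction) else character(0)
  triplets <- df_sort(triplets, c("subnetwork", "cerna_id", "mirna_id",
                                  "mrna_id"))

  node_ids <- unique(c(triplets$cerna_id, triplets$mirna_id,
                       triplets$mrna_id))
  nodes <- data.frame(id = node_ids, class = unname(cls[node_ids]),
                      status = unname(status[node_ids]),
                      stringsAsFactors = FALSE)
  edges <- unique(rbind(
    data.frame(from = triplets$mirna_id, to = triplets$cerna_id,
               type = "mirna-target", stringsAsFactors = FALSE),
    data.frame(from = triplets$mirna_id, to = triplets$mrna_id,
               type = "mirna-target", stringsAsFactors = FALSE),
    data.frame(from = triplets$cerna_id, to = triplets$mrna_id,
               type = "coexpression", stringsAsFactors = FALSE)))
  rownames(edges) <- NULL
  subnetworks <- subnetwork_summary(triplets, cls)
  net <- structure(list(nodes = nodes, edges = edges, triplets = triplets,
                        subnetworks = subnetworks), class = "cerna_network")
  attr(net, "mirna_direction_excluded") <-
    if (length(excluded)) do.call(rbind, excluded) else triplets[0, 1:7]
  net
}

subnetwork_summary <- function(triplets, cls) {
  labs <- c("circ-up", "circ-down", "lnc-up", "lnc-down")
  do.call(rbind, lapply(labs, function(l) {
    t <- triplets[triplets$subnetwork == l, , drop = FALSE]
    data.frame(subnetwork = l,
               n_cerna = length(unique(t$cerna_id)),
               n_mirna = length(unique(t$mirna_id)),
               n_mrna = length(unique(t$mrna_id)),
               n_triplets = nrow(t), stringsAsFactors = FALSE)
  }))
}

#' @export
print.cerna_network <- function(x, ...) {
  cat("cerna_network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges,",
      nrow(x$triplets), "triplets\n")
  print(x$subnetworks, row.names = FALSE)
  invisible(x)
}

#' Export a ceRNA network to SIF or GraphML
#'
#' SIF rows are `from <edge type> to` (tab-separated, sorted); GraphML
#' carries `class` and `status` node attributes and the `type` edge
#' attribute (written through igraph). Both formats round-trip through
#' [import_network()].
#'
#' @param net `cerna_network`.
#' @param path output file.
#' @param format `"sif"` or `"graphml"` (default: from file extension).
#' @return invisibly, `path`.
#' @export
export_network <- function(net, path, format = c("auto", "sif", "graphml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sif$", path)) "sif"
      else if (grepl("\\.graphml$", path)) "graphml"
      else stop("cannot infer format from path: ", path)
  e <- df_sort(net$edges, c("from", "type", "to"))
  if (format == "sif") {
    writeLines(sprintf("%s\t%s\t%s", e$from, e$type, e$to), path)
  } else {
    g <- igraph::graph_from_data_frame(
      e, directed = FALSE,
      vertices = df_sort(net$nodes, "id"))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Import a network written by [export_network()]
#'
#' @param path SIF or GraphML file.
#' @param format `"sif"`, `"graphml"` or `"auto"`.
#' @return list with `nodes` and `edges` data frames (SIF carries no node
#'   attributes).
#' @export
import_network <- function(path, format = c("auto", "sif", "graphml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sif$", path)) "sif"
      else if (grepl("\\.graphml$", path)) "graphml"
      else stop("cannot infer format from path: ", path)
  if (format == "sif") {
    f <- strsplit(readLines(path), "\t")
    edges <- data.frame(from = vapply(f, `[`, "", 1),
                        type = vapply(f, `[`, "", 2),
                        to = vapply(f, `[`, "", 3), stringsAsFactors = FALSE)
    nodes <- data.frame(id = sort(unique(c(edges$from, edges$to))),
                        stringsAsFactors = FALSE)
    list(nodes = nodes, edges = edges[, c("from", "to", "type")])
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(id = igraph::V(g)$name,
                        class = igraph::V(g)$class,
                        status = igraph::V(g)$status,
                        stringsAsFactors = FALSE)
    ee <- igraph::as_data_frame(g, what = "edges")
    list(nodes = nodes, edges = data.frame(from = ee$from, to = ee$to,
                                           type = ee$type,
                                           stringsAsFactors = FALSE))
  }
}

#' Candidate ceRNA-mRNA pairs sharing a miRNA
#'
#' Enumerates the pairs the co-expression gate should test: every
#' (ceRNA, mRNA) combination connected through at least one shared miRNA in
#' the target-edge table.
#'
#' @param target_edges [predict_targets()] output.
#' @return data frame with `x_id` (ceRNA), `y_id` (mRNA).
#' @export
candidate_pairs <- function(target_edges) {
  ce <- target_edges[target_edges$target_class %in% c("circRNA", "lncRNA"), ]
  mr <- target_edges[target_edges$target_class == "mRNA", ]
  out <- unique(merge(unique(ce[, c("mirna_id", "target_id")]),
                      unique(mr[, c("mirna_id", "target_id")]),
                      by = "mirna_id")[, c("target_id.x", "target_id.y")])
  names(out) <- c("x_id", "y_id")
  out <- unique(out)
  rownames(out) <- NULL
  df_sort(out, c("x_id", "y_id"))
}
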