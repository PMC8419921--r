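## Planted expression truth: two-group (pre/post-IFN) paired design with
## planted fold changes, planted ceRNA triplets realized through shared
## per-patient latent factors, and miRNA seed sites written into the genome
## so target prediction is exact by construction.
##
## Generative model (log2 scale), feature f, patient p, group g in {0,1}:
##   log2 x = base_f + lfc_f * g + alpha_f * z_{f,p} + noise
## where z_{f,p} ~ N(0,1) is shared between the two samples of a patient
## (the paired design) and, within a ceRNA triplet, shared across the
## triplet's ceRNA and mRNA (coefficient +alpha) and its miRNA (-alpha).
## Two features of one triplet are therefore exactly collinear in log space
## before noise, while features of different triplets share only the group
## shift. Counts are 2^x rounded when noise_sd > 0; in the noiseless limit
## rounding is skipped so planted fold changes and correlations are exact.

#' Synthetic expression/truth configuration
#'
#' @param n_trip_circ,n_trip_lnc planted ceRNA triplets with circRNA /
#'   lncRNA ceRNAs (split evenly between up and down directions).
#' @param de_mrna,de_lncrna,de_mirna,de_circ standalone planted DE feature
#'   counts (split evenly up/down), on top of triplet members.
#' @param lfc_triplet,lfc_standalone planted |log2 fold change|.
#' @param alpha_triplet,alpha_standalone latent-factor coupling (log2 sd).
#' @param base_mean,base_sd baseline log2 abundance distribution.
#' @param n_per_group samples per group (paired patients).
#' @param noise_sd per-sample log2 noise sd.
#' @param count_model `"lognormal"` (rounded) or `"nb"` (negative binomial
#'   with dispersion `nb_size`).
#' @param nb_size NB size parameter (1/dispersion).
#' @return list of class `synth_expr_config`.
#' @export
expr_config <- function(n_trip_circ = 6L, n_trip_lnc = 6L,
                        de_mrna = 14L, de_lncrna = 7L, de_mirna = 8L,
                        de_circ = 10L,
                        lfc_triplet = 4, lfc_standalone = 3,
                        alpha_triplet = 2.2, alpha_standalone = 2,
                        base_mean = 10, base_sd = 1.2,
                        n_per_group = 9L, noise_sd = 0.5,
                        count_model = c("lognormal", "nb"), nb_size = 20,
                        lib_background = 1e7) {
  stopifnot(n_per_group >= 3)
  structure(as.list(environment()), class = "synth_expr_config")
}

#' Build the planted expression truth table (and inject seed sites)
#'
#' Chooses triplet members and standalone DE features, writes an 8mer seed
#' site for each triplet's miRNA into the ceRNA and mRNA sequences (through
#' the genome text, inside exon interiors), and scrubs chance seed matches
#' of DE miRNAs from DE transcripts so the planted triplets are the only
#' fully-gated ceRNA paths in the truth. Non-DE features keep any chance
#' matches: realistic target-table noise downstream gates must reject.
#'
#' @param gm `genome_model` (after [plant_circrnas()]).
#' @param circs planted circRNA table.
#' @param config an [expr_config()].
#' @param seed integer seed.
#' @return list with `genome` (sites injected), `truth` (class
#'   `expr_truth`): `features` (feature_id, class, length, base, lfc,
#'   alpha, factor_id), `triplets` (triplet_id, cerna_id, cerna_class,
#'   mirna_id, mrna_id, direction), `sites` (planted site registry).
#' @export
plant_expression_truth <- function(gm, circs, config = expr_config(),
                                   seed = 1L) {
  stopifnot(inherits(config, "synth_expr_config"))
  with_seed(seed, {
    callable <- circs[circs$callable, , drop = FALSE]
    genes <- gm$genes
    mrna <- genes$gene_id[genes$rna_class == "mRNA"]
    lnc <- genes$gene_id[genes$rna_class == "lncRNA"]
    mir <- genes$gene_id[genes$rna_class == "miRNA"]

    n_trip <- config$n_trip_circ + config$n_trip_lnc
    stopifnot(nrow(callable) >= config$n_trip_circ,
              length(lnc) >= config$n_trip_lnc + config$de_lncrna,
              length(mir) >= n_trip + config$de_mirna,
              length(mrna) >= n_trip + config$de_mrna)

    ## triplet circRNAs get distinct host genes, and no host gene carries
    ## planted DE of its own: a host transcript contains its circRNA's
    ## injected seed site, so a DE host would hand the truth an unplanted
    ## fully-gated edge
    ord <- sample.int(nrow(callable))
    keep <- ord[!duplicated(callable$gene_id[ord])]
    stopifnot(length(keep) >= config$n_trip_circ)
    trip_circ <- callable$circ_id[keep[seq_len(config$n_trip_circ)]]
    hosts <- callable$gene_id[match(trip_circ, callable$circ_id)]
    mrna_pool <- setdiff(mrna, hosts)
    trip_lnc <- sample(setdiff(lnc, hosts), config$n_trip_lnc)
    ## DE miRNAs must be seed-compatible: no DE miRNA's 6mer core may be a
    ## substring of another triplet miRNA's injected 8mer site, or the
    ## shared planted site would hand the decoy a protected seed match in
    ## both members of that triplet
    mir_sel <- select_compatible_mirnas(gm, mir, n_trip, config$de_mirna)
    trip_mir <- mir_sel$triplet
    trip_mrna <- sample(mrna_pool, n_trip)

    cerna_ids <- c(trip_circ, trip_lnc)
    cerna_cls <- rep(c("circRNA", "lncRNA"),
                     c(config$n_trip_circ, config$n_trip_lnc))
    dir_pool <- function(n) rep(c("up", "down"), length.out = n)
    direction <- c(dir_pool(config$n_trip_circ), dir_pool(config$n_trip_lnc))
    triplets <- data.frame(
      triplet_id = sprintf("trip%02d", seq_len(n_trip)),
      cerna_id = cerna_ids, cerna_class = cerna_cls,
      mirna_id = trip_mir, mrna_id = trip_mrna, direction = direction,
      stringsAsFactors = FALSE)

    ## standalone DE features (avoid triplet members and triplet-circ hosts)
    pick_de <- function(pool, used, n) sample(setdiff(pool, used), n)
    de_mrna <- pick_de(mrna, c(trip_mrna, hosts), config$de_mrna)
    de_lnc <- pick_de(lnc, c(trip_lnc, hosts), config$de_lncrna)
    de_mir <- mir_sel$standalone
    ## standalone DE circs must not live on a triplet host either (their
    ## sequence would contain the host's injected site)
    de_circ <- pick_de(callable$circ_id[!callable$gene_id %in% hosts],
                       trip_circ, config$de_circ)

    ## feature registry
    tx_len <- function(gid) {
      e <- gm$exons[gm$exons$gene_id == gid, ]
      sum(e$end - e$start)
    }
    circ_len <- function(cid) {
      p <- callable[callable$circ_id == cid, ]
      e <- gm$exons[gm$exons$gene_id == p$gene_id, ]
      sum((e$end - e$start)[p$exon_from:p$exon_to])
    }
    feat <- function(ids, cls, lens) {
      data.frame(feature_id = ids, class = cls, length = lens,
                 base = rnorm(length(ids), config$base_mean, config$base_sd),
                 lfc = 0, alpha = 0, factor_id = NA_integer_,
                 stringsAsFactors = FALSE)
    }
    features <- rbind(
      feat(mrna, "mRNA", vapply(mrna, tx_len, 0)),
      feat(lnc, "lncRNA", vapply(lnc, tx_len, 0)),
      feat(mir, "miRNA", vapply(mir, tx_len, 0)),
      feat(callable$circ_id, "circRNA",
           vapply(callable$circ_id, circ_len, 0)))
    rownames(features) <- NULL

    set_de <- function(features, ids, lfc, alpha, factor_ids = NA_integer_) {
      i <- match(ids, features$feature_id)
      features$lfc[i] <- lfc
      features$alpha[i] <- alpha
      features$factor_id[i] <- factor_ids
      features
    }
    sgn <- function(dirs) ifelse(dirs == "up", 1, -1)
    ## triplet members share a latent factor; the miRNA is anti-coupled
    features <- set_de(features, triplets$cerna_id,
                       sgn(direction) * config$lfc_triplet,
                       config$alpha_triplet, seq_len(n_trip))
    features <- set_de(features, triplets$mrna_id,
                       sgn(direction) * config$lfc_triplet,
                       config$alpha_triplet, seq_len(n_trip))
    features <- set_de(features, triplets$mirna_id,
                       -sgn(direction) * config$lfc_triplet,
                       -config$alpha_triplet, seq_len(n_trip))
    ## standalone DE features get independent factors
    standalone <- c(de_mrna, de_lnc, de_mir, de_circ)
    features <- set_de(features, standalone,
                       sgn(dir_pool(length(standalone))) * config$lfc_standalone,
                       config$alpha_standalone,
                       n_trip + seq_along(standalone))

    ## inject an 8mer site for each triplet's miRNA into ceRNA and mRNA
    sites <- list()
    for (t in seq_len(n_trip)) {
      mseq <- transcript_seq(gm, triplets$mirna_id[t])
      site <- paste0(revcomp(substr(mseq, 2, 8)), "A")
      for (tgt in c(triplets$cerna_id[t], triplets$mrna_id[t])) {
        loc <- site_location(gm, callable, tgt)
        gm <- inject_site(gm, loc, site)
        sites[[length(sites) + 1L]] <- data.frame(
          mirna_id = triplets$mirna_id[t], target_id = tgt,
          chrom = loc$chrom, gpos = loc$gpos, strand = loc$strand,
          stringsAsFactors = FALSE)
      }
    }
    sites <- if (length(sites)) do.call(rbind, sites) else
      data.frame(mirna_id = character(), target_id = character(),
                 chrom = character(), gpos = integer(), strand = character())

    ## scrub chance seed matches of DE miRNAs from DE transcripts
    de_mirnas <- features$feature_id[features$class == "miRNA" &
                                     features$lfc != 0]
    de_targets <- features$feature_id[features$class != "miRNA" &
                                      features$lfc != 0]
    gm <- scrub_chance_sites(gm, callable, de_mirnas, de_targets, sites)

    truth <- structure(list(features = features, triplets = triplets,
                            sites = sites, circs = circs,
                            config = config), class = "expr_truth")
    list(genome = gm, truth = truth)
  })
}

## greedily pick triplet + standalone DE miRNAs so that no DE miRNA's seed
## core occurs inside any triplet miRNA's (to-be-injected) 8mer site
select_compatible_mirnas <- function(gm, mir_pool, n_trip, n_standalone) {
  seqs <- vapply(mir_pool, function(m) transcript_seq(gm, m), "")
  core <- vapply(seqs, function(s) revcomp(substr(s, 2, 7)), "")
  site <- vapply(seqs, function(s) paste0(revcomp(substr(s, 2, 8)), "A"), "")
  pool <- sample(mir_pool)
  trip <- character(0)
  for (m in pool) {
    ok <- all(!vapply(trip, function(t)
      grepl(core[m], site[t], fixed = TRUE) ||
      grepl(core[t], site[m], fixed = TRUE), TRUE))
    if (ok) trip <- c(trip, m)
    if (length(trip) == n_trip) break
  }
  if (length(trip) < n_trip)
    stop("could not find ", n_trip, " seed-compatible triplet miRNAs")
  stand <- character(0)
  for (m in setdiff(pool, trip)) {
    ok <- all(!vapply(trip, function(t)
      grepl(core[m], site[t], fixed = TRUE), TRUE))
    if (ok) stand <- c(stand, m)
    if (length(stand) == n_standalone) break
  }
  if (length(stand) < n_standalone)
    stop("could not find ", n_standalone, " seed-compatible DE miRNAs")
  list(triplet = trip, standalone = stand)
}

## where to write a planted site: exon interior, offset 40 from the exonic
## 5' end of the relevant exon (first circle exon for circRNAs, first exon
## for genes) -- comfortably clear of all splice windows
site_location <- function(gm, callable, target_id) {
  if (target_id %in% callable$circ_id) {
    p <- callable[callable$circ_id == target_id, ]
    e <- gm$exons[gm$exons$gene_id == p$gene_id, ]
    ex <- e[p$exon_from, ]
  } else {
    e <- gm$exons[gm$exons$gene_id == target_id, ]
    ex <- e[1, ]
  }
  if (ex$strand == "+") {
    list(chrom = ex$chrom, gpos = ex$start + 40L, strand = "+")
  } else {
    list(chrom = ex$chrom, gpos = ex$end - 40L - 8L, strand = "-")
  }
}

inject_site <- function(gm, loc, site) {
  s <- if (loc$strand == "-") revcomp(site) else site
  gm$chroms[[loc$chrom]] <- replace0(gm$chroms[[loc$chrom]], loc$gpos, s)
  gm
}

## remove chance 6mer seed cores of DE miRNAs from DE transcript sequences
## by mutating one base; planted-site intervals and exon-boundary margins
## are never touched
scrub_chance_sites <- function(gm, callable, de_mirnas, de_targets, sites,
                               max_pass = 5L) {
  if (!length(de_mirnas) || !length(de_targets)) return(gm)
  seeds <- vapply(de_mirnas, function(m)
    revcomp(substr(transcript_seq(gm, m), 2, 7)), "")
  for (pass in seq_len(max_pass)) {
    changed <- FALSE
    for (tgt in de_targets) {
      tl <- target_seq_spec(gm, callable, tgt)
      tseq <- tl$seq
      for (mi in seq_along(seeds)) {
        protected <- sites$gpos[sites$target_id == tgt &
                                sites$mirna_id == de_mirnas[mi]]
        m <- gregexpr(seeds[mi], tseq, fixed = TRUE)[[1]]
        if (m[1] == -1) next
        for (off in as.integer(m) - 1L) { # transcript offset of the 6mer
          ## mutate one core base (transcript positions are exonic, so the
          ## GT..AG signals are never touched); planted 8mer intervals are
          ## protected
          for (b in c(2L, 3L, 4L, 1L, 0L, 5L)) {
            g <- tl$to_genomic(off + b)
            if (is.null(g)) next
            if (in_planted(sites, tl, off, g)) next # protected base
            old <- subseq0(gm$chroms[[g$chrom]], g$pos, g$pos + 1L)
            new <- BASES[match(old, BASES) %% 4 + 1]
            gm$chroms[[g$chrom]] <- replace0(gm$chroms[[g$chrom]], g$pos, new)
            changed <- TRUE
            break
          }
        }
        tl <- target_seq_spec(gm, callable, tgt) # refresh after edits
        tseq <- tl$seq
      }
    }
    if (!changed) break
  }
  gm
}

## is this 6mer occurrence part of a planted (protected) site?
in_planted <- function(sites, tl, off, g) {
  if (!nrow(sites)) return(FALSE)
  hits <- sites$chrom == g$chrom & g$pos >= sites$gpos &
          g$pos < sites$gpos + 8L
  any(hits)
}

## sequence of a DE target (transcript or circRNA) plus an offset-to-genome
## mapper
target_seq_spec <- function(gm, callable, target_id) {
  if (target_id %in% callable$circ_id) {
    p <- callable[callable$circ_id == target_id, ]
    e <- gm$exons[gm$exons$gene_id == p$gene_id, ]
    e <- e[p$exon_from:p$exon_to, , drop = FALSE]
  } else {
    e <- gm$exons[gm$exons$gene_id == target_id, ]
  }
  strand <- e$strand[1]; chrom <- e$chrom[1]
  parts <- subseq0(gm$chroms[[chrom]], e$start, e$end)
  s <- paste(parts, collapse = "")
  if (strand == "-") s <- revcomp(s)
  etx <- if (strand == "-") e[rev(seq_len(nrow(e))), ] else e
  cum <- cumsum(c(0L, etx$end - etx$start))
  to_genomic <- function(off) {
    if (off < 0 || off >= cum[length(cum)]) return(NULL)
    i <- findInterval(off, cum)
    within <- off - cum[i]
    if (strand == "+")
      list(chrom = chrom, pos = etx$start[i] + within,
           exon_len = etx$end[i] - etx$start[i], exon_offset = within)
    else
      list(chrom = chrom, pos = etx$end[i] - within - 1L,
           exon_len = etx$end[i] - etx$start[i], exon_offset = within)
  }
  list(seq = s, to_genomic = to_genomic)
}

#' Circular RNA sequence implied by the annotation
#'
#' Spliced sequence of the host-gene exons inside the back-splice span
#' (transcript orientation).
#'
#' @param gm `genome_model`.
#' @param circs planted circRNA table (or any table with `circ_id`,
#'   `gene_id`, `exon_from`, `exon_to`).
#' @param circ_id circRNA id.
#' @return character scalar (DNA).
#' @export
circ_seq <- function(gm, circs, circ_id) {
  target_seq_spec(gm, circs[!is.na(circs$gene_id), ], circ_id)$seq
}

#' Simulate two-group paired expression matrices
#'
#' Realizes the generative model above for every RNA class in the truth.
#' At `noise_sd = 0` counts stay continuous, so planted fold changes and
#' within-triplet correlations are exact; with noise, counts are rounded
#' (or NB-sampled under `count_model = "nb"`).
#'
#' @param truth `expr_truth` from [plant_expression_truth()] (or
#'   [null_expression_truth()]).
#' @param n_per_group samples per group (default from the truth's config).
#' @param noise_sd log2 noise sd (default from config).
#' @param seed integer seed.
#' @return list of class `expr_set`: per-class list with `counts`
#'   (features x samples), plus `groups`, `patients`, `classes`.
#' @export
simulate_expression <- function(truth, n_per_group = NULL, noise_sd = NULL,
                                seed = 1L) {
  cfg <- truth$config
  n_per_group <- n_per_group %||% cfg$n_per_group
  noise_sd <- noise_sd %||% cfg$noise_sd
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(n_per_group >= 3)
  with_seed(seed, {
    f <- truth$features
    n_s <- 2L * n_per_group
    groups <- rep(c("A", "B"), each = n_per_group)
    patients <- rep(seq_len(n_per_group), 2)
    g <- as.integer(groups == "B")
    n_fac <- max(c(0L, f$factor_id), na.rm = TRUE)
    z <- if (n_fac > 0) matrix(rnorm(n_fac * n_per_group), n_fac) else
      matrix(0, 0, n_per_group)

    logx <- matrix(f$base, nrow(f), n_s) +
      outer(f$lfc, g) # group shift
    has_fac <- !is.na(f$factor_id)
    if (any(has_fac))
      logx[has_fac, ] <- logx[has_fac, ] +
        f$alpha[has_fac] * z[f$factor_id[has_fac], patients, drop = FALSE]
    if (noise_sd > 0)
      logx <- logx + matrix(rnorm(nrow(f) * n_s, 0, noise_sd), nrow(f))

    vals <- 2^logx
    if (noise_sd > 0) {
      vals <- if (cfg$count_model[1] == "nb")
        matrix(rnbinom(length(vals), mu = vals, size = cfg$nb_size), nrow(f))
      else round(vals)
    }
    dimnames(vals) <- list(f$feature_id,
                           paste0(groups, patients))
    ## per-sample library size = counted features + the mapped reads that
    ## fall outside the counted set (linear transcripts, rRNA, ...): the
    ## counted features are a sliver of a real library
    out <- lapply(split(seq_len(nrow(f)), f$class), function(i)
      list(counts = vals[i, , drop = FALSE],
           lengths = setNames(f$length[i], f$feature_id[i]),
           lib_sizes = colSums(vals[i, , drop = FALSE]) +
             cfg$lib_background))
    structure(list(matrices = out, groups = groups, patients = patients,
                   noise_sd = noise_sd), class = "expr_set")
  })
}

#' Truth table with only null features (no planted signal)
#'
#' Used for calibration runs: features have baseline expression and no fold
#' change or factor structure.
#'
#' @param n_features number of features.
#' @param rna_class class label.
#' @param config an [expr_config()].
#' @param seed integer seed (draws baselines).
#' @return `expr_truth` object.
#' @export
null_expression_truth <- function(n_features, rna_class = "mRNA",
                                  config = expr_config(), seed = 1L) {
  with_seed(seed, {
    features <- data.frame(
      feature_id = sprintf("null%05d", seq_len(n_features)),
      class = rna_class, length = 1000,
      base = rnorm(n_features, config$base_mean, config$base_sd),
      lfc = 0, alpha = 0, factor_id = NA_integer_, stringsAsFactors = FALSE)
    structure(list(features = features,
                   triplets = data.frame(), sites = data.frame(),
                   circs = data.frame(), config = config),
              class = "expr_truth")
  })
}

#' Emit miRNA-target interaction tables by seed matching
#'
#' Scans every miRNA sequence against every mRNA transcript, lncRNA
#' transcript and circRNA sequence; a row exists iff a canonical seed site
#' (6mer/7mer-A1/7mer-m8/8mer) fires. All planted triplet edges are present
#' by construction.
#'
#' @param gm `genome_model` (after site injection).
#' @param truth `expr_truth`.
#' @return data frame: `mirna_id`, `target_id`, `target_class`,
#'   `site_type`, `position` (1-based on the target).
#' @export
emit_target_tables <- function(gm, truth) {
  f <- truth$features
  mir_ids <- f$feature_id[f$class == "miRNA"]
  mirs <- setNames(vapply(mir_ids, function(m) transcript_seq(gm, m), ""),
                   mir_ids)
  callable <- truth$circs[truth$circs$callable, , drop = FALSE]
  tgt_ids <- f$feature_id[f$class != "miRNA"]
  tgts <- setNames(vapply(tgt_ids, function(tid)
    target_seq_spec(gm, callable, tid)$seq, ""), tgt_ids)
  cls <- setNames(f$class[match(tgt_ids, f$feature_id)], tgt_ids)
  predict_targets(mirs, tgts, target_class = cls)
}
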