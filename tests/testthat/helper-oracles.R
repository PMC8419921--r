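# Independent oracles, implemented from the definitions (never calling the
# package's own code paths they check).

# brute-force back-splice candidate scan over all ordered segment pairs of
# every read; returns accepted junctions and per-read first-violation
# reasons
oracle_candidates <- function(aln, max_sep = 1e6) {
  acc <- list(); rej <- list()
  for (rid in unique(aln$read_id)) {
    seg <- aln[aln$read_id == rid, , drop = FALSE]
    if (nrow(seg) < 2) next
    seg <- seg[order(seg$query_start), , drop = FALSE]
    junction <- NULL; reason <- NULL
    for (i in seq_len(nrow(seg) - 1)) {
      for (j in seq(i + 1, nrow(seg))) {
        a <- seg[i, ]; b <- seg[j, ]
        r <- NULL
        if (a$chrom != b$chrom) r <- "diff_chrom"
        else if (a$strand != b$strand) r <- "strand_mismatch"
        else {
          if (a$strand == "+") { s <- b$start; e <- a$end }
          else { s <- a$start; e <- b$end }
          if (abs(b$start - a$start) > max_sep || e - s > max_sep)
            r <- "too_far"
          else {
            rev_ok <- if (a$strand == "+") b$start < a$start
                      else b$start > a$start
            if (!rev_ok || e - s <= 0) r <- "same_order"
          }
        }
        if (is.null(r)) {
          junction <- c(chrom = a$chrom, strand = a$strand, start = s, end = e)
          break
        }
        if (is.null(reason)) reason <- r
      }
      if (!is.null(junction)) break
    }
    if (!is.null(junction)) acc[[rid]] <- junction
    else rej[[rid]] <- reason
  }
  list(accepted = acc, rejected = rej)
}

# textbook BH step-up: q_(i) = min_{j >= i} ( p_(j) * m / j ), capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- Inf
  for (i in seq(m, 1)) {
    val <- min(prev, p[o[i]] * m / i, 1)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# exhaustive hypergeometric upper tail
oracle_hyper_upper <- function(k, K, N, n) {
  js <- seq(k, min(n, K))
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# sliding-window seed-site scan from the definitions
oracle_seed_sites <- function(mirna, target) {
  comp <- function(x) chartr("ACGT", "TGCA", x)
  rc <- function(x) paste(rev(strsplit(comp(x), "")[[1]]), collapse = "")
  seed6 <- rc(substr(mirna, 2, 7))
  m8c <- comp(substr(mirna, 8, 8))
  out <- list()
  for (pos in seq_len(nchar(target) - 5)) {
    if (substr(target, pos, pos + 5) != seed6) next
    has_m8 <- pos > 1 && substr(target, pos - 1, pos - 1) == m8c
    has_a1 <- pos + 6 <= nchar(target) &&
      substr(target, pos + 6, pos + 6) == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
      else if (has_a1) "7mer-A1" else "6mer"
    out[[length(out) + 1L]] <- data.frame(position = pos, site_type = type,
                                          stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(position = integer(), site_type = character())
}

# model (population) Pearson correlation between two planted features on
# the log2 scale, from the generative parameters: shared group indicator
# (variance 1/4) plus latent factors plus independent noise
oracle_true_r <- function(truth, id_x, id_y, noise_sd) {
  f <- truth$features
  x <- f[f$feature_id == id_x, ]; y <- f[f$feature_id == id_y, ]
  shared_fac <- !is.na(x$factor_id) && !is.na(y$factor_id) &&
    x$factor_id == y$factor_id
  cov <- x$lfc * y$lfc * 0.25 + if (shared_fac) x$alpha * y$alpha else 0
  vx <- x$lfc^2 * 0.25 + x$alpha^2 + noise_sd^2
  vy <- y$lfc^2 * 0.25 + y$alpha^2 + noise_sd^2
  if (vx == 0 || vy == 0) return(0)
  cov / sqrt(vx * vy)
}

# triplet keys for set comparison
triplet_keys <- function(df) {
  if (!nrow(df)) return(character(0))
  sort(paste(df$cerna_id, df$mirna_id, df$mrna_id))
}
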