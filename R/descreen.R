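## Differential-expression screening between groups A and B at the printed
## cut-offs: |log2 fold change| > 2 with p < 0.01 (strict inequalities).

#' Screen features for differential expression
#'
#' Computes per-feature group means on the normalized scale, the fold change
#' `log2((mean_B + eps) / (mean_A + eps))`, and a p value from the selected
#' test. Status is `up` iff `log2FC > lfc_cut` and `p < p_cut`, `down` iff
#' `log2FC < -lfc_cut` and `p < p_cut`, else `ns` — all strict inequalities.
#' BH-adjusted q values are reported for transparency but never gate status.
#'
#' Tests: `welch` (default) is Welch's t on `log2(x + eps)`; with
#' `paired = TRUE` it becomes a paired t on per-patient log differences
#' (samples must be column-matched between groups). `mars` is an MA-plot
#' z-test on pooled raw counts under a random-sampling (Poisson) model, in
#' the spirit of DEGseq; `exact` is Fisher's exact test on pooled counts.
#' Both count-based tests need `counts`.
#'
#' @param mat normalized features x samples matrix.
#' @param groups factor/character of "A"/"B" per column.
#' @param test one of `"welch"`, `"mars"`, `"exact"`.
#' @param paired paired design (welch only); columns of group A and B must
#'   be in matching patient order.
#' @param lfc_cut,p_cut screening thresholds (defaults 2 and 0.01).
#' @param eps pseudo-value added before ratios/logs (default 1).
#' @param rna_class optional class label recycled into the output.
#' @param counts raw count matrix (same shape), required for `mars`/`exact`.
#' @return data frame of class `de_records`: `feature_id`, `class`,
#'   `mean_A`, `mean_B`, `log2FC`, `p_value`, `q_value`, `status`.
#' @export
de_screen <- function(mat, groups, test = c("welch", "mars", "exact"),
                      paired = FALSE, lfc_cut = 2, p_cut = 0.01, eps = 1,
                      rna_class = NA_character_, counts = NULL) {
  test <- match.arg(test)
  groups <- as.character(groups)
  stopifnot(ncol(mat) == length(groups), all(groups %in% c("A", "B")))
  a <- mat[, groups == "A", drop = FALSE]
  b <- mat[, groups == "B", drop = FALSE]
  if (test == "welch" && (ncol(a) < 2 || ncol(b) < 2))
    stop("welch test needs >= 2 samples per group")
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  lfc <- log2((mean_b + eps) / (mean_a + eps))
  p <- switch(test,
    welch = welch_p(log2(a + eps), log2(b + eps), paired = paired),
    mars = mars_p(counts, groups),
    exact = exact_p(counts, groups))
  status <- rep("ns", nrow(mat))
  sig <- !is.na(p) & p < p_cut
  status[sig & lfc > lfc_cut] <- "up"
  status[sig & lfc < -lfc_cut] <- "down"
  out <- data.frame(
    feature_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    class = rna_class, mean_A = mean_a, mean_B = mean_b, log2FC = lfc,
    p_value = p, q_value = p.adjust(p, "BH"), status = status,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "eps") <- eps
  class(out) <- c("de_records", class(out))
  out
}

## vectorized Welch / paired t on already-log-transformed matrices
welch_p <- function(la, lb, paired = FALSE) {
  if (paired) {
    stopifnot(ncol(la) == ncol(lb))
    d <- lb - la
    n <- ncol(d)
    m <- rowMeans(d)
    s2 <- apply(d, 1, var)
    t <- m / sqrt(s2 / n)
    p <- 2 * pt(-abs(t), df = n - 1)
    p[s2 == 0 & m != 0] <- 0   # constant nonzero shift
    p[s2 == 0 & m == 0] <- NA  # no signal, no variance
    return(p)
  }
  n1 <- ncol(la); n2 <- ncol(lb)
  m1 <- rowMeans(la); m2 <- rowMeans(lb)
  v1 <- apply(la, 1, var); v2 <- apply(lb, 1, var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df = df)
  p[se2 == 0 & m1 != m2] <- 0
  p[se2 == 0 & m1 == m2] <- NA
  p
}

## MA-plot z-test on pooled counts under a Poisson random-sampling model:
## M = log2(k2/N2) - log2(k1/N1), Var(M) by the delta method
mars_p <- function(counts, groups) {
  stopifnot(!is.null(counts))
  k1 <- rowSums(counts[, groups == "A", drop = FALSE])
  k2 <- rowSums(counts[, groups == "B", drop = FALSE])
  n1 <- sum(k1); n2 <- sum(k2)
  m <- log2((k2 + 0.5) / n2) - log2((k1 + 0.5) / n1)
  v <- (1 / (k1 + 0.5) + 1 / (k2 + 0.5)) / log(2)^2
  z <- m / sqrt(v)
  2 * stats::pnorm(-abs(z))
}

exact_p <- function(counts, groups) {
  stopifnot(!is.null(counts))
  k1 <- round(rowSums(counts[, groups == "A", drop = FALSE]))
  k2 <- round(rowSums(counts[, groups == "B", drop = FALSE]))
  n1 <- sum(k1); n2 <- sum(k2)
  vapply(seq_along(k1), function(i) {
    stats::fisher.test(matrix(c(k1[i], n1 - k1[i], k2[i], n2 - k2[i]), 2))$p.value
  }, 0)
}

#' Tabulate up/down/ns counts per RNA class
#'
#' @param records one `de_records` data frame or a list of them.
#' @return data frame `class` x (`up`, `down`, `ns`, `total`).
#' @export
summarize_de <- function(records) {
  if (is.data.frame(records)) records <- list(records)
  rows <- lapply(records, function(r) {
    data.frame(class = r$class[1],
               up = sum(r$status == "up"), down = sum(r$status == "down"),
               ns = sum(r$status == "ns"), total = nrow(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
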