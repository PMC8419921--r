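## Hypergeometric over-representation of network gene sets against
## user-supplied annotation (GMT), flagging significance at raw p < 0.05.

#' Read GMT gene sets
#'
#' Standard GMT: one term per line, tab-separated `term`, `description`,
#' then member genes (parsed through fgsea).
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric over-representation test
#'
#' For each term with K members in a universe of N genes and a query of n
#' genes overlapping k members, p is the upper-tail hypergeometric
#' probability of observing >= k overlaps. Results are sorted by p;
#' `significant` flags raw p < 0.05 (as printed; BH q values are reported
#' alongside but do not gate the flag).
#'
#' @param query character vector of query genes (must be a subset of
#'   `universe`; duplicates removed).
#' @param sets named list of term member vectors (e.g. [read_gmt()]).
#' @param universe character vector, the explicit finite gene universe.
#' @param p_cut significance threshold on raw p (default 0.05).
#' @return data frame of class `enrichment_results`: `term_id`, `k`, `n`,
#'   `K`, `N`, `p_value`, `q_value`, `significant`.
#' @export
ora_test <- function(query, sets, universe, p_cut = 0.05) {
  query <- unique(query)
  universe <- unique(universe)
  if (length(query) == 0) stop("empty query")
  off <- setdiff(query, universe)
  if (length(off))
    stop("query gene(s) absent from the universe: ",
         paste(off, collapse = ", "))
  sets <- lapply(sets, function(s) unique(intersect(s, universe)))
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(tid) {
    K <- length(sets[[tid]])
    k <- length(intersect(query, sets[[tid]]))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tid, k = k, n = n, K = K, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, "BH")
  out$significant <- out$p_value < p_cut
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_results", class(out))
  out
}

#' Simulate a GMT-style annotation over a gene universe
#'
#' Random term memberships, plus (optionally) one planted term enriched in
#' a supplied gene set so pipeline runs have recoverable signal.
#'
#' @param universe gene ids.
#' @param n_terms number of random terms.
#' @param term_size range of term sizes (`c(min, max)`).
#' @param planted optional character vector: genes forming the core of an
#'   extra planted term (`"planted_term"`).
#' @param seed integer seed.
#' @return named list of terms.
#' @export
simulate_annotation <- function(universe, n_terms = 25L,
                                term_size = c(5L, 15L), planted = NULL,
                                seed = 1L) {
  with_seed(seed, {
    hi <- min(term_size[2], length(universe))
    lo <- min(term_size[1], hi)
    sets <- lapply(seq_len(n_terms), function(i)
      sample(universe, sample(seq(lo, hi), 1)))
    names(sets) <- sprintf("term%03d", seq_len(n_terms))
    if (!is.null(planted) && length(planted)) {
      extra <- sample(setdiff(universe, planted),
                      min(3L, length(setdiff(universe, planted))))
      sets$planted_term <- unique(c(planted, extra))
    }
    sets
  })
}

#' Write gene sets as GMT
#'
#' @param sets named list of member vectors.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(n)
    paste(c(n, "synthetic", sets[[n]]), collapse = "\t"), ""), path)
  invisible(path)
}
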