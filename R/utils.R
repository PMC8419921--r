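#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor p.adjust pt phyper rnorm rnbinom runif setNames var
#' @importFrom utils read.delim write.table head
NULL

BASES <- c("A", "C", "G", "T")

## reverse complement of a plain character vector of DNA strings; plain
## chartr/utf8 implementation so short-window scans stay cheap
revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    intToUtf8(rev(utf8ToInt(chartr("ACGTacgt", "TGCAtgca", s))))
  }, "", USE.NAMES = FALSE)
}

complement_base <- function(x) {
  chartr("ACGTU", "TGCAA", x)
}

## substring on 0-based half-open coordinates
subseq0 <- function(seq, start, end) {
  substring(seq, start + 1L, end)
}

## overwrite seq[start, end) (0-based half-open) with replacement
replace0 <- function(seq, start, replacement) {
  stopifnot(start >= 0, start + nchar(replacement) <= nchar(seq))
  paste0(
    substring(seq, 1L, start),
    replacement,
    substring(seq, start + nchar(replacement) + 1L, nchar(seq))
  )
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

## run `expr` under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## order a data frame by the named columns
df_sort <- function(df, cols) {
  o <- do.call(order, unname(df[cols]))
  out <- df[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}
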