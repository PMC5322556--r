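# internal sequence helpers

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    comp <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# substring in element orientation; clips at sequence bounds, returns "" when empty
subseq_clip <- function(seq, start, end) {
  n <- nchar(seq)
  start <- max(1L, start)
  end <- min(n, end)
  if (start > end) return("")
  substr(seq, start, end)
}

# expand an IUPAC pattern string into the per-position allowed base sets
iupac_sets <- function(pattern) {
  tab <- list(
    A = "A", C = "C", G = "G", T = "T", U = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = DNA_BASES
  )
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(tab))
  if (length(bad)) stop("unknown IUPAC code(s): ", paste(bad, collapse = ", "))
  lapply(chars, function(ch) tab[[ch]])
}

# draw one sequence matching an IUPAC pattern
sample_iupac <- function(pattern) {
  paste(vapply(iupac_sets(pattern), function(s) {
    if (length(s) == 1L) s else sample(s, 1L)
  }, character(1)), collapse = "")
}

random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# length of the exact common prefix of two strings
common_prefix_len <- function(x, y) {
  n <- min(nchar(x), nchar(y))
  if (n == 0L) return(0L)
  xs <- strsplit(substr(x, 1, n), "", fixed = TRUE)[[1]]
  ys <- strsplit(substr(y, 1, n), "", fixed = TRUE)[[1]]
  diff <- which(xs != ys)
  if (length(diff) == 0L) n else diff[1L] - 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
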