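#' Read a rooted species tree in newick format
#'
#' A thin wrapper around [ape::read.tree()] that additionally accepts a
#' single-leaf tree (`"A;"`) and validates that leaf labels are unique.
#'
#' @param path path to a newick file, or a literal newick string.
#' @return an object of class `phylo`.
#' @export
read_species_tree <- function(path) {
  text <- if (file.exists(path)) paste(readr::read_lines(path), collapse = "") else path
  text <- trimws(text)
  if (grepl("^[^();,]+;?$", text)) {
    # single-leaf tree, which ape::read.tree does not accept
    label <- sub(";$", "", text)
    tree <- structure(
      list(edge = matrix(c(2L, 1L), 1, 2), tip.label = label,
           Nnode = 1L, edge.length = NULL),
      class = "phylo", order = "cladewise")
    return(tree)
  }
  n_open <- stringr::str_count(text, "\\(")
  n_close <- stringr::str_count(text, "\\)")
  if (n_open != n_close) stop("unbalanced parentheses in newick input")
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse newick input")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label: ", tree$tip.label[duplicated(tree$tip.label)][1])
  }
  tree
}

#' Read a locus-by-species presence/absence matrix
#'
#' @param path TSV with a `locus` column and one column per species, states
#'   coded `P` (present), `A` (absent) or `M` (missing data).
#' @return a tibble with the `locus` column and one character column per
#'   species.
#' @export
read_presence_matrix <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!"locus" %in% names(m)) stop("presence matrix needs a 'locus' column")
  states <- unlist(m[setdiff(names(m), "locus")], use.names = FALSE)
  bad <- setdiff(unique(states), c("P", "A", "M"))
  if (length(bad)) stop("invalid state(s) in presence matrix: ", paste(bad, collapse = ", "))
  if (nrow(m)) {
    all_missing <- apply(m[setdiff(names(m), "locus")] == "M", 1, all)
    if (any(all_missing)) stop("locus '", m$locus[which(all_missing)[1]], "' has no non-missing state")
  }
  m
}

#' Write a presence/absence matrix
#' @param matrix tibble as returned by [read_presence_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(matrix, path) {
  readr::write_tsv(matrix, path)
  invisible(path)
}

#' Read an EMBOSS-style substitution matrix
#'
#' Whitespace-separated square table with a header row and column of symbols,
#' e.g. the format of EMBOSS data files. Returns the 5x5 integer matrix over
#' `A,C,G,T,N` used by the aligners; symbols absent from the file score 0
#' against everything.
#'
#' @param path path to the matrix file.
#' @return a 5x5 integer matrix with dimnames `A,C,G,T,N`.
#' @seealso [scoring_scheme()]
#' @export
read_score_matrix <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("empty matrix file")
  header <- toupper(strsplit(trimws(lines[1]), "\\s+")[[1]])
  out <- matrix(0L, 5, 5, dimnames = list(c(DNA_BASES, "N"), c(DNA_BASES, "N")))
  for (line in lines[-1]) {
    f <- strsplit(trimws(line), "\\s+")[[1]]
    sym <- toupper(f[1])
    vals <- suppressWarnings(as.integer(round(as.numeric(f[-1]))))
    if (length(vals) != length(header) || anyNA(vals)) {
      stop("malformed matrix row for symbol '", sym, "'")
    }
    if (!sym %in% rownames(out)) next
    keep <- header %in% colnames(out)
    out[sym, header[keep]] <- vals[keep]
  }
  if (!isTRUE(all.equal(out, t(out)))) stop("substitution matrix must be symmetric")
  out
}
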