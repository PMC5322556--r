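#' Read sequences from a FASTA file
#'
#' Sequences are uppercased and `U` is converted to `T`, so RNA gene sequences
#' are stored in the DNA alphabet throughout. Record names are taken up to the
#' first whitespace.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `name` and `seq`.
#' @seealso [write_fasta()], [read_rna_library()]
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  name <- sub("\\s.*$", "", names(set))
  seq <- toupper(as.character(set))
  seq <- chartr("U", "T", seq)
  bad <- stringr::str_detect(seq, "[^ACGTN]")
  if (any(bad)) {
    stop("record '", name[which(bad)[1]],
         "' contains characters outside {A,C,G,T,U,N}")
  }
  tibble::tibble(name = name, seq = unname(seq))
}

#' Write sequences to a FASTA file
#'
#' @param records a data frame with columns `name` and `seq`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("name", "seq") %in% names(records)))
  set <- Biostrings::BStringSet(setNames(records$seq, records$name))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a source-RNA library, optionally with secondary structures
#'
#' Loads the user-defined library of RNA genes (tRNAs, 5S rRNA, U2, 7SK, ...)
#' that the genome was masked against. Unlike genomic sequence, source RNAs may
#' not contain `N`: identity thresholds against an ambiguous consensus are not
#' meaningful, so such records are rejected. Dot-bracket structures, when
#' given, must match their sequence in name and length.
#'
#' @param path FASTA file of RNA gene sequences (RNA or DNA alphabet).
#' @param structure_path optional dot-bracket file (FASTA-like: `>name` lines
#'   followed by a structure string; see [read_dotbracket()]).
#' @return a tibble with columns `name`, `seq`, `length` and `structure`
#'   (`NA` where no structure was supplied).
#' @export
read_rna_library <- function(path, structure_path = NULL) {
  lib <- read_fasta(path)
  if (any(stringr::str_detect(lib$seq, "N"))) {
    bad <- lib$name[stringr::str_detect(lib$seq, "N")][1]
    stop("source RNA '", bad, "' contains N; ambiguous consensus bases are not allowed")
  }
  lib$length <- nchar(lib$seq)
  lib$structure <- NA_character_
  if (!is.null(structure_path)) {
    st <- read_dotbracket(structure_path)
    idx <- match(lib$name, st$name)
    lib$structure <- st$structure[idx]
    have <- !is.na(lib$structure)
    mism <- have & nchar(lib$structure) != lib$length
    if (any(mism)) {
      stop("structure length differs from sequence length for '",
           lib$name[which(mism)[1]], "'")
    }
  }
  lib
}

#' Read dot-bracket secondary structures
#'
#' Accepts `.` for unpaired positions and any of `()[]{}<>` for paired ones;
#' pseudoknot letter codes are rejected. Brackets must balance.
#'
#' @param path FASTA-like file: a `>name` line followed by the structure.
#' @return a tibble with columns `name` and `structure`.
#' @export
read_dotbracket <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1]) stop("dot-bracket file must start with a '>' header")
  grp <- cumsum(hdr)
  name <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  structure <- vapply(split(lines[!hdr], grp[!hdr]),
                      paste, character(1), collapse = "")
  purrr::walk2(name, structure, validate_dotbracket)
  tibble::tibble(name = name, structure = unname(structure))
}

validate_dotbracket <- function(name, s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  open <- c("(", "[", "{", "<"); close <- c(")", "]", "}", ">")
  bad <- setdiff(chars, c(".", open, close))
  if (length(bad)) {
    stop("structure '", name, "' contains unsupported symbol(s) '",
         paste(unique(bad), collapse = ""), "' (pseudoknot letters are not supported)")
  }
  depth <- cumsum((chars %in% open) - (chars %in% close))
  if (any(depth < 0) || depth[length(depth)] != 0) {
    stop("unbalanced brackets in structure '", name, "'")
  }
  invisible(TRUE)
}

# per-position paired/unpaired from a dot-bracket string
structure_paired <- function(s) {
  strsplit(s, "", fixed = TRUE)[[1]] != "."
}
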