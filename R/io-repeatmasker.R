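#' Read a RepeatMasker annotation (.out) file
#'
#' Parses the classic 15-column RepeatMasker `.out` dialect: three header
#' lines, whitespace-separated fields, `C` marking minus-strand hits,
#' parentheses marking "bases left" counts, and an optional trailing `*`
#' overlap flag (tolerated and ignored). For minus-strand lines the repeat
#' begin/left/end triple is reordered at parse time so that `repeat_start <=
#' repeat_end` always refers to consensus orientation; the genomic strand is
#' kept in `strand`.
#'
#' All coordinates are 1-based inclusive, the native convention of both the
#' format and this package.
#'
#' @param path path to a `.out` file.
#' @return a tibble of masked hits with columns `sw_score`, `divergence_pct`,
#'   `deletion_pct`, `insertion_pct`, `query_name`, `query_start`,
#'   `query_end`, `query_left`, `strand` (`"+"`/`"-"`), `repeat_name`,
#'   `repeat_class`, `repeat_start`, `repeat_end`, `repeat_left`, `rm_id`.
#' @seealso [write_rmout()]
#' @export
read_rmout <- function(path) {
  lines <- readr::read_lines(path)
  # classic dialect: two header lines + one blank; be liberal and drop any
  # leading lines that do not start with a numeric score
  is_data <- grepl("^\\s*\\d", lines)
  if (length(lines)) is_data[seq_len(min(3L, length(lines)))] <- is_data[seq_len(min(3L, length(lines)))] & FALSE
  data_idx <- which(is_data & nzchar(trimws(lines)))
  rows <- purrr::map(data_idx, function(i) parse_rmout_line(lines[i], i))
  if (!length(rows)) return(empty_hits())
  dplyr::bind_rows(rows)
}

empty_hits <- function() {
  tibble::tibble(
    sw_score = integer(), divergence_pct = numeric(), deletion_pct = numeric(),
    insertion_pct = numeric(), query_name = character(), query_start = integer(),
    query_end = integer(), query_left = integer(), strand = character(),
    repeat_name = character(), repeat_class = character(),
    repeat_start = integer(), repeat_end = integer(), repeat_left = integer(),
    rm_id = integer()
  )
}

parse_rmout_line <- function(line, lineno) {
  f <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(f) == 16L && f[16] == "*") f <- f[-16]
  if (length(f) != 15L) {
    stop("malformed RepeatMasker line ", lineno, ": expected 15 columns, got ",
         length(f))
  }
  num <- suppressWarnings(as.numeric(gsub("[()]", "", f[c(1:4, 6:8, 12:15)])))
  if (anyNA(num)) stop("malformed RepeatMasker line ", lineno, ": non-numeric field")
  strand <- f[9]
  if (!strand %in% c("+", "C")) {
    stop("malformed RepeatMasker line ", lineno, ": strand must be '+' or 'C'")
  }
  if (strand == "+") {
    r_start <- num[8]; r_end <- num[9]; r_left <- num[10]
  } else {
    # C lines carry (left) end begin
    r_left <- num[8]; r_end <- num[9]; r_start <- num[10]
  }
  qs <- as.integer(num[5]); qe <- as.integer(num[6])
  if (qs > qe) stop("malformed RepeatMasker line ", lineno, ": query start > end")
  tibble::tibble(
    sw_score = as.integer(num[1]), divergence_pct = num[2],
    deletion_pct = num[3], insertion_pct = num[4],
    query_name = f[5], query_start = qs, query_end = qe,
    query_left = as.integer(num[7]),
    strand = if (strand == "+") "+" else "-",
    repeat_name = f[10], repeat_class = f[11],
    repeat_start = as.integer(r_start), repeat_end = as.integer(r_end),
    repeat_left = as.integer(r_left), rm_id = as.integer(num[11])
  )
}

#' Write masked hits as a RepeatMasker .out file
#'
#' Emits the classic 15-column dialect; `read_rmout(write_rmout(x))` returns
#' `x` field-by-field.
#'
#' @param hits a tibble of masked hits as returned by [read_rmout()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rmout <- function(hits, path) {
  header <- c(
    "   SW   perc perc perc  query     position in query     matching repeat        position in repeat",
    "score   div. del. ins.  sequence  begin end      (left) repeat   class/family  begin end   (left)  ID",
    ""
  )
  fmt_row <- function(h) {
    if (h$strand == "+") {
      rep3 <- c(h$repeat_start, h$repeat_end, sprintf("(%d)", h$repeat_left))
      strand <- "+"
    } else {
      rep3 <- c(sprintf("(%d)", h$repeat_left), h$repeat_end, h$repeat_start)
      strand <- "C"
    }
    paste(
      h$sw_score, sprintf("%.1f", h$divergence_pct),
      sprintf("%.1f", h$deletion_pct), sprintf("%.1f", h$insertion_pct),
      h$query_name, h$query_start, h$query_end, sprintf("(%d)", h$query_left),
      strand, h$repeat_name, h$repeat_class, rep3[1], rep3[2], rep3[3], h$rm_id
    )
  }
  body <- if (nrow(hits)) {
    vapply(seq_len(nrow(hits)), function(i) fmt_row(hits[i, ]), character(1))
  } else character(0)
  readr::write_lines(c(header, body), path)
  invisible(path)
}
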