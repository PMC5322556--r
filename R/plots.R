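# ggplot2 visualisations for the result types.

#' Sequence logo of a position frequency matrix
#'
#' Stacked-bar information-content logo: per position, each base contributes
#' a bar segment of height `freq x IC` bits (see [information_logo()]).
#'
#' @param object a `pfm`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pfm <- function(object, ...) {
  logo <- information_logo(object)
  logo <- logo[logo$height > 0, ]
  ggplot2::ggplot(logo, ggplot2::aes(x = .data$position, y = .data$height,
                                     fill = .data$base)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::scale_fill_manual(values = c(A = "#109648", C = "#255C99",
                                          G = "#F7B32B", T = "#D62839")) +
    ggplot2::scale_x_continuous(breaks = seq_len(object$width)) +
    ggplot2::labs(x = "position", y = "information (bits)", fill = NULL) +
    ggplot2::ylim(0, 2) +
    ggplot2::theme_minimal()
}

#' Breakpoint hotspot plot for one source RNA
#'
#' Truncation counts along the consensus, coloured by secondary-structure
#' context when available (truncation hotspots fall into loops and other
#' single-stranded regions).
#'
#' @param object a `breakpoint_histogram`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.breakpoint_histogram <- function(object, ...) {
  df <- object$counts
  df$context <- dplyr::case_when(
    is.na(df$paired) ~ "unknown",
    df$paired ~ "paired",
    TRUE ~ "unpaired")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$count,
                                   fill = .data$context)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(paired = "grey40",
                                          unpaired = "#D62839",
                                          unknown = "grey70")) +
    ggplot2::labs(title = object$rna, x = "consensus position",
                  y = "truncations", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Per-branch insertion count plot
#'
#' @param object a `branch_counts` tibble (see [branch_counts()]).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.branch_counts <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$branch <- stats::reorder(df$branch, df$count)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$branch, y = .data$count)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$pct, "%")),
                       hjust = -0.1, size = 3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "assigned insertions") +
    ggplot2::theme_minimal()
}

#' Priming-length distribution plot
#'
#' @param candidates accepted candidate tibble with `priming_length`.
#' @return a ggplot.
#' @export
plot_priming_lengths <- function(candidates) {
  dist <- priming_length_distribution(candidates)
  ggplot2::ggplot(dist$histogram,
                  ggplot2::aes(x = .data$priming_length, y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "priming length (nt)", y = "candidates") +
    ggplot2::theme_minimal()
}
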