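# ggplot2 quick-look plots for the main result types.

#' Quick-look plot
#' @param object Result object.
#' @param ... Unused.
#' @method autoplot ribo_metagene
#' @export
autoplot.ribo_metagene <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset,
                                       y = .data$mean_density)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::labs(
      x = sprintf("nt from %s codon", object$anchor[1]),
      y = "mean 3'-end density (RPM)",
      title = sprintf("%s-anchored metagene profile", object$anchor[1])
    ) +
    ggplot2::theme_minimal()
}

#' Quick-look plot
#' @param object Result object.
#' @param ... Unused.
#' @method autoplot ribo_codon_pause
#' @export
autoplot.ribo_codon_pause <- function(object, by = c("aa", "codon"), ...) {
  by <- match.arg(by)
  df <- if (by == "aa") aa_pause_table(object) else as_tibble(object)
  df$label <- if (by == "aa") df$aa3 else df$codon
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$label, -.data$mean_pause_score),
    y = .data$mean_pause_score)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = if (by == "aa") "amino acid in A-site" else
      "codon in A-site", y = "mean pause score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Quick-look plot
#' @param object Result object.
#' @param ... Unused.
#' @method autoplot ribo_gm_profile
#' @export
autoplot.ribo_gm_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$part)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$bin) +
    ggplot2::labs(x = "ORF segment (5' to 3')",
                  y = "geometric mean % of density") +
    ggplot2::theme_minimal()
}

#' Per-gene pause-score profile plot
#'
#' @param profiles A `ribo_pause_profiles` tibble.
#' @param orf_id The ORF to draw.
#' @return A ggplot object.
#' @export
plot_pause_profile <- function(profiles, orf_id) {
  df <- profiles[profiles$orf_id == orf_id, ]
  if (nrow(df) == 0) abort(sprintf("no pause profile for ORF '%s'", orf_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "ORF position (nt)", y = "pause score",
                  title = orf_id) +
    ggplot2::theme_minimal()
}
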