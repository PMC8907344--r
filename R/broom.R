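#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for pipeline result objects
#'
#' `tidy()` returns a plain long tibble for each result type; `glance()`
#' one-row summaries.
#'
#' @param x a result object.
#' @param ... unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.residue_heatmap <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    residue = rep(rownames(m), times = ncol(m)),
    position = rep(as.integer(colnames(m)), each = nrow(m)),
    signed_logp = as.vector(m)
  )
}

#' @rdname tidiers
#' @export
tidy.target_classes <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$peptide, level = "peptide"),
    dplyr::mutate(x$protein, level = "protein")
  ) |>
    dplyr::relocate("level")
}

#' @rdname tidiers
#' @export
tidy.venn_summary <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$margins, kind = "margin", class = NA_character_),
    dplyr::mutate(x$overlaps, kind = "overlap",
                  arm = NA_character_, direction = NA_character_)
  ) |>
    dplyr::select("kind", "level", "arm", "direction", "class", "n")
}

#' @rdname tidiers
#' @export
glance.fpr_curve <- function(x, ...) {
  at_max <- dplyr::slice_max(x, .data$threshold, n = 1, with_ties = FALSE)
  tibble::tibble(
    scheme = at_max$scheme, level = at_max$level,
    threshold_max = at_max$threshold,
    fpr_at_max = at_max$fpr, fp_at_max = at_max$fp, tp_at_max = at_max$tp,
    fpr_min = suppressWarnings(min(x$fpr, na.rm = TRUE))
  )
}

#' Plot an FPR curve (or several schemes overlaid)
#'
#' @param object an `fpr_curve` tibble; rows from several schemes/levels can
#'   be combined with `dplyr::bind_rows()` first.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.fpr_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$threshold, .data$fpr,
                               colour = .data$scheme,
                               linetype = .data$level)) +
    ggplot2::geom_line(linewidth = 0.7, na.rm = TRUE) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "fold-change threshold", y = "false positive rate",
                  colour = "scheme", linetype = "level") +
    ggplot2::theme_minimal()
}

#' Plot the signed residue-enrichment heatmap
#'
#' Red marks residues over-used relative to the background at a position,
#' green under-used; intensity is -log10(p).
#'
#' @param object a [residue_heatmap()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.residue_heatmap <- function(object, ...) {
  df <- tidy(object)
  lim <- max(abs(df$signed_logp), na.rm = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(.data$position,
                                   factor(.data$residue, rev(sort(unique(.data$residue)))),
                                   fill = .data$signed_logp)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "black",
                                  high = "red", limits = c(-lim, lim),
                                  na.value = "grey85") +
    ggplot2::labs(x = "position relative to acetyl-K", y = NULL,
                  fill = expression(signed -log[10](p))) +
    ggplot2::theme_minimal()
}

#' Bar chart of the top enriched gene sets
#'
#' @param result an `enrich_result` from [fisher_enrich()].
#' @param top_n number of terms to show.
#' @return A ggplot.
#' @export
plot_enrichment <- function(result, top_n = 10) {
  df <- utils::head(result, top_n)
  df$term <- factor(df$term, rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(-log10(.data$p), .data$term,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL, fill = "p < alpha") +
    ggplot2::theme_minimal()
}
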