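#' @title Differential acetylation calls and target classification
#'
#' @description
#' Threshold-based direction calls on normalized fold changes, and the
#' anti-correlation logic that separates direct deacetylase targets
#' (acetylation up on knockdown AND down on overexpression) from indirect
#' ones (the reverse pattern, implying regulation downstream of the enzyme).
#'
#' @name dex_classify
NULL

#' Call differential acetylation at a fold-change threshold
#'
#' Directions use strict inequalities: `up` iff
#' `normalized_ratio > threshold`, `down` iff
#' `normalized_ratio < 1/threshold`; a ratio exactly at the threshold is
#' `unchanged`. Excluded pairs are labeled `excluded`.
#'
#' @param changes an `acetyl_changes` tibble from [compute_changes()].
#' @param threshold linear fold-change threshold, > 1 (default 1.5, i.e.
#'   a 50% change).
#' @return `changes` with a `direction` column
#'   (up/down/unchanged/excluded), class `dex_calls`.
#' @export
call_dex <- function(changes, threshold = 1.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 1) {
    stop("`threshold` must be a single fold value > 1", call. = FALSE)
  }
  out <- dplyr::mutate(
    changes,
    direction = dplyr::case_when(
      .data$excluded ~ "excluded",
      .data$normalized_ratio > threshold ~ "up",
      .data$normalized_ratio < 1 / threshold ~ "down",
      TRUE ~ "unchanged"
    )
  )
  class(out) <- c("dex_calls", setdiff(class(out), "dex_calls"))
  attr(out, "threshold") <- threshold
  out
}

arm_labels <- function(dex) {
  arms <- unique(dex$arm)
  if (length(arms) == 0) {
    return(c(kd = "knockdown", oe = "overexpression"))
  }
  if (length(arms) != 2) stop("expected calls for exactly two arms", call. = FALSE)
  if (all(c("knockdown", "overexpression") %in% arms)) {
    c(kd = "knockdown", oe = "overexpression")
  } else {
    # fall back to arm order for pseudo-designs
    c(kd = arms[[1]], oe = arms[[2]])
  }
}

# per-key, per-arm direction summary under the any-record rule
key_directions <- function(dex, key) {
  arms <- arm_labels(dex)
  wide <- dex |>
    dplyr::filter(!.data$excluded) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key)), .data$arm) |>
    dplyr::summarise(up = any(.data$direction == "up"),
                     down = any(.data$direction == "down"),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "arm", values_from = c("up", "down"),
                       values_fill = FALSE)
  want <- c(up_kd = paste0("up_", arms[["kd"]]),
            up_oe = paste0("up_", arms[["oe"]]),
            down_kd = paste0("down_", arms[["kd"]]),
            down_oe = paste0("down_", arms[["oe"]]))
  for (i in seq_along(want)) {
    old <- want[[i]]
    new <- names(want)[[i]]
    if (old %in% names(wide)) names(wide)[names(wide) == old] <- new
  }
  wide
}

ensure_dir_cols <- function(tbl) {
  for (col in c("up_kd", "up_oe", "down_kd", "down_oe")) {
    if (!col %in% names(tbl)) tbl[[col]] <- FALSE
  }
  tbl
}

#' Classify peptides and proteins as direct or indirect targets
#'
#' Peptide-level classification requires the identical peptide — the same
#' sequence and acetyl-site set — to satisfy both arm conditions. Protein
#' level uses the any-site rule: each arm's condition may be met by a
#' different site of the protein. Proteins are consolidated by
#' case-insensitive gene symbol.
#'
#' @param dex a `dex_calls` tibble from [call_dex()] covering both arms.
#' @return List of class `target_classes` with tibbles `peptide`
#'   (`peptide`, `sites`, `gene`, arm directions, `class`) and `protein`
#'   (`gene`, arm directions, `class`); `class` is one of
#'   direct/indirect/neither.
#' @export
classify_targets <- function(dex) {
  classify_one <- function(tbl) {
    tbl <- ensure_dir_cols(tbl)
    dplyr::mutate(tbl, class = dplyr::case_when(
      .data$up_kd & .data$down_oe ~ "direct",
      .data$down_kd & .data$up_oe ~ "indirect",
      TRUE ~ "neither"
    ))
  }
  dex_pep <- dplyr::mutate(dex, gene = toupper(.data$gene))
  peptide <- classify_one(key_directions(dex_pep, c("peptide", "sites", "gene")))
  protein <- classify_one(key_directions(dex_pep, "gene"))
  structure(list(peptide = peptide, protein = protein,
                 threshold = attr(dex, "threshold")),
            class = "target_classes")
}

#' @export
print.target_classes <- function(x, ...) {
  cat(sprintf("<target_classes> threshold %.3g-fold\n", x$threshold))
  for (lvl in c("peptide", "protein")) {
    n <- table(factor(x[[lvl]]$class, c("direct", "indirect", "neither")))
    cat(sprintf("  %s level: %d direct, %d indirect, %d neither\n",
                lvl, n[["direct"]], n[["indirect"]], n[["neither"]]))
  }
  invisible(x)
}

#' Margin and overlap counts for the knockdown/overexpression Venn diagrams
#'
#' Margins count distinct up- and down-regulated sites (unique
#' accession x position, pooled over the records that cover them), peptides
#' (unique sequence + site set) and proteins (consolidated gene symbols) per
#' arm. Overlaps count direct and indirect classifications at the peptide
#' and protein level, plus the number of distinct sites carried by the
#' classified peptides.
#'
#' @param dex a `dex_calls` tibble.
#' @param classes the matching [classify_targets()] result (computed from
#'   `dex` when omitted).
#' @return List of class `venn_summary` with tibbles `margins`
#'   (`level`, `arm`, `direction`, `n`) and `overlaps`
#'   (`level`, `class`, `n`).
#' @export
venn_summary <- function(dex, classes = classify_targets(dex)) {
  kept <- dplyr::filter(dex, !.data$excluded,
                        .data$direction %in% c("up", "down"))
  kept <- dplyr::mutate(kept, gene = toupper(.data$gene))

  site_keys <- kept |>
    dplyr::mutate(position = purrr::map(.data$sites, parse_sites)) |>
    tidyr::unnest("position") |>
    dplyr::distinct(.data$arm, .data$direction,
                    site = paste(.data$accession, .data$position))
  margins <- dplyr::bind_rows(
    dplyr::count(site_keys, .data$arm, .data$direction) |>
      dplyr::mutate(level = "site"),
    kept |>
      dplyr::distinct(.data$arm, .data$direction, .data$peptide, .data$sites) |>
      dplyr::count(.data$arm, .data$direction) |>
      dplyr::mutate(level = "peptide"),
    kept |>
      dplyr::distinct(.data$arm, .data$direction, .data$gene) |>
      dplyr::count(.data$arm, .data$direction) |>
      dplyr::mutate(level = "protein")
  ) |>
    dplyr::select("level", "arm", "direction", "n")

  pep_sites <- dex |>
    dplyr::mutate(gene = toupper(.data$gene)) |>
    dplyr::distinct(.data$peptide, .data$sites, .data$gene, .data$accession) |>
    dplyr::inner_join(classes$peptide[, c("peptide", "sites", "gene", "class")],
                      by = c("peptide", "sites", "gene")) |>
    dplyr::mutate(position = purrr::map(.data$sites, parse_sites)) |>
    tidyr::unnest("position") |>
    dplyr::distinct(.data$class, site = paste(.data$accession, .data$position))

  count_class <- function(tbl, lvl) {
    tibble::tibble(level = lvl,
                   class = c("direct", "indirect"),
                   n = c(sum(tbl$class == "direct"),
                         sum(tbl$class == "indirect")))
  }
  overlaps <- dplyr::bind_rows(
    count_class(pep_sites, "site"),
    count_class(classes$peptide, "peptide"),
    count_class(classes$protein, "protein")
  )
  structure(list(margins = margins, overlaps = overlaps),
            class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat("<venn_summary>\nmargins:\n")
  print(tidyr::pivot_wider(x$margins, names_from = "direction",
                           values_from = "n", values_fill = 0L))
  cat("overlaps:\n")
  print(x$overlaps)
  invisible(x)
}

#' Overlap of called direct-target proteins with a known-substrate list
#'
#' @param direct_genes character vector of gene symbols called as direct
#'   targets.
#' @param known character vector of experimentally validated substrate gene
#'   symbols; must be non-empty.
#' @return List with `intersection` (sorted gene symbols) and `fraction`
#'   (`|intersection| / |known|`).
#' @examples
#' overlap_known(c("TUBB", "FOXO1"), c("FOXO1", "EIF5A"))
#' @export
overlap_known <- function(direct_genes, known) {
  known <- unique(toupper(known))
  if (length(known) == 0) stop("`known` must be non-empty", call. = FALSE)
  inter <- sort(intersect(unique(toupper(direct_genes)), known))
  list(intersection = inter, fraction = length(inter) / length(known))
}
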