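#' @title Sliding-threshold false-positive-rate estimation
#'
#' @description
#' An internal error estimate for the anti-correlation classification.
#' Because the two arms manipulate the deacetylase in opposite directions,
#' a site that decreases in *both* comparisons is biologically implausible:
#' such (-/-) patterns are counted as false positives, and every other
#' two-comparison change beyond the threshold — at least one comparison
#' increasing in acetylation, i.e. (+/-), (-/+) or (+/+) — as a potential
#' true positive. FPR = FP / TP, swept over a sliding fold-change grid and
#' compared against scrambled-null comparison schemes built from nonsense
#' sample pairings.
#'
#' @name fpr_validation
NULL

#' False-positive-rate curve over a sliding fold-change threshold
#'
#' At each threshold `t`, an item (peptide = sequence + site set, or protein
#' = consolidated gene symbol) qualifies iff it changes more than `t`-fold
#' in **both** comparisons among its retained pairs (retention already
#' enforces the at-most-one-imputed-value rule per comparison). Protein
#' level uses the any-site rule per arm. Qualifying items with no upward
#' change in either comparison are false positives; the rest are potential
#' true positives. FPR is NA (never 0) where no item qualifies as a true
#' positive.
#'
#' @param changes an `acetyl_changes` tibble from [compute_changes()] or
#'   [scrambled_changes()].
#' @param thresholds ascending fold grid (default 1.0 to 1.5 by 0.01).
#' @param level `"peptide"` or `"protein"`.
#' @return Tibble of class `fpr_curve`: `threshold`, `fp`, `tp`, `fpr`,
#'   `scheme`, `level`.
#' @export
fpr_curve <- function(changes, thresholds = seq(1, 1.5, by = 0.01),
                      level = c("peptide", "protein")) {
  level <- match.arg(level)
  if (length(thresholds) < 1 || is.unsorted(thresholds, strictly = TRUE) ||
      any(thresholds < 1)) {
    stop("`thresholds` must be a strictly ascending grid of folds >= 1",
         call. = FALSE)
  }
  key <- if (level == "peptide") c("peptide", "sites") else "gene"
  items <- changes |>
    dplyr::filter(!.data$excluded) |>
    dplyr::mutate(gene = toupper(.data$gene)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key)), .data$arm) |>
    dplyr::summarise(hi = max(.data$normalized_ratio),
                     lo = min(.data$normalized_ratio), .groups = "drop")
  arms <- unique(changes$arm)
  wide <- items |>
    tidyr::pivot_wider(names_from = "arm", values_from = c("hi", "lo"))
  hi1 <- wide[[paste0("hi_", arms[[1]])]]
  lo1 <- wide[[paste0("lo_", arms[[1]])]]
  hi2 <- wide[[paste0("hi_", arms[[2]])]]
  lo2 <- wide[[paste0("lo_", arms[[2]])]]

  per_t <- function(t) {
    up1 <- !is.na(hi1) & hi1 > t
    dn1 <- !is.na(lo1) & lo1 < 1 / t
    up2 <- !is.na(hi2) & hi2 > t
    dn2 <- !is.na(lo2) & lo2 < 1 / t
    qual <- (up1 | dn1) & (up2 | dn2)
    fp <- sum(qual & !up1 & !up2)
    tp <- sum(qual) - fp
    c(fp = fp, tp = tp)
  }
  counts <- t(vapply(thresholds, per_t, c(fp = 0, tp = 0)))
  out <- tibble::tibble(
    threshold = thresholds,
    fp = as.integer(counts[, "fp"]),
    tp = as.integer(counts[, "tp"]),
    fpr = unname(ifelse(counts[, "tp"] == 0, NA_real_,
                        counts[, "fp"] / counts[, "tp"])),
    scheme = attr(changes, "scheme") %||% "real",
    level = level
  )
  class(out) <- c("fpr_curve", class(out))
  out
}

#' Scrambled-null comparison schemes
#'
#' Recomputes normalized changes under nonsense comparison schemes that
#' carry no (or a broken) treatment contrast, each normalized by the
#' analogous protein pseudo-ratios:
#'
#' \describe{
#'   \item{`scrambled1`}{pairs of like samples: the two controls compared
#'     to each other (`ctrl_oe / ctrl_kd`) and the two experimental samples
#'     compared to each other (`exp_oe / exp_kd`).}
#'   \item{`scrambled2`}{differences of nonsense differences as
#'     ratio-of-ratio contrasts: `(exp_kd * exp_oe) / (ctrl_kd * ctrl_oe)`
#'     (difference of the two cross-pair nonsense differences; exactly null
#'     for anti-correlated planted effects) and
#'     `(exp_oe * ctrl_kd) / (exp_kd * ctrl_oe)` (difference of the
#'     scrambled1 nonsense differences).}
#'   \item{`scrambled2alt`}{an alternative reading: the control nonsense
#'     difference `ctrl_oe / ctrl_kd` together with
#'     `(exp_oe / exp_kd) / (ctrl_oe / ctrl_kd)`, the experimental nonsense
#'     difference corrected by the control one.}
#'   \item{`scrambled_cross`}{the literal cross-arm re-pairing
#'     `exp_kd / ctrl_oe` and `exp_oe / ctrl_kd`. Note this pairing
#'     preserves the knockdown-vs-overexpression contrast (a genuine direct
#'     target still shows an anti-correlated pattern), so under real effects
#'     it behaves like the real scheme rather than a null; it is provided
#'     for completeness.}
#' }
#'
#' For multi-sample contrasts the retention rule stays "at most one imputed
#' value per comparison".
#'
#' @param sites,proteins imputed long quant tibbles.
#' @param design the real [study_design()]; the first arm is the
#'   knockdown-like arm.
#' @param scheme one of `"scrambled1"`, `"scrambled2"`, `"scrambled2alt"`,
#'   `"scrambled_cross"`.
#' @return An `acetyl_changes` tibble with two pseudo-arms, `scheme`
#'   recorded in its attributes.
#' @export
scrambled_changes <- function(sites, proteins, design = study_design(),
                              scheme = c("scrambled1", "scrambled2",
                                         "scrambled2alt", "scrambled_cross")) {
  scheme <- match.arg(scheme)
  assert_design(design)
  e1 <- design$experimental[[1]]; c1 <- design$control[[1]]
  e2 <- design$experimental[[2]]; c2 <- design$control[[2]]
  contrasts <- switch(
    scheme,
    scrambled1 = tibble::tibble(
      arm = c("control_pair", "experimental_pair"),
      num = list(c2, e2), den = list(c1, e1)
    ),
    scrambled2 = tibble::tibble(
      arm = c("dod_cross", "dod_like"),
      num = list(c(e1, e2), c(e2, c1)), den = list(c(c1, c2), c(e1, c2))
    ),
    scrambled2alt = tibble::tibble(
      arm = c("control_pair", "dod_like"),
      num = list(c2, c(e2, c1)), den = list(c1, c(e1, c2))
    ),
    scrambled_cross = tibble::tibble(
      arm = c("cross_kd", "cross_oe"),
      num = list(e1, e2), den = list(c2, c1)
    )
  )
  contrast_changes(sites, proteins, contrasts, scheme = scheme)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
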