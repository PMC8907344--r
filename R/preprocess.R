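#' @title Imputation and protein-normalized fold changes
#'
#' @description
#' Left-censored (MNAR) imputation by Gaussian downshift, the one-of-two
#' missingness rule, and normalization of acetyl-site fold changes to the
#' parent protein's LFQ fold change. All population statistics and imputation
#' draws operate in log2 space — a Gaussian downshift is only meaningful on
#' log intensities — while fold changes and thresholds are reported on the
#' linear scale, where the field states them ("1.5-fold").
#'
#' @name preprocess
NULL

#' Impute missing intensities by Gaussian downshift
#'
#' The population mean `mu` and standard deviation `sigma` are computed over
#' the log2 values of **all** non-missing, non-imputed measurements of the
#' table (acetyl and protein tables are imputed separately, each over its
#' own population). A missing cell is eligible for imputation only when the
#' other member of its experimental/control pair in the same arm is present
#' (the one-of-two rule); eligible cells receive independent draws from
#' `N(mu - downshift * sigma, sigma^2)` truncated to
#' `mu - downshift * sigma +/- halfwidth * sigma`, drawn by rejection
#' sampling (acceptance about 24% at the defaults, cost negligible).
#' Pairs with both values missing stay missing and are excluded downstream.
#'
#' @param quant long quant tibble (site or protein).
#' @param design the [study_design()] whose pairs define eligibility.
#' @param downshift downshift in population SD units (default 1.8).
#' @param halfwidth truncation half-width in SD units (default 0.3).
#' @param seed integer seed making the draws reproducible.
#' @return `quant` with eligible missing cells filled (linear scale) and
#'   their `imputed` flags set. Observed values are never altered.
#' @export
impute_downshift <- function(quant, design = study_design(),
                             downshift = 1.8, halfwidth = 0.3, seed = 1L) {
  stopifnot(downshift > 0, halfwidth >= 0)
  assert_design(design)
  obs <- quant$intensity[!quant$imputed & !is.na(quant$intensity)]
  if (length(obs) < 2) {
    stop("imputation needs at least 2 unimputed measurements", call. = FALSE)
  }
  mu <- mean(log2(obs))
  sigma <- stats::sd(log2(obs))
  if (sigma == 0) {
    stop("degenerate population: all unimputed measurements are identical",
         call. = FALSE)
  }

  # eligibility: exactly one member of the arm pair missing
  eligible <- rep(FALSE, nrow(quant))
  for (a in seq_len(nrow(design))) {
    pair <- c(design$experimental[[a]], design$control[[a]])
    sub <- quant[quant$sample %in% pair, c("record_id", "sample", "intensity")]
    wide <- tidyr::pivot_wider(sub, names_from = "sample",
                               values_from = "intensity")
    n_miss <- is.na(wide[[pair[1]]]) + is.na(wide[[pair[2]]])
    one_missing <- wide$record_id[n_miss == 1]
    eligible <- eligible |
      (quant$sample %in% pair & is.na(quant$intensity) &
         quant$record_id %in% one_missing)
  }
  n_fill <- sum(eligible)
  if (n_fill == 0) return(quant)

  draws <- local_seed(seed, rtrunc_downshift(n_fill, mu, sigma,
                                             downshift, halfwidth))
  quant$intensity[eligible] <- 2^draws
  quant$imputed[eligible] <- TRUE
  quant
}

# rejection sampler for N(mu - d*s, s^2) truncated to +/- h*s around its mean
rtrunc_downshift <- function(n, mu, sigma, downshift, halfwidth) {
  center <- mu - downshift * sigma
  lo <- center - halfwidth * sigma
  hi <- center + halfwidth * sigma
  out <- numeric(0)
  while (length(out) < n) {
    cand <- stats::rnorm(max(n - length(out), 1) * 5, center, sigma)
    out <- c(out, cand[cand >= lo & cand <= hi])
  }
  out[seq_len(n)]
}

#' Keep/exclude decisions for every site x arm pair
#'
#' A site-arm pair is retained iff at most one of its two acetyl values was
#' imputed, at most one of the parent protein's two LFQ values in that arm
#' was imputed, and the parent protein is quantified at all. Exclusion
#' reasons: `both_missing` (acetyl pair unusable) or `protein_unquantified`
#' (no usable protein pair; this excludes every peptide of that protein in
#' that arm).
#'
#' @param sites,proteins imputed long quant tibbles.
#' @param design the [study_design()].
#' @return Tibble: `record_id`, `arm`, `keep`, `reason` (NA when kept).
#' @export
pair_filter <- function(sites, proteins, design = study_design()) {
  ch <- compute_changes(sites, proteins, design)
  tibble::tibble(record_id = ch$record_id, arm = ch$arm,
                 keep = !ch$excluded, reason = ch$reason)
}

# A comparison set: one row per pseudo-arm, numerator/denominator sample
# lists. The real design is the special case of single-sample contrasts.
design_contrasts <- function(design) {
  tibble::tibble(arm = design$arm,
                 num = as.list(design$experimental),
                 den = as.list(design$control))
}

#' Compute raw and protein-normalized fold changes per site and arm
#'
#' For each retained site-arm pair, the raw ratio is
#' experimental / control acetyl intensity (linear scale), the protein ratio
#' is the parent protein's LFQ ratio in the same samples, and the normalized
#' ratio is their quotient — the acetylation change corrected for the
#' protein-abundance change. Records mapping to several accessions are
#' normalized to the first listed accession (with a warning).
#'
#' @param sites,proteins long quant tibbles, after [impute_downshift()].
#' @param design the [study_design()].
#' @return Tibble of class `acetyl_changes`, one row per record x arm:
#'   identifiers, `raw_ratio`, `protein_ratio`, `normalized_ratio`,
#'   `n_imputed_site`, `n_imputed_protein`, `excluded`, `reason`.
#' @export
compute_changes <- function(sites, proteins, design = study_design()) {
  assert_design(design)
  contrast_changes(sites, proteins, design_contrasts(design), scheme = "real")
}

contrast_changes <- function(sites, proteins, contrasts, scheme) {
  key <- dplyr::distinct(sites[, c("record_id", "accession", "gene",
                                   "peptide", "sites")])
  key$parent <- first_accession(key$accession)

  site_w <- tidyr::pivot_wider(
    sites[, c("record_id", "sample", "intensity", "imputed")],
    names_from = "sample", values_from = c("intensity", "imputed")
  )
  prot_w <- tidyr::pivot_wider(
    proteins[, c("accession", "sample", "intensity", "imputed")],
    names_from = "sample", values_from = c("intensity", "imputed")
  )
  pi_row <- match(key$parent, prot_w$accession)

  ratio_of <- function(wide, rows, num, den) {
    log2r <- rep(0, length(rows))
    n_imp <- rep(0L, length(rows))
    usable <- !is.na(rows)
    for (s in num) {
      v <- wide[[paste0("intensity_", s)]][rows]
      log2r <- log2r + log2(v)
      n_imp <- n_imp + as.integer(wide[[paste0("imputed_", s)]][rows] %in% TRUE)
      usable <- usable & !is.na(v)
    }
    for (s in den) {
      v <- wide[[paste0("intensity_", s)]][rows]
      log2r <- log2r - log2(v)
      n_imp <- n_imp + as.integer(wide[[paste0("imputed_", s)]][rows] %in% TRUE)
      usable <- usable & !is.na(v)
    }
    list(ratio = ifelse(usable, 2^log2r, NA_real_), n_imputed = n_imp,
         usable = usable)
  }

  out <- vector("list", nrow(contrasts))
  self_rows <- seq_len(nrow(key))
  for (a in seq_len(nrow(contrasts))) {
    num <- contrasts$num[[a]]
    den <- contrasts$den[[a]]
    sr <- ratio_of(site_w, self_rows, num, den)
    pr <- ratio_of(prot_w, pi_row, num, den)
    max_imp <- 1L  # at most one imputed value per comparison, whatever its size
    site_ok <- sr$usable & sr$n_imputed <= max_imp
    prot_ok <- pr$usable & pr$n_imputed <= max_imp
    excluded <- !(site_ok & prot_ok)
    reason <- dplyr::case_when(
      !site_ok ~ "both_missing",
      !prot_ok ~ "protein_unquantified",
      TRUE ~ NA_character_
    )
    out[[a]] <- tibble::tibble(
      record_id = key$record_id, accession = key$parent, gene = key$gene,
      peptide = key$peptide, sites = key$sites, arm = contrasts$arm[[a]],
      raw_ratio = ifelse(excluded, NA_real_, sr$ratio),
      protein_ratio = ifelse(excluded, NA_real_, pr$ratio),
      normalized_ratio = ifelse(excluded, NA_real_, sr$ratio / pr$ratio),
      n_imputed_site = sr$n_imputed,
      n_imputed_protein = ifelse(is.na(pi_row), NA_integer_, pr$n_imputed),
      excluded = excluded, reason = reason
    )
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("acetyl_changes", class(res))
  attr(res, "scheme") <- scheme
  res
}
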