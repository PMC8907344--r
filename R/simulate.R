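#' @title Synthetic acetylome experiments
#'
#' @description
#' Generates a complete synthetic experiment — proteome, protein-level LFQ
#' table, site-level acetyl table, and ground-truth labels — with the
#' statistical structure the downstream analysis assumes: near-Gaussian
#' log2 intensities, planted direct/indirect deacetylase targets with
#' anti-correlated fold changes across the knockdown and overexpression
#' arms, protein-level abundance shifts that the normalization step must
#' cancel, and intensity-dependent (left-censored, MNAR) dropout.
#'
#' @name synthetic_acetylome
NULL

# Approximate human proteome amino-acid frequencies (UniProt statistics).
AA_RESIDUES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_FREQS <- c(A = 7.0, R = 5.6, N = 3.6, D = 4.7, C = 2.3, Q = 4.8,
              E = 7.1, G = 6.6, H = 2.6, I = 4.3, L = 10.0, K = 5.7,
              M = 2.1, F = 3.7, P = 6.3, S = 8.3, T = 5.3, W = 1.2,
              Y = 2.7, V = 6.0)
AA_FREQS <- AA_FREQS / sum(AA_FREQS)

#' Configure a synthetic acetylome experiment
#'
#' Defaults emulate the 4-sample knockdown/overexpression study design:
#' one replicate per condition, log-normal intensities (simulated in log2
#' space and exponentiated on write), planted targets with a 2-fold effect,
#' and logistic intensity-dependent dropout.
#'
#' `noise_sd` parameterizes the SD of the log2 measurement noise of a
#' two-sample ratio; each acetyl measurement draws independent
#' N(0, noise_sd^2 / 2) noise so that any pairwise log-ratio has SD
#' `noise_sd`. Global-protein LFQ values are generated noise-free: protein
#' LFQ aggregates evidence across many peptides, so its measurement variance
#' is far below that of a single acetyl-peptide precursor, and the
#' protein-level sample shifts (`protein_change_sd`) remain exactly
#' cancellable by normalization.
#'
#' `missing_slope = 0` disables dropout entirely. Otherwise the probability
#' that a final log2 intensity `x` drops out is
#' `plogis(missing_slope * (missing_midpoint - x))`.
#'
#' @param n_proteins number of simulated proteins.
#' @param sites_per_protein_mean,sites_per_protein_max mean (Poisson, shifted
#'   to be >= 1) and cap of acetyl sites per protein.
#' @param log2_intensity_mean,log2_intensity_sd population mean/SD of the
#'   latent log2 site and protein intensities (MaxQuant-like LFQ scale).
#' @param frac_direct,frac_indirect fractions of sites planted as direct
#'   (acetylation up on knockdown, down on overexpression) and indirect
#'   (the reverse) targets; must sum to <= 1.
#' @param effect_log2 planted |log2 fold change| of target sites.
#' @param protein_change_sd SD of log2 protein-abundance shifts per
#'   protein x sample, independent of site class.
#' @param noise_sd SD of the log2 ratio noise between two samples (see
#'   Details).
#' @param missing_midpoint,missing_slope logistic MNAR dropout parameters
#'   in log2-intensity units.
#' @param seed integer RNG seed; the whole experiment is a pure function of
#'   the configuration.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_proteins = 400,
                       sites_per_protein_mean = 2,
                       sites_per_protein_max = 5,
                       log2_intensity_mean = 25,
                       log2_intensity_sd = 2,
                       frac_direct = 0.1,
                       frac_indirect = 0.1,
                       effect_log2 = 1,
                       protein_change_sd = 0.25,
                       noise_sd = 0.2,
                       missing_midpoint = 22,
                       missing_slope = 1,
                       seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              sites_per_protein_mean = sites_per_protein_mean,
              sites_per_protein_max = as.integer(sites_per_protein_max),
              log2_intensity_mean = log2_intensity_mean,
              log2_intensity_sd = log2_intensity_sd,
              frac_direct = frac_direct,
              frac_indirect = frac_indirect,
              effect_log2 = effect_log2,
              protein_change_sd = protein_change_sd,
              noise_sd = noise_sd,
              missing_midpoint = missing_midpoint,
              missing_slope = missing_slope,
              seed = as.integer(seed))
  if (cfg$n_proteins < 1) stop("n_proteins must be >= 1", call. = FALSE)
  if (cfg$frac_direct < 0 || cfg$frac_indirect < 0 ||
      cfg$frac_direct + cfg$frac_indirect > 1) {
    stop("frac_direct + frac_indirect must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$effect_log2 <= 0) stop("effect_log2 must be positive", call. = FALSE)
  for (f in c("log2_intensity_sd", "protein_change_sd", "noise_sd",
              "missing_slope")) {
    if (cfg[[f]] < 0) stop(f, " must be >= 0", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

random_protein <- function(len, k_positions) {
  aa <- sample(AA_RESIDUES, len, replace = TRUE, prob = AA_FREQS)
  aa[k_positions] <- "K"
  paste(aa, collapse = "")
}

#' Generate a synthetic acetylome experiment
#'
#' @param config a [sim_config()].
#' @return A list of class `acetylome_sim`:
#' \describe{
#'   \item{proteome}{named character vector of protein sequences with K at
#'     every planted site position.}
#'   \item{proteins}{long protein LFQ quant tibble (linear intensities,
#'     NA where dropped out).}
#'   \item{sites}{long site quant tibble, one record per site.}
#'   \item{truth}{tibble of per-site ground truth: `record_id`, `accession`,
#'     `gene`, `position`, `class` in direct/indirect/null.}
#'   \item{protein_truth}{per-protein derived class (any-site rule).}
#'   \item{design}{the [study_design()] used (default sample ids).}
#'   \item{config}{the configuration.}
#' }
#' @examples
#' sim <- simulate_acetylome(sim_config(n_proteins = 50, seed = 7))
#' dplyr::count(sim$truth, class)
#' @export
simulate_acetylome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  design <- study_design()
  local_seed(config$seed, {
    np <- config$n_proteins
    acc <- sprintf("P%04d", seq_len(np))
    gene <- sprintf("GENE%04d", seq_len(np))
    n_sites <- pmin(1L + stats::rpois(np, max(config$sites_per_protein_mean - 1, 0)),
                    config$sites_per_protein_max)
    lens <- sample(200:600, np, replace = TRUE)

    aa_all <- sample(AA_RESIDUES, sum(lens), replace = TRUE, prob = AA_FREQS)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    site_rows <- vector("list", np)
    proteome <- character(np)
    names(proteome) <- acc
    for (i in seq_len(np)) {
      k <- n_sites[[i]]
      pos <- sort(sample(seq(16L, lens[[i]] - 15L), k))
      aa <- aa_all[starts[[i]]:ends[[i]]]
      aa[pos] <- "K"
      proteome[[i]] <- paste(aa, collapse = "")
      site_rows[[i]] <- list(accession = acc[[i]], gene = gene[[i]],
                             position = pos)
    }
    sites <- tibble::tibble(
      accession = rep(acc, n_sites), gene = rep(gene, n_sites),
      position = unlist(lapply(site_rows, `[[`, "position"), use.names = FALSE)
    )
    ns <- nrow(sites)
    sites$record_id <- sprintf("r%05d", seq_len(ns))
    # 15-residue peptide context around the site, with the site coordinate
    sites$peptide <- substr(paste0(strrep("-", 7), proteome[sites$accession],
                                   strrep("-", 7)),
                            sites$position, sites$position + 14L)
    sites$peptide <- gsub("-", "", sites$peptide, fixed = TRUE)
    sites$sites <- as.character(sites$position)

    classes <- rep("null", ns)
    n_direct <- round(config$frac_direct * ns)
    n_indirect <- round(config$frac_indirect * ns)
    idx <- sample.int(ns, n_direct + n_indirect)
    classes[idx[seq_len(n_direct)]] <- "direct"
    if (n_indirect > 0) classes[idx[n_direct + seq_len(n_indirect)]] <- "indirect"
    sites$class <- classes

    samples <- design_samples(design)  # s3 s7 experimental, s1 s5 control
    exp_kd <- design$experimental[[1]]; exp_oe <- design$experimental[[2]]

    # per protein x sample abundance shift, shared by the protein's sites
    shift <- matrix(stats::rnorm(np * 4, 0, config$protein_change_sd),
                    nrow = np, dimnames = list(acc, samples))
    prot_base <- stats::rnorm(np, config$log2_intensity_mean,
                              config$log2_intensity_sd)
    site_base <- stats::rnorm(ns, config$log2_intensity_mean,
                              config$log2_intensity_sd)

    effect_of <- function(class, sample) {
      e <- config$effect_log2
      dir_sign <- (sample == exp_kd) - (sample == exp_oe)   # +1, -1 or 0
      ifelse(class == "direct", e * dir_sign,
             ifelse(class == "indirect", -e * dir_sign, 0))
    }

    site_long <- tidyr::expand_grid(i = seq_len(ns), sample = samples)
    site_long$log2 <- site_base[site_long$i] +
      shift[cbind(sites$accession[site_long$i], site_long$sample)] +
      effect_of(sites$class[site_long$i], site_long$sample) +
      stats::rnorm(nrow(site_long), 0, config$noise_sd / sqrt(2))

    prot_long <- tidyr::expand_grid(i = seq_len(np), sample = samples)
    prot_long$log2 <- prot_base[prot_long$i] +
      shift[cbind(acc[prot_long$i], prot_long$sample)]

    dropout <- function(x) {
      if (config$missing_slope == 0) return(rep(FALSE, length(x)))
      stats::runif(length(x)) <
        stats::plogis(config$missing_slope * (config$missing_midpoint - x))
    }
    site_long$intensity <- ifelse(dropout(site_long$log2), NA_real_,
                                  2^site_long$log2)
    prot_long$intensity <- ifelse(dropout(prot_long$log2), NA_real_,
                                  2^prot_long$log2)

    sites_tbl <- tibble::tibble(
      record_id = sites$record_id[site_long$i],
      accession = sites$accession[site_long$i],
      gene = sites$gene[site_long$i],
      peptide = sites$peptide[site_long$i],
      sites = sites$sites[site_long$i],
      sample = site_long$sample,
      intensity = site_long$intensity,
      imputed = FALSE
    )
    prot_tbl <- tibble::tibble(
      record_id = sprintf("p%05d", prot_long$i),
      accession = acc[prot_long$i],
      gene = gene[prot_long$i],
      sample = prot_long$sample,
      intensity = prot_long$intensity,
      imputed = FALSE
    )
    truth <- tibble::tibble(record_id = sites$record_id,
                            accession = sites$accession, gene = sites$gene,
                            position = sites$position, class = sites$class)
    protein_truth <- truth |>
      dplyr::group_by(.data$accession, .data$gene) |>
      dplyr::summarise(class = if (any(.data$class == "direct")) "direct"
                       else if (any(.data$class == "indirect")) "indirect"
                       else "null",
                       .groups = "drop")
    structure(list(proteome = proteome, proteins = prot_tbl,
                   sites = sites_tbl, truth = truth,
                   protein_truth = protein_truth,
                   design = design, config = config),
              class = "acetylome_sim")
  })
}

#' @export
print.acetylome_sim <- function(x, ...) {
  cat(sprintf("<acetylome_sim> %d proteins, %d sites (%d direct, %d indirect), seed %d\n",
              x$config$n_proteins, nrow(x$truth),
              sum(x$truth$class == "direct"), sum(x$truth$class == "indirect"),
              x$config$seed))
  invisible(x)
}

#' Generate foreground windows with a planted motif, plus a background proteome
#'
#' A test fixture generator for the motif machinery: foreground windows are
#' K-centered with all flanking residues drawn from the proteome amino-acid
#' background, except that the planted `(position, residue)` is imposed with
#' probability `enrichment`. The returned background proteome provides
#' naturally occurring K-centered windows at base residue frequencies.
#'
#' @param n_fg number of foreground windows.
#' @param n_bg number of background proteins (length 101 each).
#' @param position planted position relative to the central K; must be
#'   nonzero and within `half_width`.
#' @param residue planted single-letter residue.
#' @param enrichment probability a foreground window carries the residue at
#'   the position (background frequency otherwise).
#' @param half_width window half-width (default 5, the motif width used for
#'   extraction).
#' @param seed RNG seed.
#' @return list with `foreground` (character windows) and `proteome`
#'   (named character vector).
#' @export
planted_motif_windows <- function(n_fg, n_bg, position, residue,
                                  enrichment, half_width = 5, seed = 1L) {
  if (position == 0) {
    stop("position 0 is the fixed central K and cannot carry a planted motif",
         call. = FALSE)
  }
  if (abs(position) > half_width) {
    stop("position outside [-half_width, half_width]", call. = FALSE)
  }
  stopifnot(residue %in% AA_RESIDUES, enrichment >= 0, enrichment <= 1)
  local_seed(seed, {
    w <- 2L * half_width + 1L
    other <- AA_FREQS[setdiff(AA_RESIDUES, residue)]
    other <- other / sum(other)
    fg <- vapply(seq_len(n_fg), function(i) {
      aa <- sample(AA_RESIDUES, w, replace = TRUE, prob = AA_FREQS)
      aa[half_width + 1L] <- "K"
      # the planted residue occurs at the position with probability
      # `enrichment` exactly; otherwise a non-matching residue is drawn
      aa[half_width + 1L + position] <-
        if (stats::runif(1) < enrichment) residue
        else sample(names(other), 1, prob = other)
      paste(aa, collapse = "")
    }, character(1))
    # background proteins are pure i.i.d. draws: their naturally occurring
    # K's provide centered windows whose flanks sit exactly at base
    # frequencies (a forced extra K would bias the background K content)
    proteome <- vapply(seq_len(n_bg), function(i) {
      paste(sample(AA_RESIDUES, 101L, replace = TRUE, prob = AA_FREQS),
            collapse = "")
    }, character(1))
    names(proteome) <- sprintf("BG%04d", seq_len(n_bg))
    list(foreground = fg, proteome = proteome)
  })
}
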