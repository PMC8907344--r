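# Fixtures are built in code; nothing is read from disk except what a test
# writes to tempfile() itself.

SAMPLES <- c("s1", "s3", "s5", "s7")

# wide rows -> long quant tibble (site table)
site_quant <- function(wide) {
  wide$record_id <- sprintf("r%05d", seq_len(nrow(wide)))
  out <- tidyr::pivot_longer(wide, dplyr::all_of(SAMPLES),
                             names_to = "sample", values_to = "intensity")
  out$imputed <- FALSE
  out
}

prot_quant <- function(wide) {
  wide$record_id <- sprintf("p%05d", seq_len(nrow(wide)))
  out <- tidyr::pivot_longer(wide, dplyr::all_of(SAMPLES),
                             names_to = "sample", values_to = "intensity")
  out$imputed <- FALSE
  out
}

# one-site-per-record quant pair where every protein ratio is 1, so the
# normalized ratio equals the raw ratio: kd/oe give the s3 and s7 values
# against controls fixed at 1000.
ratio_tables <- function(kd_ratio, oe_ratio, gene = NULL) {
  n <- length(kd_ratio)
  if (is.null(gene)) gene <- sprintf("G%04d", seq_len(n))
  acc <- sprintf("P%04d", seq_len(n))
  sites <- site_quant(tibble::tibble(
    accession = acc, gene = gene,
    peptide = sprintf("PEPTIDE%04d", seq_len(n)), sites = "5",
    s1 = 1000, s3 = 1000 * kd_ratio, s5 = 1000, s7 = 1000 * oe_ratio
  ))
  prots <- prot_quant(tibble::tibble(
    accession = unique(acc), gene = gene[!duplicated(acc)],
    s1 = 500, s3 = 500, s5 = 500, s7 = 500
  ))
  list(sites = sites, proteins = prots)
}

# normalized changes with unit protein ratios, straight to the dex layer
make_changes <- function(kd_ratio, oe_ratio, gene = NULL, peptide = NULL) {
  n <- length(kd_ratio)
  if (is.null(gene)) gene <- sprintf("G%04d", seq_len(n))
  if (is.null(peptide)) peptide <- sprintf("PEPTIDE%04d", seq_len(n))
  base <- tibble::tibble(
    record_id = sprintf("r%05d", seq_len(n)),
    accession = sprintf("P%04d", seq_len(n)),
    gene = gene, peptide = peptide, sites = "5"
  )
  out <- dplyr::bind_rows(
    dplyr::mutate(base, arm = "knockdown", normalized_ratio = kd_ratio),
    dplyr::mutate(base, arm = "overexpression", normalized_ratio = oe_ratio)
  )
  out$raw_ratio <- out$normalized_ratio
  out$protein_ratio <- 1
  out$n_imputed_site <- 0L
  out$n_imputed_protein <- 0L
  out$excluded <- is.na(out$normalized_ratio)
  out$reason <- ifelse(out$excluded, "both_missing", NA_character_)
  out
}

write_tmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# independent straightforward recount of FP/TP patterns at one threshold
recount_fpr <- function(changes, t, level = "peptide") {
  kept <- changes[!changes$excluded, ]
  kept$gene <- toupper(kept$gene)
  key <- if (level == "peptide") paste(kept$peptide, kept$sites) else kept$gene
  fp <- 0L; tp <- 0L
  for (k in unique(key)) {
    sub <- kept[key == k, ]
    arms <- split(sub$normalized_ratio, sub$arm)
    if (length(arms) < 2) next
    up <- vapply(arms, function(r) any(r > t), logical(1))
    dn <- vapply(arms, function(r) any(r < 1 / t), logical(1))
    if (all(up | dn)) {
      if (any(up)) tp <- tp + 1L else fp <- fp + 1L
    }
  }
  c(fp = fp, tp = tp)
}
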