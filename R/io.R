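#' @title Tabular and sequence input/output
#'
#' @description
#' Readers and writers for the plain-text formats the pipeline consumes:
#' tab-separated site-level acetyl-peptide intensity tables, protein-level
#' LFQ tables, proteome FASTA, and GMT gene-set collections.
#'
#' Quantification tables are held in memory in long ("tidy") form, one row
#' per record x sample, with columns `intensity` (NA = missing) and
#' `imputed`. On disk they are wide, one intensity column per sample, with
#' missing values stored as empty cells; a stored intensity of exactly zero
#' is also treated as missing on read (the MaxQuant LFQ convention that
#' 0 means "not quantified"). Parsing is strict: any non-empty cell that
#' does not parse as a plain decimal number is a row-level error, never a
#' silent NA, because silently coerced cells corrupt downstream intensity
#' ratios.
#'
#' @name io_formats
NULL

SITE_KEY_COLS <- c("accession", "gene", "peptide", "sites")
PROT_KEY_COLS <- c("accession", "gene")

parse_intensity_cells <- function(cells, rows, column) {
  x <- trimws(cells)
  missing <- x == "" | x %in% c("NA", "NaN", "nan")
  out <- rep(NA_real_, length(x))
  val <- suppressWarnings(as.numeric(x[!missing]))
  bad <- is.na(val)
  if (any(bad)) {
    i <- which(!missing)[which(bad)[1]]
    stop(sprintf("row %d, column '%s': non-numeric intensity '%s'",
                 rows[i], column, x[i]), call. = FALSE)
  }
  if (any(val < 0)) {
    i <- which(!missing)[which(val < 0)[1]]
    stop(sprintf("row %d, column '%s': negative intensity '%s'",
                 rows[i], column, x[i]), call. = FALSE)
  }
  val[val == 0] <- NA_real_  # 0 = not quantified
  out[!missing] <- val
  out
}

read_quant_file <- function(path, key_cols, design) {
  assert_design(design)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", comment.char = "#",
                           check.names = FALSE, quote = "", na.strings = NULL)
  samples <- design_samples(design)
  needed <- c(key_cols, samples)
  absent <- setdiff(needed, names(raw))
  if (length(absent) > 0) {
    stop("input table lacks required column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  raw <- tibble::as_tibble(raw[needed])
  if (nrow(raw) == 0) {
    return(raw |>
             dplyr::mutate(record_id = character(0)) |>
             tidyr::pivot_longer(dplyr::all_of(samples), names_to = "sample",
                                 values_to = "intensity") |>
             dplyr::mutate(intensity = numeric(0), imputed = logical(0)))
  }
  rows <- seq_len(nrow(raw))
  for (s in samples) {
    raw[[s]] <- parse_intensity_cells(raw[[s]], rows, s)
  }
  raw$record_id <- sprintf("r%05d", rows)
  long <- tidyr::pivot_longer(raw, dplyr::all_of(samples),
                              names_to = "sample", values_to = "intensity")
  long$imputed <- FALSE
  dplyr::relocate(long, "record_id")
}

#' Read a site-level acetyl-peptide intensity table
#'
#' Expects a tab-separated file with header columns `accession`, `gene`,
#' `peptide`, `sites` and one intensity column per sample of the design.
#' `sites` holds the 1-based protein coordinates of the acetylated lysines,
#' semicolon-separated (e.g. `"147;152"`). Lines starting with `#` are
#' ignored.
#'
#' @param path path to the TSV file.
#' @param design a [study_design()].
#' @return A long tibble with one row per record x sample: `record_id`,
#'   `accession`, `gene`, `peptide`, `sites`, `sample`, `intensity`
#'   (NA where the cell was blank or zero) and `imputed` (all FALSE).
#' @seealso [read_protein_table()], [write_site_table()]
#' @export
read_site_table <- function(path, design = study_design()) {
  out <- read_quant_file(path, SITE_KEY_COLS, design)
  keys <- dplyr::distinct(out, .data$record_id, .data$sites)
  for (i in seq_len(nrow(keys))) {
    pos <- parse_sites(keys$sites[[i]])
    if (length(pos) == 0 || anyNA(pos) || any(pos < 1)) {
      stop(sprintf("record %s: malformed 'sites' value '%s'",
                   keys$record_id[[i]], keys$sites[[i]]), call. = FALSE)
    }
  }
  attr(out, "quant_kind") <- "site"
  out
}

#' Read a protein-level LFQ table
#'
#' As [read_site_table()] but without peptide/site columns; requires
#' `accession`, `gene` and one LFQ intensity column per sample. Each
#' protein must appear on exactly one row (one LFQ vector per protein).
#'
#' @inheritParams read_site_table
#' @return Long tibble: `record_id`, `accession`, `gene`, `sample`,
#'   `intensity`, `imputed`.
#' @export
read_protein_table <- function(path, design = study_design()) {
  out <- read_quant_file(path, PROT_KEY_COLS, design)
  acc <- unique(out[, c("record_id", "accession")])$accession
  dup <- unique(acc[duplicated(acc)])
  if (length(dup) > 0) {
    stop("duplicate protein accession(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  attr(out, "quant_kind") <- "protein"
  out
}

parse_sites <- function(sites) {
  suppressWarnings(as.integer(strsplit(sites, ";", fixed = TRUE)[[1]]))
}

quant_to_wide <- function(quant, key_cols) {
  wide <- quant |>
    dplyr::select(dplyr::all_of(c("record_id", key_cols, "sample", "intensity"))) |>
    tidyr::pivot_wider(names_from = "sample", values_from = "intensity")
  wide[order(wide$record_id), , drop = FALSE]
}

write_quant_file <- function(quant, path, key_cols, seed = NULL) {
  wide <- quant_to_wide(quant, key_cols)
  samples <- setdiff(names(wide), c("record_id", key_cols))
  header <- sprintf("# acetylscope %s%s",
                    as.character(utils::packageVersion("acetylscope")),
                    if (is.null(seed)) "" else sprintf("; seed=%d", as.integer(seed)))
  fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  body <- wide[c(key_cols, samples)]
  for (s in samples) body[[s]] <- fmt_num(body[[s]])
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(names(body), collapse = "\t"), con)
  if (nrow(body) > 0) {
    writeLines(do.call(paste, c(unname(as.list(body)), sep = "\t")), con)
  }
  invisible(path)
}

#' Write quantification tables back to disk
#'
#' Writers emit UTF-8 TSV in the same wide layout the readers accept, with a
#' leading `#` comment naming the package version (and seed, if given).
#' Intensities are written with 17 significant digits so a write/read
#' round trip reproduces them bit-exactly; missing values become empty cells.
#'
#' @param quant a long quant tibble from [read_site_table()],
#'   [read_protein_table()] or [simulate_acetylome()].
#' @param path output file path.
#' @param seed optional integer recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(quant, path, seed = NULL) {
  write_quant_file(quant, path, SITE_KEY_COLS, seed)
}

#' @rdname write_site_table
#' @export
write_protein_table <- function(quant, path, seed = NULL) {
  write_quant_file(quant, path, PROT_KEY_COLS, seed)
}

#' Read a proteome FASTA
#'
#' The accession of each sequence is the first whitespace-delimited token of
#' its header line. Sequences are uppercased; duplicate accessions are an
#' error.
#'
#' @param path FASTA file path.
#' @return Named character vector, accession -> amino-acid sequence.
#' @export
read_proteome_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1)
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup) > 0) {
    stop("duplicate FASTA accession(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  seqs
}

#' @rdname read_proteome_fasta
#' @param proteome named character vector of sequences.
#' @export
write_proteome_fasta <- function(proteome, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteome), path)
  invisible(path)
}

#' Extract site-centered sequence windows from a proteome
#'
#' For every acetylation site of every record, extracts the window of
#' `2 * half_width + 1` residues centered on the modified lysine, padding
#' positions beyond the protein termini with `'-'`. Padded positions are
#' excluded from all downstream counting statistics. Sites whose protein
#' residue is not `K` are skipped with a warning (typically an isoform
#' coordinate mismatch); records whose accession is absent from the proteome
#' are an error.
#'
#' @param records a site quant tibble (long or wide); only `record_id`,
#'   `accession` and `sites` are used. For records mapping to several
#'   accessions (`"P1;P2"`) the first listed accession is used.
#' @param proteome named character vector from [read_proteome_fasta()].
#' @param half_width residues on each side of the central K (15 gives the
#'   31-residue stored windows; trim to 5 for motif extraction and 10 for
#'   the residue heatmap with [trim_windows()]).
#' @return Tibble: `record_id`, `accession`, `position`, `window`.
#' @export
extract_windows <- function(records, proteome, half_width = 15) {
  stopifnot(half_width >= 1)
  recs <- dplyr::distinct(
    tibble::as_tibble(records)[, c("record_id", "accession", "sites")]
  )
  recs$accession <- first_accession(recs$accession)
  absent <- setdiff(unique(recs$accession), names(proteome))
  if (length(absent) > 0) {
    stop("accession(s) absent from proteome: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  pad <- strrep("-", half_width)
  n_skipped <- 0L
  rows <- vector("list", nrow(recs))
  for (i in seq_len(nrow(recs))) {
    seqc <- proteome[[recs$accession[[i]]]]
    padded <- paste0(pad, seqc, pad)
    pos <- parse_sites(recs$sites[[i]])
    ok <- pos >= 1 & pos <= nchar(seqc) &
      substr(rep(seqc, length(pos)), pos, pos) == "K"
    n_skipped <- n_skipped + sum(!ok)
    pos <- pos[ok]
    if (length(pos) == 0) next
    rows[[i]] <- tibble::tibble(
      record_id = recs$record_id[[i]],
      accession = recs$accession[[i]],
      position = pos,
      window = substr(rep(padded, length(pos)), pos, pos + 2L * half_width)
    )
  }
  if (n_skipped > 0) {
    warning(sprintf("%d site position(s) did not map to 'K' and were skipped",
                    n_skipped), call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(record_id = character(), accession = character(),
                          position = integer(), window = character())
  }
  out
}

first_accession <- function(accession) {
  multi <- grepl(";", accession, fixed = TRUE)
  if (any(multi)) {
    warning(sprintf(paste0("%d record(s) map to multiple accessions; ",
                           "using the first listed accession"),
                    sum(multi)), call. = FALSE)
  }
  vapply(strsplit(accession, ";", fixed = TRUE), `[[`, character(1), 1)
}

#' Trim stored windows to a narrower half-width
#'
#' @param windows character vector of odd-length windows (all equal length).
#' @param half_width target half-width; must not exceed the stored one.
#' @return Character vector of `2 * half_width + 1`-residue windows.
#' @export
trim_windows <- function(windows, half_width) {
  w <- unique(nchar(windows))
  if (length(w) != 1 || w %% 2 != 1) {
    stop("windows must all share one odd width", call. = FALSE)
  }
  h0 <- (w - 1L) / 2L
  if (half_width > h0) stop("half_width exceeds stored window width", call. = FALSE)
  substr(windows, h0 - half_width + 1L, h0 + half_width + 1L)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `term`, `description`,
#' then member gene symbols. Members are uppercased and deduplicated within
#' each set.
#'
#' @param path GMT file path.
#' @return Tibble with columns `term`, `description`, `genes` (list column
#'   of character vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- which(nzchar(trimws(lines)))
  rows <- lapply(keep, function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    f <- trimws(f)
    members <- unique(toupper(f[-(1:2)][nzchar(f[-(1:2)])]))
    if (length(f) < 3 || length(members) == 0) {
      stop(sprintf("GMT line %d: expected term, description and >= 1 member",
                   i), call. = FALSE)
    }
    tibble::tibble(term = f[[1]], description = f[[2]], genes = list(members))
  })
  if (length(rows) == 0) {
    return(tibble::tibble(term = character(), description = character(),
                          genes = list()))
  }
  dplyr::bind_rows(rows)
}
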