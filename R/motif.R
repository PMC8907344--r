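#' @title Acetylation-site sequence motifs
#'
#' @description
#' Greedy motif extraction in the motif-x style: starting from K-centered
#' foreground windows and a proteome-wide background of K-centered windows,
#' the algorithm repeatedly fixes the single (position, residue) pair with
#' the smallest binomial upper-tail p-value among those meeting the
#' significance and occurrence floors, restricts foreground and background
#' to matching windows, and recurses; each completed motif consumes its
#' matching foreground windows before extraction restarts on the remainder.
#' Background probabilities are position-specific (not a pooled frequency)
#' because each step conditions on the previously fixed positions.
#'
#' Padding characters (`'-'`) never count as residue occurrences, and
#' windows that do not cover a position do not enter that position's totals.
#'
#' @name motif_analysis
NULL

#' Build a background model of K-centered windows
#'
#' @param proteome named character vector of protein sequences; every K in
#'   every protein contributes one centered window.
#' @param half_width window half-width.
#' @return Object of class `motif_background`: the background windows and
#'   their half-width.
#' @export
motif_background <- function(proteome, half_width = 5) {
  pad <- strrep("-", half_width)
  wins <- unlist(lapply(proteome, function(seqc) {
    padded <- paste0(pad, seqc, pad)
    pos <- which(strsplit(seqc, "")[[1]] == "K")
    if (length(pos) == 0) return(character(0))
    substr(rep(padded, length(pos)), pos, pos + 2L * half_width)
  }), use.names = FALSE)
  as_motif_background(wins, half_width)
}

#' @rdname motif_background
#' @param windows character vector of pre-extracted K-centered windows.
#' @export
as_motif_background <- function(windows, half_width = (unique(nchar(windows)) - 1) / 2) {
  check_windows(windows, half_width)
  structure(list(windows = windows, half_width = as.integer(half_width)),
            class = "motif_background")
}

#' @export
print.motif_background <- function(x, ...) {
  cat(sprintf("<motif_background> %d K-centered windows, half-width %d\n",
              length(x$windows), x$half_width))
  invisible(x)
}

check_windows <- function(windows, half_width) {
  if (length(windows) == 0) stop("no windows supplied", call. = FALSE)
  w <- unique(nchar(windows))
  if (length(w) != 1 || w != 2 * half_width + 1) {
    stop(sprintf("windows must all be %d residues wide", 2 * half_width + 1),
         call. = FALSE)
  }
  centers <- substr(windows, half_width + 1, half_width + 1)
  if (any(centers != "K")) {
    stop("every window must be centered on K", call. = FALSE)
  }
  invisible(windows)
}

# residue x position count matrix (20 x 2h+1); padding and nonstandard
# residues excluded. Also returns per-position coverage totals.
position_counts <- function(windows, half_width) {
  w <- 2L * half_width + 1L
  mat <- matrix(unlist(strsplit(windows, ""), use.names = FALSE),
                ncol = w, byrow = TRUE)
  counts <- matrix(0L, nrow = 20, ncol = w,
                   dimnames = list(AA_RESIDUES, as.character(seq_len(w) - half_width - 1L)))
  for (j in seq_len(w)) {
    tab <- table(factor(mat[, j], levels = AA_RESIDUES))
    counts[, j] <- as.integer(tab)
  }
  list(counts = counts, totals = colSums(counts))
}

#' Binomial upper-tail p-value for motif enrichment
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`: the probability of observing at
#' least `k` foreground matches when matches occur at the background
#' probability `p0`. The one-sided (enrichment-only) test used at each
#' motif-x selection step.
#'
#' @param n foreground size.
#' @param k observed matches, `0 <= k <= n`.
#' @param p0 background match probability.
#' @return The exact tail probability.
#' @examples
#' binomial_p(10, 2, 0.1)
#' @export
binomial_p <- function(n, k, p0) {
  if (any(n < 0) || any(k < 0) || any(k > n) || any(p0 < 0) || any(p0 > 1)) {
    stop("need 0 <= k <= n and 0 <= p0 <= 1", call. = FALSE)
  }
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

match_fixed <- function(windows, half_width, position, residue) {
  substr(windows, half_width + 1L + position, half_width + 1L + position) == residue
}

motif_pattern <- function(fixed, half_width) {
  chars <- rep("x", 2L * half_width + 1L)
  chars[half_width + 1L] <- "K(ac)"
  if (nrow(fixed) > 0) {
    chars[half_width + 1L + fixed$position] <- fixed$residue
  }
  first <- min(c(which(chars != "x"), half_width + 1L))
  last <- max(c(which(chars != "x"), half_width + 1L))
  paste(chars[first:last], collapse = "")
}

#' Extract over-represented motifs by greedy binomial selection
#'
#' @param foreground character vector of K-centered windows, the same width
#'   as the background (trim stored windows with [trim_windows()]; the
#'   conventional extraction width is 11, i.e. half-width 5).
#' @param background a [motif_background()] of matching half-width.
#' @param p_threshold binomial significance required to fix a position
#'   (default 0.001).
#' @param min_occurrences minimum foreground matches required to fix a
#'   position (default 12).
#' @return Tibble of class `motifx_result`, one row per motif:
#'   `pattern` (e.g. `"KxxxxK(ac)"`), `n_matching` foreground windows
#'   consumed, `n_fixed` positions, and `steps` — a list column recording
#'   each fixed (position, residue) with its foreground count, background
#'   probability and binomial p-value at the selection step. Zero rows when
#'   no motif reaches the floors.
#' @export
motifx <- function(foreground, background, p_threshold = 0.001,
                   min_occurrences = 12) {
  stopifnot(inherits(background, "motif_background"))
  h <- background$half_width
  check_windows(foreground, h)
  positions <- setdiff(seq(-h, h), 0L)

  motifs <- list()
  fg_left <- foreground
  repeat {
    if (length(fg_left) == 0) break
    fg_cur <- fg_left
    bg_cur <- background$windows
    fixed <- tibble::tibble(position = integer(), residue = character(),
                            k = integer(), p0 = numeric(), p = numeric())
    repeat {
      open <- setdiff(positions, fixed$position)
      if (length(open) == 0 || length(bg_cur) == 0) break
      fgc <- position_counts(fg_cur, h)
      bgc <- position_counts(bg_cur, h)
      best <- NULL
      for (j in open) {
        jc <- as.character(j)
        n_fg <- fgc$totals[[jc]]
        n_bg <- bgc$totals[[jc]]
        if (n_fg == 0 || n_bg == 0) next
        k <- fgc$counts[, jc]
        p0 <- bgc$counts[, jc] / n_bg
        # a residue absent from the background cannot yield p0 = 0; use the
        # smallest nonzero frequency the background could have shown
        p0 <- ifelse(p0 == 0 & k > 0, 0.5 / n_bg, p0)
        ok <- k >= min_occurrences
        if (!any(ok)) next
        p <- binomial_p(n_fg, k, p0)
        ok <- ok & p < p_threshold
        if (!any(ok)) next
        cand <- tibble::tibble(position = j, residue = AA_RESIDUES,
                               k = as.integer(k), p0 = p0, p = p)[ok, ]
        best <- dplyr::bind_rows(best, cand)
      }
      if (is.null(best) || nrow(best) == 0) break
      best <- best[order(best$p, -best$k, best$position, best$residue), ]
      pick <- best[1, ]
      fixed <- dplyr::bind_rows(fixed, pick)
      keep_fg <- match_fixed(fg_cur, h, pick$position, pick$residue)
      keep_bg <- match_fixed(bg_cur, h, pick$position, pick$residue)
      fg_cur <- fg_cur[keep_fg]
      bg_cur <- bg_cur[keep_bg]
    }
    if (nrow(fixed) == 0) break
    motifs[[length(motifs) + 1]] <- tibble::tibble(
      pattern = motif_pattern(fixed, h),
      n_matching = length(fg_cur),
      n_fixed = nrow(fixed),
      steps = list(fixed)
    )
    # consume the matched windows and look for the next motif
    consumed <- rep(TRUE, length(fg_left))
    for (i in seq_len(nrow(fixed))) {
      consumed <- consumed &
        match_fixed(fg_left, h, fixed$position[[i]], fixed$residue[[i]])
    }
    fg_left <- fg_left[!consumed]
  }
  out <- if (length(motifs) == 0) {
    tibble::tibble(pattern = character(), n_matching = integer(),
                   n_fixed = integer(), steps = list())
  } else {
    dplyr::bind_rows(motifs)
  }
  class(out) <- c("motifx_result", class(out))
  out
}

#' Signed residue-by-position Fisher-exact enrichment heatmap
#'
#' For every residue and every non-central position of the foreground
#' windows, a two-sided Fisher exact test compares the foreground count
#' against the background count at that position. The cell value is
#' `sign * -log10(p)`, positive where the residue is over-used in the
#' foreground relative to the background and negative where it is
#' under-used; the central column (always K by construction) is masked
#' as NA.
#'
#' @param foreground K-centered windows (conventionally half-width 10, a
#'   21-residue span).
#' @param background a [motif_background()] of matching half-width.
#' @return A 20 x (2 * half_width + 1) matrix of class `residue_heatmap`
#'   (rows = residues, columns = positions); attributes record foreground
#'   and background sizes.
#' @export
residue_heatmap <- function(foreground, background) {
  stopifnot(inherits(background, "motif_background"))
  h <- background$half_width
  if (length(foreground) == 0) stop("empty foreground", call. = FALSE)
  check_windows(foreground, h)
  fgc <- position_counts(foreground, h)
  bgc <- position_counts(background$windows, h)
  w <- 2L * h + 1L
  mat <- matrix(NA_real_, nrow = 20, ncol = w,
                dimnames = dimnames(fgc$counts))
  for (j in seq_len(w)) {
    if (j == h + 1L) next  # central K column masked
    n_fg <- fgc$totals[[j]]
    n_bg <- bgc$totals[[j]]
    if (n_fg == 0 || n_bg == 0) next
    for (a in seq_len(20)) {
      k <- fgc$counts[a, j]
      b <- bgc$counts[a, j]
      tab <- matrix(c(k, n_fg - k, b, n_bg - b), nrow = 2)
      p <- stats::fisher.test(tab)$p.value
      s <- sign(k / n_fg - b / n_bg)
      mat[a, j] <- s * -log10(max(p, .Machine$double.xmin))
    }
  }
  structure(mat, class = c("residue_heatmap", class(mat)),
            n_fg = length(foreground), n_bg = length(background$windows))
}
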