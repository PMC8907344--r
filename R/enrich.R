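#' @title Gene-set over-representation analysis
#'
#' @description
#' One-sided Fisher-exact (hypergeometric) tests of a hit list against a
#' gene-set collection, with the background universe defined as all
#' proteins quantified in the experiment — not the whole proteome — so the
#' test asks whether hits concentrate in a set beyond what the *observable*
#' proteome would give by chance.
#'
#' @name set_enrichment
NULL

#' Fisher-exact over-representation of a hit list in gene sets
#'
#' Set members are intersected with the background before testing; terms
#' with zero overlap are dropped (their p would be 1). The reported
#' p-value is the hypergeometric upper tail
#' `P(X >= k)` with `X ~ Hypergeom(K, N - K, n)`; q-values are
#' Benjamini-Hochberg over all tested terms.
#'
#' @param hits character vector of hit gene symbols; must be a subset of
#'   `background`.
#' @param background character vector of all quantified gene symbols.
#' @param sets gene-set tibble from [read_gmt()] (columns `term`,
#'   `description`, `genes`).
#' @param alpha significance cutoff mirrored into the `significant` flag
#'   (default 0.05).
#' @return Tibble of class `enrich_result`, sorted by p: `term`,
#'   `description`, `k` (overlap), `n` (hits), `K` (term size in
#'   background), `N` (background size), `fold` = `(k/n)/(K/N)`, `p`, `q`,
#'   `significant`.
#' @export
fisher_enrich <- function(hits, background, sets, alpha = 0.05) {
  background <- unique(toupper(background))
  hits <- unique(toupper(hits))
  if (length(background) == 0) stop("empty background", call. = FALSE)
  stray <- setdiff(hits, background)
  if (length(stray) > 0) {
    stop("hits absent from background: ", paste(stray, collapse = ", "),
         call. = FALSE)
  }
  N <- length(background)
  n <- length(hits)
  rows <- purrr::pmap(sets, function(term, description, genes, ...) {
    members <- intersect(toupper(genes), background)
    K <- length(members)
    k <- length(intersect(hits, members))
    if (k == 0) return(NULL)
    tibble::tibble(term = term, description = description,
                   k = k, n = n, K = K, N = N,
                   fold = (k / n) / (K / N),
                   p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(term = character(), description = character(),
                          k = integer(), n = integer(), K = integer(),
                          N = integer(), fold = numeric(), p = numeric())
  }
  out$q <- bh_adjust(out$p)
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$term), ]
  class(out) <- c("enrich_result", class(out))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement, as provided by
#' [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
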