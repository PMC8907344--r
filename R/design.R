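#' Define the two-arm knockdown / overexpression study design
#'
#' The pipeline compares acetyl-site intensities between an experimental and
#' a control sample in each of two arms: a deacetylase knockdown arm and a
#' deacetylase overexpression arm. Each arm is a single experimental/control
#' sample pair (one replicate per condition, as in label-free designs where
#' each condition is one LC-MS/MS run).
#'
#' @param knockdown length-2 character vector `c(experimental, control)`
#'   naming the intensity columns of the knockdown arm.
#' @param overexpression length-2 character vector `c(experimental, control)`
#'   for the overexpression arm.
#' @param labels arm labels; the first is treated as the knockdown-like arm
#'   by downstream classification.
#'
#' @return A tibble with columns `arm`, `experimental`, `control`, one row
#'   per arm.
#' @examples
#' study_design()  # the default s1/s3/s5/s7 sample numbering
#' @export
study_design <- function(knockdown = c("s3", "s1"),
                         overexpression = c("s7", "s5"),
                         labels = c("knockdown", "overexpression")) {
  stopifnot(length(knockdown) == 2, length(overexpression) == 2,
            length(labels) == 2, !anyDuplicated(labels))
  ids <- c(knockdown, overexpression)
  if (anyDuplicated(ids)) {
    stop("the four sample ids of a study design must be distinct, got: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    arm = as.character(labels),
    experimental = c(knockdown[[1]], overexpression[[1]]),
    control = c(knockdown[[2]], overexpression[[2]])
  )
}

design_samples <- function(design) {
  unique(c(design$experimental, design$control))
}

assert_design <- function(design) {
  if (!is.data.frame(design) ||
      !all(c("arm", "experimental", "control") %in% names(design)) ||
      nrow(design) != 2) {
    stop("`design` must be a two-arm design from study_design()",
         call. = FALSE)
  }
  invisible(design)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}
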