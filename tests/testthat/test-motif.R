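test_that("binomial tail probabilities are exact", {
  expect_equal(binomial_p(10, 0, 0.3), 1)
  expect_equal(binomial_p(5, 3, 1), 1)
  brute <- sum(choose(10, 2:10) * 0.1^(2:10) * 0.9^(8:0))
  expect_equal(binomial_p(10, 2, 0.1), brute, tolerance = 1e-12)
  expect_error(binomial_p(10, 11, 0.1), "k <= n")
  expect_error(binomial_p(10, 2, 1.2), "p0")
})

test_that("binomial_p is monotone in k and p0", {
  ks <- 0:50
  p_by_k <- binomial_p(50, ks, 0.2)
  expect_true(all(diff(p_by_k) <= 0))
  p0s <- seq(0.01, 0.99, by = 0.01)
  p_by_p0 <- vapply(p0s, function(p0) binomial_p(50, 10, p0), numeric(1))
  expect_true(all(diff(p_by_p0) >= 0))
})

test_that("a planted motif is recovered", {
  pm <- planted_motif_windows(200, 400, position = 5, residue = "K",
                              enrichment = 0.6, seed = 1)
  bg <- motif_background(pm$proteome, half_width = 5)
  mx <- motifx(pm$foreground, bg)
  # the planted (+5, K) signal dwarfs everything else, so it is the first
  # position fixed; secondary chance positions may occasionally co-fix at
  # this foreground size, but the planted pattern itself is always emitted
  expect_gte(nrow(mx), 1)
  expect_equal(mx$steps[[1]]$position[[1]], 5)
  expect_equal(mx$steps[[1]]$residue[[1]], "K")
  expect_true("K(ac)xxxxK" %in% mx$pattern)
  expect_gte(sum(mx$n_matching), 0.6 * 200 * 0.8)
  expect_true(all(unlist(lapply(mx$steps, `[[`, "p")) < 0.001))
  expect_true(all(unlist(lapply(mx$steps, `[[`, "k")) >= 12))
})

test_that("the mirrored planted position renders the K(ac)-last pattern", {
  pm <- planted_motif_windows(200, 400, position = -5, residue = "K",
                              enrichment = 0.6, seed = 2)
  bg <- motif_background(pm$proteome, half_width = 5)
  mx <- motifx(pm$foreground, bg)
  expect_equal(mx$steps[[1]]$position[[1]], -5)
  expect_equal(mx$steps[[1]]$residue[[1]], "K")
  expect_true("KxxxxK(ac)" %in% mx$pattern)
})

test_that("a foreground that is its own background yields no motif", {
  pm <- planted_motif_windows(1, 400, position = 5, residue = "K",
                              enrichment = 0, seed = 12)
  all_bg <- motif_background(pm$proteome, half_width = 5)
  for (s in 1:5) {
    set.seed(s)
    wins <- sample(all_bg$windows, 200)
    expect_equal(nrow(motifx(wins, as_motif_background(wins))), 0)
  }
})

test_that("the occurrence floor and width contract are enforced", {
  pm <- planted_motif_windows(11, 100, position = 5, residue = "K",
                              enrichment = 1, seed = 3)
  bg <- motif_background(pm$proteome, half_width = 5)
  mx <- motifx(pm$foreground, bg, min_occurrences = 12)
  expect_equal(nrow(mx), 0)

  wrong <- substr(pm$foreground, 1, 9)
  expect_error(motifx(wrong, bg), "11 residues")
  off_center <- paste0("A", substr(pm$foreground, 1, 10))
  expect_error(motifx(off_center, bg), "centered on K")
})

test_that("extracted motifs partition the foreground windows they consume", {
  set.seed(4)
  pm1 <- planted_motif_windows(150, 400, position = 5, residue = "K",
                               enrichment = 0.7, seed = 5)
  pm2 <- planted_motif_windows(150, 400, position = -3, residue = "P",
                               enrichment = 0.7, seed = 6)
  fg <- c(pm1$foreground, pm2$foreground)
  bg <- motif_background(c(pm1$proteome, pm2$proteome), half_width = 5)
  mx <- motifx(fg, bg)
  expect_gte(nrow(mx), 2)
  expect_lte(sum(mx$n_matching), length(fg))
  # windows matching an earlier motif are consumed before later ones
  matches <- function(w, steps) {
    m <- rep(TRUE, length(w))
    for (i in seq_len(nrow(steps))) {
      m <- m & substr(w, 6 + steps$position[[i]], 6 + steps$position[[i]]) ==
        steps$residue[[i]]
    }
    m
  }
  claimed <- matrix(FALSE, nrow = length(fg), ncol = nrow(mx))
  for (j in seq_len(nrow(mx))) claimed[, j] <- matches(fg, mx$steps[[j]])
  first_claim <- apply(claimed, 1, function(z) which(z)[1])
  for (j in seq_len(nrow(mx))) {
    expect_equal(mx$n_matching[[j]], sum(first_claim == j, na.rm = TRUE))
  }
})

test_that("heatmap cells equal a hypergeometric two-sided oracle", {
  pm <- planted_motif_windows(30, 60, position = -2, residue = "A",
                              enrichment = 0.8, half_width = 10, seed = 7)
  bg <- motif_background(pm$proteome, half_width = 10)
  hm <- residue_heatmap(pm$foreground, bg)
  td <- tidy(hm)

  fisher_oracle <- function(k, nfg, b, nbg) {
    # two-sided Fisher: sum of all table probabilities <= observed
    support <- max(0, k + b - nbg):min(k + b, nfg)
    dens <- dhyper(support, k + b, nfg + nbg - (k + b), nfg)
    obs <- dhyper(k, k + b, nfg + nbg - (k + b), nfg)
    sum(dens[dens <= obs * (1 + 1e-7)])
  }
  fg_counts <- bg_counts <- NULL
  h <- 10L
  count_at <- function(wins, res, pos) {
    sum(substr(wins, h + 1 + pos, h + 1 + pos) == res)
  }
  cover_at <- function(wins, pos) {
    sum(substr(wins, h + 1 + pos, h + 1 + pos) != "-")
  }
  for (i in sample(nrow(td), 100)) {       # spot-check plus the extremes
    pos <- td$position[[i]]; res <- td$residue[[i]]
    if (pos == 0) { expect_true(is.na(td$signed_logp[[i]])); next }
    k <- count_at(pm$foreground, res, pos)
    b <- count_at(bg$windows, res, pos)
    nfg <- cover_at(pm$foreground, pos)
    nbg <- cover_at(bg$windows, pos)
    p <- fisher_oracle(k, nfg, b, nbg)
    s <- sign(k / nfg - b / nbg)
    expect_equal(td$signed_logp[[i]], s * -log10(p), tolerance = 1e-12)
  }
  # the planted cell dominates the matrix
  expect_equal(td$signed_logp[which.max(td$signed_logp)],
               max(abs(td$signed_logp), na.rm = TRUE))
  top <- td[which.max(td$signed_logp), ]
  expect_equal(top$residue, "A")
  expect_equal(top$position, -2L)
})

test_that("a foreground copied from the background shows no enrichment", {
  pm <- planted_motif_windows(5, 80, position = 2, residue = "A",
                              enrichment = 0, half_width = 10, seed = 8)
  bg <- motif_background(pm$proteome, half_width = 10)
  set.seed(9)
  fg <- sample(bg$windows, 60)
  hm <- residue_heatmap(fg, bg)
  expect_lt(max(abs(hm), na.rm = TRUE), -log10(0.001))
})

test_that("swapping foreground and background flips every heatmap sign", {
  pm <- planted_motif_windows(40, 50, position = 3, residue = "L",
                              enrichment = 0.7, half_width = 10, seed = 10)
  bg <- motif_background(pm$proteome, half_width = 10)
  hm_ab <- residue_heatmap(pm$foreground, bg)
  hm_ba <- residue_heatmap(bg$windows, as_motif_background(pm$foreground))
  a <- tidy(hm_ab)$signed_logp; b <- tidy(hm_ba)$signed_logp
  ok <- !is.na(a) & !is.na(b)
  expect_equal(a[ok], -b[ok], tolerance = 1e-9)
})

test_that("an empty foreground is rejected", {
  pm <- planted_motif_windows(10, 20, position = 2, residue = "A",
                              enrichment = 0, half_width = 10, seed = 11)
  bg <- motif_background(pm$proteome, half_width = 10)
  expect_error(residue_heatmap(character(0), bg), "foreground|windows")
})
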