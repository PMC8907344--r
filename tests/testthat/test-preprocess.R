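test_that("a table with no missing values passes through imputation unchanged", {
  tb <- ratio_tables(c(2, 1), c(0.5, 1))
  out <- impute_downshift(tb$sites, seed = 1)
  expect_identical(out$intensity, tb$sites$intensity)
  expect_equal(sum(out$imputed), 0)
})

test_that("imputed draws follow the truncated downshifted Gaussian", {
  n <- 2000
  set.seed(101)
  wide <- tibble::tibble(
    accession = sprintf("P%05d", 1:n), gene = sprintf("G%05d", 1:n),
    peptide = "AAKAA", sites = "3",
    s1 = 2^rnorm(n, 25, 2), s3 = NA_real_,
    s5 = 2^rnorm(n, 25, 2), s7 = 2^rnorm(n, 25, 2)
  )
  quant <- site_quant(wide)
  obs <- log2(quant$intensity[!is.na(quant$intensity)])
  mu <- mean(obs); sg <- sd(obs)

  out <- impute_downshift(quant, downshift = 1.8, halfwidth = 0.3, seed = 7)
  draws <- log2(out$intensity[out$imputed])
  expect_equal(length(draws), n)  # every eligible cell, nothing else
  expect_true(all(draws >= mu - 2.1 * sg & draws <= mu - 1.5 * sg))
  # observed values untouched
  expect_identical(out$intensity[!out$imputed], quant$intensity[!is.na(quant$intensity)])

  # truncated-normal mean by numerical integration
  ctr <- mu - 1.8 * sg; lo <- ctr - 0.3 * sg; hi <- ctr + 0.3 * sg
  z <- integrate(function(x) dnorm(x, ctr, sg), lo, hi)$value
  m_tr <- integrate(function(x) x * dnorm(x, ctr, sg), lo, hi)$value / z
  v_tr <- integrate(function(x) (x - m_tr)^2 * dnorm(x, ctr, sg), lo, hi)$value / z
  expect_lt(abs(mean(draws) - m_tr), 3 * sqrt(v_tr / n))

  # reproducible from seed
  again <- impute_downshift(quant, seed = 7)
  expect_identical(out$intensity, again$intensity)
  expect_false(identical(out$intensity,
                         impute_downshift(quant, seed = 8)$intensity))
})

test_that("imputation refuses degenerate populations", {
  wide <- tibble::tibble(accession = "P1", gene = "G1", peptide = "K", sites = "1",
                         s1 = 8, s3 = 8, s5 = 8, s7 = NA_real_)
  expect_error(impute_downshift(site_quant(wide), seed = 1), "degenerate")
  wide2 <- dplyr::mutate(wide, s1 = NA_real_, s3 = NA_real_, s5 = NA_real_)
  expect_error(impute_downshift(site_quant(wide2), seed = 1), "at least 2")
})

test_that("the one-of-two rule drives keep/exclude decisions", {
  sites <- site_quant(tibble::tibble(
    accession = c("P1", "P2", "P3"), gene = c("G1", "G2", "G3"),
    peptide = c("AKA", "MKM", "CKC"), sites = "2",
    s1 = c(100, NA, 100), s3 = c(200, NA, 150),
    s5 = c(100, 120, 90), s7 = c(50, 60, 80)
  ))
  prots <- prot_quant(tibble::tibble(
    accession = c("P1", "P2", "P3"), gene = c("G1", "G2", "G3"),
    s1 = c(10, 10, NA), s3 = c(10, 10, NA),
    s5 = c(10, 10, 10), s7 = c(10, 10, 12)
  ))
  pf <- pair_filter(sites, prots)
  get <- function(rid, arm) pf[pf$record_id == rid & pf$arm == arm, ]

  expect_true(get("r00001", "knockdown")$keep)          # all observed
  kd2 <- get("r00002", "knockdown")                      # both acetyl missing
  expect_false(kd2$keep); expect_equal(kd2$reason, "both_missing")
  expect_true(get("r00002", "overexpression")$keep)
  kd3 <- get("r00003", "knockdown")                      # protein never measured in arm
  expect_false(kd3$keep); expect_equal(kd3$reason, "protein_unquantified")
  expect_true(get("r00003", "overexpression")$keep)

  # two imputed acetyl values in one pair are never retained
  s2 <- sites
  s2$imputed[s2$record_id == "r00002" & s2$sample %in% c("s1", "s3")] <- TRUE
  s2$intensity[s2$imputed] <- 50
  pf2 <- pair_filter(s2, prots)
  expect_false(pf2[pf2$record_id == "r00002" & pf2$arm == "knockdown", ]$keep)
  expect_equal(pf2[pf2$record_id == "r00002" & pf2$arm == "knockdown", ]$reason,
               "both_missing")
})

test_that("a protein unquantified in an arm excludes all its peptides there", {
  sites <- site_quant(tibble::tibble(
    accession = "P9", gene = "G9",
    peptide = c("AKAAA", "CCKCC", "DDKDD"), sites = c("2", "3", "3"),
    s1 = 100, s3 = 120, s5 = 100, s7 = 90
  ))
  prots <- prot_quant(tibble::tibble(accession = "P9", gene = "G9",
                                     s1 = NA_real_, s3 = NA_real_,
                                     s5 = 10, s7 = 10))
  ch <- compute_changes(sites, prots)
  kd <- ch[ch$arm == "knockdown", ]
  expect_true(all(kd$excluded))
  expect_true(all(kd$reason == "protein_unquantified"))
  expect_false(any(ch[ch$arm == "overexpression", ]$excluded))
})

test_that("normalized ratio is exactly raw over protein ratio", {
  sites <- site_quant(tibble::tibble(
    accession = c("P1", "P2"), gene = c("G1", "G2"),
    peptide = c("AKA", "MKM"), sites = "2",
    s1 = c(10, 10), s3 = c(30, 40), s5 = c(10, 8), s7 = c(5, 8)
  ))
  prots <- prot_quant(tibble::tibble(
    accession = c("P1", "P2"), gene = c("G1", "G2"),
    s1 = c(5, 7), s3 = c(10, 7), s5 = c(4, 3), s7 = c(4, 3)
  ))
  ch <- compute_changes(sites, prots)
  kd1 <- ch[ch$record_id == "r00001" & ch$arm == "knockdown", ]
  expect_equal(kd1$raw_ratio, 3)
  expect_equal(kd1$protein_ratio, 2)
  expect_equal(kd1$normalized_ratio, 1.5)
  kd2 <- ch[ch$record_id == "r00002" & ch$arm == "knockdown", ]
  expect_equal(kd2$protein_ratio, 1)                 # flat protein
  expect_equal(kd2$normalized_ratio, kd2$raw_ratio)  # identity
  expect_equal(ch$normalized_ratio[!ch$excluded],
               ch$raw_ratio[!ch$excluded] / ch$protein_ratio[!ch$excluded])
})

test_that("normalization is scale-invariant under paired rescaling", {
  sim <- simulate_acetylome(sim_config(n_proteins = 80, seed = 15))
  st <- impute_downshift(sim$sites, seed = 1)
  pt <- impute_downshift(sim$proteins, seed = 2)
  ch0 <- compute_changes(st, pt)

  scale_sample <- function(quant, sample, c) {
    quant$intensity[quant$sample == sample] <-
      quant$intensity[quant$sample == sample] * c
    quant
  }
  for (c in c(0.25, 3, 17.5)) {
    both <- compute_changes(scale_sample(st, "s3", c), scale_sample(pt, "s3", c))
    expect_equal(both$normalized_ratio, ch0$normalized_ratio, tolerance = 1e-12)
    kd <- ch0$arm == "knockdown" & !ch0$excluded
    expect_equal(both$raw_ratio[kd], ch0$raw_ratio[kd] * c, tolerance = 1e-12)

    acetyl_only <- compute_changes(scale_sample(st, "s3", c), pt)
    expect_equal(acetyl_only$normalized_ratio[kd],
                 ch0$normalized_ratio[kd] * c, tolerance = 1e-12)
    oe <- ch0$arm == "overexpression" & !ch0$excluded
    expect_equal(acetyl_only$normalized_ratio[oe], ch0$normalized_ratio[oe],
                 tolerance = 1e-12)
  }
})
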