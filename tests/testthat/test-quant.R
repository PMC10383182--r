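test_that("reporter extraction takes the strongest peak per channel window", {
  ch <- itraq4_channels()
  sp <- spectrum("q1", precursor_mz = 500, charge = 2,
                 mz = ch$masses, intensity = c(10, 20, 30, 40))
  expect_equal(extract_reporters(sp, ch), c(10, 20, 30, 40))

  empty_low <- spectrum("q2", precursor_mz = 500, charge = 2,
                        mz = c(250, 600), intensity = c(5, 9))
  expect_equal(extract_reporters(empty_low, ch), c(0, 0, 0, 0))

  # two peaks inside the 114.1112 +/- 0.1 window: the more intense wins
  two <- spectrum("q3", precursor_mz = 500, charge = 2,
                  mz = c(114.06, 114.16), intensity = c(7, 11))
  expect_equal(extract_reporters(two, ch)[1], 11)
  # peak just outside the window is ignored
  out <- spectrum("q4", precursor_mz = 500, charge = 2,
                  mz = 114.22, intensity = 100)
  expect_equal(extract_reporters(out, ch)[1], 0)
})

test_that("impurity correction inverts the mixing exactly and clamps", {
  p <- default_purity_matrix()
  expect_equal(correct_impurities(c(5, 6, 7, 8), validate_purity_matrix(diag(4))),
               c(5, 6, 7, 8), ignore_attr = TRUE)
  set.seed(77)
  for (k in 1:25) {
    truth <- runif(4, 10, 1e5)
    raw <- as.numeric(unclass(p) %*% truth)
    rec <- correct_impurities(raw, p)
    expect_lt(max(abs(rec - truth) / truth), 1e-8)
  }
  # a raw vector whose exact solution is negative gets clamped to zero
  raw_neg <- as.numeric(unclass(p) %*% c(100, 0, 50, 20))
  raw_neg[2] <- raw_neg[2] * 0.01
  rec <- correct_impurities(raw_neg, p)
  expect_true(all(rec >= 0))
  expect_gte(attr(rec, "n_clamped"), 1)
})

test_that("normalization factors equalize reference-run channel totals", {
  expect_equal(compute_normalization_factors(rep(100, 4))$factors,
               rep(1, 4))
  nf <- compute_normalization_factors(c(100, 200, 100, 100))
  expect_equal(nf$factors, c(1.25, 0.625, 1.25, 1.25))
  totals <- c(80, 120, 95, 105)
  f <- compute_normalization_factors(totals)$factors
  expect_lt(diff(range(totals * f)), 1e-9)
  expect_error(compute_normalization_factors(c(0, 1, 1, 1)), "> 0")

  # scale equivariance: scaling one channel by k scales its factor by 1/k
  f2 <- compute_normalization_factors(totals * c(3, 1, 1, 1))$factors
  ratio <- f2 / compute_normalization_factors(totals)$factors
  expect_equal(ratio[1] / ratio[2], 1 / 3, tolerance = 1e-12)
})

test_that("peptide ratios are sum-then-ratio, not mean of per-scan ratios", {
  ch <- itraq4_channels()
  # scans (num, den) = (10, 20) and (30, 40) on the DN/DM channels
  scans <- matrix(0, 4, 2)
  scans[group_channels(ch, "DN"), ] <- c(10, 30)
  scans[group_channels(ch, "DM"), ] <- c(20, 40)
  pq <- aggregate_and_ratio(scans, ch, list(c("DN", "DM")))
  expect_equal(pq$ratios$ratio, 40 / 60, tolerance = 1e-12)
  mean_of_ratios <- mean(c(10 / 20, 30 / 40))
  expect_false(isTRUE(all.equal(pq$ratios$ratio, mean_of_ratios)))

  single <- matrix(0, 4, 1)
  single[group_channels(ch, "DN"), ] <- 50
  single[group_channels(ch, "DM"), ] <- 25
  expect_equal(aggregate_and_ratio(single, ch,
                                   list(c("DN", "DM")))$ratios$ratio, 2)

  zero_den <- matrix(0, 4, 1)
  zero_den[group_channels(ch, "DN"), ] <- 50
  res <- aggregate_and_ratio(zero_den, ch, list(c("DN", "DM")))$ratios
  expect_true(res$flagged)
  expect_true(is.na(res$ratio))
  expect_error(aggregate_and_ratio(matrix(0, 4, 0), ch), "empty")
})

test_that("scan quantification conserves intensity through aggregation", {
  set.seed(88)
  ch <- itraq4_channels()
  p <- default_purity_matrix()
  spectra <- lapply(1:30, function(i)
    spectrum(sprintf("c%02d", i), precursor_mz = 500, charge = 2,
             mz = ch$masses, intensity = runif(4, 100, 1e4)))
  q <- quantify_scans(spectra, p, norm = NULL, channels = ch)
  psms <- do.call(rbind, lapply(1:30, function(i)
    make_psm(sprintf("c%02d", i),
             c("AASASAK", "TTVSYR", "SSSSK")[i %% 3 + 1],
             "1:S:phospho")))
  psms$modifications <- vapply(psms$sequence, function(sq) {
    sty <- which(strsplit(sq, "")[[1]] %in% c("S", "T", "Y"))[1]
    sprintf("%d:%s:phospho", sty, substring(sq, sty, sty))
  }, "")
  col <- collapse_unique_phosphopeptides(psms)
  tab <- peptide_quant_table(col$peptides, psms, q$normalized, ch,
                             list(c("DN", "DM")))
  sums <- colSums(tab[, paste0("sum_", ch$labels)])
  expect_equal(unname(sums), unname(rowSums(q$normalized)),
               tolerance = 1e-12)
  expect_identical(sum(tab$n_scans), 30L)
})
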