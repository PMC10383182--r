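test_that("FDR filter handles pure-target and pure-decoy inputs", {
  tgt <- do.call(rbind, lapply(1:20, function(i)
    make_psm(paste0("s", i), "SAMPLER", "1:S:phospho",
             score = 20 + i)))
  res <- filter_psms_by_fdr(tgt)
  expect_identical(nrow(res$psms), 20L)
  expect_equal(res$achieved_fdr, 0)

  dec <- tgt; dec$is_decoy <- TRUE
  res2 <- filter_psms_by_fdr(dec)
  expect_identical(nrow(res2$psms), 0L)
  expect_identical(res2$score_cutoff, Inf)
})

test_that("FDR filter never retains decoys and ignores non-rank-1 hits", {
  set.seed(33)
  n <- 300
  psms <- make_psm(paste0("s", 1:n), "SAMPLER", "1:S:phospho",
                   score = c(rnorm(270, 40, 8), rnorm(30, 20, 6)))
  psms$is_decoy <- rep(c(FALSE, TRUE), c(270, 30))
  r2 <- make_psm("s1", "SAMPLER", "3:S:phospho", score = 99, rank = 2L)
  res <- filter_psms_by_fdr(rbind(psms, r2))
  expect_false(any(res$psms$is_decoy))
  expect_false(any(res$psms$rank != 1L))
  expect_true(all(res$psms$score >= res$score_cutoff))
  expect_lte(res$achieved_fdr, 0.01)
})

test_that("FDR filter equals the brute-force cutoff scan on seeded instances", {
  set.seed(44)
  for (k in 1:60) {
    n_t <- sample(20:400, 1); n_d <- sample(5:80, 1)
    scores <- c(rnorm(n_t, 40, 8), rnorm(n_d, 20, 6))
    # occasional ties to exercise the tie rule
    if (k %% 5 == 0) scores <- round(scores)
    is_decoy <- rep(c(FALSE, TRUE), c(n_t, n_d))
    psms <- make_psm(paste0("s", seq_along(scores)), "SAMPLER",
                     "1:S:phospho", score = scores)
    psms$is_decoy <- is_decoy
    res <- filter_psms_by_fdr(psms, max_fdr = 0.01)
    oracle <- brute_force_fdr(scores, is_decoy, max_fdr = 0.01)
    expect_identical(res$score_cutoff, oracle$cutoff)
    expect_setequal(res$psms$spectrum_ref,
                    psms$spectrum_ref[oracle$retained])
  }
})

test_that("unique phosphopeptides merge positional isomers, split by count", {
  # same sequence, phospho at S3 vs S5, one phospho each -> counted once
  psms <- rbind(make_psm("s1", "AASASAK", "3:S:phospho"),
                make_psm("s2", "AASASAK", "5:S:phospho"))
  col <- collapse_unique_phosphopeptides(psms)
  expect_identical(nrow(col$peptides), 1L)
  expect_identical(col$peptides$n_psms, 2L)
  expect_identical(length(col$peptides$site_candidates[[1]]), 2L)

  # same sequence, 1 vs 2 phosphos -> enumerated separately
  psms2 <- rbind(make_psm("s1", "AASASAK", "3:S:phospho"),
                 make_psm("s2", "AASASAK", "3:S:phospho;5:S:phospho"))
  col2 <- collapse_unique_phosphopeptides(psms2)
  expect_identical(nrow(col2$peptides), 2L)
  expect_setequal(col2$peptides$phospho_count, c(1L, 2L))

  # empty input and non-phospho exclusion
  expect_identical(nrow(collapse_unique_phosphopeptides(
    make_psm("s1", "AASASAK", "3:S:phospho")[0, ])$peptides), 0L)
  mixed <- rbind(make_psm("s1", "AASASAK", "3:S:phospho"),
                 make_psm("s2", "SAMPLEK", ""))
  colm <- collapse_unique_phosphopeptides(mixed)
  expect_identical(colm$n_excluded_non_phospho, 1L)
})

test_that("collapsing is permutation-invariant and conserves members", {
  set.seed(55)
  seqs <- c("AASASAK", "TTVSYR", "SSSSK", "MTYSAK")
  psms <- do.call(rbind, lapply(1:80, function(i) {
    sq <- sample(seqs, 1)
    sty <- which(strsplit(sq, "")[[1]] %in% c("S", "T", "Y"))
    k <- sample(1:min(2, length(sty)), 1)
    pos <- sort(sty[sample.int(length(sty), k)])
    mods <- paste(sprintf("%d:%s:phospho", pos,
                          substring(sq, pos, pos)), collapse = ";")
    make_psm(paste0("s", i), sq, mods)
  }))
  a <- collapse_unique_phosphopeptides(psms)
  b <- collapse_unique_phosphopeptides(psms[sample(nrow(psms)), ])
  expect_identical(a$peptides$key, b$peptides$key)
  expect_identical(a$peptides$n_psms, b$peptides$n_psms)
  expect_identical(sum(a$peptides$n_psms), nrow(psms))
  # idempotence of the keying: collapsing members again changes nothing
  expect_identical(
    collapse_unique_phosphopeptides(psms)$peptides$key, a$peptides$key)
})

test_that("residue distribution reproduces printed-precision percentages", {
  rd <- residue_distribution(c(S = 179, T = 101, Y = 12))
  expect_identical(rd$n_sites, 292)
  expect_equal(unname(rd$percent), c(61.3, 34.6, 4.11))
  expect_lt(abs(sum(rd$percent) - 100), 0.1)

  single <- residue_distribution(c(S = 1, T = 0, Y = 0))
  expect_equal(unname(single$percent), c(100, 0, 0))
})

test_that("group overlap partitions proteins and rounds the all-group share", {
  presence <- c(
    replicate(31, c("NC", "DM", "DN"), simplify = FALSE),
    replicate(100, c("DN"), simplify = FALSE),
    replicate(50, c("DM", "DN"), simplify = FALSE),
    replicate(33, c("NC"), simplify = FALSE))
  names(presence) <- sprintf("P%03d", seq_along(presence))
  ov <- group_overlap(presence)
  expect_identical(ov$n_proteins, 214L)
  expect_identical(sum(ov$overlap), 214L)
  expect_equal(ov$percent_all_groups, 14.49)
})

test_that("identification summary ties sites, residues and proteins together", {
  psms <- rbind(make_psm("s1", "AASASAK", "3:S:phospho", accessions = "P1"),
                make_psm("s2", "TTVSYR", "5:Y:phospho", accessions = "P2"),
                make_psm("s3", "MTYSAK", "2:T:phospho", accessions = "P2"))
  col <- collapse_unique_phosphopeptides(psms)
  loc <- localize_peptides(col$peptides, psms)
  pm <- c("AASASAK/1" = "P1", "TTVSYR/1" = "P2", "MTYSAK/1" = "P2")
  presence <- list(P1 = c("NC", "DM", "DN"), P2 = c("DM", "DN"))
  s <- summarize_identifications(col$peptides, loc, pm, presence,
                                 n_proteins = 10L)
  expect_identical(s$n_phosphopeptides, 3L)
  expect_identical(s$n_phosphoproteins, 2L)
  expect_identical(s$n_sites, 3L)
  expect_identical(unname(s$residue_counts), c(1L, 1L, 1L))
  expect_equal(s$percent_all_groups, 50)
  expect_output(print(s), "phosphopeptides:  3")
})
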