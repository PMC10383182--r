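test_that("MGF reading handles empty files and counts blocks faithfully", {
  f <- withr::local_tempfile(fileext = ".mgf")
  writeLines(character(), f)
  expect_length(read_mgf(f), 0L)

  writeLines(c("BEGIN IONS", "TITLE=a", "PEPMASS=500.25", "CHARGE=2+",
               "100.1 10", "200.2 20", "300.3 30", "END IONS",
               "BEGIN IONS", "TITLE=b", "PEPMASS=600.5 1234", "CHARGE=3+",
               "150.5 5", "END IONS"), f)
  sp <- read_mgf(f)
  expect_length(sp, 2L)
  expect_identical(vapply(sp, function(s) nrow(s$peaks), 0L), c(3L, 1L))
  expect_equal(sp[[2]]$precursor_mz, 600.5)  # first PEPMASS token only
  expect_identical(sp[[2]]$charge, 3L)
})

test_that("MGF round-trip is lossless within numeric formatting tolerance", {
  set.seed(101)
  spectra <- lapply(1:50, function(i)
    random_spectrum(sprintf("rt%03d", i), n_peaks = sample(3:30, 1)))
  f <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(spectra, f)
  back <- read_mgf(f)
  expect_length(back, 50L)
  for (i in 1:50) {
    expect_identical(back[[i]]$scan_id, spectra[[i]]$scan_id)
    expect_identical(back[[i]]$charge, spectra[[i]]$charge)
    expect_equal(back[[i]]$peaks, spectra[[i]]$peaks, tolerance = 1e-6)
  }
})

test_that("MGF parse errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=500", "100.1 abc", "END IONS"), f)
  expect_error(read_mgf(f), "line 3")
  writeLines(c("BEGIN IONS", "PEPMASS=500", "100.1 5"), f)
  expect_error(read_mgf(f), "unterminated")
  expect_error(read_mgf(file.path(tempdir(), "nope.mgf")), "no such file")
})

test_that("FASTA reading flags decoys and uppercases sequences", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P001 some protein", "mksalt", ">REV_P001 reversed",
               "TLASKM"), f)
  rec <- read_fasta(f)
  expect_identical(rec$is_decoy, c(FALSE, TRUE))
  expect_identical(rec$sequence[1], "MKSALT")
  expect_identical(rec$accession, c("P001", "REV_P001"))
})

test_that("FASTA round-trip preserves 100 seeded records", {
  set.seed(202)
  prot <- data.frame(
    accession = sprintf("ACC%03d", 1:100),
    description = paste("protein", 1:100),
    sequence = vapply(sample(50:400, 100, TRUE), random_protein_seq, ""),
    is_decoy = FALSE, stringsAsFactors = FALSE)
  prot$accession[51:100] <- paste0("REV_", prot$accession[51:100])
  prot$is_decoy[51:100] <- TRUE
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(prot, f)
  expect_identical(read_fasta(f), prot)
})

test_that("purity matrix validation enforces shape, sign and invertibility", {
  expect_s3_class(validate_purity_matrix(diag(4)), "purity_matrix")
  bad <- diag(4); bad[2, 1] <- -0.01
  expect_error(validate_purity_matrix(bad), "negative")
  expect_error(validate_purity_matrix(diag(3)), "4x4")
  expect_error(validate_purity_matrix(matrix(0.25, 4, 4)), "singular")

  f <- withr::local_tempfile(fileext = ".csv")
  write_purity_matrix(validate_purity_matrix(diag(4)), f)
  expect_equal(unclass(read_purity_matrix(f)), diag(4),
               ignore_attr = TRUE)

  # column-stochastic 2% neighbour bleed: accepted, determinant far from 0
  m <- diag(4) * 0.96
  for (j in 1:4) for (i in c(j - 1, j + 1)) {
    if (i >= 1 && i <= 4) m[i, j] <- 0.02
  }
  m[1, 1] <- 0.98; m[4, 4] <- 0.98
  pm <- validate_purity_matrix(m)
  expect_true(abs(det(unclass(pm))) > 0.8)
  write_purity_matrix(pm, f)
  expect_equal(unclass(read_purity_matrix(f)), m, ignore_attr = TRUE)
})

test_that("default purity matrix is column-substochastic and invertible", {
  m <- default_purity_matrix()
  expect_true(all(colSums(unclass(m)) <= 1 + 1e-9))
  expect_true(all(diag(unclass(m)) > 0.9))
})

test_that("PSM tables round-trip and enforce their invariants", {
  psms <- rbind(
    make_psm("s1", "SAMPLER", "1:S:phospho", score = 41.2),
    make_psm("s2", "TESTING", "4:T:phospho", score = 33.0, charge = 3L),
    make_psm("s2", "TESTING", "3:S:phospho", score = 30.0, rank = 2L,
             charge = 3L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(psms, f)
  back <- read_psm_table(f)
  expect_equal(back, psms, ignore_attr = TRUE)

  dup <- rbind(make_psm("s1", "SAMPLER", "1:S:phospho"),
               make_psm("s1", "AAASSSK", "4:S:phospho"))
  expect_error(validate_psm_table(dup), "rank-1")
  oob <- make_psm("s1", "SAMPLER", "9:S:phospho")
  expect_error(validate_psm_table(oob), "outside peptide")
  sp <- list(spectrum("s1", precursor_mz = 500, charge = 2))
  expect_error(validate_psm_table(make_psm("sX", "SAMPLER", "1:S:phospho"),
                                  sp), "unresolved")
})

test_that("config files load from YAML and JSON", {
  fy <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("max_fdr: 0.01", "md_cutoff: 10"), fy)
  expect_equal(read_config(fy)$md_cutoff, 10)
  fj <- withr::local_tempfile(fileext = ".json")
  writeLines('{"max_fdr": 0.01, "alpha": 0.05}', fj)
  expect_equal(read_config(fj)$alpha, 0.05)
})
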