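test_that("tryptic digestion follows the K/R-not-before-P rule", {
  # K followed by P: no cleavage
  expect_identical(digest_protein("AAKPGG", missed_cleavages = 0,
                                  min_len = 1), "AAKPGG")
  expect_identical(digest_protein("AAAKGGGR", missed_cleavages = 0,
                                  min_len = 1), c("AAAK", "GGGR"))
  # missed cleavages enumerate joined fragments
  expect_setequal(digest_protein("AAAKGGGR", missed_cleavages = 1,
                                 min_len = 1),
                  c("AAAK", "GGGR", "AAAKGGGR"))
  expect_error(digest_protein(""), "empty")
})

test_that("digestion equals the exhaustive substring-scan oracle", {
  set.seed(7)
  for (k in 1:50) {
    seq <- random_protein_seq(sample(30:120, 1))
    mc <- sample(0:2, 1)
    got <- digest_protein(seq, missed_cleavages = mc, min_len = 6,
                          max_len = 40)
    want <- brute_force_digest(seq, mc = mc, min_len = 6, max_len = 40)
    expect_setequal(got, want)
  }
})

test_that("experiment generation is deterministic given the seed", {
  cfg <- sim_config(seed = 9, n_proteins = 20, n_phosphopeptides = 120,
                    n_regulated = 8)
  a <- generate_experiment(cfg)
  b <- generate_experiment(cfg)
  expect_identical(a$psms, b$psms)
  expect_identical(a$ground_truth$peptides, b$ground_truth$peptides)
  expect_identical(a$reference_totals, b$reference_totals)

  # on-disk artifacts are byte-identical across reruns
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_experiment(cfg, out_dir = d1)
  generate_experiment(cfg, out_dir = d2)
  for (fn in c("experiment.mgf", "psms.tsv", "purity.csv",
               "database.fasta", "ground_truth.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, fn))),
                     unname(tools::md5sum(file.path(d2, fn))), info = fn)
  }
})

test_that("config validation rejects infeasible designs", {
  expect_error(sim_config(seed = 1, n_phosphopeptides = 10,
                          n_regulated = 20), "exceeds")
  expect_error(sim_config(seed = 1, decoy_fraction = 1.5), "fractions")
  expect_error(sim_config(), "seed")
  cfg0 <- sim_config(seed = 2, n_proteins = 20, n_phosphopeptides = 100,
                     n_regulated = 0)
  expect_identical(nrow(generate_experiment(cfg0)$ground_truth$regulated), 0L)
})

test_that("generated artifacts satisfy the formats module's invariants", {
  cfg <- sim_config(seed = 10, n_proteins = 20, n_phosphopeptides = 100,
                    n_regulated = 5)
  d <- withr::local_tempdir()
  exp <- generate_experiment(cfg, out_dir = d)
  spectra <- read_mgf(file.path(d, "experiment.mgf"))
  expect_length(spectra, length(exp$spectra))
  psms <- read_psm_table(file.path(d, "psms.tsv"), spectra = spectra)
  expect_identical(nrow(psms), nrow(exp$psms))
  fasta <- read_fasta(file.path(d, "database.fasta"))
  expect_identical(sum(fasta$is_decoy), sum(!fasta$is_decoy))
  expect_s3_class(read_purity_matrix(file.path(d, "purity.csv")),
                  "purity_matrix")
  # every PSM's precursor matches its spectrum within tolerance
  ids <- vapply(spectra, function(s) s$scan_id, "")
  r1 <- which(psms$rank == 1L)[1:25]
  for (i in r1) {
    sp <- spectra[[match(psms$spectrum_ref[i], ids)]]
    expect_true(validate_precursor(psms$sequence[i], psms$modifications[i],
                                   sp$precursor_mz, psms$charge[i])$mass_ok)
  }
})

test_that("realized decoy fraction tracks the configured rate", {
  cfg <- sim_config(seed = 12, n_proteins = 40, n_phosphopeptides = 400,
                    n_regulated = 10, decoy_fraction = 0.1)
  exp <- generate_experiment(cfg)
  r1 <- exp$psms[exp$psms$rank == 1L, ]
  expect_lt(abs(mean(r1$is_decoy) - 0.1), 0.02)
})

test_that("noise-free identity: pipeline ratios equal the planted fold", {
  cfg <- sim_config(seed = 13, n_proteins = 30, n_phosphopeptides = 150,
                    n_regulated = 10, noise_cv = 0,
                    purity = validate_purity_matrix(diag(4)))
  exp <- generate_experiment(cfg)
  # noise-free null ratios are exactly 0, so the spread floor warning fires
  run <- suppressWarnings(
    run_pipeline(exp$psms, exp$spectra, exp$purity, pipeline_config(),
                 reference_totals = exp$reference_totals))
  dt <- run$differential[["DN/DM"]]
  gt <- exp$ground_truth
  m <- merge(gt$regulated, dt, by = "key")
  expect_gt(nrow(m), 0)
  expect_equal(m$fold_change,
               ifelse(m$direction == "up", cfg$true_fold,
                      1 / cfg$true_fold),
               tolerance = 1e-9)
  # unregulated peptides sit exactly at ratio 1
  un <- dt$fold_change[!dt$key %in% gt$regulated$key]
  expect_equal(un, rep(1, length(un)), tolerance = 1e-9)
})
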