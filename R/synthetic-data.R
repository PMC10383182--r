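# Seeded synthetic 4-plex phosphoproteomics experiment generator.
#
# Emulates the study design every stage of the pipeline needs to see:
# three groups (NC / DM / DN) plus a pooled reference on the four iTRAQ
# channels, tryptic phosphopeptides observed over 1-3 MS/MS scans, planted
# fold changes on a regulated subset (DN vs DM), multiplicative log-normal
# reporter noise, impurity bleed through the purity matrix, reversed-decoy
# PSMs with a lower score distribution, and positional-isomer competitor
# hits with configured score gaps for the localization stage.

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P, allows
#' up to `missed_cleavages` missed sites, and length-filters the products.
#'
#' @param sequence protein sequence (canonical uppercase letters).
#' @param missed_cleavages maximum missed cleavage sites (default 2).
#' @param min_len,max_len peptide length bounds (default 6 and 40).
#' @return character vector of peptides (in N-to-C order of their start,
#'   then by length).
#' @examples
#' digest_protein("AAAKGGGR", missed_cleavages = 0, min_len = 1)
#' @export
digest_protein <- function(sequence, missed_cleavages = 2L,
                           min_len = 6L, max_len = 40L) {
  if (!nzchar(sequence)) stop("empty protein sequence")
  ch <- strsplit(sequence, "")[[1L]]
  n <- length(ch)
  # cleavage after position i: K/R at i, not followed by P
  cut_after <- which(ch %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | ch[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after)
  if (bounds[length(bounds)] != n) bounds <- c(bounds, n)
  nb <- length(bounds)
  out <- character()
  for (a in seq_len(nb - 1L)) {
    for (b in (a + 1L):min(a + 1L + missed_cleavages, nb)) {
      pep <- substr(sequence, bounds[a] + 1L, bounds[b])
      if (nchar(pep) >= min_len && nchar(pep) <= max_len) {
        out <- c(out, pep)
      }
    }
  }
  out
}

#' Synthetic experiment configuration
#'
#' Defaults describe the emulated study conditions: 2,000 unique
#' phosphopeptides, 50 regulated at 2-fold between DN and DM (half up,
#' half down), 10% reporter noise CV, 10% decoy PSMs, channel map
#' 114=NC, 115=DM, 116=DN, 117=pooled reference.
#'
#' @param seed mandatory integer seed; all randomness flows from it.
#' @param n_proteins number of synthetic proteins to draw peptides from.
#' @param n_phosphopeptides number of unique phosphopeptides.
#' @param n_regulated number of regulated peptides (DN vs DM).
#' @param true_fold linear fold change planted on regulated peptides.
#' @param noise_cv coefficient of variation of multiplicative log-normal
#'   reporter noise (0 = noise-free).
#' @param decoy_fraction fraction of rank-1 PSMs that are decoys.
#' @param isomer_fraction fraction of eligible peptides given a
#'   positional-isomer competitor hit at rank 2.
#' @param gap_mean,gap_sd normal parameters of the competitor score gap
#'   (truncated at 0).
#' @param target_score,decoy_score `c(mean, sd)` of the target and decoy
#'   Mascot-like score distributions (truncated at 0).
#' @param purity purity matrix used to mix reporter signal.
#' @param group_map channel-to-group assignment.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(seed,
                       n_proteins = 150L,
                       n_phosphopeptides = 2000L,
                       n_regulated = 50L,
                       true_fold = 2,
                       noise_cv = 0.1,
                       decoy_fraction = 0.1,
                       isomer_fraction = 0.3,
                       gap_mean = 15, gap_sd = 5,
                       target_score = c(40, 8),
                       decoy_score = c(20, 6),
                       purity = default_purity_matrix(),
                       group_map = c("114" = "NC", "115" = "DM",
                                     "116" = "DN", "117" = "reference")) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  fr <- c(noise_cv = noise_cv, decoy_fraction = decoy_fraction,
          isomer_fraction = isomer_fraction)
  if (any(fr < 0) || any(fr[-1] > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  if (n_regulated > n_phosphopeptides) {
    stop("n_regulated exceeds n_phosphopeptides")
  }
  if (true_fold <= 0) stop("true_fold must be > 0")
  structure(list(seed = as.integer(seed), n_proteins = n_proteins,
                 n_phosphopeptides = n_phosphopeptides,
                 n_regulated = n_regulated, true_fold = true_fold,
                 noise_cv = noise_cv, decoy_fraction = decoy_fraction,
                 isomer_fraction = isomer_fraction,
                 gap_mean = gap_mean, gap_sd = gap_sd,
                 target_score = target_score, decoy_score = decoy_score,
                 purity = validate_purity_matrix(purity),
                 group_map = group_map),
            class = "sim_config")
}

# residue alphabet with roughly proteome-like frequencies (K/R enriched
# enough to give tryptic peptides of useful length; S/T/Y common enough
# that most peptides carry a candidate phosphosite)
.residue_freq <- c(
  A = 8, C = 1.5, D = 5.5, E = 6.5, F = 4, G = 7, H = 2.5, I = 5.5,
  K = 6, L = 9, M = 2.5, N = 4, P = 4, Q = 4, R = 5.5, S = 7.5,
  T = 5.5, V = 6.5, W = 1, Y = 3.5)

.random_protein <- function(len) {
  paste(sample(names(.residue_freq), len, replace = TRUE,
               prob = .residue_freq), collapse = "")
}

# fixed-modification string for a peptide: N-term iTRAQ, iTRAQ on K,
# carbamidomethyl on C, plus phospho at the given positions
.build_mods <- function(sequence, phospho_at) {
  ch <- strsplit(sequence, "")[[1L]]
  toks <- "0:N-term:itraq4plex"
  for (p in which(ch == "K")) toks <- c(toks, sprintf("%d:K:itraq4plex", p))
  for (p in which(ch == "C")) {
    toks <- c(toks, sprintf("%d:C:carbamidomethyl", p))
  }
  for (p in sort(phospho_at)) {
    toks <- c(toks, sprintf("%d:%s:phospho", p, ch[p]))
  }
  paste(toks, collapse = ";")
}

.sty_positions <- function(sequence) {
  which(strsplit(sequence, "")[[1L]] %in% c("S", "T", "Y"))
}

#' Generate a complete synthetic 4-plex experiment
#'
#' Deterministic given the config seed.  Returns the experiment in memory
#' and optionally writes the on-disk artifact set (MGF, PSM TSV, purity
#' CSV, FASTA, ground-truth JSON) that [read_mgf()] and friends consume.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory to write MGF/TSV/CSV/FASTA/JSON
#'   files into.
#' @return list with `spectra`, `psms`, `purity`, `proteins` (FASTA
#'   data.frame incl. reversed decoys), `reference_totals`, `channels`,
#'   and `ground_truth` (peptide truth table, regulated set, decoy scan
#'   ids, isomer gaps, group map).
#' @export
generate_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  channels <- itraq4_channels(config$group_map)
  dn_ch <- group_channels(channels, "DN")

  # --- proteins and candidate tryptic phosphopeptides -----------------------
  prot_len <- sample(200:500, config$n_proteins, replace = TRUE)
  prot_seq <- vapply(prot_len, .random_protein, "")
  prot_acc <- sprintf("SYN%04d", seq_len(config$n_proteins))
  cand <- list(); cand_acc <- character()
  for (i in seq_len(config$n_proteins)) {
    peps <- digest_protein(prot_seq[i], missed_cleavages = 0L)
    peps <- peps[vapply(peps, function(p) length(.sty_positions(p)) > 0, TRUE)]
    cand <- c(cand, as.list(peps))
    cand_acc <- c(cand_acc, rep(prot_acc[i], length(peps)))
  }
  cand <- unlist(cand)
  keep <- !duplicated(cand)
  cand <- cand[keep]; cand_acc <- cand_acc[keep]
  if (length(cand) < config$n_phosphopeptides) {
    stop("only ", length(cand), " candidate phosphopeptides from ",
         config$n_proteins, " proteins; increase n_proteins")
  }
  sel <- seq_len(config$n_phosphopeptides)
  pep_seq <- cand[sel]; pep_acc <- cand_acc[sel]
  n_pep <- length(pep_seq)

  sty <- lapply(pep_seq, .sty_positions)
  n_sty <- lengths(sty)
  phospho_count <- ifelse(n_sty >= 2L & stats::runif(n_pep) < 0.15, 2L, 1L)
  true_sites <- mapply(function(pos, k)
    sort(pos[sample.int(length(pos), k)]),
    sty, phospho_count, SIMPLIFY = FALSE)

  # --- regulation and true abundances ---------------------------------------
  regulated_idx <- if (config$n_regulated > 0) {
    sort(sample.int(n_pep, config$n_regulated))
  } else integer()
  direction <- rep(NA_character_, n_pep)
  if (length(regulated_idx)) {
    half <- ceiling(length(regulated_idx) / 2)
    direction[regulated_idx] <-
      c(rep("up", half),
        rep("down", length(regulated_idx) - half))[
          sample.int(length(regulated_idx))]
  }
  base_abund <- stats::rlnorm(n_pep, meanlog = log(1e4), sdlog = 0.5)
  truth <- matrix(rep(base_abund, each = 4L), nrow = 4L)
  up <- which(direction == "up"); down <- which(direction == "down")
  truth[dn_ch, up] <- truth[dn_ch, up] * config$true_fold
  truth[dn_ch, down] <- truth[dn_ch, down] / config$true_fold

  # --- scans ----------------------------------------------------------------
  scans_per_pep <- sample(1:3, n_pep, replace = TRUE)
  pep_of_scan <- rep(seq_len(n_pep), scans_per_pep)
  n_scan <- length(pep_of_scan)
  mixed <- unclass(config$purity) %*% truth
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  noise <- if (sdlog > 0) {
    exp(matrix(stats::rnorm(4L * n_scan, -sdlog^2 / 2, sdlog), nrow = 4L))
  } else matrix(1, 4L, n_scan)
  reporter <- mixed[, pep_of_scan, drop = FALSE] * noise

  scan_id <- sprintf("scan%06d", seq_len(n_scan))
  charge <- sample(2:4, n_scan, replace = TRUE, prob = c(0.5, 0.35, 0.15))
  mods_str <- mapply(.build_mods, pep_seq, true_sites, USE.NAMES = FALSE)
  pep_mass <- vapply(seq_len(n_pep), function(i)
    compute_peptide_mass(pep_seq[i], mods_str[i]), 0)
  prec_mz <- (pep_mass[pep_of_scan] + charge * mass_proton) / charge

  make_spectrum <- function(sid, pm, z, rep_int) {
    n_frag <- 6L
    frag_mz <- sort(stats::runif(n_frag, 200, 1300))
    frag_int <- stats::runif(n_frag, 50, 5000)
    spectrum(scan_id = sid, title = sid, precursor_mz = pm, charge = z,
             mz = c(channels$masses, frag_mz),
             intensity = c(rep_int, frag_int))
  }
  spectra <- vector("list", n_scan)
  for (s in seq_len(n_scan)) {
    spectra[[s]] <- make_spectrum(scan_id[s], prec_mz[s], charge[s],
                                  reporter[, s])
  }

  # --- target rank-1 PSMs ---------------------------------------------------
  score1 <- pmax(stats::rnorm(n_scan, config$target_score[1],
                              config$target_score[2]), 0)
  psms <- data.frame(
    spectrum_ref = scan_id,
    sequence = pep_seq[pep_of_scan],
    modifications = mods_str[pep_of_scan],
    score = score1, rank = 1L, is_decoy = FALSE,
    accessions = pep_acc[pep_of_scan],
    charge = charge, stringsAsFactors = FALSE)

  # --- positional-isomer competitor hits (rank 2) ---------------------------
  eligible <- which(n_sty > phospho_count)
  n_isomer <- round(config$isomer_fraction * length(eligible))
  isomer_pep <- sort(sample(eligible, n_isomer))
  isomer_rows <- list(); gaps <- numeric(0)
  first_scan_of_pep <- match(seq_len(n_pep), pep_of_scan)
  for (i in isomer_pep) {
    alt_pool <- setdiff(sty[[i]], true_sites[[i]])
    swap_out <- true_sites[[i]][sample.int(length(true_sites[[i]]), 1L)]
    alt_sites <- sort(c(setdiff(true_sites[[i]], swap_out),
                        alt_pool[sample.int(length(alt_pool), 1L)]))
    s <- first_scan_of_pep[i]
    gap <- max(stats::rnorm(1, config$gap_mean, config$gap_sd), 0)
    gaps <- c(gaps, gap)
    isomer_rows[[length(isomer_rows) + 1L]] <- data.frame(
      spectrum_ref = scan_id[s], sequence = pep_seq[i],
      modifications = .build_mods(pep_seq[i], alt_sites),
      score = max(score1[s] - gap, 0), rank = 2L, is_decoy = FALSE,
      accessions = pep_acc[i], charge = charge[s],
      stringsAsFactors = FALSE)
  }

  # --- decoy PSMs (reversed sequences, lower score distribution) ------------
  n_decoy <- round(config$decoy_fraction / (1 - config$decoy_fraction) *
                     n_scan)
  decoy_rows <- NULL; decoy_spectra <- list(); decoy_scan_ids <- character()
  if (n_decoy > 0) {
    src <- sample.int(n_pep, n_decoy, replace = TRUE)
    decoy_scan_ids <- sprintf("decoy%06d", seq_len(n_decoy))
    dseq <- vapply(strsplit(pep_seq[src], ""), function(chv)
      paste(rev(chv), collapse = ""), "")
    dz <- sample(2:4, n_decoy, replace = TRUE, prob = c(0.5, 0.35, 0.15))
    dmods <- character(n_decoy); dmz <- numeric(n_decoy)
    for (k in seq_len(n_decoy)) {
      dsty <- .sty_positions(dseq[k])
      dsite <- dsty[sample.int(length(dsty), 1L)]
      dmods[k] <- .build_mods(dseq[k], dsite)
      dmz[k] <- (compute_peptide_mass(dseq[k], dmods[k]) +
                   dz[k] * mass_proton) / dz[k]
    }
    dint <- mixed[, src, drop = FALSE] *
      (if (sdlog > 0)
         exp(matrix(stats::rnorm(4L * n_decoy, -sdlog^2 / 2, sdlog),
                    nrow = 4L))
       else 1)
    for (k in seq_len(n_decoy)) {
      decoy_spectra[[k]] <- make_spectrum(decoy_scan_ids[k], dmz[k], dz[k],
                                          dint[, k])
    }
    decoy_rows <- data.frame(
      spectrum_ref = decoy_scan_ids, sequence = dseq,
      modifications = dmods,
      score = pmax(stats::rnorm(n_decoy, config$decoy_score[1],
                                config$decoy_score[2]), 0),
      rank = 1L, is_decoy = TRUE,
      accessions = paste0("REV_", pep_acc[src]), charge = dz,
      stringsAsFactors = FALSE)
  }

  psms <- rbind(psms, do.call(rbind, isomer_rows), decoy_rows)
  spectra <- c(spectra, decoy_spectra)

  # --- reference run (pooled supernatant analog): equal channel truth -------
  ref_truth <- rep(sum(base_abund), 4L)
  ref_noise <- if (sdlog > 0)
    exp(stats::rnorm(4L, -sdlog^2 / 2, sdlog)) else rep(1, 4L)
  reference_totals <- as.numeric(unclass(config$purity) %*%
                                   (ref_truth * ref_noise))

  proteins <- data.frame(
    accession = c(prot_acc, paste0("REV_", prot_acc)),
    description = c(rep("synthetic protein", config$n_proteins),
                    rep("reversed decoy", config$n_proteins)),
    sequence = c(prot_seq,
                 vapply(strsplit(prot_seq, ""), function(chv)
                   paste(rev(chv), collapse = ""), "")),
    is_decoy = rep(c(FALSE, TRUE), each = config$n_proteins),
    stringsAsFactors = FALSE)

  key <- paste0(pep_seq, "/", phospho_count)
  ground_truth <- list(
    peptides = data.frame(
      key = key, sequence = pep_seq, phospho_count = phospho_count,
      true_sites = I(true_sites), accession = pep_acc,
      base_abundance = base_abund, n_scans = scans_per_pep,
      regulated = !is.na(direction), direction = direction,
      stringsAsFactors = FALSE),
    truth_channel_abundance = truth,
    regulated = data.frame(key = key[regulated_idx],
                           direction = direction[regulated_idx],
                           stringsAsFactors = FALSE),
    decoy_scan_ids = decoy_scan_ids,
    isomers = data.frame(key = key[isomer_pep], gap = gaps,
                         stringsAsFactors = FALSE),
    group_map = config$group_map,
    reference_totals = reference_totals,
    seed = config$seed)

  out <- list(spectra = spectra, psms = psms, purity = config$purity,
              proteins = proteins, reference_totals = reference_totals,
              channels = channels, ground_truth = ground_truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_mgf(spectra, file.path(out_dir, "experiment.mgf"))
    write_psm_table(psms, file.path(out_dir, "psms.tsv"))
    write_purity_matrix(config$purity, file.path(out_dir, "purity.csv"))
    write_fasta(proteins, file.path(out_dir, "database.fasta"))
    gt <- ground_truth
    gt$peptides$true_sites <- lapply(gt$peptides$true_sites, as.integer)
    gt$truth_channel_abundance <- NULL
    jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(reference_totals = reference_totals),
                         file.path(out_dir, "reference_totals.json"),
                         auto_unbox = FALSE, digits = NA)
  }
  out
}
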