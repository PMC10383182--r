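# End-to-end orchestration: validate -> charge filter -> FDR filter ->
# collapse -> localize -> extract/correct/normalize -> aggregate ->
# error model -> differential calls -> summaries.

#' Pipeline configuration
#'
#' Thresholds default to the workflow's standard settings: 0.6 Da precursor
#' and 0.1 Da fragment tolerance, charge states 2+ to 4+, 1% PSM FDR,
#' MD-score cutoff 10, fold-change threshold 1.5 at alpha 0.05, comparisons
#' DN/DM, DN/NC and DM/NC.
#'
#' @param precursor_tol precursor mass tolerance (Da).
#' @param fragment_tol fragment/reporter tolerance (Da).
#' @param charge_range inclusive precursor charge bounds.
#' @param max_fdr PSM-level target-decoy FDR bound.
#' @param md_cutoff MD-score localization cutoff.
#' @param fold_threshold minimal linear fold change.
#' @param alpha p-value threshold.
#' @param adjust p-value adjustment method (`"none"` or `"BH"`).
#' @param group_map channel-to-group assignment.
#' @param comparisons list of `c(numerator, denominator)` group pairs.
#' @param seed optional seed recorded in the run manifest.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(precursor_tol = 0.6, fragment_tol = 0.1,
                            charge_range = c(2, 4), max_fdr = 0.01,
                            md_cutoff = 10, fold_threshold = 1.5,
                            alpha = 0.05, adjust = "none",
                            group_map = c("114" = "NC", "115" = "DM",
                                          "116" = "DN", "117" = "reference"),
                            comparisons = list(c("DN", "DM"), c("DN", "NC"),
                                               c("DM", "NC")),
                            seed = NA_integer_) {
  thresholds <- c(precursor_tol, fragment_tol, max_fdr, md_cutoff,
                  fold_threshold, alpha)
  if (any(thresholds <= 0)) stop("all thresholds must be positive")
  groups <- unique(unname(group_map))
  for (cmp in comparisons) {
    if (!all(cmp %in% groups)) {
      stop("comparison references undefined group: ",
           paste(cmp, collapse = "/"))
    }
  }
  structure(list(precursor_tol = precursor_tol, fragment_tol = fragment_tol,
                 charge_range = charge_range, max_fdr = max_fdr,
                 md_cutoff = md_cutoff, fold_threshold = fold_threshold,
                 alpha = alpha, adjust = adjust, group_map = group_map,
                 comparisons = comparisons, seed = seed),
            class = "pipeline_config")
}

#' Run the full quantitative phosphoproteomics pipeline
#'
#' @param psms PSM data.frame (all ranks; see [read_psm_table()]).
#' @param spectra list of [spectrum()] objects covering the PSMs'
#'   spectrum references.
#' @param purity validated purity matrix.
#' @param config a [pipeline_config()].
#' @param reference_totals optional 4-vector of reference-run channel
#'   totals for normalization; when NULL, factors are computed from the
#'   phosphopeptide data itself (documented fallback).
#' @param presence optional named list protein -> observed groups for the
#'   identification summary's group overlap.
#' @param n_proteins optional total protein count for the summary.
#' @return object of class `"phospipe_run"` with elements `ident_summary`,
#'   `localization`, `peptide_quant`, `differential` (one data.frame per
#'   comparison), `diff_summary`, `error_models`, `counts` (records
#'   in/out of each stage), `config`, `normalization`.
#' @export
run_pipeline <- function(psms, spectra, purity, config = pipeline_config(),
                         reference_totals = NULL, presence = NULL,
                         n_proteins = NA_integer_) {
  stopifnot(inherits(config, "pipeline_config"))
  channels <- itraq4_channels(config$group_map)
  counts <- list(psms_in = nrow(psms))
  spec_index <- stats::setNames(seq_along(spectra),
                                vapply(spectra, function(s) s$scan_id, ""))

  # stage: precursor validation (mass bookkeeping against spectra);
  # theoretical masses cached per unique (sequence, modifications) pair
  r1 <- psms$rank == 1L
  pep_id <- paste(psms$sequence, psms$modifications, sep = "\r")
  uniq <- !duplicated(pep_id)
  theo_u <- vapply(which(uniq), function(i)
    compute_peptide_mass(psms$sequence[i], psms$modifications[i]), 0)
  theo <- theo_u[match(pep_id, pep_id[uniq])]
  si <- spec_index[psms$spectrum_ref]
  if (anyNA(si[r1])) {
    stop("stage validate: unresolved spectrum ref ",
         psms$spectrum_ref[r1][is.na(si[r1])][1L])
  }
  obs_mz <- vapply(seq_len(nrow(psms)), function(i)
    if (is.na(si[i])) NA_real_ else spectra[[si[i]]]$precursor_mz, 0)
  err <- (obs_mz - mass_proton) * psms$charge - theo
  valid <- !r1 | (!is.na(err) & abs(err) <= config$precursor_tol)
  counts$precursor_valid <- sum(valid & r1)

  # stage: charge filter (acquisition range), then FDR filter
  work <- filter_charge(psms[valid | !r1, , drop = FALSE],
                        config$charge_range)
  counts$after_charge_filter <- sum(work$rank == 1L)
  fdr <- filter_psms_by_fdr(work, max_fdr = config$max_fdr)
  counts$after_fdr <- nrow(fdr$psms)
  retained <- fdr$psms

  # stage: collapse to unique phosphopeptides
  col <- collapse_unique_phosphopeptides(retained)
  peptides <- col$peptides
  counts$unique_phosphopeptides <- nrow(peptides)
  counts$non_phospho_excluded <- col$n_excluded_non_phospho

  # stage: localization (candidates from all target PSMs incl. rank 2)
  localization <- localize_peptides(peptides, work,
                                    cutoff = config$md_cutoff)
  counts$localized_confident <-
    sum(localization$status %in% c("confident", "single_candidate"))

  # stage: reporter quantification
  used_scans <- unique(retained$spectrum_ref)
  scan_specs <- spectra[spec_index[used_scans]]
  norm <- if (!is.null(reference_totals)) {
    compute_normalization_factors(reference_totals, source = "reference_run")
  } else NULL
  q <- quantify_scans(scan_specs, purity, norm = norm, channels = channels,
                      tol = config$fragment_tol)
  if (is.null(norm)) {
    # fallback: normalize on the phosphopeptide data's own channel totals
    norm <- compute_normalization_factors(rowSums(q$corrected),
                                          source = "self")
    q$normalized <- apply_normalization(q$corrected, norm)
  }
  counts$scans_quantified <- ncol(q$normalized)
  counts$clamped_channels <- q$n_clamped

  # stage: aggregate (sum across scans, then ratio)
  quant <- peptide_quant_table(peptides, retained, q$normalized,
                               channels = channels,
                               comparisons = config$comparisons)

  # stage: error model + differential calls per comparison
  differential <- list(); error_models <- list()
  for (cmp in config$comparisons) {
    lbl <- paste0(cmp[1], "/", cmp[2])
    dt <- differential_table(quant, cmp, weights = quant$n_scans,
                             fold_threshold = config$fold_threshold,
                             alpha = config$alpha, adjust = config$adjust)
    differential[[lbl]] <- dt
    error_models[[lbl]] <- attr(dt, "model")
  }
  # member_rows index rows of `retained`; first accession wins
  protein_map <- stats::setNames(
    vapply(peptides$member_rows, function(rows)
      strsplit(retained$accessions[rows[1L]], ";")[[1L]][1L], ""),
    peptides$key)
  diff_summary <- summarize_differentials(
    do.call(rbind, differential), protein_map = protein_map)

  # stage: identification summary
  if (is.null(presence)) {
    # derive presence from nonzero summed group-channel intensities
    presence <- list()
    grp <- setdiff(unique(unname(config$group_map)), "reference")
    for (i in seq_len(nrow(quant))) {
      acc <- protein_map[[quant$key[i]]]
      sums <- unlist(quant[i, paste0("sum_", channels$labels)])
      seen <- grp[vapply(grp, function(g)
        sum(sums[group_channels(channels, g)]) > 0, TRUE)]
      presence[[acc]] <- union(presence[[acc]], seen)
    }
  }
  ident_summary <- summarize_identifications(
    peptides, localization, protein_map, presence = presence,
    n_proteins = n_proteins,
    groups = setdiff(unique(unname(config$group_map)), "reference"))

  structure(list(ident_summary = ident_summary,
                 localization = localization,
                 peptide_quant = quant,
                 differential = differential,
                 diff_summary = diff_summary,
                 error_models = error_models,
                 fdr = fdr[c("score_cutoff", "achieved_fdr")],
                 normalization = norm,
                 counts = counts,
                 config = config),
            class = "phospipe_run")
}

#' Run the pipeline from files on disk
#'
#' @param mgf,psm_table,purity_csv input paths.
#' @param config a [pipeline_config()].
#' @param reference_totals optional numeric 4-vector or path to a JSON
#'   file with a `reference_totals` element.
#' @param out_dir optional directory for result TSV/JSON tables.
#' @return a `"phospipe_run"` object (see [run_pipeline()]).
#' @export
run_pipeline_files <- function(mgf, psm_table, purity_csv,
                               config = pipeline_config(),
                               reference_totals = NULL, out_dir = NULL) {
  spectra <- read_mgf(mgf)
  psms <- read_psm_table(psm_table, spectra = spectra)
  purity <- read_purity_matrix(purity_csv)
  if (is.character(reference_totals)) {
    reference_totals <-
      as.numeric(jsonlite::read_json(reference_totals,
                                     simplifyVector = TRUE)$reference_totals)
  }
  run <- run_pipeline(psms, spectra, purity, config = config,
                      reference_totals = reference_totals)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_localization_table(run$localization,
                             file.path(out_dir, "localization.tsv"))
    utils::write.table(run$peptide_quant,
                       file.path(out_dir, "peptide_quant.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (lbl in names(run$differential)) {
      fn <- paste0("differential_", gsub("/", "_vs_", lbl), ".tsv")
      utils::write.table(run$differential[[lbl]], file.path(out_dir, fn),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      list(diff_summary = run$diff_summary,
           counts = run$counts,
           config = unclass(run$config)[
             c("max_fdr", "md_cutoff", "fold_threshold", "alpha")],
           seed = run$config$seed),
      file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE,
      digits = NA)
  }
  run
}

#' @export
print.phospipe_run <- function(x, ...) {
  cat("Quantitative phosphoproteomics run\n")
  cat(sprintf("  PSMs in: %d; after charge filter: %d; after %.1f%% FDR: %d (cutoff %.2f)\n",
              x$counts$psms_in, x$counts$after_charge_filter,
              100 * x$config$max_fdr, x$counts$after_fdr,
              x$fdr$score_cutoff))
  cat(sprintf("  unique phosphopeptides: %d (confidently localized: %d)\n",
              x$counts$unique_phosphopeptides, x$counts$localized_confident))
  print(x$ident_summary)
  cat("Differential phosphopeptides (fold >=",
      x$config$fold_threshold, ", p <", x$config$alpha, "):\n")
  print(x$diff_summary, row.names = FALSE)
  invisible(x)
}

#' @export
summary.phospipe_run <- function(object, ...) {
  print(object, ...)
  invisible(object)
}

#' Volcano plot of a comparison's differential results
#' @param x a `"phospipe_run"` object.
#' @param comparison comparison label (default the first configured).
#' @param ... passed to [graphics::plot()].
#' @export
plot.phospipe_run <- function(x, comparison = names(x$differential)[1],
                              ...) {
  dt <- x$differential[[comparison]]
  ok <- is.finite(dt$log2_ratio) & is.finite(dt$p_value)
  col <- ifelse(dt$status == "up", "red3",
                ifelse(dt$status == "down", "blue3", "grey60"))
  graphics::plot(dt$log2_ratio[ok], -log10(dt$p_value[ok]), col = col[ok],
                 pch = 16, cex = 0.6, xlab = "log2 fold change",
                 ylab = "-log10 p", main = paste("Volcano:", comparison),
                 ...)
  graphics::abline(h = -log10(x$config$alpha), lty = 2)
  graphics::abline(v = c(-1, 1) * log2(x$config$fold_threshold), lty = 2)
  invisible(x)
}

#' Bundled differential phosphopeptide example table
#'
#' A published DN-vs-DM differential phosphopeptide panel from a urinary
#' extracellular vesicle phosphoproteomics study, with each record tagged
#' by its direction of change, bundled as a worked example for the
#' summary/counting functions.
#'
#' @return data.frame with columns `gene`, `peptide`, `site`, `p_value`,
#'   `direction`.
#' @export
uev_dn_dm_differential <- function() {
  path <- system.file("extdata", "uev_dn_dm_differential.tsv",
                      package = "phospipe")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
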