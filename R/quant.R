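# 4-plex iTRAQ reporter quantification: reporter-ion extraction from the
# low-mass region of CAD MS/MS scans, isotope-impurity correction through
# the reagent purity matrix, channel normalization from reference-run
# totals, and sum-then-ratio aggregation to peptide-level fold changes.

#' 4-plex iTRAQ channel set
#'
#' @param group_map named character vector mapping channel label to group,
#'   e.g. `c("114" = "NC", "115" = "DM", "116" = "DN", "117" = "reference")`.
#' @param masses reporter ion m/z per channel; defaults to the 4-plex
#'   monoisotopic reporter masses.
#' @return list of class `"channel_set"` with `labels`, `masses`,
#'   `group_map`.
#' @export
itraq4_channels <- function(group_map = c("114" = "NC", "115" = "DM",
                                          "116" = "DN", "117" = "reference"),
                            masses = c(114.1112, 115.1083,
                                       116.1116, 117.1150)) {
  labels <- c("114", "115", "116", "117")
  if (!setequal(names(group_map), labels)) {
    stop("group_map must name exactly channels 114, 115, 116, 117")
  }
  group_map <- group_map[labels]
  if (length(masses) != 4L || any(diff(masses) <= 0)) {
    stop("masses must be 4 strictly increasing values")
  }
  structure(list(labels = labels, masses = unname(masses),
                 group_map = group_map),
            class = "channel_set")
}

#' Channels assigned to a group
#' @param channels a [itraq4_channels()] channel set.
#' @param group group label.
#' @return integer channel indices.
#' @export
group_channels <- function(channels, group) {
  idx <- which(channels$group_map == group)
  if (!length(idx)) stop("no channel assigned to group '", group, "'")
  idx
}

#' Extract raw reporter intensities from a spectrum
#'
#' For each channel, the intensity of the most intense peak within
#' `tol` of the reporter mass; 0 when no peak falls in the window.
#'
#' @param spec a [spectrum()].
#' @param channels channel set.
#' @param tol fragment-ion tolerance in Da (default 0.1).
#' @return numeric 4-vector of raw intensities.
#' @export
extract_reporters <- function(spec, channels = itraq4_channels(),
                              tol = 0.1) {
  mz <- spec$peaks[, 1L]; int <- spec$peaks[, 2L]
  vapply(channels$masses, function(m) {
    in_win <- which(mz >= m - tol & mz <= m + tol)
    if (!length(in_win)) 0 else max(int[in_win])
  }, 0)
}

#' Correct reporter intensities for isotope impurities
#'
#' Solves `purity %*% x = raw` for the true channel signal x; negative
#' components of the exact solution are clamped to 0 (the clamp count is
#' attached as an attribute).
#'
#' @param raw numeric 4-vector (or 4 x n matrix of scans in columns).
#' @param purity validated purity matrix.
#' @return corrected intensities, same shape as `raw`, attribute
#'   `"n_clamped"` = number of clamped entries.
#' @export
correct_impurities <- function(raw, purity) {
  m <- if (is.matrix(raw)) raw else matrix(raw, nrow = 4L)
  x <- solve(unclass(purity), m)
  n_clamped <- sum(x < 0)
  x[x < 0] <- 0
  out <- if (is.matrix(raw)) x else drop(x)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Compute channel normalization factors from reference-run totals
#'
#' The four channel totals of a designated reference analysis (summed over
#' all its peptides) are equalized: `factor_c = mean(totals) / totals_c`.
#' Applying the factors corrects minor differences in source protein
#' amounts between channels.
#'
#' @param reference_totals numeric 4-vector of summed channel intensities,
#'   all > 0.
#' @param source identifier of the reference run (bookkeeping only).
#' @return list of class `"normalization_factors"`: `factors` (4-vector),
#'   `source`.
#' @export
compute_normalization_factors <- function(reference_totals,
                                          source = "reference") {
  reference_totals <- as.numeric(reference_totals)
  if (length(reference_totals) != 4L) stop("need 4 channel totals")
  if (any(!is.finite(reference_totals)) || any(reference_totals <= 0)) {
    stop("all channel totals must be finite and > 0")
  }
  structure(list(factors = mean(reference_totals) / reference_totals,
                 source = source),
            class = "normalization_factors")
}

#' Apply normalization factors
#' @param x 4-vector or 4 x n matrix of corrected intensities.
#' @param norm a [compute_normalization_factors()] object.
#' @return normalized intensities, same shape.
#' @export
apply_normalization <- function(x, norm) {
  if (is.matrix(x)) x * norm$factors else x * norm$factors
}

#' Quantify reporter ions across spectra
#'
#' Per-scan extraction, impurity correction, and normalization in one pass.
#'
#' @param spectra list of [spectrum()] objects.
#' @param purity purity matrix.
#' @param norm normalization factors (or NULL to skip normalization).
#' @param channels channel set.
#' @param tol fragment tolerance in Da.
#' @return list with matrices `raw`, `corrected`, `normalized` (4 rows =
#'   channels, one column per scan, column names = scan ids) and
#'   `n_clamped`.
#' @export
quantify_scans <- function(spectra, purity, norm = NULL,
                           channels = itraq4_channels(), tol = 0.1) {
  raw <- vapply(spectra, extract_reporters, numeric(4L),
                channels = channels, tol = tol)
  if (!is.matrix(raw)) raw <- matrix(raw, nrow = 4L)
  colnames(raw) <- vapply(spectra, function(s) s$scan_id, "")
  corrected <- correct_impurities(raw, purity)
  n_clamped <- attr(corrected, "n_clamped")
  normalized <- if (is.null(norm)) corrected
                else apply_normalization(corrected, norm)
  rownames(raw) <- rownames(corrected) <- rownames(normalized) <-
    channels$labels
  list(raw = raw, corrected = corrected, normalized = normalized,
       n_clamped = n_clamped)
}

#' Aggregate scans of one peptide and compute group ratios
#'
#' Reporter intensities of a peptide's MS/MS scans are accumulated
#' (channel-wise sums across scans) before any ratio is taken; each
#' configured comparison then gets ratio = summed numerator channel(s) /
#' summed denominator channel(s), with its log2.  A zero denominator flags
#' the peptide and yields no ratio.
#'
#' @param scan_intensities 4 x n matrix (channels x scans) of normalized
#'   intensities for one peptide; a 4-vector is treated as one scan.
#' @param channels channel set with group assignments.
#' @param comparisons list of `c(numerator_group, denominator_group)`
#'   pairs.
#' @return list of class `"peptide_quant"`: `channel_sums` (named
#'   4-vector), `ratios` (data.frame comparison/ratio/log2_ratio/flagged),
#'   `n_scans`.
#' @export
aggregate_and_ratio <- function(scan_intensities,
                                channels = itraq4_channels(),
                                comparisons = list(c("DN", "DM"))) {
  m <- if (is.matrix(scan_intensities)) scan_intensities
       else matrix(scan_intensities, nrow = 4L)
  if (nrow(m) != 4L) stop("expected 4 channel rows")
  if (ncol(m) == 0L) stop("empty scan list")
  sums <- rowSums(m)
  names(sums) <- channels$labels
  rows <- lapply(comparisons, function(cmp) {
    num <- sum(sums[group_channels(channels, cmp[1])])
    den <- sum(sums[group_channels(channels, cmp[2])])
    flagged <- den == 0
    ratio <- if (flagged) NA_real_ else num / den
    data.frame(comparison = paste0(cmp[1], "/", cmp[2]),
               ratio = ratio,
               log2_ratio = if (flagged) NA_real_ else log2(ratio),
               flagged = flagged, stringsAsFactors = FALSE)
  })
  structure(list(channel_sums = sums,
                 ratios = do.call(rbind, rows),
                 n_scans = ncol(m)),
            class = "peptide_quant")
}

#' Peptide-level quantification table
#'
#' Applies [aggregate_and_ratio()] to every unique phosphopeptide, using
#' the scan-to-peptide assignment from collapsing.
#'
#' @param peptides unique phosphopeptide data.frame with `key` and
#'   `member_rows`.
#' @param psms the PSM table the `member_rows` index into.
#' @param scan_quant matrix of normalized intensities (4 x scans, columns
#'   named by scan id), e.g. `quantify_scans(...)$normalized`.
#' @param channels channel set.
#' @param comparisons list of group pairs.
#' @return data.frame: `key`, one `sum_<label>` column per channel, then
#'   per comparison `ratio_<num_den>` and `log2_<num_den>` columns, plus
#'   `n_scans`.
#' @export
peptide_quant_table <- function(peptides, psms, scan_quant,
                                channels = itraq4_channels(),
                                comparisons = list(c("DN", "DM"))) {
  cmp_names <- vapply(comparisons, paste, "", collapse = "_")
  out <- vector("list", nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    scans <- unique(psms$spectrum_ref[peptides$member_rows[[i]]])
    scans <- scans[scans %in% colnames(scan_quant)]
    if (!length(scans)) next
    pq <- aggregate_and_ratio(scan_quant[, scans, drop = FALSE],
                              channels, comparisons)
    row <- c(list(key = peptides$key[i]),
             as.list(stats::setNames(pq$channel_sums,
                                     paste0("sum_", channels$labels))))
    for (j in seq_along(comparisons)) {
      row[[paste0("ratio_", cmp_names[j])]] <- pq$ratios$ratio[j]
      row[[paste0("log2_", cmp_names[j])]] <- pq$ratios$log2_ratio[j]
    }
    row$n_scans <- pq$n_scans
    out[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(res) <- NULL
  res
}
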