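# PSM filtering and collapsing: charge-state filter, target-decoy FDR,
# unique-phosphopeptide collapsing, and identification summaries.

#' Filter PSMs to the acquisition charge-state range
#'
#' @param psms PSM data.frame.
#' @param charge_range inclusive charge bounds, default 2+ to 4+.
#' @return PSM data.frame restricted to the range.
#' @export
filter_charge <- function(psms, charge_range = c(2, 4)) {
  psms[psms$charge >= charge_range[1] & psms$charge <= charge_range[2], ,
       drop = FALSE]
}

#' Filter rank-1 PSMs to a target-decoy FDR bound
#'
#' FDR at a score cutoff c is estimated as
#' (number of decoy PSMs with score >= c) / (number of target PSMs with
#' score >= c).  The cutoff is the lowest observed score whose estimated
#' FDR is at or below `max_fdr`; retained PSMs are the target (non-decoy)
#' rank-1 hits at or above the cutoff.  Tied scores are counted together on
#' both sides of the ratio, so a decoy tied with the cutoff counts against
#' it (conservative).
#'
#' @param psms PSM data.frame with `score`, `is_decoy`, `rank` columns.
#'   Only rank-1 PSMs are considered.
#' @param max_fdr maximum acceptable FDR (default 0.01, i.e. 1%).
#' @return list with `psms` (retained target PSMs), `score_cutoff`
#'   (`Inf` when no cutoff satisfies the bound), `achieved_fdr`,
#'   `n_target_in`, `n_decoy_in`.
#' @export
filter_psms_by_fdr <- function(psms, max_fdr = 0.01) {
  stopifnot(max_fdr >= 0)
  r1 <- psms[psms$rank == 1L, , drop = FALSE]
  n_target <- sum(!r1$is_decoy)
  n_decoy <- sum(r1$is_decoy)
  empty <- r1[0, , drop = FALSE]
  if (nrow(r1) == 0L || n_target == 0L) {
    return(list(psms = empty, score_cutoff = Inf, achieved_fdr = NA_real_,
                n_target_in = n_target, n_decoy_in = n_decoy))
  }
  o <- order(r1$score, decreasing = TRUE)
  sc <- r1$score[o]
  dec <- r1$is_decoy[o]
  cum_dec <- cumsum(dec)
  cum_tar <- cumsum(!dec)
  # last index of each tied run: counts at cutoff = that score
  is_run_end <- c(sc[-1L] != sc[-length(sc)], TRUE)
  idx <- which(is_run_end)
  fdr_at <- cum_dec[idx] / pmax(cum_tar[idx], 1L)
  fdr_at[cum_tar[idx] == 0L] <- Inf
  ok <- fdr_at <= max_fdr
  if (!any(ok)) {
    return(list(psms = empty, score_cutoff = Inf, achieved_fdr = NA_real_,
                n_target_in = n_target, n_decoy_in = n_decoy))
  }
  pick <- max(which(ok))       # deepest run end satisfying the bound
  cutoff <- sc[idx[pick]]      # lowest qualifying score
  keep <- r1$score >= cutoff & !r1$is_decoy
  list(psms = r1[keep, , drop = FALSE],
       score_cutoff = cutoff,
       achieved_fdr = fdr_at[pick],
       n_target_in = n_target, n_decoy_in = n_decoy)
}

#' Number of phospho groups on a PSM
#' @param modifications modification string(s).
#' @return integer vector of phospho counts.
#' @export
count_phospho <- function(modifications) {
  modifications[is.na(modifications)] <- ""
  lengths(regmatches(modifications,
                     gregexpr("(^|;)[^;]*:phospho", modifications)))
}

#' Phospho site positions from a modification string
#' @param modifications single modification string.
#' @return sorted integer vector of 1-based positions.
#' @export
phospho_positions <- function(modifications) {
  mods <- parse_mods(modifications)
  sort(mods$position[mods$name == "phospho"])
}

#' Collapse PSMs into unique phosphopeptides
#'
#' The identity key is exactly (sequence, number of phospho groups):
#' positional isomers of the same sequence with the same phospho count merge
#' into one unique phosphopeptide; the same sequence with a different
#' phospho count is a separate entry.  Non-phospho variable modifications do
#' not enter the key.  PSMs without a phospho modification are excluded
#' (their count is reported).
#'
#' @param psms PSM data.frame (normally FDR-filtered rank-1 targets).
#' @return list with `peptides` (data.frame: `sequence`, `phospho_count`,
#'   `key`, `n_psms`, list-columns `member_rows` (row indices into `psms`)
#'   and `site_candidates` (distinct observed position sets)), and
#'   `n_excluded_non_phospho`.
#' @export
collapse_unique_phosphopeptides <- function(psms) {
  pc <- count_phospho(psms$modifications)
  keep <- pc >= 1L
  n_excl <- sum(!keep)
  idx <- which(keep)
  if (!length(idx)) {
    return(list(peptides = data.frame(sequence = character(),
                                      phospho_count = integer(),
                                      key = character(), n_psms = integer()),
                n_excluded_non_phospho = n_excl))
  }
  key <- paste0(psms$sequence[idx], "/", pc[idx])
  split_rows <- split(idx, key)
  keys <- sort(names(split_rows))          # deterministic, order-independent
  split_rows <- split_rows[keys]
  seqs <- sub("/[0-9]+$", "", keys)
  counts <- as.integer(sub("^.*/", "", keys))
  site_candidates <- lapply(split_rows, function(rows) {
    sets <- lapply(psms$modifications[rows], phospho_positions)
    unique(sets)
  })
  peptides <- data.frame(sequence = seqs, phospho_count = counts,
                         key = keys, n_psms = lengths(split_rows),
                         stringsAsFactors = FALSE, row.names = NULL)
  peptides$member_rows <- unname(split_rows)
  peptides$site_candidates <- unname(site_candidates)
  list(peptides = peptides, n_excluded_non_phospho = n_excl)
}

#' Residue distribution of phosphosites, at printed precision
#'
#' @param counts named vector or list with elements `S`, `T`, `Y`.
#' @param digits rounding digits per residue; serine/threonine percentages
#'   are conventionally printed with 1 decimal and tyrosine (a small class)
#'   with 2.
#' @return list with `n_sites`, `counts` and rounded `percent`.
#' @export
residue_distribution <- function(counts, digits = c(S = 1, T = 1, Y = 2)) {
  counts <- unlist(counts)[c("S", "T", "Y")]
  if (anyNA(counts)) stop("counts must contain S, T and Y")
  n <- sum(counts)
  pct <- vapply(c("S", "T", "Y"), function(r)
    round(100 * counts[[r]] / n, digits[[r]]), 0)
  list(n_sites = n, counts = counts, percent = pct)
}

#' Group-overlap summary of phosphoproteins
#'
#' Counts proteins by the exact subset of groups they appear in, and the
#' percentage present in all groups.
#'
#' @param presence named list: protein accession -> character vector of
#'   group labels it was observed in.
#' @param groups all group labels, default `c("NC", "DM", "DN")`.
#' @param digits rounding for the all-groups percentage (default 2).
#' @return list with `overlap` (named counts per group subset),
#'   `n_proteins`, `n_all_groups`, `percent_all_groups`.
#' @export
group_overlap <- function(presence, groups = c("NC", "DM", "DN"),
                          digits = 2) {
  subset_key <- vapply(presence, function(g)
    paste(groups[groups %in% g], collapse = "+"), "")
  if (any(!nzchar(subset_key))) stop("protein with empty group presence")
  overlap <- table(subset_key)
  n <- length(presence)
  all_key <- paste(groups, collapse = "+")
  n_all <- if (all_key %in% names(overlap)) overlap[[all_key]] else 0L
  list(overlap = c(overlap), n_proteins = n, n_all_groups = n_all,
       percent_all_groups = round(100 * n_all / n, digits))
}

#' Identification summary
#'
#' Headline identification numbers in the shape this field reports them:
#' total proteins, phosphoproteins, unique phosphopeptides, confidently
#' localized sites with their S/T/Y split, and group-overlap of
#' phosphoproteins.
#'
#' @param peptides unique phosphopeptide data.frame
#'   (see [collapse_unique_phosphopeptides()]).
#' @param localizations data.frame with columns `key`, `positions`
#'   (list-column of site positions), `status`; only rows with status
#'   `"confident"` or `"single_candidate"` contribute sites.
#' @param protein_map named character vector: peptide key -> protein
#'   accession.
#' @param presence named list: protein accession -> groups observed in
#'   (optional; group overlap omitted when NULL).
#' @param n_proteins total (not only phospho) protein count, if known.
#' @param groups group labels for the overlap summary.
#' @return object of class `"ident_summary"`.
#' @export
summarize_identifications <- function(peptides, localizations, protein_map,
                                      presence = NULL, n_proteins = NA_integer_,
                                      groups = c("NC", "DM", "DN")) {
  loc_ok <- localizations[localizations$status %in%
                            c("confident", "single_candidate"), , drop = FALSE]
  res_counts <- c(S = 0L, T = 0L, Y = 0L)
  for (i in seq_len(nrow(loc_ok))) {
    seqch <- strsplit(sub("/[0-9]+$", "", loc_ok$key[i]), "")[[1L]]
    for (p in loc_ok$positions[[i]]) {
      r <- seqch[p]
      if (!r %in% c("S", "T", "Y")) {
        stop("localized site on non-S/T/Y residue '", r, "' in ", loc_ok$key[i])
      }
      res_counts[[r]] <- res_counts[[r]] + 1L
    }
  }
  rd <- if (sum(res_counts) > 0) residue_distribution(res_counts) else
    list(n_sites = 0L, counts = res_counts,
         percent = c(S = NA_real_, T = NA_real_, Y = NA_real_))
  phosphoproteins <- unique(unname(protein_map[peptides$key]))
  phosphoproteins <- phosphoproteins[!is.na(phosphoproteins)]
  ov <- if (!is.null(presence) && length(presence)) {
    group_overlap(presence[names(presence) %in% phosphoproteins],
                  groups = groups)
  } else NULL
  structure(
    list(n_proteins = n_proteins,
         n_phosphoproteins = length(phosphoproteins),
         n_phosphopeptides = nrow(peptides),
         n_sites = rd$n_sites,
         residue_counts = rd$counts,
         residue_percent = rd$percent,
         group_overlap = if (is.null(ov)) NULL else ov$overlap,
         percent_all_groups = if (is.null(ov)) NA_real_ else
           ov$percent_all_groups),
    class = "ident_summary")
}

#' @export
print.ident_summary <- function(x, ...) {
  cat("Identification summary\n")
  if (!is.na(x$n_proteins)) cat("  proteins:        ", x$n_proteins, "\n")
  cat("  phosphoproteins: ", x$n_phosphoproteins, "\n")
  cat("  phosphopeptides: ", x$n_phosphopeptides, "\n")
  cat("  localized sites: ", x$n_sites, "\n")
  if (x$n_sites > 0) {
    cat(sprintf("    pS %d (%s%%), pT %d (%s%%), pY %d (%s%%)\n",
                x$residue_counts[["S"]], x$residue_percent[["S"]],
                x$residue_counts[["T"]], x$residue_percent[["T"]],
                x$residue_counts[["Y"]], x$residue_percent[["Y"]]))
  }
  if (!is.null(x$group_overlap)) {
    cat("  phosphoproteins in all groups:",
        sprintf("%s%%", x$percent_all_groups), "\n")
  }
  invisible(x)
}
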