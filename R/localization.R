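# Phosphosite localization by the Mascot delta (MD) score: the score gap
# between the best and second-best match of the same peptide sequence with
# different phosphosite placements.  A gap at or above the cutoff (10 by
# default) marks the top placement as confidently localized; a peptide with
# no competing placement is treated as unambiguously localized.

#' MD score between two site candidates
#'
#' @param top best-scoring candidate: list with `positions` (integer set)
#'   and `score`.
#' @param second runner-up candidate with different positions, or `NULL`
#'   when no competitor exists.
#' @return numeric score difference (>= 0), or `NA_real_` when there is no
#'   competitor.
#' @export
md_score <- function(top, second = NULL) {
  if (is.null(second)) return(NA_real_)
  if (setequal(top$positions, second$positions)) {
    stop("candidates share the same site positions; not a localization pair")
  }
  if (second$score > top$score) stop("top candidate must have the higher score")
  top$score - second$score
}

#' Localize phosphosites for one peptide key
#'
#' @param candidates list of site candidates (each: `positions`, `score`),
#'   sorted by score descending (re-sorted defensively).
#' @param cutoff MD-score cutoff for confident localization (default 10).
#' @return list of class `"site_localization"`: `best` (top candidate),
#'   `md_score`, `status` in `{"confident", "ambiguous",
#'   "single_candidate"}`, `cutoff`.
#' @export
localize <- function(candidates, cutoff = 10) {
  if (!length(candidates)) stop("empty candidate list")
  scores <- vapply(candidates, function(cc) cc$score, 0)
  candidates <- candidates[order(scores, decreasing = TRUE)]
  top <- candidates[[1L]]
  second <- NULL
  for (cc in candidates[-1L]) {
    if (!setequal(cc$positions, top$positions)) { second <- cc; break }
  }
  if (is.null(second)) {
    out <- list(best = top, md_score = NA_real_,
                status = "single_candidate", cutoff = cutoff)
  } else {
    md <- md_score(top, second)
    out <- list(best = top, md_score = md,
                status = if (md >= cutoff) "confident" else "ambiguous",
                cutoff = cutoff)
  }
  class(out) <- "site_localization"
  out
}

#' @export
print.site_localization <- function(x, ...) {
  cat(sprintf("<site_localization> positions {%s}, md = %s, %s\n",
              paste(x$best$positions, collapse = ","),
              if (is.na(x$md_score)) "NA" else format(x$md_score), x$status))
  invisible(x)
}

#' Localize phosphosites for a set of unique phosphopeptides
#'
#' For each unique phosphopeptide, candidate site placements are gathered
#' from all PSMs (any rank) sharing its (sequence, phospho count) key; each
#' distinct position set keeps its best score.  Ambiguous peptides retain
#' their rank-1 positions for reporting but are flagged; they still carry
#' through to quantification, which keys on (sequence, phospho count).
#'
#' @param peptides unique phosphopeptide data.frame
#'   (see [collapse_unique_phosphopeptides()]).
#' @param all_psms full PSM table (all ranks, targets), used as the
#'   candidate pool.
#' @param cutoff MD-score cutoff (default 10).
#' @return data.frame: `key`, `positions` (list-column), `md_score`,
#'   `status`.
#' @export
localize_peptides <- function(peptides, all_psms, cutoff = 10) {
  pc <- count_phospho(all_psms$modifications)
  pool_key <- paste0(all_psms$sequence, "/", pc)
  target_rows <- which(!all_psms$is_decoy)
  pool_index <- split(target_rows, pool_key[target_rows])
  out <- vector("list", nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    rows <- pool_index[[peptides$key[i]]]
    sets <- lapply(all_psms$modifications[rows], phospho_positions)
    scores <- all_psms$score[rows]
    keyset <- vapply(sets, paste, "", collapse = ",")
    best_per_set <- tapply(seq_along(rows), keyset,
                           function(j) j[which.max(scores[j])])
    cands <- lapply(unname(best_per_set), function(j)
      list(positions = sets[[j]], score = scores[j]))
    loc <- localize(cands, cutoff = cutoff)
    out[[i]] <- list(key = peptides$key[i],
                     positions = loc$best$positions,
                     md_score = loc$md_score, status = loc$status)
  }
  data.frame(key = vapply(out, `[[`, "", "key"),
             positions = I(lapply(out, `[[`, "positions")),
             md_score = vapply(out, `[[`, 0, "md_score"),
             status = vapply(out, `[[`, "", "status"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a localization table as TSV
#'
#' One row per peptide key with best positions (comma-separated), MD score
#' and status.
#'
#' @param loc localization data.frame from [localize_peptides()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_localization_table <- function(loc, path) {
  flat <- data.frame(
    key = loc$key,
    positions = vapply(loc$positions, paste, "", collapse = ","),
    md_score = loc$md_score, status = loc$status,
    stringsAsFactors = FALSE)
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
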