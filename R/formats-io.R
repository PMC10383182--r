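# Readers and writers for the external formats the pipeline touches:
# MGF spectra, FASTA protein databases, PSM/result TSV tables, the 4x4
# reporter purity matrix (CSV) and YAML/JSON pipeline configs.

#' Construct an MS/MS spectrum
#'
#' @param scan_id scan identifier (character).
#' @param title spectrum title.
#' @param precursor_mz precursor m/z (Da/e).
#' @param charge precursor charge state (>= 1).
#' @param mz numeric vector of fragment m/z values.
#' @param intensity numeric vector of intensities (>= 0), same length.
#' @param metadata named list of extra MGF headers to preserve.
#' @return object of class `"spectrum"`; peaks are stored sorted by m/z.
#' @export
spectrum <- function(scan_id, title = scan_id, precursor_mz, charge,
                     mz = numeric(), intensity = numeric(),
                     metadata = list()) {
  stopifnot(length(mz) == length(intensity))
  if (any(intensity < 0)) stop("negative peak intensity")
  if (is.na(charge) || charge < 1) stop("charge must be >= 1")
  o <- order(mz)
  structure(
    list(scan_id = as.character(scan_id), title = as.character(title),
         precursor_mz = as.numeric(precursor_mz), charge = as.integer(charge),
         peaks = cbind(mz = as.numeric(mz[o]),
                       intensity = as.numeric(intensity[o])),
         metadata = metadata),
    class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum %s> precursor %.4f m/z, charge %d+, %d peaks\n",
              x$scan_id, x$precursor_mz, x$charge, nrow(x$peaks)))
  invisible(x)
}

#' Read a Mascot Generic Format (MGF) file
#'
#' Parses BEGIN IONS / END IONS blocks with TITLE, PEPMASS (first token =
#' precursor m/z) and CHARGE ("2+" style) headers.  Unknown `KEY=value`
#' headers are preserved in each spectrum's `metadata`.  Peak lines are
#' whitespace-separated "mz intensity" pairs.
#'
#' @param path path to an MGF file.
#' @return list of [spectrum()] objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  in_block <- FALSE
  block_start <- NA_integer_
  title <- NA_character_; pepmass <- NA_real_; charge <- NA_integer_
  scans <- NA_character_
  mzs <- NULL; ints <- NULL; meta <- list()
  n_auto <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (ln == "BEGIN IONS") {
      if (in_block) stop("line ", i, ": BEGIN IONS inside an open block")
      in_block <- TRUE; block_start <- i
      title <- NA_character_; pepmass <- NA_real_; charge <- NA_integer_
      scans <- NA_character_; mzs <- numeric(); ints <- numeric()
      meta <- list()
      next
    }
    if (ln == "END IONS") {
      if (!in_block) stop("line ", i, ": END IONS without BEGIN IONS")
      n_auto <- n_auto + 1L
      sid <- if (!is.na(scans)) scans
             else if (!is.na(title)) title else sprintf("scan_%d", n_auto)
      spectra[[length(spectra) + 1L]] <- spectrum(
        scan_id = sid,
        title = if (is.na(title)) sid else title,
        precursor_mz = pepmass, charge = if (is.na(charge)) 2L else charge,
        mz = mzs, intensity = ints, metadata = meta)
      in_block <- FALSE
      next
    }
    if (!in_block) next  # headers outside blocks are ignored
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq > 0L) {
      key <- toupper(substr(ln, 1L, eq - 1L))
      val <- substr(ln, eq + 1L, nchar(ln))
      if (key == "TITLE") title <- val
      else if (key == "PEPMASS") {
        pepmass <- suppressWarnings(as.numeric(strsplit(val, "\\s+")[[1L]][1L]))
        if (is.na(pepmass)) stop("line ", i, ": non-numeric PEPMASS")
      } else if (key == "CHARGE") {
        charge <- suppressWarnings(as.integer(sub("\\+$", "", sub("^\\+", "", val))))
        if (is.na(charge)) stop("line ", i, ": unparseable CHARGE '", val, "'")
      } else if (key == "SCANS") scans <- val
      else meta[[key]] <- val
      next
    }
    toks <- strsplit(ln, "[ \t]+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks[1:2]))
    if (length(toks) < 2L || anyNA(vals)) {
      stop("line ", i, ": non-numeric peak line '", ln, "'")
    }
    mzs <- c(mzs, vals[1L]); ints <- c(ints, vals[2L])
  }
  if (in_block) {
    stop("unterminated BEGIN IONS block starting at line ", block_start)
  }
  spectra
}

#' Write spectra to an MGF file
#'
#' Emits the common Mascot dialect: one BEGIN IONS/END IONS block per
#' spectrum with TITLE, SCANS, PEPMASS, CHARGE (`2+` style) and "mz
#' intensity" peak lines, in input order.
#'
#' @param spectra list of [spectrum()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sp in spectra) {
    stopifnot(inherits(sp, "spectrum"))
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp$title), con)
    writeLines(paste0("SCANS=", sp$scan_id), con)
    writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    writeLines(sprintf("CHARGE=%d+", sp$charge), con)
    for (key in names(sp$metadata)) {
      writeLines(paste0(key, "=", sp$metadata[[key]]), con)
    }
    if (nrow(sp$peaks)) {
      writeLines(sprintf("%.6f %.6f", sp$peaks[, 1L], sp$peaks[, 2L]), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read a protein FASTA database
#'
#' @param path FASTA file.
#' @param decoy_prefix accession prefix marking reversed decoy entries
#'   (default `"REV_"`).
#' @return data.frame with columns `accession`, `description`, `sequence`
#'   (uppercased, whitespace-stripped) and `is_decoy`.
#' @export
read_fasta <- function(path, decoy_prefix = "REV_") {
  if (!file.exists(path)) stop("no such file: ", path)
  aas <- Biostrings::readAAStringSet(path)
  headers <- names(aas)
  seqs <- toupper(gsub("\\s", "", as.character(aas)))
  if (any(!nzchar(seqs))) {
    stop("record(s) with empty sequence: ",
         paste(headers[!nzchar(seqs)], collapse = ", "))
  }
  acc <- vapply(strsplit(headers, "\\s+"), `[[`, "", 1L)
  desc <- sub("^\\S+\\s*", "", headers)
  data.frame(accession = acc, description = desc, sequence = seqs,
             is_decoy = startsWith(acc, decoy_prefix),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a protein FASTA database
#' @param proteins data.frame as from [read_fasta()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  x <- Biostrings::AAStringSet(proteins$sequence)
  names(x) <- ifelse(nzchar(proteins$description),
                     paste(proteins$accession, proteins$description),
                     proteins$accession)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

# --- PSM tables -------------------------------------------------------------

# Column dialect (version 1): spectrum_ref, sequence, modifications
# (semicolon-separated pos:site:name; 0 = N-terminus), score, rank,
# is_decoy (TRUE/FALSE), accessions (semicolon-separated), charge.
.psm_columns <- c("spectrum_ref", "sequence", "modifications", "score",
                  "rank", "is_decoy", "accessions", "charge")

#' Read a PSM (peptide-spectrum match) TSV table
#'
#' The table dialect is versioned and documented in the package: columns
#' `spectrum_ref`, `sequence`, `modifications`, `score`, `rank`, `is_decoy`,
#' `accessions`, `charge`, with a header row.
#'
#' @param path TSV file.
#' @param spectra optional list of spectra; when given, every
#'   `spectrum_ref` must resolve to a scan id.
#' @return data.frame of PSMs.
#' @export
read_psm_table <- function(path, spectra = NULL) {
  psms <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  missing_cols <- setdiff(.psm_columns, names(psms))
  if (length(missing_cols)) {
    stop("PSM table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  psms$score <- as.numeric(psms$score)
  psms$rank <- as.integer(psms$rank)
  psms$charge <- as.integer(psms$charge)
  psms$is_decoy <- as.logical(psms$is_decoy)
  psms$modifications[is.na(psms$modifications)] <- ""
  validate_psm_table(psms, spectra)
  psms
}

#' Validate a PSM table's invariants
#'
#' Checks ranks >= 1, rank-1 uniqueness per spectrum, modification positions
#' within peptide bounds, and (optionally) that spectrum references resolve.
#'
#' @param psms PSM data.frame.
#' @param spectra optional spectra list for reference resolution.
#' @return invisibly, `psms`.
#' @export
validate_psm_table <- function(psms, spectra = NULL) {
  if (any(psms$rank < 1L, na.rm = TRUE)) stop("PSM rank < 1")
  r1 <- psms$spectrum_ref[psms$rank == 1L]
  if (anyDuplicated(r1)) {
    stop("multiple rank-1 PSMs for spectrum: ",
         paste(unique(r1[duplicated(r1)]), collapse = ", "))
  }
  for (i in seq_len(nrow(psms))) {
    validate_mods(psms$sequence[i], psms$modifications[i])
  }
  if (!is.null(spectra)) {
    ids <- vapply(spectra, function(s) s$scan_id, "")
    bad <- setdiff(unique(psms$spectrum_ref), ids)
    if (length(bad)) {
      stop("unresolved spectrum reference(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  invisible(psms)
}

#' Write a PSM table as TSV
#' @param psms PSM data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  utils::write.table(psms[, .psm_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- purity matrix ----------------------------------------------------------

#' Validate a reporter purity matrix
#'
#' Entry (i, j) is the fraction of channel j's reagent signal observed in
#' channel i.  Entries must be non-negative, columns must sum to at most 1
#' (small tolerance), and the matrix must be invertible.
#'
#' @param m numeric 4x4 matrix.
#' @return the matrix, with `"purity_matrix"` class prepended.
#' @export
validate_purity_matrix <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(4L, 4L))) {
    stop("purity matrix must be 4x4, got ", paste(dim(m), collapse = "x"))
  }
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("purity matrix contains missing values")
  if (any(m < 0)) stop("purity matrix has negative entries")
  if (any(colSums(m) > 1 + 1e-6)) {
    stop("purity matrix column sums exceed 1")
  }
  if (abs(det(m)) < 1e-12) stop("purity matrix is singular")
  class(m) <- c("purity_matrix", class(m))
  m
}

#' Read a 4x4 purity matrix from CSV
#'
#' @param path CSV with 4 rows and 4 columns of fractions (no row names; a
#'   header row of channel labels is accepted and ignored for numerics).
#' @return validated purity matrix.
#' @export
read_purity_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  # drop a header row of labels if present
  if (!all(vapply(raw[1, ], function(v)
    !is.na(suppressWarnings(as.numeric(v))), TRUE))) {
    raw <- raw[-1, , drop = FALSE]
  }
  m <- as.matrix(raw)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric entries in purity matrix CSV")
  dimnames(m) <- NULL
  validate_purity_matrix(m)
}

#' Write a purity matrix to CSV
#' @param m purity matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_purity_matrix <- function(m, path) {
  utils::write.table(unclass(m), path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Default 4-plex reporter purity matrix
#'
#' A representative manufacturer-style isotope impurity matrix for the
#' 114/115/116/117 reagents: each reagent bleeds a few percent into the -1
#' and +1 (and traces into +/-2) neighbouring channels; columns are
#' reagents, rows observed channels.
#'
#' @return validated 4x4 purity matrix.
#' @export
default_purity_matrix <- function() {
  # per-reagent bleed fractions: c(-2, -1, +1, +2) as percents
  bleed <- list(`114` = c(0.0, 1.0, 5.9, 0.2),
                `115` = c(0.0, 2.0, 5.6, 0.1),
                `116` = c(0.0, 3.0, 4.5, 0.1),
                `117` = c(0.1, 4.0, 3.5, 0.0))
  m <- matrix(0, 4, 4)
  for (j in 1:4) {
    b <- bleed[[j]] / 100
    m[j, j] <- 1 - sum(b)
    off <- c(-2L, -1L, 1L, 2L)
    for (k in 1:4) {
      i <- j + off[k]
      if (i >= 1L && i <= 4L) m[i, j] <- b[k]
    }
  }
  validate_purity_matrix(m)
}

#' Read a pipeline configuration file (YAML or JSON)
#'
#' @param path file ending in .yaml/.yml or .json.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
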