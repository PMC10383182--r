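# Monoisotopic mass bookkeeping for peptides and their modifications.
#
# Residue masses are the standard monoisotopic values for the 20 canonical
# amino acids; a peptide's neutral mass is the residue sum plus one water.

#' Monoisotopic masses of the 20 canonical amino-acid residues (Da)
#'
#' Residue (not free amino acid) masses, i.e. the mass contributed by each
#' letter inside a peptide chain.
#'
#' @format Named numeric vector, names are one-letter residue codes.
#' @export
aa_monoisotopic <- c(
  A = 71.03711378, C = 103.00918478, D = 115.02694302, E = 129.04259309,
  F = 147.06841391, G = 57.02146372, H = 137.05891186, I = 113.08406398,
  K = 128.09496301, L = 113.08406398, M = 131.04048491, N = 114.04292744,
  P = 97.05276385, Q = 128.05857751, R = 156.10111102, S = 87.03202840,
  T = 101.04767847, V = 99.06841391, W = 186.07931295, Y = 163.06332853
)

#' Physical constants used in mass calculations (Da)
#' @name mass-constants
#' @export
mass_water <- 18.0105646

#' @rdname mass-constants
#' @export
mass_proton <- 1.00727646

# Accurate monoisotopic deltas for the workflow's modifications.  Nominal
# integer deltas (57, 1, 16, 80, 145) are accepted via the `nominal`
# argument of compute_peptide_mass for fidelity checks against reports that
# print nominal masses.
.mod_deltas <- c(
  carbamidomethyl = 57.02146,
  deamidation     = 0.98402,
  oxidation       = 15.99491,
  phospho         = 79.96633,
  itraq4plex      = 144.10207
)

.mod_deltas_nominal <- c(
  carbamidomethyl = 57, deamidation = 1, oxidation = 16,
  phospho = 80, itraq4plex = 145
)

# residue constraints per modification; "N-term" handled separately
.mod_allowed <- list(
  carbamidomethyl = "C",
  deamidation     = c("N", "Q"),
  oxidation       = "M",
  phospho         = c("S", "T", "Y"),
  itraq4plex      = c("K", "N-term")
)

#' Modification delta masses
#'
#' @param nominal logical; return the nominal integer deltas instead of the
#'   accurate monoisotopic values.
#' @return Named numeric vector of mass deltas (Da).
#' @export
mod_deltas <- function(nominal = FALSE) {
  if (nominal) .mod_deltas_nominal else .mod_deltas
}

#' Parse a modification string
#'
#' Modifications travel through PSM tables as a semicolon-separated string of
#' `pos:site:name` triplets, where `pos` 0 denotes the peptide N-terminus and
#' positive values are 1-based residue indices; `site` is the residue letter
#' or `"N-term"`.
#'
#' @param x a single modification string ("" or NA means no modifications).
#' @return data.frame with columns `position` (integer), `site` (character),
#'   `name` (character); zero rows when unmodified.
#' @examples
#' parse_mods("0:N-term:itraq4plex;3:S:phospho")
#' @export
parse_mods <- function(x) {
  empty <- data.frame(position = integer(), site = character(),
                      name = character(), stringsAsFactors = FALSE)
  if (length(x) != 1L) stop("parse_mods() expects a single string")
  if (is.na(x) || !nzchar(trimws(x))) return(empty)
  parts <- strsplit(trimws(x), ";", fixed = TRUE)[[1L]]
  parts <- parts[nzchar(parts)]
  if (!length(parts)) return(empty)
  fields <- strsplit(parts, ":", fixed = TRUE)
  bad <- vapply(fields, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed modification token(s): ",
         paste(parts[bad], collapse = ", "))
  }
  out <- data.frame(
    position = as.integer(vapply(fields, `[[`, "", 1L)),
    site     = vapply(fields, `[[`, "", 2L),
    name     = vapply(fields, `[[`, "", 3L),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$position)) stop("non-integer modification position in: ", x)
  out
}

#' Format a modification data.frame back to its string form
#' @param mods data.frame as returned by [parse_mods()].
#' @return single character string.
#' @export
format_mods <- function(mods) {
  if (is.null(mods) || nrow(mods) == 0L) return("")
  paste(sprintf("%d:%s:%s", mods$position, mods$site, mods$name),
        collapse = ";")
}

#' Validate modifications against a peptide sequence
#'
#' Checks positional bounds, site/sequence agreement, and the chemistry
#' constraints (phospho on S/T/Y, carbamidomethyl on C, oxidation on M,
#' deamidation on N/Q, iTRAQ on the N-terminus or K).
#'
#' @param sequence peptide string (canonical uppercase letters).
#' @param mods data.frame from [parse_mods()] or a modification string.
#' @return invisibly, the parsed modification data.frame.
#' @export
validate_mods <- function(sequence, mods) {
  if (is.character(mods)) mods <- parse_mods(mods)
  if (nrow(mods) == 0L) return(invisible(mods))
  n <- nchar(sequence)
  letters_seq <- strsplit(sequence, "")[[1L]]
  for (i in seq_len(nrow(mods))) {
    m <- mods[i, ]
    if (!m$name %in% names(.mod_deltas)) {
      stop("unknown modification name: ", m$name)
    }
    allowed <- .mod_allowed[[m$name]]
    if (m$position == 0L) {
      if (!"N-term" %in% allowed) {
        stop(m$name, " is not an N-terminal modification")
      }
      next
    }
    if (m$position < 0L || m$position > n) {
      stop("modification position ", m$position,
           " outside peptide of length ", n)
    }
    res <- letters_seq[m$position]
    if (nzchar(m$site) && m$site != "N-term" && m$site != res) {
      stop("modification site ", m$site, " does not match residue ", res,
           " at position ", m$position)
    }
    if (!res %in% setdiff(allowed, "N-term")) {
      stop(m$name, " not allowed on residue ", res,
           " (position ", m$position, ")")
    }
  }
  invisible(mods)
}

#' Monoisotopic mass of a (modified) peptide
#'
#' Neutral monoisotopic mass: sum of residue masses + one water + the sum of
#' modification deltas.
#'
#' @param sequence peptide string of canonical residues.
#' @param modifications a modification string or data.frame
#'   (see [parse_mods()]); default none.
#' @param nominal use nominal integer modification deltas instead of
#'   accurate monoisotopic ones.
#' @return neutral monoisotopic mass in Da.
#' @examples
#' compute_peptide_mass("AG")              # 146.0691
#' compute_peptide_mass("ACK", "0:N-term:itraq4plex;2:C:carbamidomethyl;3:K:itraq4plex")
#' @export
compute_peptide_mass <- function(sequence, modifications = "",
                                 nominal = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nzchar(sequence))
  letters_seq <- strsplit(sequence, "")[[1L]]
  unknown <- setdiff(letters_seq, names(aa_monoisotopic))
  if (length(unknown)) {
    stop("unknown residue letter(s): ", paste(unknown, collapse = ", "))
  }
  mods <- if (is.character(modifications)) parse_mods(modifications)
          else modifications
  validate_mods(sequence, mods)
  deltas <- mod_deltas(nominal)
  base <- sum(aa_monoisotopic[letters_seq]) + mass_water
  base + sum(deltas[mods$name])
}

#' Validate a PSM's precursor mass against its spectrum
#'
#' Computes the neutral precursor mass implied by the observed precursor m/z
#' and charge, compares it to the theoretical modified peptide mass, and
#' additionally flags charges outside the acquisition range (2+ to 4+ by
#' default).
#'
#' @param sequence peptide string.
#' @param modifications modification string or data.frame.
#' @param precursor_mz observed precursor m/z (Da/e).
#' @param charge precursor charge (>= 1).
#' @param tol precursor mass tolerance in Da (default 0.6).
#' @param charge_range acceptable charge states, default `c(2, 4)`.
#' @return list with `ok` (mass within tolerance AND charge in range),
#'   `mass_ok`, `charge_ok`, `precursor_error` (observed - theoretical, Da).
#' @export
validate_precursor <- function(sequence, modifications, precursor_mz, charge,
                               tol = 0.6, charge_range = c(2, 4)) {
  if (is.na(charge) || charge < 1) stop("charge must be >= 1")
  theo <- compute_peptide_mass(sequence, modifications)
  neutral <- (precursor_mz - mass_proton) * charge
  err <- neutral - theo
  mass_ok <- abs(err) <= tol
  charge_ok <- charge >= charge_range[1] && charge <= charge_range[2]
  list(ok = mass_ok && charge_ok, mass_ok = mass_ok, charge_ok = charge_ok,
       precursor_error = err)
}

#' Precursor m/z for a peptide at a given charge
#' @inheritParams validate_precursor
#' @return m/z in Da/e.
#' @export
peptide_mz <- function(sequence, modifications = "", charge = 2L) {
  (compute_peptide_mass(sequence, modifications) +
     charge * mass_proton) / charge
}
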