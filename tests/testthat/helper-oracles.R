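# Shared fixtures and independent oracles used across test files.

# random spectrum with seeded peak content
random_spectrum <- function(id, n_peaks = 12) {
  mz <- sort(runif(n_peaks, 100, 1500))
  spectrum(scan_id = id, title = paste0("t_", id),
           precursor_mz = runif(1, 300, 1200),
           charge = sample(2:4, 1),
           mz = mz, intensity = runif(n_peaks, 1, 1e5))
}

# brute-force target-decoy FDR oracle: scan every observed score as a
# candidate cutoff, keep the lowest one whose decoy/target ratio at-or-above
# satisfies the bound
brute_force_fdr <- function(scores, is_decoy, max_fdr = 0.01) {
  cand <- sort(unique(scores))
  best <- Inf
  for (cutoff in cand) {
    n_d <- sum(is_decoy & scores >= cutoff)
    n_t <- sum(!is_decoy & scores >= cutoff)
    if (n_t > 0 && n_d / n_t <= max_fdr) {
      best <- cutoff
      break  # cand ascending: first qualifying is the lowest
    }
  }
  retained <- which(!is_decoy & scores >= best)
  list(cutoff = best, retained = retained)
}

# exhaustive substring-scan digestion oracle: a substring is a tryptic
# peptide iff both ends are valid cleavage boundaries and it spans at most
# `mc` internal cleavage sites
brute_force_digest <- function(seq, mc = 2, min_len = 6, max_len = 40) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  cut_ok <- function(i) {  # cleavage allowed after position i?
    i >= 1 && i <= n && ch[i] %in% c("K", "R") && (i == n || ch[i + 1] != "P")
  }
  out <- character()
  for (i in 1:n) {
    if (!(i == 1 || cut_ok(i - 1))) next
    for (j in i:n) {
      if (!(j == n || cut_ok(j))) next
      internal <- if (j > i) sum(vapply(i:(j - 1), cut_ok, TRUE)) else 0
      len <- j - i + 1
      if (internal <= mc && len >= min_len && len <= max_len) {
        out <- c(out, substr(seq, i, j))
      }
    }
  }
  out
}

# random protein string for digestion tests
random_protein_seq <- function(len) {
  paste(sample(c(LETTERS[!LETTERS %in% c("B", "J", "O", "U", "X", "Z")]),
               len, replace = TRUE), collapse = "")
}

# minimal PSM table row constructor
make_psm <- function(spectrum_ref, sequence, modifications = "",
                     score = 40, rank = 1L, is_decoy = FALSE,
                     accessions = "P1", charge = 2L) {
  data.frame(spectrum_ref = spectrum_ref, sequence = sequence,
             modifications = modifications, score = score, rank = rank,
             is_decoy = is_decoy, accessions = accessions, charge = charge,
             stringsAsFactors = FALSE)
}
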