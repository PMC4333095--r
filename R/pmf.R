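#' Monoisotopic residue masses
#'
#' Standard monoisotopic residue (i.e. water-free) masses in Da for the 20
#' amino acids, with the water and proton masses used to form neutral
#' peptide masses and singly protonated \[M+H\]+ ions. A fixed
#' modification (e.g. carbamidomethyl-C, +57.02146) can be applied per
#' residue.
#'
#' @param fixed_mods Optional named numeric vector of Da offsets applied to
#'   the named residues (e.g. `c(C = 57.02146)`). Default: none (no
#'   alkylation step by default).
#' @return A named numeric vector of residue masses with attributes `water`
#'   and `proton`.
#' @export
residue_masses <- function(fixed_mods = NULL) {
  m <- c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
    N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
    E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
    R = 156.10111, Y = 163.06333, W = 186.07931
  )
  if (!is.null(fixed_mods)) {
    bad <- setdiff(names(fixed_mods), names(m))
    if (length(bad)) abort(sprintf("unknown residue in fixed_mods: %s", bad[1]))
    m[names(fixed_mods)] <- m[names(fixed_mods)] + fixed_mods
  }
  attr(m, "water") <- 18.010565
  attr(m, "proton") <- 1.007276
  m
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus one water.
#'
#' @param sequence Character vector of peptide sequences.
#' @param masses Residue mass table from [residue_masses()].
#' @return Numeric vector of neutral monoisotopic masses in Da.
#' @examples
#' peptide_mass("G") # 75.0320
#' @export
peptide_mass <- function(sequence, masses = residue_masses()) {
  vapply(sequence, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    if (length(chars) == 0L) abort("empty peptide sequence")
    unknown <- setdiff(chars, names(masses))
    if (length(unknown)) {
      abort(sprintf("unknown residue '%s' in peptide", unknown[1]))
    }
    sum(masses[chars]) + attr(masses, "water")
  }, numeric(1), USE.NAMES = FALSE)
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the following residue is P (the
#' Keil rule; switchable). With `missed_cleavages = m`, every concatenation
#' of up to `m + 1` adjacent fully cleaved fragments is also emitted. The
#' zero-missed-cleavage fragments tile the parent exactly.
#'
#' @param protein A one-row protein sequence tibble, or a plain string.
#' @param missed_cleavages Maximum missed cleavages (default 0: complete
#'   digestion).
#' @param keil Apply the no-cleavage-before-proline rule (default `TRUE`).
#' @param masses Residue mass table.
#'
#' @return A tibble with one row per fragment: `sequence`, `start`, `end`
#'   (1-based inclusive on the parent), `missed_cleavages`, `neutral_mass`,
#'   `mh_plus`.
#' @examples
#' digest("AKPRGK")
#' @export
digest <- function(protein, missed_cleavages = 0L, keil = TRUE,
                   masses = residue_masses()) {
  seqstr <- if (is.data.frame(protein)) {
    stopifnot(nrow(protein) == 1L)
    if (protein$alphabet != "protein") abort("digest() requires a protein")
    protein$residues
  } else {
    as.character(protein)
  }
  if (!nzchar(seqstr)) abort("cannot digest an empty protein")
  chars <- strsplit(seqstr, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n]
  if (keil) cut_after <- cut_after[chars[cut_after + 1L] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  base <- tibble(start = starts, end = ends)
  m <- as.integer(missed_cleavages)
  frags <- purrr::map_dfr(0:m, function(k) {
    if (k + 1L > nrow(base)) return(NULL)
    idx <- seq_len(nrow(base) - k)
    tibble(
      start = base$start[idx], end = base$end[idx + k],
      missed_cleavages = k
    )
  })
  frags$sequence <- substring(seqstr, frags$start, frags$end)
  frags$neutral_mass <- peptide_mass(frags$sequence, masses)
  frags$mh_plus <- frags$neutral_mass + attr(masses, "proton")
  select(
    frags, sequence, start, end, missed_cleavages, neutral_mass, mh_plus
  ) %>%
    arrange(start, end)
}

#' Match observed peaks to theoretical fragments
#'
#' A peak matches a fragment when the relative error
#' `|observed - mh_plus| / mh_plus * 1e6` is at most `tolerance_ppm`
#' (inclusive) and the fragment's \[M+H\]+ lies inside the scanned mass
#' range. Each peak reports its best (smallest absolute ppm) match, ties
#' broken toward the smaller fragment start. Peaks are compared against
#' singly protonated masses by default, as in MALDI fingerprinting; set
#' `compare = "neutral"` to match neutral masses instead.
#'
#' @param peaks Numeric vector of observed m/z values, or a tibble with an
#'   `observed_mz` column.
#' @param fragments Fragment tibble from [digest()].
#' @param tolerance_ppm Mass tolerance in ppm (default 50).
#' @param mass_range Scanned mass window in Da (default `c(900, 4000)`).
#' @param compare `"mh_plus"` (default) or `"neutral"`.
#'
#' @return A tibble of matches: `observed_mz`, `fragment_start`,
#'   `fragment_end`, `sequence`, `mh_plus`, `error_ppm`. Unmatched peaks are
#'   absent.
#' @export
match_peaks <- function(peaks, fragments, tolerance_ppm = 50,
                        mass_range = c(900, 4000),
                        compare = c("mh_plus", "neutral")) {
  compare <- match.arg(compare)
  if (is.data.frame(peaks)) peaks <- peaks$observed_mz
  if (any(peaks <= 0)) abort("peaks must be positive m/z values")
  if (nrow(fragments) == 0L) {
    return(tibble(
      observed_mz = numeric(), fragment_start = integer(),
      fragment_end = integer(), sequence = character(),
      mh_plus = numeric(), error_ppm = numeric()
    ))
  }
  theo <- if (compare == "mh_plus") fragments$mh_plus else fragments$neutral_mass
  in_range <- theo >= mass_range[1] & theo <= mass_range[2]
  purrr::map_dfr(peaks, function(mz) {
    ppm <- (mz - theo) / theo * 1e6
    ok <- which(in_range & abs(ppm) <= tolerance_ppm)
    if (length(ok) == 0L) return(NULL)
    ord <- ok[order(abs(ppm[ok]), fragments$start[ok])]
    b <- ord[1]
    tibble(
      observed_mz = mz,
      fragment_start = fragments$start[b], fragment_end = fragments$end[b],
      sequence = fragments$sequence[b], mh_plus = fragments$mh_plus[b],
      error_ppm = ppm[b]
    )
  })
}

#' Sequence coverage of matched fragments
#'
#' @param matches Match tibble from [match_peaks()].
#' @param protein_length Parent protein length in residues.
#' @param n_total_fragments Optional total theoretical fragment count to
#'   report alongside.
#' @return One-row tibble: `covered_residues`, `fraction`,
#'   `n_matched_fragments` (distinct fragment spans), `n_total_fragments`.
#' @export
pmf_coverage <- function(matches, protein_length, n_total_fragments = NA_integer_) {
  if (nrow(matches) == 0L) {
    return(tibble(
      covered_residues = 0L, fraction = 0,
      n_matched_fragments = 0L, n_total_fragments = n_total_fragments
    ))
  }
  spans <- distinct(matches, fragment_start, fragment_end)
  ir <- IRanges::reduce(IRanges::IRanges(
    start = spans$fragment_start, end = spans$fragment_end
  ))
  covered <- sum(IRanges::width(ir))
  tibble(
    covered_residues = as.integer(covered),
    fraction = covered / protein_length,
    n_matched_fragments = nrow(spans),
    n_total_fragments = n_total_fragments
  )
}
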