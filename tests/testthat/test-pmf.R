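test_that("peptide masses agree with an independent monoisotopic oracle", {
  for (p in names(PYTEOMICS_MASSES)) {
    expect_equal(peptide_mass(p), PYTEOMICS_MASSES[[p]], tolerance = 1e-4)
  }
  expect_equal(round(peptide_mass("G"), 4), 75.0320)
  expect_equal(round(peptide_mass("GG"), 4), 132.0535)
  expect_error(peptide_mass("AB"), "unknown residue 'B'")
  expect_error(peptide_mass(""), "empty")
  # fixed modification shifts by the configured offset
  cam <- residue_masses(fixed_mods = c(C = 57.02146))
  expect_equal(
    peptide_mass("AC", cam) - peptide_mass("AC"), 57.02146,
    tolerance = 1e-6
  )
})

test_that("tryptic digestion follows the Keil rule", {
  frags <- digest("AKPRGK")
  expect_equal(frags$sequence, c("AKPR", "GK"))
  expect_equal(frags$start, c(1L, 5L))
  expect_equal(frags$end, c(4L, 6L))
  # switchable: without the proline exception AK|PR|GK
  expect_equal(digest("AKPRGK", keil = FALSE)$sequence, c("AK", "PR", "GK"))
  expect_equal(digest("MAGICSTEW")$sequence, "MAGICSTEW")
  expect_error(digest(""), "empty")
})

test_that("missed-cleavage expansion emits adjacent concatenations", {
  frags <- digest("GKGK", missed_cleavages = 1)
  expect_equal(sort(frags$sequence), c("GK", "GK", "GKGK"))
  expect_equal(frags$missed_cleavages[frags$sequence == "GKGK"], 1L)
  # m = 2 on three fragments adds the full-length concatenation
  f2 <- digest("GKGKGK", missed_cleavages = 2)
  expect_equal(sum(f2$missed_cleavages == 0), 3L)
  expect_equal(sum(f2$missed_cleavages == 1), 2L)
  expect_equal(sum(f2$missed_cleavages == 2), 1L)
})

test_that("complete digestion partitions the parent", {
  set.seed(31)
  water <- attr(residue_masses(), "water")
  for (i in 1:25) {
    prot <- random_protein_text(sample(30:300, 1))
    frags <- digest(prot)
    # concatenating in order reproduces the parent
    expect_equal(paste(frags$sequence, collapse = ""), prot)
    # fragment count = cleavage sites + 1
    chars <- strsplit(prot, "")[[1]]
    n <- length(chars)
    sites <- sum(
      chars[-n] %in% c("K", "R") & chars[-1] != "P"
    )
    expect_equal(nrow(frags), sites + 1L)
    # mass balance up to the waters released at each cleavage
    expect_equal(
      sum(frags$neutral_mass) - (nrow(frags) - 1L) * water,
      peptide_mass(prot),
      tolerance = 1e-3
    )
  }
})

test_that("peak matching applies ppm tolerance inclusively and a mass window", {
  frag <- tibble::tibble(
    sequence = "X", start = 1L, end = 9L, missed_cleavages = 0L,
    neutral_mass = 1000 - 1.007276, mh_plus = 1000
  )
  at50 <- match_peaks(1000.0500, frag)
  expect_equal(nrow(at50), 1L)
  expect_equal(at50$error_ppm, 50, tolerance = 1e-6)
  expect_equal(nrow(match_peaks(1000.06, frag)), 0L)

  low <- dplyr::mutate(frag, mh_plus = 850, neutral_mass = 850 - 1.007276)
  expect_equal(nrow(match_peaks(850, low)), 0L) # outside 900-4000 Da
  expect_equal(nrow(match_peaks(850, low, mass_range = c(800, 4000))), 1L)
  expect_equal(nrow(match_peaks(1000, frag[0, ])), 0L)
})

test_that("each peak takes its best match with a positional tie-break", {
  frags <- tibble::tibble(
    sequence = c("A", "B", "C"), start = c(10L, 1L, 30L),
    end = c(18L, 9L, 38L), missed_cleavages = 0L,
    neutral_mass = c(1000, 1000, 1000.02) - 1.007276,
    mh_plus = c(1000, 1000, 1000.02)
  )
  m <- match_peaks(1000.0, frags)
  expect_equal(nrow(m), 1L)
  expect_equal(m$sequence, "B") # 0 ppm tie broken toward smaller start
  m2 <- match_peaks(1000.019, frags)
  expect_equal(m2$sequence, "C") # closer in ppm wins outright
})

test_that("coverage is the union of matched spans", {
  m <- tibble::tibble(
    observed_mz = c(1, 2), fragment_start = c(1L, 6L),
    fragment_end = c(10L, 20L), sequence = "x", mh_plus = 1, error_ppm = 0
  )
  cov <- pmf_coverage(m, protein_length = 100)
  expect_equal(cov$covered_residues, 20L)
  expect_equal(cov$fraction, 0.20)
  expect_equal(pmf_coverage(m[0, ], 100)$fraction, 0)
  full <- tibble::tibble(
    observed_mz = 1, fragment_start = 1L, fragment_end = 100L,
    sequence = "x", mh_plus = 1, error_ppm = 0
  )
  expect_equal(pmf_coverage(full, 100)$fraction, 1)
})

test_that("coverage grows monotonically as matches accumulate", {
  set.seed(41)
  prot <- seq_record("p", random_protein_text(400), "protein")
  frags <- digest(prot)
  in_range <- frags[frags$mh_plus >= 900 & frags$mh_plus <= 4000, ]
  prev <- 0
  for (k in seq_len(nrow(in_range))) {
    m <- match_peaks(in_range$mh_plus[seq_len(k)], frags)
    cov <- pmf_coverage(m, 400)
    expect_gte(cov$fraction, prev)
    expect_lte(cov$fraction, 1)
    prev <- cov$fraction
  }
})

test_that("synthetic fingerprints are identified with no false calls", {
  set.seed(43)
  for (i in 1:5) {
    sim_p <- sim_protein_with_fingers(600, seed = 500 + i)
    frags <- digest(sim_p$protein)
    n_in_range <- sum(frags$mh_plus >= 900 & frags$mh_plus <= 4000)
    expect_gte(n_in_range, 8L) # typical digest of a 600-residue protein
    pk <- sim_peak_list(
      sim_p$protein,
      n_true_peaks = min(8L, n_in_range),
      ppm_jitter_sd = 10, n_decoys = 6, seed = 600 + i
    )
    m <- match_peaks(pk$peaks$observed_mz, frags)
    true_mz <- pk$peaks$observed_mz[!pk$peaks$is_decoy]
    decoy_mz <- pk$peaks$observed_mz[pk$peaks$is_decoy]
    # zero false negatives: every genuine peak is matched
    expect_true(all(true_mz %in% m$observed_mz))
    # zero decoys matched (placed >= 3x tolerance from all masses)
    expect_false(any(decoy_mz %in% m$observed_mz))
    # matched assignments reproduce the manifest's coverage exactly
    cov <- pmf_coverage(
      m[m$observed_mz %in% true_mz, ],
      nchar(sim_p$protein$residues)
    )
    expect_equal(cov$covered_residues, pk$expected_coverage$covered_residues)
  }
})
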