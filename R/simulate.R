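# Seeded generators with planted ground truth. Backgrounds are
# rejection-scrubbed so the only motif/finger occurrences are the planted
# ones, which makes downstream recovery assertions exact.

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Sample one concrete instance of a gapped motif with the given spacer.
sample_motif_instance <- function(motif, gap) {
  pick <- function(sets) {
    vapply(sets, function(s) sample(s, 1L), character(1))
  }
  paste0(
    paste(pick(motif$left), collapse = ""),
    random_dna(gap),
    paste(pick(motif$right), collapse = "")
  )
}

splice_at <- function(text, start, replacement) {
  end <- start + nchar(replacement) - 1L
  paste0(
    substr(text, 1L, start - 1L), replacement,
    substr(text, end + 1L, nchar(text))
  )
}

# Rerandomize background bases inside offending intervals until a scan finds
# exactly the expected footprints. Only the planted half-site blocks are
# immutable: a planted element's spacer is unconstrained by the motif, so it
# may be resampled when an accidental match runs through it (otherwise an
# accidental hit nested in a long spacer could never be removed).
half_site_blocks <- function(plants, motif) {
  if (nrow(plants) == 0L) {
    return(tibble(start = integer(), end = integer()))
  }
  # a plant may sit on either strand, so the wider half-site length is
  # protected at both ends; only interior spacer bases stay mutable
  w <- max(length(motif$left), length(motif$right))
  bind_rows(
    tibble(start = plants$start, end = pmin(plants$start + w - 1L, plants$end)),
    tibble(start = pmax(plants$end - w + 1L, plants$start), end = plants$end)
  )
}

scrub_motif_hits <- function(text, expected, protect_blocks, motif,
                             gc = 0.5, max_iter = 100L) {
  expected_key <- if (nrow(expected)) {
    paste(expected$start, expected$end)
  } else {
    character()
  }
  in_protect <- function(pos) {
    nrow(protect_blocks) > 0L &&
      any(pos >= protect_blocks$start & pos <= protect_blocks$end)
  }
  for (iter in seq_len(max_iter)) {
    fps <- dedupe_footprints(
      scan_motif(seq_record("tmp", text, "DNA"), motif)
    )
    extra <- fps[!paste(fps$start, fps$end) %in% expected_key, ]
    if (nrow(extra) == 0L) return(text)
    for (i in seq_len(nrow(extra))) {
      for (pos in extra$start[i]:extra$end[i]) {
        if (!in_protect(pos)) {
          text <- splice_at(text, pos, random_dna(1L, gc))
        }
      }
    }
  }
  abort("could not scrub accidental motif hits from the background")
}

#' Simulate DNA with planted ZTREs
#'
#' Draws a background sequence at the requested GC content, plants one
#' concrete element instance (each degenerate position sampled from its
#' residue set, spacer random) per request, and rejection-scrubs the
#' background so no accidental footprints exist outside the planted
#' intervals. A plant with a spacer outside the motif's gap range is
#' emitted literally but flagged invalid (a negative control the scanner
#' must not report).
#'
#' @param length Sequence length in bp.
#' @param plants Tibble with columns `position` (1-based start), `gap_len`,
#'   `strand`; may be empty.
#' @param motif A [gapped_motif()] (default ZTRE consensus).
#' @param gc Background GC fraction.
#' @param seed Integer seed; fixed seed gives identical output.
#'
#' @return A list: `sequence` (a sequence tibble) and `truth` (tibble
#'   `start`, `end`, `gap_len`, `strand`, `valid`, `instance`).
#' @export
sim_dna_with_ztres <- function(length, plants = tibble(), motif = ztre_motif(),
                               gc = 0.5, seed) {
  withr::with_seed(seed, {
    if (nrow(plants) > 0L) {
      plants <- mutate(
        plants,
        start = as.integer(position),
        end = as.integer(position + motif_width(motif, gap_len) - 1L),
        valid = gap_len >= motif$gap_min & gap_len <= motif$gap_max
      )
      if (any(plants$end > length) || any(plants$start < 1L)) {
        abort("planted motif extends beyond the sequence")
      }
      o <- order(plants$start)
      if (any(plants$start[o][-1] <= plants$end[o][-nrow(plants)])) {
        abort("planted motifs overlap")
      }
    }
    text <- random_dna(length, gc)
    inst <- character(nrow(plants))
    for (i in seq_len(nrow(plants))) {
      wide <- motif
      wide$gap_min <- min(wide$gap_min, plants$gap_len[i])
      wide$gap_max <- max(wide$gap_max, plants$gap_len[i])
      ins <- sample_motif_instance(wide, plants$gap_len[i])
      if (plants$strand[i] == "-") ins <- reverse_complement(ins)
      inst[i] <- ins
      text <- splice_at(text, plants$start[i], ins)
    }
    expected <- if (nrow(plants)) {
      plants[plants$valid, c("start", "end")]
    } else {
      tibble(start = integer(), end = integer())
    }
    text <- scrub_motif_hits(
      text, expected, half_site_blocks(plants, motif), motif, gc
    )
    truth <- if (nrow(plants)) {
      tibble(
        start = plants$start, end = plants$end, gap_len = plants$gap_len,
        strand = plants$strand, valid = plants$valid, instance = inst
      )
    } else {
      tibble(
        start = integer(), end = integer(), gap_len = integer(),
        strand = character(), valid = logical(), instance = character()
      )
    }
    list(sequence = seq_record("sim_dna", text, "DNA"), truth = truth)
  })
}

#' Simulate an anchor panel with contrasting element densities
#'
#' Builds a single reference carrying `n_targets + n_neighbors` anchor
#' windows of `2 * flank + 1` bp laid end to end with spacing between them.
#' Target windows receive Poisson(`target_density_per_kb` x window kb)
#' planted elements and neighbor windows Poisson(`background_density_per_kb`
#' x window kb), at non-overlapping random positions; the background is
#' scrubbed of accidental footprints.
#'
#' @param n_targets,n_neighbors Number of windows per group.
#' @param target_density_per_kb,background_density_per_kb Planting rates.
#' @param flank Half-window in bp (default 1000).
#' @param spacing Background bp between consecutive windows.
#' @param gap_range Spacer lengths sampled uniformly for planted elements.
#' @param motif,gc,seed As in [sim_dna_with_ztres()].
#'
#' @return A list: `reference` (sequence tibble), `anchors` (with `group`
#'   column, `"target"` / `"neighbor"`), `truth` (planted footprints with
#'   window and group) and `expected` (per-group planted counts and
#'   densities).
#' @export
sim_anchor_panel <- function(n_targets = 5L, n_neighbors = 5L,
                             target_density_per_kb = 0.71,
                             background_density_per_kb = 0.15,
                             flank = 1000L, spacing = 200L,
                             gap_range = c(0L, 50L),
                             motif = ztre_motif(), gc = 0.5, seed) {
  withr::with_seed(seed, {
    win_len <- 2L * flank + 1L
    n_win <- n_targets + n_neighbors
    groups <- c(rep("target", n_targets), rep("neighbor", n_neighbors))
    total_len <- n_win * (win_len + spacing) + spacing
    plants <- list()
    anchors <- list()
    for (w in seq_len(n_win)) {
      win_start <- spacing + (w - 1L) * (win_len + spacing) + 1L
      anchor_pos <- win_start + flank
      lambda <- if (groups[w] == "target") {
        target_density_per_kb
      } else {
        background_density_per_kb
      }
      n_plant <- rpois(1L, lambda * win_len / 1000)
      placed <- tibble(start = integer(), end = integer(), gap_len = integer())
      tries <- 0L
      while (nrow(placed) < n_plant && tries < 500L) {
        tries <- tries + 1L
        gap <- sample(gap_range[1]:gap_range[2], 1L)
        w_bp <- motif_width(motif, gap)
        s <- sample(win_start:(win_start + win_len - w_bp), 1L)
        e <- s + w_bp - 1L
        if (nrow(placed) == 0L ||
          all(e < placed$start - 1L | s > placed$end + 1L)) {
          placed <- bind_rows(placed, tibble(start = s, end = e, gap_len = gap))
        }
      }
      if (nrow(placed) < n_plant) {
        abort("requested density too high to place non-overlapping elements")
      }
      if (nrow(placed)) {
        placed$window <- w
        placed$group <- groups[w]
        plants[[length(plants) + 1L]] <- placed
      }
      anchors[[w]] <- tibble(
        seq_id = "sim_ref", position = anchor_pos, strand = "+",
        label = sprintf("%s_%02d", groups[w], w), group = groups[w]
      )
    }
    plants <- bind_rows(plants)
    if (nrow(plants) == 0L) {
      plants <- tibble(
        start = integer(), end = integer(), gap_len = integer(),
        window = integer(), group = character()
      )
    }
    text <- random_dna(total_len, gc)
    if (nrow(plants)) {
      plants <- arrange(plants, start)
      for (i in seq_len(nrow(plants))) {
        text <- splice_at(
          text, plants$start[i],
          sample_motif_instance(motif, plants$gap_len[i])
        )
      }
    }
    expected <- if (nrow(plants)) {
      plants[, c("start", "end")]
    } else {
      tibble(start = integer(), end = integer())
    }
    text <- scrub_motif_hits(
      text, expected, half_site_blocks(plants, motif), motif, gc
    )
    anchors <- bind_rows(anchors)
    expected <- tibble(group = c("target", "neighbor")) %>%
      mutate(
        n_planted = vapply(
          group, function(g) sum(plants$group == g), integer(1),
          USE.NAMES = FALSE
        ),
        mapped_kb = c(n_targets, n_neighbors) * win_len / 1000,
        density = n_planted / mapped_kb
      )
    list(
      reference = seq_record("sim_ref", text, "DNA"),
      anchors = anchors,
      truth = plants,
      expected = expected
    )
  })
}

#' Simulate a protein with planted zinc fingers
#'
#' Plants 21-residue finger instances (canonical or one of the two
#' variants) at the requested positions in a background whose residues are
#' drawn with a configurable combined K/R fraction (so tryptic fragment
#' counts are controllable). Finger-internal spacer residues avoid C, H and
#' R; the background is scrubbed of accidental pattern hits.
#'
#' @param length Protein length in residues.
#' @param fingers Tibble with `position` (1-based start) and
#'   `configuration` (`"canonical"`, `"H-C-H2"`, `"C2-H-R"`).
#' @param kr_fraction Combined background frequency of K and R.
#' @param seed Integer seed.
#'
#' @return A list: `protein` (sequence tibble) and `truth` (tibble `start`,
#'   `end`, `configuration`).
#' @export
sim_protein_with_fingers <- function(length, fingers = tibble(),
                                     kr_fraction = 0.1, seed) {
  withr::with_seed(seed, {
    p <- zf_pattern()
    w <- zf_width(p)
    aa <- PROTEIN_LETTERS
    probs <- setNames(rep((1 - kr_fraction) / 18, 20), aa)
    probs[c("K", "R")] <- kr_fraction / 2
    random_protein <- function(n) {
      paste(sample(aa, n, replace = TRUE, prob = probs), collapse = "")
    }
    spacer_aa <- setdiff(aa, c("C", "H", "R"))
    make_finger <- function(configuration) {
      x <- function(n) {
        paste(sample(spacer_aa, n, replace = TRUE), collapse = "")
      }
      c1 <- if (configuration == "H-C-H2") "H" else "C"
      c4 <- if (configuration == "C2-H-R") "R" else "H"
      paste0(c1, x(p$spacer1), "C", x(p$spacer2), "H", x(p$spacer3), c4)
    }
    if (nrow(fingers) > 0L) {
      fingers <- mutate(
        fingers,
        start = as.integer(position), end = as.integer(position + w - 1L)
      )
      o <- order(fingers$start)
      if (any(fingers$start[o][-1] <= fingers$end[o][-nrow(fingers)])) {
        abort("planted fingers overlap")
      }
      if (any(fingers$end > length)) {
        abort("planted finger extends beyond the protein")
      }
    }
    text <- random_protein(length)
    for (i in seq_len(nrow(fingers))) {
      text <- splice_at(
        text, fingers$start[i], make_finger(fingers$configuration[i])
      )
    }
    protect <- if (nrow(fingers)) {
      fingers[, c("start", "end")]
    } else {
      tibble(start = integer(), end = integer())
    }
    key <- paste(protect$start, protect$end)
    for (iter in seq_len(100L)) {
      ann <- scan_zinc_fingers(seq_record("tmp", text, "protein"))
      extra <- ann[!paste(ann$start, ann$end) %in% key, ]
      if (nrow(extra) == 0L) break
      for (i in seq_len(nrow(extra))) {
        for (pos in extra$start[i]:extra$end[i]) {
          if (!(nrow(protect) &&
            any(pos >= protect$start & pos <= protect$end))) {
            text <- splice_at(text, pos, random_protein(1L))
          }
        }
      }
      if (iter == 100L) abort("could not scrub accidental finger hits")
    }
    truth <- if (nrow(fingers)) {
      select(fingers, start, end, configuration)
    } else {
      tibble(start = integer(), end = integer(), configuration = character())
    }
    list(protein = seq_record("sim_protein", text, "protein"), truth = truth)
  })
}

#' Simulate a MALDI peak list from a theoretical digest
#'
#' Selects `n_true_peaks` in-range fragments of the protein's tryptic
#' digest, jitters their \[M+H\]+ values by Normal(0, `ppm_jitter_sd`) ppm,
#' and adds decoy peaks placed at least `3 x tolerance_ppm` away from every
#' theoretical fragment mass (so no decoy can be matched).
#'
#' @param protein A one-row protein sequence tibble.
#' @param n_true_peaks Number of genuine peaks.
#' @param ppm_jitter_sd Mass jitter SD in ppm (default 10).
#' @param n_decoys Number of decoy peaks.
#' @param tolerance_ppm Matching tolerance the decoys must evade.
#' @param mass_range Scanned mass window in Da.
#' @param missed_cleavages Digest parameter.
#' @param seed Integer seed.
#'
#' @return A list: `peaks` (tibble `observed_mz`, `is_decoy`), `truth`
#'   (selected fragments) and `expected_coverage` (one-row tibble from the
#'   manifest's span union).
#' @export
sim_peak_list <- function(protein, n_true_peaks, ppm_jitter_sd = 10,
                          n_decoys = 5L, tolerance_ppm = 50,
                          mass_range = c(900, 4000), missed_cleavages = 0L,
                          seed) {
  withr::with_seed(seed, {
    frags <- digest(protein, missed_cleavages = missed_cleavages)
    in_range <- frags[
      frags$mh_plus >= mass_range[1] & frags$mh_plus <= mass_range[2],
    ]
    if (n_true_peaks > nrow(in_range)) {
      abort("n_true_peaks exceeds the number of in-range fragments")
    }
    chosen <- in_range[sample(nrow(in_range), n_true_peaks), ] %>%
      arrange(start)
    observed <- chosen$mh_plus * (1 + rnorm(n_true_peaks, 0, ppm_jitter_sd) / 1e6)
    decoys <- numeric(0)
    tries <- 0L
    while (length(decoys) < n_decoys) {
      tries <- tries + 1L
      if (tries > 10000L) abort("could not place decoys away from all masses")
      cand <- runif(1, mass_range[1], mass_range[2])
      ppm_dist <- abs(cand - frags$mh_plus) / frags$mh_plus * 1e6
      if (all(ppm_dist >= 3 * tolerance_ppm)) decoys <- c(decoys, cand)
    }
    peaks <- tibble(
      observed_mz = c(observed, decoys),
      is_decoy = c(rep(FALSE, n_true_peaks), rep(TRUE, length(decoys)))
    )
    prot_len <- nchar(protein$residues[1])
    cov <- if (nrow(chosen)) {
      ir <- IRanges::reduce(IRanges::IRanges(chosen$start, chosen$end))
      sum(IRanges::width(ir))
    } else {
      0L
    }
    list(
      peaks = peaks, truth = chosen,
      expected_coverage = tibble(
        covered_residues = as.integer(cov),
        fraction = cov / prot_len
      )
    )
  })
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Encodes each gene's true fold change at the treatment condition as a
#' `-log2(fold)` Ct shift relative to the calibrator condition, plus
#' Normal(0, `noise_sd`) cycle noise; the reference gene is flat across
#' conditions. With `noise_sd = 0`, [ddct()] recovers the folds exactly.
#'
#' @param fold_changes Named numeric vector of true fold changes (> 0) for
#'   the target genes at the treatment condition.
#' @param conditions Length-2 character vector, calibrator first.
#' @param reference_gene Reference gene label.
#' @param n_per_condition Samples per condition.
#' @param base_ct Baseline Ct.
#' @param noise_sd Ct noise SD in cycles.
#' @param seed Integer seed.
#'
#' @return A list: `records` (tibble `sample_id`, `condition`, `gene`,
#'   `ct`) and `truth` (tibble `gene`, `true_fold`).
#' @export
sim_ct_table <- function(fold_changes,
                         conditions = c("3 uM zinc", "100 uM zinc"),
                         reference_gene = "GAPDH", n_per_condition = 3L,
                         base_ct = 25, noise_sd = 0.2, seed) {
  if (any(fold_changes <= 0)) abort("fold changes must be positive")
  stopifnot(length(conditions) == 2L)
  withr::with_seed(seed, {
    genes <- c(names(fold_changes), reference_gene)
    grid <- tidyr::expand_grid(
      condition = conditions,
      replicate = seq_len(n_per_condition),
      gene = genes
    )
    grid$sample_id <- sprintf(
      "%s_rep%d", gsub("[^A-Za-z0-9]+", "_", grid$condition), grid$replicate
    )
    shift <- function(gene, condition) {
      ifelse(
        gene == reference_gene | condition == conditions[1],
        0,
        -log2(fold_changes[gene])
      )
    }
    grid$ct <- base_ct + shift(grid$gene, grid$condition) +
      rnorm(nrow(grid), 0, noise_sd)
    list(
      records = select(grid, sample_id, condition, gene, ct),
      truth = tibble(gene = names(fold_changes), true_fold = unname(fold_changes))
    )
  })
}

#' Simulate a normalized expression matrix with planted effects
#'
#' Baseline per-gene log2 intensities are Normal(8, 1); planted up/down
#' genes get a +/- log2(`fold`) group effect in the treatment group;
#' Normal(0, `noise_sd`) log2 noise is added throughout and intensities are
#' returned on the linear scale. Detection p-values are small for expressed
#' probes; a fraction of null probes is marked undetected (p >= 0.01).
#'
#' @param n_genes Number of probes.
#' @param n_per_group Samples per group (default 3, two groups:
#'   `"control"`, `"knockdown"`).
#' @param n_up,n_down Planted up-/down-regulated gene counts.
#' @param fold Planted linear fold change (>= 1; default 1.5).
#' @param noise_sd Log2 replicate noise SD (default 0.15, typical of
#'   well-detected bead-array probes after variance-stabilizing
#'   normalization).
#' @param undetected_fraction Fraction of null probes given a failing
#'   detection p-value.
#' @param seed Integer seed.
#'
#' @return A list: `matrix` (tibble `probe_id` + sample columns, linear
#'   scale), `groups` (character vector per sample column), `detection`
#'   (tibble `probe_id`, `detection_p`) and `truth` (tibble `probe_id`,
#'   `direction`, `true_fold`).
#' @export
sim_expression_matrix <- function(n_genes = 500L, n_per_group = 3L,
                                  n_up = 10L, n_down = 10L, fold = 1.5,
                                  noise_sd = 0.15,
                                  undetected_fraction = 0.05, seed) {
  if (fold < 1) abort("planted fold must be >= 1")
  withr::with_seed(seed, {
    probe_id <- sprintf("probe_%04d", seq_len(n_genes))
    direction <- rep("null", n_genes)
    direction[seq_len(n_up)] <- "up"
    direction[n_up + seq_len(n_down)] <- "down"
    base <- rnorm(n_genes, 8, 1)
    effect <- ifelse(
      direction == "up", log2(fold),
      ifelse(direction == "down", -log2(fold), 0)
    )
    groups <- c(rep("control", n_per_group), rep("knockdown", n_per_group))
    mat <- sapply(seq_along(groups), function(j) {
      mu <- base + if (groups[j] == "knockdown") effect else 0
      2^(mu + rnorm(n_genes, 0, noise_sd))
    })
    colnames(mat) <- sprintf("%s_%d", groups, c(
      seq_len(n_per_group), seq_len(n_per_group)
    ))
    undetected <- direction == "null" &
      runif(n_genes) < undetected_fraction
    detection_p <- ifelse(undetected, runif(n_genes, 0.02, 0.5),
      runif(n_genes, 0, 0.009)
    )
    list(
      matrix = bind_cols(tibble(probe_id = probe_id), as_tibble(mat)),
      groups = groups,
      detection = tibble(probe_id = probe_id, detection_p = detection_p),
      truth = tibble(
        probe_id = probe_id[direction != "null"],
        direction = direction[direction != "null"],
        true_fold = fold
      )
    )
  })
}
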