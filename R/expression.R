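#' Relative quantification by the delta-delta-Ct method
#'
#' Per sample, the target gene's Ct is referenced to a housekeeping gene
#' (`delta Ct = Ct_target - Ct_reference`); per condition, the mean delta Ct
#' is referenced to the calibrator condition (`delta delta Ct`), and the
#' relative level is `2^(-ddCt)` assuming 100% amplification efficiency. The
#' calibrator's relative level is 1 by construction.
#'
#' @param records A Ct tibble with columns `sample_id`, `condition`, `gene`,
#'   `ct` (cycles, > 0).
#' @param target_gene,reference_gene Gene labels present in every sample.
#' @param calibrator Condition label used as baseline (e.g. `"3 uM zinc"`).
#'
#' @return A tibble with one row per condition: `condition`, `n_samples`,
#'   `mean_delta_ct`, `ddct`, `relative_level`.
#' @export
ddct <- function(records, target_gene, reference_gene, calibrator) {
  need <- c("sample_id", "condition", "gene", "ct")
  stopifnot(all(need %in% names(records)))
  if (any(records$ct <= 0)) abort("Ct values must be positive")
  if (!reference_gene %in% records$gene) {
    abort(sprintf("reference gene '%s' not present", reference_gene))
  }
  if (!target_gene %in% records$gene) {
    abort(sprintf("target gene '%s' not present", target_gene))
  }
  if (!calibrator %in% records$condition) {
    abort(sprintf("calibrator condition '%s' not present", calibrator))
  }
  per_sample <- records %>%
    filter(gene %in% c(target_gene, reference_gene)) %>%
    tidyr::pivot_wider(
      id_cols = c(sample_id, condition), names_from = gene, values_from = ct
    )
  if (anyNA(per_sample[[target_gene]]) || anyNA(per_sample[[reference_gene]])) {
    abort("target and reference genes must be measured in every sample")
  }
  per_sample$delta_ct <-
    per_sample[[target_gene]] - per_sample[[reference_gene]]
  by_cond <- per_sample %>%
    group_by(condition) %>%
    summarise(
      n_samples = n(), mean_delta_ct = mean(delta_ct), .groups = "drop"
    )
  cal <- by_cond$mean_delta_ct[by_cond$condition == calibrator]
  mutate(
    by_cond,
    ddct = mean_delta_ct - cal,
    relative_level = 2^(-ddct)
  )
}

#' Dilution-corrected abundance ratio from Ct values
#'
#' Ratio of a high-abundance to a low-abundance species measured by qPCR
#' when the high-abundance template was diluted `dilution_factor`-fold:
#' `ratio = dilution_factor * 2^(ct_low_abundant - ct_high_abundant)`,
#' assuming 100% efficiency.
#'
#' @param ct_low_abundant,ct_high_abundant Ct values (cycles).
#' @param dilution_factor Fold dilution applied to the high-abundance
#'   template (>= 1).
#' @return Fold ratio (high over low abundance).
#' @examples
#' abundance_ratio_from_ct(26.54, 20, dilution_factor = 20)
#' @export
abundance_ratio_from_ct <- function(ct_low_abundant, ct_high_abundant,
                                    dilution_factor = 1) {
  if (any(dilution_factor < 1)) {
    abort("dilution factor must be >= 1")
  }
  dilution_factor * 2^(ct_low_abundant - ct_high_abundant)
}

#' Rank-product differential expression
#'
#' Nonparametric two-group test: in each comparison of a treatment replicate
#' against a control replicate, genes are ranked by fold change (average
#' ranks for ties), and the rank product is the geometric mean of a gene's
#' ranks across comparisons. With `comparisons = "paired"` (default, the
#' original formulation) replicate i of the treatment group is compared to
#' replicate i of the control group, so the per-comparison fold changes —
#' and hence ranks — are independent across comparisons under the null,
#' which is what the permutation/enumeration null models. With
#' `"all_pairs"` every treatment replicate is compared against every
#' control replicate; this reuses each sample in several comparisons, so
#' ranks are positively correlated across comparisons and the independent
#' null is only an approximation (the `"within_probe"` null preserves that
#' correlation instead). Up- and down-regulation are tested by
#' two separate one-sided analyses. Significance is an estimated
#' false-positive proportion (pfp): the expected number of null genes with a
#' rank product at least as extreme, divided by the gene's rank-product
#' rank. The null is generated by drawing, per comparison, uniform random
#' rank permutations (`pfp_method = "uniform"`, the standard rank-product
#' null; seeded and deterministic), by shuffling each probe's values across
#' its samples (`"within_probe"`; conservative when many genes carry real
#' effects, which contaminate their own null), or, for tiny instances, by
#' exhaustive enumeration of all equally likely rank configurations
#' (`"exact"`).
#'
#' @param x Expression data: a tibble whose first column is `probe_id`
#'   followed by one numeric column per sample, or a numeric matrix with
#'   probe rownames. Intensities are linear unless `scale = "log2"`.
#' @param groups Character vector, one group label per sample column.
#' @param treatment,control The two group labels to compare
#'   (treatment / control fold changes).
#' @param n_permutations Number of null permutations (default 10000).
#' @param seed Integer seed for the permutation null.
#' @param pfp_method `"permutation"` or `"exact"`.
#' @param scale `"linear"` (default) or `"log2"` (inputs are inverse
#'   transformed before fold changes are formed).
#' @param comparisons `"paired"` (default; replicate i vs replicate i,
#'   requires equal group sizes) or `"all_pairs"` (every treatment vs every
#'   control replicate).
#'
#' @return An object of class `rank_product`: a list with `results` (tibble
#'   with `probe_id`, `fold_change`, `rp_up`, `pfp_up`, `rp_down`,
#'   `pfp_down`, `direction`) and the call parameters. Use [tidy()] /
#'   [glance()] to extract tibbles.
#' @export
rank_product <- function(x, groups, treatment, control,
                         n_permutations = 10000L, seed = NULL,
                         pfp_method = c("uniform", "within_probe", "exact"),
                         scale = c("linear", "log2"),
                         comparisons = c("paired", "all_pairs")) {
  pfp_method <- match.arg(pfp_method)
  scale <- match.arg(scale)
  comparisons <- match.arg(comparisons)
  if (is.data.frame(x)) {
    probe_id <- as.character(x[[1]])
    mat <- as.matrix(x[, -1, drop = FALSE])
  } else {
    probe_id <- rownames(x)
    mat <- x
  }
  if (scale == "log2") mat <- 2^mat
  stopifnot(length(groups) == ncol(mat))
  t_idx <- which(groups == treatment)
  c_idx <- which(groups == control)
  if (length(t_idx) < 2L || length(c_idx) < 2L) {
    abort("each group needs at least 2 samples")
  }
  G <- nrow(mat)
  pairs <- if (comparisons == "paired") {
    if (length(t_idx) != length(c_idx)) {
      abort("paired comparisons need equal group sizes; use comparisons = \"all_pairs\"")
    }
    data.frame(t = t_idx, c = c_idx)
  } else {
    expand.grid(t = t_idx, c = c_idx)
  }
  K <- nrow(pairs)
  fc <- vapply(
    seq_len(K),
    function(k) mat[, pairs$t[k]] / mat[, pairs$c[k]],
    numeric(G)
  )
  rp_of <- function(fold_cols, decreasing) {
    r <- apply(fold_cols, 2, function(col) {
      rank(if (decreasing) -col else col, ties.method = "average")
    })
    exp(rowMeans(log(r)))
  }
  rp_up <- rp_of(fc, decreasing = TRUE)
  rp_down <- rp_of(fc, decreasing = FALSE)
  null_rps <- switch(pfp_method,
    uniform = rp_null_uniform(G, K, n_permutations, seed),
    within_probe = rp_null_permutation(mat, pairs, n_permutations, seed),
    exact = rp_null_exact(G, K)
  )
  fold_change <- rowMeans(mat[, t_idx, drop = FALSE]) /
    rowMeans(mat[, c_idx, drop = FALSE])
  results <- tibble(
    probe_id = probe_id,
    fold_change = fold_change,
    rp_up = rp_up,
    pfp_up = pfp_from_null(rp_up, null_rps$up),
    rp_down = rp_down,
    pfp_down = pfp_from_null(rp_down, null_rps$down),
    direction = ifelse(fold_change >= 1, "up", "down")
  )
  structure(
    list(
      results = results, n_comparisons = K,
      n_permutations = if (pfp_method == "exact") NA_integer_ else n_permutations,
      pfp_method = pfp_method, treatment = treatment, control = control
    ),
    class = "rank_product"
  )
}

# Standard rank-product null: each comparison's null ranks are an
# independent uniform permutation of 1..G (the limiting null of shuffling
# exchangeable values). Unlike the within-probe shuffle it is not
# contaminated by genes with real effects.
rp_null_uniform <- function(G, K, n_permutations, seed) {
  run <- function() {
    null <- matrix(NA_real_, G, n_permutations)
    for (b in seq_len(n_permutations)) {
      r <- vapply(seq_len(K), function(k) sample.int(G), integer(G))
      null[, b] <- exp(rowMeans(log(r)))
    }
    list(up = null, down = null)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Expected count of null rank products <= observed, divided by observed rank.
pfp_from_null <- function(rp_obs, null_matrix) {
  null_sorted <- sort(as.vector(null_matrix))
  n_sets <- ncol(null_matrix)
  exp_count <- findInterval(rp_obs, null_sorted) / n_sets
  exp_count / rank(rp_obs, ties.method = "average")
}

rp_null_permutation <- function(mat, pairs, n_permutations, seed) {
  G <- nrow(mat)
  K <- nrow(pairs)
  run <- function() {
    up <- matrix(NA_real_, G, n_permutations)
    down <- matrix(NA_real_, G, n_permutations)
    for (b in seq_len(n_permutations)) {
      # shuffle each probe's values across its samples
      perm <- t(apply(mat, 1, sample))
      fc <- vapply(
        seq_len(K),
        function(k) perm[, pairs$t[k]] / perm[, pairs$c[k]],
        numeric(G)
      )
      lr_up <- apply(fc, 2, function(col) rank(-col, ties.method = "average"))
      up[, b] <- exp(rowMeans(log(lr_up)))
      lr_down <- apply(fc, 2, function(col) rank(col, ties.method = "average"))
      down[, b] <- exp(rowMeans(log(lr_down)))
    }
    list(up = up, down = down)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Exhaustive null: every comparison's rank vector is an independent uniform
# permutation of 1..G; enumerate all (G!)^K configurations.
rp_null_exact <- function(G, K) {
  perms <- all_permutations(G)
  n_conf <- nrow(perms)^K
  if (n_conf > 2e5) {
    abort("exact pfp enumeration is only feasible for tiny instances")
  }
  idx_grid <- as.matrix(expand.grid(rep(list(seq_len(nrow(perms))), K)))
  null <- apply(idx_grid, 1, function(ix) {
    r <- t(perms[ix, , drop = FALSE]) # G x K rank matrix
    exp(rowMeans(log(r)))
  })
  null <- matrix(null, nrow = G)
  # The null is symmetric in direction: same enumeration serves both sides.
  list(up = null, down = null)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Detection, fold-change and significance filters for expression results
#'
#' Mirrors the reported filtering: probes failing the detection p-value
#' cutoff are removed first; remaining probes must change by strictly more
#' than the fold threshold (in either direction, on the linear scale) and be
#' significant by rank product in their direction of change. The result is
#' sorted by direction and then by fold-change magnitude.
#'
#' @param rp A [rank_product()] fit or its `results` tibble.
#' @param detection A tibble with `probe_id` and `detection_p` columns.
#' @param detection_p_threshold Keep probes with `detection_p <` this value
#'   (default 0.01).
#' @param fold_threshold Keep probes with fold magnitude strictly greater
#'   than this (default 1.2).
#' @param pfp_threshold Keep probes with directional pfp at most this value
#'   (default 0.05).
#'
#' @return A tibble: `probe_id`, `direction` (`"up"`/`"down"`),
#'   `fold_change`, `magnitude` (`max(fc, 1/fc)`), `pfp`, sorted up list
#'   first, each by decreasing magnitude.
#' @export
apply_expression_filters <- function(rp, detection,
                                     detection_p_threshold = 0.01,
                                     fold_threshold = 1.2,
                                     pfp_threshold = 0.05) {
  results <- if (inherits(rp, "rank_product")) rp$results else rp
  stopifnot(all(c("probe_id", "detection_p") %in% names(detection)))
  results %>%
    left_join(detection, by = "probe_id") %>%
    filter(!is.na(detection_p), detection_p < detection_p_threshold) %>%
    mutate(
      magnitude = pmax(fold_change, 1 / fold_change),
      pfp = ifelse(direction == "up", pfp_up, pfp_down)
    ) %>%
    filter(magnitude > fold_threshold, pfp <= pfp_threshold) %>%
    select(probe_id, direction, fold_change, magnitude, pfp) %>%
    arrange(desc(direction), desc(magnitude))
}
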