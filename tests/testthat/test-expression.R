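make_ct <- function(target_shift = 0, ref_shift = 0) {
  # two conditions x 3 samples, target and reference genes
  grid <- tidyr::expand_grid(
    condition = c("3 uM zinc", "100 uM zinc"),
    rep = 1:3, gene = c("ZnT5", "GAPDH")
  )
  grid$sample_id <- paste0(gsub("\\W", "", grid$condition), "_", grid$rep)
  grid$ct <- 25 +
    ifelse(grid$condition == "100 uM zinc" & grid$gene == "ZnT5", target_shift, 0) +
    ifelse(grid$condition == "100 uM zinc" & grid$gene == "GAPDH", ref_shift, 0)
  grid[, c("sample_id", "condition", "gene", "ct")]
}

test_that("ddct recovers relative levels from Ct shifts", {
  flat <- ddct(make_ct(0), "ZnT5", "GAPDH", "3 uM zinc")
  expect_equal(flat$relative_level, c(1, 1))

  up1 <- ddct(make_ct(target_shift = 1), "ZnT5", "GAPDH", "3 uM zinc")
  expect_equal(up1$relative_level[up1$condition == "100 uM zinc"], 0.5)
  expect_equal(up1$relative_level[up1$condition == "3 uM zinc"], 1)

  dn1 <- ddct(make_ct(target_shift = -1), "ZnT5", "GAPDH", "3 uM zinc")
  expect_equal(dn1$relative_level[dn1$condition == "100 uM zinc"], 2)

  expect_error(ddct(make_ct(), "ZnT5", "ACTB", "3 uM zinc"), "reference gene")
  expect_error(ddct(make_ct(), "ZnT5", "GAPDH", "TPEN"), "calibrator")
})

test_that("ddct is invariant to per-sample Ct offsets", {
  base <- make_ct(target_shift = 1.5)
  shifted <- dplyr::group_by(base, sample_id) |>
    dplyr::mutate(ct = ct + match(sample_id[1], unique(base$sample_id))) |>
    dplyr::ungroup()
  a <- ddct(base, "ZnT5", "GAPDH", "3 uM zinc")
  b <- ddct(shifted, "ZnT5", "GAPDH", "3 uM zinc")
  expect_equal(a$relative_level, b$relative_level)
  # the calibrator is exactly 1 by construction
  expect_equal(b$relative_level[b$condition == "3 uM zinc"], 1)
})

test_that("noise-free simulated Ct tables give exact fold recovery", {
  sim <- sim_ct_table(
    c(ZnT5 = 0.5, ZnT10 = 0.25, CBWD = 2),
    noise_sd = 0, seed = 99
  )
  for (g in sim$truth$gene) {
    lv <- ddct(sim$records, g, "GAPDH", "3 uM zinc")
    expect_equal(
      lv$relative_level[lv$condition == "100 uM zinc"],
      sim$truth$true_fold[sim$truth$gene == g]
    )
  }
})

test_that("dilution-corrected abundance ratios follow the stated arithmetic", {
  expect_equal(abundance_ratio_from_ct(25, 25, 1), 1)
  expect_equal(abundance_ratio_from_ct(30, 20, 1), 1024)
  expect_equal(
    abundance_ratio_from_ct(26.54, 20, 20), 20 * 2^6.54,
    tolerance = 1e-12
  )
  expect_equal(round(20 * 2^6.54), 1861) # approx 1.9e3
  expect_error(abundance_ratio_from_ct(25, 25, 0), "dilution")
})

test_that("a gene ranked first in every comparison has rank product 1", {
  mat <- tibble::tibble(
    probe_id = c("hit", "mid", "low"),
    t1 = c(100, 10, 1), t2 = c(90, 9, 2),
    c1 = c(10, 10, 10), c2 = c(9, 11, 9)
  )
  fit <- rank_product(
    mat, c("t", "t", "c", "c"), "t", "c", pfp_method = "exact"
  )
  res <- tidy(fit)
  expect_equal(res$rp_up[res$probe_id == "hit"], 1)
  expect_equal(
    min(res$pfp_up), res$pfp_up[res$probe_id == "hit"]
  )
  expect_error(
    rank_product(mat[, 1:3], c("t", "t"), "t", "c"),
    "at least 2"
  )
})

test_that("exact pfp equals exhaustive enumeration on a tiny instance", {
  # 3 genes, 2 samples per group -> observed ranks from data; null
  # enumerated over all (3!)^K rank configurations
  mat <- tibble::tibble(
    probe_id = c("g1", "g2", "g3"),
    t1 = c(8, 2, 5), t2 = c(7, 1, 6),
    c1 = c(4, 4, 4), c2 = c(5, 5, 5)
  )
  fit <- rank_product(mat, c("t", "t", "c", "c"), "t", "c",
    pfp_method = "exact"
  )
  res <- tidy(fit)
  expect_equal(res$pfp_up, oracle_rp_pfp(res$rp_up, G = 3, K = 2))
  expect_equal(res$pfp_down, oracle_rp_pfp(res$rp_down, G = 3, K = 2))
})

test_that("permutation pfp converges to the exact enumeration", {
  mat <- tibble::tibble(
    probe_id = c("g1", "g2", "g3"),
    t1 = c(9, 3, 5), t2 = c(8, 2, 6),
    c1 = c(5, 4, 4), c2 = c(4, 6, 5)
  )
  groups <- c("t", "t", "c", "c")
  exact <- tidy(rank_product(mat, groups, "t", "c", pfp_method = "exact"))
  mc <- tidy(rank_product(
    mat, groups, "t", "c",
    pfp_method = "uniform", n_permutations = 4000, seed = 77
  ))
  expect_equal(mc$rp_up, exact$rp_up)
  expect_equal(mc$pfp_up, exact$pfp_up, tolerance = 0.08)
  expect_equal(mc$pfp_down, exact$pfp_down, tolerance = 0.08)
})

test_that("rank products are invariant under monotone intensity transforms", {
  em <- sim_expression_matrix(n_genes = 60, n_up = 5, n_down = 5, seed = 17)
  groups <- em$groups
  raw <- rank_product(
    em$matrix, groups, "knockdown", "control",
    n_permutations = 50, seed = 3
  )
  cubed <- em$matrix
  cubed[, -1] <- cubed[, -1]^3
  tr <- rank_product(
    cubed, groups, "knockdown", "control",
    n_permutations = 50, seed = 3
  )
  expect_equal(tidy(raw)$rp_up, tidy(tr)$rp_up)
  expect_equal(tidy(raw)$rp_down, tidy(tr)$rp_down)
  # log2-scale input declared as such reproduces the linear-scale fit
  logged <- em$matrix
  logged[, -1] <- log2(logged[, -1])
  lg <- rank_product(
    logged, groups, "knockdown", "control",
    n_permutations = 50, seed = 3, scale = "log2"
  )
  expect_equal(tidy(raw)$fold_change, tidy(lg)$fold_change)
})

test_that("filters apply detection, fold and significance in order", {
  res <- tibble::tibble(
    probe_id = c("a", "b", "c", "d"),
    fold_change = c(2, 1.19, 1.21, 0.5),
    rp_up = c(1, 2, 3, 50), pfp_up = c(0.001, 0.001, 0.01, 1),
    rp_down = c(50, 40, 30, 1), pfp_down = c(1, 1, 1, 0.001),
    direction = c("up", "up", "up", "down")
  )
  detection <- tibble::tibble(
    probe_id = c("a", "b", "c", "d"),
    detection_p = c(0.02, 0.001, 0.001, 0.001)
  )
  out <- apply_expression_filters(res, detection)
  # a: fails detection despite 2-fold; b: 1.19 < threshold (strict >1.2)
  expect_false("a" %in% out$probe_id)
  expect_false("b" %in% out$probe_id)
  expect_equal(out$probe_id, c("c", "d"))
  expect_equal(out$direction, c("up", "down"))
})

test_that("planted expression effects are recovered through the filters", {
  recovered <- function(n_per_group, seed) {
    em <- sim_expression_matrix(
      n_genes = 400, n_per_group = n_per_group,
      n_up = 10, n_down = 10, fold = 1.5, seed = seed
    )
    fit <- rank_product(
      em$matrix, em$groups, "knockdown", "control",
      n_permutations = 250, seed = 7
    )
    out <- apply_expression_filters(fit, em$detection)
    planted_up <- em$truth$probe_id[em$truth$direction == "up"]
    planted_down <- em$truth$probe_id[em$truth$direction == "down"]
    # no planted gene is ever called in the wrong direction
    expect_false(any(planted_up %in% out$probe_id[out$direction == "down"]))
    expect_false(any(planted_down %in% out$probe_id[out$direction == "up"]))
    c(
      up = sum(planted_up %in% out$probe_id[out$direction == "up"]),
      down = sum(planted_down %in% out$probe_id[out$direction == "down"])
    )
  }
  # at three replicates per group a clear majority of 1.5-fold effects
  # pass the filters ...
  at3 <- recovered(3, seed = 2024)
  expect_gte(at3[["up"]], 6)
  expect_gte(at3[["down"]], 6)
  # ... and recovery is complete as replication grows
  expect_equal(unname(recovered(4, seed = 2024)), c(10, 10))
  expect_equal(unname(recovered(5, seed = 77)), c(10, 10))
})

test_that("a null matrix yields few significant calls", {
  em <- sim_expression_matrix(
    n_genes = 300, n_up = 0, n_down = 0, seed = 31
  )
  fit <- rank_product(
    em$matrix, em$groups, "knockdown", "control",
    n_permutations = 250, seed = 13
  )
  out <- apply_expression_filters(fit, em$detection)
  # pfp approximates the expected false-positive proportion; on pure noise
  # calls at pfp <= 0.05 should be rare
  expect_lte(nrow(out), 5L)
})

test_that("tidy, glance and autoplot expose the fit", {
  em <- sim_expression_matrix(n_genes = 40, seed = 8)
  fit <- rank_product(
    em$matrix, em$groups, "knockdown", "control",
    n_permutations = 50, seed = 5
  )
  td <- tidy(fit)
  expect_true(all(c("probe_id", "rp_up", "pfp_down") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_genes, 40L)
  expect_equal(gl$n_comparisons, 3L)
  expect_s3_class(autoplot(fit), "ggplot")
})
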