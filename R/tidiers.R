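#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a rank-product fit
#'
#' @param x A [rank_product()] object.
#' @param ... Unused.
#' @return The per-gene results tibble (`probe_id`, `fold_change`, `rp_up`,
#'   `pfp_up`, `rp_down`, `pfp_down`, `direction`).
#' @export
tidy.rank_product <- function(x, ...) x$results

#' Glance at a rank-product fit
#'
#' @param x A [rank_product()] object.
#' @param ... Unused.
#' @return A one-row tibble: `n_genes`, `n_comparisons`, `n_permutations`,
#'   `pfp_method`, `treatment`, `control`.
#' @export
glance.rank_product <- function(x, ...) {
  tibble(
    n_genes = nrow(x$results),
    n_comparisons = x$n_comparisons,
    n_permutations = x$n_permutations,
    pfp_method = x$pfp_method,
    treatment = x$treatment,
    control = x$control
  )
}

#' @export
print.rank_product <- function(x, ...) {
  cat(sprintf(
    "<rank_product> %d genes, %d comparisons (%s vs %s), pfp by %s\n",
    nrow(x$results), x$n_comparisons, x$treatment, x$control, x$pfp_method
  ))
  print(x$results, n = 5)
  invisible(x)
}

#' Volcano-style plot of a rank-product fit
#'
#' Fold-change magnitude against directional pfp.
#'
#' @param object A [rank_product()] object.
#' @param pfp_threshold Significance line (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rank_product <- function(object, pfp_threshold = 0.05, ...) {
  d <- object$results %>%
    mutate(pfp = ifelse(direction == "up", pfp_up, pfp_down))
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = log2(fold_change), y = -log10(pmax(pfp, 1e-6)), color = direction
    )
  ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(
      yintercept = -log10(pfp_threshold), linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "log2 fold change", y = "-log10 pfp",
      title = "Rank-product differential expression"
    )
}
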