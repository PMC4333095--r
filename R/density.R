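#' Build merged mapped regions from anchor windows
#'
#' Each anchor contributes the window `[position - flank, position + flank]`
#' clipped to the sequence ends; overlapping windows are merged into
#' disjoint, sorted intervals. The merged ("collapsed") length is the
#' denominator of per-kilobase element densities.
#'
#' @param anchors Anchor tibble for one reference sequence
#'   ([read_anchors()]).
#' @param seq_len Reference sequence length in bp.
#' @param flank Flank size in bp (default 1000).
#'
#' @return A tibble of merged intervals: `seq_id`, `interval_start`,
#'   `interval_end`, `length_bp`, with attribute-free total length
#'   `sum(length_bp)`.
#' @export
build_mapped_regions <- function(anchors, seq_len, flank = 1000L) {
  if (nrow(anchors) == 0L) {
    return(tibble(
      seq_id = character(), interval_start = integer(),
      interval_end = integer(), length_bp = integer()
    ))
  }
  if (length(unique(anchors$seq_id)) > 1L) {
    abort("build_mapped_regions() expects anchors on a single sequence")
  }
  ir <- IRanges::reduce(IRanges::IRanges(
    start = pmax(1L, anchors$position - flank),
    end = pmin(as.integer(seq_len), anchors$position + flank)
  ))
  tibble(
    seq_id = anchors$seq_id[1],
    interval_start = IRanges::start(ir),
    interval_end = IRanges::end(ir),
    length_bp = IRanges::width(ir)
  )
}

#' Count footprints contained in mapped regions
#'
#' A footprint is counted when its interval lies entirely within some merged
#' mapped interval (containment, not overlap: a partially extracted element
#' is not a validated copy). Each footprint is counted at most once.
#'
#' @param regions Merged regions from [build_mapped_regions()].
#' @param footprints Footprint tibble from [dedupe_footprints()] on the same
#'   sequence.
#' @param rule `"within"` (default) or `"any"` (count on any overlap).
#'
#' @return Integer count.
#' @export
count_footprints <- function(regions, footprints, rule = c("within", "any")) {
  rule <- match.arg(rule)
  if (nrow(footprints) == 0L || nrow(regions) == 0L) return(0L)
  fp <- IRanges::IRanges(start = footprints$start, end = footprints$end)
  rg <- IRanges::IRanges(
    start = regions$interval_start, end = regions$interval_end
  )
  type <- if (rule == "within") "within" else "any"
  sum(IRanges::overlapsAny(fp, rg, type = type))
}

#' Per-kilobase footprint density
#'
#' @param n Footprint count.
#' @param mapped_length_bp Total merged mapped length in bp (> 0).
#' @return Density per kb (e.g. 10 footprints in 14,000 bp give 0.71/kb).
#' @examples
#' round(density_per_kb(10, 14000), 2)
#' @export
density_per_kb <- function(n, mapped_length_bp) {
  if (any(mapped_length_bp <= 0)) {
    abort("mapped length must be positive")
  }
  n / (mapped_length_bp / 1000)
}

#' Per-group density report
#'
#' Convenience wrapper producing one row per anchor group: merged mapped
#' length, contained footprint count and density per kb.
#'
#' @param anchors Anchor tibble with an additional `group` column.
#' @param footprints Footprints on the same reference.
#' @param seq_len Reference length in bp.
#' @param flank Flank in bp.
#' @return Tibble with columns `group`, `n_footprints`, `mapped_kb`,
#'   `density` (per kb).
#' @export
density_report <- function(anchors, footprints, seq_len, flank = 1000L) {
  stopifnot("group" %in% names(anchors))
  anchors %>%
    group_by(group) %>%
    dplyr::group_modify(function(g, key) {
      regions <- build_mapped_regions(g, seq_len, flank)
      n <- count_footprints(regions, footprints)
      kb <- sum(regions$length_bp) / 1000
      tibble(
        n_footprints = n, mapped_kb = kb,
        density = density_per_kb(n, sum(regions$length_bp))
      )
    }) %>%
    ungroup()
}

#' Nearest adjacent neighbor by TSS distance
#'
#' For each target TSS, finds the annotation TSS at minimum absolute
#' distance; ties are broken toward the smaller coordinate. The annotation
#' list must exclude the targets themselves.
#'
#' @param targets Integer vector of target TSS positions.
#' @param annotation Integer vector of candidate TSS positions (non-empty).
#' @return Tibble with `target`, `neighbor`, `distance`.
#' @examples
#' nearest_neighbor(1000, c(400, 1550))
#' @export
nearest_neighbor <- function(targets, annotation) {
  if (length(annotation) == 0L) {
    abort("annotation TSS list is empty")
  }
  purrr::map_dfr(targets, function(t) {
    d <- abs(annotation - t)
    best <- which(d == min(d))
    pick <- best[which.min(annotation[best])]
    tibble(
      target = t, neighbor = annotation[pick],
      distance = d[pick]
    )
  })
}

#' Compare group densities to a reference group
#'
#' @param reports A density report ([density_report()] or a tibble with
#'   `group` and `density`).
#' @param reference Name of the reference group.
#' @return The report with a `ratio` column (`density / reference density`);
#'   if the reference density is 0 the ratio is `NA` (flagged, not an
#'   error).
#' @export
compare_density <- function(reports, reference) {
  stopifnot(all(c("group", "density") %in% names(reports)))
  if (!reference %in% reports$group) {
    abort(sprintf("reference group '%s' not in report", reference))
  }
  ref <- reports$density[reports$group == reference][1]
  mutate(
    reports,
    ratio = if (ref == 0) NA_real_ else density / ref
  )
}

#' Plot a density report
#'
#' @param reports Output of [density_report()].
#' @return A ggplot bar chart of density per kb by group.
#' @export
plot_density_report <- function(reports) {
  ggplot2::ggplot(
    reports,
    ggplot2::aes(x = group, y = density, fill = group)
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(
      x = NULL, y = "footprints per kb",
      title = "Element density by anchor group"
    )
}
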