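#' Gapped two-half-site motifs
#'
#' A gapped motif is two ordered half-site patterns (each position a
#' non-empty residue set over A/C/G/T) separated by an unconstrained spacer
#' whose length may vary over `[gap_min, gap_max]`. `ztre_motif()` returns
#' the zinc transcriptional regulatory element consensus,
#' C-\[A/C\]-C-\[T/A/G\]-C-C-\[T/C\]-N(0-50)-\[G/A\]-G-\[A/T/C\]-G-\[T/G\]-G:
#' a 7-position left half-site and 6-position right half-site whose arms are
#' near reverse complements of each other.
#'
#' @param left,right Character vectors, one element per half-site position,
#'   each a string of allowed bases (e.g. `c("C", "AC", "C", ...)`).
#' @param gap_min,gap_max Inclusive spacer length bounds, `0 <= gap_min <=
#'   gap_max`.
#'
#' @return An object of class `gapped_motif`: a list with `left` and `right`
#'   (lists of character vectors of allowed bases) and `gap_min`, `gap_max`.
#' @examples
#' ztre_motif()
#' @export
gapped_motif <- function(left, right, gap_min = 0L, gap_max = 0L) {
  parse_half <- function(x, side) {
    sets <- lapply(strsplit(toupper(x), "", fixed = TRUE), unique)
    if (length(sets) == 0L) abort(sprintf("%s half-site is empty", side))
    ok <- vapply(
      sets, function(s) length(s) > 0L && all(s %in% c("A", "C", "G", "T")),
      logical(1)
    )
    if (!all(ok)) {
      abort(sprintf(
        "%s half-site position %d is not a non-empty subset of A/C/G/T",
        side, which(!ok)[1]
      ))
    }
    sets
  }
  gap_min <- as.integer(gap_min)
  gap_max <- as.integer(gap_max)
  if (gap_min < 0L || gap_max < gap_min) {
    abort("gap bounds must satisfy 0 <= gap_min <= gap_max")
  }
  structure(
    list(
      left = parse_half(left, "left"), right = parse_half(right, "right"),
      gap_min = gap_min, gap_max = gap_max
    ),
    class = "gapped_motif"
  )
}

#' @export
print.gapped_motif <- function(x, ...) {
  half <- function(h) paste(
    vapply(h, function(s) {
      s <- paste(s, collapse = "/")
      if (nchar(s) > 1) paste0("[", s, "]") else s
    }, character(1)),
    collapse = "-"
  )
  cat(sprintf(
    "<gapped_motif> %s - N(%d-%d) - %s\n",
    half(x$left), x$gap_min, x$gap_max, half(x$right)
  ))
  invisible(x)
}

#' @rdname gapped_motif
#' @export
ztre_motif <- function() {
  gapped_motif(
    left = c("C", "AC", "C", "TAG", "C", "C", "TC"),
    right = c("GA", "G", "ATC", "G", "TG", "G"),
    gap_min = 0L, gap_max = 50L
  )
}

#' Reverse complement of a gapped motif
#'
#' Complements every residue set and swaps/reverses the half-sites, so that
#' scanning the forward text with the reverse-complemented motif finds
#' reverse-strand occurrences. The gap range is preserved and the operation
#' is an involution.
#'
#' @param m A [gapped_motif()].
#' @return A `gapped_motif`.
#' @export
motif_reverse_complement <- function(m) {
  stopifnot(inherits(m, "gapped_motif"))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc_half <- function(h) rev(lapply(h, function(s) unname(comp[s])))
  structure(
    list(
      left = rc_half(m$right), right = rc_half(m$left),
      gap_min = m$gap_min, gap_max = m$gap_max
    ),
    class = "gapped_motif"
  )
}

motif_width <- function(m, gap) length(m$left) + gap + length(m$right)

# Regex for one half-site; N in the text never matches a residue set.
half_regex <- function(h) {
  paste(vapply(h, function(s) {
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Scan sequences for a gapped motif
#'
#' Reports every `(start, gap, strand)` occurrence of the motif: positions
#' where the left half-site, a spacer of some length in the motif's gap
#' range, and the right half-site match the text. Matching is
#' case-insensitive; `N` in the text never matches a half-site residue set
#' but is allowed inside the spacer (the spacer is unconstrained).
#' Reverse-strand matches are found by scanning the forward text with the
#' reverse-complemented motif and reported in forward-text coordinates.
#'
#' @param seqs A DNA sequence tibble ([read_fasta()], [seq_record()]).
#' @param motif A [gapped_motif()]; defaults to the ZTRE consensus.
#' @param strands `"both"` (default), `"+"` or `"-"`.
#'
#' @return A tibble of matches, sorted by `(seq_id, start, end, strand)`:
#'   columns `seq_id`, `start`, `end` (1-based inclusive on the forward
#'   text), `strand`, `gap_len`, `matched`. Every row satisfies
#'   `end - start + 1 == length(left) + gap_len + length(right)`.
#' @examples
#' scan_motif(seq_record("x", "CACTCCCGGAGTG"))
#' @export
scan_motif <- function(seqs, motif = ztre_motif(), strands = "both") {
  strands <- match.arg(strands, c("both", "+", "-"))
  stopifnot(inherits(motif, "gapped_motif"))
  if (any(seqs$alphabet != "DNA")) abort("scan_motif() requires DNA records")
  do_strands <- if (strands == "both") c("+", "-") else strands
  out <- purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    scan_text(seqs$id[i], toupper(seqs$residues[i]), motif, do_strands)
  })
  if (nrow(out) == 0L) {
    return(tibble(
      seq_id = character(), start = integer(), end = integer(),
      strand = character(), gap_len = integer(), matched = character()
    ))
  }
  arrange(out, seq_id, start, end, match(strand, c("+", "-")))
}

scan_text <- function(seq_id, text, motif, strands) {
  n <- nchar(text)
  res <- list()
  for (st in strands) {
    m <- if (st == "+") motif else motif_reverse_complement(motif)
    lh <- half_regex(m$left)
    rh <- half_regex(m$right)
    for (gap in m$gap_min:m$gap_max) {
      w <- motif_width(m, gap)
      if (w > n) break
      pat <- sprintf("(?=%s.{%d}%s)", lh, gap, rh)
      hits <- gregexpr(pat, text, perl = TRUE)[[1]]
      if (hits[1] == -1L) next
      starts <- as.integer(hits)
      res[[length(res) + 1L]] <- tibble(
        seq_id = seq_id, start = starts, end = starts + w - 1L,
        strand = st, gap_len = gap,
        matched = substring(text, starts, starts + w - 1L)
      )
    }
  }
  bind_rows(res)
}

#' Collapse motif matches to unique footprints
#'
#' A palindromic site typically matches on both strands over the same
#' interval; the footprint — the unique `(start, end)` interval — is what is
#' counted as one element copy. Strands of all contributing matches are
#' unioned; the canonical parse is the one with the smallest gap, preferring
#' the + strand (for a fixed interval and motif the gap is determined by the
#' interval width, so this only breaks strand ties).
#'
#' @param matches A match tibble from [scan_motif()].
#' @return A tibble with one row per distinct interval: `seq_id`, `start`,
#'   `end`, `strands` (e.g. `"+/-"`), `gap_len`, `gap_class`
#'   (see [classify_gap()]), `matched`. The row count is the element
#'   "copy count".
#' @export
dedupe_footprints <- function(matches) {
  if (nrow(matches) == 0L) {
    return(tibble(
      seq_id = character(), start = integer(), end = integer(),
      strands = character(), gap_len = integer(), gap_class = character(),
      matched = character()
    ))
  }
  strand_levels <- c("+", "-")
  matches %>%
    group_by(seq_id, start, end) %>%
    arrange(match(strand, strand_levels), gap_len, .by_group = TRUE) %>%
    summarise(
      strands = paste(
        intersect(strand_levels, unique(strand)),
        collapse = "/"
      ),
      gap_len = first(gap_len),
      matched = first(matched),
      .groups = "drop"
    ) %>%
    mutate(gap_class = classify_gap(gap_len)) %>%
    select(seq_id, start, end, strands, gap_len, gap_class, matched) %>%
    arrange(seq_id, start, end)
}

#' Classify a ZTRE spacer length
#'
#' Spacers shorter than 30 bases are `"short"`; spacers of 30 to 50 bases
#' are `"long"` — the two classes distinguished in element maps.
#'
#' @param gap Integer vector of spacer lengths in `[0, 50]`.
#' @return Character vector, `"short"` or `"long"`.
#' @examples
#' classify_gap(c(3, 29, 30, 50))
#' @export
classify_gap <- function(gap) {
  if (any(gap < 0L | gap > 50L)) {
    abort("gap length outside [0, 50]")
  }
  ifelse(gap < 30L, "short", "long")
}

#' Plot motif footprints along sequences
#'
#' A simple element map: one horizontal track per sequence with footprints
#' drawn as boxes colored by spacer class.
#'
#' @param footprints A footprint tibble from [dedupe_footprints()].
#' @param seq_lengths Optional named vector of sequence lengths for track
#'   extents.
#' @return A ggplot object.
#' @export
plot_footprints <- function(footprints, seq_lengths = NULL) {
  stopifnot(nrow(footprints) > 0L)
  p <- ggplot2::ggplot(
    footprints,
    ggplot2::aes(
      xmin = start, xmax = end,
      ymin = as.integer(factor(seq_id)) - 0.3,
      ymax = as.integer(factor(seq_id)) + 0.3,
      fill = gap_class
    )
  ) +
    ggplot2::geom_rect() +
    ggplot2::scale_y_continuous(
      breaks = seq_along(unique(footprints$seq_id)),
      labels = unique(footprints$seq_id)
    ) +
    ggplot2::labs(
      x = "position (bp)", y = NULL, fill = "spacer",
      title = "Motif footprints"
    )
  if (!is.null(seq_lengths)) {
    p <- p + ggplot2::expand_limits(x = c(1, max(seq_lengths)))
  }
  p
}
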