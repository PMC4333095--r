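# Bundled SLC30A5 promoter worked example: the 202-nt EMSA probe spanning
# promoter positions -156..+46 (no position 0), its ZTRE at -91..-76, and
# the documented feature coordinates around it.

SLC30A5_PROBE <- paste0(
  "GTGGCGGGAGGAGCCTAAGGGACGAGGAAAGGCGAGTGTTCTGCTTGCGCAGACGCAAGG",
  "CTGGGCACTCCCCCGGGAGTGAGGGTTGCTGGGCCTGATGACGTGGCTTGGCAACGTCCC",
  "TACCGCCGCTGCTTCCCGGGAACCTGGCGCCGCCGGAACTGATCGCGGCCTAGTCCCGAC",
  "GCGTGTGTGCTAGTGAGCCGGA"
)

#' SLC30A5 promoter worked-example sequences
#'
#' `slc30a5_probe()` returns the 202-nt promoter region spanning positions
#' -156 to +46 relative to the SLC30A5 (ZnT5 gene) TSS, which carries one
#' ZTRE at -91..-76 (spacer 3). `slc30a5_probe_deletion()` returns the same
#' region with the element's 5'-side 8 bases (-91..-84) deleted — the
#' deletion that destroys the element. `slc30a5_window_start()` gives the
#' promoter coordinate of the first probe base, for converting scan offsets
#' with [offset_to_promoter()].
#'
#' @return A one-row sequence tibble ([seq_record()]).
#' @examples
#' scan_motif(slc30a5_probe()) |> dedupe_footprints()
#' @export
slc30a5_probe <- function() {
  seq_record("SLC30A5_promoter", SLC30A5_PROBE, "DNA")
}

#' @rdname slc30a5_probe
#' @export
slc30a5_probe_deletion <- function() {
  ws <- slc30a5_window_start()
  from <- promoter_to_offset(-91L, ws)
  to <- promoter_to_offset(-84L, ws)
  res <- paste0(
    substr(SLC30A5_PROBE, 1L, from - 1L),
    substr(SLC30A5_PROBE, to + 1L, nchar(SLC30A5_PROBE))
  )
  seq_record("SLC30A5_promoter_del_-91_-84", res, "DNA")
}

#' @rdname slc30a5_probe
#' @export
slc30a5_window_start <- function() -156L

#' Documented SLC30A5 / rRNA assay feature coordinates
#'
#' The coordinate table behind the worked example: the EMSA probe region,
#' the ZTRE it contains, the 8-base deletion that destroys the element, the
#' 50-bp competitor oligonucleotide (all in no-zero promoter coordinates),
#' and the 18S rRNA qPCR amplicon (1-based transcript coordinates, bases
#' 92-184 of the 18S rRNA reference). Lengths are computed with
#' [interval_length()].
#'
#' @return A tibble: `feature`, `coordinates`, `start`, `end`, `length_bp`.
#' @export
slc30a5_features <- function() {
  f <- tibble(
    feature = c(
      "EMSA probe", "ZTRE", "ZTRE 5'-side deletion",
      "competitor oligo", "18S qPCR amplicon"
    ),
    coordinates = c("promoter", "promoter", "promoter", "promoter", "transcript"),
    start = c(-156L, -91L, -91L, -124L, 92L),
    end = c(46L, -76L, -84L, -75L, 184L)
  )
  mutate(f, length_bp = as.integer(interval_length(start, end)))
}
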