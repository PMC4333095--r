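#' C2H2 zinc-finger spacing pattern
#'
#' The classical Cys2-His2 finger is detected by exact residue spacing:
#' C-X2-C-X12-H-X3-H, a 21-residue window whose metal-coordinating positions
#' are 1, 4, 17 and 21. Two documented non-canonical variants can be
#' admitted: an H in place of the first C (the "His-Cys-His2" configuration)
#' and an R in place of the final H (the "Cys2-His-Arg" configuration).
#'
#' @param spacer1,spacer2,spacer3 Residue counts between the coordinating
#'   positions (defaults 2, 12, 3; the canonical spacing).
#' @param allow_H_at_pos1,allow_R_at_pos4 Enable the two variant residues at
#'   the first and fourth coordinating positions.
#' @return An object of class `zf_pattern`.
#' @export
zf_pattern <- function(spacer1 = 2L, spacer2 = 12L, spacer3 = 3L,
                       allow_H_at_pos1 = TRUE, allow_R_at_pos4 = TRUE) {
  structure(
    list(
      pos1 = if (allow_H_at_pos1) c("C", "H") else "C",
      pos2 = "C",
      pos3 = "H",
      pos4 = if (allow_R_at_pos4) c("H", "R") else "H",
      spacer1 = as.integer(spacer1),
      spacer2 = as.integer(spacer2),
      spacer3 = as.integer(spacer3)
    ),
    class = "zf_pattern"
  )
}

zf_width <- function(p) 4L + p$spacer1 + p$spacer2 + p$spacer3

zf_offsets <- function(p) {
  c(
    1L,
    2L + p$spacer1,
    3L + p$spacer1 + p$spacer2,
    4L + p$spacer1 + p$spacer2 + p$spacer3
  )
}

classify_finger <- function(c1, c4) {
  if (c1 == "H") "H-C-H2" else if (c4 == "R") "C2-H-R" else "canonical"
}

#' Annotate C2H2 zinc fingers in a protein
#'
#' Scans left to right for 21-residue windows whose positions 1, 4, 17 and
#' 21 carry the coordinating residues of the C-X2-C-X12-H-X3-H pattern.
#' Accepted windows are consumed greedily so annotated fingers never
#' overlap, mirroring how tandem finger arrays tile along the protein.
#'
#' @param protein A protein sequence tibble ([seq_record()] /
#'   [read_fasta()] with `alphabet = "protein"`); one record.
#' @param pattern A [zf_pattern()].
#' @param allow_variants If `FALSE`, only strictly canonical C2H2 windows
#'   are annotated regardless of the pattern's variant sets.
#'
#' @return A tibble with one row per finger: `index` (1..n along the
#'   sequence), `start`, `end` (1-based inclusive; `end - start == 20` for
#'   the default spacing), `configuration` (`"canonical"`, `"H-C-H2"` or
#'   `"C2-H-R"`), `sequence`.
#' @examples
#' scan_zinc_fingers(seq_record("zf", "CAACAAAAAAAAAAAAHAAAH", "protein"))
#' @export
scan_zinc_fingers <- function(protein, pattern = zf_pattern(),
                              allow_variants = TRUE) {
  if (any(protein$alphabet != "protein")) {
    abort("scan_zinc_fingers() requires protein records")
  }
  stopifnot(nrow(protein) == 1L)
  p <- pattern
  if (!allow_variants) {
    p$pos1 <- "C"
    p$pos4 <- "H"
  }
  chars <- strsplit(protein$residues, "", fixed = TRUE)[[1]]
  n <- length(chars)
  w <- zf_width(p)
  off <- zf_offsets(p)
  out <- list()
  i <- 1L
  while (i <= n - w + 1L) {
    c1 <- chars[i + off[1] - 1L]
    c2 <- chars[i + off[2] - 1L]
    c3 <- chars[i + off[3] - 1L]
    c4 <- chars[i + off[4] - 1L]
    if (c1 %in% p$pos1 && c2 %in% p$pos2 && c3 %in% p$pos3 && c4 %in% p$pos4) {
      out[[length(out) + 1L]] <- tibble(
        start = i, end = i + w - 1L,
        configuration = classify_finger(c1, c4),
        sequence = substr(protein$residues, i, i + w - 1L)
      )
      i <- i + w
    } else {
      i <- i + 1L
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble(
      index = integer(), start = integer(), end = integer(),
      configuration = character(), sequence = character()
    ))
  }
  mutate(res, index = row_number()) %>%
    select(index, start, end, configuration, sequence)
}

#' Summarise zinc-finger annotations
#'
#' @param annotations Output of [scan_zinc_fingers()].
#' @return A one-row tibble: `total` plus one count per configuration class
#'   (`canonical`, `H-C-H2` as `h_c_h2`, `C2-H-R` as `c2_h_r`).
#' @export
finger_summary <- function(annotations) {
  tibble(
    total = nrow(annotations),
    canonical = sum(annotations$configuration == "canonical"),
    h_c_h2 = sum(annotations$configuration == "H-C-H2"),
    c2_h_r = sum(annotations$configuration == "C2-H-R")
  )
}
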