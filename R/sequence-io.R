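#' Sequence records
#'
#' Sequences are carried through the package as tibbles with one row per
#' sequence and columns `id`, `alphabet` (`"DNA"` or `"protein"`) and
#' `residues` (an uppercase string). `seq_record()` builds and validates a
#' single record.
#'
#' @param id Sequence identifier (a single token string).
#' @param residues Residue string. Lowercase is accepted and folded to
#'   uppercase; DNA may contain `N` (which never matches a motif residue set).
#' @param alphabet `"DNA"` or `"protein"`.
#'
#' @return A one-row tibble with columns `id`, `alphabet`, `residues`.
#' @examples
#' seq_record("probe", "acgtACGT")
#' @export
seq_record <- function(id, residues, alphabet = c("DNA", "protein")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(as.character(residues))
  validate_residues(residues, alphabet, id)
  tibble(id = id, alphabet = alphabet, residues = residues)
}

DNA_LETTERS <- c("A", "C", "G", "T", "N")
PROTEIN_LETTERS <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

validate_residues <- function(residues, alphabet, id = "<sequence>") {
  if (!nzchar(residues)) {
    abort(sprintf("sequence '%s' is empty", id))
  }
  letters_ok <- if (alphabet == "DNA") DNA_LETTERS else PROTEIN_LETTERS
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% letters_ok)
  if (length(bad) > 0L) {
    abort(sprintf(
      "invalid %s residue '%s' at position %d of sequence '%s'",
      alphabet, chars[bad[1]], bad[1], id
    ))
  }
  invisible(residues)
}

#' Read and write FASTA files
#'
#' `read_fasta()` returns one record per header in file order; the record id
#' is the first whitespace-delimited token of the header line, residues are
#' uppercased with line breaks removed, and every residue is validated
#' against the declared alphabet (an invalid residue is reported with its
#' 1-based position). `write_fasta()` is its inverse;
#' `read_fasta(write_fasta(x))` reproduces `x` exactly.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"DNA"` or `"protein"`; used for validation only.
#'
#' @return A tibble with columns `id`, `alphabet`, `residues`.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' write_fasta(seq_record("p", "ACGT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, alphabet = c("DNA", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    abort(sprintf("FASTA parse error in %s: file is empty", path))
  }
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    abort(sprintf(
      "FASTA parse error in %s, line %d: sequence data before first '>' header",
      path, first
    ))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    abort(sprintf("FASTA parse error in %s: no records", path))
  }
  ids <- vapply(
    strsplit(names(set), "\\s+"),
    function(x) x[1], character(1)
  )
  res <- toupper(gsub("[\r\n]", "", as.character(set)))
  purrr::map2_dfr(ids, res, function(i, r) seq_record(i, r, alphabet))
}

#' @param records A sequence tibble as returned by [read_fasta()] or
#'   [seq_record()].
#' @param width Line width for wrapped sequence output.
#' @rdname read_fasta
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(all(c("id", "residues") %in% names(records)))
  set <- Biostrings::BStringSet(setNames(records$residues, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Promoter-coordinate arithmetic without a position zero
#'
#' Promoter positions are numbered relative to the transcription start site
#' with no position 0: +1 is the TSS base and -1 immediately precedes it.
#' `interval_length()` gives the inclusive length of `[a, b]` under this
#' convention; `promoter_to_offset()` converts a promoter coordinate to a
#' 1-based offset within a window starting at `window_start`, and
#' `offset_to_promoter()` is its exact inverse.
#'
#' Under this convention the documented SLC30A5 promoter features check out
#' against their printed sequences: the -156..+46 probe is 202 nt, the
#' -124..-75 competitor is 50 bp and the -91..-84 deletion removes 8 bases.
#'
#' @param a,b Promoter coordinates (non-zero integers) with `a <= b` in
#'   promoter order (..., -2, -1, +1, +2, ...).
#'
#' @return `interval_length()`: inclusive length in bp.
#' @examples
#' interval_length(-124, -75) # the 50-bp ZTRE competitor
#' interval_length(-156, +46) # the 202-nt EMSA probe
#' promoter_to_offset(-91, window_start = -156)
#' @export
interval_length <- function(a, b) {
  check_promoter_coord(a)
  check_promoter_coord(b)
  if (any(promoter_rank(a) > promoter_rank(b))) {
    abort("interval_length() requires a <= b in promoter order")
  }
  ifelse(sign(a) == sign(b), abs(b - a) + 1L, (-a) + b)
}

# Map the no-zero axis ... -2 -1 +1 +2 ... onto consecutive integers.
promoter_rank <- function(x) ifelse(x > 0, x - 1L, x)

check_promoter_coord <- function(x) {
  if (any(x == 0L)) {
    abort("invalid promoter coordinate: position 0 does not exist")
  }
  invisible(x)
}

#' @param coord Promoter coordinate to convert.
#' @param window_start Promoter coordinate of the first base of the window
#'   (offset 1).
#' @return `promoter_to_offset()`: 1-based integer offset;
#'   `offset_to_promoter()`: promoter coordinate.
#' @rdname interval_length
#' @export
promoter_to_offset <- function(coord, window_start) {
  check_promoter_coord(coord)
  check_promoter_coord(window_start)
  if (any(promoter_rank(coord) < promoter_rank(window_start))) {
    abort("coordinate lies before the window start")
  }
  as.integer(interval_length(window_start, coord))
}

#' @param offset 1-based offset within the window.
#' @rdname interval_length
#' @export
offset_to_promoter <- function(offset, window_start) {
  check_promoter_coord(window_start)
  if (any(offset < 1L)) abort("offset must be >= 1")
  out <- window_start + offset - 1L
  out <- ifelse(window_start < 0L & out >= 0L, out + 1L, out)
  as.integer(out)
}

#' Reverse complement of DNA
#'
#' Standard complement, reversed; `N` maps to `N`. Applying the function
#' twice returns the input. Needed for both-strand scanning of the
#' near-palindromic ZTRE.
#'
#' @param x A character vector of DNA strings, or a sequence tibble with
#'   `alphabet == "DNA"` (the `residues` column is complemented in place).
#'
#' @return Same shape as the input.
#' @examples
#' reverse_complement("CACTCC")
#' @export
reverse_complement <- function(x) {
  if (is.data.frame(x)) {
    if (any(x$alphabet != "DNA")) {
      abort("reverse_complement() requires DNA records")
    }
    x$residues <- reverse_complement(x$residues)
    return(x)
  }
  if (any(!nzchar(x))) abort("cannot reverse-complement an empty sequence")
  bad <- !grepl("^[ACGTNacgtn]*$", x)
  if (any(bad)) abort("reverse_complement() requires DNA input (A/C/G/T/N)")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

#' Read anchor positions
#'
#' Anchors mark a TSS or the 5' end of a processed rRNA on a reference
#' sequence. TSV anchors are 1-based with columns `seq_id`, `position`,
#' `strand`, `label`; BED anchors are 0-based half-open intervals whose start
#' base becomes the (1-based) anchor position, with the name and strand
#' columns honored when present.
#'
#' @param path Anchor file.
#' @param format `"tsv"` or `"bed"`.
#'
#' @return Tibble with columns `seq_id`, `position` (1-based), `strand`,
#'   `label`.
#' @export
read_anchors <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- readr::read_tsv(path, show_col_types = FALSE)
    need <- c("seq_id", "position", "strand", "label")
    if (!all(need %in% names(out))) {
      abort(sprintf(
        "TSV anchor file must have columns %s", paste(need, collapse = ", ")
      ))
    }
    out <- select(out, all_of(need))
  } else {
    bed <- readr::read_tsv(
      path,
      col_names = FALSE, comment = "#", show_col_types = FALSE
    )
    out <- tibble(
      seq_id = as.character(bed[[1]]),
      # BED is 0-based half-open; the interval's first base anchors.
      position = as.integer(bed[[2]]) + 1L,
      strand = if (ncol(bed) >= 6) as.character(bed[[6]]) else "+",
      label = if (ncol(bed) >= 4) as.character(bed[[4]]) else NA_character_
    )
  }
  out$position <- as.integer(out$position)
  if (any(!out$strand %in% c("+", "-"))) {
    abort("anchor strand must be '+' or '-'")
  }
  out
}

#' Extract anchored windows
#'
#' For each anchor, extracts the window `[position - flank, position + flank]`
#' clipped to the reference ends. For a minus-strand anchor the window is
#' reverse-complemented so that numbering runs along the annotated direction.
#' The returned `anchor_offset` is the 1-based offset of the anchor base
#' within the (oriented) window, so match offsets can be reported in no-zero
#' promoter numbering via [offset_to_promoter()] with
#' `window_start = offset_to_promoter(1, ...)` bookkeeping, or directly with
#' `window_offset_to_promoter()`.
#'
#' @param refs Reference sequence tibble ([read_fasta()]).
#' @param anchors Anchor tibble ([read_anchors()]).
#' @param flank Flank size in bp on each side of the anchor (default 1000,
#'   the +/- 1 kb windows used for TSS and processed-rRNA 5' ends).
#'
#' @return Tibble with one row per anchor: `seq_id`, `label`, `strand`,
#'   `window_start`, `window_end` (reference coordinates of the extracted
#'   window), `anchor_offset`, `id` (window id), `alphabet`, `residues`.
#' @export
extract_windows <- function(refs, anchors, flank = 1000L) {
  stopifnot(flank >= 0L)
  purrr::pmap_dfr(anchors, function(seq_id, position, strand, label, ...) {
    ref <- refs[refs$id == seq_id, ]
    if (nrow(ref) != 1L) {
      abort(sprintf("anchor references unknown sequence '%s'", seq_id))
    }
    len <- nchar(ref$residues)
    if (position < 1L || position > len) {
      abort(sprintf(
        "anchor at position %d is off sequence '%s' (length %d)",
        position, seq_id, len
      ))
    }
    ws <- max(1L, position - flank)
    we <- min(len, position + flank)
    win <- substr(ref$residues, ws, we)
    if (strand == "-") {
      win <- reverse_complement(win)
      anchor_offset <- we - position + 1L
    } else {
      anchor_offset <- position - ws + 1L
    }
    tibble(
      seq_id = seq_id, label = label, strand = strand,
      window_start = as.integer(ws), window_end = as.integer(we),
      anchor_offset = as.integer(anchor_offset),
      id = paste0(seq_id, ":", label), alphabet = "DNA", residues = win
    )
  })
}

#' @param offset 1-based offset within an oriented window.
#' @param anchor_offset Offset of the anchor base in the same window.
#' @return `window_offset_to_promoter()`: promoter coordinate (anchor base
#'   is +1, no position 0).
#' @rdname extract_windows
#' @export
window_offset_to_promoter <- function(offset, anchor_offset) {
  d <- offset - anchor_offset
  as.integer(ifelse(d >= 0L, d + 1L, d))
}
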