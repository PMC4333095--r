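# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals: the scanner
# oracle enumerates (start, gap) pairs by position-wise set membership and
# finds reverse-strand hits by scanning the reverse-complemented *text*
# (the package reverse-complements the *motif*); the rank-product oracle
# exhaustively enumerates rank configurations.

oracle_revcomp <- function(text) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", text), "", fixed = TRUE)[[1]]),
    collapse = ""
  )
}

oracle_half_sets <- function(x) strsplit(toupper(x), "", fixed = TRUE)

ORACLE_ZTRE_LEFT <- oracle_half_sets(c("C", "AC", "C", "TAG", "C", "C", "TC"))
ORACLE_ZTRE_RIGHT <- oracle_half_sets(c("GA", "G", "ATC", "G", "TG", "G"))

# All (start, end, gap) matches of left + spacer + right on one strand of
# `text`, by exhaustive position-wise enumeration.
oracle_scan_forward <- function(text, left = ORACLE_ZTRE_LEFT,
                                right = ORACLE_ZTRE_RIGHT,
                                gap_min = 0L, gap_max = 50L) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  nl <- length(left)
  nr <- length(right)
  ok_at <- function(sets) {
    # ok[s] = TRUE when sets match starting at position s
    len <- length(sets)
    if (n < len) return(logical(0))
    starts <- seq_len(n - len + 1L)
    res <- rep(TRUE, length(starts))
    for (i in seq_len(len)) {
      res <- res & chars[starts + i - 1L] %in% sets[[i]]
    }
    res
  }
  left_ok <- ok_at(left)
  right_ok <- ok_at(right)
  out <- list()
  for (g in gap_min:gap_max) {
    w <- nl + g + nr
    if (w > n) break
    s <- seq_len(n - w + 1L)
    hit <- s[left_ok[s] & right_ok[s + nl + g]]
    if (length(hit)) {
      out[[length(out) + 1L]] <-
        data.frame(start = hit, end = hit + w - 1L, gap_len = g)
    }
  }
  do.call(rbind, c(out, list(data.frame(
    start = integer(), end = integer(), gap_len = integer()
  ))))
}

# Both-strand oracle in forward-text coordinates.
oracle_scan_both <- function(text, ...) {
  n <- nchar(text)
  fwd <- oracle_scan_forward(text, ...)
  fwd$strand <- rep("+", nrow(fwd))
  rc <- oracle_scan_forward(oracle_revcomp(text), ...)
  rc <- data.frame(
    start = n - rc$end + 1L, end = n - rc$start + 1L,
    gap_len = rc$gap_len, strand = rep("-", nrow(rc))
  )
  out <- rbind(fwd, rc)
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

random_dna_text <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein_text <- function(n, letters = strsplit(
                                  "ACDEFGHIKLMNPQRSTVWY", ""
                                )[[1]]) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Exhaustive rank-product null for G genes and K comparisons: every
# configuration of K independent rank permutations is equally likely.
oracle_rp_pfp <- function(rp_obs, G, K) {
  perm_rows <- function(n) {
    if (n == 1L) return(matrix(1L, 1, 1))
    sub <- perm_rows(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) cbind(k, sub + (sub >= k))))
  }
  perms <- perm_rows(G)
  combos <- as.matrix(expand.grid(rep(list(seq_len(nrow(perms))), K)))
  null_rp <- apply(combos, 1, function(ix) {
    ranks <- t(perms[ix, , drop = FALSE])
    exp(rowMeans(log(ranks)))
  })
  null_all <- as.vector(null_rp)
  n_conf <- ncol(null_rp)
  exp_count <- vapply(
    rp_obs, function(r) sum(null_all <= r) / n_conf, numeric(1)
  )
  exp_count / rank(rp_obs, ties.method = "average")
}

# Frozen monoisotopic oracle values (computed independently with pyteomics).
PYTEOMICS_MASSES <- c(
  G = 75.03203, GG = 132.05349, AKPR = 470.29652, GK = 203.12699,
  GKGK = 388.24342, PEPTIDE = 799.35996
)
PYTEOMICS_MH <- c(
  G = 76.0393, GG = 133.06077, AKPR = 471.30379, GK = 204.13427,
  GKGK = 389.25069, PEPTIDE = 800.36724
)
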