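#' Scan a sequence for degenerate IUPAC motifs
#'
#' Exact degenerate matching at every offset; overlapping occurrences are all
#' counted. Reverse-strand hits are found by scanning the reverse complement
#' of each pattern along the forward sequence, and are reported at their
#' forward-strand coordinates.
#'
#' @param region DNA sequence (character scalar, ACGTN alphabet).
#' @param patterns motif library: character vector of IUPAC strings (names
#'   used as pattern ids), or a data.frame with columns `id` and `iupac`.
#' @param both_strands scan the reverse strand as well (default TRUE).
#' @return data.frame with `pattern`, `strand`, `start` (0-based), `end`
#'   (exclusive); zero rows when nothing matches.
#' @export
scan_motifs <- function(region, patterns, both_strands = TRUE) {
  pat <- as_motif_library(patterns)
  s <- chars(toupper(region))
  out <- list()
  for (i in seq_len(nrow(pat))) {
    for (strand in if (both_strands) c("+", "-") else "+") {
      p <- if (strand == "+") pat$iupac[i] else revcomp(pat$iupac[i])
      hits <- scan_starts(s, iupac_allowed(p))
      if (length(hits) > 0) {
        out[[length(out) + 1L]] <- data.frame(
          pattern = pat$id[i], strand = strand,
          start = hits, end = hits + nchar(p),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(pattern = character(0), strand = character(0),
                      start = integer(0), end = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$pattern, res$strand), , drop = FALSE]
}

# vectorized offset scan of a char vector against per-position allowed sets;
# returns 0-based start offsets
scan_starts <- function(seq_chars, allowed) {
  w <- length(allowed)
  L <- length(seq_chars)
  if (L < w) return(integer(0))
  n <- L - w + 1L
  ok <- rep(TRUE, n)
  for (k in seq_len(w)) {
    ok <- ok & seq_chars[k:(k + n - 1L)] %in% allowed[[k]]
    if (!any(ok)) return(integer(0))
  }
  which(ok) - 1L
}

# normalize a motif library to data.frame(id, iupac), validating the alphabet
as_motif_library <- function(patterns) {
  if (is.data.frame(patterns)) {
    stopifnot(all(c("id", "iupac") %in% names(patterns)))
    pat <- data.frame(id = as.character(patterns$id),
                      iupac = toupper(as.character(patterns$iupac)),
                      stringsAsFactors = FALSE)
  } else {
    ids <- names(patterns)
    if (is.null(ids)) ids <- paste0("M", seq_along(patterns))
    pat <- data.frame(id = ids, iupac = toupper(as.character(patterns)),
                      stringsAsFactors = FALSE)
  }
  if (any(nchar(pat$iupac) == 0)) stop("empty motif pattern")
  for (p in pat$iupac) iupac_allowed(p) # validates symbols
  pat
}

#' Count motif occurrences per region
#'
#' Convenience wrapper around [scan_motifs()] returning a regions x patterns
#' count matrix.
#'
#' @param regions named character vector of sequences.
#' @param patterns motif library (see [scan_motifs()]).
#' @param both_strands scan both strands.
#' @return integer matrix, regions x patterns.
#' @export
count_motifs <- function(regions, patterns, both_strands = TRUE) {
  pat <- as_motif_library(patterns)
  m <- matrix(0L, length(regions), nrow(pat),
              dimnames = list(names(regions), pat$id))
  for (g in seq_along(regions)) {
    hits <- scan_motifs(regions[[g]], pat, both_strands)
    if (nrow(hits) > 0) {
      tab <- table(hits$pattern)
      m[g, names(tab)] <- as.integer(tab)
    }
  }
  m
}

#' Default low-temperature-responsive element (LTRE) patterns
#'
#' The CCGAC core shared by LTRE elements plus the CBF/DRE variant RCCGAC.
#' The pattern list is user-overridable wherever it is consumed.
#'
#' @return named character vector of IUPAC patterns.
#' @export
ltre_patterns <- function() {
  c(LTRE_core = "CCGAC", CBF_DRE = "RCCGAC")
}
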