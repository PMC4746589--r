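#' @import stats utils
#' @importFrom Biostrings AAStringSet DNAStringSet readAAStringSet readDNAStringSet writeXStringSet pairwiseAlignment
NULL

# 20 standard amino acids, alphabetical one-letter order
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DNA4 <- c("A", "C", "G", "T")

# IUPAC nucleotide codes -> allowed bases
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# complement map over the full IUPAC alphabet
IUPAC_FROM <- "ACGTRYSWKMBDHVN"
IUPAC_TO   <- "TGCAYRSWMKVHDBN"

#' Reverse complement of a (possibly degenerate) DNA string
#'
#' Works on plain character strings over the IUPAC alphabet, so it can be
#' applied to degenerate motif patterns as well as concrete sequences.
#'
#' @param x character vector of DNA/IUPAC strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr(IUPAC_FROM, IUPAC_TO, toupper(x))
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

# split a string into single characters
chars <- function(x) strsplit(x, "")[[1]]

# random sequence helpers (rely on the caller having set the RNG state)
random_seq <- function(len, alphabet) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# mutate a residue string: each site substituted with probability p to a
# uniformly chosen *different* symbol
mutate_seq <- function(x, p, alphabet) {
  s <- chars(x)
  hit <- runif(length(s)) < p
  if (any(hit)) {
    s[hit] <- vapply(s[hit], function(a) sample(setdiff(alphabet, a), 1L), "")
  }
  paste(s, collapse = "")
}

# validate an IUPAC pattern, returning its per-position allowed-base list
iupac_allowed <- function(pattern) {
  p <- chars(toupper(pattern))
  bad <- setdiff(p, names(IUPAC_CODES))
  if (length(bad) > 0) {
    stop("invalid IUPAC symbol(s) in pattern '", pattern, "': ",
         paste(unique(bad), collapse = ", "))
  }
  IUPAC_CODES[p]
}

# one concrete realization of a degenerate pattern
realize_iupac <- function(pattern) {
  paste(vapply(iupac_allowed(pattern), function(b) sample(b, 1L), ""),
        collapse = "")
}

# check gene-model data.frame shape used throughout the package
as_gene_models <- function(models) {
  req <- c("gene_id", "chromosome", "start", "end", "strand")
  miss <- setdiff(req, names(models))
  if (length(miss) > 0) {
    stop("gene model table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(models$gene_id)) {
    stop("duplicate gene IDs in gene model table")
  }
  if (any(models$start > models$end)) stop("gene model with start > end")
  models$chromosome <- as.character(models$chromosome)
  models$gene_id <- as.character(models$gene_id)
  if (!"rank" %in% names(models)) {
    models <- add_gene_ranks(models)
  }
  models
}

#' Recompute per-chromosome gene-order ranks
#'
#' Ranks are 1-based ordinal positions along each chromosome ordered by start
#' coordinate; they drive collinearity chaining and tandem/proximal calls.
#'
#' @param models gene-model data.frame with `chromosome` and `start` columns.
#' @return the same data.frame with a `rank` column added/overwritten.
#' @export
add_gene_ranks <- function(models) {
  models$rank <- NA_integer_
  for (chr in unique(models$chromosome)) {
    i <- which(models$chromosome == chr)
    models$rank[i][order(models$start[i])] <- seq_along(i)
  }
  models
}
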