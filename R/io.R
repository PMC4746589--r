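#' Read gene models from a GFF3 file
#'
#' Imports `gene`-type features, keeping the 1-based inclusive coordinates
#' and strand of the GFF3 convention, and assigns per-chromosome gene-order
#' ranks.
#'
#' @param path GFF3 file.
#' @return data.frame with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`, `rank`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  id <- gr$ID
  if (is.null(id)) id <- gr$Name
  models <- data.frame(
    gene_id = as.character(id),
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  models$strand[!models$strand %in% c("+", "-")] <- "+"
  as_gene_models(models)
}

#' Write gene models to GFF3
#'
#' @param models gene-model data.frame (see [read_gene_models()]).
#' @param path output GFF3 file.
#' @export
write_gene_models <- function(models, path) {
  models <- as_gene_models(models)
  gr <- GenomicRanges::GRanges(
    seqnames = models$chromosome,
    ranges = IRanges::IRanges(start = models$start, end = models$end),
    strand = models$strand
  )
  gr$type <- "gene"
  gr$source <- "madsfam"
  gr$ID <- models$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a BED interval file (0-based half-open)
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start` (0-based), `end` (exclusive) and,
#'   if present, `name`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (!is.null(gr$name)) out$name <- gr$name
  out
}

#' Write intervals to BED (0-based half-open input)
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (+ optional `name`).
#' @param path output BED file.
#' @export
write_bed <- function(peaks, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
  if (!is.null(peaks$name)) gr$name <- peaks$name
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read an FPKM expression matrix from TSV
#'
#' First column is the gene identifier; remaining columns are samples.
#'
#' @param path TSV file.
#' @return numeric matrix, genes x samples.
#' @export
read_fpkm <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write an FPKM expression matrix to TSV
#'
#' @param mat numeric matrix, genes x samples.
#' @param path output TSV file.
#' @export
write_fpkm <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
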