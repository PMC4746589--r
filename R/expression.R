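#' Log2-transform an FPKM matrix
#'
#' `log2(FPKM + pseudocount)`; with the default pseudocount of 1 the
#' transform is zero-preserving and monotone, and is the matrix used for
#' heatmap export and correlation scoring.
#'
#' @param mat non-negative numeric matrix.
#' @param pseudocount added before taking logs (default 1).
#' @return transformed matrix of the same shape.
#' @export
log_transform <- function(mat, pseudocount = 1) {
  if (any(mat < 0)) stop("negative FPKM values")
  log2(mat + pseudocount)
}

#' Call expressed genes by FPKM threshold
#'
#' A gene is expressed iff its FPKM reaches `threshold` in at least one
#' sample (boundary inclusive).
#'
#' @param mat FPKM matrix (genes x samples).
#' @param threshold FPKM threshold (default 1).
#' @return data.frame with `gene`, `max_fpkm`, `expressed`; attributes
#'   `n_expressed` and `fraction_expressed`.
#' @export
call_expressed <- function(mat, threshold = 1) {
  mx <- apply(mat, 1, max)
  out <- data.frame(gene = rownames(mat), max_fpkm = unname(mx),
                    expressed = unname(mx >= threshold),
                    stringsAsFactors = FALSE)
  attr(out, "n_expressed") <- sum(out$expressed)
  attr(out, "fraction_expressed") <- mean(out$expressed)
  out
}

#' Reciprocal (anti-correlated) expression score for a gene pair
#'
#' Correlation of the two genes' log2(FPKM + 1) profiles over a stage
#' subset (default: the 10-stage dormant-bud-to-full-bloom window). The
#' pair is flagged reciprocal when the correlation is <= -0.5.
#'
#' @param mat FPKM matrix.
#' @param gene_a,gene_b gene ids (rows of `mat`).
#' @param samples character vector of sample columns to use (>= 3).
#' @param method "pearson" (default) or "spearman".
#' @param cutoff reciprocal-flag threshold (default -0.5).
#' @return list with `correlation` and `reciprocal`.
#' @export
reciprocal_score <- function(mat, gene_a, gene_b, samples = colnames(mat),
                             method = c("pearson", "spearman"),
                             cutoff = -0.5) {
  method <- match.arg(method)
  if (length(samples) < 3) stop("need at least 3 stages")
  a <- log_transform(mat[gene_a, samples, drop = TRUE])
  b <- log_transform(mat[gene_b, samples, drop = TRUE])
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant expression profile: correlation undefined")
  }
  r <- stats::cor(a, b, method = method)
  list(correlation = r, reciprocal = r <= cutoff)
}

#' Fold change by the comparative delta-delta-Ct method
#'
#' \eqn{\Delta Ct = Ct_{target} - Ct_{reference}} per sample;
#' \eqn{\Delta\Delta Ct = \Delta Ct_{test} - \Delta Ct_{calibrator}};
#' fold = \eqn{2^{-\Delta\Delta Ct}}.
#'
#' @param ct_target_test,ct_reference_test Ct values in the test sample.
#' @param ct_target_cal,ct_reference_cal Ct values in the calibrator sample.
#' @return list with `dct_test`, `dct_calibrator`, `ddct`, `fold`.
#' @export
ddct_fold <- function(ct_target_test, ct_reference_test,
                      ct_target_cal, ct_reference_cal) {
  vals <- c(ct_target_test, ct_reference_test, ct_target_cal, ct_reference_cal)
  if (any(!is.finite(vals))) stop("Ct values must be finite")
  dct_test <- ct_target_test - ct_reference_test
  dct_cal <- ct_target_cal - ct_reference_cal
  ddct <- dct_test - dct_cal
  list(dct_test = dct_test, dct_calibrator = dct_cal, ddct = ddct,
       fold = 2^(-ddct))
}

#' Concordance between FPKM and qPCR fold changes
#'
#' Pearson correlation over matched log2 fold changes.
#'
#' @param fpkm_fold,qpcr_fold positive fold-change vectors, matched points.
#' @return correlation (scalar).
#' @export
concordance <- function(fpkm_fold, qpcr_fold) {
  if (length(fpkm_fold) != length(qpcr_fold)) stop("length mismatch")
  if (length(fpkm_fold) < 3) stop("need >= 3 matched points")
  stats::cor(log2(fpkm_fold), log2(qpcr_fold))
}

#' Heatmap export matrix
#'
#' The log2-transformed FPKM matrix ordered by the phase design, exactly as
#' used for heatmap rendering.
#'
#' @param mat FPKM matrix.
#' @param design a [stage_design()] table.
#' @param pseudocount passed to [log_transform()].
#' @return transformed matrix with columns in design order.
#' @export
heatmap_matrix <- function(mat, design = stage_design(), pseudocount = 1) {
  cols <- design$sample[design$sample %in% colnames(mat)]
  log_transform(mat[, cols, drop = FALSE], pseudocount)
}
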