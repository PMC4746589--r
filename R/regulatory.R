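#' Extract upstream promoter regions
#'
#' For a + strand gene the window is `[start - window, start)` in 0-based
#' half-open genome coordinates; for a - strand gene it is `(end, end +
#' window]`, reverse-complemented, so the returned sequence always reads
#' 5'-to-3' towards the transcription start. Windows are truncated at
#' chromosome edges and the truncation recorded.
#'
#' @param models gene-model data.frame.
#' @param genome named character vector of chromosome sequences.
#' @param window upstream window in bp (2000 for target search, 1500 for
#'   LTRE-style analysis).
#' @return list with `regions` (named character vector) and `info`
#'   (data.frame `gene_id`, `length`, `truncated`).
#' @export
extract_upstream <- function(models, genome, window = 2000) {
  models <- as_gene_models(models)
  missing_chr <- setdiff(unique(models$chromosome), names(genome))
  if (length(missing_chr) > 0) {
    stop("unknown chromosome(s): ", paste(missing_chr, collapse = ", "))
  }
  regions <- character(nrow(models))
  lens <- integer(nrow(models))
  trunc <- logical(nrow(models))
  for (i in seq_len(nrow(models))) {
    chr_seq <- genome[[models$chromosome[i]]]
    chr_len <- nchar(chr_seq)
    if (models$strand[i] == "-") {
      from <- models$end[i] + 1L
      to <- min(models$end[i] + window, chr_len)
      trunc[i] <- to - from + 1L < window
      s <- if (from > to) "" else revcomp(substr(chr_seq, from, to))
    } else {
      from <- max(models$start[i] - window, 1L)
      to <- models$start[i] - 1L
      trunc[i] <- to - from + 1L < window
      s <- if (from > to) "" else substr(chr_seq, from, to)
    }
    regions[i] <- s
    lens[i] <- nchar(s)
  }
  names(regions) <- models$gene_id
  list(regions = regions,
       info = data.frame(gene_id = models$gene_id, length = lens,
                         truncated = trunc, stringsAsFactors = FALSE))
}

#' Filter a motif library by ChIP peak occurrence
#'
#' A pattern is retained iff it matches at least once (either strand) wholly
#' inside at least one peak interval; matches spanning a peak boundary do
#' not count because the scan runs on the extracted peak sequences.
#'
#' @param library motif library (see [scan_motifs()]).
#' @param peaks data.frame `chrom`, `start`, `end` (0-based half-open).
#' @param genome named character vector of chromosome sequences.
#' @param phase phase label carried through ("vegetative"/"reproductive").
#' @param both_strands scan both strands (default TRUE).
#' @return data.frame with `phase`, `id`, `iupac`, `n_peak_hits`, `retained`.
#' @export
filter_phase_motifs <- function(library, peaks, genome, phase = "phase",
                                both_strands = TRUE) {
  lib <- as_motif_library(library)
  missing_chr <- setdiff(unique(peaks$chrom), names(genome))
  if (nrow(peaks) > 0 && length(missing_chr) > 0) {
    stop("peaks on unknown chromosome(s): ",
         paste(missing_chr, collapse = ", "))
  }
  peak_seqs <- vapply(seq_len(nrow(peaks)), function(i) {
    substr(genome[[peaks$chrom[i]]], peaks$start[i] + 1L, peaks$end[i])
  }, "")
  hits <- integer(nrow(lib))
  if (length(peak_seqs) > 0) {
    cnt <- count_motifs(setNames(peak_seqs, seq_along(peak_seqs)), lib,
                        both_strands)
    hits <- colSums(cnt)
  }
  data.frame(phase = phase, id = lib$id, iupac = lib$iupac,
             n_peak_hits = as.integer(hits), retained = hits > 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Predict TF targets from phase motifs and upstream regions
#'
#' A gene is a target iff at least one retained phase motif matches its
#' upstream region; also reports how many distinct patterns are present
#' anywhere in the region set ("unique motifs present").
#'
#' @param phase_motifs output of [filter_phase_motifs()] (only `retained`
#'   rows are used), or any motif library.
#' @param regions named character vector of upstream sequences.
#' @param both_strands scan both strands.
#' @return list with `targets` (character vector), `counts` (regions x
#'   motifs matrix), `unique_motifs_present` (integer).
#' @export
predict_targets <- function(phase_motifs, regions, both_strands = TRUE) {
  if (is.data.frame(phase_motifs) && "retained" %in% names(phase_motifs)) {
    phase_motifs <- phase_motifs[phase_motifs$retained, , drop = FALSE]
  }
  lib <- as_motif_library(phase_motifs)
  if (nrow(lib) == 0 || length(regions) == 0) {
    return(list(targets = character(0),
                counts = matrix(0L, length(regions), 0,
                                dimnames = list(names(regions), NULL)),
                unique_motifs_present = 0L))
  }
  counts <- count_motifs(regions, lib, both_strands)
  list(
    targets = rownames(counts)[rowSums(counts) > 0],
    counts = counts,
    unique_motifs_present = sum(colSums(counts) > 0)
  )
}

#' Build a target-seeded protein interaction network
#'
#' Maps predicted target genes to interactome nodes via best-hit ortholog
#' calls, keeps every interactome edge with at least one endpoint in the
#' seed set, merges duplicate edges, drops self-loops, and removes seeds
#' without any interaction partner.
#'
#' @param targets character vector of target gene ids.
#' @param ortholog_map named character vector target gene -> interactome
#'   node id (e.g. from [call_orthologs()]), or NULL if `targets` already
#'   are node ids.
#' @param edges interactome edge list (data.frame, first two columns are
#'   node ids).
#' @return object of class `target_network`: list with `graph` (igraph),
#'   `seeds` (mapped seeds present in the network), `degree`, `components`,
#'   `largest_component` (node names).
#' @export
build_target_network <- function(targets, ortholog_map = NULL, edges) {
  if (nrow(edges) == 0) stop("empty interactome")
  seeds <- if (is.null(ortholog_map)) targets else
    unname(ortholog_map[intersect(targets, names(ortholog_map))])
  seeds <- unique(seeds[!is.na(seeds)])
  keep <- edges[, 1] %in% seeds | edges[, 2] %in% seeds
  sub <- edges[keep, 1:2, drop = FALSE]
  if (nrow(sub) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    g <- igraph::simplify(igraph::graph_from_data_frame(sub, directed = FALSE))
    g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  }
  comps <- igraph::components(g)
  largest <- character(0)
  if (comps$no > 0) {
    big <- which.max(comps$csize)
    largest <- names(comps$membership)[comps$membership == big]
  }
  structure(list(
    graph = g,
    seeds = intersect(seeds, igraph::V(g)$name),
    degree = igraph::degree(g),
    components = comps,
    largest_component = largest
  ), class = "target_network")
}

#' @export
print.target_network <- function(x, ...) {
  cat("target network:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges;",
      length(x$seeds), "seeds;",
      "largest component", length(x$largest_component), "nodes\n")
  invisible(x)
}

# Hurwitz zeta via the Riemann zeta minus the leading terms
hurwitz_zeta <- function(alpha, xmin) {
  z <- pracma::zeta(alpha)
  if (xmin > 1) z <- z - sum((1:(xmin - 1))^(-alpha))
  z
}

#' Discrete power-law fit of a degree distribution
#'
#' Maximum-likelihood estimate of the exponent of \eqn{P(k) \propto
#' k^{-\alpha}} for \eqn{k \ge x_{min}} (zeta distribution), with the
#' Kolmogorov–Smirnov distance between empirical and fitted CDFs, plus the
#' log-log least-squares slope and R² of the degree distribution as a
#' secondary descriptor.
#'
#' @param network a `target_network`, an igraph object, or a numeric vector
#'   of degrees.
#' @param xmin minimum degree included in the fit (default 1).
#' @return list with `alpha`, `ks_distance`, `loglog_slope`, `loglog_r2`,
#'   `n`, `xmin`, and `degree_table`.
#' @export
degree_powerlaw <- function(network, xmin = 1) {
  deg <- if (inherits(network, "target_network")) unname(network$degree)
  else if (inherits(network, "igraph")) unname(igraph::degree(network))
  else as.numeric(network)
  deg <- deg[deg >= xmin]
  if (length(deg) < 10) stop("need >= 10 nodes with degree >= xmin")
  if (length(unique(deg)) < 2) stop("degenerate degree distribution")

  slk <- sum(log(deg))
  nll <- function(a) length(deg) * log(hurwitz_zeta(a, xmin)) + a * slk
  opt <- stats::optimize(nll, c(1.0001, 25), tol = 1e-10)
  alpha <- opt$minimum

  # KS distance on the discrete support
  ks <- powerlaw_ks(deg, alpha, xmin)

  tab <- table(deg)
  k <- as.numeric(names(tab))
  pk <- as.numeric(tab) / length(deg)
  fit <- stats::lm(log(pk) ~ log(k))
  r2 <- summary(fit)$r.squared

  list(alpha = alpha, ks_distance = ks,
       loglog_slope = unname(stats::coef(fit)[2]), loglog_r2 = r2,
       n = length(deg), xmin = xmin,
       degree_table = data.frame(k = k, count = as.integer(tab),
                                 p = pk, row.names = NULL))
}

powerlaw_ks <- function(deg, alpha, xmin) {
  kmax <- max(deg)
  ks_support <- xmin:kmax
  z <- hurwitz_zeta(alpha, xmin)
  theo_cdf <- cumsum(ks_support^(-alpha) / z)
  emp_cdf <- vapply(ks_support, function(k) mean(deg <= k), 0)
  max(abs(emp_cdf - theo_cdf))
}

#' Find hub nodes of the largest connected component
#'
#' Ranks the largest component's nodes by degree (ties broken by node id)
#' and returns the top `k`, together with the hub fraction of the
#' component.
#'
#' @param network a `target_network` or igraph object.
#' @param k number of hubs (default 5).
#' @return list with `hubs`, `component_size`, `hub_fraction_percent`.
#' @export
find_hubs <- function(network, k = 5) {
  if (inherits(network, "target_network")) {
    g <- network$graph
    comp <- network$largest_component
  } else {
    g <- network
    cs <- igraph::components(g)
    if (cs$no == 0) stop("empty network")
    comp <- names(cs$membership)[cs$membership == which.max(cs$csize)]
  }
  if (length(comp) == 0) stop("empty network")
  if (k > length(comp)) {
    stop("k = ", k, " exceeds largest component size ", length(comp))
  }
  deg <- igraph::degree(g, v = comp)
  ord <- order(-deg, names(deg))
  hubs <- names(deg)[ord][seq_len(k)]
  list(hubs = hubs, component_size = length(comp),
       hub_fraction_percent = 100 * k / length(comp))
}

#' Hypergeometric GO term enrichment with BH correction
#'
#' Per term, the upper-tail hypergeometric probability of observing at
#' least the seen overlap between the gene set and the term's annotated
#' genes within the universe, Benjamini–Hochberg adjusted across all tested
#' terms; significant iff FDR < `fdr_cutoff`.
#'
#' @param gene_set character vector (must be a subset of `universe`).
#' @param annotations data.frame with columns `gene`, `term`.
#' @param universe character vector of all genes.
#' @param fdr_cutoff significance threshold (default 0.05).
#' @return data.frame with `term`, `k` (overlap), `n` (set size), `K` (term
#'   size), `N` (universe size), `p`, `fdr`, `significant`, ordered by `p`.
#' @export
go_enrichment <- function(gene_set, annotations, universe,
                          fdr_cutoff = 0.05) {
  offenders <- setdiff(gene_set, universe)
  if (length(offenders) > 0) {
    stop("gene set not contained in universe: ",
         paste(offenders, collapse = ", "))
  }
  ann <- annotations[annotations$gene %in% universe, , drop = FALSE]
  terms <- unique(ann$term)
  N <- length(universe)
  n <- length(unique(gene_set))
  rows <- lapply(terms, function(t) {
    genes_t <- unique(ann$gene[ann$term == t])
    K <- length(genes_t)
    k <- length(intersect(gene_set, genes_t))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = t, k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$fdr < fdr_cutoff
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}
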