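#' Detect homologous protein pairs
#'
#' All-vs-all local alignment with a shared-5-mer prefilter (only pairs
#' sharing at least `min_shared_kmers` distinct 5-mers are aligned, the usual
#' seed heuristic). Significance uses a Karlin–Altschul style e-value
#' \eqn{E = K m n e^{-\lambda S}} with gapped BLOSUM62 constants
#' (\eqn{\lambda = 0.267}, \eqn{K = 0.041}). Per query at most `top_k` best
#' non-self subjects under the threshold are kept; the symmetric closure is
#' then deduplicated to unordered pairs.
#'
#' @param proteins named character vector.
#' @param evalue_threshold pair-inclusion threshold (default 1e-10).
#' @param top_k best subjects kept per query (default 5).
#' @param kmer prefilter word size.
#' @param min_shared_kmers distinct shared words required to attempt an
#'   alignment.
#' @return data.frame with `gene_a`, `gene_b` (lexicographically ordered
#'   within each row), `score`, `evalue`.
#' @export
build_homolog_pairs <- function(proteins, evalue_threshold = 1e-10,
                                top_k = 5, kmer = 5, min_shared_kmers = 3) {
  ids <- names(proteins)
  n <- length(proteins)
  # seed index: kmer -> protein indices
  index <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    s <- proteins[[i]]
    L <- nchar(s)
    if (L < kmer) next
    words <- unique(substring(s, 1:(L - kmer + 1), kmer:L))
    for (wd in words) {
      index[[wd]] <- c(index[[wd]], i)
    }
  }
  pair_count <- new.env(hash = TRUE, parent = emptyenv())
  for (wd in ls(index)) {
    v <- index[[wd]]
    if (length(v) < 2) next
    for (a in seq_len(length(v) - 1)) {
      for (b in (a + 1):length(v)) {
        key <- paste(v[a], v[b])
        cur <- pair_count[[key]]
        pair_count[[key]] <- if (is.null(cur)) 1L else cur + 1L
      }
    }
  }
  lambda <- 0.267
  K <- 0.041
  cand <- ls(pair_count)
  rows <- list()
  for (key in cand) {
    if (pair_count[[key]] < min_shared_kmers) next
    ij <- as.integer(strsplit(key, " ")[[1]])
    a <- align_local(proteins[[ij[1]]], proteins[[ij[2]]])
    ev <- K * nchar(proteins[[ij[1]]]) * nchar(proteins[[ij[2]]]) *
      exp(-lambda * a$score)
    if (ev <= evalue_threshold) {
      rows[[length(rows) + 1L]] <- data.frame(
        i = ij[1], j = ij[2], score = a$score, evalue = ev,
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), evalue = numeric(0))
  if (length(rows) == 0) return(empty)
  df <- do.call(rbind, rows)
  # per-query top_k filter on the directed view, then symmetric dedup
  directed <- rbind(
    data.frame(q = df$i, s = df$j, score = df$score, evalue = df$evalue),
    data.frame(q = df$j, s = df$i, score = df$score, evalue = df$evalue)
  )
  keep <- unlist(lapply(split(seq_len(nrow(directed)), directed$q), function(r) {
    r[order(-directed$score[r])][seq_len(min(top_k, length(r)))]
  }))
  directed <- directed[sort(unique(keep)), ]
  a <- pmin(directed$q, directed$s)
  b <- pmax(directed$q, directed$s)
  u <- !duplicated(paste(a, b))
  out <- data.frame(
    gene_a = ids[a[u]], gene_b = ids[b[u]],
    score = directed$score[u], evalue = directed$evalue[u],
    stringsAsFactors = FALSE
  )
  swap <- out$gene_a > out$gene_b
  tmp <- out$gene_a[swap]
  out$gene_a[swap] <- out$gene_b[swap]
  out$gene_b[swap] <- tmp
  rownames(out) <- NULL
  out
}

# anchors for one chromosome pair: data.frame(ra, rb, idx); returns best
# chain (indices into the anchor table) and its score for one orientation
chain_dp <- function(ra, rb, max_gap, penalty, orientation) {
  n <- length(ra)
  best <- rep(1, n)
  pred <- rep(NA_integer_, n)
  ord <- order(ra, rb)
  ra <- ra[ord]
  rb <- rb[ord]
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      da <- ra[i] - ra[j]
      db <- if (orientation == "+") rb[i] - rb[j] else rb[j] - rb[i]
      if (da < 1 || db < 1) next
      if (da - 1 > max_gap || db - 1 > max_gap) next
      cand <- best[j] + 1 - penalty * ((da - 1) + (db - 1))
      if (cand > best[i] + 1e-12) {
        best[i] <- cand
        pred[i] <- j
      }
    }
  }
  end <- which.max(best) # first max: earliest-sorted end, deterministic
  chain <- integer(0)
  k <- end
  while (!is.na(k)) {
    chain <- c(k, chain)
    k <- pred[k]
  }
  list(chain = ord[chain], score = best[end])
}

#' Chain homolog pairs into collinear blocks
#'
#' Dynamic-programming chaining of homolog-pair anchors per chromosome pair:
#' each anchor scores +1 and each step pays a penalty proportional to the
#' gene-order rank gap it skips, with per-step gaps capped at `max_gap`
#' intervening ranks. Both orientations are tried. Maximal-scoring chains
#' are reported greedily (best chain, remove its anchors, repeat) and kept
#' if they contain at least `min_block` anchors.
#'
#' @param pairs homolog pairs (data.frame `gene_a`, `gene_b`).
#' @param models gene-model data.frame with ranks.
#' @param max_gap max intervening ranks per step (default 25).
#' @param min_block minimum anchors per reported block (default 5).
#' @param gap_penalty score penalty per skipped rank (default 0.01).
#' @return data.frame with one row per anchor, columns `block`, `chrom_a`,
#'   `chrom_b`, `gene_a`, `gene_b`, `rank_a`, `rank_b`, `orientation`,
#'   `chain_score`, `n_anchors`.
#' @export
chain_collinear <- function(pairs, models, max_gap = 25, min_block = 5,
                            gap_penalty = 0.01) {
  models <- as_gene_models(models)
  loc <- models[match(c(pairs$gene_a, pairs$gene_b), models$gene_id), ]
  if (anyNA(loc$gene_id)) stop("pair member missing from gene models")
  np <- nrow(pairs)
  anc <- data.frame(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    chrom_a = loc$chromosome[seq_len(np)],
    chrom_b = loc$chromosome[np + seq_len(np)],
    rank_a = loc$rank[seq_len(np)],
    rank_b = loc$rank[np + seq_len(np)],
    stringsAsFactors = FALSE
  )
  # canonical orientation of each anchor: chrom_a <= chrom_b (rank_a <= rank_b
  # within a chromosome)
  flip <- anc$chrom_a > anc$chrom_b |
    (anc$chrom_a == anc$chrom_b & anc$rank_a > anc$rank_b)
  anc[flip, c("gene_a", "gene_b", "chrom_a", "chrom_b", "rank_a", "rank_b")] <-
    anc[flip, c("gene_b", "gene_a", "chrom_b", "chrom_a", "rank_b", "rank_a")]

  out <- list()
  block_id <- 0L
  for (cp in unique(paste(anc$chrom_a, anc$chrom_b))) {
    sub <- anc[paste(anc$chrom_a, anc$chrom_b) == cp, , drop = FALSE]
    repeat {
      if (nrow(sub) < min_block) break
      fw <- chain_dp(sub$rank_a, sub$rank_b, max_gap, gap_penalty, "+")
      rv <- chain_dp(sub$rank_a, sub$rank_b, max_gap, gap_penalty, "-")
      pick <- if (rv$score > fw$score + 1e-12) list(rv, "-") else list(fw, "+")
      chain <- pick[[1]]$chain
      if (length(chain) < min_block) break
      block_id <- block_id + 1L
      blk <- sub[chain, , drop = FALSE]
      blk$block <- block_id
      blk$orientation <- pick[[2]]
      blk$chain_score <- pick[[1]]$score
      blk$n_anchors <- length(chain)
      out[[block_id]] <- blk
      sub <- sub[-chain, , drop = FALSE]
    }
  }
  if (length(out) == 0) {
    return(data.frame(block = integer(0), chrom_a = character(0),
                      chrom_b = character(0), gene_a = character(0),
                      gene_b = character(0), rank_a = integer(0),
                      rank_b = integer(0), orientation = character(0),
                      chain_score = numeric(0), n_anchors = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("block", "chrom_a", "chrom_b", "gene_a", "gene_b",
          "rank_a", "rank_b", "orientation", "chain_score", "n_anchors")]
}

#' Classify duplication mode of family genes
#'
#' Each family gene gets exactly one mode under the precedence
#' segmental > tandem > proximal > dispersed > singleton:
#' segmental if the gene anchors a collinear block; tandem if a homolog sits
#' at the adjacent gene-order rank on the same chromosome; proximal if a
#' homolog sits within `proximal_window` ranks; dispersed if it has any
#' other homolog; singleton otherwise.
#'
#' @param family character vector of family gene ids.
#' @param models gene-model data.frame with ranks.
#' @param pairs homolog pairs data.frame.
#' @param blocks output of [chain_collinear()] (may have zero rows).
#' @param proximal_window rank window for proximal calls (default 20).
#' @return data.frame with `gene_id`, `mode`.
#' @export
classify_duplications <- function(family, models, pairs, blocks,
                                  proximal_window = 20) {
  models <- as_gene_models(models)
  block_genes <- unique(c(blocks$gene_a, blocks$gene_b))
  chr <- setNames(models$chromosome, models$gene_id)
  rnk <- setNames(models$rank, models$gene_id)
  partner <- function(g) {
    c(pairs$gene_b[pairs$gene_a == g], pairs$gene_a[pairs$gene_b == g])
  }
  mode <- vapply(family, function(g) {
    if (g %in% block_genes) return("segmental")
    ps <- partner(g)
    if (length(ps) == 0) return("singleton")
    same <- ps[chr[ps] == chr[g]]
    dr <- abs(rnk[same] - rnk[g])
    if (any(dr == 1)) return("tandem")
    if (any(dr <= proximal_window)) return("proximal")
    "dispersed"
  }, "")
  data.frame(gene_id = family, mode = unname(mode), stringsAsFactors = FALSE)
}

#' Detect chromosomal gene clusters of family members
#'
#' Single-linkage grouping along each chromosome: consecutive family genes
#' are joined when separated by at most `max_rank_gap` intervening genes AND
#' at most `max_bp_gap` base pairs. Only clusters of two or more genes are
#' reported, together with their subfamily composition when a subfamily map
#' is supplied.
#'
#' @param family character vector of family gene ids.
#' @param models gene-model data.frame (all genes, for rank context).
#' @param max_rank_gap max intervening (non-cluster) genes between members.
#' @param max_bp_gap max base-pair gap between consecutive members.
#' @param subfamily optional named vector gene -> subfamily label.
#' @return data.frame with `cluster`, `chromosome`, `genes`
#'   (comma-separated, in order), `size`, `composition`, `pure_mikcc`.
#' @export
detect_clusters <- function(family, models, max_rank_gap = 5,
                            max_bp_gap = 250000, subfamily = NULL) {
  models <- as_gene_models(models)
  fam <- models[models$gene_id %in% family, , drop = FALSE]
  out <- list()
  cl_id <- 0L
  for (ch in unique(fam$chromosome)) {
    sub <- fam[fam$chromosome == ch, , drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    if (nrow(sub) == 0) next
    grp <- cumsum(c(1, (diff(sub$rank) - 1 > max_rank_gap) |
                      (sub$start[-1] - sub$end[-nrow(sub)] > max_bp_gap)))
    for (g in unique(grp)) {
      mem <- sub$gene_id[grp == g]
      if (length(mem) < 2) next
      cl_id <- cl_id + 1L
      comp <- if (is.null(subfamily)) NA_character_ else
        paste(sort(unique(subfamily[mem])), collapse = ",")
      out[[cl_id]] <- data.frame(
        cluster = cl_id, chromosome = ch,
        genes = paste(mem, collapse = ","), size = length(mem),
        composition = comp,
        pure_mikcc = if (is.null(subfamily)) NA else
          all(subfamily[mem] == "MIKCc"),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(cluster = integer(0), chromosome = character(0),
                      genes = character(0), size = integer(0),
                      composition = character(0), pure_mikcc = logical(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-chromosome family summary
#'
#' @param family character vector of family gene ids.
#' @param models gene-model data.frame.
#' @param calls output of [classify_duplications()].
#' @param clusters output of [detect_clusters()].
#' @return list with `per_chromosome` (gene and cluster counts), `per_mode`
#'   (counts and percentages over the family size).
#' @export
chromosome_summary <- function(family, models, calls, clusters) {
  models <- as_gene_models(models)
  fam <- models[models$gene_id %in% family, , drop = FALSE]
  count_by_chrom <- function(x, col) {
    if (length(x) == 0) {
      out <- data.frame(chromosome = character(0), n = integer(0))
    } else {
      out <- as.data.frame(table(chromosome = x), stringsAsFactors = FALSE)
    }
    names(out)[2] <- col
    out
  }
  per_chrom <- count_by_chrom(fam$chromosome, "n_genes")
  cl <- count_by_chrom(clusters$chromosome, "n_clusters")
  per_chrom <- merge(per_chrom, cl, by = "chromosome", all.x = TRUE)
  per_chrom$n_clusters[is.na(per_chrom$n_clusters)] <- 0L
  modes <- c("segmental", "tandem", "proximal", "dispersed", "singleton")
  cnt <- vapply(modes, function(m) sum(calls$mode == m), 0L)
  per_mode <- data.frame(
    mode = modes, n = cnt,
    percent = if (length(family) > 0) 100 * cnt / length(family) else 0,
    stringsAsFactors = FALSE
  )
  list(per_chromosome = per_chrom, per_mode = per_mode,
       family_size = length(family))
}
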