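#' Pairwise distances from a protein alignment
#'
#' p-distance (mismatches over compared sites) or Poisson-corrected distance
#' \eqn{d = -\ln(1 - p)}, with pairwise deletion of gap columns.
#'
#' @param alignment named character vector of equal-length aligned sequences.
#' @param model "poisson" (default) or "p".
#' @return symmetric distance matrix with zero diagonal.
#' @export
aln_distance <- function(alignment, model = c("poisson", "p")) {
  model <- match.arg(model)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1) stop("alignment sequences differ in length")
  n <- length(alignment)
  if (is.null(names(alignment))) names(alignment) <- paste0("t", seq_len(n))
  m <- do.call(rbind, strsplit(alignment, ""))
  gap <- m == "-" | m == "."
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- !gap[i, ] & !gap[j, ]
      if (!any(use)) stop("no comparable sites for pair ",
                          names(alignment)[i], " / ", names(alignment)[j])
      p <- sum(m[i, use] != m[j, use]) / sum(use)
      if (model == "poisson") {
        if (p >= 1) stop("saturated pair (p = 1) under Poisson model: ",
                         names(alignment)[i], " / ", names(alignment)[j])
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou–Nei agglomeration by Q-criterion minimization with the standard
#' branch-length formulas. Ties in Q are broken on the smallest (i, j) index
#' pair in cluster-creation order. Negative estimated branch lengths are
#' clamped to zero with the deficit transferred to the sibling branch of the
#' same join (their sum is preserved).
#'
#' @param d symmetric distance matrix (dimnames = taxa), n >= 3.
#' @return unrooted `phylo` tree with branch lengths.
#' @export
nj_tree <- function(d) {
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  }
  labels <- rownames(d)
  D <- unname(as.matrix(d))
  # each active cluster is a newick fragment
  nwk <- labels
  fmt <- function(x) sprintf("%.17g", max(x, 0))
  while (length(nwk) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # smallest (i, j) among minima
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]
    j <- idx[1, 2]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    if (vi < 0) {
      vj <- D[i, j]
      vi <- 0
    } else if (vj < 0) {
      vi <- D[i, j]
      vj <- 0
    }
    new_nwk <- paste0("(", nwk[i], ":", fmt(vi), ",", nwk[j], ":", fmt(vj), ")")
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
  }
  # final three-point resolution
  vx <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vy <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vz <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- paste0("(", nwk[1], ":", fmt(vx), ",", nwk[2], ":", fmt(vy),
                ",", nwk[3], ":", fmt(vz), ");")
  ape::read.tree(text = txt)
}

# bipartitions of the internal edges of a tree; canonical character keys
# (side not containing the alphabetically first taxon, sorted labels)
tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    side <- sort(tree$tip.label[p])
    if (length(side) >= length(tips) - 1) next # root / trivial
    if (tips[1] %in% side) side <- setdiff(tips, side)
    if (length(side) < 2) next
    keys <- c(keys, paste(side, collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds distance + NJ per
#' replicate, and reports for each internal edge of the original tree the
#' percentage of replicate trees containing its bipartition. Taxa are
#' canonically sorted before resampling so the result is invariant to input
#' order under a fixed seed.
#'
#' @param alignment named character vector (gap-free or gap-light).
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param model distance model for [aln_distance()].
#' @return object of class `supported_tree`: list with `tree` (phylo, with
#'   `node.label` carrying supports), `support` (data.frame `split`,
#'   `support`), `n_reps`.
#' @export
bootstrap_support <- function(alignment, n_reps = 1000, seed = 1,
                              model = "poisson") {
  alignment <- alignment[order(names(alignment))]
  set.seed(seed)
  mat <- do.call(rbind, strsplit(alignment, ""))
  rownames(mat) <- names(alignment)
  ncol_aln <- ncol(mat)
  collapse <- function(m) setNames(
    vapply(seq_len(nrow(m)), function(i) paste(m[i, ], collapse = ""), ""),
    rownames(m))
  tree <- nj_tree(aln_distance(alignment, model))
  orig <- tree_splits(tree)
  count <- setNames(rep(0L, length(orig)), orig)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
    rep_aln <- collapse(mat[, cols, drop = FALSE])
    rep_tree <- nj_tree(aln_distance(rep_aln, model))
    hit <- orig %in% tree_splits(rep_tree)
    count[hit] <- count[hit] + 1L
  }
  support <- data.frame(split = orig, support = 100 * count / n_reps,
                        stringsAsFactors = FALSE, row.names = NULL)
  # attach to node labels of the original tree
  tips <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  lab <- rep("", tree$Nnode)
  for (k in seq_along(parts)) {
    side <- sort(tree$tip.label[parts[[k]]])
    if (tips[1] %in% side) side <- setdiff(tips, side)
    key <- paste(side, collapse = "|")
    m <- match(key, support$split)
    if (!is.na(m)) lab[k] <- sprintf("%g", support$support[m])
  }
  tree$node.label <- lab
  structure(list(tree = tree, support = support, n_reps = n_reps),
            class = "supported_tree")
}

#' @export
print.supported_tree <- function(x, ...) {
  cat("NJ tree with", length(x$tree$tip.label), "taxa;",
      nrow(x$support), "internal splits;", x$n_reps,
      "bootstrap replicates\n")
  if (nrow(x$support) > 0) {
    cat(sprintf("support: min %.1f / median %.1f / max %.1f\n",
                min(x$support$support), stats::median(x$support$support),
                max(x$support$support)))
  }
  invisible(x)
}

#' Assign subfamily/clade labels and functional calls by reference anchoring
#'
#' Each query receives the label of the smallest edge-bounded subtree
#' containing it and at least one reference taxon, provided that subtree's
#' references carry a single label; otherwise it stays unassigned. A
#' functional call (e.g. DAM or FLC-like) is made when that label-pure
#' subtree also contains a functional anchor taxon and the assigned label
#' equals `functional_label` (functional calls are restricted to the
#' MIKC^C subfamily by default).
#'
#' @param tree `phylo` tree (or `supported_tree`).
#' @param reference_labels named character vector: reference taxon -> label.
#' @param anchors optional named character vector: anchor taxon -> functional
#'   class (e.g. "DAM", "FLC").
#' @param functional_label subfamily label eligible for functional calls.
#' @return data.frame with `taxon`, `label`, `functional`.
#' @export
assign_clades <- function(tree, reference_labels, anchors = NULL,
                          functional_label = "MIKCc") {
  if (inherits(tree, "supported_tree")) tree <- tree$tree
  refs <- names(reference_labels)
  if (!any(refs %in% tree$tip.label)) {
    stop("tree contains no reference taxa")
  }
  refs <- refs[refs %in% tree$tip.label]
  tips <- tree$tip.label
  # edge-bounded subtrees: every clade of the (arbitrarily rooted) phylo
  # representation and its complement
  parts <- ape::prop.part(tree)
  sets <- list()
  for (p in parts) {
    sets[[length(sets) + 1L]] <- tips[p]
    sets[[length(sets) + 1L]] <- setdiff(tips, tips[p])
  }
  for (t in tips) { # pendant edges
    sets[[length(sets) + 1L]] <- t
    sets[[length(sets) + 1L]] <- setdiff(tips, t)
  }
  keys <- vapply(sets, function(s) paste(sort(s), collapse = "|"), "")
  sets <- sets[!duplicated(keys)]
  sizes <- lengths(sets)

  queries <- setdiff(tips, character(0))
  rows <- lapply(queries, function(q) {
    cand <- which(vapply(sets, function(s) q %in% s && any(refs %in% s), TRUE))
    if (length(cand) == 0) {
      return(data.frame(taxon = q, label = "unassigned", functional = "none",
                        stringsAsFactors = FALSE))
    }
    cand <- cand[order(sizes[cand],
                       vapply(sets[cand], function(s) paste(sort(s), collapse = "|"), ""))]
    s <- sets[[cand[1]]]
    labs <- unique(reference_labels[intersect(refs, s)])
    if (length(labs) != 1) {
      return(data.frame(taxon = q, label = "unassigned", functional = "none",
                        stringsAsFactors = FALSE))
    }
    fun <- "none"
    if (!is.null(anchors) && labs == functional_label) {
      anc_in <- intersect(names(anchors), s)
      cls <- unique(anchors[anc_in])
      if (length(cls) == 1) fun <- unname(cls)
    }
    data.frame(taxon = q, label = unname(labs), functional = fun,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
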