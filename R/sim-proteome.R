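#' Simulate a proteome with a planted conserved domain
#'
#' Generates `n_family` proteins that each carry exactly one copy of a
#' conserved domain (a fixed consensus mutated at per-site probability
#' `domain_divergence`) embedded in random flanks, plus `n_background`
#' proteins drawn i.i.d. from a uniform background over the 20 amino acids.
#' A small seed alignment (low-divergence copies of the consensus) is emitted
#' for profile building.
#'
#' @param n_family number of family (domain-carrying) proteins.
#' @param n_background number of background proteins.
#' @param domain_length domain length in residues (>= 10; the canonical
#'   MADS domain is 58).
#' @param domain_divergence per-site substitution probability in [0, 1).
#' @param protein_length total protein length (>= domain_length + 2).
#' @param n_seed number of sequences in the emitted seed alignment.
#' @param seed_divergence per-site divergence of the seed alignment.
#' @param seed RNG seed; fixed seed gives identical output.
#' @return list with `proteins` (named character vector), `seed_alignment`
#'   (character vector), `consensus`, and `truth` (family membership, domain
#'   start per family protein, 0-based half-open on the protein).
#' @export
sim_proteome <- function(n_family = 50, n_background = 500,
                         domain_length = 58, domain_divergence = 0.1,
                         protein_length = 300,
                         n_seed = 10, seed_divergence = 0.05,
                         seed = 1) {
  if (domain_divergence < 0 || domain_divergence >= 1) {
    stop("domain_divergence must be in [0, 1)")
  }
  if (domain_length < 10) stop("domain_length must be >= 10")
  if (protein_length < domain_length + 2) {
    stop("protein_length must exceed domain_length + 2")
  }
  set.seed(seed)
  consensus <- random_seq(domain_length, AA20)
  seed_aln <- vapply(seq_len(n_seed), function(i) {
    mutate_seq(consensus, seed_divergence, AA20)
  }, "")
  names(seed_aln) <- sprintf("seed%02d", seq_len(n_seed))

  ids_fam <- sprintf("FAM%04d", seq_len(n_family))
  ids_bg <- sprintf("BG%04d", seq_len(n_background))
  dom_start <- integer(0)

  fam <- vapply(seq_len(n_family), function(i) {
    dom <- mutate_seq(consensus, domain_divergence, AA20)
    pos <- sample.int(protein_length - domain_length + 1L, 1L)
    dom_start[i] <<- pos - 1L
    left <- if (pos > 1) random_seq(pos - 1L, AA20) else ""
    right_len <- protein_length - domain_length - (pos - 1L)
    right <- if (right_len > 0) random_seq(right_len, AA20) else ""
    paste0(left, dom, right)
  }, "")
  bg <- vapply(seq_len(n_background), function(i) {
    random_seq(protein_length, AA20)
  }, "")

  proteins <- c(fam, bg)
  names(proteins) <- c(ids_fam, ids_bg)
  membership <- c(rep(TRUE, n_family), rep(FALSE, n_background))
  names(membership) <- names(proteins)
  names(dom_start) <- ids_fam

  list(
    proteins = proteins,
    seed_alignment = seed_aln,
    consensus = consensus,
    truth = list(family_membership = membership, domain_start = dom_start)
  )
}

#' Simulate sequence evolution along a phylogeny
#'
#' Evolves a root sequence down a rooted tree under a Poisson substitution
#' process: on a branch of length b, each site receives Poisson(b) events,
#' each replacing the residue by a uniformly chosen different symbol. The
#' result is a gap-free alignment over the leaves with column count equal to
#' the root length.
#'
#' @param tree rooted `phylo` tree with non-negative branch lengths.
#' @param root_sequence character scalar (protein by default).
#' @param alphabet residue alphabet (default the 20 amino acids).
#' @param seed RNG seed.
#' @return named character vector of leaf sequences (the alignment).
#' @export
sim_alignment <- function(tree, root_sequence, alphabet = AA20, seed = 1) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  set.seed(seed)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[root]] <- chars(root_sequence)

  evolve <- function(s, b) {
    n_events <- rpois(length(s), b)
    for (i in which(n_events > 0)) {
      for (k in seq_len(n_events[i])) {
        s[i] <- sample(setdiff(alphabet, s[i]), 1L)
      }
    }
    s
  }
  # edges of a phylo tree are stored parent-first after reorder()
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]
    child <- ord$edge[e, 2]
    seqs[[child]] <- evolve(seqs[[par]], ord$edge.length[e])
  }
  out <- vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""), "")
  names(out) <- tree$tip.label
  out
}
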