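#' Validate cross-file ID consistency of a simulated dataset
#'
#' Checks that every ground-truth record refers to an emitted entity:
#' duplication/family labels refer to genes in the gene models, planted
#' motif counts to emitted upstream regions and library patterns, hub /
#' target / annotation ids to emitted interactome nodes, and alignment
#' leaves to tree tips. Throws on the first inconsistency; returns TRUE
#' invisibly when clean.
#'
#' @param sim output of one of the `sim_*` generators.
#' @return TRUE (invisibly) if consistent.
#' @export
validate_simulation <- function(sim) {
  fail <- function(...) stop("ground-truth inconsistency: ", ...)
  tr <- sim$truth
  if (!is.null(sim$models)) {
    ids <- sim$models$gene_id
    if (!is.null(tr$duplication_class) &&
        !all(names(tr$duplication_class) %in% ids)) {
      fail("duplication labels name unknown genes")
    }
    if (!is.null(tr$family) && !all(tr$family %in% ids)) {
      fail("family members missing from gene models")
    }
    if (!is.null(sim$proteins) && !all(ids %in% names(sim$proteins))) {
      fail("genes without protein sequences")
    }
    if (!is.null(sim$genome) &&
        !all(unique(sim$models$chromosome) %in% names(sim$genome))) {
      fail("gene models on chromosomes absent from the genome")
    }
  }
  if (!is.null(tr$counts)) {
    if (!all(rownames(tr$counts) %in% names(sim$upstream))) {
      fail("planted counts for genes without upstream regions")
    }
    if (!all(colnames(tr$counts) %in% sim$motif_library$id)) {
      fail("planted counts for patterns outside the library")
    }
    if (any(tr$counts < 0)) fail("negative planted count")
    if (!all(tr$peak_subset %in% sim$motif_library$id)) {
      fail("peak subset outside the library")
    }
  }
  if (!is.null(sim$nodes)) {
    if (!all(tr$hub_nodes %in% sim$nodes)) fail("hubs not in node set")
    if (!all(tr$targets %in% sim$nodes)) fail("targets not in node set")
    if (!is.null(sim$go) && !all(sim$go$gene %in% sim$nodes)) {
      fail("annotated genes not in node set")
    }
    if (!all(c(sim$edges$node_a, sim$edges$node_b) %in% sim$nodes)) {
      fail("edge endpoints not in node set")
    }
  }
  if (!is.null(tr$family_membership) && !is.null(sim$proteins)) {
    if (!all(names(tr$family_membership) %in% names(sim$proteins))) {
      fail("membership labels name unknown proteins")
    }
  }
  invisible(TRUE)
}
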