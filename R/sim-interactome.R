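#' Simulate a scale-free interactome with planted hubs and one enriched GO term
#'
#' Draws node degrees i.i.d. from a discrete power law (zeta distribution)
#' with the target exponent, realizes them with a configuration model and
#' simplifies the result (no self-loops or multi-edges), so that the degree
#' distribution genuinely carries the stated exponent. The highest-degree
#' nodes are designated as hubs. A GO annotation table is emitted in which
#' one term annotates a fraction `enriched_term_fraction` of a designated
#' target gene set but only the background rate elsewhere.
#'
#' @param interactome_size number of nodes (>= 10).
#' @param powerlaw_exponent target exponent (> 1).
#' @param n_hubs number of designated hub nodes.
#' @param n_terms number of GO terms.
#' @param background_rate per-term background annotation probability.
#' @param target_set character vector of node ids to treat as the "true
#'   target" set, or an integer giving how many nodes to pick at random.
#' @param enriched_term_fraction fraction of the target set annotated with
#'   the planted term (0 disables the enrichment signal).
#' @param seed RNG seed.
#' @return list with `edges` (data.frame node_a/node_b), `go` (data.frame
#'   gene/term), `nodes`, and `truth` (`hub_nodes`, `enriched_term`,
#'   `targets`).
#' @export
sim_interactome <- function(interactome_size = 1000, powerlaw_exponent = 2.5,
                            n_hubs = 5, n_terms = 20,
                            background_rate = 0.05,
                            target_set = 40, enriched_term_fraction = 0.6,
                            seed = 1) {
  if (interactome_size < 10) stop("interactome_size must be >= 10")
  if (powerlaw_exponent <= 1) stop("powerlaw_exponent must be > 1")
  if (enriched_term_fraction < 0 || enriched_term_fraction > 1) {
    stop("enriched_term_fraction must be in [0, 1]")
  }
  set.seed(seed)
  n <- interactome_size

  # zeta-distributed degrees, truncated at n - 1
  kmax <- n - 1L
  pmf <- (1:kmax)^(-powerlaw_exponent)
  pmf <- pmf / sum(pmf)
  deg <- sample.int(kmax, n, replace = TRUE, prob = pmf)
  if (sum(deg) %% 2 == 1) deg[which.min(deg)] <- deg[which.min(deg)] + 1L

  g <- igraph::sample_degseq(deg, method = "configuration")
  g <- igraph::simplify(g)
  nodes <- sprintf("P%05d", seq_len(n))
  igraph::V(g)$name <- nodes

  realized <- igraph::degree(g)
  hub_nodes <- names(sort(realized, decreasing = TRUE))[seq_len(n_hubs)]

  if (length(target_set) == 1 && is.numeric(target_set)) {
    targets <- sample(nodes, target_set)
  } else {
    stopifnot(all(target_set %in% nodes))
    targets <- target_set
  }

  terms <- sprintf("GO:%07d", seq_len(n_terms))
  enriched_term <- terms[1]
  ann <- list()
  for (t in terms) {
    hit <- runif(n) < background_rate
    if (t == enriched_term && enriched_term_fraction > 0) {
      extra <- sample(targets, round(enriched_term_fraction * length(targets)))
      hit[match(extra, nodes)] <- TRUE
    }
    if (any(hit)) {
      ann[[t]] <- data.frame(gene = nodes[hit], term = t,
                             stringsAsFactors = FALSE)
    }
  }
  go <- do.call(rbind, ann)
  rownames(go) <- NULL

  el <- igraph::as_edgelist(g)
  list(
    edges = data.frame(node_a = el[, 1], node_b = el[, 2],
                       stringsAsFactors = FALSE),
    go = go,
    nodes = nodes,
    truth = list(
      hub_nodes = hub_nodes,
      enriched_term = if (enriched_term_fraction > 0) enriched_term else NA_character_,
      targets = targets
    )
  )
}
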