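#' Simulate a multi-chromosome gene layout with planted duplication events
#'
#' Lays out ordered, non-overlapping gene models on `n_chromosomes`
#' chromosomes and plants duplication events of known class:
#' \describe{
#'   \item{tandem}{duplicate at the adjacent gene-order rank, same chromosome}
#'   \item{proximal}{duplicate within `proximal_window` ranks, same chromosome}
#'   \item{segmental}{a block of >= 5 consecutive genes with homologous
#'     partners at consecutive ranks on another chromosome}
#'   \item{dispersed}{homologous pair on different chromosomes outside any
#'     collinear context}
#' }
#' Every gene also receives a protein; genes joined by an event carry
#' near-identical proteins (2\% divergence), all others are independent
#' random proteins, so homology detection sees exactly the planted events.
#'
#' @param n_chromosomes number of chromosomes.
#' @param genes_per_chromosome genes per chromosome.
#' @param events data.frame with columns `class` (one of tandem, proximal,
#'   segmental, dispersed) and `size` (gene pairs per event; must be 1 for
#'   tandem/proximal/dispersed and >= 5 for segmental).
#' @param n_singleton_family number of extra family genes with no homolog.
#' @param proximal_window max rank separation for a proximal duplicate.
#' @param protein_length protein length for simulated gene products.
#' @param seed RNG seed.
#' @return list with `genome` (named character vector of chromosome
#'   sequences), `models` (gene-model data.frame), `proteins` (named
#'   character vector), and `truth` (per-gene duplication class, event table,
#'   family membership).
#' @export
sim_genome_layout <- function(n_chromosomes = 6, genes_per_chromosome = 60,
                              events = data.frame(
                                class = c("tandem", "proximal", "segmental"),
                                size = c(1, 1, 6)
                              ),
                              n_singleton_family = 5,
                              proximal_window = 20,
                              protein_length = 250,
                              seed = 1) {
  stopifnot(n_chromosomes >= 1, genes_per_chromosome >= 2)
  if (nrow(events) > 0) {
    ok_size <- ifelse(events$class == "segmental",
                      events$size >= 5, events$size == 1)
    if (!all(events$class %in% c("tandem", "proximal", "segmental", "dispersed"))) {
      stop("unknown duplication class in events")
    }
    if (!all(ok_size)) {
      stop("event size must be 1 (tandem/proximal/dispersed) or >= 5 (segmental)")
    }
  }
  set.seed(seed)

  chroms <- sprintf("chr%02d", seq_len(n_chromosomes))
  n_genes <- n_chromosomes * genes_per_chromosome
  models <- data.frame(
    gene_id = sprintf("G%05d", seq_len(n_genes)),
    chromosome = rep(chroms, each = genes_per_chromosome),
    stringsAsFactors = FALSE
  )
  # sequential placement: random gene lengths and intergenic gaps
  glen <- sample(600:3000, n_genes, replace = TRUE)
  gap <- sample(500:2000, n_genes, replace = TRUE)
  start <- integer(n_genes)
  for (chr in chroms) {
    i <- which(models$chromosome == chr)
    start[i] <- cumsum(gap[i]) + c(0L, cumsum(glen[i])[-length(i)])
  }
  models$start <- start
  models$end <- start + glen - 1L
  models$strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  models <- add_gene_ranks(models)

  # helper: gene_id at (chromosome index, rank)
  at_rank <- function(ci, r) {
    models$gene_id[models$chromosome == chroms[ci]][order(
      models$start[models$chromosome == chroms[ci]])][r]
  }

  used <- rep(FALSE, n_genes)
  names(used) <- models$gene_id
  take <- function(ids) {
    if (any(used[ids])) return(FALSE)
    used[ids] <<- TRUE
    TRUE
  }

  event_rows <- list()
  pair_rows <- list()
  dup_class <- setNames(rep("none", n_genes), models$gene_id)
  # ranks used by intra-chromosome events, per chromosome; new events must
  # stay > 27 ranks away so unrelated pairs cannot chain into a spurious
  # collinear block under the default max_gap of 25
  intra_ranks <- replicate(n_chromosomes, integer(0), simplify = FALSE)
  min_sep <- 28L
  # chromosome pairs used by segmental blocks vs dispersed pairs are kept
  # disjoint, so a dispersed anchor can never be chained into a planted block
  seg_cp <- character(0)
  disp_cp <- character(0)
  cp_key <- function(ci) paste(sort(ci), collapse = "|")

  plant <- function(class, size) {
    for (attempt in 1:500) {
      if (class == "tandem" || class == "proximal") {
        ci <- sample.int(n_chromosomes, 1L)
        d <- if (class == "tandem") 1L else sample(2:min(proximal_window, genes_per_chromosome - 1L), 1L)
        r <- sample.int(genes_per_chromosome - d, 1L)
        if (length(intra_ranks[[ci]]) > 0 &&
            min(abs(outer(c(r, r + d), intra_ranks[[ci]], "-"))) < min_sep) {
          next
        }
        ids <- c(at_rank(ci, r), at_rank(ci, r + d))
        if (take(ids)) {
          intra_ranks[[ci]] <<- c(intra_ranks[[ci]], r, r + d)
          dup_class[ids] <<- class
          pair_rows[[length(pair_rows) + 1L]] <<- data.frame(
            gene_a = ids[1], gene_b = ids[2], stringsAsFactors = FALSE)
          return(ids)
        }
      } else if (class == "dispersed") {
        ci <- sample.int(n_chromosomes, 2L)
        if (cp_key(ci) %in% seg_cp) next
        ids <- c(at_rank(ci[1], sample.int(genes_per_chromosome, 1L)),
                 at_rank(ci[2], sample.int(genes_per_chromosome, 1L)))
        if (take(ids)) {
          disp_cp <<- c(disp_cp, cp_key(ci))
          dup_class[ids] <<- class
          pair_rows[[length(pair_rows) + 1L]] <<- data.frame(
            gene_a = ids[1], gene_b = ids[2], stringsAsFactors = FALSE)
          return(ids)
        }
      } else { # segmental
        if (n_chromosomes < 2) stop("segmental event needs >= 2 chromosomes")
        ci <- sample.int(n_chromosomes, 2L)
        if (cp_key(ci) %in% disp_cp) next
        ra <- sample.int(genes_per_chromosome - size + 1L, 1L)
        rb <- sample.int(genes_per_chromosome - size + 1L, 1L)
        a <- vapply(seq_len(size), function(k) at_rank(ci[1], ra + k - 1L), "")
        b <- vapply(seq_len(size), function(k) at_rank(ci[2], rb + k - 1L), "")
        if (take(c(a, b))) {
          seg_cp <<- c(seg_cp, cp_key(ci))
          dup_class[c(a, b)] <<- "segmental"
          for (k in seq_len(size)) {
            pair_rows[[length(pair_rows) + 1L]] <<- data.frame(
              gene_a = a[k], gene_b = b[k], stringsAsFactors = FALSE)
          }
          return(c(a, b))
        }
      }
    }
    stop("could not place a ", class, " event: layout too crowded ",
         "(increase genes_per_chromosome or reduce events)")
  }

  if (nrow(events) > 0) {
    for (e in seq_len(nrow(events))) {
      ids <- plant(events$class[e], events$size[e])
      event_rows[[length(event_rows) + 1L]] <- data.frame(
        event = length(event_rows) + 1L, class = events$class[e],
        genes = paste(ids, collapse = ","), stringsAsFactors = FALSE)
    }
  }

  # singleton family genes: family members with no homolog anywhere
  singles <- character(0)
  if (n_singleton_family > 0) {
    free <- models$gene_id[!used]
    singles <- sample(free, n_singleton_family)
    used[singles] <- TRUE
    dup_class[singles] <- "singleton"
  }

  family <- names(dup_class)[dup_class != "none"]

  # proteins: independent random sequences; event pairs share an ancestor
  proteins <- setNames(
    vapply(seq_len(n_genes), function(i) random_seq(protein_length, AA20), ""),
    models$gene_id
  )
  pairs <- if (length(pair_rows) > 0) do.call(rbind, pair_rows) else
    data.frame(gene_a = character(0), gene_b = character(0))
  for (i in seq_len(nrow(pairs))) {
    anc <- random_seq(protein_length, AA20)
    proteins[pairs$gene_a[i]] <- mutate_seq(anc, 0.02, AA20)
    proteins[pairs$gene_b[i]] <- mutate_seq(anc, 0.02, AA20)
  }

  genome <- vapply(chroms, function(chr) {
    i <- models$chromosome == chr
    random_seq(max(models$end[i]) + 1000L, DNA4)
  }, "")

  list(
    genome = genome,
    models = models,
    proteins = proteins,
    truth = list(
      duplication_class = dup_class[family],
      events = if (length(event_rows) > 0) do.call(rbind, event_rows) else
        data.frame(event = integer(0), class = character(0), genes = character(0)),
      homolog_pairs = pairs,
      family = family
    )
  )
}
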