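test_that("upstream extraction handles strands and chromosome edges", {
  genome <- c(c1 = paste(rep("ACGT", 50), collapse = "")) # 200 bp
  models <- data.frame(
    gene_id = c("plus", "minus", "edge"),
    chromosome = "c1",
    start = c(101, 21, 31), end = c(150, 60, 60),
    strand = c("+", "-", "+"), stringsAsFactors = FALSE
  )
  up <- extract_upstream(models, genome, window = 50)
  # + strand: bases [start-window, start) in genome order
  expect_identical(up$regions[["plus"]], substr(genome[["c1"]], 51, 100))
  # - strand: reverse complement of the window right of the gene
  expect_identical(up$regions[["minus"]],
                   revcomp(substr(genome[["c1"]], 61, 110)))
  # truncation at the chromosome start
  expect_identical(nchar(up$regions[["edge"]]), 30L)
  expect_true(up$info$truncated[up$info$gene_id == "edge"])
  expect_false(up$info$truncated[up$info$gene_id == "plus"])
  models$chromosome <- "c9"
  expect_error(extract_upstream(models, genome, 50), "unknown chromosome")
})

test_that("degenerate scanning matches the naive oracle and IUPAC semantics", {
  hits <- scan_motifs("AAACCGACAA", c(LTRE = "CCGAC"))
  expect_identical(hits$start, 3L)
  expect_identical(hits$strand, "+")
  # reverse-complement identity
  rc <- scan_motifs("GTCGG", c(LTRE = "CCGAC"))
  expect_identical(nrow(rc), 1L)
  expect_identical(rc$strand, "-")
  # IUPAC degeneracy
  expect_identical(nrow(scan_motifs("ACCGAC", c(x = "RCCGAC"),
                                    both_strands = FALSE)), 1L)
  expect_identical(nrow(scan_motifs("GCCGAC", c(x = "RCCGAC"),
                                    both_strands = FALSE)), 1L)
  expect_identical(nrow(scan_motifs("TCCGAC", c(x = "RCCGAC"),
                                    both_strands = FALSE)), 0L)
  expect_error(scan_motifs("ACGT", c(x = "CZG")), "Z")
  # property: counts equal the all-offsets oracle on random cases
  set.seed(55)
  iupac <- names(IUPAC_TABLE)
  for (case in 1:400) {
    L <- sample(20:200, 1)
    seqs <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    w <- sample(3:8, 1)
    pat <- paste(sample(iupac, w, TRUE, prob = c(rep(4, 4), rep(1, 11))),
                 collapse = "")
    got <- nrow(scan_motifs(seqs, c(p = pat)))
    expect_identical(got, naive_scan_counts(seqs, pat),
                     info = paste(case, pat))
  }
})

test_that("peak filtering retains exactly the patterns present in peaks", {
  pp <- sim_promoters(n_genes = 6, seed = 33,
                      peak_subset = c("LTRE", "SVPbox", "M7"))
  fm <- filter_phase_motifs(pp$motif_library, pp$peaks, pp$peak_genome,
                            phase = "vegetative")
  expect_setequal(fm$id[fm$retained], pp$truth$peak_subset)
  # empty peak set retains nothing
  fm0 <- filter_phase_motifs(pp$motif_library, pp$peaks[0, ], pp$peak_genome)
  expect_false(any(fm0$retained))
  # a match spanning a peak boundary does not count
  genome <- c(z = "AAAACCGACAAAA")
  peaks <- data.frame(chrom = "z", start = 0, end = 7) # cuts CCGAC at CCG
  fmb <- filter_phase_motifs(c(LTRE = "CCGAC"), peaks, genome)
  expect_false(any(fmb$retained))
  peaks2 <- data.frame(chrom = "z", start = 0, end = 10)
  expect_true(filter_phase_motifs(c(LTRE = "CCGAC"), peaks2, genome)$retained)
})

test_that("target prediction recovers the planted target set exactly", {
  pp <- sim_promoters(n_genes = 25, seed = 44)
  fm <- filter_phase_motifs(pp$motif_library, pp$peaks, pp$peak_genome,
                            phase = "reproductive")
  tg <- predict_targets(fm, pp$upstream)
  expect_setequal(tg$targets, pp$truth$targets)
  expect_identical(tg$unique_motifs_present,
                   sum(colSums(pp$truth$counts[, pp$truth$peak_subset,
                                               drop = FALSE]) > 0))
  # empty motif set gives no targets
  tg0 <- predict_targets(fm[fm$retained == FALSE & FALSE, ], pp$upstream)
  expect_identical(length(tg0$targets), 0L)
})

test_that("network construction merges edges, drops loops and isolates", {
  edges <- data.frame(
    a = c("n1", "n2", "n1", "n3", "n4", "n5"),
    b = c("n2", "n1", "n1", "n4", "n3", "n6")
  )
  net <- build_target_network(c("n1", "n3", "n9"), NULL, edges)
  # duplicate (n1,n2)/(n2,n1) merged; self-loop n1-n1 dropped; n9 absent
  expect_equal(igraph::ecount(net$graph), 2)
  expect_setequal(igraph::V(net$graph)$name, c("n1", "n2", "n3", "n4"))
  # seed with no partner is excluded even if annotated as a node elsewhere
  net2 <- build_target_network("n9", NULL, edges)
  expect_identical(length(net2$seeds), 0L)
  # edge count equals the set of unordered endpoint pairs (oracle)
  set.seed(66)
  rnd <- data.frame(a = sample(paste0("v", 1:30), 300, TRUE),
                    b = sample(paste0("v", 1:30), 300, TRUE))
  seeds <- paste0("v", 1:30)
  net3 <- build_target_network(seeds, NULL, rnd)
  oracle <- unique(paste(pmin(rnd$a, rnd$b), pmax(rnd$a, rnd$b))[rnd$a != rnd$b])
  expect_equal(igraph::ecount(net3$graph), length(oracle))
  expect_error(build_target_network("x", NULL, rnd[0, ]), "empty interactome")
})

test_that("power-law MLE matches grid search and degree bookkeeping", {
  # star graph degree distribution
  star <- igraph::make_star(10, mode = "undirected")
  igraph::V(star)$name <- paste0("s", 1:10)
  fit <- degree_powerlaw(star)
  expect_identical(fit$degree_table$k, c(1, 9))
  expect_identical(fit$degree_table$count, c(9L, 1L))
  # MLE equals staged grid-search maximization
  deg <- rep(c(1, 2, 3, 5, 8, 15), times = c(60, 25, 12, 6, 3, 1))
  fit2 <- degree_powerlaw(deg)
  expect_lt(abs(fit2$alpha - grid_powerlaw_alpha(deg)), 1e-6)
  deg3 <- rep(c(1, 2, 4, 9), times = c(200, 40, 10, 2))
  expect_lt(abs(degree_powerlaw(deg3)$alpha - grid_powerlaw_alpha(deg3)),
            1e-6)
  expect_error(degree_powerlaw(rep(3, 50)), "degenerate")
  expect_error(degree_powerlaw(c(1, 2, 3)), ">= 10")
})

test_that("hub detection ranks the largest component by degree", {
  star <- igraph::make_star(8, center = 1, mode = "undirected")
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:7))
  h <- find_hubs(star, k = 1)
  expect_identical(h$hubs, "hub")
  ring <- igraph::make_ring(125)
  igraph::V(ring)$name <- sprintf("r%03d", 1:125)
  h2 <- find_hubs(ring, k = 5)
  expect_equal(h2$hub_fraction_percent, 4.0)
  expect_identical(h2$component_size, 125L)
  expect_error(find_hubs(star, k = 100), "exceeds")
})

test_that("hypergeometric enrichment is exact, BH-monotone and strict", {
  universe <- paste0("g", 1:10)
  ann <- data.frame(gene = paste0("g", 1:4), term = "T1")
  res <- go_enrichment(paste0("g", 1:5), ann, universe)
  expect_equal(res$p[res$term == "T1"], 6 / 252)
  # a term annotating the whole universe has p = 1
  ann2 <- rbind(ann, data.frame(gene = universe, term = "ALL"))
  res2 <- go_enrichment(paste0("g", 1:5), ann2, universe)
  expect_equal(res2$p[res2$term == "ALL"], 1)
  # fdr >= p elementwise; fdr monotone along the p ranking
  set.seed(88)
  bigann <- data.frame(gene = sample(universe, 60, TRUE),
                       term = sample(paste0("T", 1:12), 60, TRUE))
  res3 <- go_enrichment(paste0("g", c(1, 3, 5)), bigann, universe)
  expect_true(all(res3$fdr >= res3$p - 1e-15))
  expect_true(all(diff(res3$fdr[order(res3$p)]) >= -1e-15))
  expect_error(go_enrichment(c("g1", "zz"), ann, universe), "zz")
})
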