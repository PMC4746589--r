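test_that("proteome generator plants domains at the requested divergence", {
  # zero divergence: consensus verbatim in every family protein
  pr0 <- sim_proteome(n_family = 5, n_background = 5, domain_divergence = 0,
                      seed = 7)
  for (id in names(pr0$truth$domain_start)) {
    st <- pr0$truth$domain_start[[id]]
    expect_identical(substr(pr0$proteins[[id]], st + 1, st + 58),
                     pr0$consensus)
  }
  # determinism: identical outputs under the same seed
  expect_identical(pr0, sim_proteome(n_family = 5, n_background = 5,
                                     domain_divergence = 0, seed = 7))
  # binomial expectation: observed per-site mismatch near the divergence
  pr <- sim_proteome(n_family = 50, n_background = 0,
                     domain_divergence = 0.1, seed = 11)
  cons <- strsplit(pr$consensus, "")[[1]]
  mm <- vapply(names(pr$truth$domain_start), function(id) {
    st <- pr$truth$domain_start[[id]]
    dom <- strsplit(substr(pr$proteins[[id]], st + 1, st + 58), "")[[1]]
    mean(dom != cons)
  }, 0)
  expect_lt(abs(mean(mm) - 0.1), 0.03)
  expect_error(sim_proteome(domain_divergence = 1), "divergence")
  expect_error(sim_proteome(domain_length = 5), "domain_length")
})

test_that("genome layout plants duplication events by construction", {
  gl <- sim_genome_layout(
    n_chromosomes = 4, genes_per_chromosome = 30,
    events = data.frame(class = c("tandem", "segmental"), size = c(1, 6)),
    n_singleton_family = 0, seed = 3
  )
  expect_true(validate_simulation(gl))
  rnk <- setNames(gl$models$rank, gl$models$gene_id)
  chr <- setNames(gl$models$chromosome, gl$models$gene_id)
  tand <- names(gl$truth$duplication_class)[gl$truth$duplication_class == "tandem"]
  expect_identical(chr[[tand[1]]], chr[[tand[2]]])
  expect_identical(abs(rnk[[tand[1]]] - rnk[[tand[2]]]), 1L)
  # segmental: six pairs at jointly consecutive ranks on two chromosomes
  seg_pairs <- gl$truth$homolog_pairs[
    gl$truth$duplication_class[gl$truth$homolog_pairs$gene_a] == "segmental", ]
  expect_identical(nrow(seg_pairs), 6L)
  ra <- sort(rnk[seg_pairs$gene_a])
  rb <- sort(rnk[seg_pairs$gene_b])
  expect_identical(unname(diff(ra)), rep(1L, 5))
  expect_identical(unname(diff(rb)), rep(1L, 5))
  # no events -> empty truth
  gl0 <- sim_genome_layout(n_chromosomes = 2, genes_per_chromosome = 10,
                           events = data.frame(class = character(0),
                                               size = numeric(0)),
                           n_singleton_family = 0, seed = 1)
  expect_identical(length(gl0$truth$family), 0L)
  expect_identical(nrow(gl0$truth$homolog_pairs), 0L)
  # gene models are ordered and non-overlapping within chromosomes
  for (ch in unique(gl$models$chromosome)) {
    m <- gl$models[gl$models$chromosome == ch, ]
    m <- m[order(m$start), ]
    expect_true(all(m$start[-1] > m$end[-nrow(m)]))
  }
})

test_that("alignment evolution respects branch lengths", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  root <- paste(rep("ACDEF", 20), collapse = "")
  aln0 <- sim_alignment(tr, root, seed = 5)
  expect_true(all(aln0 == root))
  # star tree with equal branches: roughly equal pairwise p-distances
  star <- ape::read.tree(text = "(a:0.3,b:0.3,c:0.3,d:0.3,e:0.3);")
  set.seed(2)
  root2 <- paste(sample(madsfam:::AA20, 2000, replace = TRUE), collapse = "")
  aln <- sim_alignment(star, root2, seed = 9)
  d <- aln_distance(aln, model = "p")
  offd <- d[upper.tri(d)]
  expect_lt(max(offd) - min(offd), 0.08)
  # replicate seeds: different alignments, same recoverable topology
  tr2 <- ape::rtree(8)
  tr2$edge.length <- runif(nrow(tr2$edge), 0.05, 0.15)
  a1 <- sim_alignment(tr2, root2, seed = 1)
  a2 <- sim_alignment(tr2, root2, seed = 2)
  expect_false(identical(a1, a2))
  expect_equal(rf_dist(nj_tree(aln_distance(a1)), tr2), 0)
  expect_equal(rf_dist(nj_tree(aln_distance(a2)), tr2), 0)
  bad <- ape::rtree(4)
  bad$edge.length[1] <- -0.1
  expect_error(sim_alignment(bad, "ACDEF"), "negative branch length")
})

test_that("expression generator plants reciprocal, expressed and silent genes", {
  ex0 <- sim_expression(n_genes = 30, n_expressed = 12, n_pairs = 4,
                        noise_sigma = 0, seed = 2)
  w <- bud_to_bloom_samples(ex0$design)
  r <- reciprocal_score(ex0$fpkm, ex0$truth$pairs$repressor[1],
                        ex0$truth$pairs$activator[1], w)
  expect_equal(r$correlation, -1)
  expect_true(r$reciprocal)
  silent <- names(ex0$truth$archetype)[ex0$truth$archetype == "silent"]
  expect_true(all(apply(ex0$fpkm[silent, , drop = FALSE], 1, max) < 1))
  # with noise: planted pairs stay strongly anti-correlated on average
  ex <- sim_expression(n_genes = 220, n_expressed = 210, n_pairs = 100,
                       noise_sigma = 0.2, seed = 6)
  cors <- vapply(seq_len(100), function(i) {
    reciprocal_score(ex$fpkm, ex$truth$pairs$repressor[i],
                     ex$truth$pairs$activator[i], w)$correlation
  }, 0)
  expect_lte(mean(cors), -0.8)
  expect_error(sim_expression(design = stage_design(1, 0, 0, 0)[1, ]),
               "2 stages")
})

test_that("promoter/peak generator realizes exact planted counts", {
  lib <- default_motif_library()
  counts <- matrix(0L, 3, nrow(lib),
                   dimnames = list(c("g1", "g2", "g3"), lib$id))
  counts["g1", "LTRE"] <- 2L
  counts["g2", "LTRE"] <- 7L
  counts["g2", "Wbox"] <- 1L
  pp <- sim_promoters(region_length = 1500, planted_counts = counts,
                      peak_subset = c("LTRE", "Wbox", "CArG"), seed = 8)
  got <- count_motifs(pp$upstream, lib)
  expect_identical(unname(got[rownames(counts), colnames(counts)]),
                   unname(counts))
  expect_true(validate_simulation(pp))
  # empty library -> zero hits anywhere
  expect_identical(nrow(scan_motifs(pp$upstream[["g1"]],
                                    lib[0, , drop = FALSE])), 0L)
  # motif longer than the region errors
  expect_error(
    sim_promoters(planted_counts = matrix(1L, 1, 1,
                                          dimnames = list("g1", "CArG")),
                  region_length = 8, seed = 1),
    "longer than|inconsistent")
})

test_that("interactome generator plants hubs and controls the null", {
  si <- sim_interactome(interactome_size = 400, n_hubs = 5, seed = 13)
  expect_true(validate_simulation(si))
  g <- igraph::graph_from_data_frame(si$edges, directed = FALSE)
  deg <- igraph::degree(g)
  top5 <- names(sort(deg, decreasing = TRUE))[1:5]
  expect_setequal(top5, si$truth$hub_nodes)
  # no self loops or duplicate edges
  expect_false(any(si$edges$node_a == si$edges$node_b))
  key <- paste(pmin(si$edges$node_a, si$edges$node_b),
               pmax(si$edges$node_a, si$edges$node_b))
  expect_false(anyDuplicated(key) > 0)
  # planted enrichment is recovered; disabled signal stays null
  en <- go_enrichment(si$truth$targets, si$go, si$nodes)
  expect_true(en$significant[en$term == si$truth$enriched_term])
  si0 <- sim_interactome(interactome_size = 400,
                         enriched_term_fraction = 0, seed = 14)
  en0 <- go_enrichment(si0$truth$targets, si0$go, si0$nodes)
  expect_false(any(en0$significant))
  expect_error(sim_interactome(powerlaw_exponent = 1), "exponent")
  expect_error(sim_interactome(interactome_size = 5), "interactome_size")
})

test_that("generators are byte-stable on disk and GFF3 round-trips", {
  gl <- sim_genome_layout(n_chromosomes = 2, genes_per_chromosome = 8,
                          events = data.frame(class = "tandem", size = 1),
                          n_singleton_family = 1, seed = 21)
  f1 <- tempfile(fileext = ".gff3")
  f2 <- tempfile(fileext = ".gff3")
  write_gene_models(gl$models, f1)
  write_gene_models(gl$models, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_gene_models(f1)
  back <- back[match(gl$models$gene_id, back$gene_id), ]
  for (col in c("gene_id", "chromosome", "start", "end", "strand", "rank")) {
    expect_equal(unname(back[[col]]), unname(gl$models[[col]]))
  }
  # BED round trip for peaks
  pp <- sim_promoters(n_genes = 2, seed = 3)
  fb <- tempfile(fileext = ".bed")
  write_bed(pp$peaks, fb)
  peaks2 <- read_bed(fb)
  expect_equal(peaks2$start, pp$peaks$start)
  expect_equal(peaks2$end, pp$peaks$end)
})
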