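test_that("profile log-odds match the closed-form counts formula", {
  # single-residue column, uniform background, vanishing pseudocount
  aln <- c("M", "M", "M")
  prof <- build_profile(aln, pseudocount = 1e-9)
  expect_equal(unname(prof$log_odds[1, "M"]), log2(20), tolerance = 1e-6)
  # a column matching background exactly scores ~0 everywhere
  aln2 <- vapply(1:20, function(i) madsfam:::AA20[i], "")
  prof2 <- build_profile(aln2, pseudocount = 1)
  expect_true(all(abs(prof2$log_odds[1, ]) < 1e-12))
  # 3-sequence toy alignment equals hand-computed arithmetic
  aln3 <- c("AC", "AC", "AD")
  prof3 <- build_profile(aln3, pseudocount = 2)
  bg <- 1 / 20
  expect_equal(unname(prof3$log_odds[1, "A"]),
               log2(((3 + 2 * bg) / (3 + 2)) / bg))
  expect_equal(unname(prof3$log_odds[2, "C"]),
               log2(((2 + 2 * bg) / (3 + 2)) / bg))
  expect_equal(unname(prof3$log_odds[2, "D"]),
               log2(((1 + 2 * bg) / (3 + 2)) / bg))
  expect_error(build_profile(c("AA", "AAA")), "ragged")
})

test_that("profile scanning finds planted windows and matches brute force", {
  pr <- sim_proteome(n_family = 4, n_background = 0, domain_divergence = 0,
                     protein_length = 200, seed = 5)
  prof <- build_profile(pr$seed_alignment)
  sc <- scan_profile(pr$proteins, prof, n_decoys = 30, seed = 1)
  expect_identical(sc$start, unname(pr$truth$domain_start[sc$protein_id]))
  # sliding-window max equals brute force over all windows
  M <- prof$log_odds
  for (id in names(pr$proteins)[1:2]) {
    p <- strsplit(pr$proteins[[id]], "")[[1]]
    idx <- match(p, madsfam:::AA20)
    brute <- max(vapply(1:(length(p) - prof$length + 1), function(s) {
      sum(M[cbind(1:prof$length, idx[s:(s + prof$length - 1)])])
    }, 0))
    expect_equal(sc$bit_score[sc$protein_id == id], brute)
  }
  # proteins shorter than the profile are silently skipped
  short <- c(tiny = "MKV")
  expect_identical(nrow(scan_profile(short, prof, n_decoys = 5)), 0L)
  # best score is invariant under reversal of the non-domain flanks
  id <- names(pr$proteins)[1]
  st <- pr$truth$domain_start[[id]]
  s <- pr$proteins[[id]]
  left <- substr(s, 1, st)
  dom <- substr(s, st + 1, st + 58)
  right <- substr(s, st + 59, nchar(s))
  flipped <- paste0(paste(rev(strsplit(left, "")[[1]]), collapse = ""), dom,
                    paste(rev(strsplit(right, "")[[1]]), collapse = ""))
  sc2 <- scan_profile(c(flip = flipped), prof, n_decoys = 30, seed = 1)
  expect_equal(sc2$bit_score, sc$bit_score[sc$protein_id == id])
})

test_that("two-stage confirmation is monotone and recovers planted members", {
  pr <- sim_proteome(n_family = 20, n_background = 60,
                     domain_divergence = 0.2, seed = 17)
  prof <- build_profile(pr$seed_alignment)
  conf <- confirm_members(pr$proteins, prof, n_decoys = 200)
  fam <- names(pr$truth$family_membership)[pr$truth$family_membership]
  expect_gte(length(intersect(conf, fam)) / length(fam), 0.95)
  expect_true(all(conf %in% attr(conf, "stage1")$protein_id[
    attr(conf, "stage1")$pass]))
  # stricter second stage can only shrink the confirmed set
  conf_strict <- confirm_members(pr$proteins, prof, n_decoys = 200,
                                 evalue_threshold = c(1e-4, 1e-6))
  expect_true(all(conf_strict %in% conf))
  # empty first stage propagates
  bg <- pr$proteins[!pr$truth$family_membership][1:5]
  conf_bg <- confirm_members(bg, prof, n_decoys = 200)
  expect_identical(length(conf_bg), 0L)
})

test_that("local alignment agrees with exhaustive enumeration and conventions", {
  B62 <- blosum62()
  a <- align_local("MKVLH", "MKVLH")
  expect_equal(a$percent_similarity, 100)
  expect_equal(a$query_coverage, 100)
  # substitution-only mismatch: poly-A vs poly-W scores 0, empty alignment
  a2 <- align_local("AAAA", "WWWW")
  expect_equal(a2$score, 0)
  expect_equal(a2$query_coverage, 0)
  # interior negative columns held by strong flanks: similarity exactly 50
  a3 <- align_local("WDDW", "WRRW")
  expect_equal(a3$percent_similarity, 50)
  expect_false(a3$percent_similarity > 50)
  # brute-force oracle on short random peptides
  set.seed(31)
  for (case in 1:12) {
    q <- paste(sample(madsfam:::AA20, sample(3:7, 1), TRUE), collapse = "")
    s <- paste(sample(madsfam:::AA20, sample(3:7, 1), TRUE), collapse = "")
    got <- align_local(q, s)$score
    expect_equal(got, brute_local_score(q, s, B62), info = paste(q, s))
  }
  expect_error(align_local("MKX2", "MKV"), "X|2")
})

test_that("ortholog calls use best hit, strict >50/>50 rule, stable ties", {
  ref <- c(B = "MKVLHAGWYE", A = "MKVLHAGWYE", C = "WWWWYYYYFF")
  oc <- call_orthologs(c(q1 = "MKVLHAGWYE"), ref)
  expect_identical(oc$subject_id, "A") # tie broken lexicographically
  expect_true(oc$regular)
  # divergent ortholog pairs are still assigned to the right partner
  set.seed(19)
  anc <- vapply(1:12, function(i)
    paste(sample(madsfam:::AA20, 60, TRUE), collapse = ""), "")
  names(anc) <- sprintf("R%02d", 1:12)
  qs <- setNames(vapply(anc, function(s)
    madsfam:::mutate_seq(s, 0.2, madsfam:::AA20), ""), sprintf("Q%02d", 1:12))
  oc2 <- call_orthologs(qs, anc)
  acc <- mean(sub("Q", "R", oc2$query_id) == oc2$subject_id)
  expect_gte(acc, 0.95)
  expect_error(call_orthologs(c(q = "MK"), character(0)), "empty")
})

test_that("positional naming is dense, ordered and permutation-invariant", {
  models <- data.frame(
    gene_id = c("x", "y", "z"),
    chromosome = c("chr1", "chr1", "chr2"),
    start = c(100, 500, 50), end = c(200, 600, 80),
    strand = "+", stringsAsFactors = FALSE
  )
  nm <- assign_names(c("z", "x", "y"), models, prefix = "MdMADS")
  expect_identical(nm$assigned_name, c("MdMADS001", "MdMADS002", "MdMADS003"))
  expect_identical(nm$gene_id, c("x", "y", "z"))
  # permuted input gives identical naming
  nm2 <- assign_names(c("y", "z", "x"), models)
  expect_identical(nm, nm2)
  # single member
  expect_identical(assign_names("x", models)$assigned_name, "MdMADS001")
  # unplaced members follow placed ones in input order
  nm3 <- assign_names(c("u2", "x", "u1"), models)
  expect_identical(nm3$gene_id, c("x", "u2", "u1"))
  expect_identical(nm3$assigned_name[2:3], c("MdMADS002", "MdMADS003"))
  expect_error(assign_names(c("x", "x"), models), "duplicate")
})
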