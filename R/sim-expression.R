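#' The default phenological stage design
#'
#' 21 samples: 3 apical bud, 5 spur bud, 6 flower and 7 fruit stages, in
#' phenological order. The "bud-to-bloom" window used for reciprocal
#' expression scoring is the 8 bud stages plus the first 2 flower stages.
#'
#' @param n_apical,n_spur,n_flower,n_fruit stage counts per phase.
#' @return data.frame with `sample`, `phase`, `stage` (overall order).
#' @export
stage_design <- function(n_apical = 3, n_spur = 5, n_flower = 6, n_fruit = 7) {
  phase <- c(rep("apical_bud", n_apical), rep("spur_bud", n_spur),
             rep("flower", n_flower), rep("fruit", n_fruit))
  idx <- c(seq_len(n_apical), seq_len(n_spur), seq_len(n_flower),
           seq_len(n_fruit))
  data.frame(
    sample = paste0(c("AB", "SB", "FL", "FR")[match(
      phase, c("apical_bud", "spur_bud", "flower", "fruit"))], idx),
    phase = phase,
    stage = seq_along(phase),
    stringsAsFactors = FALSE
  )
}

#' Samples of the dormancy-to-bloom window
#'
#' @param design a [stage_design()] table.
#' @param n_flower_stages how many early flower stages to include (default 2,
#'   giving the canonical 10-stage dormant-bud-to-full-bloom window).
#' @return character vector of sample names.
#' @export
bud_to_bloom_samples <- function(design, n_flower_stages = 2) {
  fl <- design$sample[design$phase == "flower"][seq_len(n_flower_stages)]
  c(design$sample[design$phase %in% c("apical_bud", "spur_bud")], fl)
}

#' Simulate a stage-structured FPKM matrix with planted archetypes
#'
#' Plants `n_pairs` repressor/activator gene pairs whose log-scale profiles
#' decline/rise linearly across the bud-to-bloom window (exactly
#' anti-correlated at zero noise), `n_expressed` total expressed genes, and
#' silent genes whose FPKM stays below the expressed threshold everywhere.
#' Noise is multiplicative log-normal on FPKM.
#'
#' @param n_genes total genes.
#' @param n_expressed genes expressed (FPKM >= `threshold` somewhere);
#'   includes the planted pairs.
#' @param n_pairs number of repressor/activator pairs.
#' @param noise_sigma sdlog of the multiplicative log-normal noise.
#' @param threshold expressed-call threshold the silent genes must stay under.
#' @param design a [stage_design()] table.
#' @param seed RNG seed.
#' @return list with `fpkm` (matrix), `design`, and `truth` (`archetype` per
#'   gene: repressor/activator/expressed/silent; `pairs` data.frame;
#'   `expressed` logical vector).
#' @export
sim_expression <- function(n_genes = 142, n_expressed = 63, n_pairs = 8,
                           noise_sigma = 0.2, threshold = 1,
                           design = stage_design(), seed = 1) {
  if (nrow(design) < 2) stop("need at least 2 stages")
  if (2 * n_pairs > n_expressed) stop("n_expressed too small for n_pairs")
  if (n_expressed > n_genes) stop("n_expressed exceeds n_genes")
  set.seed(seed)

  n_samples <- nrow(design)
  window <- bud_to_bloom_samples(design)
  win_idx <- match(window, design$sample)
  genes <- sprintf("MdMADS%03d", seq_len(n_genes))
  fpkm <- matrix(0, n_genes, n_samples, dimnames = list(genes, design$sample))
  archetype <- setNames(rep("silent", n_genes), genes)

  # planted pairs occupy the first 2*n_pairs gene slots
  high <- 8 # log2 units at the expressed end of the ramp
  ramp <- seq(high, 0, length.out = length(win_idx))
  pair_rows <- list()
  for (p in seq_len(n_pairs)) {
    rep_gene <- genes[2 * p - 1]
    act_gene <- genes[2 * p]
    x_rep <- x_act <- rep(1, n_samples) # modest baseline outside the window
    x_rep[win_idx] <- ramp
    x_act[win_idx] <- rev(ramp)
    fpkm[rep_gene, ] <- 2^x_rep - 1
    fpkm[act_gene, ] <- 2^x_act - 1
    archetype[c(rep_gene, act_gene)] <- c("repressor", "activator")
    pair_rows[[p]] <- data.frame(repressor = rep_gene, activator = act_gene,
                                 stringsAsFactors = FALSE)
  }

  # other expressed genes: random smooth-ish positive profiles
  other_expr <- genes[seq(2 * n_pairs + 1, n_expressed)]
  for (g in other_expr) {
    base <- runif(1, 2, 50)
    fpkm[g, ] <- base * runif(n_samples, 0.5, 2)
    archetype[g] <- "expressed"
  }
  # silent genes: strictly below threshold in every sample
  silent <- genes[archetype == "silent"]
  for (g in silent) {
    fpkm[g, ] <- runif(n_samples, 0, 0.9 * threshold)
  }

  if (noise_sigma > 0) {
    noisy <- archetype != "silent"
    fpkm[noisy, ] <- fpkm[noisy, ] *
      matrix(rlnorm(sum(noisy) * n_samples, 0, noise_sigma),
             sum(noisy), n_samples)
  }

  list(
    fpkm = fpkm,
    design = design,
    truth = list(
      archetype = archetype,
      pairs = do.call(rbind, pair_rows),
      expressed = setNames(archetype != "silent", genes)
    )
  )
}
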