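# Independent oracle implementations used to cross-check the package.
# These deliberately use naive algorithms (loops, enumeration, closed forms)
# and never call the code paths they verify.

IUPAC_TABLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

naive_revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
           W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
           N = "N")
  paste(rev(map[strsplit(x, "")[[1]]]), collapse = "")
}

# all-offsets degenerate matcher; returns 0-based starts on the forward seq
naive_match <- function(seq, pattern) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  w <- length(p)
  hits <- integer(0)
  if (length(s) < w) return(hits)
  for (off in 0:(length(s) - w)) {
    ok <- TRUE
    for (k in seq_len(w)) {
      if (!(s[off + k] %in% IUPAC_TABLE[[p[k]]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, off)
  }
  hits
}

naive_scan_counts <- function(seq, pattern, both_strands = TRUE) {
  n <- length(naive_match(seq, pattern))
  if (both_strands) n <- n + length(naive_match(seq, naive_revcomp(pattern)))
  n
}

# brute-force optimal local alignment score under affine gaps
# (gap of length k costs open + k * extend), by enumeration of all monotone
# residue pairings; matches the Biostrings cost convention
brute_local_score <- function(q, s, submat, open = 10, extend = 4) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  nq <- length(qc)
  ns <- length(sc)
  best <- 0
  gap_cost <- function(k) if (k > 0) open + k * extend else 0
  # recursively extend a pairing whose last pair is (i, j)
  extend_pairing <- function(i, j, score) {
    if (score > best) best <<- score
    if (i < nq && j < ns) {
      for (i2 in (i + 1):nq) {
        for (j2 in (j + 1):ns) {
          sub <- submat[qc[i2], sc[j2]]
          pen <- gap_cost(i2 - i - 1) + gap_cost(j2 - j - 1)
          extend_pairing(i2, j2, score + sub - pen)
        }
      }
    }
  }
  for (i in seq_len(nq)) {
    for (j in seq_len(ns)) {
      extend_pairing(i, j, submat[qc[i], sc[j]])
    }
  }
  best
}

# exhaustive best-chain enumeration for collinearity (both orientations)
enum_best_chain <- function(ra, rb, max_gap = 25, penalty = 0.01) {
  n <- length(ra)
  best <- -Inf
  step_ok <- function(i, j, orient) {
    da <- ra[j] - ra[i]
    db <- if (orient == "+") rb[j] - rb[i] else rb[i] - rb[j]
    da >= 1 && db >= 1 && (da - 1) <= max_gap && (db - 1) <= max_gap
  }
  step_score <- function(i, j, orient) {
    da <- ra[j] - ra[i]
    db <- abs(rb[j] - rb[i])
    1 - penalty * ((da - 1) + (db - 1))
  }
  grow <- function(last, score, orient) {
    if (score > best) best <<- score
    for (nxt in seq_len(n)) {
      if (step_ok(last, nxt, orient)) {
        grow(nxt, score + step_score(last, nxt, orient), orient)
      }
    }
  }
  for (orient in c("+", "-")) {
    for (st in seq_len(n)) grow(st, 1, orient)
  }
  best
}

# exact hypergeometric upper tail by combinatorial enumeration
enum_hyper_p <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# staged grid-search maximization of the zeta likelihood
grid_powerlaw_alpha <- function(deg, xmin = 1, lo = 1.01, hi = 10) {
  hz <- function(a) {
    z <- pracma::zeta(a)
    if (xmin > 1) z <- z - sum((1:(xmin - 1))^(-a))
    z
  }
  ll <- function(a) -length(deg) * log(hz(a)) - a * sum(log(deg))
  step <- (hi - lo) / 400
  while (step > 1e-8) {
    grid <- seq(lo, hi, by = step)
    vals <- vapply(grid, ll, 0)
    a <- grid[which.max(vals)]
    lo <- max(1.0001, a - 2 * step)
    hi <- a + 2 * step
    step <- step / 50
  }
  a
}

# random additive tree with positive branch lengths, as (phylo, distance)
random_additive_case <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  list(tree = tr, d = stats::cophenetic(tr))
}

rf_dist <- function(t1, t2) {
  as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)))
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}
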