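#' Default synthetic motif library
#'
#' Eight IUPAC patterns (CArG-box-like and other plant cis-element-like
#' strings) chosen so that no pattern is contained in a realization of
#' another on either strand, which keeps planted counts exactly
#' reconstructable.
#'
#' @return data.frame with `id` and `iupac`.
#' @export
default_motif_library <- function() {
  data.frame(
    id = c("CArG", "LTRE", "SVPbox", "Wbox", "Gvar", "M6", "M7", "M8"),
    iupac = c("CCWWWWWWAG", "CCGAC", "GTAAACAA", "TTGACY", "CACGTT",
              "AGATCCAA", "TGGGCY", "ATCTAGTT"),
    stringsAsFactors = FALSE
  )
}

# build one sequence of length len containing exactly the requested motif
# occurrences (plants: data.frame id, iupac, count) and no other occurrence
# of any library pattern, by planting realizations on random strands and
# rejection-fixing accidental hits
plant_sequence <- function(len, plants, library, max_iter = 300) {
  if (nrow(plants) > 0 && any(nchar(plants$iupac) > len)) {
    stop("motif longer than region")
  }
  if (nrow(plants) > 0 && sum(plants$count * (nchar(plants$iupac) + 1)) > len) {
    stop("planted counts inconsistent with region length")
  }
  pal <- plants$iupac[revcomp(plants$iupac) == plants$iupac]
  if (length(pal) > 0) {
    stop("strand-symmetric pattern(s) cannot carry exact planted counts ",
         "under double-strand scanning: ", paste(pal, collapse = ", "))
  }
  s <- chars(random_seq(len, DNA4))

  # instance table
  inst <- plants[rep(seq_len(nrow(plants)), plants$count), , drop = FALSE]
  inst$start <- rep(NA_integer_, nrow(inst)) # 0-based
  inst$strand <- rep(NA_character_, nrow(inst))
  inst$real <- rep(NA_character_, nrow(inst))

  place_instance <- function(i, inst) {
    w <- nchar(inst$iupac[i])
    for (try in 1:200) {
      st <- sample.int(len - w + 1L, 1L) - 1L
      clash <- FALSE
      for (j in seq_len(nrow(inst))) {
        if (j == i || is.na(inst$start[j])) next
        wj <- nchar(inst$iupac[j])
        if (st < inst$start[j] + wj + 1L && inst$start[j] < st + w + 1L) {
          clash <- TRUE
          break
        }
      }
      if (!clash) {
        inst$start[i] <- st
        break
      }
    }
    if (is.na(inst$start[i])) stop("could not place motif instances (region too dense)")
    inst
  }
  write_instance <- function(i, s, inst) {
    inst$strand[i] <- sample(c("+", "-"), 1L)
    r <- realize_iupac(inst$iupac[i])
    inst$real[i] <- if (inst$strand[i] == "+") r else revcomp(r)
    w <- nchar(inst$iupac[i])
    s[(inst$start[i] + 1L):(inst$start[i] + w)] <- chars(inst$real[i])
    list(s = s, inst = inst)
  }
  for (i in seq_len(nrow(inst))) {
    inst <- place_instance(i, inst)
    wr <- write_instance(i, s, inst)
    s <- wr$s
    inst <- wr$inst
  }

  in_planted <- function(pos0) { # is a 0-based position inside any instance?
    if (nrow(inst) == 0) return(rep(FALSE, length(pos0)))
    hit <- rep(FALSE, length(pos0))
    for (j in seq_len(nrow(inst))) {
      wj <- nchar(inst$iupac[j])
      hit <- hit | (pos0 >= inst$start[j] & pos0 < inst$start[j] + wj)
    }
    hit
  }

  for (iter in seq_len(max_iter)) {
    hits <- scan_motifs(paste(s, collapse = ""), library, both_strands = TRUE)
    # account planted instances: a hit matching (pattern, start) of an instance
    acc <- rep(FALSE, nrow(hits))
    found <- rep(FALSE, nrow(inst))
    for (j in seq_len(nrow(inst))) {
      k <- which(!acc & hits$pattern == inst$id[j] & hits$start == inst$start[j])
      if (length(k) > 0) {
        acc[k[1]] <- TRUE
        found[j] <- TRUE
      }
    }
    extras <- which(!acc)
    if (length(extras) == 0 && all(found)) {
      return(list(sequence = paste(s, collapse = ""),
                  instances = inst[, c("id", "iupac", "start", "strand")]))
    }
    # missing planted instance: its window was damaged or shadowed; rewrite it
    for (j in which(!found)) {
      wr <- write_instance(j, s, inst)
      s <- wr$s
      inst <- wr$inst
    }
    # extra accidental hits: mutate one free base inside each
    for (k in extras) {
      span <- hits$start[k]:(hits$end[k] - 1L)
      free <- span[!in_planted(span)]
      if (length(free) > 0) {
        p <- if (length(free) == 1) free else sample(free, 1L)
        s[p + 1L] <- sample(setdiff(DNA4, s[p + 1L]), 1L)
      } else {
        # hit entirely inside planted windows: redraw the overlapping instance
        j <- which(inst$start <= hits$start[k] &
                     inst$start + nchar(inst$iupac) >= hits$end[k])[1]
        if (is.na(j)) j <- which.min(abs(inst$start - hits$start[k]))
        wr <- write_instance(j, s, inst)
        s <- wr$s
        inst <- wr$inst
      }
    }
  }
  stop("could not realize exact motif counts; the library may contain ",
       "mutually nested patterns")
}

#' Simulate upstream promoter regions and ChIP peak sequences
#'
#' Each gene's upstream region contains exactly the planted motif
#' occurrences (on random strands) and no accidental occurrence of any
#' library pattern (enforced by rejection sampling). Peak sequences on a
#' synthetic ChIP chromosome contain a chosen subset of the library, so that
#' peak-based phase filtering must recover exactly that subset.
#'
#' @param n_genes number of upstream regions.
#' @param region_length upstream window in bp (1500 for LTRE-style analysis,
#'   2000 for target search).
#' @param motif_library data.frame `id`,`iupac` (default
#'   [default_motif_library()]).
#' @param planted_counts optional genes x motifs integer matrix of planted
#'   counts (rownames = gene ids, colnames = motif ids). Default: each gene
#'   gets 0-2 motifs at counts 1-3, with at least one gene per subset motif.
#' @param peak_subset character vector of motif ids present in peaks
#'   (default: 5 of the 8 library motifs).
#' @param n_peaks number of ChIP peaks.
#' @param peak_length peak width in bp.
#' @param seed RNG seed.
#' @return list with `upstream` (named character vector), `peaks`
#'   (data.frame chrom/start/end, 0-based half-open), `peak_genome` (named
#'   character vector, one ChIP chromosome), and `truth` (`counts` matrix,
#'   `peak_subset`, `targets` = genes carrying >= 1 subset-motif occurrence).
#' @export
sim_promoters <- function(n_genes = 30, region_length = 2000,
                          motif_library = default_motif_library(),
                          planted_counts = NULL,
                          peak_subset = NULL,
                          n_peaks = 6, peak_length = 300,
                          seed = 1) {
  set.seed(seed)
  lib <- as_motif_library(motif_library)
  if (is.null(peak_subset)) {
    peak_subset <- sort(sample(lib$id, min(5L, nrow(lib))))
  }
  stopifnot(all(peak_subset %in% lib$id))

  genes <- sprintf("PRM%03d", seq_len(n_genes))
  if (is.null(planted_counts)) {
    planted_counts <- matrix(0L, n_genes, nrow(lib),
                             dimnames = list(genes, lib$id))
    for (g in seq_len(n_genes)) {
      k <- sample(0:2, 1L)
      if (k > 0) {
        which_m <- sample(lib$id, k)
        planted_counts[g, which_m] <- sample(1:3, k, replace = TRUE)
      }
    }
    # guarantee each subset motif occurs upstream of at least one gene
    for (m in peak_subset) {
      if (sum(planted_counts[, m]) == 0) {
        planted_counts[sample.int(n_genes, 1L), m] <- 1L
      }
    }
  } else {
    planted_counts <- as.matrix(planted_counts)
    stopifnot(!is.null(rownames(planted_counts)),
              all(colnames(planted_counts) %in% lib$id),
              all(planted_counts >= 0))
    genes <- rownames(planted_counts)
    full <- matrix(0L, length(genes), nrow(lib),
                   dimnames = list(genes, lib$id))
    full[, colnames(planted_counts)] <- planted_counts
    planted_counts <- full
  }

  upstream <- setNames(character(length(genes)), genes)
  for (g in genes) {
    cnt <- planted_counts[g, ]
    plants <- lib[lib$id %in% names(cnt)[cnt > 0], , drop = FALSE]
    plants$count <- cnt[plants$id]
    upstream[g] <- plant_sequence(region_length, plants, lib)$sequence
  }

  # peaks: each subset motif planted in >= 1 peak; peaks clean otherwise
  peak_plan <- vector("list", n_peaks)
  for (i in seq_along(peak_subset)) {
    p <- ((i - 1L) %% n_peaks) + 1L
    peak_plan[[p]] <- c(peak_plan[[p]], peak_subset[i])
  }
  peak_seqs <- character(n_peaks)
  for (p in seq_len(n_peaks)) {
    ids <- peak_plan[[p]]
    plants <- lib[lib$id %in% ids, , drop = FALSE]
    plants$count <- if (nrow(plants) > 0) 1L else integer(0)
    peak_seqs[p] <- plant_sequence(peak_length, plants, lib)$sequence
  }
  gap <- 500L
  chrom_len <- n_peaks * (peak_length + gap) + gap
  chip <- chars(random_seq(chrom_len, DNA4))
  starts0 <- gap + (seq_len(n_peaks) - 1L) * (peak_length + gap)
  for (p in seq_len(n_peaks)) {
    chip[(starts0[p] + 1L):(starts0[p] + peak_length)] <- chars(peak_seqs[p])
  }
  peaks <- data.frame(
    chrom = "chip1", start = starts0, end = starts0 + peak_length,
    name = sprintf("peak%02d", seq_len(n_peaks)), stringsAsFactors = FALSE
  )

  targets <- genes[rowSums(planted_counts[, peak_subset, drop = FALSE]) > 0]
  list(
    upstream = upstream,
    peaks = peaks,
    peak_genome = c(chip1 = paste(chip, collapse = "")),
    motif_library = lib,
    truth = list(
      counts = planted_counts,
      peak_subset = sort(peak_subset),
      targets = targets
    )
  )
}
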