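#' Optimal local protein alignment with similarity and coverage
#'
#' Smith–Waterman local alignment under affine gaps (a gap of length k costs
#' `gap_open + k * gap_extend`), via Biostrings. Percent similarity follows
#' the BLASTP "positives" convention: substitution-matrix-positive matched
#' columns over all alignment columns (gaps included). Query coverage is the
#' aligned query span over the query length.
#'
#' @param query,subject protein sequences (character scalars).
#' @param matrix substitution matrix name (default "BLOSUM62").
#' @param gap_open,gap_extend affine gap parameters (default 10 / 4).
#' @return list with `score`, `percent_similarity`, `query_coverage`. An
#'   alignment whose best score is not positive is reported as empty
#'   (all three zero).
#' @export
align_local <- function(query, subject, matrix = "BLOSUM62",
                        gap_open = 10, gap_extend = 4) {
  if (nchar(query) == 0 || nchar(subject) == 0) stop("empty sequence")
  submat <- get_submat(matrix)
  check_residues(c(query, subject), rownames(submat))
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = subject, type = "local",
    substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  score <- Biostrings::score(aln)
  if (score <= 0) {
    return(list(score = 0, percent_similarity = 0, query_coverage = 0))
  }
  qa <- chars(as.character(Biostrings::alignedPattern(aln)))
  sa <- chars(as.character(Biostrings::alignedSubject(aln)))
  ncols <- length(qa)
  aligned <- qa != "-" & sa != "-"
  pos <- sum(submat[cbind(
    match(qa[aligned], rownames(submat)),
    match(sa[aligned], colnames(submat))
  )] > 0)
  span <- Biostrings::width(Biostrings::pattern(aln))
  list(
    score = score,
    percent_similarity = 100 * pos / ncols,
    query_coverage = 100 * span / nchar(query)
  )
}

get_submat <- function(matrix) {
  if (is.matrix(matrix)) return(matrix)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

check_residues <- function(seqs, alphabet) {
  for (s in seqs) {
    bad <- setdiff(unique(chars(s)), alphabet)
    if (length(bad) > 0) {
      stop("unknown residue symbol(s): ", paste(bad, collapse = ", "))
    }
  }
}

#' Best-hit ortholog calls against a reference proteome
#'
#' Aligns each query locally against every reference protein and reports the
#' best-scoring subject (ties broken by lexicographic subject id). The
#' `regular` flag applies the strict >50% similarity and >50% query coverage
#' rule.
#'
#' @param queries named character vector of query proteins.
#' @param reference named character vector of reference proteins.
#' @param ... passed to [align_local()].
#' @return data.frame with `query_id`, `subject_id`, `alignment_score`,
#'   `percent_similarity`, `query_coverage`, `regular`.
#' @export
call_orthologs <- function(queries, reference, ...) {
  if (length(reference) == 0) stop("reference proteome is empty")
  subj_ids <- sort(names(reference))
  rows <- lapply(names(queries), function(q) {
    best <- NULL
    for (sid in subj_ids) { # lexicographic order makes ties deterministic
      a <- align_local(queries[[q]], reference[[sid]], ...)
      if (is.null(best) || a$score > best$score) {
        best <- a
        best$subject <- sid
      }
    }
    data.frame(
      query_id = q, subject_id = best$subject,
      alignment_score = best$score,
      percent_similarity = best$percent_similarity,
      query_coverage = best$query_coverage,
      regular = best$percent_similarity > 50 & best$query_coverage > 50,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign positional family names
#'
#' Members are sorted by chromosome (in the declared chromosome order) and
#' ascending start coordinate, then named `<prefix>001 .. <prefix>N`
#' ("top to bottom" along each chromosome). Members without a located gene
#' model are named after all placed ones, in input order.
#'
#' @param members character vector of member gene ids.
#' @param models gene-model data.frame covering (at least) the placed members.
#' @param prefix name prefix (default "MdMADS").
#' @param chromosome_order optional explicit chromosome ordering; default is
#'   the sorted unique chromosome labels.
#' @return data.frame with `gene_id`, `assigned_name`, `chromosome`, `start`.
#' @export
assign_names <- function(members, models, prefix = "MdMADS",
                         chromosome_order = NULL) {
  if (anyDuplicated(members)) stop("duplicate gene IDs among members")
  models <- as_gene_models(models)
  placed <- members[members %in% models$gene_id]
  unplaced <- members[!members %in% models$gene_id]
  m <- models[match(placed, models$gene_id), ]
  if (is.null(chromosome_order)) {
    chromosome_order <- sort(unique(m$chromosome))
  }
  ord <- order(match(m$chromosome, chromosome_order), m$start)
  ordered_ids <- c(m$gene_id[ord], unplaced)
  data.frame(
    gene_id = ordered_ids,
    assigned_name = sprintf("%s%03d", prefix, seq_along(ordered_ids)),
    chromosome = c(m$chromosome[ord], rep(NA_character_, length(unplaced))),
    start = c(m$start[ord], rep(NA_integer_, length(unplaced))),
    stringsAsFactors = FALSE
  )
}
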