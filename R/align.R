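#' Amino-acid scoring scheme for global alignment
#'
#' Bundles a substitution matrix with affine gap penalties. The default is
#' BLOSUM62 with gap open -10 and gap extend -1 (a gap of length L costs
#' 10 + L). The ambiguity code `X` is rescored to 0 against every residue so
#' that unknown positions are identity-neutral.
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings
#'   (currently `"BLOSUM62"`), or a symmetric numeric matrix with residue
#'   dimnames.
#' @param gap_open Gap-opening penalty, a negative number.
#' @param gap_extend Gap-extension penalty (per gapped position), negative.
#' @return An object of class `scoring_scheme`.
#' @examples
#' scoring_scheme()
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = -10, gap_extend = -1) {
  if (!(is.numeric(gap_open) && gap_open < 0))
    stop("`gap_open` must be negative")
  if (!(is.numeric(gap_extend) && gap_extend < 0))
    stop("`gap_extend` must be negative")
  if (is.character(matrix)) {
    name <- match.arg(matrix, "BLOSUM62")
    env <- new.env()
    utils::data(list = name, package = "Biostrings", envir = env)
    mat <- get(name, envir = env)
  } else {
    name <- "custom"
    mat <- as.matrix(matrix)
  }
  if (!isSymmetric(unname(mat)))
    stop("substitution matrix must be symmetric")
  if ("X" %in% rownames(mat)) {
    mat["X", ] <- 0
    mat[, "X"] <- 0
  }
  structure(
    list(matrix_name = name, matrix = mat,
         gap_open = gap_open, gap_extend = gap_extend),
    class = "scoring_scheme"
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("Scoring scheme:", x$matrix_name,
      sprintf("(gap open %d, extend %d)\n", x$gap_open, x$gap_extend))
  invisible(x)
}

check_aa_sequence <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L)
    stop(what, " must be a single non-empty string")
  bad <- setdiff(strsplit(toupper(seq), "")[[1]], c(AA20, "X"))
  if (length(bad))
    stop(what, " contains characters outside the amino-acid alphabet: ",
         paste(unique(bad), collapse = ", "))
  toupper(seq)
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties, computed with
#' [Biostrings::pairwiseAlignment()]. Identity bookkeeping (identical and
#' aligned-pair counts) is derived from the gapped strings.
#'
#' @param a,b Amino-acid sequences (single strings over the 20 residues + X).
#' @param scheme A [scoring_scheme()].
#' @param a_id,b_id Optional sequence labels carried into the result.
#' @return An object of class `pairwise_alignment` with elements
#'   `query_id`, `target_id`, `aligned_query`, `aligned_target`, `score`,
#'   `identical_count`, `aligned_pair_count`, `identity_fraction`, and
#'   `column_map` (a data frame with per-column `query_pos` / `target_pos`,
#'   `NA` at gaps).
#' @examples
#' aln <- global_align("HEAGAWGHEE", "PAWHEAE")
#' aln$score
#' @export
global_align <- function(a, b, scheme = scoring_scheme(),
                         a_id = "query", b_id = "target") {
  stopifnot(inherits(scheme, "scoring_scheme"))
  a <- check_aa_sequence(a, "`a`")
  b <- check_aa_sequence(b, "`b`")
  aln <- Biostrings::pairwiseAlignment(
    a, b,
    substitutionMatrix = scheme$matrix,
    gapOpening = -scheme$gap_open,
    gapExtension = -scheme$gap_extend,
    type = "global"
  )
  ga <- as.character(Biostrings::alignedPattern(aln))
  gb <- as.character(Biostrings::alignedSubject(aln))
  new_pairwise_alignment(ga, gb, Biostrings::score(aln), a_id, b_id)
}

# assemble the alignment container from two gapped strings
new_pairwise_alignment <- function(ga, gb, score, a_id, b_id) {
  ca <- strsplit(ga, "")[[1]]
  cb <- strsplit(gb, "")[[1]]
  stopifnot(length(ca) == length(cb))
  qpos <- ifelse(ca == "-", NA_integer_, cumsum(ca != "-"))
  tpos <- ifelse(cb == "-", NA_integer_, cumsum(cb != "-"))
  paired <- ca != "-" & cb != "-"
  ident <- paired & ca == cb
  structure(
    list(
      query_id = a_id, target_id = b_id,
      aligned_query = ga, aligned_target = gb,
      score = score,
      identical_count = sum(ident),
      aligned_pair_count = sum(paired),
      identity_fraction = if (sum(paired)) sum(ident) / sum(paired) else NaN,
      column_map = data.frame(query_pos = qpos, target_pos = tpos)
    ),
    class = "pairwise_alignment"
  )
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("Global alignment %s vs %s: score %.1f, identity %.1f%% (%d/%d)\n",
              x$query_id, x$target_id, x$score,
              100 * x$identity_fraction,
              x$identical_count, x$aligned_pair_count))
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' @param aln A `pairwise_alignment`.
#' @param denominator What to divide the identical-residue count by:
#'   `"aligned_pairs"` (gap-excluded columns, the default and the convention
#'   of Clustal-style reports), `"alignment_length"`, or `"shorter_seq"`.
#' @return Percent identity (0-100).
#' @examples
#' percent_identity(global_align("AAAA", "AA"), "shorter_seq")
#' @export
percent_identity <- function(aln,
                             denominator = c("aligned_pairs",
                                             "alignment_length",
                                             "shorter_seq")) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  denominator <- match.arg(denominator)
  n <- switch(denominator,
    aligned_pairs = aln$aligned_pair_count,
    alignment_length = nchar(aln$aligned_query),
    shorter_seq = min(sum(!is.na(aln$column_map$query_pos)),
                      sum(!is.na(aln$column_map$target_pos)))
  )
  if (n == 0)
    stop("identity undefined: zero ", denominator, " in alignment")
  100 * aln$identical_count / n
}

#' All-vs-all identity and score matrices
#'
#' @param seqs Named character vector of sequences (labels must be unique).
#' @param scheme A [scoring_scheme()].
#' @return A list with symmetric matrices `identity` (fractions, unit
#'   diagonal) and `score`, rows/columns in input order.
#' @export
all_vs_all <- function(seqs, scheme = scoring_scheme()) {
  if (length(seqs) < 2) stop("need at least 2 sequences")
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("sequences must be named")
  if (anyDuplicated(ids)) stop("duplicate sequence labels")
  n <- length(seqs)
  idm <- matrix(1, n, n, dimnames = list(ids, ids))
  scm <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      aln <- global_align(seqs[[i]], seqs[[j]], scheme, ids[i], ids[j])
      idm[i, j] <- idm[j, i] <- aln$identity_fraction
      scm[i, j] <- scm[j, i] <- aln$score
    }
  }
  list(identity = idm, score = scm)
}

#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings returning/accepting plain named character
#' vectors. Output is wrapped at 60 columns.
#'
#' @param path File path.
#' @param seqs Named character vector of sequences.
#' @return `read_fasta` returns a named character vector; `write_fasta`
#'   returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Write a labeled matrix as TSV
#'
#' Writes an identity or score matrix with a leading label column, the format
#' consumed by [build_ssn()] round trips and Cytoscape imports.
#'
#' @param mat Matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
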