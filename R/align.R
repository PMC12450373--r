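#' Residue-by-residue cosine similarity matrix
#'
#' Entry (i, j) is the cosine between row i of the first residue
#' embedding matrix and row j of the second.
#'
#' @param e1,e2 residue embedding matrices (rows = residues).
#' @return `nrow(e1)` x `nrow(e2)` similarity matrix.
#' @export
residue_similarity_matrix <- function(e1, e2) {
  e1 <- rbind(e1); e2 <- rbind(e2)
  if (nrow(e1) < 1L || nrow(e2) < 1L) stop("empty embedding matrix")
  n1 <- sqrt(rowSums(e1^2)); n2 <- sqrt(rowSums(e2^2))
  if (any(n1 == 0) || any(n2 == 0))
    stop("cosine is undefined for zero rows")
  S <- tcrossprod(e1, e2) / outer(n1, n2)
  S[S > 1] <- 1
  S[S < -1] <- -1
  S
}

#' Soft-alignment configuration
#'
#' @param similarity_threshold_tau minimum cosine for a candidate match
#'   (default 0: mutual nearest neighbors alone gate matches).
#' @param min_path_length strict lower bound for [filter_alignments()]
#'   (default 18: kept paths must exceed 18).
#' @param max_sequence_length strict upper bound on sequence length for
#'   [filter_alignments()] (default 1024: sequences must be shorter).
#' @return object of class `soft_align_config`.
#' @export
soft_align_config <- function(similarity_threshold_tau = 0,
                              min_path_length = 18L,
                              max_sequence_length = 1024L) {
  structure(list(similarity_threshold_tau = similarity_threshold_tau,
                 min_path_length = as.integer(min_path_length),
                 max_sequence_length = as.integer(max_sequence_length)),
            class = "soft_align_config")
}

# first index of the row maximum (ties toward the smallest index)
argmax_first <- function(x) which.max(x)

#' Embedding-based pairwise soft alignment
#'
#' Builds candidate residue matches as mutual nearest neighbors under the
#' cosine similarity matrix (row i's best column is j and column j's best
#' row is i, ties broken toward the smallest index) with similarity at
#' least tau, then extracts the longest homologous residue path: a
#' maximum-cardinality subset of candidates strictly increasing in both
#' coordinates (longest-increasing-subsequence dynamic program). Among
#' equal-length paths the lexicographically smallest match list is
#' returned. The path length is the number of matched residue pairs.
#'
#' @param e1,e2 residue embedding matrices for the two sequences.
#' @param config a [soft_align_config()].
#' @param pair_ids optional character vector of the two sequence ids.
#' @return object of class `soft_alignment`: `matches` (two-column
#'   matrix of 1-based residue indices), `path_length`, `lengths` (the
#'   two sequence lengths), `pair_ids`.
#' @export
soft_align <- function(e1, e2, config = soft_align_config(),
                       pair_ids = c(NA, NA)) {
  S <- residue_similarity_matrix(e1, e2)
  m <- nrow(S); n <- ncol(S)
  row_best <- apply(S, 1L, argmax_first)
  col_best <- apply(S, 2L, argmax_first)
  cand_i <- which(col_best[row_best] == seq_len(m) &
                    S[cbind(seq_len(m), row_best)] >=
                      config$similarity_threshold_tau)
  cand <- cbind(i = cand_i, j = row_best[cand_i])
  cand <- cand[order(cand[, 1L]), , drop = FALSE]
  k <- nrow(cand)
  if (k == 0L) {
    matches <- cbind(i = integer(0), j = integer(0))
  } else {
    # f[t]: length of the longest strictly increasing chain starting at t
    f <- integer(k); nxt <- integer(k)
    for (t in k:1) {
      succ <- which(cand[, 1L] > cand[t, 1L] & cand[, 2L] > cand[t, 2L])
      if (!length(succ)) { f[t] <- 1L; nxt[t] <- 0L }
      else {
        # earliest successor among those achieving the max keeps the
        # reconstruction lexicographically smallest
        top <- max(f[succ])
        best <- succ[f[succ] == top][1L]
        f[t] <- 1L + top
        nxt[t] <- best
      }
    }
    target <- max(f)
    start <- which(f == target)[1L]
    path <- integer(0); t <- start
    while (t != 0L) { path <- c(path, t); t <- nxt[t] }
    matches <- cand[path, , drop = FALSE]
  }
  structure(list(matches = matches,
                 similarities = S[matches],
                 path_length = nrow(matches),
                 lengths = c(m, n), pair_ids = pair_ids),
            class = "soft_alignment")
}

#' Write a soft alignment as a TSV of (i, j, similarity) triples
#'
#' @param alignment a `soft_alignment`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_alignment_tsv <- function(alignment, path) {
  df <- data.frame(i = alignment$matches[, 1L],
                   j = alignment$matches[, 2L],
                   similarity = alignment$similarities)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.soft_alignment <- function(x, ...) {
  cat(sprintf("<soft_alignment> %s vs %s: path length %d (lengths %d, %d)\n",
              x$pair_ids[1], x$pair_ids[2], x$path_length,
              x$lengths[1], x$lengths[2]))
  invisible(x)
}

#' Filter soft alignments by path length and sequence length
#'
#' Keeps alignments whose path length strictly exceeds
#' `min_path_length` and whose two sequences are strictly shorter than
#' `max_sequence_length` (both bounds literal: a path of exactly 18 and a
#' sequence of exactly 1,024 residues are dropped).
#'
#' @param alignments list of `soft_alignment` objects.
#' @param config a [soft_align_config()].
#' @return filtered list.
#' @export
filter_alignments <- function(alignments, config = soft_align_config()) {
  Filter(function(al)
    al$path_length > config$min_path_length &&
      all(al$lengths < config$max_sequence_length),
    alignments)
}

#' Column occupancy of an alignment
#'
#' Occupancy of a column is the proportion of sequences with a residue
#' (non-gap) at that position; high mean occupancy indicates a compact,
#' complete alignment.
#'
#' @param family an [aligned_family()].
#' @return list with `per_column` occupancies and their `mean`.
#' @export
column_occupancy <- function(family) {
  stopifnot(inherits(family, "aligned_family"))
  cm <- family_char_matrix(family)
  occ <- colMeans(cm != "-")
  list(per_column = occ, mean = mean(occ))
}

#' Mean mutual information between alignment columns
#'
#' For every unordered column pair, the rows non-gapped at both columns
#' are kept; with at least `min_pair_rows` of them, the empirical mutual
#' information `sum p(a,b) log2( p(a,b) / (p(a) p(b)) )` (bits, no
#' pseudocounts) is computed; the mean over evaluated pairs is returned.
#' Pairs are visited in deterministic column order and the evaluation is
#' truncated at `max_column_pairs`. MI between columns signals
#' covariation, a proxy for co-evolving positions.
#'
#' @param family an [aligned_family()].
#' @param min_pair_rows minimum pairwise-complete rows (default 2).
#' @param max_column_pairs cap on evaluated pairs (default Inf).
#' @return list with `mean_mi` (bits; `NA` when every pair was skipped),
#'   `n_pairs_evaluated`, `n_pairs_skipped`.
#' @export
mean_mutual_information <- function(family, min_pair_rows = 2L,
                                    max_column_pairs = Inf) {
  stopifnot(inherits(family, "aligned_family"))
  cm <- family_char_matrix(family)
  W <- ncol(cm)
  if (W < 2L) stop("mutual information needs at least 2 columns")
  mis <- numeric(0)
  skipped <- 0L
  done <- 0L
  for (c1 in seq_len(W - 1L)) {
    for (c2 in (c1 + 1L):W) {
      if (done >= max_column_pairs) break
      done <- done + 1L
      keep <- cm[, c1] != "-" & cm[, c2] != "-"
      if (sum(keep) < min_pair_rows) { skipped <- skipped + 1L; next }
      mis <- c(mis, column_pair_mi(cm[keep, c1], cm[keep, c2]))
    }
    if (done >= max_column_pairs) break
  }
  list(mean_mi = if (length(mis)) mean(mis) else NA_real_,
       n_pairs_evaluated = length(mis), n_pairs_skipped = skipped)
}

# empirical MI (bits) of two aligned character vectors
column_pair_mi <- function(a, b) {
  jt <- table(a, b) / length(a)
  pa <- rowSums(jt); pb <- colSums(jt)
  nz <- jt > 0
  sum(jt[nz] * log2(jt[nz] / outer(pa, pb)[nz]))
}
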