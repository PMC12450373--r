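#' Cosine similarity between two vectors
#'
#' Standard cosine of the angle between `u` and `v`; symmetric and
#' invariant to positive rescaling. Errors on zero vectors, for which the
#' cosine is undefined.
#'
#' @param u,v numeric vectors of equal length.
#' @return value in `[-1, 1]`.
#' @export
cosine <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) stop("cosine is undefined for zero vectors")
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

#' Extract residue-level embeddings for a sequence
#'
#' Tokenizes the sequence, runs the encoder, and strips any special-token
#' rows so the returned matrix has exactly one row per residue, in
#' sequence order ("last hidden layer" representation).
#'
#' @param encoder a `plm_encoder` or `plm_adapted`.
#' @param sequence residue string.
#' @param sequence_id optional id stored as an attribute.
#' @return L x d numeric matrix of residue embeddings.
#' @export
embed_residues <- function(encoder, sequence, sequence_id = NULL) {
  config <- if (inherits(encoder, "plm_adapted")) encoder$base$config
            else encoder$config
  vocab <- config$vocab
  toks <- tokenize(sequence, vocab, max_length = config$max_sequence_length)
  out <- encoder_forward(encoder, toks)
  keep <- toks %in% vocab$residue_ids
  m <- out$hidden[keep, , drop = FALSE]
  if (!is.null(sequence_id)) attr(m, "sequence_id") <- sequence_id
  m
}

#' Mean-pool a residue embedding matrix
#'
#' The sequence-level (pooled) embedding is the arithmetic column mean of
#' the residue embedding matrix.
#'
#' @param matrix L x d residue embedding matrix with at least one row.
#' @return numeric vector of length d.
#' @export
pool <- function(matrix) {
  if (is.null(dim(matrix)) || nrow(matrix) < 1L)
    stop("cannot pool an empty embedding matrix")
  colMeans(matrix)
}

#' Embed every sequence in a group set
#'
#' Convenience wrapper computing residue matrices and pooled vectors for
#' all records.
#'
#' @param encoder a `plm_encoder` or `plm_adapted`.
#' @param data an [ortholog_group_set()].
#' @param residues also keep per-residue matrices (default TRUE).
#' @return list with `pooled` (n x d matrix, rownames = sequence ids) and,
#'   if requested, `residue` (named list of L x d matrices).
#' @export
embed_dataset <- function(encoder, data, residues = TRUE) {
  stopifnot(inherits(data, "ortholog_group_set"))
  ids <- unname(vapply(data$records, `[[`, "", "id"))
  mats <- lapply(data$records, function(r)
    embed_residues(encoder, r$sequence, sequence_id = r$id))
  pooled <- do.call(rbind, lapply(mats, pool))
  rownames(pooled) <- ids
  out <- list(pooled = pooled)
  if (residues) {
    names(mats) <- ids
    out$residue <- mats
  }
  out
}

#' Anchor-positive versus anchor-negative cosine gap
#'
#' Scores a triplet list with pooled embeddings: the mean anchor-positive
#' cosine, the mean anchor-negative cosine, and their difference (the
#' quantity contrastive fine-tuning is expected to increase).
#'
#' @param pooled pooled-embedding matrix with sequence ids as rownames.
#' @param triplets data.frame with columns `anchor`, `positive`,
#'   `negative`.
#' @return list with `mean_positive`, `mean_negative`, `gap`.
#' @export
triplet_cosine_gap <- function(pooled, triplets) {
  ap <- vapply(seq_len(nrow(triplets)), function(k)
    cosine(pooled[triplets$anchor[k], ], pooled[triplets$positive[k], ]),
    numeric(1))
  an <- vapply(seq_len(nrow(triplets)), function(k)
    cosine(pooled[triplets$anchor[k], ], pooled[triplets$negative[k], ]),
    numeric(1))
  list(mean_positive = mean(ap), mean_negative = mean(an),
       gap = mean(ap) - mean(an))
}

#' Write pooled embeddings as TSV
#'
#' @param pooled numeric matrix with sequence ids as rownames.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_embeddings_tsv <- function(pooled, path) {
  df <- data.frame(id = rownames(pooled), pooled, check.names = FALSE)
  colnames(df) <- c("id", paste0("d", seq_len(ncol(pooled))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pooled embeddings from TSV
#'
#' @param path file written by [write_embeddings_tsv()].
#' @return numeric matrix with ids as rownames.
#' @export
read_embeddings_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(df[[1]], NULL)
  m
}
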