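#' Amino-acid vocabulary for per-residue encoders
#'
#' Builds the token table used by the reference encoder: the 20 standard
#' amino acids plus the IUPAC unknown-residue symbol \code{X}, and the
#' special tokens \code{<pad>}, \code{<mask>} and (optionally)
#' \code{<bos>}/\code{<eos>} boundary markers. Gap characters are not part
#' of the vocabulary: encoders only ever see ungapped sequences.
#'
#' @param use_bos_eos logical; if \code{TRUE}, \code{tokenize()} brackets
#'   every sequence with begin/end tokens (stripped again by the embedding
#'   extractor). Default \code{FALSE}.
#' @param include_mask logical; include a mask token (required for the
#'   masked-token objective). Default \code{TRUE}.
#' @return An object of class \code{aa_vocabulary}: a list with the ordered
#'   \code{tokens} character vector, \code{size}, residue/special id sets and
#'   the ids of the individual special tokens.
#' @examples
#' v <- aa_vocabulary()
#' v$size
#' @export
aa_vocabulary <- function(use_bos_eos = FALSE, include_mask = TRUE) {
  residues <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  specials <- "<pad>"
  if (include_mask) specials <- c(specials, "<mask>")
  if (use_bos_eos) specials <- c(specials, "<bos>", "<eos>")
  tokens <- c(residues, specials)
  id <- seq_along(tokens)
  names(id) <- tokens
  v <- list(
    tokens = tokens,
    size = length(tokens),
    residue_ids = unname(id[residues]),
    special_ids = unname(id[specials]),
    x_id = unname(id["X"]),
    pad_id = unname(id["<pad>"]),
    mask_id = if (include_mask) unname(id["<mask>"]) else NA_integer_,
    bos_id = if (use_bos_eos) unname(id["<bos>"]) else NA_integer_,
    eos_id = if (use_bos_eos) unname(id["<eos>"]) else NA_integer_,
    use_bos_eos = use_bos_eos
  )
  class(v) <- "aa_vocabulary"
  v
}

#' Tokenize a residue string
#'
#' Maps each residue character to its token id; characters outside the
#' standard alphabet are mapped to the unknown-residue token \code{X}.
#' When the vocabulary carries begin/end tokens these are added at the
#' first and last positions.
#'
#' @param sequence single nonempty residue string (uppercased internally).
#' @param vocab an [aa_vocabulary()].
#' @param max_length optional length limit; a longer sequence raises an
#'   error rather than being truncated silently.
#' @return integer vector of token ids.
#' @export
tokenize <- function(sequence, vocab, max_length = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("cannot tokenize an empty sequence")
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (!is.null(max_length)) {
    budget <- max_length - if (vocab$use_bos_eos) 2L else 0L
    if (length(chars) > budget) {
      stop(sprintf("sequence length %d exceeds maximum %d (no silent truncation)",
                   length(chars), budget))
    }
  }
  id <- match(chars, vocab$tokens)
  id[is.na(id)] <- vocab$x_id
  # only residue symbols are legal input characters
  id[!(id %in% vocab$residue_ids)] <- vocab$x_id
  if (vocab$use_bos_eos) id <- c(vocab$bos_id, id, vocab$eos_id)
  as.integer(id)
}

#' Invert tokenization back to a residue string
#'
#' Drops special tokens and concatenates residue symbols; the round trip
#' \code{detokenize(tokenize(s))} is the identity for sequences over the
#' standard alphabet (unknown characters come back as \code{X}).
#'
#' @param ids integer token ids.
#' @param vocab an [aa_vocabulary()].
#' @return residue string.
#' @export
detokenize <- function(ids, vocab) {
  ids <- ids[ids %in% vocab$residue_ids]
  paste(vocab$tokens[ids], collapse = "")
}

#' @export
print.aa_vocabulary <- function(x, ...) {
  cat(sprintf("<aa_vocabulary> %d tokens (%d residues, %d specials)%s\n",
              x$size, length(x$residue_ids), length(x$special_ids),
              if (x$use_bos_eos) ", bos/eos on" else ""))
  invisible(x)
}
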