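#' A protein record
#'
#' @param id unique sequence identifier.
#' @param sequence nonempty residue string (uppercased).
#' @param group_id orthologous-group identifier.
#' @return list of class `protein_record`.
#' @export
protein_record <- function(id, sequence, group_id) {
  if (!nzchar(id)) stop("record id must be nonempty")
  if (!nzchar(sequence)) stop(sprintf("record '%s': empty sequence", id))
  structure(list(id = id, sequence = toupper(sequence),
                 group_id = as.character(group_id)),
            class = "protein_record")
}

#' A set of sequences partitioned into orthologous groups
#'
#' The unit of sampling, splitting and benchmarking: every record belongs
#' to exactly one labeled group.
#'
#' @param records list of [protein_record()]s with unique ids.
#' @return list of class `ortholog_group_set` with `records` (named by id)
#'   and `groups` (named list group_id -> member id vector).
#' @export
ortholog_group_set <- function(records) {
  ids <- unname(vapply(records, `[[`, "", "id"))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence ids: ", paste(unique(dup), collapse = ", "))
  names(records) <- ids
  gids <- unname(vapply(records, `[[`, "", "group_id"))
  groups <- split(ids, gids)
  groups <- groups[order(names(groups))]
  structure(list(records = records, groups = groups),
            class = "ortholog_group_set")
}

#' @export
print.ortholog_group_set <- function(x, ...) {
  cat(sprintf("<ortholog_group_set> %d sequences in %d groups\n",
              length(x$records), length(x$groups)))
  invisible(x)
}

#' Number of sequences in a group set
#' @param data an [ortholog_group_set()].
#' @return integer count.
#' @export
n_sequences <- function(data) length(data$records)

#' Read protein sequences with group labels from FASTA
#'
#' Group membership is taken from the header convention `id|group`, or
#' from a sidecar TSV with columns `id` and `group` when `groups_tsv` is
#' given (the sidecar wins). Parsing delegates to Biostrings; validation
#' (duplicate ids, empty sequences, missing group labels) raises errors
#' naming the offending record.
#'
#' @param path FASTA file.
#' @param groups_tsv optional sidecar TSV path (columns id, group).
#' @return an [ortholog_group_set()].
#' @export
read_fasta <- function(path, groups_tsv = NULL) {
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  seqs <- as.character(set)
  sidecar <- NULL
  if (!is.null(groups_tsv)) {
    sidecar <- utils::read.table(groups_tsv, sep = "\t", header = TRUE,
                                 colClasses = "character")
    if (!all(c("id", "group") %in% colnames(sidecar)))
      stop("sidecar TSV must have columns 'id' and 'group'")
  }
  records <- vector("list", length(seqs))
  for (k in seq_along(seqs)) {
    hd <- strsplit(headers[k], "\\s+")[[1]][1]
    if (!nzchar(seqs[k]))
      stop(sprintf("record %d ('%s'): empty sequence", k, hd))
    if (!is.null(sidecar)) {
      id <- hd
      if (!id %in% sidecar$id && grepl("|", id, fixed = TRUE))
        id <- strsplit(id, "|", fixed = TRUE)[[1]][1]
      g <- sidecar$group[match(id, sidecar$id)]
      if (is.na(g))
        stop(sprintf("record %d ('%s'): no group in sidecar TSV", k, id))
    } else {
      parts <- strsplit(hd, "|", fixed = TRUE)[[1]]
      if (length(parts) != 2L || !all(nzchar(parts)))
        stop(sprintf(
          "record %d ('%s'): header does not follow 'id|group' and no sidecar TSV given",
          k, hd))
      id <- parts[1]; g <- parts[2]
    }
    records[[k]] <- protein_record(id, seqs[k], g)
  }
  ortholog_group_set(records)
}

#' Write a group set to FASTA
#'
#' Headers use the `id|group` convention so [read_fasta()] round-trips.
#'
#' @param data an [ortholog_group_set()].
#' @param path output FASTA file.
#' @return invisibly, the path.
#' @export
write_fasta <- function(data, path) {
  stopifnot(inherits(data, "ortholog_group_set"))
  seqs <- vapply(data$records, `[[`, "", "sequence")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- vapply(data$records, function(r)
    paste0(r$id, "|", r$group_id), "")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' An aligned ortholog family
#'
#' Equal-width gapped rows with per-row maps from alignment columns to
#' ungapped residue indices. For synthetic families the generator also
#' records the ground-truth conserved columns.
#'
#' @param group_id family identifier.
#' @param rows named character vector of equal-length gapped rows (gap
#'   character `-`; `.` is normalized to `-`).
#' @param truth_conserved_columns optional integer vector of 1-based
#'   alignment columns known to be conserved (synthetic data only).
#' @return list of class `aligned_family` with `rows`, `width`,
#'   `column_maps` (per row: residue index per column, NA at gaps) and
#'   `truth_conserved_columns`.
#' @export
aligned_family <- function(group_id, rows, truth_conserved_columns = NULL) {
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("alignment rows must be named by sequence id")
  rows <- toupper(gsub(".", "-", rows, fixed = TRUE))
  w <- unique(nchar(rows))
  if (length(w) != 1L)
    stop(sprintf("ragged alignment in family '%s': widths %s",
                 group_id, paste(w, collapse = ", ")))
  column_maps <- lapply(rows, function(r) {
    ch <- strsplit(r, "")[[1]]
    map <- rep(NA_integer_, length(ch))
    nong <- ch != "-"
    map[nong] <- seq_len(sum(nong))
    map
  })
  structure(list(group_id = group_id, rows = rows, width = w,
                 column_maps = column_maps,
                 truth_conserved_columns = truth_conserved_columns),
            class = "aligned_family")
}

#' Ungapped sequences of an aligned family
#' @param family an [aligned_family()].
#' @return named character vector of gapless sequences.
#' @export
family_sequences <- function(family) {
  vapply(family$rows, function(r) gsub("-", "", r, fixed = TRUE), "")
}

#' Read an aligned FASTA file as an aligned family
#'
#' @param path aligned FASTA (all rows equal width; `.` normalized to
#'   `-`).
#' @param group_id family identifier (default: the file name).
#' @return an [aligned_family()].
#' @export
read_msa <- function(path, group_id = basename(path)) {
  set <- Biostrings::readBStringSet(path)
  rows <- as.character(set)
  names(rows) <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  aligned_family(group_id, rows)
}

#' Write an aligned family as aligned FASTA
#' @param family an [aligned_family()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_msa <- function(family, path) {
  set <- Biostrings::BStringSet(family$rows)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# rows as a character matrix (one row per sequence, one column per
# alignment column)
family_char_matrix <- function(family) {
  do.call(rbind, strsplit(unname(family$rows), ""))
}
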