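#' Enumerate all within-group sequence pairs
#'
#' Every unordered pair of members of the same orthologous group, each
#' exactly once, in deterministic order (groups by sorted id, then sorted
#' id pairs within the group). The total is `sum over groups of
#' choose(n_g, 2)`; 673 groups of exactly 10 members give 30,285 pairs.
#'
#' @param data an [ortholog_group_set()].
#' @return data.frame with columns `group_id`, `id1`, `id2`.
#' @export
enumerate_within_group_pairs <- function(data) {
  stopifnot(inherits(data, "ortholog_group_set"))
  out <- list()
  for (g in sort(names(data$groups))) {
    ids <- sort(data$groups[[g]])
    n <- length(ids)
    if (n < 2L) next
    cmb <- utils::combn(ids, 2L)
    out[[g]] <- data.frame(group_id = g, id1 = cmb[1L, ], id2 = cmb[2L, ])
  }
  if (!length(out))
    return(data.frame(group_id = character(0), id1 = character(0),
                      id2 = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

new_similarity_report <- function(pairs, values, source) {
  structure(list(pairs = pairs, values = values, source = source,
                 count = length(values),
                 median = if (length(values)) stats::median(values)
                          else NA_real_),
            class = "pairwise_similarity_report")
}

#' @export
print.pairwise_similarity_report <- function(x, ...) {
  cat(sprintf("<pairwise_similarity_report> %s: %d comparisons, median %.4f\n",
              x$source, x$count, x$median))
  invisible(x)
}

#' Pooled within-group pairwise cosine similarity
#'
#' One cosine per enumerated pair of pooled sequence embeddings, plus the
#' distribution median (the summary reported per model in the pooled
#' benchmark).
#'
#' @param pairs data.frame from [enumerate_within_group_pairs()].
#' @param pooled matrix of pooled embeddings with sequence ids as
#'   rownames.
#' @return a `pairwise_similarity_report` (values, count, median).
#' @export
pooled_pairwise_similarity <- function(pairs, pooled) {
  missing <- setdiff(unique(c(pairs$id1, pairs$id2)), rownames(pooled))
  if (length(missing))
    stop("missing pooled embeddings for: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  vals <- vapply(seq_len(nrow(pairs)), function(k)
    cosine(pooled[pairs$id1[k], ], pooled[pairs$id2[k], ]), numeric(1))
  new_similarity_report(pairs, vals, "pooled_within_group")
}

#' Criteria defining a conserved alignment column
#'
#' A column is conserved when (a) the fraction of unknown symbols is
#' strictly below `max_unknown_frac` (both the IUPAC unknown residue `X`
#' and the gap `-` count as unknown), (b) the non-unknown symbols span at
#' most `max_residue_types` distinct standard residues, and (c) the most
#' abundant standard residue makes up at least `min_majority_frac` of the
#' non-unknown symbols. Defaults: fewer than 5% unknowns, at most four
#' types, at least 70% majority.
#'
#' @param max_unknown_frac strict upper bound on the unknown fraction.
#' @param max_residue_types inclusive bound on distinct residue types.
#' @param min_majority_frac inclusive lower bound on the majority
#'   fraction.
#' @return object of class `conserved_column_criteria`.
#' @export
conserved_column_criteria <- function(max_unknown_frac = 0.05,
                                      max_residue_types = 4L,
                                      min_majority_frac = 0.70) {
  stopifnot(max_unknown_frac > 0, max_unknown_frac <= 1,
            max_residue_types >= 1,
            min_majority_frac > 0, min_majority_frac <= 1)
  structure(list(max_unknown_frac = max_unknown_frac,
                 max_residue_types = as.integer(max_residue_types),
                 min_majority_frac = min_majority_frac),
            class = "conserved_column_criteria")
}

# evaluate one column (character vector of residues/gaps over rows)
column_is_conserved <- function(col, criteria) {
  n <- length(col)
  unknown <- col %in% c("X", "-")
  if (sum(unknown) / n >= criteria$max_unknown_frac) return(FALSE)
  res <- col[!unknown]
  if (!length(res)) return(FALSE)
  tab <- table(res)
  if (length(tab) > criteria$max_residue_types) return(FALSE)
  max(tab) / length(res) >= criteria$min_majority_frac
}

#' Detect conserved columns in an aligned family
#'
#' Applies the three conserved-column criteria to every alignment column
#' and returns the 1-based indices of the qualifying ones. An alignment
#' can contain any number of conserved columns.
#'
#' @param family an [aligned_family()].
#' @param criteria a [conserved_column_criteria()].
#' @return integer vector of conserved column indices (possibly empty).
#' @export
detect_conserved_columns <- function(family,
                                     criteria = conserved_column_criteria()) {
  stopifnot(inherits(family, "aligned_family"))
  cm <- family_char_matrix(family)
  which(vapply(seq_len(ncol(cm)), function(j)
    column_is_conserved(cm[, j], criteria), logical(1)))
}

#' Residue-level similarity at conserved alignment columns
#'
#' For every conserved column of every family, all unordered pairs of
#' residue embeddings among the rows that are not gapped at that column
#' (alignment columns are mapped to ungapped residue indices through the
#' family's column maps). The enumeration is truncated deterministically
#' at `max_comparisons` in fixed iteration order: family id, column, then
#' sorted row-id pair.
#'
#' @param families list of [aligned_family()]s.
#' @param residue_embeddings named list of L x d residue matrices keyed by
#'   sequence id.
#' @param criteria a [conserved_column_criteria()].
#' @param max_comparisons global cap on comparisons (default 1e6).
#' @return a `pairwise_similarity_report`; `pairs` records family, column
#'   and the two (id, residue index) end points.
#' @export
conserved_site_similarities <- function(families, residue_embeddings,
                                        criteria = conserved_column_criteria(),
                                        max_comparisons = 1e6) {
  ord <- order(vapply(families, `[[`, "", "group_id"))
  vals <- numeric(0)
  prov <- list()
  for (f in families[ord]) {
    cons <- detect_conserved_columns(f, criteria)
    row_ids <- sort(names(f$rows))
    for (cc in cons) {
      present <- row_ids[vapply(row_ids, function(id)
        !is.na(f$column_maps[[id]][cc]), logical(1))]
      if (length(present) < 2L) next
      cmb <- utils::combn(present, 2L)
      for (k in seq_len(ncol(cmb))) {
        if (length(vals) >= max_comparisons) break
        i1 <- cmb[1L, k]; i2 <- cmb[2L, k]
        p1 <- f$column_maps[[i1]][cc]; p2 <- f$column_maps[[i2]][cc]
        e1 <- residue_embeddings[[i1]]; e2 <- residue_embeddings[[i2]]
        if (is.null(e1) || is.null(e2))
          stop("missing residue embeddings for ", i1, " or ", i2)
        if (p1 > nrow(e1) || p2 > nrow(e2))
          stop(sprintf("column map of family '%s' inconsistent with embeddings",
                       f$group_id))
        vals <- c(vals, cosine(e1[p1, ], e2[p2, ]))
        prov[[length(prov) + 1L]] <- data.frame(
          group_id = f$group_id, column = cc, id1 = i1, pos1 = p1,
          id2 = i2, pos2 = p2)
      }
      if (length(vals) >= max_comparisons) break
    }
    if (length(vals) >= max_comparisons) break
  }
  pairs <- if (length(prov)) do.call(rbind, prov)
           else data.frame(group_id = character(0), column = integer(0),
                           id1 = character(0), pos1 = integer(0),
                           id2 = character(0), pos2 = integer(0))
  new_similarity_report(pairs, vals, "conserved_sites")
}

#' Configuration of the random-site similarity benchmark
#'
#' @param min_separation positions `p_i`, `p_j` must satisfy
#'   `|p_i - p_j| > min_separation` (default 20) and `p_i != p_j`.
#' @param exclude_conserved never sample a position that falls in a
#'   conserved column (default TRUE).
#' @param pairs_target number of accepted comparisons to accumulate.
#' @param max_retries rejection-sampling retries per draw (default 100).
#' @param seed integer seed.
#' @return object of class `random_site_config`.
#' @export
random_site_config <- function(min_separation = 20L,
                               exclude_conserved = TRUE,
                               pairs_target = 1000L, max_retries = 100L,
                               seed = 1L) {
  stopifnot(min_separation >= 0, pairs_target >= 1, max_retries >= 1)
  structure(list(min_separation = as.integer(min_separation),
                 exclude_conserved = isTRUE(exclude_conserved),
                 pairs_target = as.integer(pairs_target),
                 max_retries = as.integer(max_retries),
                 seed = as.integer(seed)),
            class = "random_site_config")
}

#' Residue-level similarity at random well-separated sites
#'
#' Compares embeddings at non-homologous positions: for distinct
#' sequences s_x, s_y of a family, ungapped positions p_i in s_x and p_j
#' in s_y are drawn with `p_i != p_j` and `|p_i - p_j| > min_separation`,
#' excluding (by default) positions lying in any conserved column.
#' Row pairs are visited in deterministic order, one accepted draw per
#' pair per sweep (rejection sampling with a retry cap), sweeping until
#' `pairs_target` comparisons accumulate or no family can contribute.
#' Families with no feasible pair are skipped with a warning.
#'
#' @param families list of [aligned_family()]s.
#' @param residue_embeddings named list of residue matrices keyed by id.
#' @param config a [random_site_config()].
#' @param conserved optional named list (by family group_id) of conserved
#'   column index vectors; computed with default criteria when omitted
#'   and `exclude_conserved` is TRUE.
#' @return a `pairwise_similarity_report`.
#' @export
random_site_similarities <- function(families, residue_embeddings, config,
                                     conserved = NULL) {
  stopifnot(inherits(config, "random_site_config"))
  ord <- order(vapply(families, `[[`, "", "group_id"))
  families <- families[ord]
  if (is.null(conserved) && config$exclude_conserved) {
    conserved <- lapply(families, detect_conserved_columns)
    names(conserved) <- vapply(families, `[[`, "", "group_id")
  }
  vals <- numeric(0)
  prov <- list()
  with_seed(config$seed, {
    for (f in families) {
      if (length(vals) >= config$pairs_target) break
      row_ids <- sort(names(f$rows))
      # allowed ungapped positions per row
      allowed <- lapply(row_ids, function(id) {
        cmap <- f$column_maps[[id]]
        pos <- stats::na.omit(cmap)
        if (config$exclude_conserved) {
          bad <- stats::na.omit(cmap[conserved[[f$group_id]]])
          pos <- setdiff(pos, bad)
        }
        as.integer(pos)
      })
      names(allowed) <- row_ids
      if (length(row_ids) < 2L) next
      pairs_rows <- utils::combn(row_ids, 2L)
      accepted_any <- TRUE
      family_accepted <- 0L
      while (length(vals) < config$pairs_target && accepted_any) {
        accepted_any <- FALSE
        for (k in seq_len(ncol(pairs_rows))) {
          if (length(vals) >= config$pairs_target) break
          i1 <- pairs_rows[1L, k]; i2 <- pairs_rows[2L, k]
          a1 <- allowed[[i1]]; a2 <- allowed[[i2]]
          if (!length(a1) || !length(a2)) next
          for (try in seq_len(config$max_retries)) {
            p1 <- a1[sample.int(length(a1), 1L)]
            p2 <- a2[sample.int(length(a2), 1L)]
            if (p1 != p2 && abs(p1 - p2) > config$min_separation) {
              e1 <- residue_embeddings[[i1]]; e2 <- residue_embeddings[[i2]]
              vals <- c(vals, cosine(e1[p1, ], e2[p2, ]))
              prov[[length(prov) + 1L]] <- data.frame(
                group_id = f$group_id, id1 = i1, pos1 = p1,
                id2 = i2, pos2 = p2)
              accepted_any <- TRUE
              family_accepted <- family_accepted + 1L
              break
            }
          }
        }
      }
      if (family_accepted == 0L)
        warning(sprintf("family '%s': no feasible random-site pair; skipped",
                        f$group_id))
    }
    NULL
  })
  pairs <- if (length(prov)) do.call(rbind, prov)
           else data.frame(group_id = character(0), id1 = character(0),
                           pos1 = integer(0), id2 = character(0),
                           pos2 = integer(0))
  new_similarity_report(pairs, vals, "random_sites")
}

#' Write a similarity report as TSV + JSON summary
#'
#' @param report a `pairwise_similarity_report`.
#' @param tsv_path per-comparison TSV output.
#' @param json_path summary JSON output (source, count, median).
#' @return invisibly, a list of the two paths.
#' @export
write_similarity_report <- function(report, tsv_path, json_path) {
  df <- report$pairs
  df$value <- report$values
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(source = report$source, count = report$count,
                            median = report$median),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(tsv = tsv_path, json = json_path))
}
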