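STANDARD_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Configuration of the synthetic ortholog-family generator
#'
#' The generator emulates orthologous groups the way a curated viral
#' ortholog database presents them: each group descends from a random
#' ancestor carrying conserved motif blocks that members copy (nearly)
#' verbatim, while positions outside the blocks diverge by independent
#' point substitution, optionally with single-residue indels. Because the
#' members of one group are produced from a common ancestor, the
#' ground-truth alignment and conserved columns are known by
#' construction.
#'
#' @param n_groups number of ortholog groups.
#' @param members_per_group members per group (scalar, or length-2 range
#'   sampled uniformly per group).
#' @param ancestor_length ancestor length (scalar or length-2 range).
#' @param conserved_blocks list of `c(start, length)` pairs (1-based,
#'   within the ancestor, non-overlapping).
#' @param substitution_rate per-position substitution probability outside
#'   conserved blocks, in `[0, 1)`. The default 0.5 emulates remote
#'   ortholog families whose members share roughly half their residues
#'   outside the motifs.
#' @param conserved_noise_rate per-position flip probability inside
#'   conserved blocks (default 0: blocks copied verbatim).
#' @param indel_rate per non-conserved position, probability split evenly
#'   between deleting the position and inserting one residue after it
#'   (default 0: gapless families).
#' @param residue_frequencies length-20 ancestor residue distribution
#'   over the standard alphabet (default uniform).
#' @param shared_blocks if TRUE, all groups carry the same conserved block
#'   content (one motif set sampled once), emulating remote homologs that
#'   share motifs across families; ancestors differ elsewhere.
#' @param enforce_nonconserved if TRUE (default), non-conserved alignment
#'   columns that accidentally satisfy the conserved-column criteria are
#'   re-sampled (then forced diverse), so the configured blocks are
#'   exactly the conserved ground truth.
#' @param seed integer seed; generation is fully reproducible.
#' @return object of class `synthetic_family_config`.
#' @export
synthetic_family_config <- function(n_groups = 30L, members_per_group = 12L,
                                    ancestor_length = 60L,
                                    conserved_blocks = list(c(11L, 8L),
                                                            c(41L, 8L)),
                                    substitution_rate = 0.5,
                                    conserved_noise_rate = 0,
                                    indel_rate = 0,
                                    residue_frequencies = rep(1 / 20, 20),
                                    shared_blocks = FALSE,
                                    enforce_nonconserved = TRUE,
                                    seed = 1L) {
  stopifnot(n_groups >= 1, all(members_per_group >= 1),
            all(ancestor_length >= 1),
            substitution_rate >= 0, substitution_rate < 1,
            conserved_noise_rate >= 0, conserved_noise_rate <= 1,
            indel_rate >= 0, indel_rate < 1,
            length(residue_frequencies) == 20,
            abs(sum(residue_frequencies) - 1) < 1e-8)
  min_len <- min(ancestor_length)
  pos_sets <- lapply(conserved_blocks, function(b) seq(b[1], b[1] + b[2] - 1))
  all_pos <- unlist(pos_sets)
  if (any(duplicated(all_pos))) stop("conserved blocks overlap")
  if (length(all_pos) && max(all_pos) > min_len)
    stop("conserved blocks exceed ancestor length")
  structure(list(n_groups = as.integer(n_groups),
                 members_per_group = as.integer(members_per_group),
                 ancestor_length = as.integer(ancestor_length),
                 conserved_blocks = conserved_blocks,
                 conserved_positions = sort(all_pos),
                 substitution_rate = substitution_rate,
                 conserved_noise_rate = conserved_noise_rate,
                 indel_rate = indel_rate,
                 residue_frequencies = residue_frequencies,
                 shared_blocks = isTRUE(shared_blocks),
                 enforce_nonconserved = isTRUE(enforce_nonconserved),
                 seed = as.integer(seed)),
            class = "synthetic_family_config")
}

sample_scalar <- function(x) if (length(x) == 2L) sample(x[1]:x[2], 1L) else x

substitute_residue <- function(ch) {
  # a random residue different from the current one
  vapply(ch, function(c0) sample(setdiff(STANDARD_AA, c0), 1L), "")
}

# Force an alignment column (character vector over rows, gaps '-') to fail
# the conserved-column criteria by cycling >= 5 distinct residues.
force_diverse_column <- function(col) {
  nong <- which(col != "-")
  if (!length(nong)) return(col)
  pool <- STANDARD_AA[1:6]
  col[nong] <- pool[((seq_along(nong) - 1L) %% 6L) + 1L]
  col
}

#' Generate ground-truthed synthetic ortholog families
#'
#' Produces a labeled sequence set plus, per group, the ground-truth
#' multiple sequence alignment with its conserved columns (see
#' [synthetic_family_config()] for the generative model). With
#' `indel_rate = 0` rows are gapless and the alignment is the trivial
#' equal-length one; with indels, insertions get dedicated columns and
#' deletions become gaps, so alignments remain exact by construction.
#'
#' @param config a [synthetic_family_config()].
#' @return list with `data` (an [ortholog_group_set()]) and `families`
#'   (list of [aligned_family()] with `truth_conserved_columns`).
#' @export
generate_families <- function(config) {
  stopifnot(inherits(config, "synthetic_family_config"))
  with_seed(config$seed, {
    shared <- NULL
    if (config$shared_blocks && length(config$conserved_positions))
      shared <- sample(STANDARD_AA, length(config$conserved_positions),
                       replace = TRUE, prob = config$residue_frequencies)
    records <- list()
    families <- vector("list", config$n_groups)
    for (g in seq_len(config$n_groups)) {
      gid <- sprintf("VOG%04d", g)
      A <- sample_scalar(config$ancestor_length)
      m <- sample_scalar(config$members_per_group)
      cons <- config$conserved_positions
      ancestor <- sample(STANDARD_AA, A, replace = TRUE,
                         prob = config$residue_frequencies)
      if (!is.null(shared)) ancestor[cons] <- shared
      is_cons <- seq_len(A) %in% cons

      # members as per-ancestor-position residues ('' = deleted) plus a
      # single-residue insertion slot after each position
      res <- matrix(rep(ancestor, each = m), nrow = m)
      ins <- matrix("", nrow = m, ncol = A)
      for (j in seq_len(m)) {
        sub_mask <- !is_cons & stats::runif(A) < config$substitution_rate
        if (any(sub_mask)) res[j, sub_mask] <- substitute_residue(res[j, sub_mask])
        if (config$conserved_noise_rate > 0) {
          noise_mask <- is_cons & stats::runif(A) < config$conserved_noise_rate
          if (any(noise_mask))
            res[j, noise_mask] <- substitute_residue(res[j, noise_mask])
        }
        if (config$indel_rate > 0) {
          del_mask <- !is_cons & stats::runif(A) < config$indel_rate / 2
          res[j, del_mask] <- "-"
          ins_mask <- !is_cons & stats::runif(A) < config$indel_rate / 2
          if (any(ins_mask))
            ins[j, ins_mask] <- sample(STANDARD_AA, sum(ins_mask),
                                       replace = TRUE)
        }
      }

      # assemble alignment columns: per ancestor position, the match
      # column, then one insertion column per member that inserted there
      cols <- list()
      col_kind <- integer(0)  # ancestor position of match columns, 0 for insertions
      for (p in seq_len(A)) {
        cols[[length(cols) + 1L]] <- res[, p]
        col_kind <- c(col_kind, p)
        who <- which(nzchar(ins[, p]))
        for (j in who) {
          cc <- rep("-", m); cc[j] <- ins[j, p]
          cols[[length(cols) + 1L]] <- cc
          col_kind <- c(col_kind, 0L)
        }
      }
      cmat <- do.call(cbind, cols)
      truth <- which(col_kind %in% cons)

      if (config$enforce_nonconserved) {
        crit <- conserved_column_criteria()
        for (ci in setdiff(seq_len(ncol(cmat)), truth)) {
          p <- col_kind[ci]
          tries <- 0L
          while (column_is_conserved(cmat[, ci], crit) && tries < 20L) {
            tries <- tries + 1L
            if (p > 0L) {
              keep <- cmat[, ci] != "-"
              redraw <- keep & stats::runif(m) < config$substitution_rate
              cmat[keep, ci] <- ancestor[p]
              if (any(redraw))
                cmat[redraw, ci] <- substitute_residue(cmat[redraw, ci])
            } else break
          }
          if (column_is_conserved(cmat[, ci], crit))
            cmat[, ci] <- force_diverse_column(cmat[, ci])
        }
      }

      ids <- sprintf("%s_m%02d", gid, seq_len(m))
      rows <- apply(cmat, 1L, paste, collapse = "")
      names(rows) <- ids
      families[[g]] <- aligned_family(gid, rows,
                                      truth_conserved_columns = truth)
      seqs <- family_sequences(families[[g]])
      for (j in seq_len(m))
        records[[length(records) + 1L]] <- protein_record(ids[j], seqs[j], gid)
    }
    list(data = ortholog_group_set(records), families = families)
  })
}

#' Drop small orthologous groups
#'
#' Retains exactly the groups with strictly more than
#' `min_members_exclusive` members ("over 10 sequences" by default);
#' records of dropped groups are removed.
#'
#' @param data an [ortholog_group_set()].
#' @param min_members_exclusive strict lower bound on group size
#'   (default 10, i.e. groups of size >= 11 are kept).
#' @return filtered [ortholog_group_set()] with attribute `n_dropped`
#'   (sequences removed).
#' @export
filter_groups <- function(data, min_members_exclusive = 10L) {
  stopifnot(inherits(data, "ortholog_group_set"))
  keep_groups <- names(data$groups)[
    lengths(data$groups) > min_members_exclusive]
  keep_ids <- unlist(data$groups[keep_groups], use.names = FALSE)
  out <- ortholog_group_set(data$records[keep_ids])
  attr(out, "n_dropped") <- length(data$records) - length(keep_ids)
  out
}

#' Stratified train/test split over orthologous groups
#'
#' Every group contributes `max(1, round(test_fraction * n_g))` members to
#' the test subset, chosen uniformly without replacement, so all groups
#' are proportionately represented in both subsets (90:10 by default).
#'
#' @param data an [ortholog_group_set()]; every group must have at least
#'   2 members.
#' @param test_fraction fraction of each group held out (default 0.1).
#' @param seed integer seed.
#' @return list of class `split_result` with disjoint `train_ids`,
#'   `test_ids` covering all ids, and `ratio` (train fraction).
#' @export
stratified_split <- function(data, test_fraction = 0.1, seed = 1L) {
  stopifnot(inherits(data, "ortholog_group_set"),
            test_fraction > 0, test_fraction < 1)
  small <- names(data$groups)[lengths(data$groups) < 2L]
  if (length(small))
    stop("cannot stratify groups of size 1: ",
         paste(small, collapse = ", "))
  with_seed(seed, {
    test_ids <- unlist(lapply(data$groups, function(ids) {
      k <- max(1L, as.integer(round(test_fraction * length(ids))))
      sample(ids, k)
    }), use.names = FALSE)
    all_ids <- names(data$records)
    structure(list(train_ids = setdiff(all_ids, test_ids),
                   test_ids = test_ids,
                   ratio = 1 - test_fraction),
              class = "split_result")
  })
}

#' Build held-out evaluation triplets across a split
#'
#' Draws triplets whose anchors are held-out sequences: the positive is a
#' training-set member of the anchor's group and the negative a held-out
#' (or, failing that, any) sequence from a different group. This makes
#' the anchor-positive/anchor-negative cosine gap measurable even when a
#' stratified split leaves a single held-out member per group.
#'
#' @param data an [ortholog_group_set()].
#' @param test_ids held-out sequence ids.
#' @param n number of triplets.
#' @param seed integer seed.
#' @return data.frame with columns `anchor`, `positive`, `negative`.
#' @export
heldout_triplets <- function(data, test_ids, n, seed = 1L) {
  stopifnot(inherits(data, "ortholog_group_set"))
  gid_of <- vapply(data$records, `[[`, "", "group_id")
  train_ids <- setdiff(names(data$records), test_ids)
  eligible <- test_ids[vapply(test_ids, function(a)
    any(gid_of[train_ids] == gid_of[[a]]), logical(1))]
  if (!length(eligible))
    stop("no held-out sequence has a training-set group mate")
  with_seed(seed, {
    anchor <- sample(eligible, n, replace = TRUE)
    positive <- vapply(anchor, function(a) {
      mates <- train_ids[gid_of[train_ids] == gid_of[[a]]]
      if (length(mates) == 1L) mates else sample(mates, 1L)
    }, "")
    negative <- vapply(anchor, function(a) {
      pool <- test_ids[gid_of[test_ids] != gid_of[[a]]]
      if (!length(pool)) pool <- names(data$records)[gid_of != gid_of[[a]]]
      if (length(pool) == 1L) pool else sample(pool, 1L)
    }, "")
    data.frame(anchor = anchor, positive = positive, negative = negative,
               row.names = NULL)
  })
}

#' Subset a group set by sequence ids
#' @param data an [ortholog_group_set()].
#' @param ids sequence ids to keep.
#' @return an [ortholog_group_set()].
#' @export
subset_groups <- function(data, ids) {
  ortholog_group_set(data$records[intersect(names(data$records), ids)])
}

#' Sample contrastive triplets
#'
#' Draws `n` triplets (anchor, positive, negative): the anchor uniformly
#' over sequences of groups with at least 2 members, the positive
#' uniformly over the anchor's group mates, the negative uniformly over
#' all sequences of other groups.
#'
#' @param data an [ortholog_group_set()] with at least 2 groups.
#' @param n number of triplets.
#' @param seed integer seed.
#' @return data.frame with columns `anchor`, `positive`, `negative`
#'   (sequence ids).
#' @export
sample_triplets <- function(data, n, seed = 1L) {
  stopifnot(inherits(data, "ortholog_group_set"))
  if (length(data$groups) < 2L)
    stop("triplet sampling requires at least 2 orthologous groups")
  eligible <- names(data$groups)[lengths(data$groups) >= 2L]
  if (!length(eligible))
    stop("no group with >= 2 members to draw anchor/positive pairs from")
  anchor_pool <- unlist(data$groups[eligible], use.names = FALSE)
  gid_of <- vapply(data$records, `[[`, "", "group_id")
  all_ids <- names(data$records)
  with_seed(seed, {
    anchor <- sample(anchor_pool, n, replace = TRUE)
    positive <- vapply(anchor, function(a) {
      mates <- setdiff(data$groups[[gid_of[[a]]]], a)
      if (length(mates) == 1L) mates else sample(mates, 1L)
    }, "")
    negative <- vapply(anchor, function(a) {
      others <- all_ids[gid_of != gid_of[[a]]]
      if (length(others) == 1L) others else sample(others, 1L)
    }, "")
    data.frame(anchor = anchor, positive = positive, negative = negative,
               row.names = NULL)
  })
}
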