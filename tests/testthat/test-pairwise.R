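test_that("within-group pair enumeration matches the exhaustive double loop", {
  mk <- function(sizes) {
    recs <- list()
    for (g in seq_along(sizes)) for (j in seq_len(sizes[g]))
      recs[[length(recs) + 1L]] <- protein_record(
        sprintf("g%02d_s%02d", g, j), "ACDEF", paste0("G", g))
    ortholog_group_set(recs)
  }
  d <- mk(c(3, 5, 7))
  pairs <- enumerate_within_group_pairs(d)
  expect_equal(nrow(pairs), 3 + 10 + 21)
  # brute-force double loop over same-group id pairs
  ids <- names(d$records)
  g_of <- vapply(d$records, `[[`, "", "group_id")
  brute <- 0L
  for (i in seq_along(ids)) for (j in seq_along(ids))
    if (i < j && g_of[i] == g_of[j]) brute <- brute + 1L
  expect_equal(nrow(pairs), brute)
  expect_false(any(duplicated(paste(pairs$id1, pairs$id2))))
  expect_equal(nrow(enumerate_within_group_pairs(mk(2))), 1L)
})

test_that("pooled similarity reports values and a recomputable median", {
  d <- ortholog_group_set(lapply(1:5, function(i)
    protein_record(paste0("s", i), "ACDEF", "G1")))
  pairs <- enumerate_within_group_pairs(d)
  # identical embeddings: all values 1
  pooled <- matrix(1, 5, 4, dimnames = list(paste0("s", 1:5), NULL))
  rep1 <- pooled_pairwise_similarity(pairs, pooled)
  expect_true(all(rep1$values == 1))
  expect_equal(rep1$median, 1)
  # random embeddings: median equals the sort-based oracle
  set.seed(4)
  pooled2 <- matrix(rnorm(5 * 4), 5, 4, dimnames = list(paste0("s", 1:5), NULL))
  rep2 <- pooled_pairwise_similarity(pairs, pooled2)
  v <- sort(rep2$values)
  expect_equal(rep2$median, (v[5] + v[6]) / 2, tolerance = 1e-12)
  expect_equal(rep2$count, 10L)
  expect_error(pooled_pairwise_similarity(pairs, pooled2[1:3, ]), "missing")
})

test_that("conserved-column criteria evaluate strictly as specified", {
  # 20 rows: 16 A, 2 G, 2 V -> 0% unknown, 3 types, 80% majority
  col_ok <- c(rep("A", 16), rep("G", 2), rep("V", 2))
  fam <- aligned_family("F1", setNames(
    vapply(seq_along(col_ok), function(i) col_ok[i], ""),
    paste0("r", seq_along(col_ok))))
  expect_equal(detect_conserved_columns(fam), 1L)
  # one gap in 20 rows: 5% unknowns is NOT fewer than 5%
  col_gap <- c(rep("A", 19), "-")
  fam2 <- aligned_family("F2", setNames(col_gap, paste0("r", 1:20)))
  expect_length(detect_conserved_columns(fam2), 0L)
  # a single repeated residue qualifies
  fam3 <- aligned_family("F3", setNames(rep("W", 12), paste0("r", 1:12)))
  expect_equal(detect_conserved_columns(fam3), 1L)
  # five residue types fail criterion (b); weak majority fails (c)
  fam4 <- aligned_family("F4", setNames(
    c(rep("A", 16), "C", "D", "E", "G"), paste0("r", 1:20)))
  expect_length(detect_conserved_columns(fam4), 0L)
  fam5 <- aligned_family("F5", setNames(
    c(rep("A", 13), rep("C", 7)), paste0("r", 1:20)))
  expect_length(detect_conserved_columns(fam5), 0L)  # 65% < 70%
  # X counts as unknown
  fam6 <- aligned_family("F6", setNames(c(rep("A", 19), "X"),
                                        paste0("r", 1:20)))
  expect_length(detect_conserved_columns(fam6), 0L)
  expect_error(aligned_family("bad", c(a = "AC-", b = "AC")), "ragged")
})

test_that("detector is row-order invariant and sees all-gap rows only via unknowns", {
  gen <- small_families(n_groups = 2, members = 12, seed = 23)
  f <- gen$families[[1]]
  perm <- sample(names(f$rows))
  f_perm <- aligned_family(f$group_id, f$rows[perm])
  expect_identical(detect_conserved_columns(f),
                   detect_conserved_columns(f_perm))
  # appending an all-gap row only raises the unknown fraction
  rows2 <- c(f$rows, allgap = strrep("-", f$width))
  f2 <- aligned_family(f$group_id, rows2)
  relaxed <- conserved_column_criteria(max_unknown_frac = 0.2)
  expect_identical(detect_conserved_columns(f2, relaxed),
                   detect_conserved_columns(f, relaxed))
})

test_that("conserved-site comparisons enumerate column pairs with truncation", {
  rows <- c(s1 = "AC-DE", s2 = "ACFDE", s3 = "AC-DE", s4 = "ACGDE")
  fam <- aligned_family("F1", rows)
  emb <- lapply(rows, function(r) {
    L <- nchar(gsub("-", "", r))
    matrix(seq_len(L * 3), L, 3)
  })
  crit <- conserved_column_criteria()
  cons <- detect_conserved_columns(fam, crit)
  expect_true(all(c(1L, 2L, 4L, 5L) %in% cons))
  rep1 <- conserved_site_similarities(list(fam), emb, crit)
  # C(4,2) = 6 comparisons per fully occupied conserved column
  expect_equal(rep1$count, 6L * length(cons))
  rep2 <- conserved_site_similarities(list(fam), emb, crit,
                                      max_comparisons = 5)
  expect_equal(rep2$count, 5L)
  expect_identical(rep2$values, rep1$values[1:5])
  expect_identical(rep2$pairs, rep1$pairs[1:5, ])
})

test_that("random-site draws satisfy every constraint and are reproducible", {
  gen <- small_families(n_groups = 3, members = 6, seed = 31,
                        ancestor_length = 70L)
  emb <- embed_dataset(tiny_encoder(seed = 1), gen$data)$residue
  cfg <- random_site_config(min_separation = 20, pairs_target = 2000,
                            seed = 5)
  rep1 <- random_site_similarities(gen$families, emb, cfg)
  expect_equal(rep1$count, 2000L)
  cons <- lapply(gen$families, detect_conserved_columns)
  names(cons) <- vapply(gen$families, `[[`, "", "group_id")
  fam_of <- setNames(rep(vapply(gen$families, `[[`, "", "group_id"),
                         each = 6),
                     unlist(lapply(gen$families, function(f) names(f$rows))))
  for (k in seq_len(nrow(rep1$pairs))) {
    p <- rep1$pairs[k, ]
    expect_true(p$id1 != p$id2)
    expect_true(abs(p$pos1 - p$pos2) > 20)
    f <- gen$families[[match(p$group_id,
                             vapply(gen$families, `[[`, "", "group_id"))]]
    img1 <- stats::na.omit(f$column_maps[[p$id1]][cons[[p$group_id]]])
    img2 <- stats::na.omit(f$column_maps[[p$id2]][cons[[p$group_id]]])
    expect_false(p$pos1 %in% img1)
    expect_false(p$pos2 %in% img2)
  }
  # identical seed, identical value stream
  rep2 <- random_site_similarities(gen$families, emb, cfg)
  expect_identical(rep1$values, rep2$values)
})

test_that("families with no feasible separated pair are skipped with a warning", {
  # length-21 sequences cannot satisfy |p_i - p_j| > 20
  rows <- c(a = strrep("A", 21), b = strrep("C", 21))
  fam <- aligned_family("short", rows)
  emb <- lapply(rows, function(r) matrix(rnorm(21 * 3), 21, 3))
  cfg <- random_site_config(min_separation = 20, pairs_target = 10,
                            exclude_conserved = FALSE, seed = 1)
  expect_warning(rep0 <- random_site_similarities(list(fam), emb, cfg),
                 "no feasible")
  expect_equal(rep0$count, 0L)
})
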