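test_that("residue similarity matrix matches the elementwise oracle", {
  set.seed(14)
  e1 <- matrix(rnorm(5 * 6), 5, 6)
  e2 <- matrix(rnorm(7 * 6), 7, 6)
  S <- residue_similarity_matrix(e1, e2)
  for (i in 1:5) for (j in 1:7)
    expect_equal(S[i, j], cosine(e1[i, ], e2[j, ]), tolerance = 1e-12)
  expect_equal(residue_similarity_matrix(e2, e1), t(S), tolerance = 1e-12)
  # identical orthogonal rows give the identity pattern
  I4 <- diag(4)
  expect_equal(residue_similarity_matrix(I4, I4), diag(4))
  expect_error(residue_similarity_matrix(matrix(0, 2, 3), e1), "zero")
})

test_that("soft alignment recovers the diagonal for identical distinct rows", {
  E <- diag(6)
  al <- soft_align(E, E)
  expect_equal(al$path_length, 6L)
  expect_equal(unname(al$matches[, 1]), 1:6)
  expect_equal(unname(al$matches[, 2]), 1:6)
  # swapped arguments give the transposed path, same length
  set.seed(20)
  e1 <- matrix(rnorm(8 * 5), 8, 5); e2 <- matrix(rnorm(9 * 5), 9, 5)
  a12 <- soft_align(e1, e2); a21 <- soft_align(e2, e1)
  expect_equal(a12$path_length, a21$path_length)
})

test_that("crossing candidates are resolved by the longest monotone chain", {
  # candidates {(1,2),(2,1),(3,3)}: longest strictly increasing chain = 2
  # constructed via embeddings whose mutual NN structure is exactly that
  base <- diag(3)
  e1 <- base
  e2 <- base[c(2, 1, 3), ]
  al <- soft_align(e1, e2)
  expect_equal(al$path_length, 2L)
  expect_equal(brute_longest_chain(cbind(c(1, 2, 3), c(2, 1, 3))), 2L)
  # lexicographically smallest optimum is returned
  expect_equal(unname(al$matches), cbind(c(1, 3), c(2, 3)))
})

test_that("path length equals exhaustive search over monotone candidate subsets", {
  set.seed(33)
  for (k in 1:12) {
    e1 <- matrix(rnorm(8 * 4), 8, 4)
    e2 <- matrix(rnorm(8 * 4), 8, 4)
    al <- soft_align(e1, e2)
    # recompute the candidate set independently
    S <- residue_similarity_matrix(e1, e2)
    rb <- apply(S, 1, which.max); cb <- apply(S, 2, which.max)
    cand <- cbind(which(cb[rb] == seq_len(8)), rb[which(cb[rb] == seq_len(8))])
    expect_lte(nrow(cand), 12L)
    expect_equal(al$path_length, brute_longest_chain(cand))
    # returned matches are strictly monotone candidates
    if (al$path_length > 1) {
      expect_true(all(diff(al$matches[, 1]) > 0))
      expect_true(all(diff(al$matches[, 2]) > 0))
    }
  }
})

test_that("alignment filter applies both strict bounds literally", {
  mk <- function(len, l1 = 100L, l2 = 100L)
    structure(list(matches = cbind(seq_len(len), seq_len(len)),
                   path_length = len, lengths = c(l1, l2),
                   pair_ids = c("a", "b")), class = "soft_alignment")
  cfg <- soft_align_config()
  expect_length(filter_alignments(list(mk(18)), cfg), 0L)   # 18 not > 18
  expect_length(filter_alignments(list(mk(19, 1000, 900)), cfg), 1L)
  expect_length(filter_alignments(list(mk(19, 1024, 900)), cfg), 0L)
  expect_length(filter_alignments(list(mk(19, 1023, 1023)), cfg), 1L)
})

test_that("occupancy matches the counting oracle", {
  fam <- aligned_family("F", c(a = "AC-E", b = "ACDE", c = "A-DE",
                               d = "ACDE"))
  occ <- column_occupancy(fam)
  expect_equal(unname(occ$per_column), c(1, 0.75, 0.75, 1))
  expect_equal(occ$mean, mean(c(1, 0.75, 0.75, 1)))
  gl <- aligned_family("G", c(a = "ACDE", b = "ACDE"))
  expect_true(all(column_occupancy(gl)$per_column == 1))
  # random gapped alignment against a direct recount
  set.seed(44)
  rows <- vapply(1:6, function(i)
    paste(sample(c("A", "C", "-"), 12, replace = TRUE), collapse = ""), "")
  names(rows) <- paste0("r", 1:6)
  fam2 <- aligned_family("H", rows)
  cm <- do.call(rbind, strsplit(rows, ""))
  expect_equal(unname(column_occupancy(fam2)$per_column),
               colMeans(cm != "-"))
})

test_that("mutual information matches closed forms and sampling limits", {
  # perfectly covarying pair of columns: 1 bit
  fam <- aligned_family("F", c(r1 = "AD", r2 = "AD", r3 = "CE", r4 = "CE"))
  expect_equal(mean_mutual_information(fam)$mean_mi, 1.0, tolerance = 1e-12)
  # constant column paired with anything: exactly 0
  fam0 <- aligned_family("F0", c(r1 = "AD", r2 = "AE", r3 = "AF"))
  expect_equal(mean_mutual_information(fam0)$mean_mi, 0)
  # independent uniform columns: MI tends to 0 (<= 0.05 at n = 10,000)
  set.seed(55)
  n <- 10000
  rows <- paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 sample(c("A", "C", "G", "T"), n, replace = TRUE))
  names(rows) <- paste0("r", seq_len(n))
  expect_lt(mean_mutual_information(aligned_family("big", rows))$mean_mi,
            0.05)
  # MI of a column with itself equals its entropy
  col <- sample(c("A", "C", "G"), 60, replace = TRUE,
                prob = c(0.5, 0.3, 0.2))
  fam_self <- aligned_family("S", setNames(paste0(col, col),
                                           paste0("r", 1:60)))
  p <- table(col) / 60
  expect_equal(mean_mutual_information(fam_self)$mean_mi,
               -sum(p * log2(p)), tolerance = 1e-12)
  # gap handling: pairwise-complete rows; too few rows -> skip
  famg <- aligned_family("G", c(r1 = "A-", r2 = "-D", r3 = "C-"))
  res <- mean_mutual_information(famg, min_pair_rows = 2)
  expect_true(is.na(res$mean_mi))
  expect_equal(res$n_pairs_skipped, 1L)
})

test_that("nonnegativity of MI over random gapped alignments", {
  set.seed(66)
  for (k in 1:5) {
    rows <- vapply(1:8, function(i)
      paste(sample(c("A", "C", "D", "E", "-"), 10, replace = TRUE),
            collapse = ""), "")
    names(rows) <- paste0("r", 1:8)
    fam <- aligned_family("R", rows)
    cm <- do.call(rbind, strsplit(rows, ""))
    for (c1 in 1:9) for (c2 in (c1 + 1):10) {
      keep <- cm[, c1] != "-" & cm[, c2] != "-"
      if (sum(keep) >= 2)
        expect_gte(protlora:::column_pair_mi(cm[keep, c1], cm[keep, c2]),
                   -1e-12)
    }
  }
})
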