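test_that("FASTA round trip preserves ids, groups and sequences", {
  gen <- small_families(n_groups = 4, members = 6, seed = 8)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(gen$data, path)
  back <- read_fasta(path)
  expect_identical(names(back$records), names(gen$data$records))
  expect_identical(vapply(back$records, `[[`, "", "sequence"),
                   vapply(gen$data$records, `[[`, "", "sequence"))
  expect_identical(back$groups, gen$data$groups)
})

test_that("FASTA parsing reports malformed records and supports sidecar TSV", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">seq1|VOG1", "ACDEF", ">seq2", "GHIKL"), path)
  expect_error(read_fasta(path), "record 2 \\('seq2'\\)")
  sidecar <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tgroup", "seq1\tVOG9", "seq2\tVOG9"), sidecar)
  ds <- read_fasta(path, groups_tsv = sidecar)
  expect_equal(ds$records$seq2$group_id, "VOG9")
  # duplicate ids rejected
  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a|G1", "ACD", ">a|G1", "ACD"), dup)
  expect_error(read_fasta(dup), "duplicate")
  # hand-written 3-record file parses into one group
  p3 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x|VOG1", "AC", ">y|VOG1", "AD", ">z|VOG1", "AE"), p3)
  d3 <- read_fasta(p3)
  expect_length(d3$records, 3L)
  expect_length(d3$groups, 1L)
})

test_that("group filter keeps exactly the strictly larger groups", {
  mk <- function(sizes) {
    recs <- list()
    for (g in seq_along(sizes)) for (j in seq_len(sizes[g]))
      recs[[length(recs) + 1L]] <- protein_record(
        sprintf("g%d_s%d", g, j), random_sequence(10), paste0("G", g))
    ortholog_group_set(recs)
  }
  set.seed(2)
  d <- mk(c(10, 11, 5))
  f <- filter_groups(d, 10)
  expect_identical(names(f$groups), "G2")
  expect_equal(attr(f, "n_dropped"), 15L)
  # identity when every group qualifies
  d2 <- mk(c(11, 11))
  expect_identical(filter_groups(d2, 10)$groups, d2$groups)
  # recount over random sizes
  sizes <- sample(5:20, 8, replace = TRUE)
  d3 <- mk(sizes)
  f3 <- filter_groups(d3, 10)
  expect_equal(length(f3$records), sum(sizes[sizes > 10]))
})

test_that("stratified split covers every group at the rounded fraction", {
  gen <- small_families(n_groups = 6, members = 20, seed = 4)
  sp <- stratified_split(gen$data, 0.1, seed = 3)
  expect_length(sp$test_ids, 6 * 2)  # round(0.1 * 20) = 2 per group
  expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
  expect_setequal(c(sp$train_ids, sp$test_ids), names(gen$data$records))
  # max(1, .) rule for small groups
  gen10 <- small_families(n_groups = 1, members = 10, seed = 4)
  sp10 <- stratified_split(gen10$data, 0.1, seed = 1)
  expect_length(sp10$test_ids, 1L)
  expect_length(sp10$train_ids, 9L)
  # per-group audit over random group sizes
  set.seed(9)
  recs <- list()
  sizes <- sample(2:15, 10, replace = TRUE)
  for (g in seq_along(sizes)) for (j in seq_len(sizes[g]))
    recs[[length(recs) + 1L]] <- protein_record(
      sprintf("r%d_%d", g, j), random_sequence(8), paste0("G", g))
  d <- ortholog_group_set(recs)
  sp2 <- stratified_split(d, 0.1, seed = 8)
  for (g in names(d$groups)) {
    n_te <- sum(sp2$test_ids %in% d$groups[[g]])
    expect_equal(n_te, max(1L, round(0.1 * sizes[as.integer(sub("G", "", g))])))
  }
  # groups of size 1 cannot be stratified
  d1 <- ortholog_group_set(list(
    protein_record("a", "ACD", "G1"), protein_record("b", "ACD", "G1"),
    protein_record("c", "ACD", "G2")))
  expect_error(stratified_split(d1), "size 1")
})

test_that("generator honors rates, determinism and ground-truth alignments", {
  # zero substitution, zero indels: members identical to the ancestor
  g0 <- generate_families(synthetic_family_config(
    n_groups = 2, members_per_group = 5, substitution_rate = 0,
    enforce_nonconserved = FALSE, seed = 3))
  for (f in g0$families)
    expect_length(unique(unname(f$rows)), 1L)
  # determinism
  cfg <- synthetic_family_config(n_groups = 3, members_per_group = 6,
                                 indel_rate = 0.05, seed = 17)
  expect_identical(generate_families(cfg), generate_families(cfg))
  # rows strip-gap back to the records' sequences; conserved truth exact
  gen <- generate_families(cfg)
  for (f in gen$families) {
    expect_identical(unname(family_sequences(f)),
                     unname(vapply(names(f$rows), function(id)
                       gen$data$records[[id]]$sequence, "")))
    expect_identical(sort(detect_conserved_columns(f)),
                     sort(as.integer(f$truth_conserved_columns)))
  }
  # filter + split conserve the total sequence count
  big <- generate_families(synthetic_family_config(
    n_groups = 4, members_per_group = 12, seed = 2))
  fl <- filter_groups(big$data, 10)
  sp <- stratified_split(fl, 0.1, seed = 1)
  expect_equal(attr(fl, "n_dropped") + length(sp$train_ids) +
                 length(sp$test_ids), length(big$data$records))
})

test_that("triplet sampler respects group provenance and covers its support", {
  gen <- small_families(n_groups = 4, members = 5, seed = 19)
  tp <- sample_triplets(gen$data, 1000, seed = 2)
  g_of <- vapply(gen$data$records, `[[`, "", "group_id")
  expect_true(all(g_of[tp$anchor] == g_of[tp$positive]))
  expect_true(all(tp$anchor != tp$positive))
  expect_true(all(g_of[tp$anchor] != g_of[tp$negative]))
  # identical seeds give identical streams
  expect_identical(tp, sample_triplets(gen$data, 1000, seed = 2))
  # 2 groups of 2: all 8 valid triplet configurations are reachable
  recs <- list(protein_record("a1", "ACDE", "G1"),
               protein_record("a2", "ACDF", "G1"),
               protein_record("b1", "GHIK", "G2"),
               protein_record("b2", "GHIL", "G2"))
  d2 <- ortholog_group_set(recs)
  tp2 <- sample_triplets(d2, 5000, seed = 1)
  expect_equal(nrow(unique(tp2)), 8L)
  # a single group cannot be sampled
  d1 <- ortholog_group_set(recs[1:2])
  expect_error(sample_triplets(d1, 5, seed = 1), "at least 2")
})
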