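test_that("masking selects the rounded fraction of residue positions", {
  v <- aa_vocabulary()
  toks <- tokenize(random_sequence(100), v)
  mb <- apply_masking(toks, v, select_frac = 0.15, seed = 5)
  expect_length(mb$selected_positions, 15L)
  expect_false(any(duplicated(mb$selected_positions)))
  expect_true(all(toks[mb$selected_positions] %in% v$residue_ids))
  # length-1 sequences still select one position
  mb1 <- apply_masking(tokenize("A", v), v, select_frac = 0.15, seed = 1)
  expect_length(mb1$selected_positions, 1L)
  # specials are never selected
  vb <- aa_vocabulary(use_bos_eos = TRUE)
  tb <- tokenize(random_sequence(40), vb)
  mbb <- apply_masking(tb, vb, seed = 2)
  expect_false(any(mbb$selected_positions %in% c(1L, length(tb))))
})

test_that("mask-token substitution follows the masking probability", {
  v <- aa_vocabulary()
  toks <- tokenize(random_sequence(200), v)
  mb <- apply_masking(toks, v, mask_token_prob = 1.0, seed = 3)
  expect_true(all(mb$input_tokens[mb$selected_positions] == v$mask_id))
  expect_identical(mb$original_tokens, toks[mb$selected_positions])
  # binomial concentration at 0.8 over ~10,000 selected positions
  big <- tokenize(random_sequence(66667), v)
  mbb <- apply_masking(big, v, select_frac = 0.15, mask_token_prob = 0.8,
                       seed = 7)
  expect_gte(length(mbb$selected_positions), 10000L)
  expect_lt(abs(mean(mbb$masked) - 0.8), 0.02)
  # unmasked selected positions keep their original token and are scored
  kept <- mbb$selected_positions[!mbb$masked]
  expect_identical(mbb$input_tokens[kept], big[kept])
})

test_that("masked and classification losses match their closed forms", {
  # uniform logits over a 25-token vocabulary, 3 positions: 3 ln 25
  expect_equal(mlm_loss(matrix(0, 3, 25), c(1L, 5L, 25L)), 3 * log(25),
               tolerance = 1e-9)
  # probability ~1 on the true token: loss ~ 0
  sure <- matrix(-1e3, 2, 10)
  sure[cbind(1:2, c(3L, 7L))] <- 1e3
  expect_lt(mlm_loss(sure, c(3L, 7L)), 1e-9)
  # single position at probability 0.5: ln 2
  expect_equal(mlm_loss(matrix(c(1, 1), 1, 2), 1L), log(2),
               tolerance = 1e-9)
  # extreme logits stay finite (log-sum-exp stabilization)
  expect_true(is.finite(mlm_loss(matrix(c(1e8, -1e8), 1, 2), 1L)))
  # uniform classification over G = 10 groups, batch of 4: 4 ln 10
  head0 <- list(W = matrix(0, 6, 10), b = numeric(10))
  pooled <- matrix(rnorm(4 * 6), 4, 6)
  expect_equal(classification_loss(pooled, head0, c(1L, 2L, 9L, 10L)),
               4 * log(10), tolerance = 1e-9)
  # two groups with zero logit difference: ln 2 per item
  head2 <- list(W = matrix(0, 6, 2), b = numeric(2))
  expect_equal(classification_loss(pooled[1, , drop = FALSE], head2, 2L),
               log(2), tolerance = 1e-9)
  expect_error(classification_loss(pooled, head0, c(1L, 2L, 3L, 11L)),
               "label")
  # agreement with the hand-built probability table oracle
  set.seed(31)
  logits <- matrix(rnorm(5 * 8), 5, 8)
  labs <- sample(8L, 5L, replace = TRUE)
  p <- exp(logits) / rowSums(exp(logits))
  expect_equal(mlm_loss(logits, labs),
               -sum(log(p[cbind(1:5, labs)])), tolerance = 1e-9)
})

test_that("hybrid pair loss handles targets, modes and edge cases", {
  u <- c(1, 0, 0); w <- c(0, 1, 0)
  # identical vectors at target 1: zero in both modes
  expect_equal(hybrid_pair_loss(u, u, 1, 0.3), 0)
  expect_equal(hybrid_pair_loss(u, u, 1, 0.3, mode = "vector-mse"), 0)
  # orthogonal unit vectors, target 1, alpha 1: |1 - 0| = 1
  expect_equal(hybrid_pair_loss(u, w, 1, 1), 1)
  # identical unit vectors scored as a negative at alpha .5: .5 + .5 = 1
  expect_equal(hybrid_pair_loss(u, u, 0, 0.5), 1.0)
  expect_error(hybrid_pair_loss(u, w, 0, 0.5, mode = "vector-mse"),
               "positive pairs")
  expect_error(hybrid_pair_loss(u, 0 * u, 1, 0.5), "zero")
  expect_error(hybrid_pair_loss(u, w, 0.5, 0.5), "0 or 1")
})

test_that("triplet loss composes pair losses and is monotone in the negative cosine", {
  a <- c(1, 0); p <- c(1, 0); n <- c(0, 1)
  expect_equal(triplet_loss(a, p, n, 0.5), 0)
  expect_equal(triplet_loss(a, a, a, 0.5), 1.0)
  # rotating the negative from parallel to orthogonal strictly lowers loss
  angles <- seq(0, pi / 2, length.out = 10)
  losses <- vapply(angles, function(t)
    triplet_loss(a, p, c(cos(t), sin(t)), 0.5), numeric(1))
  expect_true(all(diff(losses) < 0))
})
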