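test_that("zero-initialized adapters leave the forward pass bitwise unchanged", {
  enc <- tiny_encoder(seed = 8)
  ad <- inject_lora(enc, lora_config(rank_r = 4, init_seed = 1))
  set.seed(3)
  for (k in 1:10) {
    toks <- tokenize(random_sequence(sample(5:40, 1)), aa_vocabulary())
    expect_identical(encoder_forward(ad, toks)$hidden,
                     encoder_forward(enc, toks)$hidden)
  }
})

test_that("merging reproduces hand-computed weights and the adapted forward", {
  # explicit small-matrix check of W' = W + (alpha/r) t(A) t(B)
  enc <- tiny_encoder(seed = 2, d = 4, layers = 1, heads = 1, ff = 8)
  ad <- inject_lora(enc, lora_config(rank_r = 2, scaling_alpha = 6,
                                     init_seed = 4))
  set.seed(9)
  A <- matrix(rnorm(2 * 4), 2, 4); B <- matrix(rnorm(4 * 2), 4, 2)
  ad$factors[[1]]$query$A <- A
  ad$factors[[1]]$query$B <- B
  merged <- merge_lora(ad)
  expect_equal(merged$params$layers[[1]]$Wq,
               enc$params$layers[[1]]$Wq + (6 / 2) * t(A) %*% t(B),
               tolerance = 1e-12)
  # merge at initialization is the identity on weights
  ad0 <- inject_lora(enc, lora_config(rank_r = 2, init_seed = 4))
  expect_identical(merge_lora(ad0)$params, enc$params)
  # merged and adapted forwards agree on random sequences
  ad2 <- randomize_factors(inject_lora(tiny_encoder(seed = 6),
                                       lora_config(rank_r = 4)), seed = 5)
  m2 <- merge_lora(ad2)
  set.seed(11)
  for (k in 1:20) {
    toks <- tokenize(random_sequence(sample(5:40, 1)), aa_vocabulary())
    h1 <- encoder_forward(ad2, toks)$hidden
    h2 <- encoder_forward(m2, toks)$hidden
    expect_lt(max(abs(h1 - h2) / (abs(h1) + 1e-9)), 1e-5)
  }
})

test_that("trainable parameter accounting is exact", {
  enc <- build_reference_encoder(encoder_config(
    embedding_dim = 64, num_layers = 2, num_heads = 4,
    feedforward_dim = 96, seed = 1))
  ad <- inject_lora(enc, lora_config(rank_r = 8))
  expect_identical(lora_parameter_count(ad), 3 * 2 * 8 * (64 + 64))
  ad_q <- inject_lora(enc, lora_config(rank_r = 8,
                                       target_projections = "query"))
  expect_identical(lora_parameter_count(ad_q), 2 * 8 * (64 + 64))
})

test_that("invalid ranks and empty target sets are rejected", {
  enc <- tiny_encoder()
  expect_error(inject_lora(enc, lora_config(rank_r = 16)), "invalid rank")
  expect_error(lora_config(target_projections = character(0)))
})

test_that("a training step moves adapters but never the frozen base", {
  gen <- small_families(n_groups = 3, members = 4, seed = 21)
  enc <- tiny_encoder(seed = 1)
  ad <- inject_lora(enc, lora_config(rank_r = 4, init_seed = 2))
  fit <- train(ad, gen$data,
               train_config("CON", learning_rate = 1e-3, epochs = 1,
                            max_steps = 2, batch_size = 2, seed = 1))
  expect_identical(fit$encoder$base, ad$base)  # freeze guarantee
  moved <- any(vapply(seq_along(ad$factors), function(l)
    any(vapply(names(ad$factors[[l]]), function(tg)
      max(abs(fit$encoder$factors[[l]][[tg]]$B -
                ad$factors[[l]][[tg]]$B)) > 0, logical(1))), logical(1)))
  expect_true(moved)
})
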