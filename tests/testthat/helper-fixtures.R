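# Shared desk-scale fixtures, built in code once per test run.

tiny_encoder <- function(seed = 1L, d = 16L, layers = 2L, heads = 4L,
                         ff = 24L, max_len = 96L, vocab = aa_vocabulary()) {
  build_reference_encoder(encoder_config(
    embedding_dim = d, num_layers = layers, num_heads = heads,
    max_sequence_length = max_len, feedforward_dim = ff, seed = seed,
    vocab = vocab))
}

random_sequence <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

small_families <- function(n_groups = 5L, members = 8L, seed = 11L, ...) {
  generate_families(synthetic_family_config(
    n_groups = n_groups, members_per_group = members, seed = seed, ...))
}

# randomize nonzero LoRA factors so adapter effects are visible
randomize_factors <- function(adapted, sd = 0.05, seed = 1L) {
  set.seed(seed)
  for (l in seq_along(adapted$factors)) {
    for (tg in names(adapted$factors[[l]])) {
      f <- adapted$factors[[l]][[tg]]
      adapted$factors[[l]][[tg]]$A <- matrix(
        rnorm(length(f$A), sd = sd), nrow(f$A), ncol(f$A))
      adapted$factors[[l]][[tg]]$B <- matrix(
        rnorm(length(f$B), sd = sd), nrow(f$B), ncol(f$B))
    }
  }
  adapted
}

# brute-force mean silhouette (explicit loops over the definition)
brute_silhouette <- function(X, labels) {
  keep <- labels != -1L
  X <- X[keep, , drop = FALSE]
  lb <- labels[keep]
  if (length(unique(lb)) < 2L) return(NA_real_)
  n <- nrow(X)
  ed <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(lb == lb[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) ed(i, j), numeric(1)))
    b <- Inf
    for (cl in setdiff(unique(lb), lb[i])) {
      oth <- which(lb == cl)
      b <- min(b, mean(vapply(oth, function(j) ed(i, j), numeric(1))))
    }
    s[i] <- if (a == b) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# exhaustive longest strictly-monotone chain over candidate matches
brute_longest_chain <- function(cand) {
  k <- nrow(cand)
  if (k == 0L) return(0L)
  best <- 0L
  for (mask in seq_len(2^k) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0L)
    if (length(idx) <= best) next
    sub <- cand[idx, , drop = FALSE]
    sub <- sub[order(sub[, 1L]), , drop = FALSE]
    ok <- all(diff(sub[, 1L]) > 0L) && all(diff(sub[, 2L]) > 0L)
    if (ok) best <- length(idx)
  }
  best
}
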