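#' Configuration for the reference per-residue encoder
#'
#' Shape and seeding parameters for the compact pre-norm transformer used as
#' a desk-scale encoder. The contract is the one large protein language
#' models satisfy: a token list of length L maps to an L x embedding_dim
#' matrix of residue vectors plus an L x vocabulary logit matrix.
#'
#' @param embedding_dim model width d; must be divisible by `num_heads`.
#' @param num_layers number of transformer blocks.
#' @param num_heads attention heads per block.
#' @param max_sequence_length hard token-length limit; longer inputs error.
#' @param feedforward_dim width of the position-wise feed-forward layer.
#' @param seed integer seed controlling weight initialization.
#' @param vocab an [aa_vocabulary()] (determines logit width).
#' @return object of class `encoder_config`.
#' @export
encoder_config <- function(embedding_dim = 32L, num_layers = 2L,
                           num_heads = 4L, max_sequence_length = 512L,
                           feedforward_dim = 64L, seed = 1L,
                           vocab = aa_vocabulary()) {
  stopifnot(embedding_dim >= 1, num_layers >= 1, num_heads >= 1,
            feedforward_dim >= 1)
  if (embedding_dim %% num_heads != 0L)
    stop("embedding_dim must be divisible by num_heads")
  if (max_sequence_length < 2L) stop("max_sequence_length must be >= 2")
  structure(list(embedding_dim = as.integer(embedding_dim),
                 num_layers = as.integer(num_layers),
                 num_heads = as.integer(num_heads),
                 max_sequence_length = as.integer(max_sequence_length),
                 feedforward_dim = as.integer(feedforward_dim),
                 seed = as.integer(seed), vocab = vocab),
            class = "encoder_config")
}

rand_mat <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, sd = sd), nrow = nr, ncol = nc)
}

#' Build the reference encoder
#'
#' Deterministically initializes a pre-norm transformer with learned
#' positional embeddings, multi-head self-attention (separate Wq/Wk/Wv/Wo
#' projections, the q/k/v matrices being the low-rank-adaptation targets), a
#' ReLU feed-forward block, a final layer norm whose output is the
#' "last hidden layer" residue representation, and a linear vocabulary head
#' for the masked-token objective.
#'
#' @param config an [encoder_config()].
#' @return object of class `plm_encoder` (list with `config` and `params`).
#' @export
build_reference_encoder <- function(config) {
  stopifnot(inherits(config, "encoder_config"))
  d <- config$embedding_dim; ff <- config$feedforward_dim
  V <- config$vocab$size
  params <- with_seed(config$seed, {
    layers <- lapply(seq_len(config$num_layers), function(l) {
      list(Wq = rand_mat(d, d), Wk = rand_mat(d, d), Wv = rand_mat(d, d),
           Wo = rand_mat(d, d),
           W1 = rand_mat(d, ff), b1 = numeric(ff),
           W2 = rand_mat(ff, d), b2 = numeric(d),
           ln1_g = rep(1, d), ln1_b = numeric(d),
           ln2_g = rep(1, d), ln2_b = numeric(d))
    })
    list(tok_emb = rand_mat(V, d),
         pos_emb = rand_mat(config$max_sequence_length, d),
         layers = layers,
         lnf_g = rep(1, d), lnf_b = numeric(d),
         Wlm = rand_mat(d, V), blm = numeric(V))
  })
  structure(list(config = config, params = params), class = "plm_encoder")
}

# Layer norm over rows; returns values needed by the backward pass.
ln_forward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv_sd <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv_sd
  list(y = sweep(sweep(xhat, 2L, g, `*`), 2L, b, `+`),
       xhat = xhat, inv_sd = inv_sd)
}

ln_backward <- function(dy, g, xhat, inv_sd) {
  dxhat <- sweep(dy, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  inv_sd * (dxhat - m1 - xhat * m2)
}

head_idx <- function(h, dh) ((h - 1L) * dh + 1L):(h * dh)

# Shared forward core. qkv_eff: per-layer list(Wq, Wk, Wv) effective
# (base + any low-rank delta) projection weights.
encoder_forward_core <- function(params, config, tokens, qkv_eff,
                                 with_cache = FALSE) {
  L <- length(tokens)
  if (L < 1L) stop("empty token list")
  if (L > config$max_sequence_length)
    stop(sprintf("token length %d exceeds max_sequence_length %d",
                 L, config$max_sequence_length))
  if (any(tokens < 1L | tokens > config$vocab$size))
    stop("token id out of vocabulary range")
  nh <- config$num_heads
  dh <- config$embedding_dim / nh
  x <- params$tok_emb[tokens, , drop = FALSE] +
    params$pos_emb[seq_len(L), , drop = FALSE]
  caches <- if (with_cache) vector("list", config$num_layers)
  for (l in seq_len(config$num_layers)) {
    ly <- params$layers[[l]]; ef <- qkv_eff[[l]]
    n1c <- ln_forward(x, ly$ln1_g, ly$ln1_b)
    n1 <- n1c$y
    Q <- n1 %*% ef$Wq; K <- n1 %*% ef$Wk; Vm <- n1 %*% ef$Wv
    O <- matrix(0, L, config$embedding_dim)
    Plist <- if (with_cache) vector("list", nh)
    for (h in seq_len(nh)) {
      idx <- head_idx(h, dh)
      S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dh)
      P <- row_softmax(S)
      O[, idx] <- P %*% Vm[, idx, drop = FALSE]
      if (with_cache) Plist[[h]] <- P
    }
    attn <- O %*% ly$Wo
    x2 <- x + attn
    n2c <- ln_forward(x2, ly$ln2_g, ly$ln2_b)
    F1 <- sweep(n2c$y %*% ly$W1, 2L, ly$b1, `+`)
    R <- pmax(F1, 0)
    x3 <- x2 + sweep(R %*% ly$W2, 2L, ly$b2, `+`)
    if (with_cache) {
      caches[[l]] <- list(n1c = n1c, n1 = n1, Q = Q, K = K, V = Vm,
                          P = Plist, O = O, x2 = x2, n2c = n2c,
                          relu_mask = F1 > 0, R = R)
    }
    x <- x3
  }
  fc <- ln_forward(x, params$lnf_g, params$lnf_b)
  hidden <- fc$y
  logits <- sweep(hidden %*% params$Wlm, 2L, params$blm, `+`)
  out <- list(hidden = hidden, logits = logits)
  if (with_cache) {
    out$cache <- list(tokens = tokens, layers = caches, x_final = x,
                      final_ln = fc, qkv_eff = qkv_eff)
  }
  out
}

#' Run the encoder forward
#'
#' Maps a token id vector of length L to an L x d residue-embedding matrix
#' (final layer-norm output) and an L x vocabulary logit matrix. Works for
#' both plain and LoRA-adapted encoders; for adapted encoders the low-rank
#' deltas are applied to the q/k/v projections on the fly.
#'
#' @param encoder a `plm_encoder` or `plm_adapted` object.
#' @param tokens integer token ids (see [tokenize()]).
#' @param with_cache keep intermediate activations (needed for gradients).
#' @return list with `hidden`, `logits` and optionally `cache`.
#' @export
encoder_forward <- function(encoder, tokens, with_cache = FALSE) {
  UseMethod("encoder_forward")
}

#' @export
encoder_forward.plm_encoder <- function(encoder, tokens, with_cache = FALSE) {
  qkv <- lapply(encoder$params$layers, function(ly)
    list(Wq = ly$Wq, Wk = ly$Wk, Wv = ly$Wv))
  encoder_forward_core(encoder$params, encoder$config, tokens, qkv, with_cache)
}
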