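# Reverse-mode gradients for the reference encoder, restricted to the
# trainable parameter set: LoRA factor pairs on the q/k/v projections plus
# the vocabulary head. Base weights are frozen, so backpropagation stops at
# the first layer's input; the chain rule through layer norm, softmax
# attention and the ReLU feed-forward block is written out explicitly.

# d_hidden: L x d gradient w.r.t. the final hidden matrix (may be NULL);
# d_logits: L x V gradient w.r.t. the vocabulary logits (may be NULL).
# Returns gradients shaped like adapted$factors plus (when d_logits is
# given) Wlm/blm head gradients.
encoder_backward <- function(adapted, cache, d_hidden = NULL,
                             d_logits = NULL) {
  stopifnot(inherits(adapted, "plm_adapted"))
  params <- adapted$base$params
  config <- adapted$base$config
  nh <- config$num_heads
  dh <- config$embedding_dim / nh
  s <- lora_scale(adapted$lora)

  grads <- list(factors = lapply(adapted$factors, function(fl)
    lapply(fl, function(f) list(A = 0 * f$A, B = 0 * f$B))))

  L <- length(cache$tokens)
  d <- config$embedding_dim
  if (is.null(d_hidden)) d_hidden <- matrix(0, L, d)
  if (!is.null(d_logits)) {
    grads$Wlm <- crossprod(cache$final_ln$y, d_logits)
    grads$blm <- colSums(d_logits)
    d_hidden <- d_hidden + d_logits %*% t(params$Wlm)
  }

  dx <- ln_backward(d_hidden, params$lnf_g, cache$final_ln$xhat,
                    cache$final_ln$inv_sd)

  for (l in rev(seq_len(config$num_layers))) {
    ly <- params$layers[[l]]
    cl <- cache$layers[[l]]
    ef <- cache$qkv_eff[[l]]
    # feed-forward block: x3 = x2 + relu(n2 W1 + b1) W2 + b2
    dR <- dx %*% t(ly$W2)
    dF1 <- dR * cl$relu_mask
    dn2 <- dF1 %*% t(ly$W1)
    dx2 <- dx + ln_backward(dn2, ly$ln2_g, cl$n2c$xhat, cl$n2c$inv_sd)
    # attention block: x2 = x + (concat_h P_h V_h) Wo
    dO <- dx2 %*% t(ly$Wo)
    dQ <- matrix(0, L, d); dK <- matrix(0, L, d); dV <- matrix(0, L, d)
    for (h in seq_len(nh)) {
      idx <- head_idx(h, dh)
      P <- cl$P[[h]]
      dOh <- dO[, idx, drop = FALSE]
      dV[, idx] <- crossprod(P, dOh)
      dP <- tcrossprod(dOh, cl$V[, idx, drop = FALSE])
      dS <- P * (dP - rowSums(dP * P))
      dQ[, idx] <- dS %*% cl$K[, idx, drop = FALSE] / sqrt(dh)
      dK[, idx] <- crossprod(dS, cl$Q[, idx, drop = FALSE]) / sqrt(dh)
    }
    dWeff <- list(Wq = crossprod(cl$n1, dQ),
                  Wk = crossprod(cl$n1, dK),
                  Wv = crossprod(cl$n1, dV))
    for (tg in names(adapted$factors[[l]])) {
      f <- adapted$factors[[l]][[tg]]
      dW <- dWeff[[proj_field[[tg]]]]
      grads$factors[[l]][[tg]]$A <- s * t(dW %*% f$B)
      grads$factors[[l]][[tg]]$B <- s * t(f$A %*% dW)
    }
    dn1 <- dQ %*% t(ef$Wq) + dK %*% t(ef$Wk) + dV %*% t(ef$Wv)
    dx <- dx2 + ln_backward(dn1, ly$ln1_g, cl$n1c$xhat, cl$n1c$inv_sd)
  }
  grads
}

# elementwise combination of two gradient pytrees (nested lists of arrays)
grad_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- grad_map2(a[[nm]], b[[nm]], f)
    out
  } else f(a, b)
}

grad_map1 <- function(a, f) {
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- grad_map1(a[[nm]], f)
    a
  } else f(a)
}
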