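#' Mask residue positions for the masked-token objective
#'
#' Selects `round(select_frac * L)` distinct residue positions uniformly at
#' random (at least one; special tokens are never selected) and replaces
#' each selected token by the mask token with probability
#' `mask_token_prob`, leaving it unchanged otherwise. All selected
#' positions are scored by the loss regardless of whether the mask token
#' was substituted. The defaults mirror common practice for fine-tuning
#' bidirectional encoders: 15% of tokens selected, 80% masking probability.
#' `round()` is base R's round-half-to-even.
#'
#' @param tokens integer token ids for one sequence.
#' @param vocab the [aa_vocabulary()] the tokens come from (must carry a
#'   mask token).
#' @param select_frac fraction of residue positions to select, in (0,1).
#' @param mask_token_prob probability of substituting the mask token at a
#'   selected position, in (0,1].
#' @param seed integer seed; the selection is reproducible.
#' @return list of class `masked_batch`: `input_tokens`,
#'   `selected_positions`, `original_tokens`, `masked` (logical per
#'   selected position).
#' @export
apply_masking <- function(tokens, vocab, select_frac = 0.15,
                          mask_token_prob = 0.8, seed = 1L) {
  if (length(tokens) == 0L) stop("tokens is empty")
  if (is.na(vocab$mask_id)) stop("vocabulary has no mask token")
  stop_if_not_scalar_prob(select_frac, "select_frac", open_left = TRUE)
  stop_if_not_scalar_prob(mask_token_prob, "mask_token_prob",
                          open_left = TRUE)
  if (select_frac >= 1) stop("select_frac must be < 1")
  residue_pos <- which(tokens %in% vocab$residue_ids)
  if (length(residue_pos) == 0L) stop("no residue positions to mask")
  n_sel <- max(1L, as.integer(round(select_frac * length(residue_pos))))
  with_seed(seed, {
    sel <- sort(sample(residue_pos, n_sel))
    masked <- stats::runif(n_sel) < mask_token_prob
    input <- tokens
    input[sel[masked]] <- vocab$mask_id
    structure(list(input_tokens = input, selected_positions = sel,
                   original_tokens = tokens[sel], masked = masked),
              class = "masked_batch")
  })
}

#' Masked-token cross-entropy loss
#'
#' The negative sum over scored positions of the log softmax probability of
#' the true token: `-sum_i log P(true_token_i | context)` (natural log).
#' Log-sum-exp stabilized, so extreme logits do not produce NaN.
#'
#' @param logits matrix with one row per scored position, one column per
#'   vocabulary token.
#' @param original_tokens integer true token id per row.
#' @param reduction "sum" (as in the loss definition) or "mean" per
#'   position; the mode used is recorded by the training loop.
#' @return nonnegative scalar loss.
#' @export
mlm_loss <- function(logits, original_tokens, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  logits <- rbind(logits)
  if (nrow(logits) != length(original_tokens))
    stop("logit row count must equal the number of scored positions")
  lse <- row_logsumexp(logits)
  ll <- logits[cbind(seq_len(nrow(logits)), original_tokens)] - lse
  loss <- -sum(ll)
  if (reduction == "mean") loss <- loss / nrow(logits)
  loss
}

#' Linear classification head
#'
#' A single affine map from the pooled embedding to one logit per
#' orthologous group.
#'
#' @param embedding_dim input width d.
#' @param n_groups number of orthologous groups G.
#' @param seed seed for the (small normal) weight initialization.
#' @return list with `W` (d x G) and `b` (G).
#' @export
classification_head <- function(embedding_dim, n_groups, seed = 1L) {
  with_seed(seed, list(W = rand_mat(embedding_dim, n_groups),
                       b = numeric(n_groups)))
}

#' Orthologous-group classification loss
#'
#' Cross-entropy of the softmaxed head logits against integer group
#' labels: `-sum_i log P(true_group_i | x_i)` over the batch.
#'
#' @param pooled matrix of pooled sequence embeddings, one row per
#'   sequence.
#' @param head a [classification_head()] whose output width equals the
#'   number of groups.
#' @param labels integer labels in `1..G`, one per row of `pooled`.
#' @param reduction "sum" or "mean" over the batch.
#' @return nonnegative scalar loss.
#' @export
classification_loss <- function(pooled, head, labels,
                                reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  pooled <- rbind(pooled)
  G <- ncol(head$W)
  if (any(labels < 1L | labels > G))
    stop(sprintf("label outside 1..%d", G))
  if (nrow(pooled) != length(labels))
    stop("one label per pooled embedding required")
  logits <- sweep(pooled %*% head$W, 2L, head$b, `+`)
  mlm_loss(logits, labels, reduction = reduction)
}

#' Hybrid cosine / mean-squared-error pair loss
#'
#' The contrastive objective scores an embedding pair against a target
#' similarity t in `{0, 1}` (1 for anchor-positive, 0 for
#' anchor-negative). The default "similarity-target" mode is
#' `alpha * |t - cos(A,B)| + (1 - alpha) * (cos(A,B) - t)^2`,
#' which pulls positives toward cosine 1 and pushes negatives toward
#' cosine 0. The alternative "vector-mse" mode applies the literal hybrid
#' formula `alpha * (1 - cos) + (1 - alpha) * mean((A - B)^2)` and is only
#' meaningful for positive pairs (t = 1), since elementwise MSE would pull
#' a negative pair together.
#'
#' @param a,b nonzero numeric vectors of equal length.
#' @param target_sim target cosine similarity, 0 or 1.
#' @param alpha_weight weight in `[0,1]` balancing the cosine and MSE
#'   terms (default 0.5).
#' @param mode "similarity-target" (default) or "vector-mse".
#' @return nonnegative scalar loss.
#' @export
hybrid_pair_loss <- function(a, b, target_sim, alpha_weight = 0.5,
                             mode = c("similarity-target", "vector-mse")) {
  mode <- match.arg(mode)
  if (alpha_weight < 0 || alpha_weight > 1)
    stop("alpha_weight must be in [0, 1]")
  if (!target_sim %in% c(0, 1)) stop("target_sim must be 0 or 1")
  cs <- cosine(a, b)
  if (mode == "vector-mse") {
    if (target_sim != 1)
      stop("vector-mse mode is only valid for positive pairs (target_sim = 1)")
    if (length(a) != length(b)) stop("vectors must have equal length")
    return(alpha_weight * (1 - cs) +
             (1 - alpha_weight) * mean((a - b)^2))
  }
  alpha_weight * abs(target_sim - cs) +
    (1 - alpha_weight) * (cs - target_sim)^2
}

#' Contrastive triplet loss
#'
#' Sum of the hybrid pair loss of the anchor-positive pair at target
#' similarity 1 and of the anchor-negative pair at target similarity 0.
#'
#' @param anchor,positive,negative nonzero numeric vectors of equal
#'   length.
#' @param alpha_weight weight in `[0,1]` (default 0.5).
#' @return nonnegative scalar loss.
#' @export
triplet_loss <- function(anchor, positive, negative, alpha_weight = 0.5) {
  hybrid_pair_loss(anchor, positive, 1, alpha_weight) +
    hybrid_pair_loss(anchor, negative, 0, alpha_weight)
}
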