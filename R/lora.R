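#' Low-rank adaptation configuration
#'
#' LoRA freezes the base weights W and learns a rank-r update so that the
#' effective projection is W + (alpha/r) * B A (for column-vector inputs);
#' r = 8 on the query/key/value attention projections is the setting used
#' for fine-tuning billion-parameter protein language models, and is the
#' default here.
#'
#' @param rank_r LoRA rank (default 8); must be smaller than the projection
#'   dimension it is attached to.
#' @param scaling_alpha scaling numerator; the applied multiplier is
#'   `scaling_alpha / rank_r`. Defaults to `rank_r` (net factor 1).
#' @param target_projections nonempty subset of c("query","key","value").
#' @param init_seed seed for the random A factors (B starts at zero).
#' @return object of class `lora_config`.
#' @export
lora_config <- function(rank_r = 8L, scaling_alpha = rank_r,
                        target_projections = c("query", "key", "value"),
                        init_seed = 1L) {
  stopifnot(rank_r >= 1, scaling_alpha > 0)
  target_projections <- match.arg(target_projections,
                                  c("query", "key", "value"),
                                  several.ok = TRUE)
  if (length(target_projections) == 0L) stop("target_projections is empty")
  structure(list(rank_r = as.integer(rank_r),
                 scaling_alpha = as.numeric(scaling_alpha),
                 target_projections = unique(target_projections),
                 init_seed = as.integer(init_seed)),
            class = "lora_config")
}

proj_field <- c(query = "Wq", key = "Wk", value = "Wv")

#' Attach LoRA adapters to an encoder
#'
#' Adds a rank-r factor pair per targeted attention projection in every
#' layer: A (r x d_in) drawn from a small seeded normal, B (d_out x r)
#' initialized to zero, so the adapted forward pass equals the base forward
#' pass exactly at initialization. Base weights are never modified; training
#' updates only the factors (and any task head).
#'
#' @param encoder a `plm_encoder`.
#' @param lora a [lora_config()].
#' @return object of class `plm_adapted`: list with `base`, `lora`
#'   (config) and `factors` (per layer, per target, `A` and `B`).
#' @export
inject_lora <- function(encoder, lora) {
  stopifnot(inherits(encoder, "plm_encoder"), inherits(lora, "lora_config"))
  d <- encoder$config$embedding_dim
  if (lora$rank_r >= d)
    stop(sprintf("invalid rank: rank_r (%d) must be < projection dim (%d)",
                 lora$rank_r, d))
  factors <- with_seed(lora$init_seed, {
    lapply(seq_len(encoder$config$num_layers), function(l) {
      fl <- list()
      for (tg in lora$target_projections) {
        fl[[tg]] <- list(A = rand_mat(lora$rank_r, d, sd = 0.02),
                         B = matrix(0, d, lora$rank_r))
      }
      fl
    })
  })
  structure(list(base = encoder, lora = lora, factors = factors),
            class = "plm_adapted")
}

lora_scale <- function(lora) lora$scaling_alpha / lora$rank_r

# Effective q/k/v projection weights (input x output orientation):
# W_eff = W + s * t(A) %*% t(B), equivalent to W + s * B A acting on
# column vectors.
adapted_qkv <- function(adapted) {
  s <- lora_scale(adapted$lora)
  lapply(seq_along(adapted$base$params$layers), function(l) {
    ly <- adapted$base$params$layers[[l]]
    ef <- list(Wq = ly$Wq, Wk = ly$Wk, Wv = ly$Wv)
    for (tg in names(adapted$factors[[l]])) {
      f <- adapted$factors[[l]][[tg]]
      ef[[proj_field[[tg]]]] <- ef[[proj_field[[tg]]]] +
        s * crossprod(f$A, t(f$B))
    }
    ef
  })
}

#' @export
encoder_forward.plm_adapted <- function(encoder, tokens, with_cache = FALSE) {
  encoder_forward_core(encoder$base$params, encoder$base$config, tokens,
                       adapted_qkv(encoder), with_cache)
}

#' Merge LoRA factors into the base weights
#'
#' Returns a plain encoder whose q/k/v projections are
#' `W + (alpha/r) * B A`; its outputs agree with the adapted forward pass to
#' numerical precision, which is how residue representations are extracted
#' after fine-tuning.
#'
#' @param adapted a `plm_adapted`.
#' @return a `plm_encoder` with merged weights.
#' @export
merge_lora <- function(adapted) {
  stopifnot(inherits(adapted, "plm_adapted"))
  merged <- adapted$base
  eff <- adapted_qkv(adapted)
  for (l in seq_along(merged$params$layers)) {
    merged$params$layers[[l]]$Wq <- eff[[l]]$Wq
    merged$params$layers[[l]]$Wk <- eff[[l]]$Wk
    merged$params$layers[[l]]$Wv <- eff[[l]]$Wv
  }
  merged
}

#' Count trainable LoRA parameters
#'
#' Exactly `sum over targeted projections of rank_r * (d_in + d_out)`;
#' task-head parameters are counted separately by the training loop.
#'
#' @param adapted a `plm_adapted`.
#' @return integer parameter count.
#' @export
lora_parameter_count <- function(adapted) {
  sum(vapply(adapted$factors, function(fl) {
    sum(vapply(fl, function(f) length(f$A) + length(f$B), numeric(1)))
  }, numeric(1)))
}

#' @export
print.plm_adapted <- function(x, ...) {
  cat(sprintf(
    "<plm_adapted> d=%d, %d layers, r=%d on {%s}, %d trainable LoRA params\n",
    x$base$config$embedding_dim, x$base$config$num_layers, x$lora$rank_r,
    paste(x$lora$target_projections, collapse = ","),
    lora_parameter_count(x)))
  invisible(x)
}

#' @export
print.plm_encoder <- function(x, ...) {
  cat(sprintf("<plm_encoder> d=%d, %d layers, %d heads, vocab %d\n",
              x$config$embedding_dim, x$config$num_layers,
              x$config$num_heads, x$config$vocab$size))
  invisible(x)
}
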