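#' Training configuration
#'
#' Settings for fine-tuning a LoRA-adapted encoder under one of the three
#' objectives: masked-token prediction (`"MLM"`), orthologous-group
#' classification (`"CLS"`), or contrastive triplet learning (`"CON"`).
#' The default learning rate 1e-9 is the setting reported for fine-tuning
#' billion-parameter encoders; on the desk-scale reference encoder a rate
#' around 1e-3 produces measurable updates and is what the examples use.
#'
#' @param objective one of "MLM", "CLS", "CON".
#' @param learning_rate Adam learning rate (default 1e-9).
#' @param epochs number of passes (default 2; typical range 2-10).
#' @param max_steps optional hard cap on optimizer steps (overrides
#'   `epochs` when smaller).
#' @param alpha_weight hybrid-loss weight in `[0,1]` (default 0.5).
#' @param select_frac fraction of residue positions scored by the masked
#'   objective (default 0.15).
#' @param mask_token_prob probability that a selected position carries the
#'   mask token (default 0.8).
#' @param batch_size sequences (or triplets) per optimizer step.
#' @param reduction "mean" (default, stable across batch sizes) or "sum"
#'   as in the loss definitions; recorded in the run manifest.
#' @param seed integer seed driving all sampling in the run.
#' @return object of class `train_config`.
#' @export
train_config <- function(objective = c("CON", "MLM", "CLS"),
                         learning_rate = 1e-9, epochs = 2L,
                         max_steps = NULL, alpha_weight = 0.5,
                         select_frac = 0.15, mask_token_prob = 0.8,
                         batch_size = 4L, reduction = c("mean", "sum"),
                         seed = 0L) {
  objective <- match.arg(objective)
  reduction <- match.arg(reduction)
  stopifnot(learning_rate >= 0, epochs >= 1, batch_size >= 1,
            alpha_weight >= 0, alpha_weight <= 1,
            select_frac > 0, select_frac < 1,
            mask_token_prob > 0, mask_token_prob <= 1)
  structure(list(objective = objective, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 max_steps = if (is.null(max_steps)) NULL
                             else as.integer(max_steps),
                 alpha_weight = alpha_weight, select_frac = select_frac,
                 mask_token_prob = mask_token_prob,
                 batch_size = as.integer(batch_size),
                 reduction = reduction, seed = as.integer(seed)),
            class = "train_config")
}

# ---- Adam ------------------------------------------------------------

adam_init <- function(params) {
  list(m = grad_map1(params, function(x) 0 * x),
       v = grad_map1(params, function(x) 0 * x), t = 0L)
}

adam_step <- function(state, params, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- grad_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- grad_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- grad_map2(state$m, state$v, function(m, v)
    lr * (m / bc1) / (sqrt(v / bc2) + eps))
  list(state = state, params = grad_map2(params, upd, `-`))
}

# ---- loss helpers ----------------------------------------------------

# cosine plus its gradients w.r.t. both vectors
cosine_with_grad <- function(u, v) {
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) stop("cosine is undefined for zero vectors")
  cs <- sum(u * v) / (nu * nv)
  list(c = cs,
       du = v / (nu * nv) - cs * u / nu^2,
       dv = u / (nu * nv) - cs * v / nv^2)
}

# d(hybrid pair loss)/d(cosine) in similarity-target mode
hybrid_loss_dcos <- function(cs, target, alpha) {
  -alpha * sign(target - cs) + 2 * (1 - alpha) * (cs - target)
}

pooled_from_forward <- function(fw, tokens, vocab) {
  keep <- tokens %in% vocab$residue_ids
  list(pooled = colMeans(fw$hidden[keep, , drop = FALSE]), keep = keep)
}

# spread a pooled-embedding gradient back over residue rows
spread_pooled_grad <- function(dpooled, keep) {
  L <- length(keep)
  dh <- matrix(0, L, length(dpooled))
  dh[keep, ] <- matrix(dpooled, sum(keep), length(dpooled), byrow = TRUE) /
    sum(keep)
  dh
}

softmax_minus_onehot <- function(logits, labels) {
  p <- row_softmax(rbind(logits))
  p[cbind(seq_along(labels), labels)] <-
    p[cbind(seq_along(labels), labels)] - 1
  p
}

#' Fine-tune a LoRA-adapted encoder
#'
#' Runs seeded minibatch optimization with Adam under the configured
#' objective. Only the LoRA factor pairs and the objective's task head are
#' updated; the base encoder weights are never touched. The per-epoch loss
#' trajectory is evaluated on a fixed (seed-derived) evaluation batch so
#' trajectories are comparable across epochs, and a held-out split, when
#' supplied, is scored the same way.
#'
#' @param adapted a `plm_adapted` encoder (see [inject_lora()]).
#' @param data an [ortholog_group_set()] of training sequences.
#' @param config a [train_config()].
#' @param test_data optional held-out [ortholog_group_set()] scored at
#'   each epoch end.
#' @param eval_cap max sequences/triplets in each evaluation batch
#'   (default 64).
#' @return object of class `plm_training`: list with `encoder` (the
#'   updated `plm_adapted`), `head` (task head or NULL), `history`
#'   (data.frame epoch/train_loss/test_loss), `step_losses`, and a
#'   `manifest` echoing configuration, seeds and parameter counts.
#' @export
train <- function(adapted, data, config, test_data = NULL, eval_cap = 64L) {
  stopifnot(inherits(adapted, "plm_adapted"),
            inherits(data, "ortholog_group_set"),
            inherits(config, "train_config"))
  if (length(data$records) == 0L) stop("empty training set")
  vocab <- adapted$base$config$vocab
  d <- adapted$base$config$embedding_dim
  obj <- config$objective
  if (obj %in% c("CLS", "CON") && length(data$groups) < 2L)
    stop(sprintf("%s objective requires at least 2 orthologous groups", obj))
  if (obj == "MLM" && is.na(vocab$mask_id))
    stop("masked objective requires a mask token in the vocabulary")

  ids <- names(data$records)
  gid_of <- vapply(data$records, `[[`, "", "group_id")
  group_names <- sort(unique(gid_of))
  labels_all <- match(gid_of, group_names)
  tokens_of <- lapply(data$records, function(r)
    tokenize(r$sequence, vocab,
             max_length = adapted$base$config$max_sequence_length))

  head <- switch(obj,
    MLM = list(W = adapted$base$params$Wlm, b = adapted$base$params$blm),
    CLS = classification_head(d, length(group_names),
                              seed = config$seed + 1L),
    CON = NULL)

  n_units <- length(ids)
  steps_per_epoch <- max(1L, ceiling(n_units / config$batch_size))
  total_steps <- steps_per_epoch * config$epochs
  if (!is.null(config$max_steps))
    total_steps <- min(total_steps, config$max_steps)
  n_epochs <- ceiling(total_steps / steps_per_epoch)

  trainable <- list(factors = adapted$factors)
  if (!is.null(head)) trainable$head <- head
  opt <- adam_init(trainable)

  mean_red <- config$reduction == "mean"

  # loss (and optionally gradients) of one batch under current parameters
  batch_pass <- function(adapted, head, batch, rng_seeds, with_grad) {
    gsum <- NULL
    loss <- 0
    n_items <- if (obj == "CON") nrow(batch) else length(batch)
    if (is.null(batch) || n_items == 0L)
      return(list(loss = NA_real_, grads = NULL))
    scl <- if (mean_red) 1 / n_items else 1
    add_grad <- function(g) {
      if (is.null(gsum)) gsum <<- g
      else gsum <<- grad_map2(gsum, g, `+`)
    }
    if (obj == "CON") {
      for (k in seq_len(n_items)) {
        trip <- batch[k, ]
        fws <- lapply(c(trip$anchor, trip$positive, trip$negative),
                      function(id) encoder_forward(adapted, tokens_of[[id]],
                                                   with_cache = with_grad))
        pk <- lapply(seq_len(3L), function(i)
          pooled_from_forward(fws[[i]],
                              tokens_of[[c(trip$anchor, trip$positive,
                                           trip$negative)[i]]], vocab))
        u <- pk[[1]]$pooled; v <- pk[[2]]$pooled; w <- pk[[3]]$pooled
        cp <- cosine_with_grad(u, v)
        cn <- cosine_with_grad(u, w)
        a <- config$alpha_weight
        loss <- loss + scl *
          (a * abs(1 - cp$c) + (1 - a) * (cp$c - 1)^2 +
           a * abs(0 - cn$c) + (1 - a) * (cn$c - 0)^2)
        if (with_grad) {
          gp <- hybrid_loss_dcos(cp$c, 1, a) * scl
          gn <- hybrid_loss_dcos(cn$c, 0, a) * scl
          dps <- list(gp * cp$du + gn * cn$du, gp * cp$dv, gn * cn$dv)
          for (i in seq_len(3L)) {
            dh <- spread_pooled_grad(dps[[i]], pk[[i]]$keep)
            g <- encoder_backward(adapted, fws[[i]]$cache, d_hidden = dh)
            add_grad(list(factors = g$factors))
          }
        }
      }
    } else if (obj == "CLS") {
      for (k in seq_len(n_items)) {
        id <- batch[k]
        fw <- encoder_forward(adapted, tokens_of[[id]],
                              with_cache = with_grad)
        pk <- pooled_from_forward(fw, tokens_of[[id]], vocab)
        logits <- drop(pk$pooled %*% head$W) + head$b
        lab <- labels_all[[match(id, ids)]]
        loss <- loss + scl * (log(sum(exp(logits - max(logits)))) +
                                max(logits) - logits[lab])
        if (with_grad) {
          dlog <- drop(softmax_minus_onehot(logits, lab)) * scl
          dW <- outer(pk$pooled, dlog)
          db <- dlog
          dpooled <- drop(head$W %*% dlog)
          dh <- spread_pooled_grad(dpooled, pk$keep)
          g <- encoder_backward(adapted, fw$cache, d_hidden = dh)
          add_grad(list(factors = g$factors, head = list(W = dW, b = db)))
        }
      }
    } else {  # MLM
      for (k in seq_len(n_items)) {
        id <- batch[k]
        toks <- tokens_of[[id]]
        mb <- apply_masking(toks, vocab, config$select_frac,
                            config$mask_token_prob, seed = rng_seeds[k])
        fw <- encoder_forward(adapted, mb$input_tokens,
                              with_cache = with_grad)
        hid_sel <- fw$hidden[mb$selected_positions, , drop = FALSE]
        logits <- sweep(hid_sel %*% head$W, 2L, head$b, `+`)
        nsel <- length(mb$selected_positions)
        iscl <- scl * (if (mean_red) 1 / nsel else 1)
        loss <- loss + iscl * mlm_loss(logits, mb$original_tokens, "sum")
        if (with_grad) {
          dlog <- softmax_minus_onehot(logits, mb$original_tokens) * iscl
          dW <- crossprod(hid_sel, dlog)
          db <- colSums(dlog)
          dh <- matrix(0, length(toks), d)
          dh[mb$selected_positions, ] <- dlog %*% t(head$W)
          g <- encoder_backward(adapted, fw$cache, d_hidden = dh)
          add_grad(list(factors = g$factors, head = list(W = dW, b = db)))
        }
      }
    }
    list(loss = loss, grads = gsum)
  }

  # fixed (seed-derived) evaluation batches, identical at every epoch end
  eval_seed <- with_seed(config$seed, sample.int(.Machine$integer.max, 1L))
  make_eval <- function(set, shift = 0L) {
    with_seed(eval_seed + shift, {
      if (obj == "CON") {
        eligible <- names(set$groups)[lengths(set$groups) >= 2L]
        pool <- unlist(set$groups[eligible], use.names = FALSE)
        if (!length(pool) || length(set$groups) < 2L) return(NULL)
        anchors <- sample(pool, min(eval_cap, length(pool)))
        g_of <- vapply(set$records, `[[`, "", "group_id")
        data.frame(
          anchor = anchors,
          positive = vapply(anchors, function(a) {
            m <- setdiff(set$groups[[g_of[[a]]]], a)
            if (length(m) == 1L) m else sample(m, 1L)
          }, ""),
          negative = vapply(anchors, function(a) {
            o <- names(set$records)[g_of != g_of[[a]]]
            if (length(o) == 1L) o else sample(o, 1L)
          }, ""))
      } else {
        sids <- names(set$records)
        sample(sids, min(eval_cap, length(sids)))
      }
    })
  }
  eval_train <- make_eval(data)
  eval_test <- NULL
  if (!is.null(test_data)) {
    eval_test <- make_eval(test_data, shift = 1L)
    for (r in test_data$records)
      if (is.null(tokens_of[[r$id]]))
        tokens_of[[r$id]] <- tokenize(
          r$sequence, vocab,
          max_length = adapted$base$config$max_sequence_length)
    labels_all <- c(labels_all, match(
      vapply(test_data$records, `[[`, "", "group_id"), group_names))
    ids <- c(ids, names(test_data$records))
  }

  step_losses <- numeric(0)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        test_loss = numeric(0))
  with_seed(config$seed, {
    invisible(sample.int(.Machine$integer.max, 1L))  # skip the eval_seed draw
    eligible <- names(data$groups)[lengths(data$groups) >= 2L]
    anchor_pool <- unlist(data$groups[eligible], use.names = FALSE)
    train_ids <- names(data$records)
    g_of <- vapply(data$records, `[[`, "", "group_id")
    step <- 0L
    for (ep in seq_len(n_epochs)) {
      n_this <- min(steps_per_epoch, total_steps - step)
      for (s in seq_len(n_this)) {
        step <- step + 1L
        if (obj == "CON") {
          if (!length(anchor_pool))
            stop("no group with >= 2 members for triplet sampling")
          anchors <- sample(anchor_pool, config$batch_size, replace = TRUE)
          batch <- data.frame(
            anchor = anchors,
            positive = vapply(anchors, function(a) {
              m <- setdiff(data$groups[[g_of[[a]]]], a)
              if (length(m) == 1L) m else sample(m, 1L)
            }, ""),
            negative = vapply(anchors, function(a) {
              o <- train_ids[g_of != g_of[[a]]]
              if (length(o) == 1L) o else sample(o, 1L)
            }, ""))
          rs <- integer(0)
        } else {
          batch <- sample(train_ids, config$batch_size, replace = TRUE)
          rs <- sample.int(.Machine$integer.max, config$batch_size)
        }
        bp <- batch_pass(adapted, head, batch, rs, with_grad = TRUE)
        step_losses[step] <- bp$loss
        if (config$learning_rate > 0 && !is.null(bp$grads)) {
          cur <- list(factors = adapted$factors)
          if (!is.null(head)) cur$head <- head
          res <- adam_step(opt, cur, bp$grads, config$learning_rate)
          opt <- res$state
          adapted$factors <- res$params$factors
          if (!is.null(head)) head <- res$params$head
        }
      }
      # epoch-end evaluation on fixed batches
      ev_seeds <- with_seed(eval_seed, {
        sample.int(.Machine$integer.max,
                   if (obj == "CON") nrow(eval_train) else length(eval_train))
      })
      tr_loss <- batch_pass(adapted, head, eval_train, ev_seeds,
                            with_grad = FALSE)$loss
      te_loss <- NA_real_
      if (!is.null(test_data) && !is.null(eval_test)) {
        te_seeds <- with_seed(eval_seed + 1L, {
          sample.int(.Machine$integer.max,
                     if (obj == "CON") nrow(eval_test) else length(eval_test))
        })
        te_loss <- batch_pass(adapted, head, eval_test, te_seeds,
                              with_grad = FALSE)$loss
      }
      history[nrow(history) + 1L, ] <- list(ep, tr_loss, te_loss)
      if (step >= total_steps) break
    }
    NULL
  })

  manifest <- list(
    objective = obj, learning_rate = config$learning_rate,
    epochs_run = nrow(history), steps_run = length(step_losses),
    batch_size = config$batch_size, reduction = config$reduction,
    alpha_weight = config$alpha_weight, select_frac = config$select_frac,
    mask_token_prob = config$mask_token_prob, seed = config$seed,
    lora_rank = adapted$lora$rank_r,
    lora_targets = adapted$lora$target_projections,
    trainable_lora_parameters = lora_parameter_count(adapted),
    trainable_head_parameters = if (is.null(head)) 0L
      else length(head$W) + length(head$b),
    n_train_sequences = n_units,
    n_groups = length(group_names),
    train_loss = history$train_loss,
    test_loss = history$test_loss)

  structure(list(encoder = adapted, head = head, history = history,
                 step_losses = step_losses, group_levels = group_names,
                 manifest = manifest),
            class = "plm_training")
}

#' Held-out classification accuracy of a trained model
#'
#' Pools embeddings with the fine-tuned encoder, applies the trained
#' classification head, and scores argmax group predictions against the
#' true group labels.
#'
#' @param fit a `plm_training` result from the "CLS" objective.
#' @param data an [ortholog_group_set()] whose groups were seen in
#'   training.
#' @return fraction of correctly classified sequences.
#' @export
classification_accuracy <- function(fit, data) {
  stopifnot(inherits(fit, "plm_training"))
  if (is.null(fit$head) || !identical(fit$manifest$objective, "CLS"))
    stop("classification_accuracy needs a CLS training result")
  pooled <- embed_dataset(fit$encoder, data, residues = FALSE)$pooled
  logits <- sweep(pooled %*% fit$head$W, 2L, fit$head$b, `+`)
  pred <- fit$group_levels[max.col(logits, ties.method = "first")]
  truth <- vapply(data$records, `[[`, "", "group_id")
  mean(pred == truth[rownames(pooled)])
}

#' @export
print.plm_training <- function(x, ...) {
  cat(sprintf("<plm_training> %s, %d steps, final train loss %.4g\n",
              x$manifest$objective, x$manifest$steps_run,
              utils::tail(x$history$train_loss, 1)))
  invisible(x)
}
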