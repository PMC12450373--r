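# End-to-end commands tying the modules into reproducible, manifest-backed
# runs. Every command writes its artifacts plus a manifest.json echoing the
# resolved configuration, seeds and counts, so each numerical report can be
# reproduced from its manifest alone. No timestamps: reruns with the same
# inputs are byte-identical.

unclass_cfg <- function(x) {
  if (inherits(x, "aa_vocabulary")) {
    return(list(use_bos_eos = x$use_bos_eos,
                include_mask = !is.na(x$mask_id)))
  }
  if (is.list(x)) return(lapply(unclass(x), unclass_cfg))
  x
}

write_manifest <- function(out_dir, command, config, counts = list()) {
  manifest <- list(command = command, config = unclass_cfg(config),
                   counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Save an encoder (plain or adapted) to disk
#'
#' JSON layout with the configuration and parameter arrays; for adapted
#' encoders the LoRA factors are stored separately from the frozen base
#' weights, so merging stays reversible.
#'
#' @param encoder a `plm_encoder` or `plm_adapted`.
#' @param path output .json file.
#' @return invisibly, the path.
#' @export
save_encoder <- function(encoder, path) {
  if (inherits(encoder, "plm_adapted")) {
    obj <- list(type = "plm_adapted",
                base = list(config = unclass_cfg(encoder$base$config),
                            params = encoder$base$params),
                lora = unclass(encoder$lora),
                factors = encoder$factors)
  } else {
    obj <- list(type = "plm_encoder",
                base = list(config = unclass_cfg(encoder$config),
                            params = encoder$params))
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

relist_params <- function(p) {
  # jsonlite round-trips matrices and vectors; coerce 1-row lists back
  p$tok_emb <- as.matrix(p$tok_emb)
  p$pos_emb <- as.matrix(p$pos_emb)
  p$layers <- lapply(p$layers, function(ly) {
    for (nm in c("Wq", "Wk", "Wv", "Wo", "W1", "W2"))
      ly[[nm]] <- as.matrix(ly[[nm]])
    ly
  })
  p$Wlm <- as.matrix(p$Wlm)
  p
}

#' Load an encoder written by [save_encoder()]
#' @param path .json file.
#' @return a `plm_encoder` or `plm_adapted`.
#' @export
load_encoder <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cfg <- obj$base$config
  config <- encoder_config(cfg$embedding_dim, cfg$num_layers, cfg$num_heads,
                           cfg$max_sequence_length, cfg$feedforward_dim,
                           cfg$seed,
                           vocab = aa_vocabulary(cfg$vocab$use_bos_eos,
                                                 cfg$vocab$include_mask))
  base <- structure(list(config = config,
                         params = relist_params(obj$base$params)),
                    class = "plm_encoder")
  if (identical(obj$type, "plm_encoder")) return(base)
  lora <- lora_config(obj$lora$rank_r, obj$lora$scaling_alpha,
                      obj$lora$target_projections, obj$lora$init_seed)
  factors <- lapply(obj$factors, function(fl)
    lapply(fl, function(f) list(A = as.matrix(f$A), B = as.matrix(f$B))))
  structure(list(base = base, lora = lora, factors = factors),
            class = "plm_adapted")
}

ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

#' Simulate synthetic ortholog families
#'
#' Generates the labeled sequence set and per-family ground-truth MSAs,
#' writing `sequences.fasta`, `msa/<group>.fasta` and a manifest.
#'
#' @param out_dir output directory (created).
#' @param config a [synthetic_family_config()].
#' @return invisibly, the [generate_families()] result.
#' @export
run_simulate <- function(out_dir, config = synthetic_family_config()) {
  ensure_dir(out_dir)
  gen <- generate_families(config)
  write_fasta(gen$data, file.path(out_dir, "sequences.fasta"))
  msa_dir <- ensure_dir(file.path(out_dir, "msa"))
  for (f in gen$families)
    write_msa(f, file.path(msa_dir, paste0(f$group_id, ".fasta")))
  write_manifest(out_dir, "simulate", config,
                 list(n_sequences = length(gen$data$records),
                      n_groups = length(gen$data$groups)))
  invisible(gen)
}

#' Fine-tune an encoder on a labeled sequence set
#'
#' Optionally filters small groups and makes a stratified split, injects
#' LoRA into a freshly built (or supplied) reference encoder, trains
#' under the chosen objective, and writes the adapted encoder checkpoint
#' plus a manifest with the loss trajectory.
#'
#' @param out_dir output directory.
#' @param data an [ortholog_group_set()] or a FASTA path.
#' @param tc a [train_config()].
#' @param encoder_cfg an [encoder_config()] (ignored when `encoder`
#'   given).
#' @param lora_cfg a [lora_config()].
#' @param encoder optional pre-built `plm_encoder`.
#' @param min_members_exclusive strict group-size filter applied first
#'   (NULL = no filtering).
#' @param test_fraction held-out fraction for the stratified split
#'   (NULL = train on everything).
#' @return invisibly, the `plm_training` result.
#' @export
run_finetune <- function(out_dir, data, tc = train_config(),
                         encoder_cfg = encoder_config(),
                         lora_cfg = lora_config(), encoder = NULL,
                         min_members_exclusive = NULL,
                         test_fraction = 0.1) {
  ensure_dir(out_dir)
  if (is.character(data)) data <- read_fasta(data)
  n0 <- length(data$records)
  if (!is.null(min_members_exclusive))
    data <- filter_groups(data, min_members_exclusive)
  test_data <- NULL
  if (!is.null(test_fraction)) {
    sp <- stratified_split(data, test_fraction, seed = tc$seed)
    test_data <- subset_groups(data, sp$test_ids)
    data <- subset_groups(data, sp$train_ids)
    utils::write.table(
      data.frame(id = c(sp$train_ids, sp$test_ids),
                 subset = rep(c("train", "test"),
                              c(length(sp$train_ids),
                                length(sp$test_ids)))),
      file.path(out_dir, "split.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  if (is.null(encoder)) encoder <- build_reference_encoder(encoder_cfg)
  adapted <- inject_lora(encoder, lora_cfg)
  fit <- train(adapted, data, tc, test_data = test_data)
  save_encoder(fit$encoder, file.path(out_dir, "encoder.json"))
  utils::write.table(fit$history, file.path(out_dir, "history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "finetune",
                 list(train = tc, encoder = encoder$config,
                      lora = lora_cfg),
                 c(fit$manifest,
                   list(n_input_sequences = n0,
                        n_heldout_sequences =
                          if (is.null(test_data)) 0L
                          else length(test_data$records))))
  invisible(fit)
}

#' Embed a sequence set and write pooled embeddings
#'
#' @param out_dir output directory.
#' @param encoder encoder object or checkpoint path.
#' @param data an [ortholog_group_set()] or FASTA path.
#' @return invisibly, the [embed_dataset()] result.
#' @export
run_embed <- function(out_dir, encoder, data) {
  ensure_dir(out_dir)
  if (is.character(encoder)) encoder <- load_encoder(encoder)
  if (is.character(data)) data <- read_fasta(data)
  emb <- embed_dataset(encoder, data, residues = FALSE)
  write_embeddings_tsv(emb$pooled, file.path(out_dir, "pooled.tsv"))
  write_manifest(out_dir, "embed", list(),
                 list(n_sequences = nrow(emb$pooled),
                      embedding_dim = ncol(emb$pooled)))
  invisible(emb)
}

#' Run the pairwise-similarity benchmark
#'
#' Pooled within-group similarity, conserved-site similarity and
#' random-site similarity, written as TSV + JSON reports.
#'
#' @param out_dir output directory.
#' @param encoder encoder object or checkpoint path.
#' @param data an [ortholog_group_set()] or FASTA path.
#' @param families list of [aligned_family()]s (may be empty).
#' @param criteria a [conserved_column_criteria()].
#' @param random_cfg a [random_site_config()].
#' @param max_comparisons conserved-site cap.
#' @return invisibly, list of the three reports.
#' @export
run_bench_pairwise <- function(out_dir, encoder, data, families = list(),
                               criteria = conserved_column_criteria(),
                               random_cfg = random_site_config(),
                               max_comparisons = 1e6) {
  ensure_dir(out_dir)
  if (is.character(encoder)) encoder <- load_encoder(encoder)
  if (is.character(data)) data <- read_fasta(data)
  emb <- embed_dataset(encoder, data, residues = length(families) > 0L)
  pairs <- enumerate_within_group_pairs(data)
  pooled_rep <- pooled_pairwise_similarity(pairs, emb$pooled)
  write_similarity_report(pooled_rep, file.path(out_dir, "pooled.tsv"),
                          file.path(out_dir, "pooled.json"))
  out <- list(pooled = pooled_rep)
  if (length(families)) {
    cons_rep <- conserved_site_similarities(families, emb$residue,
                                            criteria, max_comparisons)
    rand_rep <- random_site_similarities(families, emb$residue, random_cfg)
    write_similarity_report(cons_rep, file.path(out_dir, "conserved.tsv"),
                            file.path(out_dir, "conserved.json"))
    write_similarity_report(rand_rep, file.path(out_dir, "random.tsv"),
                            file.path(out_dir, "random.json"))
    out$conserved <- cons_rep
    out$random <- rand_rep
  }
  write_manifest(out_dir, "bench-pairwise",
                 list(criteria = criteria, random = random_cfg,
                      max_comparisons = max_comparisons),
                 list(n_pairs = pooled_rep$count,
                      n_conserved = if (length(families)) out$conserved$count
                                    else 0L,
                      n_random = if (length(families)) out$random$count
                                 else 0L))
  invisible(out)
}

#' Run the bootstrap clustering benchmark
#'
#' @param out_dir output directory.
#' @param encoder encoder object or checkpoint path.
#' @param data an [ortholog_group_set()] or FASTA path.
#' @param boot a [bootstrap_config()].
#' @param params a [density_cluster_params()].
#' @return invisibly, the `clustering_report`.
#' @export
run_bench_cluster <- function(out_dir, encoder, data,
                              boot = bootstrap_config(),
                              params = density_cluster_params()) {
  ensure_dir(out_dir)
  if (is.character(encoder)) encoder <- load_encoder(encoder)
  if (is.character(data)) data <- read_fasta(data)
  emb <- embed_dataset(encoder, data, residues = FALSE)
  rep <- bootstrap_cluster_silhouette(data, emb$pooled, boot, params)
  jsonlite::write_json(
    list(per_iteration_scores = rep$per_iteration_scores,
         max_score = rep$max_score, n_defined = rep$n_defined,
         skipped = rep$skipped),
    file.path(out_dir, "clustering.json"), digits = NA, auto_unbox = TRUE,
    na = "null")
  write_manifest(out_dir, "bench-cluster",
                 list(bootstrap = boot, cluster = params),
                 list(iterations = length(rep$per_iteration_scores),
                      defined = rep$n_defined))
  invisible(rep)
}

#' Run the soft-alignment and MSA-metric benchmark
#'
#' Soft-aligns all within-group sequence pairs, applies the path-length
#' filter, and (when families are given) computes MSA mutual information
#' and occupancy.
#'
#' @param out_dir output directory.
#' @param encoder encoder object or checkpoint path.
#' @param data an [ortholog_group_set()] or FASTA path.
#' @param families optional list of [aligned_family()]s for the MSA
#'   metrics.
#' @param config a [soft_align_config()].
#' @param max_column_pairs MI evaluation cap per family.
#' @return invisibly, list with `alignments`, `kept`, `path_lengths`,
#'   `msa_metrics`.
#' @export
run_bench_align <- function(out_dir, encoder, data, families = list(),
                            config = soft_align_config(),
                            max_column_pairs = 5000L) {
  ensure_dir(out_dir)
  if (is.character(encoder)) encoder <- load_encoder(encoder)
  if (is.character(data)) data <- read_fasta(data)
  emb <- embed_dataset(encoder, data)
  pairs <- enumerate_within_group_pairs(data)
  alignments <- lapply(seq_len(nrow(pairs)), function(k)
    soft_align(emb$residue[[pairs$id1[k]]], emb$residue[[pairs$id2[k]]],
               config, pair_ids = c(pairs$id1[k], pairs$id2[k])))
  kept <- filter_alignments(alignments, config)
  pl <- vapply(alignments, `[[`, numeric(1), "path_length")
  msa_metrics <- NULL
  if (length(families)) {
    msa_metrics <- lapply(families, function(f) {
      mi <- mean_mutual_information(f, max_column_pairs = max_column_pairs)
      occ <- column_occupancy(f)
      list(group_id = f$group_id, mean_mi = mi$mean_mi,
           mean_occupancy = occ$mean)
    })
  }
  jsonlite::write_json(
    list(n_alignments = length(alignments), n_kept = length(kept),
         mean_path_length = mean(pl),
         mean_kept_path_length = if (length(kept))
           mean(vapply(kept, `[[`, numeric(1), "path_length"))
           else NA_real_,
         msa = msa_metrics),
    file.path(out_dir, "align.json"), digits = NA, auto_unbox = TRUE,
    na = "null")
  write_manifest(out_dir, "bench-align", config,
                 list(n_alignments = length(alignments),
                      n_kept = length(kept)))
  invisible(list(alignments = alignments, kept = kept, path_lengths = pl,
                 msa_metrics = msa_metrics))
}

#' Collect command manifests into one run report
#'
#' @param run_dir directory whose subdirectories hold command manifests.
#' @param out_path output JSON (default `report.json` inside `run_dir`).
#' @return invisibly, the aggregated report list.
#' @export
run_report <- function(run_dir, out_path = file.path(run_dir, "report.json")) {
  mans <- list.files(run_dir, pattern = "^manifest\\.json$",
                     recursive = TRUE, full.names = TRUE)
  rep <- lapply(mans, jsonlite::read_json)
  names(rep) <- dirname(gsub(paste0("^", run_dir, "/?"), "", mans))
  jsonlite::write_json(rep, out_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(rep)
}
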