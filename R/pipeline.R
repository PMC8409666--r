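# End-to-end orchestration: simulate -> train -> segment -> filter ->
# evaluate -> count, with persisted CSV reports and a run manifest.

#' Default pipeline configuration
#'
#' Desk-scale defaults: small phantoms and a narrow network so the whole
#' chain runs on one CPU in minutes. Every field can be overridden via
#' `modifyList()`-style named arguments or a YAML file (see
#' [load_pipeline_config()]).
#'
#' @param ... named overrides of the defaults.
#' @return Nested configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_train = 8L, n_val = 2L, n_eval = 4L,
    phantom = list(shape = c(16L, 64L, 64L), n_lesions = 3L,
                   groups = c("51-100", ">100"), ring_fraction = 0.25,
                   lesion_boost = 0.5, noise_sd = 0.05,
                   contrast_jitter = 0.1, n_distractors = 3L),
    train = list(loss = "dice", K = 1024L, batch_size = 8L,
                 lr = 1e-3, epochs = 10L, base_filters = 4L,
                 keep_empty_prob = 0.1, threshold = 0.5),
    rf = list(n_trees = 100L, score_threshold = 0.5),
    min_size = 5L
  )
  overrides <- list(...)
  if (length(overrides)) cfg <- utils::modifyList(cfg, overrides)
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [pipeline_config()]
#'   fields.
#' @return Configuration list (defaults filled in).
#' @export
load_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.phantom_spec_from <- function(cfg, seed) {
  do.call(phantom_spec, c(cfg$phantom, list(seed = as.integer(seed))))
}

#' Run the full two-stage pipeline on synthetic phantoms
#'
#' Simulates train/validation/evaluation phantom cohorts, trains the UNet,
#' segments the evaluation scans, fits the random-forest candidate filter
#' on the training scans' candidates, applies it, and evaluates lesion-wise
#' performance before and after filtering plus the per-scan count
#' confusion. All intermediate tables are written to `out_dir` (when
#' given) together with a run manifest; a fixed seed reproduces the run
#' byte-identically.
#'
#' @param config a [pipeline_config()] list.
#' @param out_dir optional output directory for CSV reports and manifest.
#' @param verbose print stage progress.
#' @return List with `fit` (the `unet_fit`), `rf` (the `gad_rf`),
#'   `eval_pre`, `eval_post` (`lesion_eval` reports before/after the RF
#'   filter), `counts` (`count_confusion`), and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message("[gadseg] ", ...)
  seed <- as.integer(config$seed)
  n_all <- config$n_train + config$n_val + config$n_eval

  say("simulate: ", n_all, " phantoms")
  phs <- lapply(seq_len(n_all), function(i)
    generate_phantom(.phantom_spec_from(config, seed + 7L * i)))
  scans <- lapply(phs, `[[`, "stack")
  idx_train <- seq_len(config$n_train)
  idx_val <- config$n_train + seq_len(config$n_val)
  idx_eval <- config$n_train + config$n_val + seq_len(config$n_eval)

  say("train: ", config$train$loss, ", ", config$train$epochs, " epochs")
  tcfg <- do.call(train_config, c(config$train, list(seed = seed)))
  fit <- train_unet(scans[idx_train], scans[idx_val], tcfg,
                    verbose = verbose)

  say("segment + candidate extraction")
  seg <- function(i) {
    pm <- predict_volume(fit, scans[[i]], tcfg$threshold)
    cand <- extract_candidates(pm$binary, scans[[i]], config$min_size)
    list(pred = pm, cand = cand)
  }
  seg_train <- lapply(c(idx_train, idx_val), seg)
  seg_eval <- lapply(idx_eval, seg)

  say("filter: fitting random forest on ",
      sum(vapply(seg_train, function(s) nrow(s$cand$candidates),
                 integer(1))), " candidates")
  labeled <- do.call(rbind, lapply(seq_along(seg_train), function(k) {
    i <- c(idx_train, idx_val)[k]
    label_candidates(seg_train[[k]]$cand, scans[[i]]$mask)
  }))
  rfcfg <- do.call(rf_config, c(config$rf, list(seed = seed)))
  rf <- fit_rf(labeled, rfcfg)

  say("evaluate")
  pre_masks <- list(); post_masks <- list()
  pre_matches <- list(); post_matches <- list()
  pred_counts_pre <- integer(0); pred_counts_post <- integer(0)
  true_counts <- integer(0)
  for (k in seq_along(idx_eval)) {
    i <- idx_eval[k]
    manual <- phs[[i]]$mask
    pre <- seg_eval[[k]]$cand
    filt <- apply_rf(rf, pre)
    pre_mask <- pre$labels > 0L
    pre_masks[[k]] <- list(pred = pre_mask, manual = manual)
    post_masks[[k]] <- list(pred = filt$mask, manual = manual)
    pre_matches[[k]] <- match_lesions(pre_mask, manual, config$min_size)
    post_matches[[k]] <- match_lesions(filt$mask, manual, config$min_size)
    pred_counts_pre[k] <- nrow(pre$candidates)
    pred_counts_post[k] <- length(filt$kept_ids)
    true_counts[k] <- phs[[i]]$spec$n_lesions
  }
  eval_pre <- lesion_metrics(pre_matches, pre_masks, config$min_size)
  eval_post <- lesion_metrics(post_matches, post_masks, config$min_size)
  counts <- count_confusion(
    vapply(pred_counts_post, categorize_count, character(1)),
    vapply(true_counts, categorize_count, character(1)))

  res <- list(fit = fit, rf = rf, eval_pre = eval_pre,
              eval_post = eval_post, counts = counts, config = config)
  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  res
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(res$eval_pre$by_group,
            file.path(out_dir, "lesion_eval_pre_rf.csv"), row.names = FALSE)
  write.csv(res$eval_post$by_group,
            file.path(out_dir, "lesion_eval_post_rf.csv"), row.names = FALSE)
  write.csv(res$fit$log, file.path(out_dir, "training_log.csv"),
            row.names = FALSE)
  cm <- as.data.frame(res$counts$matrix)
  write.csv(cm, file.path(out_dir, "count_confusion.csv"),
            row.names = FALSE)
  imp <- data.frame(feature = names(res$rf$importance),
                    importance = as.numeric(res$rf$importance))
  write.csv(imp, file.path(out_dir, "rf_importance.csv"), row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("gadseg")),
    seed = res$config$seed,
    config = res$config,
    outputs = c("lesion_eval_pre_rf.csv", "lesion_eval_post_rf.csv",
                "training_log.csv", "count_confusion.csv",
                "rf_importance.csv"))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Save / load a trained UNet checkpoint
#'
#' Plain `saveRDS` of the parameter and running-statistics lists plus the
#' architecture spec; [load_unet()] rebuilds the `unet2d`.
#'
#' @param net a `unet2d` or `unet_fit`.
#' @param path checkpoint path (`.rds`).
#' @return `path` ([save_unet()]); a `unet2d` ([load_unet()]).
#' @export
save_unet <- function(net, path) {
  if (inherits(net, "unet_fit")) net <- net$net
  stopifnot(inherits(net, "unet2d"))
  saveRDS(list(spec = unclass(net$spec), par = net$par, state = net$state),
          path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  obj <- readRDS(path)
  structure(list(spec = structure(obj$spec, class = "unet_spec"),
                 par = obj$par, state = obj$state),
            class = "unet2d")
}
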