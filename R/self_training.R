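#' Train the teacher ensemble on clean records
#'
#' The teacher shares the ensemble architecture and is trained on the clean
#' training split produced by the annotation loop (optionally warm-started
#' from the annotation-phase ensemble). Its inference output is the
#' mean-logit sigmoid aggregate. Metrics are computed on the clean test
#' split only.
#'
#' @param clean_train clean-provenance [frame_record()]s for training.
#' @param clean_test clean-provenance records for evaluation.
#' @param vocab a [tool_vocabulary()].
#' @param cfg a [train_config()].
#' @param init optional ensemble to warm-start from (e.g. the fine-tuned
#'   annotation-phase ensemble); `NULL` trains fresh members.
#' @return A list of class `stage_result`: `ensemble`, `metrics` (an
#'   [evaluate_method()] table) and `method` name.
#' @export
train_teacher <- function(clean_train, clean_test, vocab,
                          cfg = train_config(), init = NULL) {
  check_provenance(clean_train, "clean")
  check_provenance(clean_test, "clean")
  ens <- fit_ensemble(clean_train, vocab, cfg = cfg, init = init)
  stage_result(ens, clean_test, "teacher")
}

check_provenance <- function(records, expected) {
  prov <- vapply(records, `[[`, character(1), "provenance")
  if (!all(prov == expected))
    stopf("all records must have provenance '%s'", expected)
}

stage_result <- function(ensemble, test_records, method) {
  structure(list(ensemble = ensemble,
                 metrics = evaluate_method(ensemble, test_records,
                                           method = method),
                 method = method),
            class = "stage_result")
}

#' @export
print.stage_result <- function(x, ...) {
  cat(sprintf("Stage result: %s\n", x$method))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Pseudo-label the noisy pool with the teacher
#'
#' Queries the teacher on every pool record, discards the original noisy
#' labels, and attaches the teacher's mean-logit sigmoid output as soft
#' labels (`pseudo_label_mode = "soft"`, the default) or the top-3 decision
#' as hard labels (`"top3-hard"`); provenance becomes `pseudo` either way
#' (hard labels are also mirrored into the binary label slot).
#'
#' @param teacher a teacher `tool_ensemble` (or `stage_result`).
#' @param pool_records noisy records not in the clean set.
#' @param clean_ids record ids of the clean set, used to reject overlap.
#' @param pseudo_label_mode `"soft"` or `"top3-hard"`.
#' @return List of pseudo-provenance [frame_record()]s.
#' @export
pseudo_label_pool <- function(teacher, pool_records, clean_ids = character(0),
                              pseudo_label_mode = c("soft", "top3-hard")) {
  pseudo_label_mode <- match.arg(pseudo_label_mode)
  if (inherits(teacher, "stage_result")) teacher <- teacher$ensemble
  if (length(pool_records) == 0L) return(list())
  overlap <- intersect(record_ids(pool_records), clean_ids)
  if (length(overlap) > 0L)
    stopf("pool overlaps the clean set (%d records)", length(overlap))
  P <- predict(teacher, pool_records, type = "prob",
               aggregate = "mean_sigmoid")
  lapply(seq_along(pool_records), function(i) {
    r <- pool_records[[i]]
    r$provenance <- "pseudo"
    if (pseudo_label_mode == "soft") {
      r$soft_labels <- P[i, ]
      r$labels <- as.integer(P[i, ] >= 0.5)
    } else {
      lab <- integer(ncol(P))
      lab[decide_top3(P[i, ])] <- 1L
      r$labels <- lab
      r$soft_labels <- as.numeric(lab)
    }
    r
  })
}

#' Train the student ensemble on pseudo + clean data
#'
#' The student (same architecture, warm-started from the teacher by
#' default) trains on the union of the pseudo-labelled pool and the clean
#' training split. With `smoothing = TRUE` the label-smoothed softmax loss
#' is used instead of BCE. Inference and evaluation use the mean-logit
#' sigmoid with top-3 decisions.
#'
#' @param pseudo_records pseudo-provenance records from
#'   [pseudo_label_pool()].
#' @param clean_train,clean_test clean splits from the annotation loop.
#' @param vocab a [tool_vocabulary()].
#' @param cfg a [train_config()].
#' @param init ensemble to warm-start from (usually the teacher).
#' @param smoothing use the label-smoothed loss.
#' @return A `stage_result` (method `"student"` or `"label smoothing"`).
#' @export
train_student <- function(pseudo_records, clean_train, clean_test, vocab,
                          cfg = train_config(), init = NULL,
                          smoothing = FALSE) {
  if (length(pseudo_records) == 0L || length(clean_train) == 0L)
    stopf("student training needs both pseudo and clean records")
  records <- c(pseudo_records, clean_train)
  ens <- fit_ensemble(records, vocab, cfg = cfg,
                      loss_mode = if (smoothing) "smoothed" else "multilabel",
                      init = init)
  stage_result(ens, clean_test,
               if (smoothing) "label smoothing" else "student")
}

#' Weighted-data-loader fine-tuning
#'
#' Head-only fine-tuning of an existing ensemble with batches drawn by the
#' reciprocal-log combination weights, so minority label combinations are
#' over-sampled for a few extra epochs. Member bodies are untouched
#' (freeze contract, guarding against catastrophic forgetting); zero epochs
#' is the identity.
#'
#' @param ensemble a trained `tool_ensemble` (or `stage_result`).
#' @param records training records to resample from.
#' @param weights per-record sampling weights (defaults to the
#'   reciprocal-log combination weights of `records`).
#' @param epochs head-only fine-tuning epochs.
#' @param seed RNG seed for the weighted draws.
#' @return The fine-tuned `tool_ensemble`.
#' @export
wdl_finetune <- function(ensemble, records, weights = NULL, epochs = 3L,
                         seed = 1L) {
  if (inherits(ensemble, "stage_result")) ensemble <- ensemble$ensemble
  if (epochs == 0L) return(ensemble)
  weights <- weights %||% record_wdl_weights(records, ensemble$vocab)
  n <- length(records)
  batches <- weighted_sampler(n, weights, ensemble$cfg$batch_size,
                              n_batches = max(1L, ceiling(n / ensemble$cfg$batch_size)),
                              seed = seed)
  resampled <- records[unlist(batches)]
  cfg <- ensemble$cfg
  cfg$head_epochs <- as.integer(epochs)
  cfg$full_epochs <- 0L
  # gentle refinement of an already-trained head: reduced peak rate, as in
  # the discriminative fine-tuning of the other warm-started stages
  cfg$learning_rate <- cfg$learning_rate / 4
  cfg$seed <- ensemble$cfg$seed + 7919L + as.integer(seed)
  fit_ensemble(resampled, ensemble$vocab,
               members = lapply(ensemble$members, `[[`, "spec"),
               cfg = cfg, loss_mode = "multilabel",
               loss_weights = ensemble$loss_weights,
               init = ensemble, freeze_body = TRUE)
}

#' Pipeline configuration
#'
#' Bundles the generator, training and annotation settings of a full
#' end-to-end run at desk scale.
#'
#' @param generator a [generator_config()].
#' @param train a [train_config()].
#' @param k annotation budget of the cleaning loop.
#' @param al_batch_size annotation batch size.
#' @param finetune_epochs head-only epochs between annotation batches.
#' @param wdl_epochs head-only epochs of the weighted fine-tune arm.
#' @param pseudo_label_mode `"soft"` or `"top3-hard"`.
#' @param n_mask_annotations frames with oracle-annotated masks used to fit
#'   the foreground segmenter.
#' @param seed master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            train = train_config(),
                            k = 300L, al_batch_size = 50L,
                            finetune_epochs = 15L, wdl_epochs = 3L,
                            pseudo_label_mode = c("soft", "top3-hard"),
                            n_mask_annotations = 40L, seed = 1L) {
  structure(list(generator = generator, train = train, k = as.integer(k),
                 al_batch_size = as.integer(al_batch_size),
                 finetune_epochs = as.integer(finetune_epochs),
                 wdl_epochs = as.integer(wdl_epochs),
                 pseudo_label_mode = match.arg(pseudo_label_mode),
                 n_mask_annotations = as.integer(n_mask_annotations),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full robust-training pipeline
#'
#' End to end on synthetic data: generate -> preprocess (keyframes, fitted
#' segmenter + dynamic cropping, black-frame relabelling, label
#' extrapolation) -> noisy baseline ensemble -> active-learning label
#' cleaning -> teacher -> pseudo-labelling -> student -> label-smoothing
#' arm -> weighted-data-loader arm -> evaluation and method comparison.
#' Fully reproducible under `cfg$seed`.
#'
#' @param cfg a [pipeline_config()].
#' @param dataset optional pre-generated `surg_dataset` (with truth) to use
#'   instead of generating one.
#' @return A list of class `tool_pipeline` with the preprocessed records,
#'   the AL result, `stages` (stage results for `baseline`, `teacher`,
#'   `student`, `label smoothing`, `weighted data loaders`), `metrics` (the
#'   combined long table) and `comparison` (a [compare_methods()] report
#'   over the four self-training arms).
#' @export
run_pipeline <- function(cfg = pipeline_config(), dataset = NULL) {
  gen <- cfg$generator
  gen$seed <- gen$seed + cfg$seed * 101L
  vocab <- tool_vocabulary()
  dataset <- dataset %||% generate_dataset(vocab, gen)
  prep <- preprocess_dataset(dataset, cfg)
  records <- prep$records
  oracle <- annotation_oracle(dataset)

  tcfg <- cfg$train
  tcfg$seed <- cfg$train$seed + cfg$seed

  baseline <- fit_ensemble(records, vocab, cfg = tcfg)
  al <- run_al(baseline, records, oracle, k = min(cfg$k, length(records)),
               batch_size = cfg$al_batch_size,
               finetune_epochs = cfg$finetune_epochs, seed = cfg$seed)

  baseline_stage <- stage_result(baseline, al$clean_test, "noisy baseline")
  teacher <- train_teacher(al$clean_train, al$clean_test, vocab, cfg = tcfg,
                           init = al$ensemble)
  pool <- records[!record_ids(records) %in% al$state$clean_ids]
  pseudo <- pseudo_label_pool(teacher, pool, clean_ids = al$state$clean_ids,
                              pseudo_label_mode = cfg$pseudo_label_mode)
  student <- train_student(pseudo, al$clean_train, al$clean_test, vocab,
                           cfg = tcfg, init = teacher$ensemble)
  smooth <- train_student(pseudo, al$clean_train, al$clean_test, vocab,
                          cfg = tcfg, init = teacher$ensemble,
                          smoothing = TRUE)
  wdl_ens <- wdl_finetune(student$ensemble, c(pseudo, al$clean_train),
                          epochs = cfg$wdl_epochs, seed = cfg$seed)
  wdl <- structure(list(ensemble = wdl_ens,
                        metrics = evaluate_method(wdl_ens, al$clean_test,
                                                  method = "weighted data loaders"),
                        method = "weighted data loaders"),
                   class = "stage_result")

  stages <- list(baseline = baseline_stage, teacher = teacher,
                 student = student, smoothing = smooth, wdl = wdl)
  metrics <- do.call(rbind, lapply(stages, `[[`, "metrics"))
  rownames(metrics) <- NULL
  arms <- metrics[metrics$method != "noisy baseline", ]
  structure(list(records = records, al = al, stages = stages,
                 metrics = metrics, comparison = compare_methods(arms),
                 segmenter = prep$segmenter, vocab = vocab, cfg = cfg),
            class = "tool_pipeline")
}

# Preprocess a generated dataset: keyframes, fitted segmenter, dynamic
# cropping, black-frame relabelling, clip-label extrapolation. The
# segmenter trains on a small set of oracle-annotated masks (one frame per
# sampled clip), mirroring the hand-annotated mask subset of the real
# protocol.
preprocess_dataset <- function(dataset, cfg) {
  vocab <- dataset$vocab
  clips <- dataset$clips
  gen <- dataset$cfg
  n_ann <- min(cfg$n_mask_annotations, length(clips))
  ann_clips <- with_seed(cfg$seed + 17L,
                         sample(seq_along(clips), n_ann))
  frames <- list(); masks <- list()
  for (j in ann_clips) {
    clip <- clips[[j]]
    f <- 1L + (cfg$seed + j) %% length(clip$frames)
    frames <- c(frames, clip$frames[f])
    masks <- c(masks, list(box_to_mask(clip$truths[[f]]$foreground_box,
                                       gen$image_height, gen$image_width)))
  }
  seg <- fit_foreground_segmenter(frames, masks)
  # majority vote of the annotated masks: fallback for frames on which the
  # segmenter finds no foreground (e.g. fully black frames)
  fallback_mask <- Reduce(`+`, masks) > length(masks) / 2
  records <- list()
  for (clip in clips) {
    kf <- extract_keyframes(clip, source_fps = 10, target_fps = 10,
                            max_keyframes = gen$frames_per_clip)
    cropped <- lapply(kf, function(i) {
      m <- predict(seg, clip$frames[[i]])
      if (!any(m)) m <- fallback_mask
      crop_foreground(clip$frames[[i]], m)
    })
    records <- c(records, extrapolate_labels(clip, kf, vocab,
                                             frames = cropped))
  }
  records <- handle_black_frames(records, vocab)
  records <- cache_features(records, resize_mode = cfg$train$resize_mode)
  list(records = records, segmenter = seg)
}

#' Summarise a pipeline run
#'
#' Collects the headline quantities of one end-to-end run: the manual
#' correction curve and its Spearman trend, ensemble macro metrics per
#' method arm, and the minority-class F1 change due to weighted-data-loader
#' fine-tuning (minority = tools in the lower half of clean-training
#' positive counts, restricted to tools present in the clean test set; NA
#' when no tool qualifies).
#'
#' @param object a `tool_pipeline` from [run_pipeline()].
#' @param ... unused.
#' @return A list of class `summary.tool_pipeline`.
#' @export
summary.tool_pipeline <- function(object, ...) {
  corr <- object$al$state$corrections_per_batch
  rho <- if (length(corr) >= 3L && stats::sd(corr) > 0)
    stats::cor(seq_along(corr), corr, method = "spearman") else NA_real_
  ens <- object$metrics[object$metrics$member == "Ensemble", ]
  arm <- function(m, col = "mAF1") ens[[col]][ens$method == m]

  vocab <- object$vocab
  tools <- seq_len(vocab$n_tools)
  Ytr <- truth_matrix(object$al$clean_train, vocab)
  Yts <- truth_matrix(object$al$clean_test, vocab)
  counts <- colSums(Ytr)[tools]
  minority <- tools[counts <= stats::quantile(counts, 0.5)]
  minority <- minority[colSums(Yts)[minority] > 0]
  min_f1 <- function(stage) {
    if (length(minority) == 0L) return(NA_real_)
    B <- predict(stage$ensemble, object$al$clean_test, type = "top3")
    pcm <- per_class_metrics(B, Yts, vocab$names)
    mean(pcm$f1[minority])
  }
  structure(list(
    corrections = corr,
    correction_spearman = rho,
    ensemble_mAF1 = stats::setNames(ens$mAF1, ens$method),
    student_vs_baseline = arm("student") - arm("noisy baseline"),
    minority_classes = vocab$names[minority],
    minority_f1_student = min_f1(object$stages$student),
    minority_f1_wdl = min_f1(object$stages$wdl),
    n_records = length(object$records),
    n_clean = length(object$al$clean_records)
  ), class = "summary.tool_pipeline")
}

#' @export
print.summary.tool_pipeline <- function(x, ...) {
  cat("Pipeline summary\n")
  cat("  corrections per batch:", paste(x$corrections, collapse = " "),
      sprintf(" (Spearman trend %.2f)\n", x$correction_spearman))
  for (m in names(x$ensemble_mAF1))
    cat(sprintf("  ensemble mAF1 [%s]: %.4f\n", m, x$ensemble_mAF1[[m]]))
  cat(sprintf("  student - baseline mAF1: %+.4f\n", x$student_vs_baseline))
  cat(sprintf("  minority-class F1: student %.4f -> WDL %.4f (%d classes)\n",
              x$minority_f1_student, x$minority_f1_wdl,
              length(x$minority_classes)))
  invisible(x)
}

#' @export
print.tool_pipeline <- function(x, ...) {
  cat("Robust tool-classification pipeline run\n")
  cat(sprintf("  records: %d; cleaned: %d (%d train / %d test)\n",
              length(x$records), length(x$al$clean_records),
              length(x$al$clean_train), length(x$al$clean_test)))
  cat("  ensemble mAF1 by method:\n")
  ens <- x$metrics[x$metrics$member == "Ensemble", c("method", "mAF1")]
  for (i in seq_len(nrow(ens)))
    cat(sprintf("    %-22s %.4f\n", ens$method[i], ens$mAF1[i]))
  invisible(x)
}
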