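#' Annotation oracle backed by generator ground truth
#'
#' Stands in for the human experts of the annotation loop: given a record
#' id, returns the true visible-tool set of that frame (the `blank` class
#' for black or tool-free frames). Deterministic; counts its queries.
#'
#' @param dataset a `surg_dataset` with ground truth (`truth` present).
#' @return A list of class `annotation_oracle` with `$query(id)` returning
#'   a character label set and `$n_queries()` the cost counter.
#' @export
annotation_oracle <- function(dataset) {
  if (is.null(dataset$truth)) stopf("dataset carries no ground truth")
  vocab <- dataset$vocab
  key <- paste0(dataset$truth$clip_id, ":", dataset$truth$frame_index)
  visible <- strsplit(dataset$truth$visible_tools, ";", fixed = TRUE)
  visible <- lapply(visible, function(v) v[nzchar(v)])
  names(visible) <- key
  env <- new.env(parent = emptyenv())
  env$count <- 0L
  black <- dataset$truth$is_black
  names(black) <- key
  query <- function(id) {
    if (!id %in% names(visible)) stopf("oracle has no truth for record '%s'", id)
    env$count <- env$count + 1L
    v <- visible[[id]]
    # the blank class marks lens-out (black) frames; a frame whose installed
    # tools are merely out of view gets the empty label set
    if (black[[id]] && !is.na(vocab$blank_index))
      v <- vocab$names[vocab$blank_index]
    v
  }
  structure(list(query = query, n_queries = function() env$count,
                 vocab = vocab),
            class = "annotation_oracle")
}

#' Score the pool and select the next annotation batch
#'
#' Computes the per-record ensemble loss of each pool record's (noisy)
#' labels against the max-probability aggregated ensemble output -- the
#' loss-based epistemic score -- and returns the `batch_size` record ids
#' with the largest loss, in descending score order, ties broken toward the
#' lexicographically lower id. When the pool is smaller than the batch, the
#' whole pool is returned.
#'
#' @param ensemble a `tool_ensemble`.
#' @param pool_records nonempty list of [frame_record()]s still carrying
#'   noisy labels.
#' @param batch_size number of records to select.
#' @return Character vector of selected record ids (descending score).
#' @export
score_and_select <- function(ensemble, pool_records, batch_size = 50L) {
  if (length(pool_records) == 0L) stopf("empty annotation pool")
  scores <- record_scores(ensemble, pool_records)
  ids <- record_ids(pool_records)
  ord <- order(-scores, ids)
  ids[ord][seq_len(min(batch_size, length(ids)))]
}

#' Annotate one batch against the oracle
#'
#' Each record's labels are replaced by the oracle truth and its provenance
#' set to `clean`. The correction count is the number of records whose
#' shown prediction differs (as a set) from the truth -- the manual-effort
#' measure tracked across the annotation loop.
#'
#' @param records list of [frame_record()]s to annotate.
#' @param oracle an [annotation_oracle()].
#' @param predictions list (parallel to `records`) of predicted label sets
#'   shown to the annotator, as character vectors.
#' @param vocab a [tool_vocabulary()].
#' @return List with `records` (corrected, provenance `clean`) and
#'   `corrections` (integer count).
#' @export
annotate_batch <- function(records, oracle, predictions, vocab) {
  if (length(predictions) != length(records))
    stopf("one prediction per record required")
  corrections <- 0L
  out <- vector("list", length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    truth <- oracle$query(r$id)
    if (!setequal(predictions[[i]], truth)) corrections <- corrections + 1L
    r$labels <- label_vector(truth, vocab)
    r$provenance <- "clean"
    r$soft_labels <- NULL
    out[[i]] <- r
  }
  list(records = out, corrections = corrections)
}

#' Run the active-learning label-cleaning loop
#'
#' Repeats select-hardest / oracle-correct / fine-tune until `k` records
#' have been cleaned: each iteration scores the pool with
#' [score_and_select()], shows the annotator the ensemble's top-3
#' max-probability predictions, replaces labels with oracle truth, then
#' fine-tunes the ensemble heads on all clean records so far. The cleaned
#' set is finally split 80/20 (stratified by corrected label combination)
#' into clean train and test sets.
#'
#' @param ensemble a trained baseline `tool_ensemble`.
#' @param records the noisy record list (the pool).
#' @param oracle an [annotation_oracle()].
#' @param k annotation budget: total records to clean (`0 < k <=`
#'   `length(records)`).
#' @param batch_size records per annotation batch.
#' @param finetune_epochs head-only epochs after each completed batch. The
#'   default gives the optimiser enough steps on the small clean set to
#'   move the heads appreciably between batches; with one epoch the
#'   correction effort barely responds to fine-tuning.
#' @param clean_ratio train fraction of the final clean split.
#' @param seed seed for the final clean split.
#' @return A list of class `al_result`: `clean_records`, `clean_train`,
#'   `clean_test`, `state` (an `al_state` with `corrections_per_batch`,
#'   `clean_ids`, `pool_ids`, `batch_size`, `budget`) and `ensemble`
#'   (fine-tuned).
#' @export
run_al <- function(ensemble, records, oracle, k, batch_size = 50L,
                   finetune_epochs = 15L, clean_ratio = 0.8, seed = 1L) {
  if (k <= 0L) stopf("annotation budget k must be > 0")
  if (k > length(records)) stopf("k exceeds the pool size")
  pool <- records
  clean <- list()
  corrections <- integer(0)
  batch_no <- 0L
  while (length(clean) < k) {
    batch_no <- batch_no + 1L
    take <- min(batch_size, k - length(clean), length(pool))
    sel <- score_and_select(ensemble, pool, take)
    pick <- match(sel, record_ids(pool))
    batch <- pool[pick]
    # show the annotator the thresholded multi-label decision: a forced
    # top-3 view would mark every frame with < 3 visible tools as a
    # correction regardless of model quality
    probs <- predict(ensemble, batch, type = "prob", aggregate = "max_prob")
    preds <- lapply(seq_len(nrow(probs)), function(i)
      ensemble$vocab$names[probs[i, ] >= 0.5])
    ann <- annotate_batch(batch, oracle, preds, ensemble$vocab)
    corrections <- c(corrections, ann$corrections)
    clean <- c(clean, ann$records)
    pool <- pool[-pick]
    if (finetune_epochs > 0L) {
      cfg <- ensemble$cfg
      cfg$head_epochs <- as.integer(finetune_epochs)
      cfg$full_epochs <- 0L
      cfg$seed <- ensemble$cfg$seed + batch_no
      ensemble <- fit_ensemble(clean, ensemble$vocab,
                               members = lapply(ensemble$members, `[[`, "spec"),
                               cfg = cfg, loss_mode = ensemble$loss_mode,
                               loss_weights = ensemble$loss_weights,
                               init = ensemble, freeze_body = TRUE)
    }
  }
  state <- structure(list(corrections_per_batch = corrections,
                          clean_ids = record_ids(clean),
                          pool_ids = record_ids(pool),
                          batch_size = as.integer(batch_size),
                          budget = as.integer(k)),
                     class = "al_state")
  split <- clean_record_split(clean, ensemble$vocab, clean_ratio, seed)
  structure(list(clean_records = clean, clean_train = split$train,
                 clean_test = split$test, state = state,
                 ensemble = ensemble),
            class = "al_result")
}

# 80/20 split of cleaned records, stratified by corrected label combination
# at the record level (clips are no longer the annotation unit here).
clean_record_split <- function(records, vocab, ratio = 0.8, seed = 1L) {
  df <- data.frame(
    clip_id = record_ids(records),
    combo = vapply(records, function(r)
      combo_key(vocab$names[r$labels == 1L]), character(1)),
    stringsAsFactors = FALSE)
  plan <- stratified_split(df, ratio = ratio, seed = seed)
  ids <- record_ids(records)
  list(train = records[ids %in% plan$train_clip_ids],
       test = records[ids %in% plan$test_clip_ids])
}

#' @export
print.al_state <- function(x, ...) {
  cat(sprintf("Active-learning state: %d cleaned / budget %d (batch size %d)\n",
              length(x$clean_ids), x$budget, x$batch_size))
  cat("corrections per batch:", paste(x$corrections_per_batch, collapse = ", "),
      "\n")
  invisible(x)
}

#' Plot the manual-correction curve of an annotation run
#'
#' @param x an `al_state` (or `al_result`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.al_state <- function(x, ...) {
  y <- x$corrections_per_batch
  graphics::plot(seq_along(y), y, type = "b", xlab = "annotation batch",
                 ylab = "manual corrections", ...)
  invisible(x)
}

#' @export
print.al_result <- function(x, ...) {
  print(x$state)
  cat(sprintf("clean split: %d train / %d test\n",
              length(x$clean_train), length(x$clean_test)))
  invisible(x)
}
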