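#' Stratified split by unique label combination
#'
#' Clips are clustered by their unique tool-label combination; within each
#' combination, clips are shuffled (seeded) and `round(ratio * n)` assigned
#' to the training side (round half up), the remainder to the test side.
#' Every combination with at least two clips is guaranteed representation on
#' both sides; singleton combinations are exempt and assigned to the
#' training side (maximising the label coverage available for learning).
#'
#' @param clips list of `surg_clip`s, or a data frame with columns
#'   `clip_id` and `combo` (a combination key string).
#' @param ratio training fraction, in (0, 1).
#' @param seed RNG seed for the within-combination shuffles.
#' @return A list of class `split_plan`: `train_clip_ids`, `test_clip_ids`
#'   (disjoint; union = all clips) and `ratio`.
#' @export
stratified_split <- function(clips, ratio = 0.8, seed = 1L) {
  if (ratio <= 0 || ratio >= 1) stopf("ratio must lie in (0, 1)")
  df <- if (is.data.frame(clips)) clips else data.frame(
    clip_id = vapply(clips, `[[`, character(1), "clip_id"),
    combo = vapply(clips, function(c) combo_key(c$label_set), character(1)),
    stringsAsFactors = FALSE)
  train <- character(0); test <- character(0)
  with_seed(seed, {
    for (combo in sort(unique(df$combo))) {
      ids <- df$clip_id[df$combo == combo]
      n <- length(ids)
      if (n == 1L) {
        train <- c(train, ids)
        next
      }
      ids <- ids[sample.int(n)]
      n_tr <- floor(ratio * n + 0.5)          # round half up
      n_tr <- min(max(n_tr, 1L), n - 1L)      # both sides represented
      train <- c(train, ids[seq_len(n_tr)])
      test <- c(test, ids[(n_tr + 1L):n])
    }
  })
  structure(list(train_clip_ids = train, test_clip_ids = test, ratio = ratio),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  n <- length(x$train_clip_ids) + length(x$test_clip_ids)
  cat(sprintf("Stratified split plan: %d train / %d test (target ratio %.2f, achieved %.3f)\n",
              length(x$train_clip_ids), length(x$test_clip_ids), x$ratio,
              length(x$train_clip_ids) / n))
  invisible(x)
}

#' Count label combinations
#'
#' @param records list of [frame_record()]s, or a character vector of
#'   combination keys.
#' @param vocab a [tool_vocabulary()] (needed for record input).
#' @return Named integer vector: combination key -> count.
#' @export
combo_counts <- function(records, vocab = NULL) {
  keys <- if (is.character(records)) records else
    vapply(records, function(r) combo_key(vocab$names[r$labels == 1L]),
           character(1))
  tab <- table(keys)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Reciprocal-log weights for imbalance-aware sampling
#'
#' Weight per sample: `1 / ln(1 + count)` of its label-combination
#' frequency -- the reciprocal-logarithm rule that instructs the batch
#' sampler to draw minority combinations more often. (The `1 + count` guard
#' keeps the reciprocal-log shape finite at frequency 1.) Strictly
#' decreasing in count, always finite and positive.
#'
#' @param counts named integer vector of combination counts (from
#'   [combo_counts()]); all entries must be >= 1.
#' @return Named numeric vector of per-combination weights.
#' @export
wdl_weights <- function(counts) {
  if (any(counts < 1)) stopf("combination counts must be >= 1")
  w <- 1 / log(1 + counts)
  names(w) <- names(counts)
  w
}

# Per-record weights: each record inherits its combination's weight.
record_wdl_weights <- function(records, vocab) {
  keys <- vapply(records, function(r) combo_key(vocab$names[r$labels == 1L]),
                 character(1))
  counts <- combo_counts(keys)
  w <- wdl_weights(counts)
  # index by position: "" (empty combination) is a legal key
  unname(w[match(keys, names(w))])
}

#' Weighted batch sampler
#'
#' Draws record indices with replacement, proportional to weight, grouped
#' into batches -- the weighted-data-loader mechanism that over-samples
#' minority label combinations. Deterministic under a fixed seed.
#'
#' @param n number of records (weights align with `1:n`).
#' @param weights positive sampling weights, length `n`.
#' @param batch_size records per batch.
#' @param n_batches number of batches to draw.
#' @param seed RNG seed.
#' @return List of `n_batches` integer index vectors.
#' @export
weighted_sampler <- function(n, weights, batch_size, n_batches, seed = 1L) {
  if (length(weights) != n) stopf("weights must align with records")
  if (all(weights == 0)) stopf("all sampling weights are zero")
  if (any(weights < 0)) stopf("weights must be >= 0")
  with_seed(seed, {
    draws <- sample.int(n, batch_size * n_batches, replace = TRUE,
                        prob = weights)
    split(draws, rep(seq_len(n_batches), each = batch_size))
  })
}
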