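#' Weighted ensemble loss
#'
#' The ensemble objective is a weighted sum of the four member losses,
#' `alpha*L1 + beta*L2 + gamma*L3 + delta*L4`. With uniform weights it is
#' proportional to the mean member loss; it is also the per-record scoring
#' function used by the active-learning loop.
#'
#' @param member_losses numeric vector of 4 finite member losses.
#' @param loss_weights numeric vector of 4 nonnegative weights
#'   (`alpha, beta, gamma, delta`); default uniform 0.25.
#' @return Scalar weighted loss.
#' @export
ensemble_loss <- function(member_losses, loss_weights = rep(0.25, 4)) {
  if (length(member_losses) != 4L || length(loss_weights) != 4L)
    stopf("expected 4 member losses and 4 weights")
  if (!all(is.finite(member_losses))) stopf("member losses must be finite")
  if (any(loss_weights < 0)) stopf("loss weights must be >= 0")
  sum(loss_weights * member_losses)
}

#' Max-probability aggregation
#'
#' Elementwise maximum of the member probability vectors: each class is
#' scored by the most confident member. Used during the active-learning
#' phase.
#'
#' @param per_member_probs list of equal-length probability vectors (or a
#'   members x classes matrix).
#' @return Probability vector (elementwise maximum).
#' @export
aggregate_max_prob <- function(per_member_probs) {
  M <- as_prob_matrix(per_member_probs)
  if (any(M < 0 | M > 1)) stopf("probabilities must lie in [0, 1]")
  apply(M, 2L, max)
}

#' Mean-logit sigmoid aggregation
#'
#' The teacher/student inference rule: the sigmoid of the member-averaged
#' logits, elementwise.
#'
#' @param per_member_logits list of equal-length logit vectors (or a
#'   members x classes matrix).
#' @return Probability vector.
#' @export
aggregate_mean_sigmoid <- function(per_member_logits) {
  M <- as_prob_matrix(per_member_logits)
  if (!all(is.finite(M))) stopf("logits must be finite")
  sigmoid(colMeans(M))
}

as_prob_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  lens <- lengths(x)
  if (length(unique(lens)) != 1L) stopf("member vectors differ in length")
  do.call(rbind, x)
}

#' Top-3 decision rule
#'
#' The final classification decision: the indices of the three largest
#' probabilities (clips carry three installed tools). Ties break toward the
#' lower index; invariant under strictly monotone transforms of the scores.
#'
#' @param probs numeric vector of length >= 3.
#' @return Integer vector of 3 class indices, in decreasing score order.
#' @export
decide_top3 <- function(probs) {
  if (length(probs) < 3L) stopf("need at least 3 class scores")
  order(-probs, seq_along(probs))[1:3]
}

#' Label smoothing of a one-hot target
#'
#' Assigns probability `p` to the correct class and distributes the
#' remaining `1 - p` uniformly over the other `T - 1` classes.
#'
#' @param correct index of the correct class in `1..T`.
#' @param smoothing_p correct-class probability, `1/T < p <= 1`.
#' @param T number of classes.
#' @return Probability vector of length `T` summing to 1.
#' @export
smooth_targets <- function(correct, smoothing_p, T) {
  if (smoothing_p <= 1 / T) stopf("smoothing_p <= 1/T inverts the target")
  if (smoothing_p > 1) stopf("smoothing_p must be <= 1")
  if (correct < 1L || correct > T) stopf("correct class out of range")
  out <- rep((1 - smoothing_p) / (T - 1), T)
  out[correct] <- smoothing_p
  out
}

#' Fit a four-member classifier ensemble
#'
#' The central model object: four small image classifiers with different
#' feature views (see [default_members()]), trained independently on the
#' same records, combined at inference by max-probability or
#' mean-logit-sigmoid aggregation and monitored through the weighted
#' [ensemble_loss()].
#'
#' @param records nonempty list of [frame_record()]s.
#' @param vocab a [tool_vocabulary()].
#' @param members list of [member_spec()]s (default the standard four).
#' @param cfg a [train_config()].
#' @param loss_mode `"multilabel"` (per-class BCE, the default) or
#'   `"smoothed"` (label-smoothed softmax CE).
#' @param loss_weights ensemble loss weights `(alpha, beta, gamma, delta)`.
#' @param init optional `tool_ensemble` to warm-start member parameters
#'   from (transfer learning between pipeline stages).
#' @param freeze_body train heads only, keeping member bodies fixed.
#' @return An object of class `tool_ensemble` with components `members`
#'   (trained member models), `loss_weights`, `traces` (per-member epoch
#'   loss traces), `vocab` and `cfg`.
#' @export
fit_ensemble <- function(records, vocab, members = default_members(),
                         cfg = train_config(),
                         loss_mode = c("multilabel", "smoothed"),
                         loss_weights = rep(0.25, 4), init = NULL,
                         freeze_body = FALSE) {
  loss_mode <- match.arg(loss_mode)
  if (length(records) == 0L) stopf("no training records")
  if (length(members) != 4L) stopf("the ensemble has exactly 4 members")
  if (any(loss_weights < 0)) stopf("loss weights must be >= 0")
  n_out <- n_classes(vocab)
  # keep at least ~10 optimiser steps per epoch on small record sets:
  # epoch counts are calibrated against step counts, not sample counts
  cfg$batch_size <- min(cfg$batch_size,
                        max(8L, as.integer(ceiling(length(records) / 10))))
  fitted <- vector("list", 4L)
  traces <- vector("list", 4L)
  for (m in seq_len(4L)) {
    spec <- members[[m]]
    feats <- featurize_records(spec, records, cfg$resize_mode)
    model <- if (!is.null(init)) init$members[[m]] else
      with_seed(cfg$seed + m, init_member(spec, ncol(feats), n_out))
    mcfg <- cfg
    mcfg$seed <- cfg$seed + 1000L * m
    out <- train_member(model, records, mcfg, loss_mode = loss_mode,
                        freeze_body = freeze_body,
                        discriminative = !is.null(init), features = feats)
    fitted[[m]] <- out$model
    traces[[m]] <- out$trace
  }
  names(fitted) <- vapply(members, `[[`, character(1), "id")
  names(traces) <- names(fitted)
  structure(list(members = fitted, loss_weights = loss_weights,
                 traces = traces, vocab = vocab, cfg = cfg,
                 loss_mode = loss_mode),
            class = "tool_ensemble")
}

#' Predict from a tool ensemble
#'
#' @param object a `tool_ensemble`.
#' @param records list of [frame_record()]s.
#' @param type `"prob"` (aggregated probabilities), `"logit"` (per-member
#'   logit matrices), `"member_probs"` (per-member sigmoid probabilities) or
#'   `"top3"` (a records x classes binary matrix of top-3 decisions).
#' @param aggregate aggregation rule for `type = "prob"`/`"top3"`:
#'   `"mean_sigmoid"` (teacher/student inference) or `"max_prob"`
#'   (active-learning phase).
#' @param ... unused.
#' @return Matrix (records x classes) for `"prob"`/`"top3"`; a list of four
#'   matrices for the per-member types.
#' @export
predict.tool_ensemble <- function(object, records,
                                  type = c("prob", "top3", "logit",
                                           "member_probs"),
                                  aggregate = c("mean_sigmoid", "max_prob"),
                                  ...) {
  type <- match.arg(type)
  aggregate <- match.arg(aggregate)
  logits <- lapply(object$members, predict_member, records = records,
                   resize_mode = object$cfg$resize_mode)
  if (type == "logit") return(logits)
  if (type == "member_probs") return(lapply(logits, sigmoid))
  P <- if (aggregate == "mean_sigmoid") {
    sigmoid(Reduce(`+`, logits) / length(logits))
  } else {
    Reduce(pmax, lapply(logits, sigmoid))
  }
  colnames(P) <- object$vocab$names
  rownames(P) <- record_ids(records)
  if (type == "prob") return(P)
  B <- matrix(0L, nrow(P), ncol(P), dimnames = dimnames(P))
  for (i in seq_len(nrow(P))) B[i, decide_top3(P[i, ])] <- 1L
  B
}

#' @export
print.tool_ensemble <- function(x, ...) {
  cat("Four-member tool classification ensemble\n")
  cat(sprintf("  members: %s\n", paste(names(x$members), collapse = ", ")))
  cat(sprintf("  classes: %d (%s)\n", n_classes(x$vocab),
              if (!is.na(x$vocab$blank_index)) "incl. blank" else "no blank"))
  cat(sprintf("  loss mode: %s; loss weights: %s\n", x$loss_mode,
              paste(format(x$loss_weights), collapse = ", ")))
  invisible(x)
}

#' @export
summary.tool_ensemble <- function(object, ...) {
  tr <- vapply(object$traces, function(t)
    c(first = if (length(t)) t[1L] else NA_real_,
      last = if (length(t)) t[length(t)] else NA_real_), numeric(2))
  cat("Four-member tool classification ensemble\n")
  print(data.frame(member = names(object$members),
                   epochs = vapply(object$traces, length, integer(1)),
                   first_loss = tr["first", ], last_loss = tr["last", ],
                   row.names = NULL))
  invisible(object)
}

#' Plot member training loss traces
#'
#' @param x a `tool_ensemble`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.tool_ensemble <- function(x, ...) {
  tr <- x$traces[lengths(x$traces) > 0]
  if (length(tr) == 0L) {
    warning("no loss traces to plot")
    return(invisible(x))
  }
  L <- do.call(cbind, tr)
  graphics::matplot(L, type = "l", lty = 1, xlab = "epoch",
                    ylab = "mean loss", ...)
  graphics::legend("topright", legend = colnames(L), col = seq_len(ncol(L)),
                   lty = 1, bty = "n")
  invisible(x)
}

# Per-record ensemble scores: BCE of the max-prob aggregated output against
# each record's (noisy) labels -- the epistemic score used to rank pool
# records for annotation.
record_scores <- function(ensemble, records) {
  P <- predict(ensemble, records, type = "prob", aggregate = "max_prob")
  Y <- t(vapply(records, function(r) as.numeric(r$labels),
                numeric(n_classes(ensemble$vocab))))
  eps <- 1e-12
  -rowMeans(Y * log(P + eps) + (1 - Y) * log(1 - P + eps))
}
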