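#' Member model specifications
#'
#' Each ensemble member is a small image classifier: a fixed feature
#' extractor followed by a one-hidden-layer network whose hidden layer is
#' the "body" and whose final linear layer is the "head" (the unit of
#' head-only fine-tuning and body freezing). Scene content is colour-coded
#' and moves freely within the frame, so all four default members build on
#' position-invariant chromatic statistics -- four "model families" of
#' comparable strength whose errors decorrelate through genuinely
#' different pooling mechanisms:
#'
#' * `hue_hist`: saturation- and value-weighted global hue histogram
#'   (24 bins) plus intensity statistics, tanh body.
#' * `hue_presence`: per-bin *max*-pooled hue evidence -- a detector for
#'   "is this hue present anywhere", robust to glyph size, ReLU body.
#' * `quad_hue`: per-quadrant (2 x 2) hue histograms (12 bins each) --
#'   coarsely localised chromatic evidence, tanh body.
#' * `hue_fine`: fine 36-bin histogram under a square-root transform that
#'   amplifies small-area evidence, tanh body.
#'
#' @param id member identifier string.
#' @param extractor one of `"hue_hist"`, `"hue_presence"`, `"quad_hue"`,
#'   `"hue_fine"`.
#' @param hidden hidden-layer width.
#' @param activation `"tanh"` or `"relu"`.
#' @param bins histogram bins for the extractor.
#' @return A list of class `member_spec`.
#' @export
member_spec <- function(id, extractor, hidden = 24L,
                        activation = c("tanh", "relu"), bins = 24L) {
  structure(list(id = id, extractor = extractor, hidden = as.integer(hidden),
                 activation = match.arg(activation), bins = as.integer(bins)),
            class = "member_spec")
}

#' Default four-member architecture set
#'
#' @return List of four [member_spec()]s.
#' @export
default_members <- function() {
  list(
    member_spec("hue_hist", "hue_hist", hidden = 16L, activation = "tanh",
                bins = 24L),
    member_spec("hue_presence", "hue_presence", hidden = 24L,
                activation = "relu", bins = 24L),
    member_spec("quad_hue", "quad_hue", hidden = 24L, activation = "tanh",
                bins = 12L),
    member_spec("hue_fine", "hue_fine", hidden = 20L, activation = "tanh",
                bins = 36L)
  )
}

# Feature vector for one image under a member spec. `resize_mode` controls
# how off-aspect (e.g. cropped) images are conformed before pooling.
extract_features <- function(spec, img, resize_mode = "squish") {
  img <- conform_image(img, mode = resize_mode)
  switch(spec$extractor,
    hue_hist = {
      hsv <- rgb_to_hsv_mats(img)
      wgt <- hsv$s * hsv$v
      bin <- pmin(spec$bins, floor(hsv$h * spec$bins) + 1L)
      hist <- vapply(seq_len(spec$bins), function(b) sum(wgt[bin == b]),
                     numeric(1)) / length(wgt)
      c(hist, mean(hsv$v), stats::sd(as.vector(hsv$v)), mean(hsv$v < 0.05))
    },
    quad_hue = {
      hsv <- rgb_to_hsv_mats(img)
      wgt <- hsv$s * hsv$v
      bin <- pmin(floor(hsv$h * spec$bins) + 1L, spec$bins)  # keeps dim
      h <- nrow(wgt); w <- ncol(wgt)
      qr <- (seq_len(h) - 1L) < h / 2
      qc <- (seq_len(w) - 1L) < w / 2
      out <- numeric(0)
      for (rr in list(qr, !qr)) for (cc in list(qc, !qc)) {
        sub_w <- wgt[rr, cc]; sub_b <- bin[rr, cc]
        out <- c(out, vapply(seq_len(spec$bins), function(b)
          sum(sub_w[sub_b == b]), numeric(1)) / length(sub_w))
      }
      out
    },
    hue_presence = {
      hsv <- rgb_to_hsv_mats(img)
      wgt <- hsv$s * hsv$v
      bin <- pmin(floor(hsv$h * spec$bins) + 1L, spec$bins)
      pres <- vapply(seq_len(spec$bins), function(b) {
        m <- wgt[bin == b]
        if (length(m) == 0L) 0 else max(m)
      }, numeric(1))
      c(pres, mean(hsv$v), mean(hsv$v < 0.05))
    },
    hue_fine = {
      hsv <- rgb_to_hsv_mats(img)
      wgt <- hsv$s * hsv$v
      bin <- pmin(floor(hsv$h * spec$bins) + 1L, spec$bins)
      hist <- vapply(seq_len(spec$bins), function(b) sum(wgt[bin == b]),
                     numeric(1)) / length(wgt)
      c(sqrt(hist), mean(hsv$v), mean(hsv$v < 0.05))
    },
    stopf("unknown extractor '%s'", spec$extractor)
  )
}

# Feature matrix for a list of records (rows = records). Records may carry a
# per-member feature cache in $features (see cache_features()); cached rows
# are reused, so repeated inference over a stable pool costs one extraction.
featurize_records <- function(spec, records, resize_mode = "squish") {
  one <- function(r) {
    f <- r$features[[spec$id]]
    if (is.null(f)) f <- extract_features(spec, r$image, resize_mode)
    f
  }
  t(vapply(records, one, numeric(length(one(records[[1L]])))))
}

#' Precompute member features on a record list
#'
#' Attaches each member's feature vector to every record, so the repeated
#' inference passes of the annotation loop and the pipeline stages reuse
#' them instead of re-extracting from pixels. Safe across label changes:
#' the cache depends only on the image.
#'
#' @param records list of [frame_record()]s.
#' @param members list of [member_spec()]s.
#' @param resize_mode image conformation mode (see [train_config()]).
#' @return The records with a populated `$features` list.
#' @export
cache_features <- function(records, members = default_members(),
                           resize_mode = "squish") {
  lapply(records, function(r) {
    if (is.null(r$features)) r$features <- list()
    for (spec in members) {
      if (is.null(r$features[[spec$id]]))
        r$features[[spec$id]] <- extract_features(spec, r$image, resize_mode)
    }
    r
  })
}

#' Training configuration
#'
#' Defaults follow the study protocol at desk scale: batch size 64, learning
#' rate 1e-2 under a one-cycle schedule, 12 head-only epochs followed by 12
#' full-model epochs, squish resizing, and label-smoothing mass `p = 0.9`
#' on the correct classes when the smoothed loss is selected.
#'
#' @param batch_size minibatch size.
#' @param learning_rate peak learning rate of the one-cycle schedule.
#' @param head_epochs epochs with the body frozen (head-only).
#' @param full_epochs subsequent epochs training all parameters.
#' @param resize_mode `"squish"`, `"crop"` or `"pad"` (how off-aspect images
#'   are conformed before feature pooling).
#' @param smoothing_p correct-class probability for label smoothing,
#'   `0.5 < p <= 1`.
#' @param seed RNG seed for initialisation and batch shuffling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, learning_rate = 1e-2,
                         head_epochs = 12L, full_epochs = 12L,
                         resize_mode = c("squish", "crop", "pad"),
                         smoothing_p = 0.9, seed = 1L) {
  if (head_epochs < 0L || full_epochs < 0L) stopf("epochs must be >= 0")
  if (smoothing_p <= 0.5 || smoothing_p > 1)
    stopf("smoothing_p must lie in (0.5, 1]")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 head_epochs = as.integer(head_epochs),
                 full_epochs = as.integer(full_epochs),
                 resize_mode = match.arg(resize_mode),
                 smoothing_p = smoothing_p, seed = as.integer(seed)),
            class = "train_config")
}

# Initialise a member model's parameters for a given feature dimension.
init_member <- function(spec, n_features, n_out) {
  W1 <- matrix(stats::rnorm(n_features * spec$hidden, sd = 1 / sqrt(n_features)),
               n_features, spec$hidden)
  W2 <- matrix(stats::rnorm(spec$hidden * n_out, sd = 1 / sqrt(spec$hidden)),
               spec$hidden, n_out)
  structure(list(spec = spec, W1 = W1, b1 = numeric(spec$hidden),
                 W2 = W2, b2 = numeric(n_out),
                 feat_mean = numeric(n_features), feat_sd = rep(1, n_features),
                 n_out = as.integer(n_out)),
            class = "member_model")
}

member_activation <- function(spec, Z) {
  if (spec$activation == "relu") pmax(Z, 0) else tanh(Z)
}

member_activation_grad <- function(spec, Z, H) {
  if (spec$activation == "relu") (Z > 0) * 1 else 1 - H^2
}

# Forward pass to logits for a standardized feature matrix.
member_logits_std <- function(model, Xs) {
  Z <- sweep(Xs %*% model$W1, 2L, model$b1, "+")
  H <- member_activation(model$spec, Z)
  sweep(H %*% model$W2, 2L, model$b2, "+")
}

standardize_features <- function(model, X) {
  sweep(sweep(X, 2L, model$feat_mean, "-"), 2L, model$feat_sd, "/")
}

# Logits for raw records or a feature matrix.
predict_member <- function(model, records, resize_mode = "squish",
                           features = NULL) {
  X <- features %||% featurize_records(model$spec, records, resize_mode)
  member_logits_std(model, standardize_features(model, X))
}

# One-cycle learning-rate schedule: linear warmup over the first 30% of
# steps from peak/10 to peak, then linear anneal down to peak/100.
one_cycle_lr <- function(step, total, peak) {
  if (total <= 1L) return(peak)
  warm <- max(1, floor(0.3 * total))
  if (step <= warm) peak / 10 + (peak - peak / 10) * (step - 1) / max(1, warm - 1)
  else peak - (peak - peak / 100) * (step - warm) / max(1, total - warm)
}

#' Train one ensemble member
#'
#' Runs `head_epochs` epochs with the body (input-to-hidden layer) frozen,
#' then `full_epochs` epochs over all parameters -- unless `freeze_body` is
#' set, in which case every epoch is head-only. Minibatch SGD with momentum
#' under a one-cycle learning-rate schedule; deterministic for a fixed
#' `cfg$seed`.
#'
#' Two loss modes: `"multilabel"` is per-class binary cross-entropy on
#' sigmoid outputs (targets may be soft, e.g. teacher probabilities);
#' `"smoothed"` is softmax cross-entropy against label-smoothed target
#' distributions built from the records' label sets (see
#' [smooth_targets()]).
#'
#' @param model a `member_model` (from the internal initialiser or a
#'   previous training run; pass through [fit_ensemble()] for the usual
#'   entry point).
#' @param records nonempty list of [frame_record()]s.
#' @param cfg a [train_config()].
#' @param loss_mode `"multilabel"` or `"smoothed"`.
#' @param freeze_body keep all body parameters fixed in every epoch.
#' @param discriminative after unfreezing, use reduced discriminative peak
#'   rates (head `lr/4`, body `lr/400`) so a warm-started model is refined
#'   rather than overwritten. Appropriate when `model` carries transferred
#'   weights; a fresh random body needs the full rate.
#' @param features optional precomputed feature matrix (rows = records).
#' @return List with `model` (trained) and `trace` (mean loss per epoch;
#'   empty when zero epochs are requested).
#' @export
train_member <- function(model, records, cfg = train_config(),
                         loss_mode = c("multilabel", "smoothed"),
                         freeze_body = FALSE, discriminative = FALSE,
                         features = NULL) {
  loss_mode <- match.arg(loss_mode)
  if (length(records) == 0L) stopf("no training records")
  total_epochs <- cfg$head_epochs + cfg$full_epochs
  if (total_epochs == 0L) return(list(model = model, trace = numeric(0)))

  X <- features %||% featurize_records(model$spec, records, cfg$resize_mode)
  Y <- training_targets(records, model$n_out, loss_mode, cfg$smoothing_p)

  with_seed(cfg$seed, {
    # standardisation parameters are part of the (frozen) body: set them
    # only on a fresh model, never when fine-tuning an existing one
    if (all(model$feat_mean == 0) && all(model$feat_sd == 1)) {
      model$feat_mean <- colMeans(X)
      model$feat_sd <- pmax(apply(X, 2L, stats::sd), 1e-6)
    }
    Xs <- standardize_features(model, X)
    n <- nrow(Xs)
    steps_per_epoch <- max(1L, ceiling(n / cfg$batch_size))
    head_steps <- cfg$head_epochs * steps_per_epoch
    full_steps <- cfg$full_epochs * steps_per_epoch
    # Adam moments (fit-one-cycle pairs the one-cycle schedule with Adam)
    zero <- function(x) x * 0
    m1 <- list(W1 = zero(model$W1), b1 = zero(model$b1),
               W2 = zero(model$W2), b2 = zero(model$b2))
    m2 <- m1
    b1_ <- 0.9; b2_ <- 0.99; eps_ <- 1e-8
    trace <- numeric(total_epochs)
    step <- 0L
    for (e in seq_len(total_epochs)) {
      head_only <- freeze_body || e <= cfg$head_epochs
      ord <- sample.int(n)
      epoch_loss <- 0
      for (s in seq_len(steps_per_epoch)) {
        step <- step + 1L
        idx <- ord[((s - 1L) * cfg$batch_size + 1L):min(s * cfg$batch_size, n)]
        xb <- Xs[idx, , drop = FALSE]
        yb <- Y[idx, , drop = FALSE]
        Z1 <- sweep(xb %*% model$W1, 2L, model$b1, "+")
        H <- member_activation(model$spec, Z1)
        Z2 <- sweep(H %*% model$W2, 2L, model$b2, "+")
        if (loss_mode == "multilabel") {
          P <- sigmoid(Z2)
          eps <- 1e-12
          # mean over the batch, sum over classes
          loss <- -mean(rowSums(yb * log(P + eps) + (1 - yb) * log(1 - P + eps)))
          dZ2 <- (P - yb) / nrow(xb)
        } else {
          P <- softmax_rows(Z2)
          loss <- -mean(rowSums(yb * log(P + 1e-12)))
          dZ2 <- (P - yb) / nrow(xb)
        }
        epoch_loss <- epoch_loss + loss * length(idx)
        # one cycle per phase; with `discriminative`, the unfrozen phase
        # uses reduced peak rates (head lr/4, body lr/400) so a warm start
        # is refined rather than overwritten
        in_head_phase <- !freeze_body && e <= cfg$head_epochs
        if (freeze_body) {
          lr <- one_cycle_lr(step, head_steps + full_steps, cfg$learning_rate)
          lr_body <- 0
        } else if (in_head_phase) {
          lr <- one_cycle_lr(step, head_steps, cfg$learning_rate)
          lr_body <- 0
        } else {
          div <- if (discriminative) c(4, 400) else c(1, 1)
          lr <- one_cycle_lr(step - head_steps, full_steps,
                             cfg$learning_rate / div[1L])
          lr_body <- one_cycle_lr(step - head_steps, full_steps,
                                  cfg$learning_rate / div[2L])
        }
        adam <- function(name, grad, rate = lr) {
          m1[[name]] <<- b1_ * m1[[name]] + (1 - b1_) * grad
          m2[[name]] <<- b2_ * m2[[name]] + (1 - b2_) * grad^2
          mh <- m1[[name]] / (1 - b1_^step)
          vh <- m2[[name]] / (1 - b2_^step)
          model[[name]] <<- model[[name]] - rate * mh / (sqrt(vh) + eps_)
        }
        adam("W2", crossprod(H, dZ2))
        adam("b2", colSums(dZ2))
        if (!head_only) {
          dH <- dZ2 %*% t(model$W2)
          dZ1 <- dH * member_activation_grad(model$spec, Z1, H)
          adam("W1", crossprod(xb, dZ1), rate = lr_body)
          adam("b1", colSums(dZ1), rate = lr_body)
        }
      }
      trace[e] <- epoch_loss / n
    }
    list(model = model, trace = trace)
  })
}

# Target matrix for a record list. Multilabel: rows are binary (or soft,
# for pseudo records). Smoothed: label-smoothed distributions with total
# mass smoothing_p spread over the record's positive classes.
training_targets <- function(records, n_out, loss_mode, smoothing_p) {
  Y <- t(vapply(records, function(r) {
    if (!is.null(r$soft_labels)) as.numeric(r$soft_labels)
    else as.numeric(r$labels)
  }, numeric(n_out)))
  if (loss_mode == "smoothed") {
    Y <- t(apply(Y, 1L, function(y) {
      pos <- which(y >= 0.5)
      if (length(pos) == 0L) pos <- which.max(y)
      out <- rep((1 - smoothing_p) / (n_out - length(pos)), n_out)
      out[pos] <- smoothing_p / length(pos)
      out
    }))
  }
  Y
}
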