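# Ensemble loss, aggregation rules, label smoothing, member training.

test_that("ensemble loss is the weighted member-loss sum", {
  expect_equal(ensemble_loss(c(0.2, 0.4, 0.6, 0.8), rep(0.25, 4)), 0.5)
  expect_equal(ensemble_loss(c(0.3, 9, 9, 9), c(1, 0, 0, 0)), 0.3)
  # linearity: uniform weights and identical losses give 4 * w * L
  expect_equal(ensemble_loss(rep(0.7, 4), rep(1, 4)), 4 * 0.7)
  expect_error(ensemble_loss(c(1, 2, 3, 4), c(-1, 1, 1, 1)), "weight")
  expect_error(ensemble_loss(c(1, 2, 3), rep(0.25, 4)), "4")

  set.seed(20)
  for (i in 1:100) {
    l <- stats::runif(4); w <- stats::runif(4)
    expect_equal(ensemble_loss(l, w), sum(w * l), tolerance = 1e-12)
  }
})

test_that("max-prob aggregation is the elementwise member maximum", {
  members <- list(c(0.1, 0.9), c(0.8, 0.2), c(0.5, 0.5), c(0.3, 0.3))
  expect_equal(aggregate_max_prob(members), c(0.8, 0.9))
  same <- replicate(4, c(0.2, 0.6, 0.9), simplify = FALSE)
  expect_equal(aggregate_max_prob(same), c(0.2, 0.6, 0.9))
  expect_error(aggregate_max_prob(list(c(0.1), c(0.1, 0.2), c(0.3), c(0.4))),
               "length")

  set.seed(21)
  for (i in 1:100) {
    M <- matrix(stats::runif(4 * 15), 4, 15)
    agg <- aggregate_max_prob(M)
    brute <- vapply(1:15, function(j) max(M[, j]), numeric(1))
    expect_identical(agg, brute)
    expect_true(all(sweep(M, 2L, agg, "<=")))   # dominates every member
  }
})

test_that("mean-logit sigmoid aggregation matches the closed form", {
  z <- replicate(4, rep(0, 5), simplify = FALSE)
  expect_equal(aggregate_mean_sigmoid(z), rep(0.5, 5))
  z2 <- list(c(2, 2), c(-2, -2), c(2, 2), c(-2, -2))
  expect_equal(aggregate_mean_sigmoid(z2), c(0.5, 0.5))
  z3 <- replicate(4, rep(2, 3), simplify = FALSE)
  expect_equal(aggregate_mean_sigmoid(z3), rep(1 / (1 + exp(-2)), 3))
  expect_error(aggregate_mean_sigmoid(list(c(Inf, 0), c(0, 0), c(0, 0),
                                           c(0, 0))), "finite")

  set.seed(22)
  for (i in 1:50) {
    M <- matrix(stats::rnorm(4 * 10), 4, 10)
    agg <- aggregate_mean_sigmoid(M)
    sig <- 1 / (1 + exp(-M))
    # strictly between the member sigmoid extremes for non-degenerate logits
    expect_true(all(agg <= apply(sig, 2L, max) + 1e-12))
    expect_true(all(agg >= apply(sig, 2L, min) - 1e-12))
  }
})

test_that("top-3 decisions sort correctly, break ties low, ignore monotone maps", {
  expect_setequal(decide_top3(c(0.9, 0.1, 0.8, 0.7, 0.2)), c(1L, 3L, 4L))
  expect_equal(sort(decide_top3(rep(0.5, 6))), 1:3)
  expect_error(decide_top3(c(0.4, 0.6)), "3")

  set.seed(23)
  for (i in 1:100) {
    p <- stats::runif(15)
    brute <- sort(order(p, decreasing = TRUE)[1:3])
    expect_equal(sort(decide_top3(p)), brute)
    expect_equal(sort(decide_top3(stats::qlogis(p))), brute)  # monotone map
  }
})

test_that("label smoothing yields a valid soft distribution", {
  expect_equal(smooth_targets(1L, 0.9, 3L), c(0.9, 0.05, 0.05))
  expect_equal(smooth_targets(2L, 1, 4L), c(0, 1, 0, 0))
  s <- smooth_targets(5L, 0.9, 14L)
  expect_equal(s[5L], 0.9)
  expect_equal(unique(s[-5L]), 0.1 / 13)
  expect_equal(sum(s), 1, tolerance = 1e-12)
  expect_error(smooth_targets(1L, 1 / 14, 14L), "inverts")
  expect_error(smooth_targets(1L, 1.1, 3L), "<= 1")

  for (p in c(0.51, 0.7, 0.95, 1)) {
    s <- smooth_targets(3L, p, 10L)
    expect_true(all(s >= 0))
    expect_equal(sum(s), 1, tolerance = 1e-12)
    expect_equal(which.max(s), 3L)
  }
})

test_that("member training honours epoch, freeze and determinism contracts", {
  fx <- fx_separable()
  recs <- fx$records[1:120]
  spec <- default_members()[[2L]]
  X <- noisytools:::featurize_records(spec, recs)
  m0 <- noisytools:::with_seed(1, noisytools:::init_member(spec, ncol(X), 15L))

  # zero epochs: unchanged model, empty trace
  out0 <- train_member(m0, recs, train_config(head_epochs = 0L,
                                              full_epochs = 0L), features = X)
  expect_identical(out0$model, m0)
  expect_length(out0$trace, 0L)

  # training decreases the loss in trend
  cfg <- train_config(head_epochs = 2L, full_epochs = 6L, seed = 5L)
  out <- train_member(m0, recs, cfg, features = X)
  expect_lt(out$trace[length(out$trace)], out$trace[1L])

  # freeze contract: body parameters bit-identical
  outf <- train_member(out$model, recs, cfg, freeze_body = TRUE, features = X)
  expect_identical(outf$model$W1, out$model$W1)
  expect_identical(outf$model$b1, out$model$b1)
  expect_false(identical(outf$model$W2, out$model$W2))

  # seeded determinism
  out2 <- train_member(m0, recs, cfg, features = X)
  expect_identical(out$model, out2$model)
  expect_identical(out$trace, out2$trace)

  expect_error(train_member(m0, list(), cfg), "records")
})

test_that("a member reaches high macro-F1 on a separable fixture", {
  fx <- fx_separable()
  set.seed(31)
  recs <- fx$records[sample(length(fx$records), 200L)]
  spec <- default_members()[[2L]]
  X <- noisytools:::featurize_records(spec, recs)
  m0 <- noisytools:::with_seed(2, noisytools:::init_member(spec, ncol(X), 15L))
  # small batches: with 200 records the optimiser needs step count, not
  # epoch count
  out <- train_member(m0, recs, train_config(batch_size = 8L,
                                             head_epochs = 4L,
                                             full_epochs = 16L, seed = 6L),
                      features = X)
  P <- noisytools:::sigmoid(noisytools:::predict_member(out$model, recs,
                                                        features = X))
  Y <- noisytools:::truth_matrix(recs, fx$vocab)
  f1 <- macro_on_present(binarize(P), Y)[["mAF1"]]
  expect_gte(f1, 0.95)
})

test_that("fit_ensemble is reproducible and exposes the model surface", {
  fx <- fx_separable()
  recs <- fx$records[1:100]
  cfg <- train_config(head_epochs = 1L, full_epochs = 2L, seed = 9L)
  e1 <- fit_ensemble(recs, fx$vocab, cfg = cfg)
  e2 <- fit_ensemble(recs, fx$vocab, cfg = cfg)
  expect_identical(e1$members, e2$members)
  expect_length(e1$members, 4L)
  expect_output(print(e1), "Four-member")
  expect_output(summary(e1), "first_loss")
  P <- predict(e1, recs[1:5], type = "prob")
  expect_equal(dim(P), c(5L, 15L))
  expect_true(all(P >= 0 & P <= 1))
  B <- predict(e1, recs[1:5], type = "top3")
  expect_true(all(rowSums(B) == 3L))
})
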