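# Student-teacher self-training, pseudo-labelling, WDL fine-tuning.

# One shared small self-training run on the separable fixture.
fx_st <- function() {
  fixture("selftrain", function() {
    fx <- fx_noisy()
    ens <- fit_ensemble(fx$records, fx$vocab,
                        cfg = train_config(head_epochs = 2L, full_epochs = 4L,
                                           seed = 17L))
    oracle <- annotation_oracle(fx$dataset)
    al <- run_al(ens, fx$records, oracle, k = 150L, batch_size = 50L,
                 finetune_epochs = 5L, seed = 17L)
    teacher <- train_teacher(al$clean_train, al$clean_test, fx$vocab,
                             cfg = train_config(seed = 18L),
                             init = al$ensemble)
    pool <- fx$records[!noisytools:::record_ids(fx$records) %in%
                         al$state$clean_ids]
    pseudo <- pseudo_label_pool(teacher, pool, clean_ids = al$state$clean_ids)
    list(fx = fx, al = al, teacher = teacher, pool = pool, pseudo = pseudo)
  })
}

test_that("teacher training demands clean provenance and reproduces", {
  st <- fx_st()
  fx <- st$fx
  expect_error(train_teacher(fx$records[1:10], st$al$clean_test, fx$vocab),
               "provenance 'clean'")
  expect_s3_class(st$teacher, "stage_result")
  expect_equal(st$teacher$metrics$member,
               c("hue_hist", "hue_presence", "quad_hue", "hue_fine",
                 "Ensemble"))
  expect_true(all(st$teacher$metrics[, c("mAP", "mAR", "mAA", "mAF1")] >= 0 &
                  st$teacher$metrics[, c("mAP", "mAR", "mAA", "mAF1")] <= 1))

  t2 <- train_teacher(st$al$clean_train, st$al$clean_test, fx$vocab,
                      cfg = train_config(seed = 18L), init = st$al$ensemble)
  expect_identical(t2$metrics, st$teacher$metrics)
})

test_that("pseudo-labelling discards noisy labels and partitions the data", {
  st <- fx_st()
  expect_length(pseudo_label_pool(st$teacher, list()), 0L)
  expect_error(pseudo_label_pool(st$teacher, st$al$clean_records,
                                 clean_ids = st$al$state$clean_ids),
               "overlap")

  expect_length(st$pseudo, length(st$pool))
  for (r in st$pseudo[1:10]) {
    expect_equal(r$provenance, "pseudo")
    expect_length(r$soft_labels, 15L)
    expect_true(all(r$soft_labels >= 0 & r$soft_labels <= 1))
  }
  # data conservation: |pseudo pool| + |clean| = |D|
  expect_equal(length(st$pseudo) + length(st$al$clean_records),
               length(st$fx$records))

  # an all-zero-logit teacher emits 0.5 everywhere
  zero <- st$teacher$ensemble
  for (m in seq_along(zero$members)) {
    zero$members[[m]]$W2[] <- 0
    zero$members[[m]]$b2[] <- 0
  }
  p0 <- pseudo_label_pool(zero, st$pool[1:3])
  for (r in p0) expect_equal(unname(r$soft_labels), rep(0.5, 15L))

  # hard mode mirrors top-3 decisions into the binary labels
  ph <- pseudo_label_pool(st$teacher, st$pool[1:5],
                          pseudo_label_mode = "top3-hard")
  for (r in ph) expect_equal(sum(r$labels), 3L)
})

test_that("pseudo labels agree with visible truth more than noisy labels do", {
  st <- fx_st()
  oracle <- annotation_oracle(st$fx$dataset)
  v <- st$fx$vocab
  agree <- function(lab, truth) mean(lab == label_vector(truth, v))
  pseudo_agree <- 0; noisy_agree <- 0
  for (i in seq_along(st$pool)) {
    truth <- oracle$query(st$pool[[i]]$id)
    pseudo_agree <- pseudo_agree +
      agree(as.integer(st$pseudo[[i]]$soft_labels >= 0.5), truth)
    noisy_agree <- noisy_agree + agree(st$pool[[i]]$labels, truth)
  }
  expect_gt(pseudo_agree, noisy_agree)
})

test_that("student training and smoothing behave per contract", {
  st <- fx_st()
  fx <- st$fx
  cfg <- train_config(head_epochs = 2L, full_epochs = 2L, seed = 19L)
  expect_error(train_student(list(), st$al$clean_train, st$al$clean_test,
                             fx$vocab, cfg), "pseudo and clean")

  student <- train_student(st$pseudo, st$al$clean_train, st$al$clean_test,
                           fx$vocab, cfg, init = st$teacher$ensemble)
  expect_equal(student$method, "student")
  # student inference emits exactly 3 labels per record
  B <- predict(student$ensemble, st$al$clean_test, type = "top3")
  expect_true(all(rowSums(B) == 3L))

  smoothed <- train_student(st$pseudo, st$al$clean_train, st$al$clean_test,
                            fx$vocab, cfg, init = st$teacher$ensemble,
                            smoothing = TRUE)
  expect_equal(smoothed$method, "label smoothing")
  expect_false(identical(smoothed$metrics, student$metrics))
  # smoothing caps confidence: soft targets keep probabilities off 1
  Ps <- predict(smoothed$ensemble, st$al$clean_test, type = "prob")
  expect_lt(max(Ps), 1)
})

test_that("WDL fine-tuning freezes bodies and is the identity at 0 epochs", {
  st <- fx_st()
  student <- fixture("wdl_student", function() {
    st <- fx_st()
    train_student(st$pseudo, st$al$clean_train, st$al$clean_test,
                  st$fx$vocab, train_config(head_epochs = 2L,
                                            full_epochs = 2L, seed = 19L),
                  init = st$teacher$ensemble)
  })
  recs <- c(st$pseudo, st$al$clean_train)
  expect_identical(wdl_finetune(student$ensemble, recs, epochs = 0L),
                   student$ensemble)
  tuned <- wdl_finetune(student$ensemble, recs, epochs = 2L, seed = 4L)
  for (m in seq_along(tuned$members)) {
    expect_identical(tuned$members[[m]]$W1, student$ensemble$members[[m]]$W1)
    expect_identical(tuned$members[[m]]$b1, student$ensemble$members[[m]]$b1)
  }
  expect_false(identical(tuned$members[[1L]]$W2,
                         student$ensemble$members[[1L]]$W2))
})

test_that("clean test records never enter any training stage", {
  st <- fx_st()
  test_ids <- noisytools:::record_ids(st$al$clean_test)
  train_ids <- c(noisytools:::record_ids(st$al$clean_train),
                 noisytools:::record_ids(st$pseudo))
  expect_length(intersect(test_ids, train_ids), 0L)
})

test_that("the ensemble is competitive with its best member on clean data", {
  fx <- fx_separable()
  recs <- lapply(fx$records, function(r) { r$provenance <- "clean"; r })
  split <- noisytools:::clean_record_split(recs, fx$vocab, 0.8, seed = 7L)
  stage <- train_teacher(split$train, split$test, fx$vocab,
                         cfg = train_config(head_epochs = 4L,
                                            full_epochs = 8L, seed = 21L))
  tab <- stage$metrics
  best_member <- max(tab$mAF1[tab$member != "Ensemble"])
  expect_gte(tab$mAF1[tab$member == "Ensemble"], best_member - 0.02)
})
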