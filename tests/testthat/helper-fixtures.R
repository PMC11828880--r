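# Shared fixtures, built in code and memoised for the test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Small separable dataset: uniform prevalence, no dropout, a few black
# frames; preprocessed (cropped, relabelled, feature-cached) records.
fx_separable <- function() {
  fixture("separable", function() {
    vocab <- tool_vocabulary()
    cfg <- generator_config(n_clips = 40L, p_out = 0, p_black = 0.05,
                            prevalence = rep(1, 14), seed = 101L)
    ds <- generate_dataset(vocab, cfg)
    pc <- pipeline_config(generator = cfg, seed = 101L)
    prep <- noisytools:::preprocess_dataset(ds, pc)
    list(vocab = vocab, cfg = cfg, dataset = ds, records = prep$records,
         segmenter = prep$segmenter)
  })
}

# Small noisy dataset (Zipf prevalence, p_out = 0.3), preprocessed.
fx_noisy <- function() {
  fixture("noisy", function() {
    vocab <- tool_vocabulary()
    cfg <- generator_config(n_clips = 40L, p_out = 0.3, p_black = 0.05,
                            seed = 202L)
    ds <- generate_dataset(vocab, cfg)
    pc <- pipeline_config(generator = cfg, seed = 202L)
    prep <- noisytools:::preprocess_dataset(ds, pc)
    list(vocab = vocab, cfg = cfg, dataset = ds, records = prep$records,
         segmenter = prep$segmenter)
  })
}

# A quickly trained small ensemble on the separable records.
fx_sep_ensemble <- function() {
  fixture("sep_ensemble", function() {
    fx <- fx_separable()
    cfg <- train_config(head_epochs = 4L, full_epochs = 8L, seed = 303L)
    fit_ensemble(fx$records, fx$vocab, cfg = cfg)
  })
}

# Macro metrics of a binary prediction matrix against record labels,
# restricted to classes that occur (drops degenerate all-negative classes).
macro_on_present <- function(B, Y) {
  present <- colSums(Y) > 0
  macro_report(per_class_metrics(B[, present, drop = FALSE],
                                 Y[, present, drop = FALSE]))
}

# Dirty-dialect fuzzer for label strings: random canonical tools wrapped in
# random combinations of brackets/quotes/underscores/case noise.
fuzz_dirty_label <- function(vocab, n_tools = 3L) {
  tools <- sample(vocab$names[seq_len(vocab$n_tools)], n_tools)
  toks <- vapply(tools, function(x) {
    x <- gsub(" ", sample(c("_", " "), 1L), x)
    if (stats::runif(1) < 0.5)
      x <- paste0(toupper(substring(x, 1, 1)), substring(x, 2))
    if (stats::runif(1) < 0.5) x <- paste0("'", x, "'")
    if (stats::runif(1) < 0.3) x <- paste0("\"", x, "\"")
    x
  }, character(1))
  s <- paste(toks, collapse = ", ")
  if (stats::runif(1) < 0.7) s <- paste0("[", s, "]")
  if (stats::runif(1) < 0.3) s <- paste0(s, "\\")
  s
}
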