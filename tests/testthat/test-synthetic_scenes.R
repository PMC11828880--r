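# Synthetic clip generator: sampling, rendering, leakage, determinism.

mini_vocab <- function(n) {
  structure(list(names = letters[seq_len(n)], n_tools = n,
                 blank_index = NA_integer_),
            class = "tool_vocabulary")
}

test_that("vocabulary invariants hold", {
  v <- tool_vocabulary()
  expect_equal(v$n_tools, 14L)
  expect_equal(length(v$names), 15L)
  expect_equal(v$names[v$blank_index], "blank")
  expect_false(anyDuplicated(v$names) > 0)
  expect_false(any(grepl("[][_\"']|[A-Z]", v$names)))
  v0 <- tool_vocabulary(with_blank = FALSE)
  expect_equal(length(v0$names), 14L)
  expect_true(is.na(v0$blank_index))
})

test_that("sample_installed_tools covers the degenerate draws", {
  v <- mini_vocab(5L)
  cfg <- generator_config(tools_per_clip = 5L, prevalence = rep(1, 5))
  set.seed(1)
  expect_setequal(sample_installed_tools(v, cfg), v$names)

  cfg1 <- generator_config(tools_per_clip = 1L,
                           prevalence = c(1, rep(1e-12, 4)))
  set.seed(1)
  draws <- replicate(50, sample_installed_tools(v, cfg1))
  expect_true(all(draws == "a"))

  cfg_bad <- generator_config(tools_per_clip = 6L, prevalence = rep(1, 5))
  expect_error(sample_installed_tools(v, cfg_bad), "tools_per_clip")
})

test_that("inclusion frequencies match brute-force without-replacement marginals", {
  # oracle: enumerate ordered draws for successive weighted sampling
  # without replacement and accumulate inclusion probabilities
  inclusion_probs <- function(p, k) {
    n <- length(p)
    inc <- numeric(n)
    recurse <- function(remaining, prob, chosen) {
      if (length(chosen) == k) {
        inc[chosen] <<- inc[chosen] + prob
        return(invisible())
      }
      for (i in remaining) {
        recurse(setdiff(remaining, i),
                prob * p[i] / sum(p[remaining]), c(chosen, i))
      }
    }
    recurse(seq_len(n), 1, integer(0))
    inc
  }
  v <- mini_vocab(5L)
  p <- (1:5)^(-1.5); p <- p / sum(p)
  cfg <- generator_config(tools_per_clip = 2L, prevalence = p)
  expected <- inclusion_probs(p, 2L)
  n_draws <- 10000L
  set.seed(42)
  counts <- table(factor(unlist(
    replicate(n_draws, sample_installed_tools(v, cfg), simplify = FALSE)),
    levels = v$names))
  for (i in 1:5) {
    sd_i <- sqrt(n_draws * expected[i] * (1 - expected[i]))
    expect_lt(abs(counts[[i]] - n_draws * expected[i]), 3 * sd_i)
  }
})

test_that("clip generation honours the dropout and black-frame contracts", {
  v <- tool_vocabulary()
  cfg0 <- generator_config(frames_per_clip = 10L, p_out = 0, p_black = 0,
                           image_height = 36L, image_width = 64L,
                           banner_height = 4L)
  set.seed(3)
  clip <- generate_clip(v, cfg0, "c1")
  expect_s3_class(clip, "surg_clip")
  expect_length(clip$label_set, 3L)
  expect_length(clip$truths, 10L)
  for (t in clip$truths) expect_setequal(t$visible_tools, clip$label_set)

  cfg1 <- generator_config(frames_per_clip = 10L, p_out = 1, p_black = 0,
                           image_height = 36L, image_width = 64L,
                           banner_height = 4L)
  set.seed(3)
  clip1 <- generate_clip(v, cfg1, "c2")
  expect_length(clip1$label_set, 3L)
  for (t in clip1$truths) expect_length(t$visible_tools, 0L)

  cfg_bad <- generator_config(frames_per_clip = 0L)
  set.seed(3)
  expect_error(generate_clip(v, cfg_bad, "c3"), "frames_per_clip")
})

test_that("realised dropout rate converges to p_out at binomial tolerance", {
  v <- tool_vocabulary()
  cfg <- generator_config(n_clips = 3L, frames_per_clip = 200L, p_out = 0.3,
                          p_black = 0, image_height = 36L, image_width = 64L,
                          banner_height = 4L, seed = 5L)
  ds <- generate_dataset(v, cfg)
  invisible_pairs <- 0L; installed_pairs <- 0L
  for (clip in ds$clips) {
    for (t in clip$truths) {
      installed_pairs <- installed_pairs + length(clip$label_set)
      invisible_pairs <- invisible_pairs +
        sum(!clip$label_set %in% t$visible_tools)
    }
  }
  sd3 <- 3 * sqrt(installed_pairs * 0.3 * 0.7)
  expect_lt(abs(invisible_pairs - installed_pairs * 0.3), sd3)
})

test_that("the banner leaks the installed label set on every non-black frame", {
  fx <- fx_noisy()
  ok <- TRUE
  for (clip in fx$dataset$clips) {
    for (f in seq_along(clip$frames)) {
      if (clip$truths[[f]]$is_black) {
        ok <- ok && identical(banner_read_labels(clip$frames[[f]], fx$vocab),
                              character(0))
      } else {
        ok <- ok && setequal(banner_read_labels(clip$frames[[f]], fx$vocab),
                             clip$label_set)
      }
    }
  }
  expect_true(ok)
})

test_that("dataset generation is deterministic and standardisation round-trips", {
  v <- tool_vocabulary()
  cfg <- generator_config(n_clips = 6L, frames_per_clip = 4L,
                          image_height = 36L, image_width = 64L,
                          banner_height = 4L, seed = 9L)
  ds1 <- generate_dataset(v, cfg)
  ds2 <- generate_dataset(v, cfg)
  expect_identical(ds1$manifest, ds2$manifest)
  expect_identical(lapply(ds1$clips, `[[`, "frames"),
                   lapply(ds2$clips, `[[`, "frames"))

  # empty dataset
  ds0 <- generate_dataset(v, generator_config(n_clips = 0L))
  expect_length(ds0$clips, 0L)
  expect_equal(nrow(ds0$manifest), 0L)

  # raw manifest strings round-trip to each clip's label set
  for (clip in ds1$clips) {
    raw <- ds1$manifest$raw_label_string[ds1$manifest$clip_id == clip$clip_id][1L]
    expect_setequal(standardize_label(raw, v), clip$label_set)
  }
  combos <- unique(vapply(ds1$clips, function(c)
    noisytools:::combo_key(c$label_set), character(1)))
  expect_lte(length(combos), choose(14, 3))
})

test_that("PNG round trip preserves pixel data byte for byte", {
  v <- tool_vocabulary()
  cfg <- generator_config(n_clips = 2L, frames_per_clip = 3L,
                          image_height = 36L, image_width = 64L,
                          banner_height = 4L, seed = 10L)
  ds <- generate_dataset(v, cfg)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  write_dataset(ds, d1)
  write_dataset(generate_dataset(v, cfg), d2)
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  back <- read_dataset(d1, v, read_truth = TRUE)
  expect_length(back$clips, 2L)
  expect_setequal(back$clips[[1L]]$label_set, ds$clips[[1L]]$label_set)
  # 8-bit quantisation: pixels match to 1/255
  expect_lt(max(abs(back$clips[[1L]]$frames[[1L]] - ds$clips[[1L]]$frames[[1L]])),
            1 / 255)
  unlink(c(d1, d2), recursive = TRUE)
})
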