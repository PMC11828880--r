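#' Configuration for the synthetic clip generator
#'
#' The generator emulates the structure of clip-annotated endoscopic video
#' at desk scale: each clip carries one set of installed tools (the
#' clip-level annotation), but on any given frame each installed tool is
#' independently out of the field of view with probability `p_out` -- the
#' label-noise mechanism that arises when clip-level labels are extrapolated
#' to frames. A UI banner strip at the bottom of every frame deterministically
#' encodes the *installed* (not the visible) tools, the label-leakage
#' channel. Frames are fully black (scene blanked, banner persists) with
#' probability `p_black`. Tool prevalence is long-tailed (Zipf by default).
#'
#' @param n_clips number of clips.
#' @param frames_per_clip frames per clip.
#' @param tools_per_clip installed tools per clip (the clip label set size).
#' @param image_height,image_width frame size in pixels; the default 72 x 128
#'   preserves the 16:9 aspect of the source videos.
#' @param prevalence per-tool sampling weight vector of length `n_tools`;
#'   positive, normalised internally. Default: Zipf with exponent `zipf_s`.
#' @param zipf_s Zipf exponent used when `prevalence` is `NULL`.
#' @param p_out probability that an installed tool is out of view on a frame.
#' @param p_black probability that a frame is fully black.
#' @param banner_height height in pixels of the leakage banner strip.
#' @param seed integer seed controlling the whole dataset draw.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_clips = 200L, frames_per_clip = 20L,
                             tools_per_clip = 3L,
                             image_height = 72L, image_width = 128L,
                             prevalence = NULL, zipf_s = 1.5,
                             p_out = 0.3, p_black = 0.05,
                             banner_height = 8L, seed = 1L) {
  if (n_clips < 0L) stopf("n_clips must be >= 0")
  if (p_out < 0 || p_out > 1 || p_black < 0 || p_black >= 1)
    stopf("p_out must lie in [0, 1] and p_black in [0, 1)")
  if (banner_height < 1L || banner_height >= image_height)
    stopf("banner_height must lie in [1, image_height)")
  cfg <- list(
    n_clips = as.integer(n_clips),
    frames_per_clip = as.integer(frames_per_clip),
    tools_per_clip = as.integer(tools_per_clip),
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    prevalence = prevalence, zipf_s = zipf_s,
    p_out = p_out, p_black = p_black,
    banner_height = as.integer(banner_height),
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  cfg
}

resolve_prevalence <- function(cfg, vocab) {
  p <- cfg$prevalence
  if (is.null(p)) p <- (seq_len(vocab$n_tools))^(-cfg$zipf_s)
  if (length(p) != vocab$n_tools)
    stopf("prevalence must have length %d", vocab$n_tools)
  if (any(p <= 0)) stopf("prevalence entries must be > 0")
  p / sum(p)
}

#' Sample the installed tool set for one clip
#'
#' Draws `tools_per_clip` distinct tools without replacement, successively
#' proportional to the prevalence weights (the long-tail mechanism behind the
#' heavily imbalanced tool frequencies).
#'
#' Uses the current RNG state; seed via [with_seed()]-style wrappers or
#' `set.seed()` for reproducibility.
#'
#' @param vocab a [tool_vocabulary()].
#' @param cfg a [generator_config()].
#' @return Character vector of `tools_per_clip` distinct canonical names.
#' @export
sample_installed_tools <- function(vocab, cfg) {
  if (cfg$tools_per_clip > vocab$n_tools)
    stopf("tools_per_clip (%d) exceeds number of tools (%d)",
          cfg$tools_per_clip, vocab$n_tools)
  p <- resolve_prevalence(cfg, vocab)
  idx <- sample.int(vocab$n_tools, cfg$tools_per_clip, replace = FALSE, prob = p)
  vocab$names[idx]
}

# --- glyph rendering ---------------------------------------------------------

# Each tool renders as a class-unique (polygon family, hue) pair so that
# classes are learnable by small models while remaining visually distinct.
glyph_table <- function(vocab) {
  shapes <- rep(c("disc", "square", "triangle", "diamond", "ring", "cross", "bar"),
                length.out = vocab$n_tools)
  data.frame(
    tool = vocab$names[seq_len(vocab$n_tools)],
    shape = shapes,
    hue = (seq_len(vocab$n_tools) - 1) / vocab$n_tools,
    stringsAsFactors = FALSE
  )
}

# Paint one glyph onto img (in place value semantics: returns modified copy).
render_glyph <- function(img, shape, hue, cy, cx, radius, angle) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  r0 <- max(1L, floor(cy - radius - 1)); r1 <- min(h, ceiling(cy + radius + 1))
  c0 <- max(1L, floor(cx - radius - 1)); c1 <- min(w, ceiling(cx + radius + 1))
  ys <- r0:r1; xs <- c0:c1
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- cos(angle) * dx + sin(angle) * dy
  v <- -sin(angle) * dx + cos(angle) * dy
  m <- switch(shape,
    disc = u^2 + v^2 <= radius^2,
    square = pmax(abs(u), abs(v)) <= 0.8 * radius,
    diamond = abs(u) + abs(v) <= radius,
    ring = {
      d2 <- u^2 + v^2
      d2 <= radius^2 & d2 >= (0.55 * radius)^2
    },
    cross = (abs(u) <= 0.35 * radius & abs(v) <= radius) |
            (abs(v) <= 0.35 * radius & abs(u) <= radius),
    bar = abs(u) <= radius & abs(v) <= 0.3 * radius,
    triangle = {
      # equilateral triangle, vertices at angles 90/210/330 degrees
      a <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
      px <- radius * cos(a); py <- radius * sin(a)
      inside <- matrix(TRUE, length(ys), length(xs))
      for (k in 1:3) {
        k2 <- if (k == 3) 1 else k + 1
        ex <- px[k2] - px[k]; ey <- py[k2] - py[k]
        inside <- inside & (ex * (v - py[k]) - ey * (u - px[k]) <= 0)
      }
      inside
    },
    stopf("unknown glyph shape '%s'", shape)
  )
  col <- hsv_to_rgb1(hue, 1, 1)
  for (ch in 1:3) {
    plane <- img[ys, xs, ch]
    plane[m] <- col[ch]
    img[ys, xs, ch] <- plane
  }
  img
}

# Banner geometry: tool i occupies an equal-width column cell; installed tools
# get a bright central mark in their cell. Deterministic by construction --
# this is the leakage channel that mirrors a device UI reflecting installation.
banner_cells <- function(vocab, width) {
  t_n <- vocab$n_tools
  lo <- floor((seq_len(t_n) - 1L) * width / t_n) + 1L
  hi <- floor(seq_len(t_n) * width / t_n)
  cbind(lo, hi)
}

BANNER_BG <- 0.04
BANNER_MARK_V <- 0.4

render_banner <- function(img, installed, vocab, banner_height) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  rows <- (h - banner_height + 1L):h
  img[rows, , ] <- BANNER_BG
  cells <- banner_cells(vocab, w)
  gt <- glyph_table(vocab)
  mark_rows <- rows[ceiling(banner_height * 0.2):ceiling(banner_height * 0.8)]
  for (tool in installed) {
    i <- match(tool, vocab$names)
    lo <- cells[i, 1L]; hi <- cells[i, 2L]
    span <- hi - lo + 1L
    cols <- (lo + ceiling(span * 0.2)):(lo + floor(span * 0.8))
    col <- hsv_to_rgb1(gt$hue[i], 1, BANNER_MARK_V)
    for (ch in 1:3) img[mark_rows, cols, ch] <- col[ch]
  }
  img
}

#' Read the clip label set straight off the leakage banner
#'
#' A trivial banner-reading "classifier": decodes the per-tool marks in the
#' bottom banner strip of a frame. On uncropped synthetic frames this
#' recovers the installed label set perfectly, which is exactly why the
#' banner is a label-leakage hazard; after dynamic cropping the bottom rows
#' are scene content and the decode collapses.
#'
#' @param frame image array (any height; the bottom `banner_height` rows are
#'   read).
#' @param vocab a [tool_vocabulary()].
#' @param banner_height banner strip height in pixels.
#' @param threshold mark-brightness decision threshold.
#' @return Character vector of decoded tool names (possibly empty).
#' @export
banner_read_labels <- function(frame, vocab, banner_height = 8L, threshold = 0.2) {
  h <- dim(frame)[1L]; w <- dim(frame)[2L]
  if (h < banner_height) return(character(0))
  rows <- (h - banner_height + 1L):h
  mark_rows <- rows[ceiling(banner_height * 0.2):ceiling(banner_height * 0.8)]
  cells <- banner_cells(vocab, w)
  out <- character(0)
  for (i in seq_len(vocab$n_tools)) {
    lo <- cells[i, 1L]; hi <- cells[i, 2L]
    span <- hi - lo + 1L
    cols <- (lo + ceiling(span * 0.2)):(lo + floor(span * 0.8))
    cell <- frame[mark_rows, cols, , drop = FALSE]
    if (max(apply(cell, 3L, mean)) > threshold) out <- c(out, vocab$names[i])
  }
  out
}

# --- clip / dataset generation ----------------------------------------------

SCENE_BG <- c(0.35, 0.2, 0.16)  # dark tissue-like background
SCENE_NOISE_SD <- 0.03

#' Generate one synthetic clip
#'
#' Samples the clip's installed tool set, then renders `frames_per_clip`
#' frames. Per frame, each installed tool is visible with probability
#' `1 - p_out` (rendered as its class-unique glyph at random position, scale
#' and rotation); the frame is fully black with probability `p_black` (scene
#' blanked, banner persists); the banner always encodes the installed set.
#' Hidden per-frame ground truth (`visible_tools`, `is_black`,
#' `foreground_box`) is recorded alongside.
#'
#' Uses the current RNG state (see [generate_dataset()] for the seeded
#' entry point).
#'
#' @param vocab a [tool_vocabulary()].
#' @param cfg a [generator_config()].
#' @param clip_id clip identifier string.
#' @return A list of class `surg_clip` with `clip_id`, `frames` (list of
#'   h x w x 3 arrays in `[0, 1]`), `label_set`, and `truths` (one list per
#'   frame). `foreground_box` is a half-open 0-based rectangle
#'   `(row_start, row_end, col_start, col_end)`, origin top-left, excluding
#'   the banner rows.
#' @export
generate_clip <- function(vocab, cfg, clip_id) {
  if (cfg$frames_per_clip < 1L) stopf("frames_per_clip must be >= 1")
  installed <- sample_installed_tools(vocab, cfg)
  h <- cfg$image_height; w <- cfg$image_width; bh <- cfg$banner_height
  gt <- glyph_table(vocab)
  fg_box <- c(row_start = 0L, row_end = h - bh, col_start = 0L, col_end = w)
  frames <- vector("list", cfg$frames_per_clip)
  truths <- vector("list", cfg$frames_per_clip)
  for (f in seq_len(cfg$frames_per_clip)) {
    is_black <- stats::runif(1) < cfg$p_black
    if (is_black) {
      # fully black: nothing rendered, banner included (lens removed)
      img <- array(0, dim = c(h, w, 3))
      visible <- character(0)
    } else {
      img <- array(0, dim = c(h, w, 3))
      for (ch in 1:3) {
        img[, , ch] <- pmin(1, pmax(0,
          SCENE_BG[ch] + stats::rnorm(h * w, sd = SCENE_NOISE_SD)))
      }
      visible <- installed[stats::runif(length(installed)) >= cfg$p_out]
      for (tool in visible) {
        i <- match(tool, vocab$names)
        radius <- stats::runif(1, 6, 12)
        cy <- stats::runif(1, radius + 1, (h - bh) - radius - 1)
        cx <- stats::runif(1, radius + 1, w - radius - 1)
        angle <- stats::runif(1, 0, 2 * pi)
        img <- render_glyph(img, gt$shape[i], gt$hue[i], cy, cx, radius, angle)
      }
      img <- render_banner(img, installed, vocab, bh)
    }
    frames[[f]] <- img
    truths[[f]] <- list(visible_tools = visible, is_black = is_black,
                        foreground_box = fg_box)
  }
  structure(list(clip_id = clip_id, frames = frames,
                 label_set = installed, truths = truths),
            class = "surg_clip")
}

# Write a label set in the raw "dirty" annotation dialect (brackets, quotes,
# underscores, capitalised first letter) that the standardisation stage must
# undo.
dirty_label_string <- function(labels) {
  toks <- vapply(labels, function(x) {
    x <- gsub(" ", "_", x)
    paste0(toupper(substring(x, 1L, 1L)), substring(x, 2L))
  }, character(1))
  paste0("['", paste(toks, collapse = "', '"), "']")
}

#' Generate a clip-structured synthetic dataset
#'
#' Seeded, fully deterministic: identical `cfg` (including `cfg$seed`)
#' reproduces identical pixel data, manifest and ground truth.
#'
#' @param vocab a [tool_vocabulary()].
#' @param cfg a [generator_config()].
#' @return A list of class `surg_dataset` with `clips`, a per-frame `manifest`
#'   data frame (`clip_id`, `frame_index`, `raw_label_string` -- the label
#'   written in the dirty annotation dialect), a hidden-`truth` data frame
#'   (`clip_id`, `frame_index`, `visible_tools`, `is_black`, box columns),
#'   plus `vocab` and `cfg`.
#' @export
generate_dataset <- function(vocab, cfg) {
  with_seed(cfg$seed, {
    clips <- vector("list", cfg$n_clips)
    man <- vector("list", cfg$n_clips)
    tru <- vector("list", cfg$n_clips)
    for (j in seq_len(cfg$n_clips)) {
      id <- sprintf("clip_%04d", j)
      clip <- generate_clip(vocab, cfg, id)
      clips[[j]] <- clip
      raw <- dirty_label_string(clip$label_set)
      man[[j]] <- data.frame(
        clip_id = id, frame_index = seq_along(clip$frames) - 1L,
        raw_label_string = raw, stringsAsFactors = FALSE)
      tru[[j]] <- data.frame(
        clip_id = id, frame_index = seq_along(clip$frames) - 1L,
        visible_tools = vapply(clip$truths, function(t)
          paste(t$visible_tools, collapse = ";"), character(1)),
        is_black = vapply(clip$truths, function(t) t$is_black, logical(1)),
        row_start = vapply(clip$truths, function(t) t$foreground_box[["row_start"]], integer(1)),
        row_end = vapply(clip$truths, function(t) t$foreground_box[["row_end"]], integer(1)),
        col_start = vapply(clip$truths, function(t) t$foreground_box[["col_start"]], integer(1)),
        col_end = vapply(clip$truths, function(t) t$foreground_box[["col_end"]], integer(1)),
        stringsAsFactors = FALSE)
    }
    manifest <- if (cfg$n_clips > 0L) do.call(rbind, man) else
      data.frame(clip_id = character(0), frame_index = integer(0),
                 raw_label_string = character(0))
    truth <- if (cfg$n_clips > 0L) do.call(rbind, tru) else NULL
    structure(list(clips = clips, manifest = manifest, truth = truth,
                   vocab = vocab, cfg = cfg),
              class = "surg_dataset")
  })
}

#' @export
print.surg_dataset <- function(x, ...) {
  cat(sprintf("Synthetic clip dataset: %d clips x %d frames (%dx%d px), p_out=%.2f, p_black=%.2f\n",
              x$cfg$n_clips, x$cfg$frames_per_clip, x$cfg$image_height,
              x$cfg$image_width, x$cfg$p_out, x$cfg$p_black))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Frames are written as PNG under `dir/<clip_id>/frame_<index>.png`; the
#' manifest and the hidden ground truth as CSV. The truth CSV is never read
#' by the training path except through the annotation oracle.
#'
#' @param dataset a `surg_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (clip in dataset$clips) {
    cdir <- file.path(dir, clip$clip_id)
    dir.create(cdir, showWarnings = FALSE)
    for (f in seq_along(clip$frames)) {
      png::writePNG(clip$frames[[f]],
                    file.path(cdir, sprintf("frame_%03d.png", f - 1L)))
    }
  }
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  if (!is.null(dataset$truth))
    utils::write.csv(dataset$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.csv` and clip subdirs.
#' @param vocab a [tool_vocabulary()].
#' @param read_truth also load `truth.csv` when present (oracle use only).
#' @return A `surg_dataset` (without `cfg`; `truth` is `NULL` unless
#'   `read_truth = TRUE`). `label_set` on each clip is recovered by
#'   [standardize_label()] from the raw manifest strings.
#' @export
read_dataset <- function(dir, vocab, read_truth = FALSE) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  clips <- lapply(split(manifest, manifest$clip_id), function(m) {
    m <- m[order(m$frame_index), ]
    frames <- lapply(m$frame_index, function(i) {
      a <- png::readPNG(file.path(dir, m$clip_id[1L], sprintf("frame_%03d.png", i)))
      if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
      a[, , 1:3, drop = FALSE]
    })
    structure(list(clip_id = m$clip_id[1L], frames = frames,
                   label_set = standardize_label(m$raw_label_string[1L], vocab),
                   truths = NULL),
              class = "surg_clip")
  })
  clips <- clips[order(names(clips))]
  names(clips) <- NULL
  truth <- if (read_truth && file.exists(file.path(dir, "truth.csv")))
    utils::read.csv(file.path(dir, "truth.csv"), stringsAsFactors = FALSE)
  else NULL
  structure(list(clips = clips, manifest = manifest, truth = truth,
                 vocab = vocab, cfg = NULL),
            class = "surg_dataset")
}
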