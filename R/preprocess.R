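#' Frame records
#'
#' A frame record couples one image with its binary label vector over the
#' vocabulary and a provenance tag: `noisy` (extrapolated clip label),
#' `clean` (human/oracle corrected) or `pseudo` (teacher-generated). Pseudo
#' records additionally carry soft probability labels.
#'
#' @param image h x w x 3 array in `[0, 1]`.
#' @param clip_id,frame_index provenance of the frame within its clip.
#' @param labels 0/1 integer vector over `vocab$names`.
#' @param provenance one of `"noisy"`, `"clean"`, `"pseudo"`.
#' @param soft_labels optional probability vector (required iff
#'   `provenance = "pseudo"`).
#' @return A list of class `frame_record`; `$id` is `"<clip_id>:<frame_index>"`.
#' @export
frame_record <- function(image, clip_id, frame_index, labels,
                         provenance = c("noisy", "clean", "pseudo"),
                         soft_labels = NULL) {
  provenance <- match.arg(provenance)
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be binary")
  if ((provenance == "pseudo") != !is.null(soft_labels))
    stopf("soft_labels must be present iff provenance is 'pseudo'")
  if (!is.null(soft_labels) && (any(soft_labels < 0) || any(soft_labels > 1)))
    stopf("soft_labels must lie in [0, 1]")
  structure(list(image = image, clip_id = clip_id,
                 frame_index = as.integer(frame_index),
                 id = paste0(clip_id, ":", frame_index),
                 labels = as.integer(labels), provenance = provenance,
                 soft_labels = soft_labels),
            class = "frame_record")
}

record_ids <- function(records) vapply(records, `[[`, character(1), "id")

#' Standardise a raw tool-label string
#'
#' Undoes the dirty annotation dialect: strips brackets, quotes, hyphens and
#' slashes, replaces underscores with spaces, lowercases, collapses repeated
#' whitespace, then splits on `delimiter` and validates every token against
#' the vocabulary. Idempotent: applying it to its own output is a no-op.
#'
#' @param raw a raw label string, e.g. `"['Needle_driver', 'Stapler']"`.
#' @param vocab a [tool_vocabulary()].
#' @param delimiter token separator (default comma).
#' @return Character vector of canonical tool names (a set: unique, in order
#'   of first appearance).
#' @export
standardize_label <- function(raw, vocab, delimiter = ",") {
  s <- gsub("[][\"'\\\\/-]", "", raw)
  s <- gsub("_", " ", s)
  s <- tolower(s)
  toks <- strsplit(s, delimiter, fixed = TRUE)[[1L]]
  toks <- gsub("[[:space:]]+", " ", trimws(toks))
  toks <- toks[nzchar(toks)]
  unknown <- setdiff(toks, vocab$names)
  if (length(unknown) > 0L)
    stopf("unknown tool label token(s) after cleaning: %s",
          paste(sQuote(unknown), collapse = ", "))
  unique(toks)
}

#' Keyframe extraction by temporal resampling + greedy scene-change filter
#'
#' First uniformly subsamples the clip from `source_fps` to `target_fps`,
#' then greedily keeps frames whose mean absolute pixel difference from the
#' last kept frame exceeds `diff_threshold`, capped at `max_keyframes`. The
#' first retained frame is always kept. Defaults follow the study protocol
#' of resampling to 10 Hz and keeping about twenty keyframes per clip.
#'
#' @param clip a `surg_clip` (or a plain list of frame arrays).
#' @param source_fps,target_fps frame rates; `source_fps >= target_fps >= 1`.
#' @param max_keyframes cap on retained keyframes.
#' @param diff_threshold mean-absolute-difference threshold in `[0, 1]` units.
#' @return Strictly increasing integer vector of frame indices (1-based into
#'   the clip's frame list).
#' @export
extract_keyframes <- function(clip, source_fps = 60, target_fps = 10,
                              max_keyframes = 20L, diff_threshold = 10 / 255) {
  frames <- if (inherits(clip, "surg_clip")) clip$frames else clip
  if (length(frames) == 0L) stopf("empty clip")
  if (source_fps < target_fps || target_fps < 1)
    stopf("need source_fps >= target_fps >= 1")
  stride <- max(1L, as.integer(round(source_fps / target_fps)))
  cand <- seq(1L, length(frames), by = stride)
  kept <- cand[1L]
  last <- frames[[cand[1L]]]
  for (i in cand[-1L]) {
    if (length(kept) >= max_keyframes) break
    d <- mean(abs(frames[[i]] - last))
    if (d > diff_threshold) {
      kept <- c(kept, i)
      last <- frames[[i]]
    }
  }
  kept[seq_len(min(length(kept), max_keyframes))]
}

#' Relabel black frames to the blank class
#'
#' Frames whose mean intensity falls below `intensity_threshold` have their
#' tool labels cleared and replaced by the `blank` class; all other records
#' are returned unchanged. Absorbing black frames into a dedicated class
#' (rather than discarding them) lets the classifier recognise lens-out
#' frames explicitly.
#'
#' @param records list of [frame_record()]s.
#' @param vocab a [tool_vocabulary()] with a blank class.
#' @param intensity_threshold mean-intensity cutoff (default 5/255; synthetic
#'   black frames are near zero, the margin tolerates compression artefacts).
#' @return The records, with black frames relabelled.
#' @export
handle_black_frames <- function(records, vocab, intensity_threshold = 5 / 255) {
  if (is.na(vocab$blank_index)) stopf("vocabulary has no blank class")
  lapply(records, function(r) {
    if (mean_intensity(r$image) < intensity_threshold) {
      lab <- integer(n_classes(vocab))
      lab[vocab$blank_index] <- 1L
      r$labels <- lab
    }
    r
  })
}

#' Crop a frame to its foreground mask
#'
#' Returns the tight bounding-box crop (half-open box on the largest
#' connected component of the mask). When the mask excludes the UI banner
#' rows -- as the fitted segmenter's masks do -- the crop removes the
#' label-leakage strip.
#'
#' @param frame h x w x 3 image array.
#' @param mask logical (or 0/1) matrix of the same height/width.
#' @return The cropped image array.
#' @export
crop_foreground <- function(frame, mask) {
  mask <- mask > 0
  if (!any(mask)) stopf("empty foreground mask: frame unusable")
  if (!all(dim(mask) == dim(frame)[1:2])) stopf("mask/frame size mismatch")
  # fast path: a mask that is one axis-aligned rectangle (as the fitted
  # segmenter emits) is its own largest connected component
  rk <- rowSums(mask) > 0; ck <- colSums(mask) > 0
  if (identical(mask, outer(rk, ck, FUN = "&"))) {
    rows <- range(which(rk)); cols <- range(which(ck))
    return(frame[rows[1L]:rows[2L], cols[1L]:cols[2L], , drop = FALSE])
  }
  lab <- EBImage::bwlabel(mask * 1)
  tab <- tabulate(as.integer(lab[lab > 0]))
  comp <- which.max(tab)
  keep <- lab == comp
  rows <- range(which(rowSums(keep) > 0))
  cols <- range(which(colSums(keep) > 0))
  frame[rows[1L]:rows[2L], cols[1L]:cols[2L], , drop = FALSE]
}

#' Extrapolate the clip-level label to selected frames
#'
#' Every selected frame receives the clip's full label set as its binary
#' label vector, tagged `provenance = "noisy"`. This is the dominant noise
#' source: a frame on which a tool has moved out of view still inherits that
#' tool's label from the clip.
#'
#' @param clip a `surg_clip`.
#' @param keyframe_indices 1-based frame indices (e.g. from
#'   [extract_keyframes()]).
#' @param vocab a [tool_vocabulary()].
#' @param frames optional replacement frame list (e.g. cropped frames),
#'   parallel to `keyframe_indices`; defaults to the clip's own frames.
#' @return List of [frame_record()]s.
#' @export
extrapolate_labels <- function(clip, keyframe_indices, vocab, frames = NULL) {
  if (any(keyframe_indices < 1L) || any(keyframe_indices > length(clip$frames)))
    stopf("keyframe index out of range")
  lab <- label_vector(clip$label_set, vocab)
  lapply(seq_along(keyframe_indices), function(k) {
    i <- keyframe_indices[k]
    img <- if (is.null(frames)) clip$frames[[i]] else frames[[k]]
    frame_record(img, clip$clip_id, i - 1L, lab, provenance = "noisy")
  })
}
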