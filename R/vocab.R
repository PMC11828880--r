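#' Canonical surgical tool vocabulary
#'
#' The classification task covers fourteen robotic surgical tools plus an
#' optional extra `blank` class used to absorb fully black frames (camera
#' lens removed or being cleaned). Canonical names are lowercase,
#' single-space separated, with no brackets, quotes or underscores; all
#' label handling in the package is expressed against this vocabulary.
#'
#' @param with_blank logical; append the `blank` class used for black frames.
#' @return An object of class `tool_vocabulary`: a list with `names` (the
#'   ordered class names, including `blank` when enabled), `n_tools` (number
#'   of real tools, 14 by default) and `blank_index` (index of the blank
#'   class, or `NA` when disabled).
#' @examples
#' v <- tool_vocabulary()
#' v$n_tools
#' v$names[v$blank_index]
#' @export
tool_vocabulary <- function(with_blank = TRUE) {
  names <- c(
    "needle driver",
    "monopolar curved scissor",
    "force bipolar",
    "clip applier",
    "tip up fenestrated grasper",
    "cadiere forceps",
    "bipolar forceps",
    "vessel sealer",
    "suction irrigator",
    "bipolar dissector",
    "prograsp forceps",
    "stapler",
    "permanent cautery hook spatula",
    "grasping retractor"
  )
  stopifnot(!anyDuplicated(names))
  if (with_blank) names <- c(names, "blank")
  structure(
    list(
      names = names,
      n_tools = if (with_blank) length(names) - 1L else length(names),
      blank_index = if (with_blank) length(names) else NA_integer_
    ),
    class = "tool_vocabulary"
  )
}

#' @export
print.tool_vocabulary <- function(x, ...) {
  cat(sprintf("Tool vocabulary: %d tools%s\n", x$n_tools,
              if (!is.na(x$blank_index)) " + 'blank' class" else ""))
  cat(paste0("  ", seq_along(x$names), ". ", x$names, collapse = "\n"), "\n")
  invisible(x)
}

n_classes <- function(vocab) length(vocab$names)

#' Encode a label set as a binary vector over the vocabulary
#'
#' @param labels character vector of canonical tool names (may include
#'   `"blank"`).
#' @param vocab a [tool_vocabulary()].
#' @return Named integer 0/1 vector of length `length(vocab$names)`.
#' @export
label_vector <- function(labels, vocab) {
  idx <- match(labels, vocab$names)
  if (anyNA(idx)) {
    stopf("unknown label(s): %s",
          paste(sQuote(labels[is.na(idx)]), collapse = ", "))
  }
  v <- integer(n_classes(vocab))
  v[idx] <- 1L
  names(v) <- vocab$names
  v
}

# Canonical key for a label combination (order-insensitive).
combo_key <- function(labels) paste(sort(labels), collapse = " | ")
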