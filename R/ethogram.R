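#' Behaviour vocabulary
#'
#' Construct the fixed vocabulary of behavioural actions used to annotate
#' 1-s ethogram bins. The default vocabulary is the 15-action set used for
#' cold-exposure recordings, in a fixed order so that integer codes are
#' stable across runs: sitting gets code 0, walking code 14.
#'
#' @param actions Character vector of unique action names. Defaults to the
#'   15-action cold-exposure vocabulary.
#' @return An object of class `behavior_vocabulary` with elements
#'   `actions` (ordered names) and `index` (named integer vector mapping
#'   action name to 0-based code).
#' @examples
#' v <- behavior_vocabulary()
#' v$index[["eating"]]  # 6
#' @export
behavior_vocabulary <- function(actions = default_actions()) {
  if (!is.character(actions) || length(actions) == 0)
    stop("`actions` must be a non-empty character vector")
  if (anyDuplicated(actions))
    stop("action names must be unique")
  idx <- seq_along(actions) - 1L
  names(idx) <- actions
  structure(list(actions = actions, index = idx),
            class = "behavior_vocabulary")
}

#' Default 15-action behaviour set
#'
#' The annotation vocabulary for mice under cold exposure, in canonical
#' order (codes 0..14).
#' @return Character vector of length 15.
#' @export
default_actions <- function() {
  c("sitting", "shivering", "head grooming", "turning",
    "lower body grooming", "moving out", "eating", "moving back",
    "pushing bedding", "standing up", "bedding retrieval", "drinking",
    "digging", "grooming tail", "walking")
}

#' @export
print.behavior_vocabulary <- function(x, ...) {
  cat("Behaviour vocabulary:", length(x$actions), "actions\n")
  cat(paste0("  [", x$index, "] ", x$actions, collapse = "\n"), "\n")
  invisible(x)
}

#' Ethogram: 1-s-binned behaviour labels for one animal
#'
#' @param labels Character vector of action names, one per bin.
#' @param vocab A [behavior_vocabulary()]; every label must belong to it.
#' @param animal_id Animal identifier.
#' @param condition Experimental condition label (e.g. `"4C"`, `"30C"`).
#' @param t0 Start time of the first bin, seconds.
#' @param bin_s Bin width in seconds (default 1).
#' @return An object of class `ethogram`.
#' @export
ethogram <- function(labels, vocab = behavior_vocabulary(),
                     animal_id = "animal", condition = "", t0 = 0,
                     bin_s = 1) {
  if (length(labels) == 0)
    stop("ethogram must contain at least one bin")
  if (!inherits(vocab, "behavior_vocabulary"))
    stop("`vocab` must be a behavior_vocabulary")
  bad <- which(!(labels %in% vocab$actions))
  if (length(bad) > 0)
    stop(sprintf("unknown behaviour label '%s' at bin %d", labels[bad[1]],
                 bad[1]))
  if (!is.numeric(bin_s) || bin_s <= 0)
    stop("`bin_s` must be a positive duration in seconds")
  structure(list(labels = as.character(labels), vocab = vocab,
                 animal_id = as.character(animal_id),
                 condition = as.character(condition),
                 t0 = as.numeric(t0), bin_s = as.numeric(bin_s)),
            class = "ethogram")
}

#' @export
print.ethogram <- function(x, ...) {
  cat(sprintf("Ethogram '%s'%s: %d bins of %g s (%.1f min)\n", x$animal_id,
              if (nzchar(x$condition)) paste0(" [", x$condition, "]") else "",
              length(x$labels), x$bin_s,
              length(x$labels) * x$bin_s / 60))
  invisible(x)
}

#' @export
length.ethogram <- function(x) length(x$labels)

#' Read an ethogram file
#'
#' Ethogram files are UTF-8 comma-separated text with columns
#' `time_s,behavior`, one row per bin, and optional `# animal_id=` /
#' `# condition=` comment headers. Bins must be contiguous with a constant
#' width, and every label must belong to the vocabulary.
#'
#' @param path File path.
#' @param vocab A [behavior_vocabulary()].
#' @return An [ethogram()].
#' @export
read_ethogram <- function(path, vocab = behavior_vocabulary()) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- read_comment_meta(path)
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c("numeric", "character"))
  if (!identical(names(df), c("time_s", "behavior")))
    stop("ethogram file must have header 'time_s,behavior'")
  if (nrow(df) == 0) stop("ethogram file has no data rows")
  o <- order(df$time_s)
  df <- df[o, ]
  bad <- which(!(df$behavior %in% vocab$actions))
  if (length(bad) > 0)
    stop(sprintf("unknown behaviour label '%s' at row %d",
                 df$behavior[bad[1]], bad[1]))
  if (nrow(df) > 1) {
    dt <- diff(df$time_s)
    if (any(dt <= 0))
      stop("duplicated or non-increasing time bins in ethogram file")
    if (max(dt) - min(dt) > 1e-9 * max(dt))
      stop("non-contiguous bins: bin width is not constant")
    bin_s <- dt[1]
  } else {
    bin_s <- 1
  }
  ethogram(df$behavior, vocab = vocab,
           animal_id = meta[["animal_id"]] %||% "animal",
           condition = meta[["condition"]] %||% "",
           t0 = df$time_s[1], bin_s = bin_s)
}

#' Write an ethogram file
#'
#' Inverse of [read_ethogram()]; the written file round-trips losslessly.
#'
#' @param e An [ethogram()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ethogram <- function(e, path) {
  stopifnot(inherits(e, "ethogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# animal_id=%s", e$animal_id), con)
  if (nzchar(e$condition))
    writeLines(sprintf("# condition=%s", e$condition), con)
  writeLines("time_s,behavior", con)
  t <- e$t0 + (seq_along(e$labels) - 1) * e$bin_s
  writeLines(paste(num_chr(t), e$labels, sep = ","), con)
  invisible(path)
}

#' Encode an ethogram as an integer observation sequence
#'
#' Maps each behaviour label to its 0-based vocabulary code, the input
#' format the HMM functions consume.
#'
#' @param e An [ethogram()].
#' @param vocab Vocabulary to encode against (defaults to the ethogram's own).
#' @return An object of class `observation_sequence`: list with integer
#'   `codes` (0-based), vocabulary size `V` and `animal_id`.
#' @export
encode_observations <- function(e, vocab = e$vocab) {
  stopifnot(inherits(e, "ethogram"))
  bad <- which(!(e$labels %in% vocab$actions))
  if (length(bad) > 0)
    stop(sprintf("label '%s' not in vocabulary", e$labels[bad[1]]))
  codes <- unname(vocab$index[e$labels])
  structure(list(codes = as.integer(codes),
                 V = length(vocab$actions),
                 animal_id = e$animal_id),
            class = "observation_sequence")
}

#' Decode an observation sequence back to labels
#'
#' @param obs An `observation_sequence`.
#' @param vocab The vocabulary it was encoded with.
#' @return Character vector of action names.
#' @export
decode_observations <- function(obs, vocab) {
  stopifnot(inherits(obs, "observation_sequence"))
  if (length(vocab$actions) < obs$V)
    stop("vocabulary smaller than encoding size")
  vocab$actions[obs$codes + 1L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# parse leading "# key=value" comment lines
read_comment_meta <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  cm <- grep("^#", lines, value = TRUE)
  out <- list()
  for (l in cm) {
    m <- regmatches(l, regexec("^#\\s*([A-Za-z_0-9]+)\\s*=\\s*(.*)$", l))[[1]]
    if (length(m) == 3) out[[m[2]]] <- trimws(m[3])
  }
  out
}

# full-precision numeric formatting so CSV round trips are lossless
num_chr <- function(x) {
  s <- sprintf("%.17g", x)
  short <- sprintf("%.15g", x)
  ok <- as.numeric(short) == x
  s[ok] <- short[ok]
  s
}
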