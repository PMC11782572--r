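# Framing spectral profiles into labeled 16x16 samples ---------------------
#
# Normalized profiles are cut into frames of 256 samples with an overlap of
# 100 (hop 156), each reshaped row-major into a 16x16 grid. Class 1 =
# periodic/exon, class 2 = non-periodic/intron; a frame takes class 1 when
# at least half of its positions fall inside annotated exons.

FRAME_LENGTH <- 256L
FRAME_OVERLAP <- 100L

#' Per-position class labels from exon intervals
#'
#' @param annotations integer matrix with columns `start`, `end`
#'   (0-based half-open exon intervals), or NULL for none.
#' @param length sequence length.
#' @return integer vector of length `length`; 1 inside exons, 2 elsewhere.
#' @export
position_labels <- function(annotations, length) {
  length <- check_count(length, "length")
  labels <- rep(2L, length)
  if (!is.null(annotations) && nrow(annotations) > 0) {
    if (any(annotations[, "start"] < 0) || any(annotations[, "end"] > length)) {
      stop("exon interval out of sequence bounds", call. = FALSE)
    }
    for (i in seq_len(nrow(annotations))) {
      labels[seq.int(annotations[i, "start"] + 1L, annotations[i, "end"])] <- 1L
    }
  }
  labels
}

#' Cut a profile into labeled frames
#'
#' Frames start at position 0 and advance by `frame_length - overlap`
#' (156 by default); a trailing partial frame is discarded. The frame label
#' is class 1 if at least 50% of its positions are class 1, else class 2.
#'
#' @param profile a `spectrum_profile` or numeric vector (normalized).
#' @param labels per-position class vector from [position_labels()].
#' @param frame_length frame size (a perfect square; 256 -> 16x16).
#' @param overlap overlap in samples between consecutive frames.
#' @return list of frames; each has `source_id`, `start` (0-based),
#'   `vector` (length `frame_length`) and `label`. Empty (with a warning)
#'   if the profile is shorter than one frame.
#' @export
extract_frames <- function(profile, labels, frame_length = FRAME_LENGTH,
                           overlap = FRAME_OVERLAP) {
  id <- if (inherits(profile, "spectrum_profile")) profile$id else "profile"
  v <- if (inherits(profile, "spectrum_profile")) profile$values else profile
  frame_length <- check_count(frame_length, "frame_length")
  overlap <- check_count(overlap, "overlap", min = 0L)
  if (overlap >= frame_length) stop_field("overlap", "must be < frame_length")
  if (length(v) != length(labels)) {
    stop("profile and labels differ in length", call. = FALSE)
  }
  if (length(v) < frame_length) {
    warning(sprintf("profile '%s' shorter than one frame; no frames", id),
            call. = FALSE)
    return(list())
  }
  hop <- frame_length - overlap
  starts <- seq.int(0L, length(v) - frame_length, by = hop)
  lapply(starts, function(s) {
    idx <- s + seq_len(frame_length)
    lab <- if (mean(labels[idx] == 1L) >= 0.5) 1L else 2L
    list(source_id = id, start = s, vector = v[idx], label = lab)
  })
}

#' Row-major 16x16 view of a frame vector
#'
#' @param frame a frame from [extract_frames()].
#' @return a square matrix filled row by row; flattening it row-major
#'   recovers the vector exactly.
#' @export
frame_grid <- function(frame) {
  side <- as.integer(sqrt(length(frame$vector)))
  if (side * side != length(frame$vector)) {
    stop("frame length is not a perfect square", call. = FALSE)
  }
  matrix(frame$vector, nrow = side, byrow = TRUE)
}

#' Shuffle and split frames into train/test sets
#'
#' Stratified by class: each class is shuffled uniformly and split so the
#' overall training size is exactly `floor(train_fraction * N)` (the
#' remainder goes to the class with the largest fractional quota), which
#' reproduces e.g. 8885 -> 7108/1777 and 14164 -> 11331/2833 at 0.8.
#'
#' @param frames list of frames (both classes must be present).
#' @param train_fraction fraction of frames assigned to training.
#' @param seed integer seed for the shuffle.
#' @return an object of class `frame_dataset`: list with `frames`,
#'   `train` / `test` (index vectors into `frames`), `seed`.
#' @export
shuffle_split <- function(frames, train_fraction = 0.8, seed = 1L) {
  if (length(frames) < 2L) stop("need at least 2 frames", call. = FALSE)
  labels <- vapply(frames, `[[`, integer(1), "label")
  if (length(unique(labels)) < 2L) {
    stop("single-class input: classifier untrainable", call. = FALSE)
  }
  n <- length(frames)
  n_train <- floor(train_fraction * n)
  classes <- sort(unique(labels))
  quota <- vapply(classes, function(cl) train_fraction * sum(labels == cl),
                  numeric(1))
  take <- floor(quota)
  rem <- n_train - sum(take)
  if (rem > 0) {
    ord <- order(quota - take, decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
  }
  with_seed(seed, {
    train <- integer(0)
    for (i in seq_along(classes)) {
      idx <- shuffle(which(labels == classes[i]))
      train <- c(train, idx[seq_len(take[i])])
    }
    train <- shuffle(train)             # mix classes within the train set
    test <- shuffle(setdiff(seq_len(n), train))
    structure(list(frames = frames, train = train, test = test, seed = seed),
              class = "frame_dataset")
  })
}

#' Frame a profile per class: separate first, then cut
#'
#' Splits the profile into its exon (class 1) and intron (class 2)
#' position streams, concatenates each stream, and frames the two streams
#' independently, so every frame is class-pure by construction. This is
#' the reference feature-extraction order (classes are separated according
#' to their periodicity before framing); the sliding-window alternative in
#' [extract_frames()] labels mixed frames by majority instead.
#'
#' @inheritParams extract_frames
#' @return list of frames; `start` is the offset within the class stream.
#' @export
class_stream_frames <- function(profile, labels, frame_length = FRAME_LENGTH,
                                overlap = FRAME_OVERLAP) {
  id <- if (inherits(profile, "spectrum_profile")) profile$id else "profile"
  v <- if (inherits(profile, "spectrum_profile")) profile$values else profile
  if (length(v) != length(labels)) {
    stop("profile and labels differ in length", call. = FALSE)
  }
  out <- list()
  for (cl in c(1L, 2L)) {
    stream <- v[labels == cl]
    if (length(stream) < frame_length) next
    fr <- extract_frames(stream, rep(cl, length(stream)),
                         frame_length, overlap)
    fr <- lapply(fr, function(f) { f$source_id <- id; f })
    out <- c(out, fr)
  }
  out
}

#' Expected frame count for a profile length
#'
#' `floor((L - frame_length) / hop) + 1` for `L >= frame_length`, else 0.
#'
#' @inheritParams extract_frames
#' @param length profile length L.
#' @export
n_frames <- function(length, frame_length = FRAME_LENGTH,
                     overlap = FRAME_OVERLAP) {
  hop <- frame_length - overlap
  ifelse(length < frame_length, 0L,
         (length - frame_length) %/% hop + 1L)
}

# Frames as a dense matrix (rows = frames) plus label vector, the form the
# classifier consumes.
frames_to_matrix <- function(frames, index = seq_along(frames)) {
  x <- t(vapply(frames[index], `[[`, numeric(FRAME_LENGTH), "vector"))
  y <- vapply(frames[index], `[[`, integer(1), "label")
  list(x = x, y = y)
}

#' Build a labeled frame dataset from annotated sequences
#'
#' Convenience pipeline: Voss mapping, spectrum (Gabor wavelet by default
#' or the ST-DFT baseline), min-max normalization, framing, stratified
#' shuffle/split. With `framing = "per_class"` (the reference order) the
#' normalized profile of each sequence is separated into exon and intron
#' streams before framing, so frames are class-pure; `"sliding"` frames
#' the whole profile and labels each frame by majority exon coverage.
#'
#' @param sequences list of annotated sequences ([generate_genome()] output
#'   or sequences read from FASTA/BED).
#' @param grid a [scale_grid()] for the Gabor transform.
#' @param method `"mgwt"` or `"stdft"`.
#' @param framing `"per_class"` or `"sliding"`.
#' @param window_length ST-DFT window (used when `method = "stdft"`).
#' @param train_fraction,seed passed to [shuffle_split()].
#' @return a `frame_dataset`.
#' @export
frame_dataset <- function(sequences, grid = scale_grid(),
                          method = c("mgwt", "stdft"),
                          framing = c("per_class", "sliding"),
                          window_length = 351L,
                          train_fraction = 0.8, seed = 1L) {
  method <- match.arg(method)
  framing <- match.arg(framing)
  frames <- list()
  for (s in sequences) {
    ind <- voss_map(s$sequence, id = s$id)
    prof <- if (method == "mgwt") mgwt_spectrum(ind, grid)
            else stdft_spectrum(ind, window_length)
    prof <- normalize_profile(prof)
    labels <- position_labels(s$exons, nchar(s$sequence))
    frames <- c(frames, if (framing == "per_class") {
      class_stream_frames(prof, labels)
    } else {
      extract_frames(prof, labels)
    })
  }
  shuffle_split(frames, train_fraction, seed)
}

#' @export
print.frame_dataset <- function(x, ...) {
  labels <- vapply(x$frames, `[[`, integer(1), "label")
  cat(sprintf(
    "frame_dataset: %d frames (%d exon / %d intron), train %d / test %d\n",
    length(x$frames), sum(labels == 1L), sum(labels == 2L),
    length(x$train), length(x$test)))
  invisible(x)
}
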