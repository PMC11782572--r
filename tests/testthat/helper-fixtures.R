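# Shared fixtures, built in code once per test run.

.fixture_env <- new.env()

# small annotated genome: strong codon bias, a handful of sequences
fixture_genome <- function() {
  if (is.null(.fixture_env$genome)) {
    .fixture_env$genome <- generate_genome(synthetic_genome_spec(
      n_sequences = 4L, seed = 2024L))
  }
  .fixture_env$genome
}

# frame dataset over the fixture genome (MGWT features)
fixture_dataset <- function() {
  if (is.null(.fixture_env$dataset)) {
    .fixture_env$dataset <- frame_dataset(fixture_genome(), seed = 99L)
  }
  .fixture_env$dataset
}

# stub frames carrying only labels (enough for split arithmetic)
stub_frames <- function(labels) {
  lapply(labels, function(l) list(source_id = "stub", start = 0L,
                                  vector = numeric(0), label = as.integer(l)))
}

# brute-force double-loop Gabor transform, the independent oracle for
# mgwt_coefficients (kernel truncated at +/- 4b like the implementation)
brute_mgwt <- function(track, grid) {
  n <- length(track)
  out <- matrix(0i, n, length(grid$scales))
  for (j in seq_along(grid$scales)) {
    b <- grid$scales[j]
    k <- ceiling(4 * b)
    for (a in seq_len(n)) {
      xs <- max(1, a - k):min(n, a + k)
      d <- xs - a
      out[a, j] <- sum(track[xs] * exp(-d^2 / (2 * b^2)) *
                         exp(1i * grid$center_frequency * d))
    }
  }
  out
}

# direct single-window DFT power at the period-3 bin, oracle for stdft
brute_stdft_value <- function(tracks, start, w) {
  k <- round(w / 3)
  val <- 0
  for (r in seq_len(nrow(tracks))) {
    u <- tracks[r, start:(start + w - 1)]
    val <- val + Mod(sum(u * exp(-2i * pi * k * (0:(w - 1)) / w)))^2
  }
  val
}
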