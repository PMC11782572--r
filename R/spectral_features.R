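# Period-3 spectral features ----------------------------------------------
#
# The modified Gabor wavelet transform evaluates a single centre frequency
# (here the period-3 angular frequency 2*pi/3 per sample) over a grid of
# Gaussian scales b, so short and long coding regions both respond without
# committing to one window length. The classical short-time DFT detector is
# included as the fixed-window baseline.

#' Scale grid for the Gabor wavelet transform
#'
#' Default: 24 logarithmically spaced scales spanning 9 to 400 samples,
#' covering short to long exon widths, at the period-3 centre frequency.
#'
#' @param scales strictly increasing vector of positive scales b (samples).
#' @param center_frequency angular frequency omega_0 (radians/sample);
#'   `2 * pi / 3` targets three-base periodicity regardless of sequence
#'   length.
#' @return an object of class `scale_grid`.
#' @export
scale_grid <- function(scales = exp(seq(log(9), log(400), length.out = 24)),
                       center_frequency = 2 * pi / 3) {
  if (length(scales) == 0 || any(!is.finite(scales)) || any(scales <= 0)) {
    stop_field("scales", "must be positive reals")
  }
  if (is.unsorted(scales, strictly = TRUE)) {
    stop_field("scales", "must be strictly increasing")
  }
  if (length(center_frequency) != 1L || !is.finite(center_frequency) ||
      center_frequency <= 0) {
    stop_field("center_frequency", "must be a positive real")
  }
  structure(list(scales = as.numeric(scales),
                 center_frequency = as.numeric(center_frequency)),
            class = "scale_grid")
}

#' Gabor kernel sampled on an integer offset grid
#'
#' `exp(-(x - a)^2 / (2 b^2)) * exp(1i * omega_0 * (x - a))`: a Gaussian
#' envelope of width b modulating a complex exponential at the centre
#' frequency. (The decaying-envelope sign convention is used; a positive
#' exponent would diverge.)
#'
#' @param position_offset_grid integer vector of offsets x - a.
#' @param scale Gaussian scale b > 0 (samples).
#' @param center_frequency angular frequency omega_0.
#' @return complex vector, one value per offset.
#' @export
gabor_kernel <- function(position_offset_grid, scale,
                         center_frequency = 2 * pi / 3) {
  if (length(scale) != 1L || !is.finite(scale) || scale <= 0) {
    stop_field("scale", "must be a positive real")
  }
  d <- as.numeric(position_offset_grid)
  exp(-d^2 / (2 * scale^2)) * exp(1i * center_frequency * d)
}

# valid complex cross-correlation via FFT:
# corr[s] = sum_m u[s + m - 1] * kern[m],  s = 1 .. length(u) - length(kern) + 1
.corr_valid_fft <- function(u_fft, L, kern, out_index) {
  kf <- stats::fft(c(rev(kern), rep(0, L - length(kern))))
  c_full <- stats::fft(u_fft * kf, inverse = TRUE) / L
  c_full[out_index]
}

#' Gabor wavelet coefficients of one indicator track
#'
#' For each position a and scale b, the inner product of the track with the
#' Gabor kernel centred at a, support truncated at +/- 4b (positions
#' outside the sequence contribute zero).
#'
#' @param track numeric (binary) vector.
#' @param grid a [scale_grid()].
#' @return complex matrix, positions x scales.
#' @export
mgwt_coefficients <- function(track, grid) {
  if (length(track) == 0) stop("'track' must be non-empty", call. = FALSE)
  if (!inherits(grid, "scale_grid")) stop("'grid' must be a scale_grid",
                                          call. = FALSE)
  n <- length(track)
  ks <- ceiling(4 * grid$scales)
  kmax <- max(ks)
  padded <- c(rep(0, kmax), as.numeric(track), rep(0, kmax))
  L <- stats::nextn(length(padded) + 2L * kmax + 1L)
  uf <- stats::fft(c(padded, rep(0, L - length(padded))))
  out <- matrix(0i, nrow = n, ncol = length(grid$scales))
  for (j in seq_along(grid$scales)) {
    k <- ks[j]
    kern <- gabor_kernel(seq.int(-k, k), grid$scales[j], grid$center_frequency)
    out[, j] <- .corr_valid_fft(uf, L, kern, kmax + k + seq_len(n))
  }
  out
}

#' Period-3 spectrum of a sequence via the Gabor wavelet transform
#'
#' Per position, sums the squared moduli of the coefficients over the four
#' indicator tracks, then reduces over scales (`max` by default: the best
#' response across scales; `sum` pools all scales).
#'
#' @param indicator an `indicator_matrix` from [voss_map()].
#' @param grid a [scale_grid()].
#' @param scale_reduction `"max"` or `"sum"`.
#' @param keep_per_scale keep the positions x scales energy matrix?
#' @return an object of class `spectrum_profile`: list with `id`, `values`
#'   (non-negative, length N) and optionally `per_scale`.
#' @export
mgwt_spectrum <- function(indicator, grid = scale_grid(),
                          scale_reduction = c("max", "sum"),
                          keep_per_scale = FALSE) {
  stopifnot(inherits(indicator, "indicator_matrix"))
  scale_reduction <- match.arg(scale_reduction)
  n <- ncol(indicator$tracks)
  energy <- matrix(0, nrow = n, ncol = length(grid$scales))
  for (b in rownames(indicator$tracks)) {
    u <- mgwt_coefficients(indicator$tracks[b, ], grid)
    energy <- energy + Mod(u)^2
  }
  values <- if (scale_reduction == "max") {
    do.call(pmax, asplit(energy, 2))
  } else {
    rowSums(energy)
  }
  structure(list(id = indicator$id, values = as.numeric(values),
                 per_scale = if (keep_per_scale) energy else NULL,
                 reduction = scale_reduction),
            class = "spectrum_profile")
}

#' Short-time DFT period-3 spectrum (fixed-window baseline)
#'
#' A rectangular window slides along the sequence; at each centre position
#' the squared modulus of the DFT coefficient at the period-3 bin
#' (window_length / 3) is summed over the four indicator tracks. Positions
#' whose window would overhang the sequence take the value of the nearest
#' valid centre.
#'
#' @param indicator an `indicator_matrix`.
#' @param window_length window length W (>= 3, <= sequence length);
#'   the classical choice is 351.
#' @return a `spectrum_profile` of length N.
#' @export
stdft_spectrum <- function(indicator, window_length = 351L) {
  stopifnot(inherits(indicator, "indicator_matrix"))
  n <- ncol(indicator$tracks)
  w <- check_count(window_length, "window_length", min = 3L)
  if (w > n) stop_field("window_length", "longer than the sequence")
  k <- round(w / 3)
  kern <- exp(-2i * pi * k * (0:(w - 1)) / w)
  L <- stats::nextn(n + w)
  n_valid <- n - w + 1L
  power <- numeric(n_valid)
  for (b in rownames(indicator$tracks)) {
    uf <- stats::fft(c(indicator$tracks[b, ], rep(0, L - n)))
    x <- .corr_valid_fft(uf, L, kern, w - 1L + seq_len(n_valid))
    power <- power + Mod(x)^2
  }
  h <- (w - 1L) %/% 2L               # centre offset within the window
  values <- power[pmin(pmax(seq_len(n) - h, 1L), n_valid)]
  structure(list(id = indicator$id, values = as.numeric(values),
                 per_scale = NULL, reduction = "stdft"),
            class = "spectrum_profile")
}

#' Min-max normalization of a spectrum profile to \[0, 1\]
#'
#' Per sequence; a constant profile maps to all zeros. Idempotent.
#'
#' @param profile a `spectrum_profile` or bare numeric vector.
#' @return same type as the input, values in \[0, 1\].
#' @export
normalize_profile <- function(profile) {
  v <- if (inherits(profile, "spectrum_profile")) profile$values else profile
  if (length(v) == 0) stop("'profile' must be non-empty", call. = FALSE)
  rng <- range(v)
  v <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else rep(0, length(v))
  if (inherits(profile, "spectrum_profile")) {
    profile$values <- v
    profile
  } else {
    v
  }
}
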