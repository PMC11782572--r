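test_that("gabor kernel has unit response at the centre and a Gaussian envelope", {
  expect_equal(gabor_kernel(0, scale = 10), 1 + 0i)
  g <- gabor_kernel(-20:20, scale = 7)
  expect_equal(Mod(g), rev(Mod(g)))                 # even envelope
  expect_equal(Mod(gabor_kernel(7, scale = 7)), exp(-0.5))
  expect_error(gabor_kernel(0:3, scale = 0), "scale")
})

test_that("mgwt coefficients match the brute-force double-loop oracle", {
  grid <- scale_grid(scales = c(4, 11, 33))
  set.seed(501)
  for (n in c(60, 200, 480)) {
    track <- as.numeric(stats::runif(n) < 0.25)
    got <- mgwt_coefficients(track, grid)
    want <- brute_mgwt(track, grid)
    expect_lt(max(Mod(got - want)) / max(Mod(want)), 1e-9)
  }
})

test_that("degenerate tracks behave: zeros stay zero, constants cancel", {
  grid <- scale_grid(scales = c(6, 18))
  expect_equal(Mod(mgwt_coefficients(rep(0, 80), grid)), matrix(0, 80, 2))
  # constant track at the period-3 frequency: oscillatory cancellation
  U <- mgwt_coefficients(rep(1, 300), scale_grid(scales = 12))
  expect_lt(max(Mod(U[100:200, 1])), 0.05)
  # period-3 impulse train: response grows with the envelope mass (scale)
  train <- rep(c(1, 0, 0), 100)
  U2 <- mgwt_coefficients(train, scale_grid(scales = c(5, 20, 60)))
  mid <- Mod(U2[150, ])
  expect_true(all(diff(mid) > 0))
  expect_error(mgwt_coefficients(numeric(0), grid), "non-empty")
})

test_that("mgwt spectrum is non-negative, zero on all-N input, and exceeds intron background on biased exons", {
  expect_equal(mgwt_spectrum(voss_map("NNNNNNNNNN"),
                             scale_grid(scales = c(3, 9)))$values, rep(0, 10))
  spec <- synthetic_genome_spec(n_sequences = 1, exon_length_range = c(300, 300),
                                intron_length_range = c(300, 300),
                                exons_per_sequence_range = c(1, 1),
                                codon_bias_strength = 0.9, seed = 8)
  s <- generate_genome(spec)[[1]]
  prof <- mgwt_spectrum(voss_map(s$sequence, s$id), scale_grid())
  expect_true(all(prof$values >= 0))
  lab <- position_labels(s$exons, 900L)
  # on this 900 bp toy the widest scales bleed exon energy into the short
  # flanking introns, so the contrast is modest but strictly positive
  ratio <- mean(prof$values[lab == 1L]) / mean(prof$values[lab == 2L])
  expect_gt(ratio, 1)
  # at realistic segment lengths the contrast is strong
  s2 <- fixture_genome()[[1]]
  prof2 <- mgwt_spectrum(voss_map(s2$sequence, s2$id), scale_grid())
  lab2 <- position_labels(s2$exons, nchar(s2$sequence))
  ratio2 <- mean(prof2$values[lab2 == 1L]) / mean(prof2$values[lab2 == 2L])
  expect_gt(ratio2, 1.5)
})

test_that("single-scale reduction reproduces the per-scale column exactly", {
  ind <- voss_map(fixture_genome()[[1]]$sequence)
  one <- mgwt_spectrum(ind, scale_grid(scales = 15), keep_per_scale = TRUE)
  expect_equal(one$values, unname(one$per_scale[, 1]))
  both_max <- mgwt_spectrum(ind, scale_grid(scales = c(15, 40)),
                            keep_per_scale = TRUE)
  expect_equal(both_max$values,
               pmax(both_max$per_scale[, 1], both_max$per_scale[, 2]))
  both_sum <- mgwt_spectrum(ind, scale_grid(scales = c(15, 40)),
                            scale_reduction = "sum", keep_per_scale = TRUE)
  expect_equal(both_sum$values, unname(rowSums(both_sum$per_scale)))
})

test_that("stdft spectrum matches the direct DFT oracle and handles degenerate windows", {
  seq3 <- paste(rep("ACG", 200), collapse = "")
  ind <- voss_map(seq3)
  prof <- stdft_spectrum(ind, 351)
  # interior values equal (periodic signal, sliding window sees same content)
  expect_lt(stats::sd(prof$values[200:400]), 1e-6)
  expect_equal(prof$values[300], brute_stdft_value(ind$tracks, 300 - 175, 351),
               tolerance = 1e-9)
  # homopolymer run: all energy at DC, none at the period-3 bin
  flat <- stdft_spectrum(voss_map(strrep("A", 500)), 351)
  expect_lt(max(flat$values), 1e-12)
  # degenerate full-length window: one DFT value replicated
  full <- stdft_spectrum(ind, nchar(seq3))
  expect_equal(length(unique(round(full$values, 9))), 1L)
  expect_error(stdft_spectrum(ind, 1000), "window_length")
})

test_that("min-max normalization is exact, total and idempotent", {
  expect_equal(normalize_profile(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(normalize_profile(c(5, 5)), c(0, 0))
  v <- stats::runif(100)
  expect_equal(normalize_profile(normalize_profile(v)), normalize_profile(v))
  prof <- structure(list(id = "p", values = c(1, 3), per_scale = NULL),
                    class = "spectrum_profile")
  expect_equal(normalize_profile(prof)$values, c(0, 1))
})

test_that("per-position exon discrimination by the mgwt profile beats chance and grows with bias", {
  aucs <- vapply(c(0.3, 0.9), function(bias) {
    spec <- synthetic_genome_spec(n_sequences = 1, codon_bias_strength = bias,
                                  exon_length_range = c(300, 600),
                                  seed = 42)
    s <- generate_genome(spec)[[1]]
    prof <- mgwt_spectrum(voss_map(s$sequence), scale_grid())
    lab <- position_labels(s$exons, nchar(s$sequence))
    roc_and_auc(prof$values, lab)$auc
  }, numeric(1))
  expect_gt(aucs[2], 0.8)
  expect_gt(aucs[2], aucs[1])
})
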