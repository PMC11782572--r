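test_that("genotype validation enforces positive counts and the 3-11 total", {
  expect_s3_class(genotype(1, 1, 1), "genotype")
  expect_error(genotype(0, 1, 1), "n_conv")
  expect_error(genotype(5, 4, 3), "\\[3, 11\\]")
})

test_that("population initialization respects bounds, sum constraint and seed", {
  m <- init_population(10, seed = 4)
  expect_equal(dim(m), c(10L, 3L))
  expect_true(all(rowSums(m) >= 3 & rowSums(m) <= 11))
  expect_identical(m, init_population(10, seed = 4))
  deg <- init_population(5, bounds = list(c(1, 1), c(1, 1), c(1, 1)), seed = 1)
  expect_true(all(deg == 1L))
  expect_error(init_population(3, bounds = list(c(6, 9), c(5, 9), c(5, 9))),
               "unattainable")
})

test_that("initialization marginals are near-uniform over each dimension's range", {
  m <- init_population(4000, bounds = list(c(1, 5), c(1, 4), c(1, 2)),
                       seed = 21)
  # max total is 11, so the sum constraint never rejects: marginals uniform
  for (d in 1:3) {
    tab <- table(m[, d])
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    expect_gt(p, 1e-4)
  }
})

test_that("decoding reproduces the reference layer totals 12 and 17", {
  expect_equal(n_layers(decode_genotype(genotype(3, 1, 2))), 12L)
  expect_equal(n_layers(decode_genotype(genotype(4, 3, 2))), 17L)
  p <- decode_genotype(genotype(1, 1, 1))
  kinds <- vapply(p$layers, `[[`, character(1), "kind")
  expect_equal(kinds, c("convolution", "batch_normalization", "activation",
                        "max_pooling", "fully_connected"))
  expect_equal(p$layers[[5]]$params$units, 2L)
})

test_that("decoded plans respect structural invariants for random genotypes", {
  set.seed(9)
  for (i in 1:25) {
    repeat {
      g <- c(sample(1:5, 1), sample(1:4, 1), sample(1:3, 1))
      if (sum(g) >= 3 && sum(g) <= 11) break
    }
    plan <- decode_genotype(genotype(g[1], g[2], g[3]), seed = i)
    kinds <- vapply(plan$layers, `[[`, character(1), "kind")
    expect_equal(kinds[1], "convolution")
    expect_equal(kinds[length(kinds)], "fully_connected")
    expect_equal(sum(kinds == "convolution"), g[1])
    expect_lte(sum(kinds == "max_pooling"), g[2])
    expect_equal(sum(kinds == "fully_connected"), g[3])
    # conv always followed by batch norm + activation
    for (ci in which(kinds == "convolution")) {
      expect_equal(kinds[ci + 1], "batch_normalization")
      expect_equal(kinds[ci + 2], "activation")
    }
    # fully connected layers contiguous at the tail
    fc <- which(kinds == "fully_connected")
    expect_equal(fc, seq.int(length(kinds) - g[3] + 1L, length(kinds)))
    # total count when nothing was repaired
    if (length(plan$repair_log) == 0) {
      expect_equal(n_layers(plan), 3L * g[1] + g[2] + g[3])
    }
    expect_identical(plan_to_json(plan),
                     plan_to_json(decode_genotype(genotype(g[1], g[2], g[3]),
                                                  seed = i)))
  }
})

test_that("hyperparameter dimension is 2c + p + h with the output layer excluded", {
  expect_equal(hyperparameter_dimension(genotype(3, 1, 3)), 9L)   # h = 2
  expect_equal(hyperparameter_dimension(genotype(1, 1, 2)), 4L)   # h = 1
  expect_equal(hyperparameter_dimension(genotype(4, 3, 3)), 13L)  # h = 2
  expect_equal(hyperparameter_dimension(genotype(3, 1, 2)), 8L)
})

test_that("continuous positions map to nearest admissible hyperparameters, idempotently", {
  g <- genotype(1, 1, 2)                 # m = 4, position length 6
  hp <- position_to_hyperparameters(c(15.7, 4.2, -3, 700.2, 2.6, 100), g)
  expect_equal(hp$filters, 16L)          # 15.7 -> nearest of {8, 16, 32}
  expect_equal(hp$filter_size, 5L)
  expect_equal(hp$pool_size, 2L)         # -3 clamped to [2, 5]
  expect_equal(hp$hidden_units, 700L)
  expect_equal(hp$optimizer, "rmsprop")
  expect_equal(hp$batch_size, 128L)      # 100 -> nearest of the batch set
  again <- position_to_hyperparameters(hp$values, g)
  expect_equal(again$values, hp$values)  # idempotent on admissible vectors
  expect_error(position_to_hyperparameters(1:3, g), "m \\+ 2")
})

test_that("repair removes right-most pooling until the spatial path is valid", {
  g <- genotype(1, 4, 1)
  hyper <- list(filters = 8L, filter_size = 3L, pool_size = rep(2L, 4),
                hidden_units = integer(0))
  plan <- decode_genotype(g, seed = 2, hyper = hyper)
  kinds <- vapply(plan$layers, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "max_pooling"), 4L)   # 16 -> 8 -> 4 -> 2 -> 1

  # five poolings cannot fit: construct directly and repair
  mk <- function(n_pool) {
    layers <- c(
      list(list(kind = "convolution", params = list(filters = 8L, filter_size = 3L)),
           list(kind = "batch_normalization", params = list()),
           list(kind = "activation", params = list())),
      rep(list(list(kind = "max_pooling", params = list(pool_size = 2L))), n_pool),
      list(list(kind = "fully_connected", params = list(units = 2L))))
    structure(list(layers = layers, n_classes = 2L,
                   input_shape = c(16L, 16L, 1L),
                   genotype = genotype(1, min(n_pool, 4), 1), seed = 1L,
                   repair_log = character(0)),
              class = "architecture_plan")
  }
  repaired <- validate_and_repair(mk(5))
  kinds <- vapply(repaired$layers, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "max_pooling"), 4L)
  expect_length(repaired$repair_log, 1L)
  # a valid plan passes through unchanged
  ok <- mk(2)
  expect_identical(validate_and_repair(ok), ok)
})
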