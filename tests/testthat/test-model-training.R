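# easy, linearly separable frames: class 1 high plateau, class 2 low
separable_frames <- function(n = 120, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::runif(n * 256, 0, 0.2), n)
  y <- rep(c(1L, 2L), length.out = n)
  x[y == 1L, ] <- x[y == 1L, ] + 0.7
  list(x = x, y = y)
}

test_that("model building is deterministic and counts parameters in closed form", {
  plan <- decode_genotype(genotype(1, 1, 1), seed = 3)
  m1 <- build_model(plan, seed = 5)
  m2 <- build_model(plan, seed = 5)
  expect_identical(m1$layers, m2$layers)
  # conv 8 filters of 3x3x1 + bias: 8*9 + 8 = 80; batch norm: 2*8 = 16;
  # fc: 16x16 -> pool 2 -> 8x8x8 = 512 inputs, 2 units: 2*512 + 2 = 1026
  expect_equal(n_parameters(m1), 80 + 16 + 1026)
})

test_that("class scores are normalized probabilities", {
  plan <- decode_genotype(genotype(1, 1, 1), seed = 3)
  model <- build_model(plan, seed = 5)
  d <- separable_frames(20)
  sc <- predict_scores(model, d$x)
  expect_equal(dim(sc), c(20L, 2L))
  expect_equal(unname(rowSums(sc)), rep(1, 20))
  expect_true(all(sc >= 0))
})

test_that("training runs the requested epochs and learns separable frames", {
  plan <- decode_genotype(genotype(1, 1, 1), seed = 3)
  model <- build_model(plan, seed = 5)
  d <- separable_frames(120)
  same <- train_model(model, d$x, d$y, training_options(epochs = 0))
  expect_identical(same$layers, model$layers)
  fitted <- train_model(model, d$x, d$y,
                        training_options(epochs = 10, seed = 2))
  expect_length(fitted$loss_trace, 10L)
  acc <- fitness_ber(fitted, d$x, d$y)$accuracy
  expect_gte(acc, 0.95)
  # every optimizer can fit the easy problem
  for (opt in c("sgdm", "rmsprop")) {
    f2 <- train_model(build_model(plan, seed = 5), d$x, d$y,
                      training_options(optimizer = opt, epochs = 10,
                                       learning_rate = 0.01, seed = 2))
    expect_gte(fitness_ber(f2, d$x, d$y)$accuracy, 0.9)
  }
})

test_that("BER equals the misclassified fraction", {
  cc <- confusion(c(1L, 1L, 2L, 2L), c(1L, 1L, 2L, 2L))
  expect_equal(metrics(cc)$ber, 0)
  cc <- confusion(c(2L, 2L, 1L, 1L), c(1L, 1L, 2L, 2L))
  expect_equal(metrics(cc)$ber, 1)
  cc <- structure(list(TP = 8L, FP = 2L, TN = 8L, FN = 2L),
                  class = "confusion_counts")
  expect_equal(metrics(cc)$ber, 0.2)
})

test_that("the architecture objective is cached per row and bounded", {
  ds <- fixture_dataset()
  clear_objective_cache()
  opts <- training_options(epochs = 1, seed = 3)
  b1 <- architecture_objective(c(1, 1, 1), ds, opts)
  runs_after_first <- training_runs()
  b2 <- architecture_objective(c(1.2, 0.8, 1.4), ds, opts)
  expect_identical(b1, b2)                       # rounds to the same genotype
  expect_equal(training_runs(), runs_after_first)  # served from cache
  expect_gte(b1, 0); expect_lte(b1, 1)
  # an out-of-constraint row fails gracefully
  expect_true(is.nan(architecture_objective(c(5, 4, 3), ds, opts)))
})

test_that("three-stage search completes, improves monotonically and reproduces per seed", {
  ds <- fixture_dataset()
  fit <- exon_cnn(ds, population_size = 4, max_iterations = 3,
                  search_epochs = 2, final_epochs = 2, seed = 17)
  expect_s3_class(fit, "exon_cnn")
  expect_true(all(diff(fit$stage1$history$best_fitness) <= 0))
  expect_true(all(diff(fit$stage2$history$best_fitness) <= 0))
  # stage 2 starts from the incumbent defaults: can only improve
  expect_lte(fit$stage2$best_fitness, fit$stage1$best_fitness)
  expect_true(is.finite(fit$test_metrics$accuracy))
  expect_equal(fit$test_metrics$accuracy + fit$test_metrics$ber, 1)
  expect_length(fit$loss_trace, 2L)

  fit2 <- exon_cnn(ds, population_size = 4, max_iterations = 3,
                   search_epochs = 2, final_epochs = 2, seed = 17)
  expect_identical(experiment_record(fit), experiment_record(fit2))
  expect_identical(plan_to_json(fit$plan), plan_to_json(fit2$plan))

  # S3 surface
  expect_output(print(fit), "held-out test")
  expect_output(summary(fit), "Three-stage")
  pr <- predict(fit, ds)
  expect_equal(dim(pr), c(length(ds$frames), 2L))
  cls <- predict(fit, exonscan:::frames_to_matrix(ds$frames, ds$test)$x,
                 type = "class")
  expect_true(all(cls %in% c(1L, 2L)))
})
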