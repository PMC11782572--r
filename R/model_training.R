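# BER objective and the three-stage architecture search --------------------
#
# Stage 1: AVOA over the genotype box (conv, pool, fc counts), training
# each candidate briefly with fixed default hyperparameters and scoring it
# by bit error rate (BER = misclassified fraction = 1 - accuracy) on a
# validation subset carved out of the training split (never the held-out
# test set). Stage 2: AVOA over the m + 2 hyperparameter vector of the
# stage-1 winner, with the incumbent defaults seeded into the initial
# population so stage 2 can only improve. Stage 3: final training of the
# winning configuration on the full training split, evaluated once on the
# held-out test frames.

.objective_cache <- new.env(parent = emptyenv())
.train_counter <- new.env(parent = emptyenv())
.train_counter$n <- 0L

#' Reset the objective-evaluation cache and training counter
#' @export
clear_objective_cache <- function() {
  rm(list = ls(.objective_cache), envir = .objective_cache)
  .train_counter$n <- 0L
  invisible(NULL)
}

#' Number of actual (non-cached) training runs since the last reset
#' @return integer counter.
#' @export
training_runs <- function() .train_counter$n

#' Bit error rate of a fitted model on an evaluation split
#'
#' `BER = (FP + FN) / (TP + FP + TN + FN) = 1 - accuracy` from the argmax
#' predictions.
#'
#' @param model a fitted `cnn_model`.
#' @param x evaluation frames (matrix, 256 columns).
#' @param y true labels in \{1, 2\}.
#' @return list with `ber`, `accuracy`, `confusion` (a `confusion_counts`).
#' @export
fitness_ber <- function(model, x, y) {
  if (length(y) == 0) stop("evaluation split is empty", call. = FALSE)
  scores <- predict_scores(model, x)
  pred <- ifelse(scores[, 1] >= scores[, 2], 1L, 2L)
  cc <- confusion(pred, y)
  m <- metrics(cc)
  list(ber = m$ber, accuracy = m$accuracy, confusion = cc)
}

# Candidate fitness is a pure function of (candidate, dataset): the
# validation carve-out, the architecture placement and the training run are
# all seeded from the dataset and the candidate's own content, never from
# the search's run seed. This removes evaluation noise between identical
# candidates (a standard variance-reduction device in architecture search)
# and makes repeated evaluations cacheable.

# cheap deterministic fingerprint of a dataset / candidate
.content_seed <- function(...) {
  vals <- unlist(list(...))
  s <- 0
  for (v in vals) s <- (s * 31 + (as.double(v) %% 97)) %% 2147483647
  as.integer(s) + 1L
}

.data_fingerprint <- function(data) {
  .content_seed(data$seed, length(data$frames), length(data$train),
                sum(vapply(data$frames, `[[`, integer(1), "label")))
}

# stratified validation carve-out from the training indices
.fitness_split <- function(data, val_fraction = 0.2) {
  labels <- vapply(data$frames[data$train], `[[`, integer(1), "label")
  with_seed(derive_seed(data$seed, 7L), {
    val <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      val <- c(val, sample_from(idx, max(1L, floor(val_fraction * length(idx)))))
    }
    list(fit = data$train[-val], val = data$train[val])
  })
}

.default_hyper_values <- function(g) {
  c(rep(c(DEFAULT_HYPER$filters, DEFAULT_HYPER$filter_size), g$n_conv),
    rep(DEFAULT_HYPER$pool_size, g$n_pool),
    rep(DEFAULT_HYPER$hidden_units, max(0L, g$n_fc - 1L)),
    match(DEFAULT_HYPER$optimizer, OPTIMIZER_CHOICES),
    DEFAULT_HYPER$batch_size)
}

# decode -> build -> train -> BER, memoized on (candidate, dataset)
.evaluate_candidate <- function(g, hyper, data, split, options,
                                fingerprint = .data_fingerprint(data)) {
  key <- paste(c(g$n_conv, g$n_pool, g$n_fc,
                 if (is.null(hyper)) "default" else hyper$values,
                 options$optimizer, options$batch_size, options$epochs,
                 fingerprint), collapse = "_")
  if (!is.null(.objective_cache[[key]])) return(.objective_cache[[key]])
  cand_seed <- .content_seed(
    fingerprint, g$n_conv, g$n_pool, g$n_fc,
    if (is.null(hyper)) 0 else hyper$values)
  plan <- decode_genotype(g, n_classes = 2L,
                          seed = derive_seed(cand_seed, 11L), hyper = hyper)
  model <- build_model(plan, seed = derive_seed(cand_seed, 13L))
  tr <- frames_to_matrix(data$frames, split$fit)
  opts <- options
  opts$seed <- derive_seed(cand_seed, 17L)
  model <- train_model(model, tr$x, tr$y, opts)
  .train_counter$n <- .train_counter$n + 1L
  va <- frames_to_matrix(data$frames, split$val)
  ber <- fitness_ber(model, va$x, va$y)$ber
  .objective_cache[[key]] <- ber
  ber
}

#' Architecture-search objective: genotype row to BER
#'
#' Rounds a continuous 3-vector to a genotype, decodes it with the default
#' hyperparameters, trains briefly and returns the BER on the validation
#' subset of `data`'s training split. Evaluations are memoized on
#' (row, seed); an invalid genotype or failed training yields `NaN`, which
#' the optimizer converts to its worst-fitness sentinel.
#'
#' @param row numeric vector of length 3 (conv, pool, fc counts).
#' @param data a `frame_dataset`.
#' @param options a [training_options()] (stage-1 epochs live here).
#' @return scalar BER in \[0, 1\] (or NaN on failure).
#' @export
architecture_objective <- function(row, data, options = training_options()) {
  split <- .fitness_split(data)
  tryCatch({
    g <- genotype(round(row[1]), round(row[2]), round(row[3]))
    # explicit default hyperparameters: the same candidate re-evaluated in
    # stage 2 (the incumbent) must hash to the same key and seed
    hyper <- position_to_hyperparameters(.default_hyper_values(g), g)
    .evaluate_candidate(g, hyper, data, split, options)
  }, error = function(e) NaN)
}

#' Fit an exon/intron frame classifier by three-stage vulture search
#'
#' The top-level fitting function. Stage 1 searches the layer-count
#' genotype, stage 2 the hyperparameter vector of the stage-1 winner
#' (seeded with the incumbent defaults), stage 3 trains the winning
#' configuration on the full training split and evaluates it on the
#' held-out test split.
#'
#' @param data a `frame_dataset` (see [frame_dataset()]).
#' @param population_size vultures per stage.
#' @param max_iterations AVOA iterations per stage.
#' @param search_epochs training epochs per candidate evaluation
#'   (stages 1-2).
#' @param final_epochs training epochs of the final model (stage 3).
#' @param learning_rate fixed learning rate for every training run.
#' @param seed master seed; every stage derives its own stream from it.
#' @param avoa_args named list of extra [avoa_config()] arguments
#'   (Q1, Q2, Q3, L1, L2, w, ...).
#' @return an object of class `exon_cnn`: the fitted `model`, the decoded
#'   `plan`, `hyper` (winning hyperparameters), `genotype`, per-stage
#'   search results (`stage1`, `stage2`), final `train_ber` trace,
#'   held-out `test_metrics`, and the `data` split bookkeeping.
#' @export
exon_cnn <- function(data, population_size = 10L, max_iterations = 20L,
                     search_epochs = 10L, final_epochs = 10L,
                     learning_rate = 0.001, seed = 1L,
                     avoa_args = list()) {
  stopifnot(inherits(data, "frame_dataset"))
  split <- .fitness_split(data)
  fingerprint <- .data_fingerprint(data)
  stage_options <- training_options(
    optimizer = DEFAULT_HYPER$optimizer, batch_size = DEFAULT_HYPER$batch_size,
    epochs = search_epochs, learning_rate = learning_rate, seed = seed)

  # Stage 1: layer-count genotype --------------------------------------
  gb <- genotype_bounds()
  cfg1 <- do.call(avoa_config, c(list(
    lower = vapply(gb, `[`, integer(1), 1),
    upper = vapply(gb, `[`, integer(1), 2),
    population_size = population_size, max_iterations = max_iterations,
    seed = derive_seed(seed, 1L)), avoa_args))
  obj1 <- function(x) architecture_objective(x, data, stage_options)
  init1 <- init_population(population_size, gb, seed = derive_seed(seed, 2L))
  s1 <- avoa_optimize(obj1, cfg1, init = init1)
  g_best <- genotype(round(s1$best_position[1]), round(s1$best_position[2]),
                     round(s1$best_position[3]))

  # Stage 2: hyperparameters of the winner ------------------------------
  hb <- hyperparameter_bounds(g_best)
  cfg2 <- do.call(avoa_config, c(list(
    lower = hb$lower, upper = hb$upper,
    population_size = population_size, max_iterations = max_iterations,
    seed = derive_seed(seed, 3L)), avoa_args))
  obj2 <- function(x) {
    tryCatch({
      hyper <- position_to_hyperparameters(x, g_best)
      opts <- training_options(optimizer = hyper$optimizer,
                               batch_size = hyper$batch_size,
                               epochs = search_epochs,
                               learning_rate = learning_rate, seed = seed)
      .evaluate_candidate(g_best, hyper, data, split, opts, fingerprint)
    }, error = function(e) NaN)
  }
  s2 <- avoa_optimize(obj2, cfg2,
                      init = matrix(.default_hyper_values(g_best), nrow = 1))
  hyper_best <- position_to_hyperparameters(s2$best_position, g_best)

  # Stage 3: final training on the full training split ------------------
  # the decoded architecture is the one the evaluations scored
  # (content-addressed placement seed); the final weights and shuffles
  # derive from the run seed
  cand_seed <- .content_seed(fingerprint, g_best$n_conv, g_best$n_pool,
                             g_best$n_fc, hyper_best$values)
  plan <- decode_genotype(g_best, n_classes = 2L,
                          seed = derive_seed(cand_seed, 11L),
                          hyper = hyper_best)
  model <- build_model(plan, seed = derive_seed(seed, 13L))
  final_options <- training_options(optimizer = hyper_best$optimizer,
                                    batch_size = hyper_best$batch_size,
                                    epochs = final_epochs,
                                    learning_rate = learning_rate, seed = seed)
  tr <- frames_to_matrix(data$frames, data$train)
  model <- train_model(model, tr$x, tr$y, final_options)
  te <- frames_to_matrix(data$frames, data$test)
  scores <- predict_scores(model, te$x)
  test_metrics <- metrics_report(scores, te$y)

  structure(list(
    model = model, plan = plan, genotype = g_best, hyper = hyper_best,
    stage1 = s1, stage2 = s2,
    final_options = final_options,
    loss_trace = model$loss_trace,
    test_metrics = test_metrics,
    data_counts = list(n_frames = length(data$frames),
                       n_train = length(data$train),
                       n_test = length(data$test)),
    seed = seed),
    class = "exon_cnn")
}

#' @export
print.exon_cnn <- function(x, ...) {
  cat("Optimized exon/intron frame classifier\n")
  cat(sprintf("  genotype: %d conv / %d pool / %d fc  (%d layers)\n",
              x$genotype$n_conv, x$genotype$n_pool, x$genotype$n_fc,
              n_layers(x$plan)))
  cat(sprintf("  search BER: stage 1 %.4f -> stage 2 %.4f\n",
              x$stage1$best_fitness, x$stage2$best_fitness))
  cat(sprintf("  held-out test: accuracy %.4f, BER %.4f, AUC %.4f\n",
              x$test_metrics$accuracy, x$test_metrics$ber,
              x$test_metrics$auc))
  invisible(x)
}

#' @export
summary.exon_cnn <- function(object, ...) {
  m <- object$test_metrics
  cat("Three-stage vulture search summary\n")
  cat(sprintf("  frames: %d (train %d / test %d)\n",
              object$data_counts$n_frames, object$data_counts$n_train,
              object$data_counts$n_test))
  cat(sprintf("  hyperparameters: optimizer %s, batch %d\n",
              object$hyper$optimizer, object$hyper$batch_size))
  print(object$plan)
  cat(sprintf(
    "  test metrics: accuracy %.4f  precision %.4f  recall %.4f  f1 %.4f  auc %.4f\n",
    m$accuracy, m$precision, m$recall, m$f1, m$auc))
  invisible(object)
}

#' @export
predict.exon_cnn <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "frame_dataset")) {
    frames_to_matrix(newdata$frames)$x
  } else as.matrix(newdata)
  scores <- predict_scores(object$model, x)
  if (type == "prob") scores
  else ifelse(scores[, 1] >= scores[, 2], 1L, 2L)
}

#' @export
plot.exon_cnn <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::plot(x$stage1$history$iteration, x$stage1$history$best_fitness,
                 type = "s", xlab = "iteration", ylab = "best BER",
                 main = "Stage 1: architecture", ...)
  graphics::plot(x$stage2$history$iteration, x$stage2$history$best_fitness,
                 type = "s", xlab = "iteration", ylab = "best BER",
                 main = "Stage 2: hyperparameters", ...)
  invisible(x)
}

#' Experiment record as JSON
#'
#' Serializes the winning architecture, hyperparameters, seeds, search
#' histories and test metrics of a fit.
#'
#' @param fit an `exon_cnn`.
#' @param path optional output path.
#' @export
experiment_record <- function(fit, path = NULL) {
  obj <- list(
    seed = fit$seed,
    genotype = unclass(fit$genotype),
    hyperparameters = fit$hyper[c("filters", "filter_size", "pool_size",
                                  "hidden_units", "optimizer", "batch_size")],
    n_layers = n_layers(fit$plan),
    stage1_history = fit$stage1$history,
    stage2_history = fit$stage2$history,
    test_metrics = fit$test_metrics[c("accuracy", "ber", "precision",
                                      "recall", "f1", "auc")],
    data_counts = fit$data_counts)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}
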