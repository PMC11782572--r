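# African Vulture Optimization Algorithm -----------------------------------
#
# Population metaheuristic minimizing a black-box objective over a
# box-bounded vector. A scalar "satiety" schedule F shrinks over the run;
# |F| >= 1 keeps a vulture exploring (long moves around a roulette-selected
# group best), 0.5 <= |F| < 1 engages a siege / rotating-flight phase, and
# |F| < 0.5 an accumulation-around-the-bests / Levy-flight phase. The two
# group bests are the two lowest-fitness solutions of the current
# population; the global best is tracked elitistically, so its trace is
# non-increasing by construction.

#' AVOA configuration
#'
#' Defaults are the reference settings: population 10, 20 iterations,
#' Q1/Q2/Q3 = 0.6/0.4/0.6 (phase-branch probabilities), selection weights
#' L1/L2 = 0.8/0.2, satiety exponent w = 2.5, h drawn from \[-2, 2\].
#'
#' @param lower,upper numeric vectors: per-dimension box bounds.
#' @param population_size number of vultures.
#' @param max_iterations iteration budget.
#' @param Q1,Q2,Q3 branch probabilities of the three phases, in \[0, 1\].
#' @param L1,L2 roulette weights for the two group bests; must sum to 1.
#' @param w satiety exponent (gamma).
#' @param h_range interval from which the satiety term h is drawn.
#' @param seed integer seed; the whole search is deterministic per seed.
#' @param roulette `"weights"` (two-arm roulette with weights L1, L2) or
#'   `"fitness"` (probabilities `F_j / sum(F_j)` over the two bests).
#' @param rotating `"printed"` or `"original"` form of the rotating-flight
#'   move (the alternative uses the distance to the current position as the
#'   rotation angle).
#' @param boundary `"clamp"` (positions are clamped to the box after every
#'   update).
#' @return an object of class `avoa_config`.
#' @export
avoa_config <- function(lower, upper,
                        population_size = 10L, max_iterations = 20L,
                        Q1 = 0.6, Q2 = 0.4, Q3 = 0.6,
                        L1 = 0.8, L2 = 0.2, w = 2.5,
                        h_range = c(-2, 2), seed = 1L,
                        roulette = c("weights", "fitness"),
                        rotating = c("printed", "original"),
                        boundary = "clamp") {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper) || any(!is.finite(c(lower, upper))) ||
      any(lower >= upper)) {
    stop_field("bounds", "need finite lower < upper per dimension")
  }
  for (q in c(Q1, Q2, Q3)) check_unit(q, "Q1/Q2/Q3")
  if (abs(L1 + L2 - 1) > 1e-12) stop_field("L1/L2", "must sum to 1")
  cfg <- list(lower = lower, upper = upper,
              population_size = check_count(population_size, "population_size", 2L),
              max_iterations = check_count(max_iterations, "max_iterations"),
              Q1 = Q1, Q2 = Q2, Q3 = Q3, L1 = L1, L2 = L2, w = w,
              h_range = as.numeric(h_range), seed = check_count(seed, "seed", 0L),
              roulette = match.arg(roulette), rotating = match.arg(rotating),
              boundary = boundary)
  class(cfg) <- "avoa_config"
  cfg
}

.clamp <- function(x, cfg) pmin(pmax(x, cfg$lower), cfg$upper)

#' Fitness-share normalization of Eq.-(6) form
#'
#' `q_i = F_i / sum(F)`; e.g. fitnesses (1, 3) give shares (0.25, 0.75).
#'
#' @param fitness numeric vector of fitness values.
#' @return numeric vector of shares summing to 1.
#' @export
fitness_share <- function(fitness) fitness / sum(fitness)

#' Roulette selection between the two group bests
#'
#' Default mode: two-arm roulette with weights L1 and L2 (so best1 is
#' returned with probability L1). Mode `"fitness"` uses the fitness-share
#' normalization of the two bests instead.
#'
#' @param best1,best2 lists with `position` and `fitness`.
#' @param L1,L2 selection weights summing to 1.
#' @param mode `"weights"` or `"fitness"`.
#' @return the selected position vector.
#' @export
roulette_select <- function(best1, best2, L1 = 0.8, L2 = 0.2,
                            mode = c("weights", "fitness")) {
  mode <- match.arg(mode)
  p1 <- if (mode == "weights") L1 / (L1 + L2)
        else fitness_share(c(best1$fitness, best2$fitness))[1]
  if (stats::runif(1) < p1) best1$position else best2$position
}

#' Satiety schedule F
#'
#' `u = h * (sin^w(pi/2 * t) + cos(pi/2 * t) - 1)` with
#' `t = iteration / max_iterations` and h drawn uniformly from `h_range`;
#' `F = (2 * rand1 + 1) * z1 * (1 - t) + u` with z1 uniform on \[-1, 1\].
#' Exactly 0 at the final iteration for any draws.
#'
#' @param iteration current iteration (0 to `max_iterations`).
#' @param max_iterations iteration budget.
#' @param config an [avoa_config()] (supplies w and h_range).
#' @return scalar F.
#' @export
satiety <- function(iteration, max_iterations, config) {
  t <- iteration / max_iterations
  h <- stats::runif(1, config$h_range[1], config$h_range[2])
  z1 <- stats::runif(1, -1, 1)
  rand1 <- stats::runif(1)
  u <- h * (sin(pi / 2 * t)^config$w + cos(pi / 2 * t) - 1)
  (2 * rand1 + 1) * z1 * (1 - t) + u
}

#' Exploration move (|F| >= 1)
#'
#' With probability Q1: `X - |T * X - Q| * F` with T drawn uniformly from
#' \[0, 2\] per dimension (prey-encircling move around the selected best X);
#' otherwise a jump toward a random point of the box:
#' `X - F + r2 * ((ub - lb) * r3 + lb)`. Clamped to the bounds.
#'
#' @param X selected best position.
#' @param Q current vulture position.
#' @param F satiety value.
#' @param config an [avoa_config()].
#' @return new position vector.
#' @export
explore_step <- function(X, Q, F, config) {
  d <- length(X)
  new <- if (stats::runif(1) <= config$Q1) {
    T <- stats::runif(d, 0, 2)
    X - abs(T * X - Q) * F
  } else {
    r2 <- stats::runif(1)
    r3 <- stats::runif(d)
    X - F + r2 * ((config$upper - config$lower) * r3 + config$lower)
  }
  .clamp(new, config)
}

# Mantegna's algorithm for Levy-stable step lengths (stability beta = 1.5).
levy_flight <- function(d, beta = 1.5) {
  sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
                (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- stats::rnorm(d, 0, sigma_u)
  v <- stats::rnorm(d)
  u / abs(v)^(1 / beta)
}

#' Exploitation move (|F| < 1)
#'
#' For `0.5 <= |F| < 1` (phase 1), branch on Q2: a siege move
#' `|T * X - Q| * (F + r4) - (X - Q)` or a rotating-flight move
#' `X - X * (Q / (2*pi)) * (r5 * cos(Q) + r6 * sin(Q))`. For `|F| < 0.5`
#' (phase 2), branch on Q3: accumulation around the two group bests
#' `0.5 * (BV1 + BV2 - (BV1*Q/(BV1 - Q^2) + BV2*Q/(BV2 - Q^2)) * F)`
#' or a Levy-flight scatter `X - |X - Q| * F * LF(d)`. Any non-finite
#' component of the accumulation move (degenerate denominator) falls back
#' to the current position. Clamped to the bounds.
#'
#' @inheritParams explore_step
#' @param best1,best2 group bests (lists with `position`).
#' @return new position vector.
#' @export
exploit_step <- function(X, Q, F, best1, best2, config) {
  d <- length(X)
  new <- if (abs(F) >= 0.5) {
    if (stats::runif(1) <= config$Q2) {
      T <- stats::runif(d, 0, 2)
      r4 <- stats::runif(1)
      abs(T * X - Q) * (F + r4) - (X - Q)
    } else {
      r5 <- stats::runif(1); r6 <- stats::runif(1)
      angle <- if (config$rotating == "printed") Q else X - Q
      X - X * (angle / (2 * pi)) * (r5 * cos(angle) + r6 * sin(angle))
    }
  } else {
    if (stats::runif(1) <= config$Q3) {
      bv1 <- best1$position; bv2 <- best2$position
      a1 <- bv1 * Q / (bv1 - Q^2)
      a2 <- bv2 * Q / (bv2 - Q^2)
      out <- 0.5 * (bv1 + bv2 - (a1 + a2) * F)
      out[!is.finite(out)] <- Q[!is.finite(out)]
      out
    } else {
      X - abs(X - Q) * F * levy_flight(d)
    }
  }
  .clamp(new, config)
}

#' Minimize a black-box objective with the vulture algorithm
#'
#' Runs the evaluate / rank-two-bests / roulette-target / satiety /
#' explore-or-exploit loop for `max_iterations` iterations. Candidates
#' whose objective errors or returns a non-finite value absorb the worst
#' finite fitness seen so far (1.0 -- the BER maximum -- if none yet) so
#' the population size stays fixed. Deterministic per config seed.
#'
#' @param objective function mapping a numeric vector to a scalar fitness
#'   (lower is better).
#' @param config an [avoa_config()].
#' @param init optional matrix of initial positions (rows; recycled /
#'   truncated to the population size), e.g. to seed the search with an
#'   incumbent solution.
#' @return list with `best_position`, `best_fitness`, `history`
#'   (data.frame: iteration, best_fitness, satiety mean), `best_trace`
#'   (matrix of per-iteration best positions), `n_failures`,
#'   `personal_best` (list of per-vulture bests).
#' @export
avoa_optimize <- function(objective, config, init = NULL) {
  stopifnot(inherits(config, "avoa_config"))
  d <- length(config$lower)
  K <- config$population_size
  worst_seen <- -Inf
  n_fail <- 0L

  eval_one <- function(x) {
    f <- tryCatch(objective(x), error = function(e) NaN)
    if (!is.finite(f)) {
      n_fail <<- n_fail + 1L
      f <- if (is.finite(worst_seen)) worst_seen else 1.0
    }
    worst_seen <<- max(worst_seen, f)
    f
  }

  with_seed(config$seed, {
    pos <- matrix(stats::runif(K * d, rep(config$lower, each = K),
                               rep(config$upper, each = K)), nrow = K)
    if (!is.null(init)) {
      init <- matrix(init, ncol = d)
      for (i in seq_len(min(nrow(init), K))) {
        pos[i, ] <- .clamp(init[i, ], config)
      }
    }
    fit <- apply(pos, 1, eval_one)
    pbest_pos <- pos
    pbest_fit <- fit
    gbest_i <- which.min(fit)
    gbest <- list(position = pos[gbest_i, ], fitness = fit[gbest_i])

    hist_fit <- numeric(config$max_iterations + 1L)
    hist_sat <- numeric(config$max_iterations + 1L)
    best_trace <- matrix(0, nrow = config$max_iterations + 1L, ncol = d)
    hist_fit[1] <- gbest$fitness
    best_trace[1, ] <- gbest$position

    for (it in seq_len(config$max_iterations)) {
      ord <- order(fit)
      best1 <- list(position = pos[ord[1], ], fitness = fit[ord[1]])
      best2 <- list(position = pos[ord[2], ], fitness = fit[ord[2]])
      sats <- numeric(K)
      for (j in seq_len(K)) {
        X <- roulette_select(best1, best2, config$L1, config$L2,
                             mode = config$roulette)
        F <- satiety(it, config$max_iterations, config)
        sats[j] <- F
        Q <- pos[j, ]
        pos[j, ] <- if (abs(F) >= 1) {
          explore_step(X, Q, F, config)
        } else {
          exploit_step(X, Q, F, best1, best2, config)
        }
      }
      fit <- apply(pos, 1, eval_one)
      improved <- fit < pbest_fit
      pbest_pos[improved, ] <- pos[improved, , drop = FALSE]
      pbest_fit[improved] <- fit[improved]
      if (min(fit) < gbest$fitness) {
        i <- which.min(fit)
        gbest <- list(position = pos[i, ], fitness = fit[i])
      }
      hist_fit[it + 1L] <- gbest$fitness
      hist_sat[it + 1L] <- mean(sats)
      best_trace[it + 1L, ] <- gbest$position
    }

    list(best_position = gbest$position,
         best_fitness = gbest$fitness,
         history = data.frame(iteration = 0:config$max_iterations,
                              best_fitness = hist_fit,
                              mean_satiety = hist_sat),
         best_trace = best_trace,
         n_failures = n_fail,
         personal_best = list(positions = pbest_pos, fitness = pbest_fit))
  })
}

#' Write a search history as CSV
#' @param result an [avoa_optimize()] result.
#' @param path output path.
#' @export
write_history <- function(result, path) {
  utils::write.csv(cbind(result$history,
                         as.data.frame(result$best_trace)),
                   path, row.names = FALSE)
  invisible(path)
}
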