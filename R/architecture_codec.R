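# Genotype <-> CNN architecture codec --------------------------------------
#
# A candidate network is an integer triple (c, p, f): the numbers of
# convolutional, pooling and fully connected layers. Decoding places one
# convolution block first, the f fully connected layers contiguously at the
# tail (the last one with n_classes units), and interleaves the remaining
# conv blocks and poolings at seeded-random positions. Counting convention
# (which reproduces the printed 12- and 17-layer reference stacks): every
# convolution contributes conv + batch-norm + activation (3 layers),
# pooling and fully connected layers contribute 1 each, so the stack has
# 3c + p + f layers.

FILTER_CHOICES <- c(8L, 16L, 32L)
FILTER_SIZE_CHOICES <- c(3L, 5L, 7L)
POOL_RANGE <- c(2L, 5L)
HIDDEN_RANGE <- c(10L, 1024L)
BATCH_CHOICES <- c(8L, 16L, 32L, 64L, 128L)
OPTIMIZER_CHOICES <- c("adam", "sgdm", "rmsprop")
LAYER_TOTAL_RANGE <- c(3L, 11L)

# stage-1 fixed hyperparameters while the layer structure is being searched
DEFAULT_HYPER <- list(filters = 8L, filter_size = 3L, pool_size = 2L,
                      hidden_units = 1024L, optimizer = "adam",
                      batch_size = 32L)

#' CNN genotype: layer counts (conv, pool, fully connected)
#'
#' @param n_conv,n_pool,n_fc layer counts, each >= 1, with
#'   `n_conv + n_pool + n_fc` in \[3, 11\].
#' @return an object of class `genotype`.
#' @export
genotype <- function(n_conv, n_pool, n_fc) {
  g <- list(n_conv = check_count(n_conv, "n_conv"),
            n_pool = check_count(n_pool, "n_pool"),
            n_fc = check_count(n_fc, "n_fc"))
  total <- g$n_conv + g$n_pool + g$n_fc
  if (total < LAYER_TOTAL_RANGE[1] || total > LAYER_TOTAL_RANGE[2]) {
    stop_field("n_conv + n_pool + n_fc",
               sprintf("must lie in [%d, %d]", LAYER_TOTAL_RANGE[1],
                       LAYER_TOTAL_RANGE[2]))
  }
  structure(g, class = "genotype")
}

#' Default per-dimension bounds of the genotype search space
#'
#' Minimum one layer of each kind; maxima 5/4/3 span both reference
#' architectures.
#' @return list of three integer intervals (conv, pool, fc).
#' @export
genotype_bounds <- function() {
  list(conv = c(1L, 5L), pool = c(1L, 4L), fc = c(1L, 3L))
}

#' Initialize a random genotype population
#'
#' Each row is drawn uniformly per dimension (integer `randint` draws) and
#' rejection-resampled until the total layer count constraint (3-11) holds.
#'
#' @param K population size.
#' @param bounds list of three integer intervals as in [genotype_bounds()].
#' @param seed integer seed.
#' @return K x 3 integer matrix; every row is a valid genotype.
#' @export
init_population <- function(K, bounds = genotype_bounds(), seed = 1L) {
  K <- check_count(K, "K")
  lo <- vapply(bounds, function(b) as.integer(b[1]), integer(1))
  hi <- vapply(bounds, function(b) as.integer(b[2]), integer(1))
  if (any(lo < 1L) || any(hi < lo)) stop_field("bounds", "must have 1 <= lo <= hi")
  if (sum(lo) > LAYER_TOTAL_RANGE[2] || sum(hi) < LAYER_TOTAL_RANGE[1]) {
    stop_field("bounds", "total layer count constraint unattainable")
  }
  with_seed(seed, {
    draw_row <- function() {
      repeat {
        row <- vapply(seq_len(3), function(d)
          sample_from(seq.int(lo[d], hi[d]), 1L), integer(1))
        s <- sum(row)
        if (s >= LAYER_TOTAL_RANGE[1] && s <= LAYER_TOTAL_RANGE[2]) return(row)
      }
    }
    m <- t(vapply(seq_len(K), function(.) draw_row(), integer(3)))
    colnames(m) <- c("conv", "pool", "fc")
    m
  })
}

#' Number of free hyperparameters of a genotype
#'
#' `m = 2c + p + h`: two per convolution (filter count, filter size), one
#' per pooling (kernel size), one per hidden fully connected layer
#' (`h = n_fc - 1`; the output layer's width is fixed at the class count).
#'
#' @param g a [genotype()].
#' @return integer m.
#' @export
hyperparameter_dimension <- function(g) {
  stopifnot(inherits(g, "genotype"))
  2L * g$n_conv + g$n_pool + (g$n_fc - 1L)
}

.layer <- function(kind, ...) list(kind = kind, params = list(...))

#' Decode a genotype into an ordered layer stack
#'
#' The first layer is always a convolution (followed, like every
#' convolution, by batch normalization and an activation); the fully
#' connected layers sit contiguously at the tail, the last one with
#' `n_classes` units. The remaining conv blocks and pooling layers are
#' interleaved at seeded-uniform random positions. Spatial validity is
#' enforced afterwards by [validate_and_repair()].
#'
#' @param g a [genotype()].
#' @param n_classes output classes (2 here: exon vs intron).
#' @param seed integer seed for the placement draw.
#' @param hyper optional hyperparameter assignment from
#'   [position_to_hyperparameters()]; defaults are filters 8, size 3,
#'   pool 2, hidden 1024.
#' @return an object of class `architecture_plan`.
#' @export
decode_genotype <- function(g, n_classes = 2L, seed = 1L, hyper = NULL) {
  stopifnot(inherits(g, "genotype"))
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  mid <- c(rep("conv", g$n_conv - 1L), rep("pool", g$n_pool))
  order <- with_seed(seed, shuffle(mid))
  tokens <- c("conv", order, rep("fc", g$n_fc - 1L), "out")

  h <- if (is.null(hyper)) {
    list(filters = rep(DEFAULT_HYPER$filters, g$n_conv),
         filter_size = rep(DEFAULT_HYPER$filter_size, g$n_conv),
         pool_size = rep(DEFAULT_HYPER$pool_size, g$n_pool),
         hidden_units = rep(DEFAULT_HYPER$hidden_units, max(0L, g$n_fc - 1L)))
  } else hyper

  layers <- list()
  i_conv <- 0L; i_pool <- 0L; i_fc <- 0L
  for (tok in tokens) {
    if (tok == "conv") {
      i_conv <- i_conv + 1L
      layers <- c(layers, list(
        .layer("convolution", filters = h$filters[i_conv],
               filter_size = h$filter_size[i_conv]),
        .layer("batch_normalization"),
        .layer("activation")))
    } else if (tok == "pool") {
      i_pool <- i_pool + 1L
      layers <- c(layers, list(.layer("max_pooling",
                                      pool_size = h$pool_size[i_pool])))
    } else if (tok == "fc") {
      i_fc <- i_fc + 1L
      layers <- c(layers, list(.layer("fully_connected",
                                      units = h$hidden_units[i_fc])))
    } else {
      layers <- c(layers, list(.layer("fully_connected", units = n_classes)))
    }
  }
  plan <- structure(
    list(layers = layers, n_classes = n_classes,
         input_shape = c(16L, 16L, 1L), genotype = g, seed = seed,
         repair_log = character(0)),
    class = "architecture_plan")
  validate_and_repair(plan)
}

#' Count layers of an architecture plan
#' @param plan an `architecture_plan`.
#' @return integer: length of the layer stack.
#' @export
n_layers <- function(plan) length(plan$layers)

#' Validate spatial dimensions and repair invalid pooling
#'
#' Simulates the spatial size through the stack starting from 16x16
#' (convolutions preserve size; a pooling of size P maps d to
#' `floor(d / P)` and requires `d >= P`). Any pooling layer that would
#' reduce a dimension below 1 is removed, right-most first, until the plan
#' is valid; removals are recorded in `repair_log`.
#'
#' @param plan an `architecture_plan`.
#' @return the repaired plan.
#' @export
validate_and_repair <- function(plan) {
  stopifnot(inherits(plan, "architecture_plan"))
  kinds <- vapply(plan$layers, `[[`, character(1), "kind")
  if (length(kinds) == 0 || kinds[1] != "convolution") {
    stop("first layer must be a convolution", call. = FALSE)
  }
  if (kinds[length(kinds)] != "fully_connected") {
    stop("last layer must be fully connected", call. = FALSE)
  }
  repeat {
    kinds <- vapply(plan$layers, `[[`, character(1), "kind")
    d <- plan$input_shape[1]
    offender <- 0L
    for (i in seq_along(kinds)) {
      if (kinds[i] == "max_pooling") {
        p <- plan$layers[[i]]$params$pool_size
        if (d < p) { offender <- i; break }
        d <- d %/% p
      }
    }
    if (offender == 0L) break
    drop <- max(which(kinds == "max_pooling"))   # right-most first
    plan$repair_log <- c(plan$repair_log, sprintf(
      "removed max_pooling at layer %d (size %d): spatial dimension would drop below 1",
      drop, plan$layers[[drop]]$params$pool_size))
    plan$layers[[drop]] <- NULL
    if (!any(vapply(plan$layers, `[[`, character(1), "kind") == "convolution")) {
      stop("irreparable plan: no valid convolution path", call. = FALSE)
    }
  }
  plan
}

#' @export
print.architecture_plan <- function(x, ...) {
  cat(sprintf("architecture_plan: %d layers (genotype c=%d p=%d f=%d)\n",
              n_layers(x), x$genotype$n_conv, x$genotype$n_pool,
              x$genotype$n_fc))
  for (l in x$layers) {
    p <- if (length(l$params)) {
      paste0(" [", paste(names(l$params), unlist(l$params), sep = "=",
                         collapse = ", "), "]")
    } else ""
    cat("  -", l$kind, p, "\n")
  }
  if (length(x$repair_log)) cat("  repairs:", length(x$repair_log), "\n")
  invisible(x)
}

# Nearest admissible value in a discrete set (ties -> smaller value).
.nearest <- function(x, set) set[which.min(abs(set - x))]

.clamp_round <- function(x, range) {
  as.integer(min(max(round(x), range[1]), range[2]))
}

#' Map a continuous position to a hyperparameter assignment
#'
#' The AVOA searches a continuous box; each coordinate is clamped to its
#' range and rounded to the nearest admissible value. The vector has
#' length m + 2: per convolution (filters, filter size), per pooling
#' (kernel size), per hidden fully connected layer (units), then the
#' optimizer slot (1-3) and the mini-batch size slot. Idempotent on
#' admissible vectors.
#'
#' @param position numeric vector of length
#'   `hyperparameter_dimension(g) + 2`.
#' @param g a [genotype()].
#' @return list with per-layer assignments (`filters`, `filter_size`,
#'   `pool_size`, `hidden_units`), `optimizer`, `batch_size`, and `values`,
#'   the admissible numeric vector the position maps to.
#' @export
position_to_hyperparameters <- function(position, g) {
  stopifnot(inherits(g, "genotype"))
  m <- hyperparameter_dimension(g)
  if (length(position) != m + 2L) {
    stop(sprintf("position length %d; expected m + 2 = %d",
                 length(position), m + 2L), call. = FALSE)
  }
  c_ <- g$n_conv; p_ <- g$n_pool; h_ <- g$n_fc - 1L
  filters <- integer(c_); fsize <- integer(c_)
  for (i in seq_len(c_)) {
    filters[i] <- .nearest(position[2L * i - 1L], FILTER_CHOICES)
    fsize[i] <- .nearest(position[2L * i], FILTER_SIZE_CHOICES)
  }
  pool <- vapply(seq_len(p_), function(i)
    .clamp_round(position[2L * c_ + i], POOL_RANGE), integer(1))
  hidden <- if (h_ > 0) vapply(seq_len(h_), function(i)
    .clamp_round(position[2L * c_ + p_ + i], HIDDEN_RANGE), integer(1))
    else integer(0)
  opt_i <- .clamp_round(position[m + 1L], c(1L, 3L))
  batch <- .nearest(position[m + 2L], BATCH_CHOICES)
  list(filters = filters, filter_size = fsize, pool_size = pool,
       hidden_units = hidden,
       optimizer = OPTIMIZER_CHOICES[opt_i], batch_size = batch,
       values = c(rbind(filters, fsize)[seq_len(2L * c_)], pool, hidden,
                  opt_i, batch))
}

#' Search-box bounds for the hyperparameter vector of a genotype
#'
#' @param g a [genotype()].
#' @return list with `lower` and `upper` numeric vectors of length m + 2.
#' @export
hyperparameter_bounds <- function(g) {
  stopifnot(inherits(g, "genotype"))
  c_ <- g$n_conv; p_ <- g$n_pool; h_ <- g$n_fc - 1L
  lower <- c(rep(c(min(FILTER_CHOICES), min(FILTER_SIZE_CHOICES)), c_),
             rep(POOL_RANGE[1], p_), rep(HIDDEN_RANGE[1], h_),
             1, min(BATCH_CHOICES))
  upper <- c(rep(c(max(FILTER_CHOICES), max(FILTER_SIZE_CHOICES)), c_),
             rep(POOL_RANGE[2], p_), rep(HIDDEN_RANGE[2], h_),
             3, max(BATCH_CHOICES))
  list(lower = as.numeric(lower), upper = as.numeric(upper))
}

#' Serialize an architecture plan to JSON
#' @param plan an `architecture_plan`.
#' @param path optional file path; if NULL the JSON string is returned.
#' @export
plan_to_json <- function(plan, path = NULL) {
  obj <- list(
    genotype = unclass(plan$genotype),
    n_classes = plan$n_classes,
    input_shape = plan$input_shape,
    seed = plan$seed,
    repair_log = plan$repair_log,
    layers = lapply(plan$layers, function(l)
      c(list(kind = l$kind), l$params)))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}
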