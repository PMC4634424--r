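# Kohonen self-organizing map: PCA linear initialization, winner search,
# Gaussian-neighborhood updates, and the sequential training loop with a
# linearly decaying learning rate eta(k) = eta0 * (1 - k / NK).

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.as_feature_matrix <- function(data) {
  if (is.list(data) && !is.data.frame(data)) data <- do.call(rbind, data)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("non-finite feature values")
  data
}

.grid_coords <- function(M, N) {
  # row-major neuron order: neuron j = (r-1)*N + c
  cbind(row = rep(seq_len(M), each = N), col = rep(seq_len(N), times = M))
}

.new_som_grid <- function(weights, M, N, schedule = NULL) {
  structure(list(M = as.integer(M), N = as.integer(N),
                 dim = ncol(weights), weights = weights,
                 coords = .grid_coords(M, N), schedule = schedule),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("som_grid: %d x %d neurons, %d-D weights\n", x$M, x$N, x$dim))
  invisible(x)
}

#' Training schedule for the self-organizing map
#'
#' Defaults are the published operating point: initial learning rate
#' `eta0 = 0.1`, `n_epochs = 100` iterations (the epoch counter is the `k`
#' of the decay `eta(k) = eta0 * (1 - k / NK)` with `NK = n_epochs`), and a
#' constant Gaussian neighborhood width `sigma = 1.0` grid unit.
#'
#' @param eta0 Initial learning rate in `(0, 1]`.
#' @param n_epochs Number of passes over the data (`NK`).
#' @param sigma Neighborhood width (grid units), constant over training.
#' @param seed Integer seed driving initialization and per-epoch shuffles.
#' @return List of class `"som_schedule"`.
#' @export
som_schedule <- function(eta0 = 0.1, n_epochs = 100L, sigma = 1.0, seed = 1L) {
  stopifnot(eta0 >= 0, eta0 <= 1, n_epochs >= 1, sigma > 0)
  structure(list(eta0 = eta0, n_epochs = as.integer(n_epochs),
                 sigma = sigma, seed = as.integer(seed)),
            class = "som_schedule")
}

#' Initialize a map on the data's principal plane
#'
#' Linear initialization: grid rows span the first principal direction of
#' the training data and grid columns the second, each over the range of the
#' data's projections, shrunk (uniformly, so planar data stays planar) until
#' every initial weight lies inside the axis-aligned bounding box of the
#' data. When the data have rank < 2 the missing directions are replaced by
#' small seeded jitter; fully degenerate data collapse every weight onto the
#' common point.
#'
#' @param data Feature matrix (rows = observations) or list of vectors.
#' @param M,N Grid rows / columns, both >= 2.
#' @param seed Integer seed (used only by the jitter fallback).
#' @return A `som_grid`.
#' @export
initialize_grid <- function(data, M, N, seed = 1L) {
  data <- .as_feature_matrix(data)
  if (nrow(data) == 0L) stop("empty training data")
  stopifnot(M >= 2, N >= 2)
  d <- ncol(data)
  mu <- colMeans(data)
  lo <- apply(data, 2L, min)
  hi <- apply(data, 2L, max)
  centered <- sweep(data, 2L, mu)
  sv <- svd(centered, nu = 0L, nv = min(2L, d))
  tol <- max(sv$d[1L], 0) * 1e-8
  rank2 <- sum(sv$d[seq_len(min(2L, length(sv$d)))] > tol)

  coords <- .grid_coords(M, N)
  offsets <- .with_seed(seed, {
    span <- function(v, K, steps) {
      p <- as.vector(centered %*% v)
      a <- seq(min(p), max(p), length.out = K)
      outer(a[steps], v)
    }
    if (rank2 >= 2L) {
      span(sv$v[, 1L], M, coords[, "row"]) + span(sv$v[, 2L], N, coords[, "col"])
    } else {
      jit <- matrix(stats::rnorm(M * N * d, sd = 1e-3 * max(hi - lo, 1e-12)),
                    nrow = M * N)
      if (rank2 == 1L) span(sv$v[, 1L], M, coords[, "row"]) + jit else jit
    }
  })

  # uniform shrink so every weight stays in the data bounding box
  s <- 1
  for (k in seq_len(d)) {
    off <- offsets[, k]
    pos <- off > 0
    neg <- off < 0
    if (any(pos)) s <- min(s, (hi[k] - mu[k]) / max(off[pos]))
    if (any(neg)) s <- min(s, (lo[k] - mu[k]) / min(off[neg]))
  }
  s <- max(s, 0)
  weights <- sweep(s * offsets, 2L, mu, `+`)
  colnames(weights) <- colnames(data)
  .new_som_grid(weights, M, N)
}

#' Winning neuron of an input
#'
#' Minimum-Euclidean-distance competition over all `M x N` neurons; ties go
#' to the lowest row-major linear index.
#'
#' @param grid A `som_grid`.
#' @param x Feature vector matching the grid dimension.
#' @return Integer neuron index in `1..M*N` (row-major).
#' @export
find_winner <- function(grid, x) {
  x <- as.numeric(x)
  if (length(x) != grid$dim) {
    stop("input dimension ", length(x), " does not match grid dimension ",
         grid$dim)
  }
  d2 <- rowSums(sweep(grid$weights, 2L, x)^2)
  which.min(d2)
}

#' @rdname find_winner
#' @param X Feature matrix, one input per row.
#' @return `find_winners`: integer vector of winner indices, one per row.
#' @export
find_winners <- function(grid, X) {
  X <- .as_feature_matrix(X)
  if (ncol(X) != grid$dim) {
    stop("input dimension ", ncol(X), " does not match grid dimension ",
         grid$dim)
  }
  W <- grid$weights
  # ||x - w||^2 = ||x||^2 - 2 x.w + ||w||^2; ||x||^2 constant per row
  cross <- X %*% t(W)
  d2 <- sweep(-2 * cross, 2L, rowSums(W * W), `+`)
  max.col(-d2, ties.method = "first")
}

#' Single neighborhood-weighted update
#'
#' Moves every neuron toward `x` by `eta * exp(-d^2 / (2 sigma^2))`, where
#' `d` is the Euclidean lateral distance on the grid from the winner. The
#' reference R implementation of the update rule; training uses an
#' equivalent compiled loop.
#'
#' @param grid A `som_grid`.
#' @param x Input vector.
#' @param winner Winner index (from [find_winner()]).
#' @param eta Learning rate in `[0, 1]`.
#' @param sigma Neighborhood width.
#' @return Updated `som_grid`.
#' @export
update_weights <- function(grid, x, winner, eta, sigma = 1.0) {
  stopifnot(eta >= 0, eta <= 1, sigma > 0)
  x <- as.numeric(x)
  d2 <- (grid$coords[, "row"] - grid$coords[winner, "row"])^2 +
    (grid$coords[, "col"] - grid$coords[winner, "col"])^2
  lam <- eta * exp(-d2 / (2 * sigma^2))
  target <- matrix(x, nrow = nrow(grid$weights), ncol = grid$dim, byrow = TRUE)
  grid$weights <- grid$weights + lam * (target - grid$weights)
  grid
}

#' Train a self-organizing map
#'
#' Sequential Kohonen training: data shuffled each epoch with the seeded
#' generator, winner by [find_winner()]'s rule, Gaussian-neighborhood update
#' of all neurons, learning rate `eta(k) = eta0 * (1 - k / NK)` with `k` the
#' number of completed epochs (all samples of one epoch share one rate; the
#' final epoch runs at `eta0 / NK`). Deterministic given the schedule seed.
#'
#' @param data Feature matrix or list of feature vectors.
#' @param M,N Grid size (default 10 x 10).
#' @param schedule A [som_schedule()].
#' @return Trained `som_grid` (schedule stored in the result).
#' @export
som_train <- function(data, M = 10L, N = 10L, schedule = som_schedule()) {
  data <- .as_feature_matrix(data)
  if (nrow(data) == 0L) stop("empty training data")
  grid <- initialize_grid(data, M, N, seed = schedule$seed)
  n <- nrow(data)
  E <- schedule$n_epochs
  orders <- .with_seed(schedule$seed + 1L,
                       vapply(seq_len(E), function(e) sample.int(n), integer(n)))
  etas <- schedule$eta0 * (1 - (seq_len(E) - 1) / E)
  tW <- som_train_cpp(t(grid$weights), t(data),
                      grid$coords[, "row"], grid$coords[, "col"],
                      orders - 1L, etas, schedule$sigma)
  grid$weights <- t(tW)
  colnames(grid$weights) <- colnames(data)
  grid$schedule <- schedule
  grid
}

#' Mean quantization error
#'
#' Mean Euclidean distance from each data vector to its winning neuron's
#' weight; the standard SOM fit diagnostic.
#'
#' @param grid A `som_grid`.
#' @param data Feature matrix.
#' @return Non-negative scalar.
#' @export
quantization_error <- function(grid, data) {
  data <- .as_feature_matrix(data)
  w <- find_winners(grid, data)
  mean(sqrt(rowSums((data - grid$weights[w, , drop = FALSE])^2)))
}
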