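# Basic posture units: U-matrix of a trained map, marker-controlled
# watershed into catchment basins, merging of shallow basins into their
# deeper neighbors (over-segmentation control), and per-basin
# representative postures.

.neighbors8 <- function(M, N) {
  # list of 8-connected neighbor linear indices (row-major) per cell
  coords <- .grid_coords(M, N)
  lapply(seq_len(M * N), function(j) {
    r <- coords[j, 1L]; c0 <- coords[j, 2L]
    rr <- rep(r + (-1):1, each = 3L)
    cc <- rep(c0 + (-1):1, times = 3L)
    keep <- rr >= 1L & rr <= M & cc >= 1L & cc <= N & !(rr == r & cc == c0)
    (rr[keep] - 1L) * N + cc[keep]
  })
}

#' Unified distance matrix (U-matrix) of a trained map
#'
#' Entry `(r, c)` is the mean Euclidean distance between neuron `(r, c)`'s
#' weight and the weights of its 8-connected grid neighbors (edge and corner
#' neurons average over the neighbors they have), min-max normalized to
#' `[0, 1]`. A constant-weight map yields all zeros. High values mark
#' cluster borders.
#'
#' @param grid A `som_grid`.
#' @return `M x N` numeric matrix in `[0, 1]`.
#' @export
compute_umatrix <- function(grid) {
  M <- grid$M; N <- grid$N
  nb <- .neighbors8(M, N)
  W <- grid$weights
  u <- vapply(seq_len(M * N), function(j) {
    diff <- W[nb[[j]], , drop = FALSE] -
      matrix(W[j, ], nrow = length(nb[[j]]), ncol = ncol(W), byrow = TRUE)
    mean(sqrt(rowSums(diff * diff)))
  }, numeric(1L))
  rng <- max(u) - min(u)
  if (rng > 0) u <- (u - min(u)) / rng else u <- rep(0, length(u))
  matrix(u, nrow = M, ncol = N, byrow = TRUE)
}

#' Watershed segmentation of a U-matrix
#'
#' Marker-controlled flooding: the U-matrix is quantized to 256 gray levels,
#' markers are its 8-connected regional minima (plateaus with no strictly
#' lower neighbor), and basins grow by Meyer's priority flood in increasing
#' height, so every neuron is assigned to exactly one 8-connected basin.
#' Deterministic: markers are numbered in row-major order of their first
#' cell; floods pop the lowest (level, insertion-order) cell and adopt the
#' label of the lowest-valued labeled neighbor (ties to the lowest index).
#'
#' @param umatrix Matrix from [compute_umatrix()] (values in `[0, 1]`).
#' @return Integer `M x N` label matrix with values `1..B`.
#' @export
watershed_basins <- function(umatrix) {
  M <- nrow(umatrix); N <- ncol(umatrix)
  q <- as.integer(round(t(umatrix) * 255))  # row-major vector, 256 levels
  n <- M * N
  nb <- .neighbors8(M, N)

  # regional minima: flood equal-value plateaus, keep those with no lower rim
  labels <- integer(n)
  B <- 0L
  for (start in seq_len(n)) {
    if (labels[start] != 0L) next
    # collect the plateau of equal quantized value containing `start`
    plateau <- start
    frontier <- start
    seen <- logical(n); seen[start] <- TRUE
    while (length(frontier)) {
      nxt <- unique(unlist(nb[frontier]))
      nxt <- nxt[!seen[nxt] & q[nxt] == q[start]]
      seen[nxt] <- TRUE
      plateau <- c(plateau, nxt)
      frontier <- nxt
    }
    rim <- setdiff(unique(unlist(nb[plateau])), plateau)
    if (!length(rim) || all(q[rim] > q[start])) {
      if (any(labels[plateau] != 0L)) next
      B <- B + 1L
      labels[plateau] <- B
    } else {
      labels[plateau] <- -1L  # visited, not a minimum
    }
  }
  labels[labels == -1L] <- 0L

  # Meyer flood: priority = (quantized level, insertion counter)
  counter <- 0L
  in_queue <- logical(n)
  qlev <- integer(0); qord <- integer(0); qcell <- integer(0)
  push <- function(cells) {
    for (cell in cells) {
      if (labels[cell] == 0L && !in_queue[cell]) {
        counter <<- counter + 1L
        in_queue[cell] <<- TRUE
        qlev <<- c(qlev, q[cell]); qord <<- c(qord, counter)
        qcell <<- c(qcell, cell)
      }
    }
  }
  push(unlist(nb[which(labels != 0L)]))
  while (length(qcell)) {
    best <- order(qlev, qord)[1L]
    cell <- qcell[best]
    qlev <- qlev[-best]; qord <- qord[-best]; qcell <- qcell[-best]
    labeled <- nb[[cell]][labels[nb[[cell]]] != 0L]
    labeled <- labeled[order(q[labeled], labeled)]
    labels[cell] <- labels[labeled[1L]]
    push(nb[[cell]])
  }
  matrix(labels, nrow = M, ncol = N, byrow = TRUE)
}

.basin_depths <- function(labeling, umatrix) {
  # per-basin depth = (lowest boundary saddle with any neighbor) - (min U),
  # where the saddle over an adjacent cell pair is max(u_a, u_b)
  M <- nrow(labeling); N <- ncol(labeling)
  lab <- as.integer(t(labeling))
  u <- as.numeric(t(umatrix))
  nb <- .neighbors8(M, N)
  ids <- sort(unique(lab))
  saddle <- matrix(Inf, length(ids), length(ids), dimnames = list(ids, ids))
  for (j in seq_along(lab)) {
    for (k in nb[[j]]) {
      if (lab[k] != lab[j]) {
        a <- match(lab[j], ids); b <- match(lab[k], ids)
        s <- max(u[j], u[k])
        if (s < saddle[a, b]) saddle[a, b] <- saddle[b, a] <- s
      }
    }
  }
  minu <- vapply(ids, function(id) min(u[lab == id]), numeric(1L))
  list(ids = ids, saddle = saddle, minu = minu,
       depth = vapply(seq_along(ids),
                      function(a) min(saddle[a, -a]) - minu[a], numeric(1L)))
}

#' Merge shallow catchment basins
#'
#' Over-segmentation control: a basin's depth is the lowest saddle value on
#' its boundary minus its minimum U-value. While any basin has depth
#' strictly below `depth_frac` (on the normalized U scale), the shallowest
#' such basin (ties to the lowest label) is absorbed into the neighbor with
#' which it shares its lowest saddle. The basin count never increases, and
#' `depth_frac = 0` is a no-op.
#'
#' @param labeling Label matrix from [watershed_basins()].
#' @param umatrix The matching U-matrix.
#' @param depth_frac Depth threshold in `[0, 1]`; default 0.15.
#' @return Label matrix with consecutive labels `1..B` (row-major order of
#'   first appearance).
#' @export
merge_shallow_basins <- function(labeling, umatrix, depth_frac = 0.15) {
  stopifnot(depth_frac >= 0, depth_frac <= 1)
  lab <- labeling
  repeat {
    ids <- sort(unique(as.integer(lab)))
    if (length(ids) <= 1L) break
    d <- .basin_depths(lab, umatrix)
    shallow <- which(d$depth < depth_frac)
    if (!length(shallow)) break
    a <- shallow[order(d$depth[shallow], d$ids[shallow])][1L]
    others <- setdiff(seq_along(d$ids), a)
    tgt <- others[order(d$saddle[a, others], d$ids[others])][1L]
    lab[lab == d$ids[a]] <- d$ids[tgt]
  }
  # relabel 1..B in row-major first-appearance order
  seen <- unique(as.integer(t(lab)))
  matrix(match(as.integer(t(lab)), seen), nrow = nrow(lab),
         ncol = ncol(lab), byrow = TRUE)
}

#' Build the basic posture unit map
#'
#' Composes [compute_umatrix()], [watershed_basins()] and
#' [merge_shallow_basins()] on a trained map, then picks each basin's
#' representative posture: the weight vector of the basin's minimum-U neuron
#' (the basin's density core; ties to the lowest row-major index).
#'
#' @param grid Trained `som_grid`.
#' @param data Optional feature matrix; only used to check that its
#'   dimension matches the grid.
#' @param depth_frac Shallow-basin threshold, see [merge_shallow_basins()].
#' @return Object of class `"posture_map"`: list with `grid`, `umatrix`,
#'   `labeling`, `n_units`, `representatives` (B x dim matrix) and
#'   `rep_neurons` (their neuron indices).
#' @export
build_posture_map <- function(grid, data = NULL, depth_frac = 0.15) {
  if (!is.null(data)) {
    data <- .as_feature_matrix(data)
    if (ncol(data) != grid$dim) stop("data dimension does not match grid")
  }
  um <- compute_umatrix(grid)
  lab <- merge_shallow_basins(watershed_basins(um), um, depth_frac)
  B <- max(lab)
  uvec <- as.numeric(t(um))
  labvec <- as.integer(t(lab))
  rep_neurons <- vapply(seq_len(B), function(b) {
    members <- which(labvec == b)
    members[order(uvec[members], members)][1L]
  }, integer(1L))
  structure(list(grid = grid, umatrix = um, labeling = lab, n_units = B,
                 representatives = grid$weights[rep_neurons, , drop = FALSE],
                 rep_neurons = rep_neurons, depth_frac = depth_frac),
            class = "posture_map")
}

#' @export
print.posture_map <- function(x, ...) {
  cat(sprintf("posture_map: %d x %d map, %d basic posture units\n",
              x$grid$M, x$grid$N, x$n_units))
  invisible(x)
}

#' Basic posture unit of an input
#'
#' Label of the winning neuron's basin.
#'
#' @param pmap A `posture_map`.
#' @param x Feature vector.
#' @return Basin id in `1..B`.
#' @export
assign_basin <- function(pmap, x) {
  j <- find_winner(pmap$grid, x)
  as.integer(t(pmap$labeling))[j]
}

#' @rdname assign_basin
#' @param X Feature matrix, one input per row.
#' @return `assign_basins`: integer vector of basin ids.
#' @export
assign_basins <- function(pmap, X) {
  as.integer(t(pmap$labeling))[find_winners(pmap$grid, X)]
}
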