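# Shared fixtures: small frames, grids and posture maps built in code.

# random valid skeleton frame: canonical stance plus bounded joint noise
random_frame <- function(sd = 0.03) {
  f <- canonical_skeleton()
  skeleton_frame(f + matrix(stats::rnorm(60, sd = sd), 20, 3))
}

rotation_y <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
}

random_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]  # proper rotation only
  Q
}

rotate_frame <- function(frame, R, center = c(0, 0, 0)) {
  skeleton_frame(sweep(sweep(frame, 2, center) %*% t(R), 2, center, `+`))
}

# a som_grid with given weights (rows = neurons, row-major)
fixture_grid <- function(weights, M, N) {
  g <- initialize_grid(rbind(weights, weights), M, N, seed = 1)
  g$weights <- weights
  g
}

# posture map with a hand-made labeling; weights are 2-D points placed so
# that the input c(b, 0) wins a neuron of basin b
fixture_pmap <- function(labeling) {
  M <- nrow(labeling); N <- ncol(labeling)
  lab_vec <- as.integer(t(labeling))
  weights <- cbind(lab_vec, 1e-4 * seq_along(lab_vec))
  grid <- fixture_grid(weights, M, N)
  B <- max(lab_vec)
  rep_neurons <- match(seq_len(B), lab_vec)
  structure(list(grid = grid, umatrix = matrix(0, M, N), labeling = labeling,
                 n_units = B,
                 representatives = weights[rep_neurons, , drop = FALSE],
                 rep_neurons = rep_neurons, depth_frac = 0),
            class = "posture_map")
}

# feature matrix whose encoded basin sequence under fixture_pmap is `syms`
fixture_inputs <- function(syms) {
  cbind(as.numeric(syms), 0)
}

# exhaustive LCS oracle: enumerate all subsequences of the shortest input
# and keep the longest one common to all (first in enumeration order)
oracle_lcs <- function(seqs) {
  is_subseq <- function(sub, full) {
    if (length(sub) == 0) return(TRUE)
    j <- 1
    for (x in full) {
      if (x == sub[j]) {
        j <- j + 1
        if (j > length(sub)) return(TRUE)
      }
    }
    FALSE
  }
  base <- seqs[[which.min(lengths(seqs))]]
  n <- length(base)
  best <- integer(0)
  for (mask in seq_len(2^n) - 1L) {
    sub <- base[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
    if (length(sub) > length(best) &&
        all(vapply(seqs, function(s) is_subseq(sub, s), logical(1)))) {
      best <- sub
    }
  }
  best
}

is_subsequence <- function(sub, full) {
  if (length(sub) == 0) return(TRUE)
  j <- 1
  for (x in full) {
    if (x == sub[j]) {
      j <- j + 1
      if (j > length(sub)) return(TRUE)
    }
  }
  FALSE
}

# 8-connectivity check of every labeled region
regions_connected <- function(labeling) {
  M <- nrow(labeling); N <- ncol(labeling)
  for (b in unique(as.integer(labeling))) {
    cells <- which(labeling == b, arr.ind = TRUE)
    seen <- 1L
    frontier <- 1L
    done <- logical(nrow(cells))
    done[1] <- TRUE
    while (length(frontier)) {
      nxt <- integer(0)
      for (i in frontier) {
        adj <- which(!done & abs(cells[, 1] - cells[i, 1]) <= 1 &
                       abs(cells[, 2] - cells[i, 2]) <= 1)
        done[adj] <- TRUE
        nxt <- c(nxt, adj)
      }
      frontier <- nxt
    }
    if (!all(done)) return(FALSE)
  }
  TRUE
}
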