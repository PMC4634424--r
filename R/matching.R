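# Template distillation and classification: pairwise and exact
# multi-sequence longest common subsequence (LCS) to derive one template
# per exercise, normalized image correlation between trajectory maps, and
# maximum-similarity classification with threshold rejection.

#' Longest common subsequence of two sequences
#'
#' Standard dynamic program with a deterministic backtrack: prefer the
#' diagonal match, then the cell above (drop from `a`), then the cell to the
#' left (drop from `b`).
#'
#' @param a,b Integer vectors (collapsed posture sequences).
#' @return One longest common subsequence as an integer vector.
#' @export
lcs_pair <- function(a, b) {
  lcs_multi(list(a, b))
}

#' Longest common subsequence of up to six sequences
#'
#' Exact k-dimensional dynamic program: a cell scores the diagonal plus one
#' when all k current symbols agree, otherwise the maximum over dropping one
#' symbol from a single sequence. Guards (k <= 6, each length <= 64, at most
#' 2e6 table cells) keep the table tractable; beyond them the call errors
#' and advises pairwise approximation. Backtrack is deterministic: prefer
#' the all-match transition, then single-axis drops in axis order.
#'
#' @param seqs List of integer vectors.
#' @return A maximal-length common subsequence of every input (possibly
#'   empty), as an integer vector.
#' @export
lcs_multi <- function(seqs) {
  stopifnot(is.list(seqs), length(seqs) >= 1L)
  seqs <- lapply(seqs, as.integer)
  k <- length(seqs)
  lens <- lengths(seqs)
  if (k > 6L) stop("lcs_multi supports at most 6 sequences; ",
                   "fold longer collections pairwise")
  if (any(lens > 64L)) stop("lcs_multi sequences must have length <= 64; ",
                            "fold longer collections pairwise")
  if (k == 1L) return(seqs[[1L]])
  if (any(lens == 0L)) return(integer(0))
  dims <- lens + 1L
  ncells <- prod(dims)
  if (ncells > 2e6) stop("lcs_multi table would need ", ncells,
                         " cells; fold the collection pairwise")
  strides <- cumprod(c(1L, dims[-k]))

  val <- integer(ncells)
  idx <- integer(k)                 # odometer over 0..lens
  syms <- integer(k)
  for (lin in seq_len(ncells)) {    # lin = 1 + sum(idx * strides)
    if (all(idx > 0L)) {
      for (i in seq_len(k)) syms[i] <- seqs[[i]][idx[i]]
      if (all(syms == syms[1L])) {
        val[lin] <- val[lin - sum(strides)] + 1L
      } else {
        best <- 0L
        for (i in seq_len(k)) {
          v <- val[lin - strides[i]]
          if (v > best) best <- v
        }
        val[lin] <- best
      }
    }                               # any zero index -> empty prefix -> 0
    # advance odometer
    for (i in seq_len(k)) {
      if (idx[i] < lens[i]) { idx[i] <- idx[i] + 1L; break }
      idx[i] <- 0L
    }
  }

  # deterministic backtrack from the full corner
  idx <- lens
  lin <- ncells
  out <- integer(0)
  while (all(idx > 0L) && val[lin] > 0L) {
    for (i in seq_len(k)) syms[i] <- seqs[[i]][idx[i]]
    if (all(syms == syms[1L]) && val[lin] == val[lin - sum(strides)] + 1L) {
      out <- c(syms[1L], out)
      idx <- idx - 1L
      lin <- lin - sum(strides)
    } else {
      for (i in seq_len(k)) {
        if (idx[i] > 0L && val[lin - strides[i]] == val[lin]) {
          idx[i] <- idx[i] - 1L
          lin <- lin - strides[i]
          break
        }
      }
    }
  }
  out
}

#' Distill one template from multiple instances of an exercise
#'
#' Encodes and collapses every instance, takes the multi-sequence LCS as the
#' template sequence, and renders it as the template trajectory map.
#'
#' @param pmap A `posture_map`.
#' @param label Exercise label.
#' @param instances List of trajectories, each a feature matrix (one row per
#'   frame) or a list of feature vectors.
#' @param g_max Passed to [render_trajectory_map()].
#' @return List with `label`, `sequence`, `map` and the collapsed
#'   `instance_sequences`.
#' @export
build_template <- function(pmap, label, instances, g_max = 200L) {
  stopifnot(length(instances) >= 1L)
  seqs <- lapply(instances, function(tr)
    collapse_repetitions(encode_trajectory(pmap, tr)))
  template <- lcs_multi(seqs)
  if (length(template) == 0L) {
    stop("instances of '", label, "' share no common posture subsequence")
  }
  list(label = as.character(label), sequence = template,
       map = render_trajectory_map(pmap, template, g_max = g_max),
       instance_sequences = seqs)
}

#' Assemble a template library
#'
#' @param templates List of entries from [build_template()].
#' @param threshold Rejection threshold on the correlation similarity, in
#'   `[-1, 1]`; default 0.5.
#' @return Object of class `"template_library"` with entries sorted by
#'   label (the classification tie order).
#' @export
template_library <- function(templates, threshold = 0.5) {
  stopifnot(length(templates) >= 1L, threshold >= -1, threshold <= 1)
  labels <- vapply(templates, `[[`, character(1L), "label")
  if (anyDuplicated(labels)) stop("duplicate template labels")
  templates <- templates[order(labels)]
  names(templates) <- sort(labels)
  structure(list(entries = templates, threshold = threshold),
            class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("template_library: %d templates, rejection threshold %.2f\n",
              length(x$entries), x$threshold))
  invisible(x)
}

#' Normalized correlation similarity of two trajectory maps
#'
#' Pearson-type normalized cross-correlation of the two images about their
#' means:
#' `S = sum((p - mean(p)) * (t - mean(t))) / sqrt(sum((p - mean(p))^2) * sum((t - mean(t))^2))`.
#' Symmetric, in `[-1, 1]`, and invariant to positive affine rescaling of
#' either image's intensities.
#'
#' @param p,t `trajectory_map` objects (or plain image matrices) of equal
#'   size; each must be non-constant, otherwise the similarity is undefined
#'   and an error is raised.
#' @return Scalar in `[-1, 1]`.
#' @export
similarity <- function(p, t) {
  img <- function(x) if (inherits(x, "trajectory_map")) x$image else as.matrix(x)
  pi_ <- img(p); ti_ <- img(t)
  if (!all(dim(pi_) == dim(ti_))) stop("trajectory maps differ in size")
  dp <- as.numeric(pi_) - mean(pi_)
  dt <- as.numeric(ti_) - mean(ti_)
  sp <- sum(dp * dp); st <- sum(dt * dt)
  if (sp == 0 || st == 0) {
    stop("similarity undefined for a constant trajectory map")
  }
  sum(dp * dt) / sqrt(sp * st)
}

#' Classify a trajectory map against a template library
#'
#' Computes the correlation similarity to every template and returns the
#' best label, unless the best similarity falls below the library's
#' rejection threshold, in which case the trajectory is declared to match no
#' known exercise. Ties go to the lexicographically smallest label.
#'
#' @param p A `trajectory_map`.
#' @param lib A `template_library`.
#' @return List with `label` (`NA` when rejected), `similarity` (best S),
#'   `rejected` flag and the full named `scores` vector.
#' @export
classify_map <- function(p, lib) {
  stopifnot(inherits(lib, "template_library"))
  scores <- vapply(lib$entries, function(e) similarity(p, e$map), numeric(1L))
  best <- which.max(scores)   # entries sorted by label -> lexicographic ties
  if (scores[best] >= lib$threshold) {
    list(label = names(scores)[best], similarity = unname(scores[best]),
         rejected = FALSE, scores = scores)
  } else {
    list(label = NA_character_, similarity = unname(scores[best]),
         rejected = TRUE, scores = scores)
  }
}
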