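# Trajectory maps: a motion trajectory becomes a sequence of basic posture
# units, repetitions are collapsed, and the collapsed sequence is rendered
# on the posture map as a fixed-size gray image whose shades encode visit
# order (darker = earlier), with per-basin appearance-order binary strings.

#' Encode a trajectory as a posture sequence
#'
#' Each frame's feature vector is input to the posture map and replaced by
#' the basin of its winning neuron.
#'
#' @param pmap A `posture_map`.
#' @param features Feature matrix (one row per frame) or list of feature
#'   vectors, on the same scale the map was trained on.
#' @return Integer vector of basin ids, one per frame (raw, uncollapsed).
#' @export
encode_trajectory <- function(pmap, features) {
  features <- .as_feature_matrix(features)
  if (nrow(features) == 0L) stop("empty trajectory")
  assign_basins(pmap, features)
}

#' Collapse adjacent repetitions of a sequence
#'
#' Runs of identical symbols carry no extra information and are reduced to a
#' single symbol (e.g. `1,1,1,8,8,8,3,3,8,8,8,8,1,1` becomes `1,8,3,8,1`).
#' Idempotent; preserves order and the set of distinct symbols.
#'
#' @param seq Integer vector of basin ids.
#' @return Collapsed integer vector.
#' @export
collapse_repetitions <- function(seq) {
  seq <- as.integer(seq)
  if (length(seq) == 0L) return(integer(0))
  rle(seq)$values
}

#' Appearance-order binary strings
#'
#' For each basin occurring in a collapsed sequence of length `L`, a string
#' of `L` binary digits with `1` wherever the sequence visits that basin:
#' for sequence `1,5,1`, basin 1 gets `"101"` and basin 5 `"010"`.
#'
#' @param seq Collapsed posture sequence (integer vector).
#' @return Named character vector, one entry per distinct basin, named by
#'   basin id, in first-appearance order.
#' @export
appearance_strings <- function(seq) {
  seq <- as.integer(seq)
  basins <- unique(seq)
  out <- vapply(basins, function(b)
    paste(as.integer(seq == b), collapse = ""), character(1L))
  stats::setNames(out, basins)
}

#' Render a collapsed posture sequence as a trajectory map
#'
#' Visited basins are ranked by first appearance; the basin of rank `r`
#' (out of `D` distinct basins) takes gray level
#' `round((r - 1) * g_max / max(D - 1, 1))`, so the first basin is black
#' (0), the last distinct basin is `g_max`, and shades increase strictly
#' with first-appearance order (darker = earlier). Re-visited basins keep
#' the shade of their first appearance (revisits stay recoverable from the
#' appearance strings). Unvisited basins are white (255).
#'
#' @param pmap A `posture_map`.
#' @param seq Collapsed posture sequence; all ids must be basins of `pmap`.
#' @param g_max Darkest-to-lightest span for visited basins; default 200,
#'   keeping every visited basin distinguishable from white.
#' @return Object of class `"trajectory_map"`: list with `image` (`M x N`
#'   integer matrix in `[0, 255]`), `appearance` (binary strings) and
#'   `sequence`.
#' @export
render_trajectory_map <- function(pmap, seq, g_max = 200L) {
  seq <- as.integer(seq)
  if (length(seq) == 0L) stop("empty posture sequence")
  B <- pmap$n_units
  if (any(seq < 1L | seq > B)) {
    stop("unknown basin id ", seq[which(seq < 1L | seq > B)[1L]],
         " (map has ", B, " units)")
  }
  basins <- unique(seq)                      # first-appearance order
  shade <- as.integer(round((seq_along(basins) - 1) * g_max /
                              max(length(basins) - 1, 1)))
  img <- matrix(255L, nrow = pmap$grid$M, ncol = pmap$grid$N)
  for (i in seq_along(basins)) {
    img[pmap$labeling == basins[i]] <- shade[i]
  }
  structure(list(image = img, appearance = appearance_strings(seq),
                 sequence = seq, g_max = as.integer(g_max)),
            class = "trajectory_map")
}

#' @export
print.trajectory_map <- function(x, ...) {
  cat(sprintf("trajectory_map: %d x %d image, sequence %s\n",
              nrow(x$image), ncol(x$image), paste(x$sequence, collapse = ",")))
  invisible(x)
}
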