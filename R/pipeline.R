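# End-to-end pipeline helpers: fit a posture map from a labeled dataset,
# distill the template library, classify a dataset and summarize accuracy.

.dataset_trajectories <- function(dataset) {
  if (inherits(dataset, "motion_dataset")) dataset$trajectories else dataset
}

#' Fit a basic posture unit map from a motion dataset
#'
#' Extracts the 71-D scaled features of every frame (optionally striding
#' frames to bound compute), trains the map, and segments it into basic
#' posture units.
#'
#' @param dataset A `motion_dataset` (or plain list of trajectory records).
#' @param M,N Grid size, default 10 x 10.
#' @param schedule A [som_schedule()].
#' @param depth_frac Shallow-basin merge threshold.
#' @param frame_stride Use every `frame_stride`-th frame of each trajectory
#'   for map training (default 1 = all frames). Striding only thins the
#'   training sample; encoding always uses full trajectories.
#' @return A `posture_map`.
#' @export
fit_posture_map <- function(dataset, M = 10L, N = 10L,
                            schedule = som_schedule(), depth_frac = 0.15,
                            frame_stride = 1L) {
  trajs <- .dataset_trajectories(dataset)
  feats <- lapply(trajs, function(tr) {
    f <- tr$frames[seq(1L, length(tr$frames), by = frame_stride)]
    trajectory_features(f)
  })
  X <- do.call(rbind, feats)
  grid <- som_train(X, M, N, schedule)
  build_posture_map(grid, X, depth_frac = depth_frac)
}

#' Build a template library from a labeled dataset
#'
#' Groups trajectories by label and distills one LCS template per exercise
#' with [build_template()]. At most `max_instances` instances per label are
#' used (the exact multi-sequence LCS is limited to 6 sequences); the first
#' `max_instances` in dataset order are taken, which for the standard
#' template cohort is one instance per subject.
#'
#' @param pmap A `posture_map`.
#' @param dataset Labeled dataset.
#' @param threshold Rejection threshold of the resulting library.
#' @param g_max Shade span, see [render_trajectory_map()].
#' @param max_instances Cap on instances per label (<= 6).
#' @return A `template_library`.
#' @export
build_template_library <- function(pmap, dataset, threshold = 0.5,
                                   g_max = 200L, max_instances = 5L) {
  stopifnot(max_instances >= 1L, max_instances <= 6L)
  trajs <- .dataset_trajectories(dataset)
  labels <- vapply(trajs, `[[`, character(1L), "label")
  templates <- lapply(unique(labels), function(lb) {
    sel <- which(labels == lb)
    sel <- sel[seq_len(min(length(sel), max_instances))]
    build_template(pmap, lb,
                   lapply(trajs[sel], function(tr) trajectory_features(tr$frames)),
                   g_max = g_max)
  })
  template_library(templates, threshold = threshold)
}

#' Classify every trajectory of a dataset
#'
#' @param pmap A `posture_map`.
#' @param lib A `template_library`.
#' @param dataset Dataset to classify (labels, when present, are echoed as
#'   the truth column).
#' @param g_max Shade span used when rendering each trajectory's map.
#' @return Data frame with columns `label` (truth, `NA` when absent),
#'   `predicted` (`NA` on rejection), `similarity`, `rejected`.
#' @export
classify_dataset <- function(pmap, lib, dataset, g_max = 200L) {
  trajs <- .dataset_trajectories(dataset)
  rows <- lapply(trajs, function(tr) {
    seq_ <- collapse_repetitions(
      encode_trajectory(pmap, trajectory_features(tr$frames)))
    # a degenerate map (e.g. a single basin) yields constant images whose
    # correlation is undefined; such trajectories are recorded as
    # rejections rather than aborting the whole report
    res <- tryCatch(
      classify_map(render_trajectory_map(pmap, seq_, g_max = g_max), lib),
      error = function(e) list(label = NA_character_,
                               similarity = NA_real_, rejected = TRUE))
    data.frame(label = if (is.null(tr$label)) NA_character_ else tr$label,
               predicted = res$label, similarity = res$similarity,
               rejected = res$rejected, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Accuracy and confusion matrix of a classification report
#'
#' @param report Data frame from [classify_dataset()] with a truth column.
#' @return List with `accuracy` (rejections count as errors) and `confusion`
#'   (truth in rows; rejected trajectories tallied under `"REJECT"`).
#' @export
evaluate_accuracy <- function(report) {
  stopifnot(all(c("label", "predicted") %in% names(report)))
  pred <- ifelse(report$rejected, "REJECT", report$predicted)
  acc <- mean(!report$rejected & report$predicted == report$label)
  list(accuracy = acc,
       confusion = table(truth = report$label, predicted = pred))
}
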