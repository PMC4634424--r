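# JSON serialization of trained objects (map grid, posture map, trajectory
# map, template library) and plain-text PGM export of map images.

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# lists of row vectors come back from jsonlite either as a matrix (rows in
# row order) or as a list; normalize to a matrix with `n` rows
.rows_to_matrix <- function(x, n) {
  if (is.matrix(x)) {
    m <- x
  } else {
    m <- matrix(unlist(x), nrow = n, byrow = TRUE)
  }
  unname(m)
}

#' Save / load a trained map grid
#'
#' JSON layout: `{M, N, dim, weights (row-major, one array per neuron),
#' schedule, seed}`.
#'
#' @param grid A `som_grid`.
#' @param path File path.
#' @return `load_som_grid` returns a `som_grid`; savers return `path`
#'   invisibly.
#' @export
save_som_grid <- function(grid, path) {
  .write_json(list(
    M = grid$M, N = grid$N, dim = grid$dim,
    weights = lapply(seq_len(nrow(grid$weights)),
                     function(j) unname(grid$weights[j, ])),
    schedule = unclass(grid$schedule),
    seed = if (is.null(grid$schedule)) NULL else grid$schedule$seed), path)
}

#' @rdname save_som_grid
#' @export
load_som_grid <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- .rows_to_matrix(obj$weights, obj$M * obj$N)
  sched <- if (!is.null(obj$schedule) && length(obj$schedule)) {
    som_schedule(obj$schedule$eta0, obj$schedule$n_epochs,
                 obj$schedule$sigma, obj$schedule$seed)
  }
  .new_som_grid(W, obj$M, obj$N, sched)
}

#' Save / load a posture map
#'
#' @param pmap A `posture_map`.
#' @param path File path.
#' @return `load_posture_map` returns a `posture_map`.
#' @export
save_posture_map <- function(pmap, path) {
  .write_json(list(
    grid = list(M = pmap$grid$M, N = pmap$grid$N, dim = pmap$grid$dim,
                weights = lapply(seq_len(nrow(pmap$grid$weights)),
                                 function(j) unname(pmap$grid$weights[j, ])),
                schedule = unclass(pmap$grid$schedule)),
    umatrix = lapply(seq_len(nrow(pmap$umatrix)),
                     function(r) unname(pmap$umatrix[r, ])),
    labeling = lapply(seq_len(nrow(pmap$labeling)),
                      function(r) unname(pmap$labeling[r, ])),
    n_units = pmap$n_units,
    rep_neurons = pmap$rep_neurons,
    depth_frac = pmap$depth_frac), path)
}

#' @rdname save_posture_map
#' @export
load_posture_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- obj$grid
  W <- .rows_to_matrix(g$weights, g$M * g$N)
  sched <- if (!is.null(g$schedule) && length(g$schedule)) {
    som_schedule(g$schedule$eta0, g$schedule$n_epochs, g$schedule$sigma,
                 g$schedule$seed)
  }
  grid <- .new_som_grid(W, g$M, g$N, sched)
  um <- .rows_to_matrix(obj$umatrix, g$M)
  lab <- .rows_to_matrix(obj$labeling, g$M)
  storage.mode(lab) <- "integer"
  rep_neurons <- as.integer(obj$rep_neurons)
  structure(list(grid = grid, umatrix = um, labeling = lab,
                 n_units = as.integer(obj$n_units),
                 representatives = W[rep_neurons, , drop = FALSE],
                 rep_neurons = rep_neurons,
                 depth_frac = obj$depth_frac),
            class = "posture_map")
}

#' Save / load a trajectory map
#'
#' @param tmap A `trajectory_map`.
#' @param path File path.
#' @return `load_trajectory_map` returns a `trajectory_map`.
#' @export
save_trajectory_map <- function(tmap, path) {
  .write_json(list(
    M = nrow(tmap$image), N = ncol(tmap$image),
    image = lapply(seq_len(nrow(tmap$image)),
                   function(r) unname(tmap$image[r, ])),
    appearance = as.list(tmap$appearance),
    sequence = tmap$sequence, g_max = tmap$g_max), path)
}

#' @rdname save_trajectory_map
#' @export
load_trajectory_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    image = local({
      im <- .rows_to_matrix(obj$image, obj$M)
      storage.mode(im) <- "integer"
      im
    }),
    appearance = unlist(obj$appearance),
    sequence = as.integer(obj$sequence),
    g_max = as.integer(obj$g_max)), class = "trajectory_map")
}

#' Save / load a template library
#'
#' @param lib A `template_library`.
#' @param path File path.
#' @return `load_template_library` returns a `template_library`.
#' @export
save_template_library <- function(lib, path) {
  .write_json(list(
    threshold = lib$threshold,
    entries = lapply(lib$entries, function(e) list(
      label = e$label, sequence = e$sequence,
      map = list(M = nrow(e$map$image), N = ncol(e$map$image),
                 image = lapply(seq_len(nrow(e$map$image)),
                                function(r) unname(e$map$image[r, ])),
                 appearance = as.list(e$map$appearance),
                 sequence = e$map$sequence, g_max = e$map$g_max)))), path)
}

#' @rdname save_template_library
#' @export
load_template_library <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- lapply(obj$entries, function(e) list(
    label = e$label, sequence = as.integer(e$sequence),
    map = structure(list(
      image = local({
        im <- .rows_to_matrix(e$map$image, e$map$M)
        storage.mode(im) <- "integer"
        im
      }),
      appearance = unlist(e$map$appearance),
      sequence = as.integer(e$map$sequence),
      g_max = as.integer(e$map$g_max)), class = "trajectory_map")))
  template_library(entries, threshold = obj$threshold)
}

#' Write a gray image as plain-text PGM (P2)
#'
#' For visual inspection of U-matrices and trajectory maps in any image
#' viewer.
#'
#' @param image Numeric matrix; values are clamped to `[0, maxval]` and
#'   rounded.
#' @param path File path (conventionally `.pgm`).
#' @param maxval Maximum gray value (default 255).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path, maxval = 255L) {
  img <- round(pmin(pmax(as.matrix(image), 0), maxval))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  writeLines(apply(img, 1L, paste, collapse = " "), con)
  invisible(path)
}
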