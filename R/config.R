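#' Co-occurrence analysis configuration
#'
#' Bundles every tunable of the texture stage: the gray-level count used
#' for range-relative quantization, the voxel distances and lattice
#' directions that generate the co-occurrence matrices (5 distances x 13
#' directions = 65 matrices by default), symmetric pair counting, the
#' entropy log base, and how per-matrix attribute values are aggregated
#' into one feature vector.
#'
#' @param n_levels Number of gray levels `Ng` (>= 2). Default 32, the
#'   common radiomics compromise between matrix sparsity and
#'   discriminability.
#' @param distances Positive integer voxel distances. Default `1:5`.
#' @param directions List of integer 3-vectors, no zero vector, no
#'   antipodal duplicates. Default [direction_set()].
#' @param symmetric Count each voxel pair in both orders (default `TRUE`).
#' @param log_base Base for all entropy terms: `2` (default) or `exp(1)`.
#' @param aggregation `"mean_over_matrices"` (default: unweighted mean of
#'   each attribute over all non-empty matrices) or
#'   `"mean_over_directions_then_distances"`.
#' @return An object of class `bonetex_glcm_config`.
#' @export
glcm_config <- function(n_levels = 32L,
                        distances = 1:5,
                        directions = direction_set(),
                        symmetric = TRUE,
                        log_base = 2,
                        aggregation = c("mean_over_matrices",
                                        "mean_over_directions_then_distances")) {
  aggregation <- match.arg(aggregation)
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 2L) {
    abort("`n_levels` must be an integer >= 2.", class = "bonetex_value_error")
  }
  distances <- as.integer(distances)
  if (length(distances) == 0L || anyNA(distances) || any(distances < 1L)) {
    abort("`distances` must be positive integers.", class = "bonetex_value_error")
  }
  if (!is.list(directions) || length(directions) == 0L) {
    abort("`directions` must be a nonempty list of integer 3-vectors.",
          class = "bonetex_value_error")
  }
  directions <- lapply(directions, function(d) as.integer(d))
  keys <- vapply(directions, paste, collapse = ",", FUN.VALUE = "")
  neg_keys <- vapply(directions, function(d) paste(-d, collapse = ","), "")
  if (any(vapply(directions, function(d) length(d) != 3L || all(d == 0L),
                 logical(1)))) {
    abort("each direction must be a nonzero integer 3-vector.",
          class = "bonetex_value_error")
  }
  if (anyDuplicated(keys) || any(neg_keys %in% keys)) {
    abort("directions must be unique with no antipodal pairs.",
          class = "bonetex_value_error")
  }
  if (!isTRUE(all.equal(log_base, 2)) && !isTRUE(all.equal(log_base, exp(1)))) {
    abort("`log_base` must be 2 or exp(1).", class = "bonetex_value_error")
  }
  structure(list(n_levels = n_levels,
                 distances = distances,
                 directions = directions,
                 symmetric = isTRUE(symmetric),
                 log_base = log_base,
                 aggregation = aggregation),
            class = "bonetex_glcm_config")
}

#' @export
print.bonetex_glcm_config <- function(x, ...) {
  cat(sprintf(paste0("<bonetex_glcm_config> Ng=%d, distances=%s, %d directions, ",
                     "symmetric=%s, log_base=%s, aggregation=%s\n"),
              x$n_levels, paste(x$distances, collapse = ","),
              length(x$directions), x$symmetric,
              if (isTRUE(all.equal(x$log_base, 2))) "2" else "e",
              x$aggregation))
  invisible(x)
}

#' Write / read a texture configuration as a YAML key-value file
#'
#' The on-disk form mirrors the configuration fields exactly, so a
#' write/read round-trip reproduces the configuration bit-for-bit
#' (`log_base` is stored as the token `"2"` or `"e"`).
#'
#' @param config A [glcm_config()].
#' @param path File path.
#' @return `write_glcm_config()` returns `path` invisibly;
#'   `read_glcm_config()` returns a [glcm_config()].
#' @export
write_glcm_config <- function(config, path) {
  stopifnot(inherits(config, "bonetex_glcm_config"))
  out <- list(
    n_levels = config$n_levels,
    distances = config$distances,
    directions = lapply(config$directions, as.integer),
    symmetric = config$symmetric,
    log_base = if (isTRUE(all.equal(config$log_base, 2))) "2" else "e",
    aggregation = config$aggregation
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_glcm_config
#' @export
read_glcm_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), class = "bonetex_io_error")
  }
  raw <- yaml::read_yaml(path)
  glcm_config(
    n_levels = raw$n_levels %||% 32L,
    distances = unlist(raw$distances) %||% 1:5,
    directions = if (is.null(raw$directions)) direction_set()
                 else lapply(raw$directions, as.integer),
    symmetric = raw$symmetric %||% TRUE,
    log_base = if (identical(raw$log_base, "e")) exp(1) else 2,
    aggregation = raw$aggregation %||% "mean_over_matrices"
  )
}
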