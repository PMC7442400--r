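#' Specification of a synthetic vertebral phantom
#'
#' The phantom emulates the texture-bearing content of a sagittal
#' T2-weighted vertebral acquisition: a spatially correlated random
#' field (smoothed white noise) inside an ellipsoidal vertebral-body
#' VOI, on an anisotropic grid whose slice spacing matches a routine FSE
#' protocol. The correlation length controls trabecular-like coarseness
#' and is the single knob the cohort generator couples to bone density.
#'
#' @param shape Grid dimensions (default `c(32, 32, 16)`).
#' @param spacing Voxel size in mm (default `c(0.8, 0.8, 3.0)`).
#' @param correlation_length Isotropic Gaussian smoothing scale in
#'   voxels; larger is coarser/smoother texture.
#' @param noise_sd Additive white-noise level, expressed relative to the
#'   SD of the smoothed field (an inverse SNR).
#' @param voi_margin Border voxels excluded from the ellipsoidal mask.
#' @param seed Integer RNG seed; the phantom is a pure function of its
#'   spec.
#' @return An object of class `bonetex_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32L, 32L, 16L),
                         spacing = c(0.8, 0.8, 3.0),
                         correlation_length = 2,
                         noise_sd = 0.1,
                         voi_margin = 2L,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 1L)) {
    abort("`shape` must be three positive integers.", class = "bonetex_value_error")
  }
  if (!is.numeric(correlation_length) || correlation_length <= 0) {
    abort("`correlation_length` must be > 0.", class = "bonetex_value_error")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be >= 0.", class = "bonetex_value_error")
  }
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 correlation_length = correlation_length,
                 noise_sd = noise_sd, voi_margin = as.integer(voi_margin),
                 seed = as.integer(seed)),
            class = "bonetex_phantom_spec")
}

# Separable Gaussian smoothing along each axis; kernel rows renormalized
# at the grid edges so the filter preserves a constant field exactly.
gauss_smooth3 <- function(arr, ell) {
  dims <- dim(arr)
  for (axis in 1:3) {
    n <- dims[axis]
    K <- exp(-outer(seq_len(n), seq_len(n), `-`)^2 / (2 * ell^2))
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    a <- array(K %*% matrix(a, nrow = n), dim = dims[perm])
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Generate a synthetic vertebral phantom
#'
#' Intensity field: unit white noise smoothed at the spec's correlation
#' length, plus independent noise of relative SD `noise_sd`, windowed at
#' two SDs about the mean and affinely rescaled to the fixed positive
#' range `[0, 1000]`. Fields whose
#' dynamic range collapses below 1e-6 of the noise scale (the
#' large-correlation-length limit) are emitted as exactly constant
#' volumes. The VOI is the ellipsoid inscribed in the grid minus
#' `voi_margin` voxels per face.
#'
#' @param spec A [phantom_spec()].
#' @return A list: `volume` ([image_volume()]), `mask` (logical array),
#'   `coarseness` (the correlation length actually used).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "bonetex_phantom_spec"))
  dims <- spec$shape
  f <- withr::with_seed(spec$seed, {
    w <- array(rnorm(prod(dims)), dim = dims)
    s <- gauss_smooth3(w, spec$correlation_length)
    s + spec$noise_sd * sd(s) * array(rnorm(prod(dims)), dim = dims)
  })
  # Fixed-width intensity windowing at +/- 2 SD (as in MR display
  # windowing) before rescaling: keeps the gray-level histogram shape
  # comparable across coarseness levels, so texture statistics respond
  # to spatial correlation rather than to extreme-value range.
  f <- pmin(pmax(f, mean(f) - 2 * sd(f)), mean(f) + 2 * sd(f))
  rng <- max(f) - min(f)
  vol <- if (rng < 1e-6) {
    array(500, dim = dims)
  } else {
    (f - min(f)) / rng * 1000
  }
  ctr <- (dims + 1) / 2
  semi <- dims / 2 - spec$voi_margin
  if (any(semi <= 0)) {
    abort("`voi_margin` leaves no room for the VOI.", class = "bonetex_spec_error")
  }
  gx <- (seq_len(dims[1]) - ctr[1]) / semi[1]
  gy <- (seq_len(dims[2]) - ctr[2]) / semi[2]
  gz <- (seq_len(dims[3]) - ctr[3]) / semi[3]
  mask <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`) <= 1
  if (sum(mask) < 100L) {
    abort(sprintf("VOI has only %d voxels (< 100): enlarge the grid or shrink the margin.",
                  sum(mask)),
          class = "bonetex_spec_error")
  }
  list(volume = image_volume(vol, spacing = spec$spacing),
       mask = mask,
       coarseness = spec$correlation_length)
}

shift_bool <- function(a, d) {
  dims <- dim(a)
  out <- array(FALSE, dim = dims)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    lo <- max(1L, 1L + d[k])
    hi <- min(dims[k], dims[k] + d[k])
    if (lo > hi) return(out)
    dst[[k]] <- lo:hi
    src[[k]] <- (lo - d[k]):(hi - d[k])
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

face_neighbours <- list(c(1L, 0L, 0L), c(-1L, 0L, 0L),
                        c(0L, 1L, 0L), c(0L, -1L, 0L),
                        c(0L, 0L, 1L), c(0L, 0L, -1L))

dilate6 <- function(a) {
  Reduce(`|`, lapply(face_neighbours, function(d) shift_bool(a, d)), a)
}

erode6 <- function(a) {
  Reduce(`&`, lapply(face_neighbours, function(d) shift_bool(a, d)), a)
}

#' Simulate a second rater's segmentation of a VOI
#'
#' Applies patchwise morphological boundary perturbation of depth at
#' most `jitter` voxels: a smooth random patch field selects about a
#' quarter of the boundary for dilation and a quarter for erosion
#' (6-neighbourhood, depth `jitter`), mimicking where a second human
#' rater would trace a slightly looser or tighter contour. `jitter = 0`
#' returns the mask unchanged; the result always stays inside the grid.
#'
#' @param mask 3-D logical array.
#' @param jitter Nonnegative integer perturbation depth in voxels.
#' @param seed Integer RNG seed.
#' @return A perturbed logical mask of the same shape.
#' @export
perturb_mask <- function(mask, jitter = 1L, seed = 1L) {
  if (!is.logical(mask) || length(dim(mask)) != 3L) {
    abort("`mask` must be a 3-D logical array.", class = "bonetex_value_error")
  }
  jitter <- as.integer(jitter)
  if (is.na(jitter) || jitter < 0L) {
    abort("`jitter` must be >= 0.", class = "bonetex_value_error")
  }
  if (jitter == 0L) return(mask)
  u <- withr::with_seed(seed, {
    gauss_smooth3(array(rnorm(length(mask)), dim = dim(mask)), 2)
  })
  u <- (u - mean(u)) / sd(u)
  grow <- mask
  shrink <- mask
  for (t in seq_len(jitter)) {
    grow <- dilate6(grow)
    shrink <- erode6(shrink)
  }
  thr <- qnorm(0.75)
  out <- mask
  out[u > thr] <- grow[u > thr]
  out[u < -thr] <- shrink[u < -thr]
  if (!any(out)) {
    abort("perturbation emptied the mask.", class = "bonetex_empty_voi")
  }
  out
}
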