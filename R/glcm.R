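#' The 13 lattice orientations of a 3-D co-occurrence analysis
#'
#' The 26-neighbourhood of a voxel contains 13 distinct displacement axes
#' once each direction is identified with its opposite. With symmetric
#' pair counting these 13 axes capture every ordered neighbour pair, and
#' the set (as a whole) is closed under 90-degree grid rotations, which
#' makes the aggregated feature vector rotation-invariant.
#'
#' @return A list of 13 integer 3-vectors in canonical order.
#' @export
#' @examples
#' length(direction_set())
direction_set <- function() {
  list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L),
       c(1L, 1L, 0L), c(1L, -1L, 0L),
       c(1L, 0L, 1L), c(1L, 0L, -1L),
       c(0L, 1L, 1L), c(0L, 1L, -1L),
       c(1L, 1L, 1L), c(1L, 1L, -1L), c(1L, -1L, 1L), c(1L, -1L, -1L))
}

#' Quantize a VOI to discrete gray levels
#'
#' Equal-width binning over the in-mask intensity range:
#' `level = min(Ng, floor((v - vmin) * Ng / (vmax - vmin)) + 1)`.
#' Binning is range-relative, so adding a constant to all intensities (or
#' rescaling them) leaves the levels unchanged. A constant VOI maps every
#' voxel to level 1.
#'
#' @param volume A [image_volume()].
#' @param mask 3-D logical array of the same shape.
#' @param n_levels Number of gray levels `Ng` (>= 2).
#' @return An object of class `bonetex_qvoi`: fields `levels` (integer
#'   array, `NA` outside the mask), `mask`, `n_levels`.
#' @export
quantize <- function(volume, mask, n_levels = 32L) {
  stopifnot(inherits(volume, "bonetex_volume"))
  if (!is.logical(mask) || !identical(dim(mask), dim(volume$data))) {
    abort("`mask` must be a logical array with the volume's shape.",
          class = "bonetex_geometry_error")
  }
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 2L) {
    abort("`n_levels` must be >= 2.", class = "bonetex_value_error")
  }
  v <- volume$data[mask]
  if (length(v) < 2L) {
    abort("VOI must contain at least 2 voxels.", class = "bonetex_empty_voi")
  }
  vmin <- min(v)
  vmax <- max(v)
  lv <- if (vmax == vmin) {
    rep(1L, length(v))
  } else {
    pmin(n_levels, as.integer(floor((v - vmin) * n_levels / (vmax - vmin))) + 1L)
  }
  levels <- array(NA_integer_, dim = dim(mask))
  levels[mask] <- lv
  structure(list(levels = levels, mask = mask, n_levels = n_levels),
            class = "bonetex_qvoi")
}

#' Wrap a probability matrix as a co-occurrence matrix object
#'
#' Mostly useful for constructing small fixtures directly; [compute_glcm()]
#' is the production constructor.
#'
#' @param p Square matrix of nonnegative pair probabilities summing to 1.
#' @param offset Generating displacement (informational).
#' @param n_pairs Raw voxel-pair count behind `p` (informational).
#' @param symmetric Whether `p` was symmetrically counted.
#' @return An object of class `bonetex_glcm`.
#' @export
as_glcm <- function(p, offset = c(0L, 0L, 0L), n_pairs = NA_integer_,
                    symmetric = TRUE) {
  p <- as.matrix(p)
  if (nrow(p) != ncol(p) || any(p < 0) || abs(sum(p) - 1) > 1e-12) {
    abort("`p` must be square, nonnegative, and sum to 1.",
          class = "bonetex_value_error")
  }
  structure(list(p = p, offset = as.integer(offset),
                 n_pairs = n_pairs, n_levels = nrow(p),
                 symmetric = isTRUE(symmetric)),
            class = "bonetex_glcm")
}

#' Compute a 3-D gray-level co-occurrence matrix
#'
#' Counts ordered in-mask voxel pairs `(v, v + direction * distance)` whose
#' endpoints both lie inside the VOI, optionally adds the transposed counts
#' (symmetric counting, the default), and normalizes to pair probabilities
#' `p(i, j)`.
#'
#' @param qvoi A [quantize()]d VOI.
#' @param direction Integer 3-vector lattice direction.
#' @param distance Positive integer voxel distance.
#' @param symmetric Count each pair in both orders.
#' @return A `bonetex_glcm`: `p` (`Ng x Ng`), `offset`, `n_pairs` (raw
#'   ordered-pair count before symmetrization/normalization), `n_levels`,
#'   `symmetric`.
#' @export
compute_glcm <- function(qvoi, direction, distance = 1L, symmetric = TRUE) {
  stopifnot(inherits(qvoi, "bonetex_qvoi"))
  direction <- as.integer(direction)
  distance <- as.integer(distance)
  if (length(direction) != 3L || all(direction == 0L)) {
    abort("`direction` must be a nonzero integer 3-vector.",
          class = "bonetex_value_error")
  }
  if (is.na(distance) || distance < 1L) {
    abort("`distance` must be a positive integer.", class = "bonetex_value_error")
  }
  disp <- direction * distance
  L <- qvoi$levels
  dims <- dim(L)
  idx <- vector("list", 3L)
  for (k in 1:3) {
    lo <- max(1L, 1L - disp[k])
    hi <- min(dims[k], dims[k] - disp[k])
    if (lo > hi) {
      abort("displacement exceeds the grid: no voxel pair exists.",
            class = "bonetex_empty_glcm")
    }
    idx[[k]] <- lo:hi
  }
  a <- L[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  b <- L[idx[[1]] + disp[1], idx[[2]] + disp[2], idx[[3]] + disp[3],
         drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  n_pairs <- sum(keep)
  if (n_pairs == 0L) {
    abort(sprintf("no in-mask voxel pair for displacement (%s).",
                  paste(disp, collapse = ",")),
          class = "bonetex_empty_glcm")
  }
  ng <- qvoi$n_levels
  counts <- tabulate((a[keep] - 1L) * ng + b[keep], nbins = ng * ng)
  C <- matrix(counts, nrow = ng, ncol = ng, byrow = TRUE)
  if (symmetric) C <- C + t(C)
  structure(list(p = C / sum(C), offset = disp, n_pairs = n_pairs,
                 n_levels = ng, symmetric = isTRUE(symmetric)),
            class = "bonetex_glcm")
}

#' @export
print.bonetex_glcm <- function(x, ...) {
  cat(sprintf("<bonetex_glcm> Ng=%d, offset=(%s), n_pairs=%s, symmetric=%s\n",
              x$n_levels, paste(x$offset, collapse = ","),
              format(x$n_pairs), x$symmetric))
  invisible(x)
}

#' Marginal and entropy summaries of a co-occurrence matrix
#'
#' Computes the intermediate statistics every co-occurrence attribute is
#' built from: the row/column marginals `px`, `py` with their means and
#' SDs, the cross-sum distribution `p_plus(k) = sum_{i+j=k} p(i,j)` for
#' `k = 2..2Ng`, the cross-difference distribution
#' `p_minus(k) = sum_{|i-j|=k} p(i,j)` for `k = 0..Ng-1`, and the
#' entropies `HX`, `HY`, `HXY`, `HXY1`, `HXY2`. All `0 * log 0` terms
#' are taken as 0.
#'
#' @param g A `bonetex_glcm`.
#' @param log_base Entropy log base, `2` or `exp(1)`.
#' @return An object of class `bonetex_glcm_derived`.
#' @export
glcm_derived <- function(g, log_base = 2) {
  stopifnot(inherits(g, "bonetex_glcm"))
  p <- g$p
  ng <- nrow(p)
  lev <- seq_len(ng)
  px <- rowSums(p)
  py <- colSums(p)
  mu_x <- sum(lev * px)
  mu_y <- sum(lev * py)
  sd_x <- sqrt(sum((lev - mu_x)^2 * px))
  sd_y <- sqrt(sum((lev - mu_y)^2 * py))
  isum <- row(p) + col(p)
  idiff <- abs(row(p) - col(p))
  p_plus <- as.vector(rowsum(as.vector(p), group = as.vector(isum)))
  names(p_plus) <- as.character(2:(2 * ng))
  p_minus <- as.vector(rowsum(as.vector(p), group = as.vector(idiff)))
  names(p_minus) <- as.character(0:(ng - 1))
  lb <- log(log_base)
  H <- function(q) {
    q <- q[q > 0]
    -sum(q * log(q)) / lb
  }
  pxy <- outer(px, py)
  sel <- p > 0            # p>0 implies px*py>0
  hxy1 <- -sum(p[sel] * log(pxy[sel])) / lb
  hxy2 <- H(pxy)
  structure(list(px = px, py = py,
                 mu_x = mu_x, mu_y = mu_y, sd_x = sd_x, sd_y = sd_y,
                 p_plus = p_plus, p_minus = p_minus,
                 HX = H(px), HY = H(py), HXY = H(p),
                 HXY1 = hxy1, HXY2 = hxy2,
                 log_base = log_base),
            class = "bonetex_glcm_derived")
}
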