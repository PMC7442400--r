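#' Canonical names of the 22 co-occurrence texture attributes
#'
#' The fixed order used by every feature vector, report, and CSV this
#' package writes.
#'
#' @return A character vector of length 22.
#' @export
glcm_attributes <- function() {
  c("autocorrelation", "cluster_prominence", "cluster_shade",
    "cluster_tendency", "contrast", "correlation", "difference_entropy",
    "dissimilarity", "energy", "entropy", "homogeneity1", "homogeneity2",
    "imc1", "imc2", "idmn", "idn", "inverse_variance", "max_probability",
    "sum_average", "sum_entropy", "sum_variance", "variance")
}

#' Compute the 22 texture attributes of one co-occurrence matrix
#'
#' Standard co-occurrence statistics. Degenerate cases take defined
#' finite values: `correlation` and `imc1` fall back to 0 when their
#' denominators vanish, the `imc2` radicand is clamped at 0, and
#' `inverse_variance` skips the diagonal.
#'
#' @param g A `bonetex_glcm`.
#' @param derived Optional precomputed [glcm_derived()] (must match
#'   `log_base`).
#' @param log_base Entropy log base, `2` (default) or `exp(1)`.
#' @return A named numeric vector of length 22 in [glcm_attributes()]
#'   order.
#' @export
compute_features <- function(g, derived = NULL, log_base = 2) {
  stopifnot(inherits(g, "bonetex_glcm"))
  dv <- derived %||% glcm_derived(g, log_base = log_base)
  stopifnot(inherits(dv, "bonetex_glcm_derived"))
  p <- g$p
  ng <- nrow(p)
  ii <- row(p)
  jj <- col(p)
  gap <- ii - jj
  agap <- abs(gap)
  lb <- log(dv$log_base)
  ent <- function(q) {
    q <- q[q > 0]
    -sum(q * log(q)) / lb
  }

  autocorrelation <- sum(ii * jj * p)
  cs <- ii + jj - dv$mu_x - dv$mu_y
  k <- as.numeric(names(dv$p_plus))
  sum_average <- sum(k * dv$p_plus)
  den_corr <- dv$sd_x * dv$sd_y
  correlation <- if (den_corr > 0) {
    (autocorrelation - dv$mu_x * dv$mu_y) / den_corr
  } else 0
  max_h <- max(dv$HX, dv$HY)
  imc1 <- if (max_h > 0) (dv$HXY - dv$HXY1) / max_h else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (dv$HXY2 - dv$HXY))))
  off <- gap != 0
  mu_bar <- (dv$mu_x + dv$mu_y) / 2

  c(autocorrelation = autocorrelation,
    cluster_prominence = sum(cs^4 * p),
    cluster_shade = sum(cs^3 * p),
    cluster_tendency = sum(cs^2 * p),
    contrast = sum(gap^2 * p),
    correlation = correlation,
    difference_entropy = ent(dv$p_minus),
    dissimilarity = sum(agap * p),
    energy = sum(p^2),
    entropy = dv$HXY,
    homogeneity1 = sum(p / (1 + agap)),
    homogeneity2 = sum(p / (1 + gap^2)),
    imc1 = imc1,
    imc2 = imc2,
    idmn = sum(p / (1 + gap^2 / ng^2)),
    idn = sum(p / (1 + agap / ng)),
    inverse_variance = sum(p[off] / gap[off]^2),
    max_probability = max(p),
    sum_average = sum_average,
    sum_entropy = ent(dv$p_plus),
    sum_variance = sum((k - sum_average)^2 * dv$p_plus),
    variance = sum((ii - mu_bar)^2 * p))
}

#' Extract the aggregated texture feature vector of a VOI
#'
#' Quantizes the VOI, builds one co-occurrence matrix per
#' (distance, direction) pair — 65 with the default configuration —
#' computes the 22 attributes of each, and aggregates them into a single
#' feature vector. Displacements for which no in-mask voxel pair exists
#' are skipped with a warning; the `n_matrices` column records how many
#' matrices were non-empty.
#'
#' @param volume A [image_volume()].
#' @param mask 3-D logical VOI mask.
#' @param config A [glcm_config()].
#' @return A one-row tibble: the 22 attribute columns in canonical order
#'   plus `n_matrices`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(12, 12, 8), seed = 1))
#' extract_features(ph$volume, ph$mask)
extract_features <- function(volume, mask, config = glcm_config()) {
  stopifnot(inherits(config, "bonetex_glcm_config"))
  q <- quantize(volume, mask, config$n_levels)
  grid <- expand.grid(dir = seq_along(config$directions),
                      dist = seq_along(config$distances))
  rows <- purrr::pmap(grid, function(dir, dist) {
    g <- tryCatch(
      compute_glcm(q, config$directions[[dir]], config$distances[[dist]],
                   symmetric = config$symmetric),
      bonetex_empty_glcm = function(e) {
        warn(sprintf("skipping empty co-occurrence matrix: direction (%s), distance %d",
                     paste(config$directions[[dir]], collapse = ","),
                     config$distances[[dist]]),
             class = "bonetex_empty_glcm_warning")
        NULL
      })
    if (is.null(g)) return(NULL)
    list(dist = dist, feats = compute_features(g, log_base = config$log_base))
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0L) {
    abort("every co-occurrence matrix is empty for this VOI.",
          class = "bonetex_empty_voi")
  }
  feats <- do.call(rbind, purrr::map(rows, "feats"))
  agg <- if (config$aggregation == "mean_over_matrices") {
    colMeans(feats)
  } else {
    dist_of <- vapply(rows, function(r) r$dist, 0L)
    per_dist <- rowsum(feats, group = dist_of) / as.vector(table(dist_of))
    colMeans(per_dist)
  }
  out <- as_tibble(as.list(agg))
  out$n_matrices <- nrow(feats)
  out
}
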