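#' Lin's concordance correlation coefficient
#'
#' Agreement between two raters' measurements, combining precision
#' (Pearson correlation) and accuracy (bias from the 45-degree line):
#' `ccc = 2 * s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)`,
#' with 1/n (biased) moment estimators as in Lin's 1989 estimator.
#' The confidence interval applies the inverse-hyperbolic-tangent
#' (Fisher z) transform with Lin's asymptotic variance and
#' back-transforms. Perfect (anti-)concordance gives a degenerate
#' interval at the point estimate.
#'
#' @param x,y Paired measurements (n >= 3, finite).
#' @param alpha Two-sided confidence level is `1 - alpha` (default 0.05).
#' @param attribute Optional name carried into tidy output.
#' @return An object of class `bonetex_ccc`: `ccc`, `ci_low`, `ci_high`,
#'   `strength` (see [strength_label()]), `pearson_r`, `n`, `alpha`,
#'   `attribute`.
#' @export
#' @examples
#' lin_ccc(c(1, 2, 3), c(2, 3, 4))
lin_ccc <- function(x, y, alpha = 0.05, attribute = NULL) {
  check_paired(x, y, 3L, "paired observations")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1).", class = "bonetex_value_error")
  }
  n <- length(x)
  mx <- mean(x)
  my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sx2 == 0 && sy2 == 0) {
    abort(sprintf("both sequences are constant%s: concordance is undefined.",
                  if (is.null(attribute)) "" else paste0(" for attribute `",
                                                         attribute, "`")),
          class = "bonetex_undefined_ccc")
  }
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- if (sx2 > 0 && sy2 > 0) sxy / sqrt(sx2 * sy2) else NA_real_

  if (abs(ccc) >= 1 - 1e-12) {
    ci <- c(ccc, ccc)
  } else {
    u2 <- if (sx2 > 0 && sy2 > 0) (mx - my)^2 / sqrt(sx2 * sy2) else Inf
    v2 <- ccc^2
    r2 <- r^2
    var_z <- if (is.na(r) || r2 == 0 || n <= 2) {
      Inf
    } else {
      ((1 - r2) * v2 / ((1 - v2) * r2) +
         2 * ccc^3 * (1 - ccc) * u2 / (r * (1 - v2)^2) -
         ccc^4 * u2^2 / (2 * r2 * (1 - v2)^2)) / (n - 2)
    }
    if (!is.finite(var_z) || var_z < 0) {
      ci <- c(-1, 1)
    } else {
      z <- atanh(ccc)
      h <- qnorm(1 - alpha / 2) * sqrt(var_z)
      ci <- tanh(c(z - h, z + h))
    }
  }
  structure(list(ccc = ccc, ci_low = ci[1], ci_high = ci[2],
                 strength = strength_label(ccc),
                 pearson_r = r, n = n, alpha = alpha,
                 attribute = attribute),
            class = "bonetex_ccc")
}

#' @export
print.bonetex_ccc <- function(x, ...) {
  cat(sprintf("Lin's CCC%s: %.4f [%.4f, %.4f] (%s), n = %d\n",
              if (is.null(x$attribute)) "" else paste0(" (", x$attribute, ")"),
              x$ccc, x$ci_low, x$ci_high, x$strength, x$n))
  invisible(x)
}

#' @export
tidy.bonetex_ccc <- function(x, ...) {
  tibble(attribute = x$attribute %||% NA_character_,
         estimate = x$ccc,
         conf.low = x$ci_low,
         conf.high = x$ci_high,
         strength = x$strength)
}

#' @export
glance.bonetex_ccc <- function(x, ...) {
  tibble(n = x$n, alpha = x$alpha, pearson_r = x$pearson_r)
}

#' Conventional strength label of an agreement coefficient
#'
#' The kappa-style ranges: poor 0.00-0.19, fair 0.20-0.39, moderate
#' 0.40-0.59, substantial 0.60-0.79, almost perfect 0.80-1.00. Each
#' boundary belongs to the upper label (0.20 is "fair"); negative
#' agreement is "poor"; values above 1 are outside the coefficient's
#' domain.
#'
#' @param value Agreement coefficient(s), each <= 1.
#' @return Character vector of labels.
#' @export
#' @examples
#' strength_label(c(0.1, 0.3, 0.55, 0.7, 0.95))
strength_label <- function(value) {
  if (!is.numeric(value) || anyNA(value)) {
    abort("`value` must be numeric without NA.", class = "bonetex_value_error")
  }
  if (any(value > 1 + 1e-12)) {
    abort("agreement coefficients cannot exceed 1.",
          class = "bonetex_domain_error")
  }
  labels <- c("poor", "fair", "moderate", "substantial", "almost perfect")
  labels[findInterval(value, c(0.2, 0.4, 0.6, 0.8)) + 1L]
}
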