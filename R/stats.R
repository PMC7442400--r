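check_paired <- function(x, y, min_n, what = "paired values") {
  if (length(x) != length(y)) {
    abort("input vectors must have equal length.", class = "bonetex_value_error")
  }
  if (length(x) < min_n) {
    abort(sprintf("need at least %d %s.", min_n, what),
          class = "bonetex_value_error")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("inputs must be finite.", class = "bonetex_value_error")
  }
  invisible(TRUE)
}

#' Simple linear association of BMD with one texture attribute
#'
#' Ordinary least squares of BMD on the attribute ("model 1"): reports
#' the slope in g/cm^2 per attribute unit, its two-sided p-value from
#' the t distribution with n - 2 degrees of freedom, and the Pearson
#' correlation between attribute and BMD.
#'
#' @param feature Numeric attribute values, one per subject.
#' @param bmd Bone mineral density values (g/cm^2).
#' @param attribute Attribute name recorded in the result row.
#' @return A one-row tibble: `attribute`, `estimated_coefficient`,
#'   `p_value`, `pearson_r`, `model`, `n`.
#' @export
#' @examples
#' fit_model1(c(1, 2, 3), c(1, 2, 4))
fit_model1 <- function(feature, bmd, attribute = "feature") {
  check_paired(feature, bmd, 3L, "paired observations")
  if (sd(feature) == 0) {
    abort("feature has zero variance: slope is not identifiable.",
          class = "bonetex_degenerate_predictor")
  }
  fit <- lm(bmd ~ feature)
  sm <- summary(fit)$coefficients
  tibble(attribute = attribute,
         estimated_coefficient = sm["feature", "Estimate"],
         p_value = sm["feature", "Pr(>|t|)"],
         pearson_r = as.numeric(cor(feature, bmd)),
         model = "model1",
         n = length(feature))
}

#' Age- and BMI-adjusted association of BMD with one attribute
#'
#' Multiple least squares of BMD on (attribute, age, BMI, intercept)
#' ("model 2"); reports the attribute slope and its two-sided t p-value.
#' Covariates that are constant (and therefore aliased with the
#' intercept) are dropped by the fit, so the model degrades gracefully
#' to model 1; a feature that is itself collinear with the covariates is
#' an error.
#'
#' @inheritParams fit_model1
#' @param age,bmi Subject covariates.
#' @return A one-row tibble with the same columns as [fit_model1()],
#'   `model = "model2"`.
#' @export
fit_model2 <- function(feature, bmd, age, bmi, attribute = "feature") {
  check_paired(feature, bmd, 5L, "paired observations")
  check_paired(age, bmi, length(feature), "covariate values")
  if (sd(feature) == 0) {
    abort("feature has zero variance: slope is not identifiable.",
          class = "bonetex_degenerate_predictor")
  }
  d <- data.frame(bmd = bmd, age = age, bmi = bmi, feature = feature)
  fit <- lm(bmd ~ age + bmi + feature, data = d)
  if (is.na(coef(fit)["feature"])) {
    abort("feature is collinear with age/BMI: design is rank deficient.",
          class = "bonetex_collinearity_error")
  }
  sm <- summary(fit)$coefficients
  tibble(attribute = attribute,
         estimated_coefficient = sm["feature", "Estimate"],
         p_value = sm["feature", "Pr(>|t|)"],
         pearson_r = as.numeric(cor(feature, bmd)),
         model = "model2",
         n = length(feature))
}

#' One-way ANOVA comparison of a variable across groups
#'
#' With two groups the F test is exactly the squared pooled-variance
#' t test. When every value is identical across groups the F statistic
#' is 0/0; the comparison is then reported as p = 1 (no evidence of a
#' difference).
#'
#' @param values Numeric observations.
#' @param group Group labels (coerced to factor; >= 2 nonempty groups).
#' @return The F-test p-value.
#' @export
compare_groups <- function(values, group) {
  group <- as.factor(as.vector(group))
  if (length(values) != length(group) || length(values) < 3L) {
    abort("need matching `values`/`group` with total n >= 3.",
          class = "bonetex_value_error")
  }
  if (nlevels(droplevels(group)) < 2L) {
    abort("need at least two nonempty groups.", class = "bonetex_value_error")
  }
  if (!all(is.finite(values))) {
    abort("values must be finite.", class = "bonetex_value_error")
  }
  if (max(values) == min(values)) return(1)  # no variation at all
  an <- suppressWarnings(anova(lm(values ~ group)))
  p <- an[["Pr(>F)"]][1]
  f <- an[["F value"]][1]
  if (is.nan(f)) return(1)       # zero variance within and between
  if (is.infinite(f)) return(0)  # zero within-group variance only
  p
}
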