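test_that("simple regression recovers hand-computed slope, p, and r", {
  perfect <- suppressWarnings(fit_model1(c(1, 2, 3, 4), 2 * c(1, 2, 3, 4)))
  expect_equal(perfect$estimated_coefficient, 2)
  expect_equal(perfect$pearson_r, 1)

  m <- fit_model1(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$estimated_coefficient, 1.5)
  expect_equal(m$pearson_r, sqrt(27 / 28))
  # two-sided p from t with n-2 = 1 df, t = r sqrt((n-2)/(1-r^2))
  tstat <- sqrt(27 / 28) * sqrt(1 / (1 - 27 / 28))
  expect_equal(m$p_value, 2 * stats::pt(tstat, df = 1, lower.tail = FALSE))

  expect_error(fit_model1(rep(1, 5), rnorm(5)),
               class = "bonetex_degenerate_predictor")
  expect_error(fit_model1(1:2, 1:2), class = "bonetex_value_error")
})

test_that("OLS identity links the slope to the Pearson correlation", {
  for (s in 1:20) {
    d <- withr::with_seed(s, data.frame(x = rnorm(30), y = rnorm(30)))
    m <- fit_model1(d$x, d$y)
    expect_equal(m$estimated_coefficient * sd(d$x) / sd(d$y), m$pearson_r)
  }
})

test_that("adjusted regression degrades gracefully and flags collinearity", {
  withr::local_seed(21)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  # constant covariates: feature slope reduces to model 1
  m2 <- fit_model2(x, y, age = rep(40, 30), bmi = rep(22, 30))
  m1 <- fit_model1(x, y)
  expect_equal(m2$estimated_coefficient, m1$estimated_coefficient)
  expect_equal(m2$p_value, m1$p_value)

  expect_error(fit_model2(x, y, age = x, bmi = rnorm(30)),
               class = "bonetex_collinearity_error")
})

test_that("adjusted regression recovers a known coupling within 3 SE", {
  withr::local_seed(31)
  n <- 200
  feature <- rnorm(n)
  age <- runif(n, 20, 68)
  bmi <- runif(n, 18, 25)
  bmd <- 1 + 0.05 * feature - 0.001 * age + 0.002 * bmi + rnorm(n, 0, 0.01)
  m <- fit_model2(feature, bmd, age, bmi)
  se <- abs(m$estimated_coefficient /
              stats::qt(m$p_value / 2, df = n - 4, lower.tail = FALSE))
  expect_lt(abs(m$estimated_coefficient - 0.05), 3 * se)
})

test_that("Lin concordance matches hand-worked fixtures", {
  id <- lin_ccc(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id$ccc, 1)
  expect_equal(id$ci_low, 1)
  expect_identical(id$strength, "almost perfect")

  shifted <- lin_ccc(c(1, 2, 3), c(2, 3, 4))
  expect_equal(shifted$ccc, 4 / 7)
  expect_lte(shifted$ci_low, shifted$ccc)
  expect_gte(shifted$ci_high, shifted$ccc)

  rev <- lin_ccc(c(1, 2, 3), c(3, 2, 1))
  expect_equal(rev$ccc, -1)

  expect_error(lin_ccc(rep(1, 5), rep(2, 5)), class = "bonetex_undefined_ccc")
})

test_that("Lin CCC obeys its inequality, symmetry, and shift invariance", {
  for (s in 1:100) {
    d <- withr::with_seed(s, {
      n <- sample(5:40, 1)
      list(x = rnorm(n, sd = runif(1, 0.5, 3)),
           y = rnorm(n, mean = runif(1, -2, 2)))
    })
    cc <- lin_ccc(d$x, d$y)
    expect_lte(abs(cc$ccc), abs(cor(d$x, d$y)) + 1e-12)
    expect_lte(abs(cc$ccc), 1)
    expect_lte(cc$ci_low, cc$ccc + 1e-12)
    expect_gte(cc$ci_high, cc$ccc - 1e-12)
    expect_equal(lin_ccc(d$y, d$x)$ccc, cc$ccc)
    expect_equal(lin_ccc(d$x + 5, d$y + 5)$ccc, cc$ccc)
  }
})

test_that("ccc objects have tidy and glance methods", {
  cc <- lin_ccc(c(1, 2, 3, 5), c(1.1, 2.2, 2.9, 4.8), attribute = "entropy")
  td <- tidy(cc)
  expect_identical(td$attribute, "entropy")
  expect_named(td, c("attribute", "estimate", "conf.low", "conf.high",
                     "strength"))
  expect_identical(glance(cc)$n, 4L)
})

test_that("strength labels reproduce the conventional ranges at boundaries", {
  expect_identical(strength_label(0.95), "almost perfect")
  expect_identical(strength_label(0.30), "fair")
  expect_identical(strength_label(0.10), "poor")
  expect_identical(strength_label(c(0, 0.19, 0.2, 0.39, 0.4, 0.59, 0.6,
                                    0.79, 0.8, 1)),
                   c("poor", "poor", "fair", "fair", "moderate", "moderate",
                     "substantial", "substantial", "almost perfect",
                     "almost perfect"))
  expect_identical(strength_label(-0.4), "poor")
  expect_error(strength_label(1.5), class = "bonetex_domain_error")
})

test_that("two-group comparison equals the squared-t test and handles degeneracy", {
  expect_equal(compare_groups(c(1, 2, 3, 1, 2, 3),
                              rep(c("a", "b"), each = 3)), 1)

  withr::local_seed(41)
  x <- rnorm(12); g <- rep(c("a", "b"), each = 6)
  p_f <- compare_groups(x, g)
  p_t <- stats::t.test(x ~ g, var.equal = TRUE)$p.value
  expect_equal(p_f, p_t)

  expect_lt(compare_groups(c(0, 0, 0, 0, 1, 1, 1, 1),
                           rep(c("a", "b"), each = 4)), 1e-12)
  expect_equal(compare_groups(rep(5, 6), rep(c("a", "b"), 3)), 1)
})
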