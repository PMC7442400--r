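test_that("quantization is equal-width, range-relative, and handles degeneracy", {
  dims <- c(8, 8, 8)
  mask <- array(TRUE, dims)

  ramp <- image_volume(array(rep(0:255, length.out = prod(dims)), dims))
  q <- quantize(ramp, mask, 32)
  expect_identical(unique(q$levels[ramp$data == 16]), 3L)
  expect_identical(unique(q$levels[ramp$data == 0]), 1L)
  expect_identical(unique(q$levels[ramp$data == 255]), 32L)
  expect_identical(sort(unique(as.vector(q$levels))), 1:32)

  const <- image_volume(array(7, dims))
  expect_identical(unique(as.vector(quantize(const, mask, 32)$levels)), 1L)

  two <- image_volume(array(c(2, 9), dims))
  lv <- quantize(two, mask, 32)$levels
  expect_setequal(unique(as.vector(lv)), c(1L, 32L))

  tiny <- array(FALSE, dims); tiny[1] <- TRUE
  expect_error(quantize(ramp, tiny, 32), class = "bonetex_empty_voi")
})

test_that("the direction set has 13 antipodally unique offsets incl. the axes", {
  ds <- direction_set()
  expect_length(ds, 13L)
  keys <- vapply(ds, paste, collapse = ",", FUN.VALUE = "")
  negs <- vapply(ds, function(d) paste(-d, collapse = ","), "")
  expect_length(unique(keys), 13L)
  expect_length(intersect(keys, negs), 0L)
  expect_true(all(c("1,0,0", "0,1,0", "0,0,1") %in% keys))
  expect_true(all(vapply(ds, function(d) max(abs(d)) == 1L, logical(1))))
})

test_that("co-occurrence counting matches hand enumeration on a 1x1x4 column", {
  v <- image_volume(array(c(1, 1, 2, 2), c(1, 1, 4)))
  q <- quantize(v, array(TRUE, c(1, 1, 4)), 2)
  g <- compute_glcm(q, c(0, 0, 1), 1, symmetric = TRUE)
  expect_equal(g$p, matrix(c(2, 1, 1, 2) / 6, 2, 2))
  expect_identical(g$n_pairs, 3L)

  g1 <- compute_glcm(q, c(0, 0, 1), 1, symmetric = FALSE)
  expect_equal(g1$p, matrix(c(1, 1, 0, 1) / 3, 2, 2, byrow = TRUE))

  # constant VOI: all mass at (1, 1)
  qc <- quantize(image_volume(array(5, c(3, 3, 3))), array(TRUE, c(3, 3, 3)), 4)
  gc <- compute_glcm(qc, c(1, 0, 0), 1)
  expect_identical(gc$p[1, 1], 1)
  expect_identical(sum(gc$p), 1)

  # displacement exits the grid entirely
  expect_error(compute_glcm(q, c(0, 0, 1), 4), class = "bonetex_empty_glcm")
})

test_that("compute_glcm matches the brute-force pair oracle exactly", {
  dirs <- direction_set()
  cases <- expand.grid(seed = 1:4, ng = 2:4, dist = 1:2)
  for (ci in seq_len(nrow(cases))) {
    q <- random_qvoi(c(5, 5, 5), cases$ng[ci], mask_prob = 0.7,
                     seed = cases$seed[ci])
    for (d in dirs[c(1, 3, 5, 10, 13)]) {
      disp <- d * cases$dist[ci]
      ref <- brute_glcm(q$levels, q$mask, disp, q$n_levels)
      got <- tryCatch(compute_glcm(q, d, cases$dist[ci]),
                      bonetex_empty_glcm = function(e) NULL)
      if (ref$n_pairs == 0L) {
        expect_null(got)
      } else {
        expect_identical(got$p, ref$p)
        expect_identical(got$n_pairs, ref$n_pairs)
      }
    }
  }
})

test_that("derived marginals, cross-distributions, and entropies are correct", {
  g <- as_glcm(matrix(c(0, 0.5, 0.5, 0), 2, 2))
  dv <- glcm_derived(g, log_base = 2)
  expect_equal(dv$px, c(0.5, 0.5))
  expect_equal(dv$py, c(0.5, 0.5))
  expect_equal(unname(dv$p_plus["3"]), 1)
  expect_equal(unname(dv$p_minus["1"]), 1)
  expect_equal(dv$HX, 1)
  expect_equal(dv$HXY, 1)
  expect_equal(dv$HXY1, 2)  # -sum p log2(px py) = -log2(1/4)

  g1 <- as_glcm(matrix(1))
  dv1 <- glcm_derived(g1)
  expect_equal(dv1$HXY, 0)
  expect_equal(dv1$mu_x, 1)
  expect_equal(dv1$mu_y, 1)

  # total-mass invariants on random matrices
  for (s in 1:20) {
    m <- withr::with_seed(s, matrix(stats::rexp(36), 6, 6))
    m <- (m + t(m)); m <- m / sum(m)
    dvr <- glcm_derived(as_glcm(m))
    expect_equal(sum(dvr$px), 1)
    expect_equal(sum(dvr$py), 1)
    expect_equal(sum(dvr$p_plus), 1)
    expect_equal(sum(dvr$p_minus), 1)
    expect_gte(dvr$HXY1, dvr$HXY - 1e-12)
    expect_gte(min(dvr$HX, dvr$HY, dvr$HXY), 0)
  }
})

test_that("the 22 attributes take their closed-form values on tiny matrices", {
  f <- compute_features(as_glcm(matrix(c(0, 0.5, 0.5, 0), 2, 2)), log_base = 2)
  expect_named(f, glcm_attributes())
  expect_equal(unname(f["energy"]), 0.5)
  expect_equal(unname(f["contrast"]), 1)
  expect_equal(unname(f["dissimilarity"]), 1)
  expect_equal(unname(f["max_probability"]), 0.5)
  expect_equal(unname(f["entropy"]), 1)
  expect_equal(unname(f["autocorrelation"]), 2)
  expect_equal(unname(f["correlation"]), -1)
  expect_equal(unname(f["sum_average"]), 3)
  expect_equal(unname(f["sum_entropy"]), 0)
  expect_equal(unname(f["sum_variance"]), 0)
  expect_equal(unname(f["difference_entropy"]), 0)
  expect_equal(unname(f["homogeneity1"]), 0.5)
  expect_equal(unname(f["homogeneity2"]), 0.5)
  expect_equal(unname(f["imc1"]), -1)
  expect_equal(unname(f["idmn"]), 0.8)
  expect_equal(unname(f["idn"]), 2 / 3)
  expect_equal(unname(f["inverse_variance"]), 1)
  expect_equal(unname(f["variance"]), 0.25)
  expect_equal(unname(f["cluster_tendency"]), 0)

  fc <- compute_features(as_glcm(matrix(1)))
  expect_equal(unname(fc["energy"]), 1)
  expect_equal(unname(fc["entropy"]), 0)
  expect_equal(unname(fc["contrast"]), 0)
  expect_equal(unname(fc["correlation"]), 0)  # defined fallback
})

test_that("homogeneity1 dominates homogeneity2 and feature bounds hold", {
  for (s in 1:15) {
    m <- withr::with_seed(s, matrix(stats::rexp(64), 8, 8))
    m <- m + t(m); m <- m / sum(m)
    f <- compute_features(as_glcm(m))
    expect_gte(f[["homogeneity1"]], f[["homogeneity2"]] - 1e-12)
    expect_lte(f[["homogeneity1"]], 1)
    expect_gt(f[["energy"]], 0)
    expect_lte(f[["energy"]], 1)
    expect_gte(f[["entropy"]], 0)
    expect_gte(f[["contrast"]], 0)
    expect_lte(abs(f[["correlation"]]), 1 + 1e-12)
  }
})

test_that("extraction builds 65 matrices, 22 attributes, and degenerates cleanly", {
  ph <- generate_phantom(phantom_spec(shape = c(12, 12, 10), voi_margin = 1,
                                      seed = 6))
  fv <- extract_features(ph$volume, ph$mask)
  expect_identical(fv$n_matrices, 65L)
  expect_identical(setdiff(names(fv), "n_matrices"), glcm_attributes())

  const <- image_volume(array(3, c(8, 8, 8)))
  fc <- extract_features(const, array(TRUE, c(8, 8, 8)))
  expect_equal(fc$energy, 1)
  expect_equal(fc$entropy, 0)
})

test_that("features are invariant to intensity shifts and to transposing p", {
  ph <- generate_phantom(phantom_spec(shape = c(12, 12, 12), voi_margin = 1,
                                      seed = 8))
  f0 <- extract_features(ph$volume, ph$mask)
  shifted <- image_volume(ph$volume$data + 123.456, ph$volume$spacing)
  f1 <- extract_features(shifted, ph$mask)
  expect_equal(f0, f1)

  m <- withr::with_seed(3, matrix(stats::rexp(25), 5, 5))
  m <- m + t(m); m <- m / sum(m)
  expect_equal(compute_features(as_glcm(m)), compute_features(as_glcm(t(m))))
})

test_that("the aggregated feature vector is invariant to 90-degree rotations", {
  ph <- generate_phantom(phantom_spec(shape = c(14, 14, 10), voi_margin = 1,
                                      seed = 12))
  f0 <- unlist(extract_features(ph$volume, ph$mask)[glcm_attributes()])
  for (axis in c("x", "y", "z")) {
    vr <- image_volume(rotate90(ph$volume$data, axis))
    mr <- rotate90(ph$mask, axis)
    fr <- unlist(extract_features(vr, mr)[glcm_attributes()])
    expect_lt(max(abs(f0 - fr)), 1e-10)
  }
})

test_that("aggregation modes agree when every matrix is present", {
  ph <- generate_phantom(phantom_spec(shape = c(12, 12, 12), voi_margin = 1,
                                      seed = 9))
  f_m <- extract_features(ph$volume, ph$mask, glcm_config())
  f_d <- extract_features(ph$volume, ph$mask,
                          glcm_config(aggregation =
                                        "mean_over_directions_then_distances"))
  expect_equal(f_m, f_d)
})

test_that("displacements that exit a thin VOI are skipped with a warning", {
  ph <- generate_phantom(phantom_spec(shape = c(16, 16, 7), voi_margin = 1,
                                      seed = 10))
  expect_warning(fv <- extract_features(ph$volume, ph$mask),
                 class = "bonetex_empty_glcm_warning")
  expect_lt(fv$n_matrices, 65L)
  expect_gt(fv$n_matrices, 0L)
})

test_that("texture config YAML round-trips bit-for-bit", {
  cfg <- glcm_config(n_levels = 16, distances = c(1L, 3L), log_base = exp(1),
                     aggregation = "mean_over_directions_then_distances")
  f <- withr::local_tempfile(fileext = ".yaml")
  write_glcm_config(cfg, f)
  expect_identical(read_glcm_config(f), cfg)
  expect_identical(read_glcm_config(f)$log_base, exp(1))
})
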