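# Independent brute-force co-occurrence oracle: triple loop over every
# voxel, look up the partner at +displacement, accumulate counts. Shares
# no code with compute_glcm.
brute_glcm <- function(levels, mask, displacement, n_levels,
                       symmetric = TRUE) {
  dims <- dim(levels)
  C <- matrix(0L, n_levels, n_levels)
  n_pairs <- 0L
  for (x in seq_len(dims[1])) {
    for (y in seq_len(dims[2])) {
      for (z in seq_len(dims[3])) {
        if (!mask[x, y, z]) next
        xx <- x + displacement[1]
        yy <- y + displacement[2]
        zz <- z + displacement[3]
        if (xx < 1 || xx > dims[1] || yy < 1 || yy > dims[2] ||
            zz < 1 || zz > dims[3]) next
        if (!mask[xx, yy, zz]) next
        i <- levels[x, y, z]
        j <- levels[xx, yy, zz]
        C[i, j] <- C[i, j] + 1L
        n_pairs <- n_pairs + 1L
      }
    }
  }
  if (symmetric) C <- C + t(C)
  list(p = if (sum(C) > 0) C / sum(C) else C, n_pairs = n_pairs)
}

# Random quantized VOI fixture on a small grid.
random_qvoi <- function(dims, n_levels, mask_prob = 0.8, seed = 1) {
  withr::with_seed(seed, {
    mask <- array(runif(prod(dims)) < mask_prob, dim = dims)
    if (sum(mask) < 2) mask[1:2] <- TRUE
    vals <- array(sample.int(n_levels, prod(dims), replace = TRUE),
                  dim = dims)
    levels <- array(NA_integer_, dim = dims)
    levels[mask] <- vals[mask]
    structure(list(levels = levels, mask = mask, n_levels = n_levels),
              class = "bonetex_qvoi")
  })
}

# 90-degree rotation of a 3-D array about one axis.
rotate90 <- function(a, axis) {
  switch(axis,
         x = {
           r <- aperm(a, c(1, 3, 2))
           r[, dim(r)[2]:1, , drop = FALSE]
         },
         y = {
           r <- aperm(a, c(3, 2, 1))
           r[, , dim(r)[3]:1, drop = FALSE]
         },
         z = {
           r <- aperm(a, c(2, 1, 3))
           r[dim(r)[1]:1, , , drop = FALSE]
         })
}

# Cohort CSV text fixture written to a temp file.
write_cohort_csv <- function(n = 5, path = tempfile(fileext = ".csv"),
                             seed = 1) {
  withr::with_seed(seed, {
    df <- data.frame(id = sprintf("P%02d", seq_len(n)),
                     age = round(runif(n, 20, 68), 1),
                     sex = sample(c("F", "M"), n, replace = TRUE),
                     bmi = round(runif(n, 18, 25), 1),
                     bmd = round(rnorm(n, 1, 0.13), 4))
  })
  write.csv(df, path, row.names = FALSE)
  path
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

quiet <- function(expr) {
  withCallingHandlers(expr,
                      message = function(m) invokeRestart("muffleMessage"))
}
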