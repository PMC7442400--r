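#' Construct a 3-D image volume
#'
#' A volume couples a 3-D scalar intensity grid with its per-axis voxel
#' spacing in millimetres. All texture computation happens on the voxel
#' lattice; spacing is carried through I/O but never used to rescale
#' displacements.
#'
#' @param data A 3-D numeric array of finite intensities.
#' @param spacing Numeric vector of three positive voxel sizes in mm.
#' @return An object of class `bonetex_volume` with fields `data` and
#'   `spacing`.
#' @export
#' @examples
#' v <- image_volume(array(rnorm(64), c(4, 4, 4)), spacing = c(0.8, 0.8, 3))
#' dim(v)
image_volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3-D array.", class = "bonetex_dim_error")
  }
  if (any(dim(data) < 1L)) {
    abort("all volume dimensions must be >= 1.", class = "bonetex_dim_error")
  }
  if (!all(is.finite(data))) {
    abort("volume intensities must be finite.", class = "bonetex_value_error")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three positive numbers (mm).",
          class = "bonetex_value_error")
  }
  structure(list(data = data, spacing = spacing), class = "bonetex_volume")
}

#' @export
dim.bonetex_volume <- function(x) dim(x$data)

#' @export
print.bonetex_volume <- function(x, ...) {
  cat(sprintf("<bonetex_volume> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Read a 3-D volume from a NIfTI file
#'
#' The grid is returned in index space with the header voxel spacing; no
#' resampling or reorientation is performed.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [image_volume()].
#' @export
read_volume <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(sprintf("volume file not found: %s", path), class = "bonetex_io_error")
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    abort(sprintf("expected a 3-D image, got %d dimensions: %s",
                  length(d), path),
          class = "bonetex_dim_error")
  }
  image_volume(array(as.numeric(img), dim = d),
               spacing = as.numeric(RNifti::pixdim(img))[seq_len(3)])
}

#' Write a 3-D volume to a NIfTI file
#'
#' @param volume A [image_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "bonetex_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  tryCatch(RNifti::writeNifti(img, path),
           error = function(e) abort(sprintf("cannot write %s: %s", path,
                                             conditionMessage(e)),
                                     class = "bonetex_io_error"))
  invisible(path)
}

#' Read a binary VOI mask from a NIfTI file
#'
#' Any nonzero stored value marks a voxel as inside the volume of interest
#' (the usual NIfTI segmentation convention).
#'
#' @param path Path to the mask file.
#' @param volume The companion [image_volume()]; the mask grid must match its
#'   shape exactly.
#' @return A 3-D logical array.
#' @export
read_mask <- function(path, volume) {
  stopifnot(inherits(volume, "bonetex_volume"))
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(sprintf("mask file not found: %s", path), class = "bonetex_io_error")
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    abort(sprintf("expected a 3-D mask, got %d dimensions: %s",
                  length(d), path),
          class = "bonetex_dim_error")
  }
  if (!identical(as.integer(d), as.integer(dim(volume$data)))) {
    abort(sprintf("mask shape (%s) does not match volume shape (%s)",
                  paste(d, collapse = "x"),
                  paste(dim(volume$data), collapse = "x")),
          class = "bonetex_geometry_error")
  }
  m <- array(as.numeric(img) != 0, dim = d)
  if (!any(m)) {
    abort("mask contains no nonzero voxel (empty VOI).",
          class = "bonetex_empty_voi")
  }
  m
}

#' Write a binary mask to a NIfTI file
#'
#' @param mask 3-D logical array.
#' @param path Output path.
#' @param spacing Voxel spacing to record in the header (mm).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, spacing = c(1, 1, 1)) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)))
  RNifti::pixdim(img) <- spacing
  tryCatch(RNifti::writeNifti(img, path),
           error = function(e) abort(sprintf("cannot write %s: %s", path,
                                             conditionMessage(e)),
                                     class = "bonetex_io_error"))
  invisible(path)
}

#' Read a subject covariate table
#'
#' Expects a CSV with header columns `id`, `age`, `sex`, `bmi`, `bmd`
#' (extra columns such as `ell_true` are preserved). Missing or
#' non-numeric covariates are hard errors: association models require a
#' complete cohort.
#'
#' @param path Path to the cohort CSV.
#' @return A tibble with one row per subject, `id` as character.
#' @export
read_cohort <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(sprintf("cohort file not found: %s", path), class = "bonetex_io_error")
  }
  df <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  )
  required <- c("id", "age", "sex", "bmi", "bmd")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    abort(sprintf("cohort is missing required column(s): %s",
                  paste(miss, collapse = ", ")),
          class = "bonetex_schema_error")
  }
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    dup <- unique(df$id[duplicated(df$id)])
    abort(sprintf("duplicate subject id(s): %s", paste(dup, collapse = ", ")),
          class = "bonetex_schema_error")
  }
  for (col in c("age", "bmi", "bmd")) {
    if (!is.numeric(df[[col]])) {
      abort(sprintf("column `%s` must be numeric.", col),
            class = "bonetex_parse_error")
    }
    if (anyNA(df[[col]])) {
      abort(sprintf("column `%s` has missing values.", col),
            class = "bonetex_parse_error")
    }
    if (any(df[[col]] <= 0)) {
      abort(sprintf("column `%s` must be strictly positive.", col),
            class = "bonetex_value_error")
    }
  }
  df$sex <- as.character(df$sex)
  if (!all(df$sex %in% c("F", "M"))) {
    abort("column `sex` must contain only \"F\" or \"M\".",
          class = "bonetex_schema_error")
  }
  as_tibble(df)
}

#' Write an analysis report CSV with deterministic formatting
#'
#' Association reports carry columns `attribute`, `estimated_coefficient`,
#' `p_value`, `pearson_r`; concordance reports carry `attribute`, `ccc`,
#' `ci_low`, `ci_high`, `strength`. Any data frame with an `attribute`
#' column is accepted (the extended two-model report included). Numbers
#' are printed with `%.17g`, so a round-trip read reproduces every double
#' bit-for-bit and repeated writes are byte-identical.
#'
#' @param rows Nonempty data frame of results.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0L) {
    abort("report has no rows.", class = "bonetex_empty_input")
  }
  if (!any(c("attribute", "id") %in% names(rows))) {
    abort("report must have an `attribute` (or `id`) key column.",
          class = "bonetex_schema_error")
  }
  cells <- vapply(rows, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  }, FUN.VALUE = character(nrow(rows)))
  cells <- matrix(cells, nrow = nrow(rows),
                  dimnames = list(NULL, names(rows)))
  lines <- c(paste(names(rows), collapse = ","),
             apply(cells, 1L, paste, collapse = ","))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) abort(sprintf("cannot open %s: %s", path,
                                                    conditionMessage(e)),
                                            class = "bonetex_io_error"))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
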