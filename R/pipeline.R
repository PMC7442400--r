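bonetex_log <- function(fmt, ..., level = "INFO") {
  message(sprintf("[bonetex %s] %s", level, sprintf(fmt, ...)))
}

# Tiny rolling hash so runs can log a stable fingerprint of their
# configuration without extra dependencies.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = ""))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Extract texture features for every subject of a cohort directory
#'
#' Reads the `cohort.csv` manifest in `dir`, then for each subject loads
#' `volumes/<id>.nii.gz` and `<masks>/<id>.nii.gz` and runs
#' [extract_features()]. A missing or failing subject aborts with the
#' subject id named. One log line per subject records the number of
#' non-empty co-occurrence matrices.
#'
#' @param dir Cohort directory as written by [generate_cohort()] (or any
#'   directory with the same layout).
#' @param config A [glcm_config()].
#' @param masks Mask subdirectory to use: `"masks_a"` (default) or
#'   `"masks_b"`.
#' @param out Optional CSV path; written via [write_report()] formatting
#'   so reruns are byte-identical.
#' @return A tibble: `id`, the 22 attribute columns, `n_matrices`.
#' @export
run_extract <- function(dir, config = glcm_config(), masks = "masks_a",
                        out = NULL) {
  manifest <- read_cohort(file.path(dir, "cohort.csv"))
  bonetex_log("extract: %d subjects, config %s, masks=%s",
              nrow(manifest), config_hash(config), masks)
  rows <- purrr::map(manifest$id, function(id) {
    vol_path <- file.path(dir, "volumes", paste0(id, ".nii.gz"))
    mask_path <- file.path(dir, masks, paste0(id, ".nii.gz"))
    for (p in c(vol_path, mask_path)) {
      if (!file.exists(p)) {
        abort(sprintf("subject %s: missing file %s", id, p),
              class = "bonetex_io_error")
      }
    }
    fv <- tryCatch({
      vol <- read_volume(vol_path)
      extract_features(vol, read_mask(mask_path, vol), config)
    }, error = function(e) {
      if (inherits(e, "bonetex_io_error")) stop(e)
      abort(sprintf("subject %s: %s", id, conditionMessage(e)),
            class = "bonetex_subject_error")
    })
    bonetex_log("extract %s: %d matrices", id, fv$n_matrices)
    dplyr::bind_cols(tibble(id = id), fv)
  })
  features <- dplyr::bind_rows(rows)
  if (!is.null(out)) write_report(features, out)
  features
}

as_table <- function(x, what) {
  if (is.character(x) && length(x) == 1L) {
    df <- suppressWarnings(readr::read_csv(x, show_col_types = FALSE,
                                           progress = FALSE))
  } else if (is.data.frame(x)) {
    df <- x
  } else {
    abort(sprintf("`%s` must be a data frame or a CSV path.", what),
          class = "bonetex_value_error")
  }
  df <- as_tibble(df)
  if (!"id" %in% names(df)) {
    abort(sprintf("`%s` must have an `id` column.", what),
          class = "bonetex_schema_error")
  }
  df$id <- as.character(df$id)
  df
}

#' Associate every texture attribute with BMD
#'
#' Joins the feature table to the cohort by subject id and fits, per
#' attribute, the simple BMD-on-attribute regression (model 1, with its
#' Pearson correlation) and the age/BMI-adjusted regression (model 2).
#' Rows appear in canonical attribute order; rows with model-1
#' p < alpha are flagged significant. No multiple-testing correction is
#' applied by default (matching the convention of reporting raw p over
#' the 22 attributes); `add_bh = TRUE` appends a Benjamini-Hochberg
#' adjusted column.
#'
#' @param features Feature tibble from [run_extract()] (or CSV path).
#' @param cohort Cohort tibble from [read_cohort()] (or CSV path).
#' @param alpha Significance level (default 0.05).
#' @param add_bh Append a `q_value` column (BH-adjusted model-1 p).
#' @param out Optional CSV path for the report.
#' @return A tibble of class `bonetex_assoc`: `attribute`, `n`,
#'   `coefficient_model1`, `p_model1`, `pearson_r`, `coefficient_model2`,
#'   `p_model2`, `significant` (+ `q_value` if requested).
#' @export
run_associate <- function(features, cohort, alpha = 0.05, add_bh = FALSE,
                          out = NULL) {
  features <- as_table(features, "features")
  cohort <- if (is.character(cohort)) read_cohort(cohort) else
    as_table(cohort, "cohort")
  only_f <- setdiff(features$id, cohort$id)
  only_c <- setdiff(cohort$id, features$id)
  if (length(only_f) || length(only_c)) {
    abort(sprintf("feature/cohort ids do not match 1:1 (only in features: %s; only in cohort: %s)",
                  paste(only_f, collapse = ",") %0% "none",
                  paste(only_c, collapse = ",") %0% "none"),
          class = "bonetex_join_error")
  }
  d <- dplyr::inner_join(features, cohort, by = "id")
  attrs <- intersect(glcm_attributes(), names(features))
  if (length(attrs) == 0L) {
    abort("feature table has no known attribute column.",
          class = "bonetex_schema_error")
  }
  bonetex_log("associate: %d subjects x %d attributes, alpha=%g",
              nrow(d), length(attrs), alpha)
  res <- purrr::map_dfr(attrs, function(a) {
    m1 <- fit_model1(d[[a]], d$bmd, attribute = a)
    m2 <- fit_model2(d[[a]], d$bmd, d$age, d$bmi, attribute = a)
    tibble(attribute = a, n = m1$n,
           coefficient_model1 = m1$estimated_coefficient,
           p_model1 = m1$p_value,
           pearson_r = m1$pearson_r,
           coefficient_model2 = m2$estimated_coefficient,
           p_model2 = m2$p_value,
           significant = m1$p_value < alpha)
  })
  if (add_bh) res$q_value <- stats::p.adjust(res$p_model1, method = "BH")
  class(res) <- c("bonetex_assoc", class(res))
  if (!is.null(out)) write_report(res, out)
  res
}

`%0%` <- function(x, fallback) if (nzchar(x)) x else fallback

#' Interobserver concordance of texture attributes
#'
#' Pairs two raters' feature tables by subject id and computes Lin's
#' concordance correlation coefficient with its confidence interval and
#' strength label for each attribute.
#'
#' @param features_a,features_b Feature tibbles (or CSV paths) with the
#'   same ids and attribute columns.
#' @param alpha CI level is `1 - alpha` (default 0.05).
#' @param out Optional CSV report path.
#' @return A tibble of class `bonetex_concordance`: `attribute`, `ccc`,
#'   `ci_low`, `ci_high`, `strength`, `n`.
#' @export
run_concordance <- function(features_a, features_b, alpha = 0.05, out = NULL) {
  a <- as_table(features_a, "features_a")
  b <- as_table(features_b, "features_b")
  if (!setequal(a$id, b$id)) {
    abort("the two feature tables cover different subjects.",
          class = "bonetex_join_error")
  }
  attrs_a <- intersect(glcm_attributes(), names(a))
  attrs_b <- intersect(glcm_attributes(), names(b))
  if (!identical(attrs_a, attrs_b) || length(attrs_a) == 0L) {
    abort("the two feature tables carry different attribute sets.",
          class = "bonetex_schema_error")
  }
  b <- b[match(a$id, b$id), ]
  bonetex_log("concordance: %d subjects x %d attributes", nrow(a),
              length(attrs_a))
  res <- purrr::map_dfr(attrs_a, function(at) {
    cc <- lin_ccc(a[[at]], b[[at]], alpha = alpha, attribute = at)
    tibble(attribute = at, ccc = cc$ccc, ci_low = cc$ci_low,
           ci_high = cc$ci_high, strength = cc$strength, n = cc$n)
  })
  class(res) <- c("bonetex_concordance", class(res))
  if (!is.null(out)) write_report(res, out)
  res
}
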