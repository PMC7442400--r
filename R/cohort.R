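#' Specification of a simulated study cohort
#'
#' Emulates the structure of a lumbar-spine MRI + DXA cohort: each
#' subject gets a phantom whose trabecular coarseness (correlation
#' length) is drawn uniformly from `ell_range`, a DXA-scale bone
#' mineral density coupled to that coarseness,
#' `bmd = bmd_mean + beta * standardize(ell) + N(0, bmd_sd)`,
#' uniform age and BMI within typical inclusion ranges, and a second
#' rater's mask produced by [perturb_mask()]. BMD is linked to the
#' coarseness parameter — not to any texture attribute — so recovery
#' tests do not tautologically encode a feature formula.
#'
#' @param n Number of subjects (default 49).
#' @param beta Coupling: change in true BMD (g/cm^2) per SD of
#'   coarseness (default 0.05).
#' @param bmd_mean,bmd_sd Mean and residual SD of BMD in g/cm^2
#'   (defaults 1.0 and 0.13, the DXA scale of a healthy adult cohort).
#' @param ell_range Range of subject coarseness in voxels (default
#'   `c(1, 4)`).
#' @param age_range,bmi_range Uniform covariate ranges (defaults 20-68
#'   years, 18-25 kg/m^2).
#' @param rater_jitter Mask perturbation depth for rater B (default 1).
#' @param phantom Base [phantom_spec()]; its correlation length and seed
#'   are overridden per subject.
#' @param seed Top-level integer seed; every per-subject stream is
#'   derived from it (subject i uses `seed + 7919 * i`), so the whole
#'   cohort is reproducible.
#' @return An object of class `bonetex_cohort_spec`.
#' @export
cohort_sim_spec <- function(n = 49L,
                            beta = 0.05,
                            bmd_mean = 1.0,
                            bmd_sd = 0.13,
                            ell_range = c(1, 4),
                            age_range = c(20, 68),
                            bmi_range = c(18, 25),
                            rater_jitter = 1L,
                            phantom = phantom_spec(),
                            seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L) {
    abort("`n` must be >= 3.", class = "bonetex_value_error")
  }
  if (!is.numeric(bmd_sd) || bmd_sd <= 0) {
    abort("`bmd_sd` must be > 0.", class = "bonetex_value_error")
  }
  stopifnot(inherits(phantom, "bonetex_phantom_spec"))
  structure(list(n = n, beta = beta, bmd_mean = bmd_mean, bmd_sd = bmd_sd,
                 ell_range = as.numeric(ell_range),
                 age_range = as.numeric(age_range),
                 bmi_range = as.numeric(bmi_range),
                 rater_jitter = as.integer(rater_jitter),
                 phantom = phantom, seed = as.integer(seed)),
            class = "bonetex_cohort_spec")
}

#' Generate a simulated cohort directory
#'
#' Writes, per subject, a phantom volume (`volumes/<id>.nii.gz`), the
#' reference segmentation (`masks_a/<id>.nii.gz`), a simulated second
#' rater's segmentation (`masks_b/<id>.nii.gz`), and a manifest
#' `cohort.csv` with columns `id`, `age`, `sex`, `bmi`, `bmd`,
#' `ell_true`. Fully reproducible from the spec's seed.
#'
#' @param spec A [cohort_sim_spec()].
#' @param dir Output directory (created if needed).
#' @return The cohort manifest tibble, invisibly.
#' @export
generate_cohort <- function(spec = cohort_sim_spec(), dir) {
  stopifnot(inherits(spec, "bonetex_cohort_spec"))
  for (sub in c("volumes", "masks_a", "masks_b")) {
    ok <- dir.exists(file.path(dir, sub)) ||
      dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
    if (!ok) {
      abort(sprintf("cannot create output directory %s", file.path(dir, sub)),
            class = "bonetex_io_error")
    }
  }
  n <- spec$n
  draws <- withr::with_seed(spec$seed, {
    list(ell = runif(n, spec$ell_range[1], spec$ell_range[2]),
         age = runif(n, spec$age_range[1], spec$age_range[2]),
         bmi = runif(n, spec$bmi_range[1], spec$bmi_range[2]),
         sex = sample(c("F", "M"), n, replace = TRUE, prob = c(29, 20) / 49),
         eps = rnorm(n, 0, spec$bmd_sd))
  })
  ell_std <- as.vector(scale(draws$ell))
  bmd <- spec$bmd_mean + spec$beta * ell_std + draws$eps
  ids <- sprintf("S%03d", seq_len(n))
  for (i in seq_len(n)) {
    ph_spec <- spec$phantom
    ph_spec$correlation_length <- draws$ell[i]
    ph_spec$seed <- spec$seed + 7919L * i
    ph <- generate_phantom(ph_spec)
    write_volume(ph$volume, file.path(dir, "volumes", paste0(ids[i], ".nii.gz")))
    write_mask(ph$mask, file.path(dir, "masks_a", paste0(ids[i], ".nii.gz")),
               spacing = ph_spec$spacing)
    mb <- perturb_mask(ph$mask, spec$rater_jitter,
                       seed = spec$seed + 7919L * i + 1L)
    write_mask(mb, file.path(dir, "masks_b", paste0(ids[i], ".nii.gz")),
               spacing = ph_spec$spacing)
  }
  manifest <- tibble(id = ids, age = draws$age, sex = draws$sex,
                     bmi = draws$bmi, bmd = bmd, ell_true = draws$ell)
  readr::write_csv(manifest, file.path(dir, "cohort.csv"))
  invisible(manifest)
}
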