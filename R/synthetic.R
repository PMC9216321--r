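#' Population specification for synthetic calibration studies
#'
#' Describes the subject population the generator draws from: a shared true
#' threshold field, log-normally distributed individual force scales
#' (positive and right-skewed, reflecting the strong individuality of the
#' maximum force per cross-section), normally distributed conforming-coil
#' distance offsets, and the observation-noise level as a coefficient of
#' variation relative to the mean recruited force.
#'
#' @param n_subjects number of subjects
#' @param e_th true threshold field (V/m); default 65
#' @param force_median median of the individual force scale (N/m^2 for the
#'   cross-section basis, N/m^3 for the volume basis)
#' @param force_sdlog log-scale dispersion of the force scale
#' @param apl0_sd standard deviation of the conforming-coil distance offset
#'   (m); 0 disables the offsets
#' @param noise_cv observation noise as a fraction of the mean positive
#'   noiseless force
#' @param seed integer seed (mandatory; all draws are reproducible)
#' @return an object of class `population_spec`
#' @export
population_spec <- function(n_subjects = 10, e_th = 65, force_median = 3e5,
                            force_sdlog = 0.25, apl0_sd = 0.003,
                            noise_cv = 0.1, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_subjects >= 1, e_th > 0, force_median > 0, force_sdlog >= 0,
            apl0_sd >= 0, noise_cv >= 0)
  structure(list(n_subjects = n_subjects, e_th = e_th,
                 force_median = force_median, force_sdlog = force_sdlog,
                 apl0_sd = apl0_sd, noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# run code under a local RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  force(code)
}

#' Draw a subject population
#'
#' Reproducible draws of the per-subject ground-truth parameters: force
#' scales `f_i` (or `v_i`) from a log-normal with the specified median and
#' dispersion, and distance offsets `APL0_i` from a zero-mean normal.
#'
#' @param spec a [population_spec()]
#' @return `data.frame` with columns `subject`, `force_scale`, `apl0`
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(spec$seed, {
    f <- if (spec$force_sdlog > 0)
      rlnorm(spec$n_subjects, log(spec$force_median), spec$force_sdlog)
    else rep(spec$force_median, spec$n_subjects)   # degenerate: exact median
    a <- if (spec$apl0_sd > 0) rnorm(spec$n_subjects, 0, spec$apl0_sd)
         else rep(0, spec$n_subjects)
    data.frame(subject = sprintf("S%02d", seq_len(spec$n_subjects)),
               force_scale = f, apl0 = a, stringsAsFactors = FALSE)
  })
}

#' Study design for synthetic observations
#'
#' @param conditions `data.frame` with columns `coil`, `distance_mm`: the
#'   coil/distance cells of the design
#' @param amplitudes output-fraction grid in `[0, 1]`
#' @param missing_prob per-subject probability that a coil is entirely
#'   missing (emulating incomplete experimental coverage); at least one
#'   coil is always retained per subject
#' @return an object of class `design_spec`
#' @export
design_spec <- function(conditions,
                        amplitudes = seq(0.1, 1, length.out = 15),
                        missing_prob = 0) {
  stopifnot(all(c("coil", "distance_mm") %in% names(conditions)),
            all(amplitudes >= 0 & amplitudes <= 1),
            missing_prob >= 0, missing_prob <= 1)
  structure(list(conditions = conditions, amplitudes = amplitudes,
                 missing_prob = missing_prob), class = "design_spec")
}

#' Generate a synthetic observation table
#'
#' Runs the recruitment model generatively: for every subject and design
#' cell, the noiseless mean `f_i * A_eff` (or `v_i * V_eff`, with the
#' subject's distance offset when the generating model enables it) plus
#' i.i.d. zero-mean Gaussian noise. The noise standard deviation is
#' `noise_cv` times the mean positive noiseless force of the data set
#' (homoscedastic, matching the likelihood the calibration assumes); forces
#' are baseline-corrected readings and may come out slightly negative under
#' noise. Per subject, whole coils are dropped with the design's missing
#' probability. The generating ground truth is attached as attribute
#' `ground_truth`.
#'
#' @param population `data.frame` from [generate_population()]
#' @param design a [design_spec()]
#' @param spec the generating [recruitment_model_spec()]
#' @param library a [build_field_library()] covering the design
#' @param seed integer seed for noise and missingness
#' @param e_th true threshold field (V/m)
#' @param noise_cv noise level relative to the mean positive force
#' @param noise_scale absolute noise standard deviation (N); overrides
#'   `noise_cv` when given
#' @return an [observation_table()] with attribute `ground_truth`
#' @export
generate_observations <- function(population, design, spec, library, seed,
                                  e_th = 65, noise_cv = 0.1,
                                  noise_scale = NULL) {
  stopifnot(inherits(design, "design_spec"),
            inherits(spec, "recruitment_model_spec"))
  bad <- !design$conditions$coil %in% library$coils
  if (any(bad))
    stop("design references coil(s) not in the field library: ",
         paste(unique(design$conditions$coil[bad]), collapse = ", "))
  params <- parameter_set(
    e_th = e_th,
    force_scale = setNames(population$force_scale, population$subject),
    apl0 = setNames(if (spec$apl_shift) population$apl0
                    else rep(0, nrow(population)), population$subject),
    noise_scale = 1)
  rows <- list()
  for (s in population$subject) {
    for (r in seq_len(nrow(design$conditions))) {
      coil <- design$conditions$coil[r]
      d_mm <- design$conditions$distance_mm[r]
      mu <- predict_force(spec, params, library, coil, d_mm,
                          design$amplitudes, s)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, coil = coil, distance_mm = d_mm,
        amplitude = design$amplitudes, force_N = mu,
        stringsAsFactors = FALSE)
    }
  }
  obs <- do.call(rbind, rows)
  if (is.null(noise_scale)) {
    pos <- obs$force_N[obs$force_N > 0]
    noise_scale <- if (length(pos)) noise_cv * mean(pos) else 0
  }
  obs <- with_seed(seed, {
    if (noise_scale > 0)
      obs$force_N <- obs$force_N + rnorm(nrow(obs), 0, noise_scale)
    if (design$missing_prob > 0) {
      keep <- rep(TRUE, nrow(obs))
      for (s in population$subject) {
        coils <- unique(obs$coil[obs$subject == s])
        drop <- coils[runif(length(coils)) < design$missing_prob]
        if (length(drop) == length(coils))
          drop <- drop[-sample.int(length(drop), 1)]
        keep[obs$subject == s & obs$coil %in% drop] <- FALSE
      }
      obs <- obs[keep, , drop = FALSE]
    }
    obs
  })
  obs <- observation_table(obs)
  attr(obs, "ground_truth") <- list(
    e_th = e_th, population = population, model = model_name(spec),
    noise_scale = noise_scale, seed = as.integer(seed))
  obs
}
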