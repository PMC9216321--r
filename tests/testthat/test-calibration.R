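make_fit <- function(model, L, k, n) {
  structure(list(model_name = model, logLik = L, k = k, n = n,
                 bic = bic(L, k, n),
                 params = list(e_th = 65)), class = "recruit_fit")
}

test_that("Gaussian log-likelihood matches its closed forms and is additive", {
  an <- cuboid_muscle_anatomy(6, 6, 12, pitch = 0.001)
  E <- array(0, dim(an$labels))
  E[an$labels == 1L] <- 100
  lib <- cuboid_library(an, list(uni = list("0" = E)))
  spec <- recruitment_model_spec("cross_section")
  par <- parameter_set(65, c(S01 = 1, S02 = 2), noise_scale = 1)
  obs <- observation_table(data.frame(
    subject = c("S01", "S01", "S02"), coil = "uni", distance_mm = 0,
    amplitude = c(0.8, 0.9, 0.8), force_N = 0))
  g <- magrecruit:::model_means(spec, 65, par$apl0, obs, lib)
  obs$force_N <- g * par$force_scale[obs$subject]   # zero residuals
  L0 <- log_likelihood(spec, par, obs, lib)
  expect_equal(L0, -nrow(obs) / 2 * log(2 * pi), tolerance = 1e-12)
  # one record with residual 2 at unit noise
  obs1 <- obs[1, , drop = FALSE]
  obs1$force_N <- obs1$force_N + 2
  expect_equal(log_likelihood(spec, par, obs1, lib),
               -0.5 * log(2 * pi) - 2, tolerance = 1e-12)
  # deleting a record changes L by exactly that record's term
  obs_mix <- rbind(obs, obs1)
  L_full <- log_likelihood(spec, par, obs_mix, lib)
  L_drop <- log_likelihood(spec, par, obs_mix[-4, , drop = FALSE], lib)
  expect_equal(L_full - L_drop, -0.5 * log(2 * pi) - 2, tolerance = 1e-12)
  bad <- par; bad$noise_scale <- 0
  expect_error(log_likelihood(spec, bad, obs, lib), "noise_scale")
})

test_that("Schwarz criterion follows k ln n - 2 L with parsimony tie-breaking", {
  expect_identical(bic(0, 0, 10), 0)
  expect_equal(bic(-10, 2, 100), 20 + 2 * log(100))
  expect_gt(bic(-10, 3, 100), bic(-10, 2, 100))
  fits <- list(make_fit("1A", -15675, 12, 5000),
               make_fit("1B", -15450, 22, 5000))
  tab <- select_model(fits)
  expect_identical(tab$model[1], "1B")   # likelihood gain beats the penalty
  # single candidate passes through unchanged
  one <- select_model(fits[[1]])
  expect_identical(nrow(one), 1L)
  # ties break toward fewer parameters
  t1 <- make_fit("a", -100, 5, 50)
  t2 <- make_fit("b", -100 - 0.5 * (4 - 5) * log(50) / 1, 4, 50)
  t2$bic <- t1$bic
  expect_identical(select_model(list(t1, t2))$model[1], "b")
})

test_that("reported model ranking reproduces a published-style BIC table ordering", {
  # four candidate scores with the cross-section + shift model lowest
  L <- c("1A" = -15675, "1B" = -15450, "2A" = -16261, "2B" = -15683)
  S <- c("1A" = 31363, "1B" = 30919, "2A" = 32536, "2B" = 31385)
  fits <- lapply(names(L), function(m) {
    f <- make_fit(m, L[[m]], 1, 10)
    f$bic <- S[[m]]
    f
  })
  tab <- select_model(fits)
  expect_identical(tab$model, c("1B", "1A", "2B", "2A"))
})

test_that("noiseless synthetic data are recovered to within 1%", {
  lib <- unit_library()
  spec <- recruitment_model_spec("cross_section")
  pop <- generate_population(population_spec(4, seed = 21))
  obs <- generate_observations(pop, unit_design(), spec, lib, seed = 22,
                               e_th = 65, noise_scale = 1e-9)
  fit <- fit_model(spec, obs, lib, fit_control(seed = 1))
  expect_equal(fit$params$e_th, 65, tolerance = 0.01)
  expect_equal(unname(fit$params$force_scale[pop$subject]),
               pop$force_scale, tolerance = 0.01)
  expect_identical(fit$k, 2L + 4L)
  expect_identical(fit$n, nrow(obs))
  expect_equal(fit$bic, fit$k * log(fit$n) - 2 * fit$logLik)
})

test_that("the distance-shift model recovers per-subject offsets from shifted data", {
  lib <- unit_library()
  gen <- recruitment_model_spec("cross_section", apl_shift = TRUE,
                                apl_coil = "saddle")
  pop <- generate_population(population_spec(4, apl0_sd = 0.002, seed = 31))
  obs <- generate_observations(pop, unit_design(), gen, lib, seed = 32,
                               e_th = 65, noise_scale = 1e-9)
  fit <- fit_model(gen, obs, lib, fit_control(seed = 1))
  expect_equal(fit$params$e_th, 65, tolerance = 0.02)
  expect_lt(max(abs(fit$params$apl0[pop$subject] - pop$apl0)),
            0.15 * max(abs(pop$apl0)))
  # offsets count as free parameters only for subjects with conforming-coil
  # records
  expect_identical(fit$k, 2L + 4L + 4L)
})

test_that("record order does not affect the fit and missing cells are neutral", {
  lib <- unit_library()
  spec <- recruitment_model_spec("cross_section")
  pop <- generate_population(population_spec(3, seed = 41))
  obs <- generate_observations(pop, unit_design(), spec, lib, seed = 42,
                               e_th = 65, noise_cv = 0.05)
  fit1 <- fit_model(spec, obs, lib, fit_control(seed = 1))
  perm <- withr::with_seed(7, sample.int(nrow(obs)))
  fit2 <- fit_model(spec, observation_table(as.data.frame(obs)[perm, ]),
                    lib, fit_control(seed = 1))
  expect_equal(fit1$params$e_th, fit2$params$e_th, tolerance = 1e-9)
  expect_equal(fit1$logLik, fit2$logLik, tolerance = 1e-9)
  # NA forces are dropped as missing and leave n accordingly
  obs_na <- as.data.frame(obs)
  obs_na$force_N[c(2, 5)] <- NA
  fit3 <- fit_model(spec, observation_table(obs_na), lib,
                    fit_control(seed = 1))
  expect_identical(fit3$n, nrow(obs) - 2L)
})

test_that("rescaling forces shifts the likelihood by -n log c and keeps the threshold", {
  lib <- unit_library()
  spec <- recruitment_model_spec("cross_section")
  pop <- generate_population(population_spec(3, seed = 51))
  obs <- generate_observations(pop, unit_design(), spec, lib, seed = 52,
                               e_th = 65, noise_cv = 0.08)
  fit1 <- fit_model(spec, obs, lib, fit_control(seed = 1))
  c_scale <- 3.7
  obs2 <- obs
  obs2$force_N <- obs2$force_N * c_scale
  fit2 <- fit_model(spec, obs2, lib, fit_control(seed = 1))
  expect_equal(fit2$logLik - fit1$logLik, -fit1$n * log(c_scale),
               tolerance = 1e-6)
  expect_equal(fit2$params$e_th, fit1$params$e_th, tolerance = 1e-9)
  expect_equal(fit2$params$force_scale, fit1$params$force_scale * c_scale,
               tolerance = 1e-9)
})

test_that("threshold summaries follow mean/median conventions and flag outliers", {
  s <- summarize_threshold(c(60, 65, 70))
  expect_equal(s$mean, 65)
  expect_equal(s$median, 65)
  one <- summarize_threshold(42)
  expect_equal(one$mean, 42)
  expect_equal(one$median, 42)
  expect_identical(one$sd, 0)
  # an extreme value drags the mean more than the median
  s2 <- summarize_threshold(c(60, 62, 64, 65, 66, 68, 70, 151))
  expect_gt(abs(s2$mean - 65), abs(s2$median - 65))
  expect_true(any(s2$outlier))
  base <- summarize_threshold(c(60, 62, 64, 65, 66, 68, 70))
  expect_false(any(base$outlier))
})
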