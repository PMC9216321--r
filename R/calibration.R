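#' Observation table
#'
#' Validates a calibration data set: records of (subject, coil, distance,
#' amplitude, force) with arbitrary missingness by (subject, coil). Forces
#' are baseline-corrected sensor readings, so individual values may be
#' slightly negative under noise; amplitudes are stimulator output fractions
#' in `[0, 1]`.
#'
#' @param df `data.frame` with columns `subject`, `coil`, `distance_mm`,
#'   `amplitude`, `force_N`
#' @return the validated `data.frame` (class `observation_table`)
#' @export
observation_table <- function(df) {
  need <- c("subject", "coil", "distance_mm", "amplitude", "force_N")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(df$amplitude < 0 | df$amplitude > 1))
    stop("amplitudes must lie in [0, 1]")
  if (!nrow(df)) stop("empty observation table")
  df$subject <- as.character(df$subject)
  df$coil <- as.character(df$coil)
  class(df) <- c("observation_table", "data.frame")
  df
}

#' Log-likelihood of a recruitment model
#'
#' Joint Gaussian log-likelihood of the forward model over all present
#' records: `L = sum_ij log N(F_ij - mean_ij; 0, noise_scale^2)`. Records
#' with missing force are dropped before this point and contribute nothing;
#' the sample count `n` used downstream counts only present records.
#'
#' @param spec a [recruitment_model_spec()]
#' @param params a [parameter_set()]
#' @param observations an [observation_table()]
#' @param library a [build_field_library()]
#' @return the scalar log-likelihood
#' @export
log_likelihood <- function(spec, params, observations, library) {
  if (params$noise_scale <= 0) stop("noise_scale must be > 0")
  mu <- model_means(spec, params$e_th, params$apl0, observations, library)
  mu <- mu * params$force_scale[observations$subject]
  sum(dnorm(observations$force_N - mu, 0, params$noise_scale, log = TRUE))
}

# unit-scale basis values g_ij (A_eff or V_eff at the record's condition);
# force mean = force_scale[subject] * g_ij. The per-subject distance offset
# only affects records of the conforming coil, so all other (coil, distance)
# cells are shared across subjects and evaluated once with a vector of
# thresholds.
model_means <- function(spec, e_th, apl0, observations, library) {
  g <- numeric(nrow(observations))
  apl_rec <- if (spec$apl_shift) observations$coil == spec$apl_coil
             else rep(FALSE, nrow(observations))
  key <- paste(observations$coil, observations$distance_mm)
  key[apl_rec] <- paste(observations$subject[apl_rec], key[apl_rec])
  for (kk in unique(key)) {
    rows <- which(key == kk)
    coil <- observations$coil[rows[1]]
    d_eff <- observations$distance_mm[rows[1]]
    if (apl_rec[rows[1]]) {
      s <- observations$subject[rows[1]]
      a0 <- if (s %in% names(apl0)) apl0[[s]] else 0
      d_eff <- d_eff + a0 * 1000
    }
    xs <- observations$amplitude[rows]
    gr <- numeric(length(xs))
    pos <- xs > 0
    if (any(pos))
      gr[pos] <- basis_value(library, spec, coil, d_eff, e_th / xs[pos])
    g[rows] <- gr
  }
  g
}

#' Schwarz Bayesian information criterion
#'
#' The classical Schwarz form `S_BIC = k ln(n) - 2 L`; `k` counts every
#' parameter actually free in the model variant (shared threshold, noise
#' scale, one force scale per subject, and one distance offset per subject
#' that has records of the conforming coil when the shift is enabled), and
#' `n` counts only non-missing records.
#'
#' @param L maximized log-likelihood
#' @param k number of free parameters
#' @param n number of (non-missing) records
#' @return the BIC value
#' @export
bic <- function(L, k, n) k * log(n) - 2 * L

#' Fit control settings
#'
#' @param seed integer seed driving the multi-start draws (recorded in the
#'   result; the fit is deterministic given the seed)
#' @param n_starts number of jittered threshold grids
#' @param n_grid points per threshold grid
#' @param eth_range search range for the threshold field (V/m); default
#'   derived from the library's field values over the extensors
#' @param refine number of local refinement passes around the best grid
#'   point
#' @return list of control settings
#' @export
fit_control <- function(seed = 1, n_starts = 3, n_grid = 48,
                        eth_range = NULL, refine = 3) {
  list(seed = as.integer(seed), n_starts = n_starts, n_grid = n_grid,
       eth_range = eth_range, refine = refine)
}

# profile the likelihood at fixed e_th: closed-form f_i per subject, 1-D
# box-constrained search over apl0_i for subjects with conforming-coil
# records; returns RSS, per-subject parameters
profile_at_eth <- function(spec, e_th, observations, library, apl_box) {
  subjects <- unique(observations$subject)
  f <- setNames(numeric(length(subjects)), subjects)
  a0 <- setNames(numeric(length(subjects)), subjects)
  n <- nrow(observations)
  apl_rec <- if (spec$apl_shift) observations$coil == spec$apl_coil
             else rep(FALSE, n)

  # shared cells: g depends only on (coil, distance, amplitude); one
  # vectorized evaluation per cell covers all subjects
  g <- numeric(n)
  key <- paste(observations$coil, observations$distance_mm)
  for (kk in unique(key[!apl_rec])) {
    rows <- which(!apl_rec & key == kk)
    xs <- observations$amplitude[rows]
    gr <- numeric(length(xs))
    pos <- xs > 0
    if (any(pos))
      gr[pos] <- basis_value(library, spec, observations$coil[rows[1]],
                             observations$distance_mm[rows[1]],
                             e_th / xs[pos])
    g[rows] <- gr
  }
  # conforming-coil cells: the offset only moves the interpolation weight
  # between the fixed library distances, so evaluate the basis at every
  # library distance once and reduce the inner 1-D search to arithmetic
  apl_tab <- list()
  if (any(apl_rec)) {
    lib_ds <- library$distances[[spec$apl_coil]]
    for (kk in unique(key[apl_rec])) {
      rows <- which(apl_rec & key == kk)
      xs <- observations$amplitude[rows]
      G <- matrix(0, length(lib_ds), length(xs))
      pos <- xs > 0
      for (di in seq_along(lib_ds)) {
        e <- library$entries[[entry_key(spec$apl_coil, lib_ds[di])]]
        G[di, pos] <- if (spec$force_basis == "cross_section")
          a_eff_entry(e, e_th / xs[pos])
        else v_eff_entry(e, e_th / xs[pos], library$voxel_volume)
      }
      apl_tab[[kk]] <- list(rows = rows, G = G,
                            d_mm = observations$distance_mm[rows[1]])
    }
  }
  g_apl_at <- function(rows, apl0_s) {
    lib_ds <- library$distances[[spec$apl_coil]]
    out <- numeric(length(rows))
    for (tab in apl_tab) {
      rr <- intersect(tab$rows, rows)
      if (!length(rr)) next
      d_eff <- min(max(tab$d_mm + apl0_s * 1000, lib_ds[1]),
                   lib_ds[length(lib_ds)])
      i <- findInterval(d_eff, lib_ds)
      i <- min(max(i, 1L), max(length(lib_ds) - 1L, 1L))
      gv <- if (length(lib_ds) == 1L) tab$G[1, ] else {
        w <- (d_eff - lib_ds[i]) / (lib_ds[i + 1] - lib_ds[i])
        (1 - w) * tab$G[i, ] + w * tab$G[i + 1, ]
      }
      out[match(rr, rows)] <- gv[match(rr, tab$rows)]
    }
    out
  }

  rss <- 0
  for (s in subjects) {
    rows_s <- which(observations$subject == s)
    F_s <- observations$force_N[rows_s]
    apl_s <- rows_s[apl_rec[rows_s]]
    fix_s <- rows_s[!apl_rec[rows_s]]
    g_fix <- g[fix_s]
    F_fix <- observations$force_N[fix_s]
    F_apl <- observations$force_N[apl_s]
    sub_rss <- function(apl0_s) {
      g_s <- if (length(apl_s)) c(g_fix, g_apl_at(apl_s, apl0_s)) else g_fix
      F_all <- c(F_fix, F_apl)
      den <- sum(g_s^2)
      fi <- if (den > 0) max(0, sum(g_s * F_all) / den) else 0
      list(rss = sum((F_all - fi * g_s)^2), f = fi)
    }
    if (length(apl_s) && !is.null(apl_box) && diff(apl_box) > 1e-9) {
      opt <- optimize(function(a) sub_rss(a)$rss, interval = apl_box,
                      tol = 1e-5)
      # the profile is piecewise smooth; also check the box ends and 0
      cand <- unique(c(opt$minimum, apl_box, 0))
      cand <- cand[cand >= apl_box[1] & cand <= apl_box[2]]
      vals <- vapply(cand, function(a) sub_rss(a)$rss, numeric(1))
      a0[s] <- cand[which.min(vals)]
    }
    pr <- sub_rss(a0[s])
    f[s] <- pr$f
    rss <- rss + pr$rss
  }
  list(rss = rss, force_scale = f, apl0 = a0)
}

#' Fit a recruitment model by joint maximum likelihood
#'
#' Maximizes one overall Gaussian likelihood with shared parameters
#' (threshold field, noise scale) and per-subject individual parameters
#' (force scale, optional conforming-coil distance offset), tolerant of
#' missing (subject, coil) cells. The likelihood is piecewise flat in the
#' threshold (thresholding a finite voxel set), so the outer search is a
#' derivative-free multi-start grid over the threshold with local
#' refinement; for each candidate threshold the force scales have a closed
#' form, the noise scale is profiled analytically, and the distance offsets
#' are found by box-constrained 1-D search per subject.
#'
#' @param spec a [recruitment_model_spec()]
#' @param observations an [observation_table()] (rows with `NA` force are
#'   dropped as missing)
#' @param library a [build_field_library()]
#' @param control a [fit_control()]
#' @return an object of class `recruit_fit`: fitted [parameter_set()],
#'   `logLik`, `k`, `n`, `bic` and `diagnostics`
#' @export
fit_model <- function(spec, observations, library, control = fit_control()) {
  observations <- observations[!is.na(observations$force_N), , drop = FALSE]
  observations <- observation_table(as.data.frame(observations))
  n <- nrow(observations)
  namp <- tapply(observations$amplitude, observations$subject,
                 function(a) length(unique(a)))
  if (any(namp < 2))
    warning("subject(s) with fewer than 2 distinct amplitudes: ",
            paste(names(namp)[namp < 2], collapse = ", "),
            " - force scale weakly identified")

  # threshold search range from the library's extensor field values
  er <- control$eth_range
  if (is.null(er)) {
    vmax <- max(vapply(library$entries, function(e)
      if (length(e$vol_values)) max(e$vol_values) else 0, numeric(1)))
    xmax <- max(observations$amplitude)
    er <- c(0.01, 1) * vmax * xmax
  }

  # apl0 box: effective distance must stay inside the library span for
  # every conforming-coil record
  apl_box <- NULL
  if (spec$apl_shift) {
    sel <- observations$coil == spec$apl_coil
    if (any(sel)) {
      ds <- library$distances[[spec$apl_coil]]
      drec <- observations$distance_mm[sel]
      apl_box <- c(ds[1] - min(drec), ds[length(ds)] - max(drec)) / 1000
      if (apl_box[1] > apl_box[2]) apl_box <- c(0, 0)
    }
  }

  evals <- 0L
  best <- list(obj = Inf)
  consider <- function(e_th) {
    pr <- profile_at_eth(spec, e_th, observations, library, apl_box)
    evals <<- evals + 1L
    if (pr$rss < best$obj) best <<- list(obj = pr$rss, e_th = e_th, pr = pr)
    pr$rss
  }

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(control$seed)
  offsets <- runif(control$n_starts)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)

  for (off in offsets) {
    grid <- er[1] + (seq_len(control$n_grid) - 1 + off) / control$n_grid *
      (er[2] - er[1])
    for (e in grid) consider(e)
  }
  # local refinement: shrink around the incumbent
  width <- (er[2] - er[1]) / control$n_grid
  for (pass in seq_len(control$refine)) {
    lo <- max(er[1], best$e_th - width)
    hi <- min(er[2], best$e_th + width)
    for (e in seq(lo, hi, length.out = 17)) consider(e)
    width <- (hi - lo) / 16
  }

  if (!is.finite(best$obj)) stop("fit did not converge: no finite objective")
  sigma2 <- max(best$obj / n, 1e-12)
  L <- -n / 2 * (log(2 * pi * sigma2) + 1)
  subjects <- unique(observations$subject)
  k <- 2L + length(subjects)
  if (spec$apl_shift) {
    with_apl <- unique(observations$subject[
      observations$coil == spec$apl_coil])
    k <- k + length(with_apl)
  }
  params <- parameter_set(e_th = best$e_th,
                          force_scale = best$pr$force_scale,
                          apl0 = best$pr$apl0,
                          noise_scale = sqrt(sigma2))
  structure(list(model = spec, model_name = model_name(spec),
                 params = params, logLik = L, k = k, n = n,
                 bic = bic(L, k, n),
                 diagnostics = list(seed = control$seed,
                                    restarts = control$n_starts,
                                    evaluations = evals,
                                    rss = best$obj)),
            class = "recruit_fit")
}

#' @exportS3Method base::print
print.recruit_fit <- function(x, ...) {
  cat(sprintf("recruit_fit model %s: L = %.2f, k = %d, n = %d, BIC = %.2f\n",
              x$model_name, x$logLik, x$k, x$n, x$bic))
  cat(sprintf("  E_th = %.2f V/m, noise = %.3g N\n", x$params$e_th,
              x$params$noise_scale))
  cat("  force scales:", paste(signif(x$params$force_scale, 4),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Rank fitted models by BIC
#'
#' Ascending Schwarz-BIC ranking of candidate fits; ties are broken toward
#' the model with fewer parameters.
#'
#' @param fits list of `recruit_fit` objects
#' @return `data.frame` with one row per model in rank order
#' @export
select_model <- function(fits) {
  if (inherits(fits, "recruit_fit")) fits <- list(fits)
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(model = f$model_name, logLik = f$logLik, k = f$k, n = f$n,
               bic = f$bic, e_th = f$params$e_th,
               stringsAsFactors = FALSE)))
  tab <- tab[order(tab$bic, tab$k), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Summarize threshold estimates across fits
#'
#' Descriptive statistics over per-fit threshold-field estimates, with an
#' outlier flag for estimates more than 2 standard deviations from the
#' median. For a single estimate the standard deviation is reported as 0 by
#' convention.
#'
#' @param e_th numeric vector of threshold estimates (V/m), or a list of
#'   `recruit_fit` objects
#' @return list with `mean`, `sd`, `median`, `n`, `outlier` (logical vector)
#' @export
summarize_threshold <- function(e_th) {
  if (is.list(e_th) && length(e_th) && inherits(e_th[[1]], "recruit_fit"))
    e_th <- vapply(e_th, function(f) f$params$e_th, numeric(1))
  e_th <- as.numeric(e_th)
  s <- if (length(e_th) > 1) sd(e_th) else 0
  med <- median(e_th)
  list(mean = mean(e_th), sd = s, median = med, n = length(e_th),
       outlier = if (s > 0) abs(e_th - med) > 2 * s
                 else rep(FALSE, length(e_th)))
}
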