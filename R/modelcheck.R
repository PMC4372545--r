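#' Voxels within a sphere
#'
#' Enumerates grid voxels whose center lies within `radius` mm
#' (center-to-center Euclidean distance, inclusive) of the center voxel.
#'
#' @param center Integer voxel coordinate (0-based, length 3).
#' @param radius Radius in mm.
#' @param grid_shape Integer grid dimensions.
#' @param voxel_size Isotropic voxel size in mm.
#' @return Integer matrix of member voxel coordinates (0-based, one row per
#'   voxel) with attribute `flat` (1-based flat indices).
#' @export
sphere_voxels <- function(center, radius, grid_shape, voxel_size = 1.5) {
  stopifnot(length(center) == 3, radius >= 0, voxel_size > 0)
  r_vox <- floor(radius / voxel_size)
  rng <- lapply(1:3, function(d) {
    v <- (center[d] - r_vox):(center[d] + r_vox)
    v[v >= 0 & v <= grid_shape[d] - 1]
  })
  g <- as.matrix(expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]]))
  d2 <- colSums((t(g) - center)^2) * voxel_size^2
  g <- g[d2 <= radius^2, , drop = FALSE]
  if (nrow(g) == 0) stop("sphere contains no voxels")
  attr(g, "flat") <- g[, 1] + grid_shape[1] * g[, 2] +
    grid_shape[1] * grid_shape[2] * g[, 3] + 1L
  g
}

#' Extract the mean time series of a spherical ROI
#'
#' @param bold 4D array (x, y, z, t).
#' @param center 0-based voxel coordinate of the sphere center.
#' @param radius Radius in mm.
#' @param voxel_size Isotropic voxel size in mm.
#' @return Numeric vector (one value per volume): mean over member voxels.
#' @export
extract_sphere_signal <- function(bold, center, radius, voxel_size = 1.5) {
  stopifnot(length(dim(bold)) == 4)
  grid_shape <- dim(bold)[1:3]
  members <- sphere_voxels(center, radius, grid_shape, voxel_size)
  flat <- attr(members, "flat")
  n_t <- dim(bold)[4]
  Y <- matrix(bold, prod(grid_shape), n_t)
  colMeans(Y[flat, , drop = FALSE])
}

#' Trial-locked, z-scored, category-averaged time course
#'
#' Each participant's whole series is z-scored (variance floor for constant
#' series), epoched around every sample onset on the TR grid, and averaged
#' within confidence category pooling trials over participants. The
#' uncertainty band is +/- 2 standard errors over trials.
#'
#' @param series_list List of numeric series, one per participant.
#' @param schedules List of schedules (same length/order).
#' @param behaviors List of behavior records (same length/order).
#' @param window Epoch window in seconds relative to sample onset.
#' @param tr Repetition time (s).
#' @param var_floor Minimum series SD treated as nonzero.
#' @return A `trial_timecourse` data.frame: `category`, `time`, `mean`,
#'   `se` (NA when a cell has a single trial), `n_trials`.
#' @export
trial_average <- function(series_list, schedules, behaviors,
                          window = c(-4, 24), tr = 2, var_floor = 1e-12) {
  if (!is.list(series_list)) series_list <- list(series_list)
  if (inherits(schedules, "trial_schedule")) schedules <- list(schedules)
  if (inherits(behaviors, "behavior_record")) behaviors <- list(behaviors)
  stopifnot(length(series_list) == length(schedules),
            length(schedules) == length(behaviors))
  offsets <- seq(ceiling(window[1] / tr), floor(window[2] / tr)) # in TRs
  times <- offsets * tr
  epochs <- list(); cats <- character(0)
  n_dropped <- 0L
  for (i in seq_along(series_list)) {
    z <- series_list[[i]]
    sdv <- stats::sd(z)
    z <- if (sdv > var_floor) (z - mean(z)) / sdv else z * 0
    sch <- schedules[[i]]
    spec <- attr(sch, "spec")
    vol_per_run <- if (!is.null(spec)) spec$volumes_per_run else
      length(z) %/% (max(sch$run) + 1L)
    beh <- behaviors[[i]]$trials
    for (k in seq_len(nrow(sch))) {
      onset_tr <- round(sch$sample_onset[k] / tr) + sch$run[k] * vol_per_run
      idx <- onset_tr + offsets + 1L
      run_lo <- sch$run[k] * vol_per_run + 1L
      run_hi <- (sch$run[k] + 1L) * vol_per_run
      if (any(idx < run_lo | idx > run_hi)) { n_dropped <- n_dropped + 1L
        next }
      epochs[[length(epochs) + 1L]] <- z[idx]
      cats <- c(cats, beh$smt_rating[k])
    }
  }
  if (n_dropped > 0)
    message(n_dropped, " partial epoch(s) outside run bounds dropped")
  if (length(epochs) == 0) stop("no complete epochs in the window")
  E <- do.call(rbind, epochs)
  out <- lapply(sort(unique(cats)), function(cat) {
    M <- E[cats == cat, , drop = FALSE]
    n <- nrow(M)
    data.frame(category = cat, time = times, mean = colMeans(M),
               se = if (n > 1) apply(M, 2, stats::sd) / sqrt(n) else
                 NA_real_,
               n_trials = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("trial_timecourse", "data.frame")
  out
}

#' Posterior predictive replicates of a fitted time series
#'
#' Standard noninformative-prior conjugate draws from a single-voxel (or
#' ROI-average) least-squares fit: residual variance from its scaled
#' inverse-chi-square posterior, coefficients from their conditional
#' normal, then `y_rep = X beta_draw + Normal(0, sigma_draw)` noise.
#'
#' @param fit A [fit_voxelwise()] result for exactly one series.
#' @param n_sim Number of replicates.
#' @param seed Integer seed.
#' @param fixed Skip the posterior draws and replicate the fitted values
#'   plus noise at the point estimates (used by degenerate tests).
#' @return Numeric matrix, volumes x `n_sim`.
#' @export
posterior_predictive_simulate <- function(fit, n_sim = 20L, seed = 1L,
                                          fixed = FALSE) {
  stopifnot(inherits(fit, "first_level_fit"))
  if (ncol(fit$beta) != 1)
    stop("posterior predictive simulation expects a single fitted series")
  if (fit$df <= 0) stop("df must be positive")
  set.seed(as.integer(seed))
  X <- fit$design$X
  beta_hat <- fit$beta[, 1]
  s2 <- fit$sigma2[1]
  cR <- chol(fit$xtx_inv)
  reps <- matrix(NA_real_, nrow(X), n_sim)
  for (r in seq_len(n_sim)) {
    if (fixed) {
      sigma2_draw <- s2
      beta_draw <- beta_hat
    } else {
      sigma2_draw <- fit$df * s2 / stats::rchisq(1, df = fit$df)
      beta_draw <- beta_hat +
        sqrt(sigma2_draw) * drop(crossprod(cR, stats::rnorm(length(beta_hat))))
    }
    reps[, r] <- X %*% beta_draw +
      stats::rnorm(nrow(X), 0, sqrt(sigma2_draw))
  }
  reps
}

#' Discrepancy between observed and replicated time courses
#'
#' Per (category, time point), flags the observed mean when it falls
#' outside the replicate envelope (pointwise min-max by default, or the
#' central 95% band), and summarizes misfit as the mean squared
#' standardized distance of the observed mean from the replicate mean.
#'
#' @param observed A `trial_timecourse`.
#' @param replicates List of `trial_timecourse`s, one per replicate run
#'   through the identical averaging pipeline.
#' @param envelope `"minmax"` or `"central95"`.
#' @param sd_floor Floor for the across-replicate SD in the standardization.
#' @return A `ppc_result`: `table` (category, time, observed, rep_mean,
#'   lower, upper, flagged), `misfit`, `n_sim`, `n_flagged`.
#' @export
ppc_discrepancy <- function(observed, replicates,
                            envelope = c("minmax", "central95"),
                            sd_floor = 1e-12) {
  envelope <- match.arg(envelope)
  stopifnot(inherits(observed, "trial_timecourse"), length(replicates) >= 2)
  key <- paste(observed$category, observed$time)
  rep_mat <- vapply(replicates, function(r) {
    if (!identical(paste(r$category, r$time), key))
      stop("replicate time grid or categories do not match the observed")
    r$mean
  }, numeric(nrow(observed)))
  rep_mean <- rowMeans(rep_mat)
  rep_sd <- pmax(apply(rep_mat, 1, stats::sd), sd_floor)
  if (envelope == "minmax") {
    lower <- apply(rep_mat, 1, min); upper <- apply(rep_mat, 1, max)
  } else {
    lower <- apply(rep_mat, 1, stats::quantile, probs = 0.025)
    upper <- apply(rep_mat, 1, stats::quantile, probs = 0.975)
  }
  flagged <- observed$mean < lower | observed$mean > upper
  misfit <- mean(((observed$mean - rep_mean) / rep_sd)^2)
  structure(list(table = data.frame(category = observed$category,
                                    time = observed$time,
                                    observed = observed$mean,
                                    rep_mean = rep_mean, lower = lower,
                                    upper = upper, flagged = flagged),
                 misfit = misfit, n_sim = length(replicates),
                 n_flagged = sum(flagged)),
            class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat(sprintf("PPC: %d replicates, misfit %.3f, %d/%d points flagged\n",
              x$n_sim, x$misfit, x$n_flagged, nrow(x$table)))
  invisible(x)
}

#' Run the full posterior predictive check for one encoding model
#'
#' Fits the model's design to the ROI-average series, simulates `n_sim`
#' posterior predictive replicates, passes the observed series and every
#' replicate through the identical trial-averaging pipeline, and scores the
#' discrepancy.
#'
#' @param series ROI-average series (one participant).
#' @param schedule,behavior,motion,spec The participant's components.
#' @param model Encoding model name.
#' @param n_sim Number of replicates.
#' @param seed Integer seed.
#' @param window Epoch window (s).
#' @param hrf [hrf_params()].
#' @return A `ppc_result` with the fitted model name attached.
#' @export
ppc_check_model <- function(series, schedule, behavior, motion,
                            spec = acq_spec(),
                            model = c("sample_only", "sample_plus_delay",
                                      "decay"),
                            n_sim = 20L, seed = 1L, window = c(-4, 24),
                            hrf = hrf_params()) {
  model <- match.arg(model)
  design <- build_design(schedule, behavior, motion, model = model,
                         hrf = hrf, spec = spec)
  fit <- fit_voxelwise(matrix(series, ncol = 1), design)
  reps <- posterior_predictive_simulate(fit, n_sim = n_sim, seed = seed)
  observed_tc <- trial_average(list(series), list(schedule), list(behavior),
                               window = window, tr = spec$tr)
  rep_tcs <- lapply(seq_len(n_sim), function(r)
    trial_average(list(reps[, r]), list(schedule), list(behavior),
                  window = window, tr = spec$tr))
  out <- ppc_discrepancy(observed_tc, rep_tcs)
  out$model <- model
  out
}

#' Compare encoding models by posterior predictive misfit
#'
#' Fits each candidate encoding model to the ROI-average series of one
#' participant, runs the posterior predictive check for each, and returns
#' the models ranked by increasing misfit (rank 1 = best).
#'
#' @param participant A [simulate_participant()] result (or compatible list
#'   with `bold`, `schedule`, `behavior`, `motion`, `spec`).
#' @param models Character vector of encoding model names (>= 1).
#' @param center 0-based sphere center; default the centroid of the ground
#'   truth effect mask when present.
#' @param radius Sphere radius in mm.
#' @param n_sim,seed,window Passed to [ppc_check_model()].
#' @return A `model_comparison` data.frame: `model`, `misfit`, `n_flagged`,
#'   `rank`; the per-model `ppc_result`s in attribute `ppc`.
#' @export
compare_models <- function(participant,
                           models = c("sample_only", "sample_plus_delay",
                                      "decay"),
                           center = NULL, radius = 5, n_sim = 20L,
                           seed = 1L, window = c(-4, 24)) {
  stopifnot(length(models) >= 1)
  spec <- participant$spec
  if (is.null(center)) {
    mask <- participant$truth$effect_mask
    if (is.null(mask)) mask <- .default_effect_mask(spec$grid_shape)
    idx <- which(as.logical(mask))
    cc <- arrayInd(idx, spec$grid_shape)
    center <- round(colMeans(cc)) - 1
  }
  series <- extract_sphere_signal(participant$bold, center, radius,
                                  spec$voxel_size)
  ppcs <- lapply(seq_along(models), function(i)
    ppc_check_model(series, participant$schedule, participant$behavior,
                    participant$motion, spec, model = models[i],
                    n_sim = n_sim, seed = seed + i, window = window))
  out <- data.frame(model = models,
                    misfit = vapply(ppcs, `[[`, numeric(1), "misfit"),
                    n_flagged = vapply(ppcs, `[[`, numeric(1), "n_flagged"))
  out$rank <- rank(out$misfit, ties.method = "first")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  attr(out, "ppc") <- ppcs
  class(out) <- c("model_comparison", "data.frame")
  out
}
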