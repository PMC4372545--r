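#' Acquisition specification
#'
#' Describes one participant's functional acquisition: repetition time,
#' number of runs, volumes per run, and the voxel grid. Defaults mirror a
#' high-resolution medial-temporal-lobe protocol (TR = 2 s, 8 runs of 144
#' volumes) on a desk-scale 20 x 20 x 12 grid of 1.5 mm isotropic voxels.
#'
#' @param tr Repetition time in seconds.
#' @param n_runs Number of scanning runs.
#' @param volumes_per_run Functional volumes acquired per run.
#' @param grid_shape Integer vector of three voxel counts (x, y, z).
#' @param voxel_size Isotropic voxel edge length in mm.
#' @return An object of class `acq_spec`.
#' @export
acq_spec <- function(tr = 2, n_runs = 8, volumes_per_run = 144,
                     grid_shape = c(20L, 20L, 12L), voxel_size = 1.5) {
  stopifnot(tr > 0, n_runs >= 1, volumes_per_run >= 1,
            length(grid_shape) == 3, all(grid_shape >= 1), voxel_size > 0)
  structure(list(tr = tr, n_runs = as.integer(n_runs),
                 volumes_per_run = as.integer(volumes_per_run),
                 grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size),
            class = "acq_spec")
}

#' @export
print.acq_spec <- function(x, ...) {
  cat(sprintf("Acquisition: TR %gs, %d run(s) x %d volumes, grid %s @ %g mm\n",
              x$tr, x$n_runs, x$volumes_per_run,
              paste(x$grid_shape, collapse = "x"), x$voxel_size))
  invisible(x)
}

# Trial phase durations (s) and the balanced jitter set. A run is
# 12 x (2 + 10 + 2) s of trial time plus 12 inter-trial intervals drawn
# balanced from {6, 10, 14} s (4 of each), hence exactly 288 s = 144 TRs.
.SAMPLE_DUR <- 2
.DELAY_DUR <- 10
.TEST_DUR <- 2
.TRIAL_DUR <- .SAMPLE_DUR + .DELAY_DUR + .TEST_DUR
.ITI_SET <- c(6, 10, 14)
.TRIALS_PER_RUN <- 12L

#' Generate a delayed match-to-sample trial schedule
#'
#' Lays out every trial of one participant: 12 trials per run, each a 2 s
#' sample scene, a 10 s delay, and a 2 s test scene, separated by jittered
#' inter-trial intervals of 6, 10 or 14 s (four of each per run, shuffled).
#' Match and non-match test conditions are balanced 6/6 within run and
#' pseudo-randomized. The first sample of each run is at t = 0.
#'
#' @param spec An [acq_spec()]. Its `volumes_per_run * tr` must equal the
#'   288 s run duration implied by the trial arithmetic.
#' @param seed Integer seed for the jitter and condition shuffles.
#' @return A `trial_schedule`: a data.frame with one row per trial and
#'   columns `run` (0-based), `trial`, `sample_onset`, `delay_onset`,
#'   `test_onset`, `iti_after`, `condition`.
#' @export
generate_schedule <- function(spec = acq_spec(), seed = 1L) {
  run_dur <- .TRIALS_PER_RUN * .TRIAL_DUR +
    .TRIALS_PER_RUN * mean(rep(.ITI_SET, length.out = .TRIALS_PER_RUN))
  if (!isTRUE(all.equal(spec$volumes_per_run * spec$tr, run_dur))) {
    stop(sprintf(paste0("configuration error: volumes_per_run (%d) x tr (%g s)",
                        " = %g s does not match the %g s run duration"),
                 spec$volumes_per_run, spec$tr,
                 spec$volumes_per_run * spec$tr, run_dur))
  }
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(spec$n_runs) - 1L, function(r) {
    itis <- sample(rep(.ITI_SET, each = .TRIALS_PER_RUN / length(.ITI_SET)))
    cond <- sample(rep(c("match", "nonmatch"), each = .TRIALS_PER_RUN / 2))
    onset <- cumsum(c(0, (.TRIAL_DUR + itis)[-.TRIALS_PER_RUN]))
    data.frame(run = r, trial = seq_len(.TRIALS_PER_RUN) - 1L,
               sample_onset = onset,
               delay_onset = onset + .SAMPLE_DUR,
               test_onset = onset + .SAMPLE_DUR + .DELAY_DUR,
               iti_after = itis, condition = cond,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "spec") <- spec
  class(out) <- c("trial_schedule", "data.frame")
  out
}

#' Ground truth for a synthetic participant
#'
#' Bundles the generative parameters: which encoding model shapes the neural
#' response, which voxels carry the effect, the brain-behavior link
#' (trial amplitude = `gamma0 + gamma1 * strength code`), the noise level,
#' nuisance magnitudes, and the ordinal-rating model for behavior.
#'
#' The behavioral model is ordinal-probit style: each studied item has a
#' latent memory strength drawn `Normal(latent_mean_old, 1)`; lures draw from
#' `Normal(latent_mean_lure, 1)`; confidence ratings 1/2/3/4/R arise by
#' cutting the latent value at four ordered thresholds.
#'
#' @param generative_model One of `"sample_only"`, `"sample_plus_delay"`,
#'   `"decay"`.
#' @param effect_mask Logical 3D array marking effect-carrying voxels, or
#'   `NULL` for a centered 3x3x3 block.
#' @param gamma0 Baseline trial response amplitude (signal units).
#' @param gamma1 Amplitude increment per memory-strength unit.
#' @param noise_sd Standard deviation of i.i.d. Gaussian scanner noise.
#' @param baseline Mean signal level added to every voxel.
#' @param drift_sd Scale of per-run random cubic drift (0 disables).
#' @param motion_coupling Scale of per-voxel loadings on the six simulated
#'   motion series (0 disables).
#' @param rating_thresholds Four strictly increasing cut points on the latent
#'   strength axis.
#' @param latent_mean_old,latent_mean_lure Latent strength means for studied
#'   items and lures.
#' @param p_dms Probability a simulated trial's match/non-match judgment is
#'   correct.
#' @param seed Integer seed recorded with the dataset.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(generative_model = c("decay", "sample_only",
                                              "sample_plus_delay"),
                         effect_mask = NULL,
                         gamma0 = 1, gamma1 = 0.5, noise_sd = 1,
                         baseline = 100, drift_sd = 0.5,
                         motion_coupling = 0.1,
                         rating_thresholds = c(-0.3, 0.7, 1.7, 2.4),
                         latent_mean_old = 1.4, latent_mean_lure = 0,
                         p_dms = 0.95, seed = 1L) {
  generative_model <- match.arg(generative_model)
  stopifnot(noise_sd >= 0, length(rating_thresholds) == 4,
            all(diff(rating_thresholds) > 0),
            p_dms >= 0, p_dms <= 1)
  structure(list(generative_model = generative_model,
                 effect_mask = effect_mask,
                 gamma0 = gamma0, gamma1 = gamma1, noise_sd = noise_sd,
                 baseline = baseline, drift_sd = drift_sd,
                 motion_coupling = motion_coupling,
                 rating_thresholds = rating_thresholds,
                 latent_mean_old = latent_mean_old,
                 latent_mean_lure = latent_mean_lure,
                 p_dms = p_dms, seed = as.integer(seed)),
            class = "ground_truth")
}

.default_effect_mask <- function(grid_shape, half = 1L) {
  m <- array(FALSE, dim = grid_shape)
  ctr <- pmax(1L, as.integer(ceiling(grid_shape / 2)))
  idx <- lapply(seq_len(3), function(d) {
    rng <- (ctr[d] - half):(ctr[d] + half)
    rng[rng >= 1 & rng <= grid_shape[d]]
  })
  m[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  m
}

.RATING_LEVELS <- c("1", "2", "3", "4", "R")

.cut_latent <- function(latent, thresholds) {
  .RATING_LEVELS[findInterval(latent, thresholds) + 1L]
}

#' Simulate recognition behavior for a scheduled participant
#'
#' Draws a latent memory strength per studied trial, converts it to a 1-4/R
#' confidence rating through the ordered thresholds in `truth`, draws the
#' match/non-match judgment correct with probability `truth$p_dms`, and rates
#' `n_lures` unstudied lure scenes from the lower-mean lure distribution.
#'
#' @param schedule A [generate_schedule()] result.
#' @param truth A [ground_truth()].
#' @param seed Integer seed.
#' @param n_lures Number of lure items rated at the subsequent memory test.
#' @return A `behavior_record`: list with `trials` (data.frame adding
#'   `latent_strength`, `dms_response`, `dms_correct`, `smt_rating` to the
#'   schedule keys) and `lure_ratings` (character vector).
#' @export
simulate_behavior <- function(schedule, truth = ground_truth(), seed = 1L,
                              n_lures = 144L) {
  stopifnot(inherits(schedule, "trial_schedule"))
  set.seed(as.integer(seed))
  n <- nrow(schedule)
  latent <- stats::rnorm(n, truth$latent_mean_old, 1)
  rating <- .cut_latent(latent, truth$rating_thresholds)
  correct <- stats::runif(n) < truth$p_dms
  is_match <- schedule$condition == "match"
  response <- ifelse(is_match == correct, "yes", "no")
  trials <- data.frame(run = schedule$run, trial = schedule$trial,
                       condition = schedule$condition,
                       latent_strength = latent,
                       dms_response = response,
                       dms_correct = correct,
                       smt_rating = rating,
                       stringsAsFactors = FALSE)
  lure_latent <- stats::rnorm(n_lures, truth$latent_mean_lure, 1)
  structure(list(trials = trials,
                 lure_ratings = .cut_latent(lure_latent,
                                            truth$rating_thresholds)),
            class = "behavior_record")
}

#' Simulate motion parameter series
#'
#' Six smooth AR(1) channels (three translations, three rotations) per the
#' full acquisition, concatenated across runs.
#'
#' @param spec An [acq_spec()].
#' @param sd Innovation scale; the stationary series sd is about 3x this.
#' @param seed Integer seed.
#' @return A numeric matrix, total volumes x 6, with standard column names.
#' @export
simulate_motion <- function(spec, sd = 0.05, seed = 1L) {
  set.seed(as.integer(seed))
  n <- spec$n_runs * spec$volumes_per_run
  m <- vapply(seq_len(6), function(j) {
    as.numeric(stats::filter(stats::rnorm(n, 0, sd), 0.95,
                             method = "recursive"))
  }, numeric(n))
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_pitch", "rot_roll", "rot_yaw")
  m
}

#' Simulate a 4D BOLD acquisition
#'
#' Effect-mask voxels receive, on every trial, a neural response shaped by
#' the ground-truth encoding model (placed at the sample onset) with
#' amplitude `gamma0 + gamma1 * strength_code(rating)`, plus a fixed
#' `gamma0`-amplitude response to the test scene; the neural series is
#' convolved with the same canonical double-gamma HRF the analysis uses.
#' All voxels then receive per-run baseline, a random cubic drift, loadings
#' on the simulated motion series, and i.i.d. Gaussian noise.
#'
#' @param schedule,behavior,truth,spec The participant's schedule, behavior,
#'   ground truth and acquisition spec.
#' @param seed Integer seed.
#' @param hrf [hrf_params()] used for the generative convolution.
#' @return List with `bold` (4D array x,y,z,t), `motion` (volumes x 6
#'   matrix), and `affine` (4x4 voxel-to-world matrix).
#' @export
simulate_bold <- function(schedule, behavior, truth = ground_truth(),
                          spec = acq_spec(), seed = 1L, hrf = hrf_params()) {
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(behavior, "behavior_record"))
  mask <- truth$effect_mask
  if (is.null(mask)) mask <- .default_effect_mask(spec$grid_shape)
  if (!all(dim(mask) == spec$grid_shape))
    stop("effect_mask dimensions do not match the acquisition grid")
  set.seed(as.integer(seed))
  n_vox <- prod(spec$grid_shape)
  n_t <- spec$n_runs * spec$volumes_per_run

  # Task signal via the generative design: per-category amplitudes are
  # constant, so the effect series is the interest columns times a fixed
  # amplitude vector (exact recovery under noiseless regression).
  interest <- interest_regressors(schedule, behavior,
                                  model = truth$generative_model,
                                  hrf = hrf, spec = spec)
  cats <- attr(interest, "category")
  epoch <- attr(interest, "epoch")
  amp <- ifelse(epoch == "encoding",
                truth$gamma0 + truth$gamma1 * strength_code(cats),
                truth$gamma0)
  signal <- as.numeric(interest %*% amp)

  motion <- simulate_motion(spec, seed = seed + 1L)

  run_of_row <- rep(seq_len(spec$n_runs), each = spec$volumes_per_run)
  drift <- numeric(n_t)
  if (truth$drift_sd > 0) {
    for (r in seq_len(spec$n_runs)) {
      idx <- run_of_row == r
      u <- seq_len(spec$volumes_per_run)
      u <- (u - mean(u)) / max(abs(u - mean(u)))
      cf <- stats::rnorm(3, 0, truth$drift_sd)
      drift[idx] <- cf[1] * u + cf[2] * u^2 + cf[3] * u^3
    }
  }

  nuis_common <- truth$baseline + drift
  bold <- matrix(stats::rnorm(n_vox * n_t, 0, truth$noise_sd), n_t, n_vox)
  bold <- bold + nuis_common
  if (truth$motion_coupling > 0) {
    loadings <- matrix(stats::rnorm(n_vox * 6, 0, truth$motion_coupling),
                       6, n_vox)
    bold <- bold + motion %*% loadings
  }
  eff <- which(as.logical(mask))
  if (length(eff) > 0) bold[, eff] <- bold[, eff] + signal
  dim(bold) <- NULL
  bold <- array(t(matrix(bold, n_t, n_vox)),
                dim = c(spec$grid_shape, n_t))
  list(bold = bold, motion = motion, affine = .voxel_affine(spec$voxel_size))
}

.voxel_affine <- function(voxel_size) {
  a <- diag(c(rep(voxel_size, 3), 1))
  a
}

#' Simulate one complete participant
#'
#' Convenience wrapper chaining [generate_schedule()], [simulate_behavior()]
#' and [simulate_bold()] with sub-seeds derived from `seed`.
#'
#' @inheritParams simulate_bold
#' @return A `participant` list: `spec`, `truth`, `schedule`, `behavior`,
#'   `bold`, `motion`, `affine`, `seed`.
#' @export
simulate_participant <- function(spec = acq_spec(), truth = ground_truth(),
                                 seed = 1L) {
  seed <- as.integer(seed)
  schedule <- generate_schedule(spec, seed = seed)
  behavior <- simulate_behavior(schedule, truth, seed = seed + 1000L)
  sim <- simulate_bold(schedule, behavior, truth, spec, seed = seed + 2000L)
  structure(list(spec = spec, truth = truth, schedule = schedule,
                 behavior = behavior, bold = sim$bold, motion = sim$motion,
                 affine = sim$affine, seed = seed),
            class = "participant")
}

#' Write a simulated participant to disk
#'
#' Emits the standard file set: `bold.nii` (4D), `events.tsv` (three rows
#' per trial: sample, delay, test), `motion.tsv`, `behavior.tsv`,
#' `lures.tsv`, `ground_truth.json` (parameters + seed), and `rois.nii`
#' (integer labels; the effect mask is label 1).
#'
#' @param participant A [simulate_participant()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(participant, dir) {
  stopifnot(inherits(participant, "participant"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  spec <- participant$spec
  write_nifti(participant$bold, p("bold.nii"),
              voxel_size = spec$voxel_size, tr = spec$tr)

  sch <- participant$schedule
  beh <- participant$behavior$trials
  ev <- data.frame(
    onset = c(sch$sample_onset, sch$delay_onset, sch$test_onset),
    duration = rep(c(.SAMPLE_DUR, .DELAY_DUR, .TEST_DUR), each = nrow(sch)),
    trial_type = rep(c("sample", "delay", "test"), each = nrow(sch)),
    run = rep(sch$run, 3),
    condition = rep(sch$condition, 3),
    dms_correct = rep(beh$dms_correct, 3),
    smt_rating = rep(beh$smt_rating, 3))
  ev <- ev[order(ev$run, ev$onset), ]
  write_tsv(ev, p("events.tsv"))
  write_tsv(as.data.frame(participant$motion), p("motion.tsv"))
  write_tsv(beh, p("behavior.tsv"))
  write_tsv(data.frame(smt_rating = participant$behavior$lure_ratings),
            p("lures.tsv"))

  truth <- participant$truth
  gt <- truth[setdiff(names(truth), "effect_mask")]
  gt$seed <- participant$seed
  jsonlite::write_json(gt, p("ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)

  mask <- truth$effect_mask
  if (is.null(mask)) mask <- .default_effect_mask(spec$grid_shape)
  write_nifti(array(as.integer(mask), dim = spec$grid_shape), p("rois.nii"),
              voxel_size = spec$voxel_size, datatype = "int16")
  invisible(c(bold = p("bold.nii"), events = p("events.tsv"),
              motion = p("motion.tsv"), behavior = p("behavior.tsv"),
              lures = p("lures.tsv"), ground_truth = p("ground_truth.json"),
              rois = p("rois.nii")))
}

#' Simulate group-level coefficient data directly
#'
#' Coefficient-level shortcut for calibration studies that do not need BOLD
#' volumes: per (subject, category) row and voxel, draws a first-level
#' encoding coefficient `y = subject intercept + gamma1 * code + noise`
#' with heterogeneous per-row-and-voxel variances (noise variance drawn
#' uniformly in `var_range`), and weights equal to the true inverse
#' variances.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_voxels Number of voxels.
#' @param gamma1 True memory-strength slope (0 gives a null dataset).
#' @param missing_categories Number of (subject, category) cells dropped,
#'   emulating subjects who never used some ratings (removed from the last
#'   subjects, never below 2 categories each).
#' @param subject_sd SD of the subject intercepts.
#' @param var_range Range of the heterogeneous first-level variances.
#' @param seed Integer seed.
#' @return A `group_data`.
#' @export
simulate_group_coefficients <- function(n_subjects = 28, n_voxels = 50,
                                        gamma1 = 0, missing_categories = 0,
                                        subject_sd = 0.5,
                                        var_range = c(0.05, 0.5),
                                        seed = 1L) {
  stopifnot(n_subjects >= 2, n_voxels >= 1, missing_categories >= 0)
  set.seed(as.integer(seed))
  subj <- rep(sprintf("sub%02d", seq_len(n_subjects)),
              each = length(.RATING_LEVELS))
  cat <- rep(.RATING_LEVELS, n_subjects)
  if (missing_categories > 0) {
    # drop one category from each of the last `missing_categories` subjects
    if (missing_categories > n_subjects)
      stop("cannot drop more categories than subjects")
    drop_sub <- sprintf("sub%02d",
                        n_subjects - seq_len(missing_categories) + 1L)
    drop <- paste(subj, cat) %in% paste(drop_sub, "R")
    subj <- subj[!drop]; cat <- cat[!drop]
  }
  n <- length(subj)
  code <- strength_code(cat)
  alpha <- stats::rnorm(n_subjects, 0, subject_sd)
  names(alpha) <- sprintf("sub%02d", seq_len(n_subjects))
  v <- matrix(stats::runif(n * n_voxels, var_range[1], var_range[2]),
              n, n_voxels)
  y <- alpha[subj] + gamma1 * code +
    matrix(stats::rnorm(n * n_voxels), n, n_voxels) * sqrt(v)
  group_data(subject = subj, code = code, y = y, w = 1 / v, category = cat)
}
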