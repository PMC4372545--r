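test_that("schedule arithmetic: 96 trials, balanced jitter, 288 s runs", {
  sch <- generate_schedule(acq_spec(), seed = 1)
  expect_equal(nrow(sch), 96L)
  expect_equal(length(unique(sch$run)), 8L)
  for (r in 0:7) {
    run <- sch[sch$run == r, ]
    expect_equal(nrow(run), 12L)
    # balanced ITIs: four each of 6/10/14 s
    expect_equal(as.numeric(table(factor(run$iti_after, c(6, 10, 14)))),
                 c(4, 4, 4))
    expect_equal(sum(run$condition == "match"), 6L)
    # phase offsets fixed: delay at +2 s, test at +12 s
    expect_equal(run$delay_onset, run$sample_onset + 2)
    expect_equal(run$test_onset, run$sample_onset + 12)
    # non-overlapping, ordered; run ends (incl. final ITI) at exactly 288 s
    expect_true(all(diff(run$sample_onset) >= 14 + 6))
    expect_equal(run$test_onset[12] + 2 + run$iti_after[12], 288)
  }
  # total volume count at defaults
  spec <- acq_spec()
  expect_equal(spec$n_runs * spec$volumes_per_run, 1152L)
})

test_that("schedule respects spec and seeds", {
  one <- generate_schedule(acq_spec(n_runs = 1), seed = 3)
  expect_true(all(one$run == 0L))
  expect_error(generate_schedule(acq_spec(volumes_per_run = 100)),
               "configuration error")
  expect_identical(generate_schedule(seed = 7), generate_schedule(seed = 7))
  expect_false(identical(generate_schedule(seed = 7)$iti_after,
                         generate_schedule(seed = 8)$iti_after))
})

test_that("behavior follows the ordinal latent-threshold model", {
  # large sample: many runs of the fixed 12-trial structure
  sch <- generate_schedule(acq_spec(n_runs = 100), seed = 2)
  truth <- ground_truth()
  beh <- simulate_behavior(sch, truth, seed = 9, n_lures = 20000)
  # closed-form category probabilities from normal CDF differences
  cuts <- c(-Inf, truth$rating_thresholds, Inf)
  p_old <- diff(pnorm(cuts, mean = truth$latent_mean_old))
  obs <- as.numeric(table(factor(beh$trials$smt_rating,
                                 c("1", "2", "3", "4", "R")))) / 1200
  expect_true(all(abs(obs - p_old) < 4 * sqrt(p_old * (1 - p_old) / 1200)))
  p_lure <- diff(pnorm(cuts, mean = truth$latent_mean_lure))
  obs_l <- as.numeric(table(factor(beh$lure_ratings,
                                   c("1", "2", "3", "4", "R")))) / 20000
  expect_true(all(abs(obs_l - p_lure) <
                    4 * sqrt(p_lure * (1 - p_lure) / 20000)))
  # dms_correct consistent with condition and response
  tr <- beh$trials
  expect_equal(tr$dms_correct,
               (tr$condition == "match") == (tr$dms_response == "yes"))
})

test_that("behavior degenerate cases", {
  sch <- generate_schedule(seed = 1)
  all_one <- simulate_behavior(sch, ground_truth(
    rating_thresholds = c(1e6, 2e6, 3e6, 4e6)), seed = 1)
  expect_true(all(all_one$trials$smt_rating == "1"))
  all_r <- simulate_behavior(sch, ground_truth(
    rating_thresholds = c(-4e6, -3e6, -2e6, -1e6)), seed = 1)
  expect_true(all(all_r$trials$smt_rating == "R"))
  perfect <- simulate_behavior(sch, ground_truth(p_dms = 1), seed = 1)
  expect_true(all(perfect$trials$dms_correct))
  expect_error(ground_truth(rating_thresholds = c(1, 1, 2, 3)))
})

test_that("noiseless BOLD: identical trial responses when amplitudes equal", {
  spec <- tiny_spec(c(4, 4, 2))
  truth <- clean_truth("sample_plus_delay", gamma1 = 0)
  sch <- generate_schedule(spec, seed = 4)
  beh <- simulate_behavior(sch, truth, seed = 4)
  # 20 s kernel: only the immediately preceding trial can bleed into an
  # epoch, so stratifying by the preceding ITI makes identity exact
  sim <- simulate_bold(sch, beh, truth, spec, seed = 4,
                       hrf = hrf_params(kernel_length = 20))
  v <- effect_voxels(spec)[1]
  cc <- arrayInd(v, spec$grid_shape)
  series <- sim$bold[cc[1], cc[2], cc[3], ]
  epochs <- t(vapply(seq_len(nrow(sch)), function(k) {
    start <- sch$sample_onset[k] / spec$tr + sch$run[k] * spec$volumes_per_run
    series[start + 1:7]
  }, numeric(7)))
  prev_iti <- ave(sch$iti_after, sch$run,
                  FUN = function(x) c(NA, x[-length(x)]))
  for (g in unique(stats::na.omit(prev_iti))) {
    grp <- epochs[which(prev_iti == g), , drop = FALSE]
    expect_lt(max(abs(sweep(grp, 2, grp[1, ]))), 1e-10)
  }
})

test_that("noiseless decay simulation recovers generative amplitudes", {
  spec <- tiny_spec(c(4, 4, 2))
  truth <- clean_truth("decay", gamma0 = 1, gamma1 = 0.5)
  sch <- generate_schedule(spec, seed = 5)
  beh <- simulate_behavior(sch, truth, seed = 5)
  sim <- simulate_bold(sch, beh, truth, spec, seed = 5)
  design <- build_design(sch, beh, sim$motion, "decay", spec = spec)
  fit <- fit_voxelwise(sim$bold, design, mask = effect_voxels(spec))
  co <- encoding_coefficients(fit)
  expected <- truth$gamma0 + truth$gamma1 * strength_code(co$category)
  expect_equal(co$beta, expected, tolerance = 1e-8)
})

test_that("seeded simulation is bit-identical", {
  a <- tiny_participant(seed = 11, grid = c(4, 4, 2))
  b <- tiny_participant(seed = 11, grid = c(4, 4, 2))
  expect_identical(a$bold, b$bold)
  expect_identical(a$behavior, b$behavior)
  c <- tiny_participant(seed = 12, grid = c(4, 4, 2))
  expect_false(identical(a$bold, c$bold))
})

test_that("effect mask is validated against the grid", {
  spec <- tiny_spec(c(4, 4, 2))
  truth <- ground_truth(effect_mask = array(TRUE, c(9, 9, 9)))
  sch <- generate_schedule(spec, seed = 1)
  beh <- simulate_behavior(sch, truth, seed = 1)
  expect_error(simulate_bold(sch, beh, truth, spec, seed = 1),
               "effect_mask")
})

test_that("write_dataset emits a complete, exactly round-tripping file set", {
  dir <- withr::local_tempdir()
  p <- tiny_participant(seed = 21, grid = c(4, 4, 2))
  files <- write_dataset(p, dir)
  expect_true(all(file.exists(files)))
  rt <- read_nifti(files[["bold"]])
  expect_identical(as.numeric(rt$data), as.numeric(p$bold))
  expect_equal(rt$voxel_size, rep(1.5, 3))
  ev <- read_tsv_file(files[["events"]])
  expect_equal(nrow(ev), 96L * 3L)
  expect_setequal(unique(ev$trial_type), c("sample", "delay", "test"))
  gt <- jsonlite::read_json(files[["ground_truth"]])
  expect_equal(gt$seed, 21L)
  expect_equal(gt$generative_model, "decay")
  rois <- read_nifti(files[["rois"]])
  expect_equal(sum(rois$data == 1),
               sum(delaymem:::.default_effect_mask(c(4L, 4L, 2L))))
})

test_that("group coefficient simulator has the declared structure", {
  gd <- simulate_group_coefficients(28, 10, gamma1 = 0.3,
                                    missing_categories = 8, seed = 2)
  expect_equal(nrow(gd$y), 28 * 5 - 8)
  expect_equal(ncol(gd$y), 10)
  expect_true(all(gd$w > 0))
  # slope recovered on average across many voxels at high information
  gf <- fit_wls(gd)
  expect_lt(abs(mean(gf$slope) - 0.3), 0.1)
})
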