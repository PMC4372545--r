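test_that("sphere membership by center-to-center distance", {
  # brute-force lattice oracle, computed independently over a superset box
  oracle_count <- function(radius, voxel) {
    r <- ceiling(radius / voxel)
    g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
    sum((g$x^2 + g$y^2 + g$z^2) * voxel^2 <= radius^2)
  }
  big <- c(30L, 30L, 30L)
  s <- sphere_voxels(c(15, 15, 15), 5, big, voxel_size = 1.5)
  expect_equal(nrow(s), oracle_count(5, 1.5))   # = 171
  expect_equal(nrow(s), 171L)
  # radius below voxel size: the center voxel only
  s1 <- sphere_voxels(c(15, 15, 15), 1, big, voxel_size = 1.5)
  expect_equal(nrow(s1), 1L)
  expect_equal(as.numeric(s1[1, ]), c(15, 15, 15))
  # clipped at grid edges
  edge <- sphere_voxels(c(0, 0, 0), 5, big, voxel_size = 1.5)
  expect_lt(nrow(edge), 171L)
  expect_true(all(edge >= 0))
  expect_error(sphere_voxels(c(2, 2, 2), 5, c(1, 1, 1), 100), "no voxels")
})

test_that("sphere extraction averages member voxels", {
  bold <- array(7, c(6, 6, 4, 10))
  s <- extract_sphere_signal(bold, c(3, 3, 2), 3, voxel_size = 1.5)
  expect_equal(s, rep(7, 10))               # uniform volume -> constant
  # put a ramp in a face neighbor (0-based (4,3,2)) of the center (3,3,2)
  bold[5, 4, 3, ] <- 1:10
  s1 <- extract_sphere_signal(bold, c(3, 3, 2), 1, voxel_size = 1.5)
  expect_equal(s1, rep(7, 10))              # radius < voxel: center only
  s2 <- extract_sphere_signal(bold, c(3, 3, 2), 1.6, voxel_size = 1.5)
  expect_false(all(s2 == 7))                # neighbor with ramp included
  expect_equal(s2, (7 * 6 + 1:10) / 7)      # mean over the 7-voxel sphere
})

test_that("trial averaging z-scores, epochs, and pools correctly", {
  spec <- tiny_spec(c(4, 4, 2))
  sch <- generate_schedule(spec, seed = 3)
  beh <- simulate_behavior(sch, ground_truth(), seed = 3)
  series <- rnorm(1152, mean = 50, sd = 4)
  tc <- quiet(trial_average(list(series), list(sch), list(beh)))
  expect_s3_class(tc, "trial_timecourse")
  expect_equal(sort(unique(tc$time)), seq(-4, 24, by = 2))
  # trials pooled per category; trials whose -4..+24 s window leaves the
  # run (first/last trials of a run) are dropped before pooling
  in_window <- sch$sample_onset >= 4 & sch$sample_onset <= 286 - 24
  expect_equal(unique(tc$n_trials[tc$category == "4"]),
               sum(beh$trials$smt_rating == "4" & in_window))
  # z-scoring: constant series maps to all-zero means
  tc0 <- quiet(trial_average(list(rep(5, 1152)), list(sch), list(beh)))
  expect_true(all(tc0$mean == 0))
  # single-trial categories report missing bands
  one_cat <- beh
  one_cat$trials$smt_rating <- c("R", rep("4", 95))
  tc1 <- quiet(trial_average(list(series), list(sch), list(one_cat)))
  expect_true(all(is.na(tc1$se[tc1$category == "R"])))
  expect_false(anyNA(tc1$se[tc1$category == "4"]))
})

test_that("epochs that leave the run are dropped with a message", {
  spec <- tiny_spec(c(4, 4, 2))
  sch <- generate_schedule(spec, seed = 3)
  beh <- simulate_behavior(sch, ground_truth(), seed = 3)
  expect_message(trial_average(list(rnorm(1152)), list(sch), list(beh),
                               window = c(-20, 24)),
                 "dropped")
})

test_that("posterior predictive replicates: fixed point and shape", {
  set.seed(11)
  X <- cbind(1, rnorm(30))
  colnames(X) <- c("a", "b")
  y <- X %*% c(1, 2) + rnorm(30, 0, 0.5)
  fit <- fit_voxelwise(matrix(y, ncol = 1), manual_design(X))
  reps <- posterior_predictive_simulate(fit, n_sim = 20, seed = 2)
  expect_equal(dim(reps), c(30L, 20L))
  # sigma2 = 0 and fixed draws reproduce the fitted values exactly
  y0 <- X %*% c(1, 2)
  fit0 <- fit_voxelwise(matrix(y0, ncol = 1), manual_design(X))
  reps0 <- posterior_predictive_simulate(fit0, n_sim = 3, seed = 2,
                                         fixed = TRUE)
  expect_equal(reps0, matrix(rep(y0, 3), 30, 3), tolerance = 1e-8)
  # multi-voxel fits are refused
  fit2 <- fit_voxelwise(cbind(y, y), manual_design(X))
  expect_error(posterior_predictive_simulate(fit2), "single fitted series")
})

test_that("discrepancy scoring flags envelope exits and scores misfit", {
  tc <- function(m) {
    out <- data.frame(category = rep(c("4", "R"), each = 3),
                      time = rep(c(0, 2, 4), 2), mean = m,
                      se = 0.1, n_trials = 10)
    class(out) <- c("trial_timecourse", "data.frame")
    out
  }
  obs <- tc(rep(0, 6))
  reps <- lapply(c(-0.1, -0.05, 0.05, 0.1), function(d) tc(rep(d, 6)))
  r <- ppc_discrepancy(obs, reps)
  expect_equal(r$misfit, 0)                  # observed == replicate mean
  expect_equal(r$n_flagged, 0L)
  shifted <- tc(rep(10, 6))
  r2 <- ppc_discrepancy(shifted, reps)
  expect_equal(r2$n_flagged, 6L)             # far outside the envelope
  expect_gt(r2$misfit, 100)
  expect_error(ppc_discrepancy(tc(rep(0, 6))[1:5, ], reps), "match")
})

test_that("PPC under the true model keeps the observed curve inside", {
  p <- tiny_participant("decay", seed = 31, grid = c(4, 4, 2))
  cmp <- quiet(compare_models(p, models = "decay", n_sim = 20, seed = 3))
  ppc <- attr(cmp, "ppc")[[1]]
  # min-max envelope over 20 replicates: expect few exits under truth
  expect_lte(ppc$n_flagged / nrow(ppc$table), 0.15)
})

test_that("model comparison ranks the generative model first", {
  for (g in c("sample_plus_delay", "decay")) {
    p <- tiny_participant(g, seed = 17, grid = c(4, 4, 2))
    cmp <- quiet(compare_models(p, n_sim = 20, seed = 5))
    expect_equal(cmp$model[cmp$rank == 1], g)
  }
  p <- tiny_participant("decay", seed = 18, grid = c(4, 4, 2))
  single <- quiet(compare_models(p, models = "decay", n_sim = 5, seed = 1))
  expect_equal(nrow(single), 1L)
  expect_equal(single$rank, 1L)
})
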