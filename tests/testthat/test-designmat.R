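test_that("double-gamma HRF has canonical shape", {
  h <- double_gamma_hrf(hrf_params(), tr = 2, oversampling = 16)
  t_grid <- (seq_along(h) - 1) * attr(h, "dt")
  expect_equal(max(h), 1)                       # peak-normalized
  peak_t <- t_grid[which.max(h)]
  expect_gte(peak_t, 4); expect_lte(peak_t, 6)  # mode of the response gamma
  expect_lt(min(h), 0)                          # undershoot present
  # undershoot_ratio -> Inf: single gamma, everywhere nonnegative
  h1 <- double_gamma_hrf(hrf_params(undershoot_ratio = Inf), tr = 2)
  expect_true(all(h1 >= 0))
  expect_error(hrf_params(peak_delay = -1), "positive")
})

test_that("encoding kernels match their stated forms", {
  expect_equal(encoding_kernel("decay", 1, 5),
               c(1, 1 / 4, 1 / 9, 1 / 16, 1 / 25, 1 / 36))
  expect_equal(encoding_kernel("sample_only", 1, 5), 1)
  expect_equal(encoding_kernel("sample_plus_delay", 1, 5), rep(1, 6))
  # properties: decay strictly decreasing, all kernels nonnegative
  for (m in c("sample_only", "sample_plus_delay", "decay"))
    expect_true(all(encoding_kernel(m) >= 0))
  expect_true(all(diff(encoding_kernel("decay")) < 0))
  expect_error(encoding_kernel("decay", 0, 5), "positive")
})

test_that("interest regressors: one encoding + one test column per used category", {
  spec <- tiny_spec()
  sch <- generate_schedule(spec, seed = 1)
  beh <- simulate_behavior(sch, ground_truth(), seed = 2)
  stopifnot(length(unique(beh$trials$smt_rating)) == 5)  # fixture sanity
  X <- interest_regressors(sch, beh, "decay", spec = spec)
  expect_equal(ncol(X), 10L)
  expect_equal(nrow(X), 1152L)
  expect_equal(sum(attr(X, "epoch") == "encoding"), 5L)

  # a subject who used only 3 categories gets 6 columns
  beh3 <- beh
  beh3$trials$smt_rating <- c("1", "3", "R")[1 + seq_len(96) %% 3]
  expect_equal(ncol(interest_regressors(sch, beh3, "decay", spec = spec)),
               6L)

  # empty schedule yields zero columns
  empty <- sch[sch$run < 0, ]
  attr(empty, "spec") <- spec
  class(empty) <- class(sch)
  beh0 <- list(trials = beh$trials[0, ])
  expect_equal(ncol(interest_regressors(empty, beh0, "decay", spec = spec)),
               0L)
})

test_that("convolution is linear in trials", {
  spec <- acq_spec(n_runs = 1)
  sch <- generate_schedule(spec, seed = 3)
  one_cat <- function(rows) {
    s <- sch[rows, ]; attr(s, "spec") <- spec; class(s) <- class(sch)
    b <- list(trials = data.frame(smt_rating = rep("4", length(rows))))
    interest_regressors(s, b, "decay", spec = spec)[, "enc_4"]
  }
  expect_equal(one_cat(c(1, 5)), one_cat(1) + one_cat(5), tolerance = 1e-12)
})

test_that("nuisance block: 8 + 48 + 24 columns with zero-sum drift", {
  spec <- acq_spec()
  motion <- simulate_motion(spec, seed = 1)
  N <- nuisance_regressors(motion, spec)
  expect_equal(ncol(N), 8L + 48L + 24L)
  run_of_row <- rep(0:7, each = 144)
  for (r in 0:7) for (p in 1:3)
    expect_equal(sum(N[run_of_row == r, sprintf("drift%d_run%d", p, r)]), 0,
                 tolerance = 1e-9)
  # motion channels are copied into their own run only
  expect_true(all(N[run_of_row != 3, "trans_x_run3"] == 0))
  expect_equal(N[run_of_row == 3, "trans_x_run3"],
               motion[run_of_row == 3, "trans_x"])
  expect_error(nuisance_regressors(motion[1:100, ], spec), "must be")
})

test_that("zero motion is flagged degenerate and dropped at assembly", {
  spec <- acq_spec(n_runs = 1)
  N <- nuisance_regressors(matrix(0, 144, 6), spec)
  expect_length(attr(N, "degenerate"), 6L)
  sch <- generate_schedule(spec, seed = 1)
  beh <- simulate_behavior(sch, ground_truth(), seed = 1)
  X <- interest_regressors(sch, beh, "decay", spec = spec)
  expect_message(d <- assemble_design(X, N, spec), "degenerate")
  expect_false(any(grepl("trans|rot", d$column_names)))
})

test_that("assembly checks rank and reports totals", {
  spec <- tiny_spec()
  sch <- generate_schedule(spec, seed = 1)
  beh <- simulate_behavior(sch, ground_truth(), seed = 2)
  d <- build_design(sch, beh, simulate_motion(spec, seed = 3), "decay",
                    spec = spec)
  expect_equal(dim(d$X), c(1152L, 90L))
  expect_length(d$interest_columns, 10L)
  # duplicating a column must raise and name the collinear column
  X <- interest_regressors(sch, beh, "decay", spec = spec)
  X2 <- cbind(X, dup = X[, 1])
  N <- nuisance_regressors(simulate_motion(spec, seed = 3), spec)
  expect_error(assemble_design(X2, N, spec), "rank deficient")
})

test_that("nuisance-only fit absorbs pure drift exactly", {
  spec <- acq_spec(n_runs = 2)
  motion <- simulate_motion(spec, seed = 5)
  N <- nuisance_regressors(motion, spec)
  run_of_row <- rep(0:1, each = 144)
  u <- seq_len(144) - 72.5
  y <- 3 + 0.01 * rep(u, 2) - 2e-5 * rep(u, 2)^3
  fit <- lm.fit(N, y)
  expect_lt(max(abs(fit$residuals)), 1e-9)
})
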