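#' Canonical double-gamma HRF parameters
#'
#' The widely used canonical parameterization: response gamma peaking ~5 s,
#' undershoot gamma peaking ~15 s scaled by 1/ratio, 32 s support.
#'
#' @param peak_delay Response peak delay (s); gamma shape = delay/dispersion.
#' @param undershoot_delay Undershoot delay (s).
#' @param peak_dispersion,undershoot_dispersion Gamma scale parameters (s).
#' @param undershoot_ratio Response:undershoot amplitude ratio.
#' @param kernel_length Kernel truncation (s).
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       undershoot_ratio = 6, kernel_length = 32) {
  vals <- c(peak_delay, undershoot_delay, peak_dispersion,
            undershoot_dispersion, undershoot_ratio, kernel_length)
  if (any(!is.finite(vals) & !is.infinite(vals)) || any(vals <= 0))
    stop("hrf_params: all parameters must be positive")
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 undershoot_ratio = undershoot_ratio,
                 kernel_length = kernel_length),
            class = "hrf_params")
}

#' Sample the canonical double-gamma HRF
#'
#' Difference of two gamma densities (undershoot scaled by
#' `1/undershoot_ratio`), sampled on a grid of `tr/oversampling` s steps
#' from 0 to `kernel_length`, then peak-normalized to 1.
#'
#' @param params An [hrf_params()].
#' @param tr Repetition time (s).
#' @param oversampling Integer sub-TR sampling factor (>= 1).
#' @return Numeric kernel vector with attribute `dt` (grid step, s).
#' @export
double_gamma_hrf <- function(params = hrf_params(), tr = 2,
                             oversampling = 16L) {
  stopifnot(inherits(params, "hrf_params"), tr > 0, oversampling >= 1)
  dt <- tr / oversampling
  t <- seq(0, params$kernel_length, by = dt)
  peak <- stats::dgamma(t, shape = params$peak_delay / params$peak_dispersion,
                        scale = params$peak_dispersion)
  under <- stats::dgamma(t, shape = params$undershoot_delay /
                           params$undershoot_dispersion,
                         scale = params$undershoot_dispersion)
  h <- peak - under / params$undershoot_ratio
  h <- h / max(h)
  attr(h, "dt") <- dt
  h
}

#' Pre-convolution encoding-model weights
#'
#' Weights placed on the TR grid starting at the sample onset, one value per
#' time point of the modeled encoding epoch:
#' `sample_only` covers the sample TR only (`[1]`); `sample_plus_delay` is a
#' constant boxcar over sample + delay; `decay` gives time point n weight
#' n^-2, expressing persistent activity that wanes over the delay.
#'
#' @param model `"sample_only"`, `"sample_plus_delay"`, or `"decay"`.
#' @param n_sample_tp Sample-phase time points (1 at TR = 2 s).
#' @param n_delay_tp Delay-phase time points (5 at TR = 2 s).
#' @return Numeric weight vector (length 1 or `n_sample_tp + n_delay_tp`).
#' @export
encoding_kernel <- function(model = c("sample_only", "sample_plus_delay",
                                      "decay"),
                            n_sample_tp = 1L, n_delay_tp = 5L) {
  model <- match.arg(model)
  if (n_sample_tp < 1 || n_delay_tp < 1)
    stop("encoding_kernel: time point counts must be positive")
  n <- n_sample_tp + n_delay_tp
  switch(model,
         sample_only = rep(1, n_sample_tp),
         sample_plus_delay = rep(1, n),
         decay = seq_len(n)^-2)
}

.ENCODING_MODELS <- c("sample_only", "sample_plus_delay", "decay")

# Build one HRF-convolved regressor column on the TR grid. Events are
# weighted boxcars on an oversampled grid, convolved per run (no bleed
# across run boundaries since runs are modeled independently but share the
# concatenated time axis), then decimated back to the TR grid.
.convolved_column <- function(onsets, durations, weights, runs, spec, hrf,
                              oversampling = 16L) {
  n_run_tr <- spec$volumes_per_run
  os <- as.integer(oversampling)
  dt <- spec$tr / os
  kern <- double_gamma_hrf(hrf, tr = spec$tr, oversampling = os)
  col <- numeric(n_run_tr * spec$n_runs)
  for (r in sort(unique(runs))) {
    sel <- runs == r
    fine <- numeric(n_run_tr * os)
    for (i in which(sel)) {
      j0 <- round(onsets[i] / dt)
      j1 <- round((onsets[i] + durations[i]) / dt) - 1L
      if (j0 < 0 || j1 >= length(fine))
        stop("regressor onset outside run bounds: onset ", onsets[i],
             " s in run ", r)
      fine[(j0:j1) + 1L] <- fine[(j0:j1) + 1L] + weights[i]
    }
    conv <- stats::convolve(fine, rev(kern), type = "open")[seq_along(fine)]
    idx <- r * n_run_tr + seq_len(n_run_tr)
    col[idx] <- conv[seq(1L, by = os, length.out = n_run_tr)]
  }
  col
}

#' Regressors of interest for an encoding model
#'
#' One encoding regressor and one test regressor per confidence-rating
#' category the participant actually used: the encoding regressor places the
#' model's pre-convolution weights at each sample onset (each weight spans
#' one TR); the test regressor is a 2 s boxcar at the test onset. Trials are
#' pooled over match/non-match and over DMS correctness; all columns are
#' convolved with the canonical double-gamma HRF. A participant using all
#' five categories therefore contributes 10 columns.
#'
#' @param schedule A [generate_schedule()] result.
#' @param behavior A [simulate_behavior()] result (or compatible list with a
#'   `trials` data.frame holding `smt_rating` per scheduled trial).
#' @param model Encoding model name.
#' @param hrf [hrf_params()].
#' @param spec [acq_spec()].
#' @param oversampling Sub-TR grid factor for the convolution.
#' @return Numeric matrix (total volumes x columns) with named columns
#'   (`enc_<cat>`, `test_<cat>`) and attributes `category` and `epoch`.
#' @export
interest_regressors <- function(schedule, behavior,
                                model = c("sample_only", "sample_plus_delay",
                                          "decay"),
                                hrf = hrf_params(), spec = acq_spec(),
                                oversampling = 16L) {
  model <- match.arg(model)
  trials <- behavior$trials
  stopifnot(nrow(trials) == nrow(schedule))
  if (anyNA(trials$smt_rating))
    stop("every trial needs an smt_rating to be categorized")
  n_sample_tp <- as.integer(round(.SAMPLE_DUR / spec$tr))
  n_delay_tp <- as.integer(round(.DELAY_DUR / spec$tr))
  w <- encoding_kernel(model, max(n_sample_tp, 1L), max(n_delay_tp, 1L))
  used <- .RATING_LEVELS[.RATING_LEVELS %in% unique(trials$smt_rating)]
  cols <- list()
  meta_cat <- character(0)
  meta_epoch <- character(0)
  for (cat in used) {
    sel <- trials$smt_rating == cat
    # encoding epoch: one weighted TR-boxcar per kernel element per trial
    onsets <- rep(schedule$sample_onset[sel], each = length(w)) +
      spec$tr * (seq_along(w) - 1L)
    weights <- rep(w, sum(sel))
    runs <- rep(schedule$run[sel], each = length(w))
    cols[[paste0("enc_", cat)]] <- .convolved_column(
      onsets, rep(spec$tr, length(onsets)), weights, runs, spec, hrf,
      oversampling)
    meta_cat <- c(meta_cat, cat); meta_epoch <- c(meta_epoch, "encoding")
    cols[[paste0("test_", cat)]] <- .convolved_column(
      schedule$test_onset[sel], rep(.TEST_DUR, sum(sel)),
      rep(1, sum(sel)), schedule$run[sel], spec, hrf, oversampling)
    meta_cat <- c(meta_cat, cat); meta_epoch <- c(meta_epoch, "test")
  }
  X <- if (length(cols) == 0) {
    matrix(numeric(0), nrow = spec$volumes_per_run * spec$n_runs, ncol = 0)
  } else {
    do.call(cbind, cols)
  }
  colnames(X) <- names(cols)
  attr(X, "category") <- meta_cat
  attr(X, "epoch") <- meta_epoch
  X
}

#' Nuisance regressors: run baselines, motion-by-run, cubic drift-by-run
#'
#' The intercept is split into one indicator per run; each of the six motion
#' channels enters as per-run copies (cell-means coding of the motion-by-run
#' interaction); and scanner drift is a cubic polynomial per run built from
#' a centered unit-step sequence, with each power re-centered within run so
#' every drift column sums to zero.
#'
#' @param motion Numeric matrix, total volumes x 6.
#' @param spec [acq_spec()].
#' @return Matrix with named columns and attribute `degenerate` naming
#'   all-zero columns (e.g. motion channels that never move), which
#'   [assemble_design()] drops.
#' @export
nuisance_regressors <- function(motion, spec = acq_spec()) {
  n_t <- spec$volumes_per_run * spec$n_runs
  motion <- as.matrix(motion)
  if (nrow(motion) != n_t || ncol(motion) != 6)
    stop(sprintf("motion table must be %d x 6, got %d x %d",
                 n_t, nrow(motion), ncol(motion)))
  run_of_row <- rep(seq_len(spec$n_runs) - 1L, each = spec$volumes_per_run)
  mot_names <- colnames(motion)
  if (is.null(mot_names)) mot_names <- paste0("motion", 1:6)

  cols <- list()
  for (r in seq_len(spec$n_runs) - 1L)
    cols[[sprintf("run_%d", r)]] <- as.numeric(run_of_row == r)
  for (j in 1:6) for (r in seq_len(spec$n_runs) - 1L) {
    v <- numeric(n_t); sel <- run_of_row == r
    v[sel] <- motion[sel, j]
    cols[[sprintf("%s_run%d", mot_names[j], r)]] <- v
  }
  u <- seq_len(spec$volumes_per_run)
  u <- u - mean(u)                      # -71.5 ... 71.5 at 144 volumes
  for (p in 1:3) for (r in seq_len(spec$n_runs) - 1L) {
    v <- numeric(n_t); sel <- run_of_row == r
    v[sel] <- u^p - mean(u^p)
    cols[[sprintf("drift%d_run%d", p, r)]] <- v
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  degen <- colnames(X)[apply(X, 2, function(v) all(v == 0))]
  attr(X, "degenerate") <- degen
  X
}

#' Assemble and validate a first-level design matrix
#'
#' Concatenates interest and nuisance blocks, drops nuisance columns flagged
#' degenerate, checks full column rank, and records the partition plus the
#' run index of every row. No inter-trial-interval regressor exists; that
#' task component is absorbed by the per-run intercepts.
#'
#' @param interest Matrix from [interest_regressors()].
#' @param nuisance Matrix from [nuisance_regressors()].
#' @param spec [acq_spec()].
#' @return A `design_matrix`: list with `X`, `column_names`,
#'   `interest_columns`, `category`/`epoch` per interest column, and
#'   `run_of_row`.
#' @export
assemble_design <- function(interest, nuisance, spec = acq_spec()) {
  if (nrow(interest) != nrow(nuisance))
    stop("interest and nuisance blocks have different row counts")
  degen <- attr(nuisance, "degenerate")
  if (length(degen) > 0) {
    message("dropping degenerate nuisance column(s): ",
            paste(degen, collapse = ", "))
    nuisance <- nuisance[, setdiff(colnames(nuisance), degen), drop = FALSE]
  }
  X <- cbind(interest, nuisance)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  structure(list(X = X,
                 column_names = colnames(X),
                 interest_columns = colnames(interest),
                 category = attr(interest, "category"),
                 epoch = attr(interest, "epoch"),
                 run_of_row = rep(seq_len(spec$n_runs) - 1L,
                                  each = spec$volumes_per_run)),
            class = "design_matrix")
}

#' Build the full design for one participant in one call
#'
#' @inheritParams interest_regressors
#' @param motion Motion matrix (total volumes x 6).
#' @return A `design_matrix`.
#' @export
build_design <- function(schedule, behavior, motion,
                         model = c("sample_only", "sample_plus_delay",
                                   "decay"),
                         hrf = hrf_params(), spec = acq_spec()) {
  model <- match.arg(model)
  interest <- interest_regressors(schedule, behavior, model, hrf, spec)
  nuisance <- nuisance_regressors(motion, spec)
  assemble_design(interest, nuisance, spec)
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix: %d rows x %d columns (%d interest, %d nuisance)\n",
              nrow(x$X), ncol(x$X), length(x$interest_columns),
              ncol(x$X) - length(x$interest_columns)))
  invisible(x)
}
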