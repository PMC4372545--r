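# Shared fixtures: everything is generated in code at test time.

# Desk-scale acquisition used throughout the suite (full temporal structure,
# tiny spatial grid so whole-brain fits take milliseconds).
tiny_spec <- function(grid = c(6L, 6L, 4L)) acq_spec(grid_shape = grid)

# Clean ground truth: no drift/motion/noise unless asked for.
clean_truth <- function(model = "decay", ...) {
  ground_truth(model, noise_sd = 0, drift_sd = 0, motion_coupling = 0, ...)
}

quiet <- function(expr) suppressMessages(expr)

# A minimal hand-built design_matrix for unit tests that bypass assembly.
manual_design <- function(X, interest = colnames(X), category = NULL,
                          epoch = NULL, runs = NULL) {
  structure(list(X = X, column_names = colnames(X),
                 interest_columns = interest, category = category,
                 epoch = epoch,
                 run_of_row = if (is.null(runs)) rep(0L, nrow(X)) else runs),
            class = "design_matrix")
}

# Brute-force (weighted) least-squares oracle via explicit normal equations.
wls_oracle <- function(X, y, w = rep(1, length(y))) {
  XtW <- t(X * w)
  A <- solve(XtW %*% X)
  beta <- A %*% (XtW %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(w * res^2) / df
  list(beta = unname(drop(beta)), se = unname(sqrt(s2 * diag(A))),
       df = df, sigma2 = s2)
}

# Small simulated participant with a central effect block.
tiny_participant <- function(model = "decay", seed = 1L, grid = c(6L, 6L, 4L),
                             ...) {
  simulate_participant(tiny_spec(grid), ground_truth(model, ...),
                       seed = seed)
}

effect_voxels <- function(spec) {
  which(as.logical(delaymem:::.default_effect_mask(spec$grid_shape)))
}
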