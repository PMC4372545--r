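#' Voxel-wise least-squares fit of a BOLD time series
#'
#' Plain (unwhitened) OLS, solved through a single QR decomposition of the
#' shared design matrix so the whole-brain fit reduces to one matrix
#' product. Per voxel: `beta = argmin ||y - X b||^2`, residual variance
#' `sigma2 = RSS / df` with `df = rows - rank(X)`, and coefficient variances
#' `sigma2 * diag((X'X)^-1)`.
#'
#' @param bold 4D array (x, y, z, t) or a time x voxel matrix.
#' @param design A `design_matrix` from [assemble_design()].
#' @param mask Optional logical 3D array (or voxel index vector) selecting
#'   voxels to fit; default all.
#' @return A `first_level_fit`: `beta` (p x V), `beta_var` (p x V), `sigma2`
#'   (V), `df`, `xtx_inv`, `design`, `voxels` (flat indices),
#'   `grid_shape` (when 4D input).
#' @export
fit_voxelwise <- function(bold, design, mask = NULL) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$X
  grid_shape <- NULL
  if (is.array(bold) && length(dim(bold)) == 4) {
    grid_shape <- dim(bold)[1:3]
    n_t <- dim(bold)[4]
    Y <- matrix(bold, prod(grid_shape), n_t)
    voxels <- seq_len(prod(grid_shape))
    if (!is.null(mask)) {
      voxels <- if (is.logical(mask)) which(as.logical(mask)) else
        as.integer(mask)
      if (any(voxels < 1 | voxels > prod(grid_shape)))
        stop("mask indexes voxels outside the grid")
    }
    Y <- t(Y[voxels, , drop = FALSE])
  } else {
    Y <- as.matrix(bold)
    voxels <- seq_len(ncol(Y))
  }
  if (nrow(Y) != nrow(X))
    stop(sprintf("BOLD has %d volumes but the design has %d rows",
                 nrow(Y), nrow(X)))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    stop("design matrix is rank deficient")    # caught earlier at assembly
  beta <- qr.coef(qr_x, Y)
  res <- Y - X %*% beta
  df <- nrow(X) - qr_x$rank
  rss <- colSums(res^2)
  sigma2 <- rss / df
  R <- qr.R(qr_x)
  xtx_inv <- chol2inv(R)
  # chol2inv of qr.R inverts X'X in pivoted order; map back
  piv <- qr_x$pivot
  xtx_inv[piv, piv] <- xtx_inv
  beta_var <- diag(xtx_inv) %o% sigma2
  rownames(beta) <- rownames(beta_var) <- colnames(X)
  structure(list(beta = beta, beta_var = beta_var, sigma2 = sigma2, df = df,
                 xtx_inv = xtx_inv, design = design, voxels = voxels,
                 grid_shape = grid_shape),
            class = "first_level_fit")
}

#' @export
print.first_level_fit <- function(x, ...) {
  cat(sprintf("First-level fit: %d voxel(s), %d coefficient(s), df = %d\n",
              ncol(x$beta), nrow(x$beta), x$df))
  invisible(x)
}

#' Encoding coefficients per response category
#'
#' Extracts the encoding-epoch (sample-and-onward) regressor coefficient and
#' its variance for every confidence category the participant used - the
#' per-subject data points the group model consumes. Categories without a
#' regressor are simply absent.
#'
#' @param fit A [fit_voxelwise()] result.
#' @param categories Optional subset of category names to extract; all
#'   requested names must exist in the fit.
#' @return data.frame with columns `voxel`, `category`, `beta`, `beta_var`.
#' @export
encoding_coefficients <- function(fit, categories = NULL) {
  stopifnot(inherits(fit, "first_level_fit"))
  des <- fit$design
  enc_idx <- which(des$epoch == "encoding")
  enc_names <- des$interest_columns[enc_idx]
  enc_cats <- des$category[enc_idx]
  if (!is.null(categories)) {
    unknown <- setdiff(categories, enc_cats)
    if (length(unknown) > 0)
      stop("unknown response category: ", paste(unknown, collapse = ", "))
    keep <- enc_cats %in% categories
    enc_names <- enc_names[keep]; enc_cats <- enc_cats[keep]
  }
  v <- length(fit$voxels)
  data.frame(
    voxel = rep(fit$voxels, times = length(enc_names)),
    category = rep(enc_cats, each = v),
    beta = as.numeric(t(fit$beta[enc_names, , drop = FALSE])),
    beta_var = as.numeric(t(fit$beta_var[enc_names, , drop = FALSE])),
    stringsAsFactors = FALSE)
}
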