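#' Linear memory-strength code
#'
#' Maps the five-point recognition confidence scale onto a linear strength
#' axis: "1" (high-confidence new) = -2 through "R" (recollected) = +2, unit
#' steps in between. The group slope is then interpretable as BOLD signal
#' change per point of memory strength.
#'
#' @param rating Character (or factor) vector of ratings in
#'   `{"1","2","3","4","R"}`.
#' @return Integer vector of codes in -2..2.
#' @export
strength_code <- function(rating) {
  map <- c("1" = -2L, "2" = -1L, "3" = 0L, "4" = 1L, "R" = 2L)
  rating <- as.character(rating)
  unknown <- setdiff(unique(rating), names(map))
  if (length(unknown) > 0)
    stop("unknown rating(s): ", paste(unknown, collapse = ", "))
  unname(map[rating])
}

#' Stack per-subject encoding coefficients for the group model
#'
#' Builds the group-level data: one row per (subject, used category) with,
#' per voxel, the first-level encoding coefficient as response and the
#' inverse first-level coefficient variance as weight. Subjects missing
#' categories simply contribute fewer rows; the residual degrees of freedom
#' shrink accordingly. Weights are clipped at `weight_max` so noiseless
#' synthetic data cannot produce infinite weights.
#'
#' @param coef_tables Named list (one element per subject) of
#'   [encoding_coefficients()] data.frames. All subjects must cover the same
#'   voxel set.
#' @param weight_max Upper clip for the inverse-variance weights.
#' @return A `group_data`: `subject` (factor), `category`, `code`, `y`
#'   (rows x voxels), `w` (rows x voxels), `voxels`.
#' @export
stack_group_data <- function(coef_tables, weight_max = 1e8) {
  stopifnot(is.list(coef_tables), length(coef_tables) >= 2)
  if (is.null(names(coef_tables)))
    names(coef_tables) <- sprintf("sub%02d", seq_along(coef_tables))
  voxels <- sort(unique(coef_tables[[1]]$voxel))
  rows <- list(); ys <- list(); ws <- list()
  for (s in names(coef_tables)) {
    tab <- coef_tables[[s]]
    if (!setequal(unique(tab$voxel), voxels))
      stop("subject ", s, " covers a different voxel set")
    cats <- sort(unique(tab$category))
    if (length(cats) < 2)
      stop("subject ", s, " used fewer than 2 response categories")
    tab <- tab[order(match(tab$category, .RATING_LEVELS),
                     match(tab$voxel, voxels)), ]
    for (cat in .RATING_LEVELS[.RATING_LEVELS %in% cats]) {
      sel <- tab$category == cat
      rows[[length(rows) + 1L]] <- data.frame(subject = s, category = cat,
                                              stringsAsFactors = FALSE)
      ys[[length(ys) + 1L]] <- tab$beta[sel]
      ws[[length(ws) + 1L]] <- pmin(1 / tab$beta_var[sel], weight_max)
    }
  }
  meta <- do.call(rbind, rows)
  structure(list(subject = factor(meta$subject),
                 category = meta$category,
                 code = as.numeric(strength_code(meta$category)),
                 y = do.call(rbind, ys),
                 w = do.call(rbind, ws),
                 voxels = voxels),
            class = "group_data")
}

#' Construct group data directly from components
#'
#' Lower-level constructor used by simulations and tests: supply the row
#' structure and the per-voxel response/weight matrices yourself.
#'
#' @param subject Factor (or coercible) of subject labels, one per row.
#' @param code Numeric strength code per row.
#' @param y,w Matrices rows x voxels of responses and weights.
#' @param category Optional category labels per row.
#' @return A `group_data`.
#' @export
group_data <- function(subject, code, y, w, category = NULL) {
  y <- as.matrix(y); w <- as.matrix(w)
  stopifnot(length(subject) == nrow(y), length(code) == nrow(y),
            all(dim(y) == dim(w)), all(w > 0))
  structure(list(subject = factor(subject), category = category,
                 code = as.numeric(code), y = y, w = w,
                 voxels = seq_len(ncol(y))),
            class = "group_data")
}

# Weighted within-subject centering: removes the per-voxel weighted subject
# means of v (a vector over rows, or rows x voxel matrix) under weights w.
# This is the Frisch-Waugh step that absorbs the subject intercept factors.
.wls_center <- function(v, w, subject_mat) {
  if (is.null(dim(v))) v <- matrix(v, nrow(w), ncol(w))
  num <- crossprod(subject_mat, w * v)
  den <- crossprod(subject_mat, w)
  v - subject_mat %*% (num / den)
}

#' Weighted least squares group fit of the memory-strength slope
#'
#' Fits, per voxel, `y = subject intercepts + slope * code` by weighted
#' least squares with the stacked inverse-variance weights. The subject
#' factors are absorbed by weighted within-subject centering
#' (Frisch-Waugh), which gives results identical to solving the full
#' weighted normal equations. By default the slope variance is rescaled by
#' the weighted residual variance (`RSS_w / df`); with `rescale = FALSE` the
#' weights are taken as known inverse variances.
#'
#' @param gd A `group_data`.
#' @param rescale Rescale the slope variance by the weighted residual mean
#'   square (default) or treat weights as known variances.
#' @return A `group_fit`: per-voxel `slope`, `se`, `t`, plus `df` and
#'   `n_points`.
#' @export
fit_wls <- function(gd, rescale = TRUE) {
  stopifnot(inherits(gd, "group_data"))
  n <- nrow(gd$y)
  S <- stats::model.matrix(~ 0 + gd$subject)
  n_sub <- ncol(S)
  df <- n - (n_sub + 1L)
  if (df < 1) stop("not enough rows for the group design: df = ", df)
  ct <- .wls_center(gd$code, gd$w, S)
  swc2 <- colSums(gd$w * ct^2)
  if (any(swc2 <= 1e-12 * max(swc2, 1)))
    stop("rank-deficient group design: strength code constant within ",
         "subjects at some voxel")
  yt <- .wls_center(gd$y, gd$w, S)
  slope <- colSums(gd$w * yt * ct) / swc2
  if (rescale) {
    rss <- colSums(gd$w * yt^2) - slope^2 * swc2
    rss <- pmax(rss, 0)
    se <- sqrt((rss / df) / swc2)
  } else {
    se <- sqrt(1 / swc2)
  }
  structure(list(slope = slope, se = se, t = slope / se, df = df,
                 n_points = n, voxels = gd$voxels),
            class = "group_fit")
}

#' @export
print.group_fit <- function(x, ...) {
  cat(sprintf("Group WLS fit: %d voxel(s), %d data points, df = %d\n",
              length(x$slope), x$n_points, x$df))
  invisible(x)
}

#' Confidence interval for the group slope
#'
#' @param fit A `group_fit`.
#' @param level Confidence level.
#' @return Matrix voxels x 2 (`lower`, `upper`).
#' @export
slope_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "group_fit"))
  q <- stats::qt(1 - (1 - level) / 2, df = fit$df)
  cbind(lower = fit$slope - q * fit$se, upper = fit$slope + q * fit$se)
}

#' Long-format view of stacked group data
#'
#' @param gd A `group_data`.
#' @return data.frame with `voxel`, `subject`, `category`, `code`, `y`, `w`.
#' @export
group_data_table <- function(gd) {
  stopifnot(inherits(gd, "group_data"))
  v <- ncol(gd$y)
  data.frame(voxel = rep(gd$voxels, each = nrow(gd$y)),
             subject = rep(as.character(gd$subject), v),
             category = if (is.null(gd$category)) NA_character_ else
               rep(gd$category, v),
             code = rep(gd$code, v),
             y = as.numeric(gd$y), w = as.numeric(gd$w),
             stringsAsFactors = FALSE)
}
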