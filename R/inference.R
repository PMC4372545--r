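#' Uncorrected two-tailed thresholding of a t map
#'
#' Flags voxels whose |t| exceeds the two-tailed Student-t critical value at
#' `alpha`, keeping the sign, and reports positive and negative counts
#' separately.
#'
#' @param t_map Numeric vector or 3D array of t statistics.
#' @param df Residual degrees of freedom (> 0).
#' @param alpha Two-tailed uncorrected level, in (0, 1).
#' @return List: `map` (same shape, values -1/0/+1), `critical`,
#'   `n_positive`, `n_negative`.
#' @export
threshold_map <- function(t_map, df, alpha = 0.01) {
  if (df <= 0) stop("df must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  crit <- stats::qt(1 - alpha / 2, df = df)
  m <- sign(t_map) * (abs(t_map) > crit)
  list(map = m, critical = crit,
       n_positive = sum(m > 0), n_negative = sum(m < 0))
}

.CONNECTIVITY_OFFSETS <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1,
                 "18" = nz >= 1 & rowSums(off != 0) <= 2,
                 "26" = nz >= 1)
  off[keep, , drop = FALSE]
}

#' Label connected clusters in a signed threshold map
#'
#' Finds maximal connected components separately for positive and negative
#' suprathreshold voxels, and summarizes each: size in voxels, peak |t|
#' voxel and its coordinate (world mm when `affine` given, else 0-based
#' voxel indices).
#'
#' @param map Signed binary 3D array (from [threshold_map()]).
#' @param connectivity Neighborhood: 6 (faces), 18 (+edges), 26 (+corners).
#' @param t_map Optional t-statistic array for peak localization.
#' @param affine Optional 4x4 voxel-to-world matrix.
#' @return A data.frame (`cluster_table`): `cluster`, `sign`, `size`,
#'   `peak_x`, `peak_y`, `peak_z`, `peak_t`, sorted by decreasing size.
#' @export
label_clusters <- function(map, connectivity = 26L, t_map = NULL,
                           affine = NULL) {
  stopifnot(length(dim(map)) == 3)
  dims <- dim(map)
  offs <- .CONNECTIVITY_OFFSETS(as.integer(connectivity))
  labels <- array(0L, dims)
  next_label <- 0L
  comp_sign <- integer(0)
  for (sgn in c(1, -1)) {
    todo <- which(map == sgn & labels == 0L)
    for (start in todo) {
      if (labels[start] != 0L) next
      next_label <- next_label + 1L
      comp_sign <- c(comp_sign, sgn)
      queue <- start
      labels[start] <- next_label
      while (length(queue) > 0) {
        cur <- queue[length(queue)]
        queue <- queue[-length(queue)]
        cc <- arrayInd(cur, dims)
        nb <- sweep(offs, 2, as.integer(cc), "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
        nb <- nb[ok, , drop = FALSE]
        ni <- nb[, 1] + dims[1] * (nb[, 2] - 1L) +
          dims[1] * dims[2] * (nb[, 3] - 1L)
        grow <- ni[map[ni] == sgn & labels[ni] == 0L]
        labels[grow] <- next_label
        queue <- c(queue, grow)
      }
    }
  }
  if (next_label == 0L)
    return(data.frame(cluster = integer(0), sign = integer(0),
                      size = integer(0), peak_x = numeric(0),
                      peak_y = numeric(0), peak_z = numeric(0),
                      peak_t = numeric(0)))
  rows <- lapply(seq_len(next_label), function(l) {
    idx <- which(labels == l)
    tv <- if (is.null(t_map)) rep(NA_real_, length(idx)) else t_map[idx]
    peak <- if (all(is.na(tv))) idx[1] else idx[which.max(abs(tv))]
    cc <- as.numeric(arrayInd(peak, dims)) - 1  # 0-based voxel indices
    if (!is.null(affine)) cc <- as.numeric(affine %*% c(cc, 1))[1:3]
    data.frame(cluster = l, sign = comp_sign[l], size = length(idx),
               peak_x = cc[1], peak_y = cc[2], peak_z = cc[3],
               peak_t = if (all(is.na(tv))) NA_real_ else tv[which.max(abs(tv))])
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$size), ]
  out$cluster <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Max-statistic permutation family-wise error correction
#'
#' Builds the null distribution of the image-wise maximum |t| by refitting
#' the group model to permutations of the memory-strength codes (the same
#' permutation applied at every voxel), then assigns each voxel a corrected
#' p: the proportion of null maxima at or beyond its observed |t|.
#'
#' @param gd A `group_data`.
#' @param B Number of permutations (>= 1).
#' @param scheme `"global"` shuffles the code vector across all rows (the
#'   default); `"within_subject"` shuffles codes within each subject.
#' @param seed Integer seed.
#' @param p_definition `"greater"`: p = proportion of null maxima strictly
#'   greater than observed (can be 0); `"add_one"`: (b + 1) / (B + 1).
#' @param rescale Passed to [fit_wls()].
#' @param store_t Keep the full B x voxels permuted |t| matrix (needed by
#'   [count_exceedances()]).
#' @param max_redraws Permutations that break the design rank (code constant
#'   within subjects) are redrawn and logged, up to this many times total.
#' @return A `permutation_null`: `max_abs_t` (length B), `p_corrected` per
#'   voxel, `observed` (`group_fit`), `B`, `scheme`, `seed`, and optionally
#'   `perm_t`.
#' @export
permutation_fwe <- function(gd, B = 1000L, scheme = c("global",
                                                      "within_subject"),
                            seed = 1L,
                            p_definition = c("greater", "add_one"),
                            rescale = TRUE, store_t = TRUE,
                            max_redraws = 100L) {
  scheme <- match.arg(scheme)
  p_definition <- match.arg(p_definition)
  stopifnot(inherits(gd, "group_data"), B >= 1)
  observed <- fit_wls(gd, rescale = rescale)
  n <- nrow(gd$y)
  S <- stats::model.matrix(~ 0 + gd$subject)
  df <- observed$df
  w <- gd$w
  yt <- .wls_center(gd$y, w, S)
  swy2 <- colSums(w * yt^2)
  sub_idx <- split(seq_len(n), gd$subject)

  draw_perm <- function() {
    if (scheme == "global") sample.int(n) else {
      p <- integer(n)
      for (ii in sub_idx) p[ii] <- ii[sample.int(length(ii))]
      p
    }
  }
  perm_t_stat <- function(code_perm) {
    ct <- .wls_center(code_perm, w, S)
    swc2 <- colSums(w * ct^2)
    if (any(swc2 <= 1e-12 * max(swc2, 1))) return(NULL)  # rank break
    slope <- colSums(w * yt * ct) / swc2
    if (rescale) {
      rss <- pmax(swy2 - slope^2 * swc2, 0)
      se <- sqrt((rss / df) / swc2)
    } else se <- sqrt(1 / swc2)
    abs(slope / se)
  }

  set.seed(as.integer(seed))
  max_abs_t <- numeric(B)
  perm_t <- if (store_t) matrix(NA_real_, B, ncol(gd$y)) else NULL
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      tt <- perm_t_stat(gd$code[draw_perm()])
      if (!is.null(tt)) break
      redraws <- redraws + 1L
      if (redraws > max_redraws)
        stop("too many rank-breaking permutations (", redraws, ")")
      message("permutation broke design rank; redrawing")
    }
    max_abs_t[b] <- max(tt)
    if (store_t) perm_t[b, ] <- tt
  }
  obs <- abs(observed$t)
  p_corr <- if (p_definition == "greater") {
    vapply(obs, function(o) mean(max_abs_t > o), numeric(1))
  } else {
    vapply(obs, function(o) (sum(max_abs_t >= o) + 1) / (B + 1), numeric(1))
  }
  structure(list(max_abs_t = max_abs_t, p_corrected = p_corr,
                 observed = observed, B = as.integer(B), scheme = scheme,
                 seed = as.integer(seed), p_definition = p_definition,
                 perm_t = perm_t, n_redraws = redraws),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(paste0("Permutation null: B = %d (%s shuffle), ",
                     "min corrected p = %.4g\n"),
              x$B, x$scheme, min(x$p_corrected)))
  invisible(x)
}

#' Count FWE-significant voxels and their chance probability
#'
#' Counts voxels with corrected p at or below `level`, and estimates by
#' Monte Carlo the probability of seeing at least that many under the null:
#' for each stored permutation, the number of its voxels exceeding the
#' `1 - level` quantile of the null max distribution is compared to the
#' observed count.
#'
#' @param pn A `permutation_null` with stored permutation t maps.
#' @param level Corrected significance level.
#' @return List: `count`, `level`, `chance_prob`.
#' @export
count_exceedances <- function(pn, level = 0.05) {
  stopifnot(inherits(pn, "permutation_null"))
  count <- sum(pn$p_corrected <= level)
  if (is.null(pn$perm_t))
    stop("permutation t maps were not stored; rerun with store_t = TRUE")
  thr <- stats::quantile(pn$max_abs_t, probs = 1 - level, type = 1)
  null_counts <- rowSums(pn$perm_t > thr)
  list(count = count, level = level,
       chance_prob = mean(null_counts >= count))
}
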