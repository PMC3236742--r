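# Fold-wise group analysis and feature assembly.
#
# Across the sample subjects of a fold, each voxel's contrast value is
# regressed on [intercept, BDI-II, AAI] by OLS (one joint model, both
# psychometric regressors together). The t statistic of each regressor
# (dof = n - 3) is mapped to a Z score by matching cumulative
# probabilities, Z = qnorm(pt(t, dof)), computed on the log scale so the
# far tails that matter at the 4.265 cutoff stay accurate. The ROI is the
# union, over all 6 (contrast, regressor) maps, of voxels exceeding the Z
# threshold.

#' ROI selection configuration
#'
#' @param z_threshold Z cutoff; voxels must exceed it strictly
#'   (default 4.265, the upper-tail normal quantile of P = 1e-5).
#' @param two_sided Select on |Z| (default) or on Z alone.
#' @param fallback_k If no voxel is suprathreshold, take the `fallback_k`
#'   voxels with the largest max-|Z| instead (default 50, the nominal ROI
#'   size), with a warning.
#' @return An object of class `roi_config`.
#' @export
roi_config <- function(z_threshold = 4.265, two_sided = TRUE,
                       fallback_k = 50L) {
  check_scalar_number(z_threshold, "z_threshold", .Machine$double.eps)
  check_scalar_number(fallback_k, "fallback_k", 2)
  structure(list(z_threshold = z_threshold, two_sided = isTRUE(two_sided),
                 fallback_k = as.integer(fallback_k)),
            class = "roi_config")
}

# Tail-stable t -> Z conversion: strictly monotone, sign-preserving,
# Z(0) = 0 exactly.
z_from_t <- function(t, dof) {
  z <- numeric(length(t))
  pos <- !is.na(t) & t >= 0
  z[pos] <- -qnorm(pt(t[pos], dof, lower.tail = FALSE, log.p = TRUE),
                   log.p = TRUE)
  z[!pos] <- qnorm(pt(t[!pos], dof, lower.tail = TRUE, log.p = TRUE),
                   log.p = TRUE)
  z[is.na(t)] <- NA_real_
  z
}

#' Group Z maps from per-subject contrasts
#'
#' @param contrast_sets List of [contrast_set()] objects (shared grid), one
#'   per subject.
#' @param records Matching cohort data frame rows (same order).
#' @return A `group_zmaps` object: `z[[contrast]][[regressor]]` volumes for
#'   the 3 contrasts x {BDI, AAI}, plus `dof`.
#' @export
group_zmaps <- function(contrast_sets, records) {
  n <- length(contrast_sets)
  if (n != nrow(records))
    stopf("%d contrast sets but %d subject records", n, nrow(records))
  if (n < 4L) stopf("group model needs at least 4 subjects, got %d", n)
  gd <- contrast_sets[[1]]$grid_dims
  for (cs in contrast_sets)
    if (!identical(cs$grid_dims, gd)) stopf("contrast grids differ")
  X <- cbind(intercept = 1, BDI = as.numeric(records$bdi),
             AAI = as.numeric(records$aai))
  for (j in 2:3) if (sd(X[, j]) == 0)
    stopf("regressor '%s' is constant across subjects", colnames(X)[j])
  if (qr(X)$rank < 3L) stopf("group design is rank deficient")
  xtx_inv <- chol2inv(chol(crossprod(X)))
  dof <- n - 3L
  nv <- prod(gd)
  z <- lapply(CONTRAST_KEYS, function(k) {
    Y <- vapply(contrast_sets, function(cs) as.numeric(cs$maps[[k]]$data),
                numeric(nv))
    Y <- t(matrix(Y, ncol = n))               # subjects x voxels
    betas <- xtx_inv %*% crossprod(X, Y)
    res <- Y - X %*% betas
    sigma2 <- colSums(res^2) / dof
    per_reg <- lapply(2:3, function(j) {
      se <- sqrt(sigma2 * xtx_inv[j, j])
      t <- ifelse(se > 0, betas[j, ] / se,
                  ifelse(betas[j, ] == 0, 0, sign(betas[j, ]) * Inf))
      new_volume(array(z_from_t(t, dof), gd),
                 voxel_dims = contrast_sets[[1]]$maps[[k]]$voxel_dims,
                 allow_nonfinite = TRUE)
    })
    names(per_reg) <- REGRESSOR_KEYS
    per_reg
  })
  names(z) <- CONTRAST_KEYS
  structure(list(z = z, dof = dof, grid_dims = gd), class = "group_zmaps")
}

#' Select the ROI from group Z maps
#'
#' The mask is the union over all 6 (contrast, regressor) maps of voxels
#' with `|Z| > z_threshold` (strictly; `Z > z_threshold` one-sided when
#' `two_sided = FALSE`). An empty union falls back to the `fallback_k`
#' voxels of largest max-|Z|, with a warning, so downstream folds stay
#' runnable on weak-signal data.
#'
#' @param zmaps A [group_zmaps()] object.
#' @param cfg A [roi_config()].
#' @return A `roi_mask`: sorted unique 0-based linear voxel `indices` plus
#'   `grid_dims`.
#' @export
select_roi <- function(zmaps, cfg = roi_config()) {
  stopifnot(inherits(zmaps, "group_zmaps"), inherits(cfg, "roi_config"))
  nv <- prod(zmaps$grid_dims)
  stat <- rep(-Inf, nv)
  for (k in CONTRAST_KEYS) for (r in REGRESSOR_KEYS) {
    zi <- as.numeric(zmaps$z[[k]][[r]]$data)
    s <- if (cfg$two_sided) abs(zi) else zi
    s[is.na(s)] <- -Inf
    stat <- pmax(stat, s)
  }
  supra <- which(stat > cfg$z_threshold)
  if (length(supra) == 0L) {
    warning(sprintf(
      "no voxel exceeded Z = %g in any map; falling back to the top %d by max |Z|",
      cfg$z_threshold, cfg$fallback_k), call. = FALSE)
    abs_stat <- rep(-Inf, nv)
    for (k in CONTRAST_KEYS) for (r in REGRESSOR_KEYS) {
      zi <- abs(as.numeric(zmaps$z[[k]][[r]]$data))
      zi[is.na(zi)] <- -Inf
      abs_stat <- pmax(abs_stat, zi)
    }
    supra <- order(abs_stat, decreasing = TRUE)[seq_len(cfg$fallback_k)]
  }
  roi_mask(pos_to_lin(sort(supra)), zmaps$grid_dims)
}

#' Construct an ROI mask
#'
#' @param indices 0-based linear voxel indices (x fastest).
#' @param grid_dims 3-axis voxel counts.
#' @return An object of class `roi_mask` with sorted unique indices.
#' @export
roi_mask <- function(indices, grid_dims) {
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) == 0L) stopf("ROI mask is empty")
  if (any(indices < 0L) || any(indices >= prod(grid_dims)))
    stopf("ROI indices out of grid")
  structure(list(indices = indices, grid_dims = as.integer(grid_dims)),
            class = "roi_mask")
}

#' Mask volume for an ROI
#' @param mask A [roi_mask()].
#' @param voxel_dims Voxel dimensions for the output volume.
#' @return A binary [new_volume()] (1 inside the ROI).
#' @export
mask_volume <- function(mask, voxel_dims = c(1, 1, 1)) {
  dat <- array(0, mask$grid_dims)
  dat[lin_to_pos(mask$indices)] <- 1
  new_volume(dat, voxel_dims = voxel_dims)
}

#' Assemble the PCR feature matrix
#'
#' Per subject, the masked voxel values of the three contrasts are
#' concatenated in fixed block order (M-F, then M-S, then F-S), voxels
#' sorted by linear index within each block -- a pure re-indexing, no
#' arithmetic. With `source = "z"` each value is instead the per-subject
#' pseudo-Z, effect / sqrt(variance) (requires variance maps).
#'
#' @param contrast_sets List of [contrast_set()] objects (or a single one).
#' @param mask A [roi_mask()] on the same grid.
#' @param source `"effect"` (default) or `"z"`.
#' @return Numeric matrix, subjects x `3 * length(mask$indices)`.
#' @export
assemble_features <- function(contrast_sets, mask, source = c("effect", "z")) {
  source <- match.arg(source)
  if (inherits(contrast_sets, "contrast_set"))
    contrast_sets <- list(contrast_sets)
  stopifnot(inherits(mask, "roi_mask"))
  pos <- lin_to_pos(mask$indices)
  rows <- lapply(contrast_sets, function(cs) {
    if (!identical(cs$grid_dims, mask$grid_dims))
      stopf("mask grid does not match the contrast grid")
    unlist(lapply(CONTRAST_KEYS, function(k) {
      v <- as.numeric(cs$maps[[k]]$data)[pos]
      if (source == "z") {
        if (is.null(cs$variances))
          stopf("source = 'z' needs variance maps")
        v <- v / sqrt(as.numeric(cs$variances[[k]]$data)[pos])
      }
      v
    }), use.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(contrast_sets)
  colnames(out) <- as.vector(t(outer(CONTRAST_KEYS, mask$indices,
                                     function(k, i) paste0(k, ":", i))))
  out
}
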