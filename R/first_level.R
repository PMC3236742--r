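# First-level analysis: from 4-D BOLD runs to per-subject contrast maps.
#
# The model is the standard event-related GLM: one regressor per viewing
# condition (M, F, S), built by convolving the event indicator with the
# canonical double-gamma HRF, optional confound columns passed through
# unchanged, and an intercept. Fitting is voxelwise OLS (the synthetic noise
# model is white; no prewhitening). Contrasts are combined across runs by
# inverse-variance fixed-effects averaging.

#' Canonical double-gamma HRF kernel
#'
#' `h(t) = g(t; 6, 1) - g(t; 16, 1) / 6` with `g` the gamma density
#' (shape = delay / dispersion, scale = dispersion) -- the conventional
#' canonical parameters: response peak near 5 s, undershoot near 15 s, 32-s
#' support. The kernel is peak-normalized to 1.
#'
#' @param dt Sampling interval, s.
#' @param duration Kernel support, s (default 32).
#' @param peak_delay,undershoot_delay,peak_disp,undershoot_disp,ratio
#'   Double-gamma shape parameters.
#' @return Numeric kernel of length `ceiling(duration / dt)`, sampled at
#'   `t = 0, dt, 2 dt, ...`.
#' @export
canonical_hrf <- function(dt, duration = 32, peak_delay = 6,
                          undershoot_delay = 16, peak_disp = 1,
                          undershoot_disp = 1, ratio = 1 / 6) {
  check_scalar_number(dt, "dt", .Machine$double.eps)
  if (dt > duration) stopf("dt (%g) exceeds duration (%g)", dt, duration)
  t <- (seq_len(ceiling(duration / dt)) - 1) * dt
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    ratio * stats::dgamma(t, shape = undershoot_delay / undershoot_disp,
                          scale = undershoot_disp)
  h / max(h)
}

# Event indicator on the frame grid convolved with the canonical HRF.
# Onsets are snapped to the nearest frame (snap = TRUE, the default) or
# split between the two bracketing frames by linear interpolation.
convolve_events <- function(events, n_frames, tr, snap = TRUE) {
  ind <- numeric(n_frames)
  for (i in seq_len(nrow(events))) {
    nfr <- max(1L, as.integer(round(events$duration[i] / tr)))
    pos <- events$onset[i] / tr
    if (snap) {
      f0 <- as.integer(round(pos))
      fr <- f0 + seq_len(nfr) - 1L
      fr <- fr[fr >= 0L & fr < n_frames]
      ind[fr + 1L] <- ind[fr + 1L] + 1
    } else {
      lo <- floor(pos); frac <- pos - lo
      for (off in seq_len(nfr) - 1L) {
        f <- as.integer(lo) + off
        if (f >= 0L && f < n_frames) ind[f + 1L] <- ind[f + 1L] + (1 - frac)
        if (f + 1L >= 0L && f + 1L < n_frames)
          ind[f + 2L] <- ind[f + 2L] + frac
      }
    }
  }
  h <- canonical_hrf(tr)
  y <- stats::convolve(c(ind, numeric(length(h))), rev(h), type = "open")
  y[seq_len(n_frames)]
}

#' Build a run design matrix
#'
#' One column per condition (M, F, S order) -- the event indicator convolved
#' with [canonical_hrf()] and truncated to the run -- then any confound
#' columns unchanged, then the intercept.
#'
#' @param events Run event data frame (`condition`, `onset`, `duration`).
#' @param n_frames Frames in the run.
#' @param tr Repetition time, s.
#' @param confounds Optional numeric matrix with `n_frames` rows (e.g.
#'   motion parameters, white-matter mean signal); passed through as given
#'   -- any centering is the caller's responsibility.
#' @param snap Snap onsets to the TR grid (default) or linearly interpolate.
#' @return A `design_matrix`: list with `X` (frames x regressors) and
#'   `names`.
#' @export
build_design <- function(events, n_frames, tr, confounds = NULL,
                         snap = TRUE) {
  task <- vapply(CONDITIONS, function(cond) {
    ev <- events[events$condition == cond, , drop = FALSE]
    convolve_events(ev, n_frames, tr, snap = snap)
  }, numeric(n_frames))
  X <- task
  nms <- CONDITIONS
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n_frames)
      stopf("confounds have %d rows but the run has %d frames",
            nrow(confounds), n_frames)
    cn <- colnames(confounds)
    if (is.null(cn)) cn <- sprintf("confound%d", seq_len(ncol(confounds)))
    X <- cbind(X, confounds)
    nms <- c(nms, cn)
  }
  X <- cbind(X, 1)
  nms <- c(nms, "intercept")
  colnames(X) <- nms
  structure(list(X = X, names = nms), class = "design_matrix")
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian with per-axis `sigma` (in voxels) of
#' `fwhm_mm / (2 sqrt(2 ln 2)) / voxel_dim`, reflect boundary handling,
#' kernel truncated at 4 sigma. A 4-D volume is smoothed frame-wise.
#'
#' @param vol A [new_volume()].
#' @param fwhm_mm Full width at half maximum, mm; `0` is the identity.
#' @return Smoothed volume on the same grid.
#' @export
gaussian_smooth <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "volume"))
  check_scalar_number(fwhm_mm, "fwhm_mm", 0)
  if (fwhm_mm == 0) return(vol)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vol$voxel_dims
  dat <- vol$data
  nd <- length(dim(dat))
  for (axis in 1:3) dat <- smooth_axis(dat, axis, sigma_vox[axis])
  new_volume(dat, voxel_dims = vol$voxel_dims, affine = vol$affine)
}

# 1-D Gaussian filter along one array axis with reflect padding.
smooth_axis <- function(arr, axis, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  n <- d[axis]
  m <- matrix(a, nrow = n)
  p <- m[reflect_index(seq(1L - r, n + r), n), , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (o in 0:(2L * r)) out <- out + k[o + 1L] * p[(1L + o):(n + o), , drop = FALSE]
  a <- array(out, d[perm])
  aperm(a, order(perm))
}

# Mirror-boundary index mapping (edge value not repeated), valid for any
# offset: 0 -> 2, -1 -> 3, n+1 -> n-1, ...
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * (n - 1L))
  ifelse(j < n, j + 1L, 2L * n - 1L - j)
}

#' Fit the voxelwise GLM by OLS
#'
#' @param run A 4-D [new_volume()] (time last).
#' @param design A [build_design()] object with matching frame count.
#' @return A `glm_fit`: per-voxel `betas` (regressors x voxels), `sigma2`
#'   (residual variance), `dof` (`frames - rank`), plus the design and grid
#'   metadata needed by [contrast_map()].
#' @export
fit_glm <- function(run, design) {
  stopifnot(inherits(run, "volume"), inherits(design, "design_matrix"))
  d <- dim(run$data)
  if (length(d) != 4L) stopf("fit_glm needs a 4-D run")
  X <- design$X
  n <- nrow(X)
  if (d[4] != n) stopf("design has %d frames but the run has %d", n, d[4])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- design$names[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stopf("design is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  nv <- prod(d[1:3])
  Y <- t(matrix(run$data, nv, n))            # frames x voxels
  betas <- qr.coef(qrX, Y)
  res <- Y - X %*% betas
  dof <- n - qrX$rank
  sigma2 <- colSums(res^2) / dof
  structure(list(betas = betas, sigma2 = sigma2, dof = dof,
                 names = design$names,
                 xtx_inv = chol2inv(chol(crossprod(X))),
                 grid_dims = d[1:3], voxel_dims = run$voxel_dims,
                 affine = run$affine),
            class = "glm_fit")
}

#' Contrast effect and variance maps
#'
#' `effect = c' beta` per voxel and `variance = sigma2 * c' (X'X)^{-1} c`.
#' A contrast given over the task columns only is zero-padded across the
#' confound and intercept columns.
#'
#' @param fit A [fit_glm()] object.
#' @param contrast Numeric contrast vector of length 3 (task columns) or
#'   of the full design width.
#' @return List with `effect` and `variance` volumes.
#' @export
contrast_map <- function(fit, contrast) {
  stopifnot(inherits(fit, "glm_fit"))
  p <- nrow(fit$betas)
  if (length(contrast) == length(CONDITIONS) && p > length(CONDITIONS))
    contrast <- c(contrast, numeric(p - length(CONDITIONS)))
  if (length(contrast) != p)
    stopf("contrast length %d does not match the %d design columns",
          length(contrast), p)
  eff <- as.numeric(crossprod(contrast, fit$betas))
  v <- fit$sigma2 * as.numeric(crossprod(contrast, fit$xtx_inv %*% contrast))
  list(effect = new_volume(array(eff, fit$grid_dims),
                           voxel_dims = fit$voxel_dims, affine = fit$affine),
       variance = new_volume(array(v, fit$grid_dims),
                             voxel_dims = fit$voxel_dims,
                             affine = fit$affine))
}

#' Fixed-effects combination across runs
#'
#' Inverse-variance-weighted mean per voxel; the combined variance is
#' `1 / sum(1 / v_i)`. Voxels with a zero variance in any run fall back to
#' the unweighted mean (combined variance `mean(v) / n`) with a warning.
#'
#' @param effects List of effect volumes (one per run, shared grid).
#' @param variances Matching list of variance volumes.
#' @return List with combined `effect` and `variance` volumes.
#' @export
fixed_effects_combine <- function(effects, variances) {
  if (length(effects) == 0L) stopf("no runs to combine")
  if (length(effects) != length(variances))
    stopf("effects and variances differ in length")
  gd <- grid_dims(effects[[1]])
  for (v in c(effects, variances))
    if (!identical(grid_dims(v), gd)) stopf("grid mismatch across runs")
  E <- vapply(effects, function(v) as.numeric(v$data), numeric(prod(gd)))
  V <- vapply(variances, function(v) as.numeric(v$data), numeric(prod(gd)))
  E <- matrix(E, ncol = length(effects))
  V <- matrix(V, ncol = length(effects))
  zero <- rowSums(V <= 0) > 0
  W <- 1 / V
  eff <- rowSums(E * W) / rowSums(W)
  var_c <- 1 / rowSums(W)
  if (any(zero)) {
    warning(sprintf(
      "%d voxel(s) with zero run variance: unweighted-mean fallback",
      sum(zero)), call. = FALSE)
    eff[zero] <- rowMeans(E[zero, , drop = FALSE])
    var_c[zero] <- rowMeans(V[zero, , drop = FALSE]) / ncol(V)
  }
  list(effect = new_volume(array(eff, gd),
                           voxel_dims = effects[[1]]$voxel_dims,
                           affine = effects[[1]]$affine),
       variance = new_volume(array(var_c, gd),
                             voxel_dims = effects[[1]]$voxel_dims,
                             affine = effects[[1]]$affine))
}

#' Construct a contrast set
#'
#' The three per-subject contrast effect maps (M-F, M-S, F-S) on a shared
#' grid, with optional matching variance maps.
#'
#' @param maps Named list of three effect volumes keyed `M-F`, `M-S`, `F-S`.
#' @param variances Optional matching named list of variance volumes.
#' @return An object of class `contrast_set`.
#' @export
contrast_set <- function(maps, variances = NULL) {
  if (!identical(sort(names(maps)), sort(CONTRAST_KEYS)))
    stopf("contrast maps must be keyed exactly {%s}",
          paste(CONTRAST_KEYS, collapse = ", "))
  maps <- maps[CONTRAST_KEYS]
  gd <- grid_dims(maps[[1]])
  for (m in maps) if (!identical(grid_dims(m), gd))
    stopf("contrast maps must share one grid")
  if (!is.null(variances)) {
    variances <- variances[CONTRAST_KEYS]
    for (m in variances) if (!identical(grid_dims(m), gd))
      stopf("variance maps must share the contrast grid")
  }
  structure(list(maps = maps, variances = variances, grid_dims = gd),
            class = "contrast_set")
}

#' Full first-level analysis for one subject
#'
#' Optionally smooths each run, fits the GLM per run, forms the three
#' contrasts, and combines them across runs by fixed effects.
#'
#' @param runs List of 4-D run volumes.
#' @param schedule An `event_schedule` (one event data frame per run).
#' @param tr Repetition time, s.
#' @param fwhm_mm Spatial smoothing FWHM, mm (default 9; 0 disables).
#' @param confounds Optional list of per-run confound matrices.
#' @return A [contrast_set()] with fixed-effects-combined effect and
#'   variance maps.
#' @export
subject_contrasts <- function(runs, schedule, tr, fwhm_mm = 9,
                              confounds = NULL) {
  cvec <- list("M-F" = c(1, -1, 0), "M-S" = c(1, 0, -1),
               "F-S" = c(0, 1, -1))
  per_run <- lapply(seq_along(runs), function(r) {
    run <- runs[[r]]
    if (fwhm_mm > 0) run <- gaussian_smooth(run, fwhm_mm)
    n_frames <- dim(run$data)[4]
    des <- build_design(schedule[[r]], n_frames, tr,
                        confounds = if (is.null(confounds)) NULL
                        else confounds[[r]])
    fit <- fit_glm(run, des)
    lapply(cvec, function(cv) contrast_map(fit, cv))
  })
  maps <- vars <- setNames(vector("list", 3), CONTRAST_KEYS)
  for (k in CONTRAST_KEYS) {
    comb <- fixed_effects_combine(
      lapply(per_run, function(pr) pr[[k]]$effect),
      lapply(per_run, function(pr) pr[[k]]$variance))
    maps[[k]] <- comb$effect
    vars[[k]] <- comb$variance
  }
  contrast_set(maps, vars)
}
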