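# Synthetic cohort generator.
#
# Emulates the study conditions the decoding pipeline assumes: a balanced
# cohort of 14 control / 14 depressed women, four 12.6-minute event-related
# runs at TR = 2 s with randomly interleaved Mother / Friend / Stranger
# picture events, and a single contiguous ~50-voxel cluster whose contrast
# amplitudes are linear in the subject's BDI-II (and weakly in AAI), under
# i.i.d. Gaussian observation noise. Every output is a pure function of
# (spec$seed, subject_id, operation), so identical seeds give bit-identical
# cohorts.

#' Specify a synthetic cohort
#'
#' Defaults encode the emulated study design: 14 + 14 subjects, four
#' 12.6-minute runs at TR = 2 s, 2x2x3 mm voxels, and a planted 50-voxel
#' cluster. The effect sizes have no published physical-unit values; the
#' defaults are this package's calibration (in arbitrary contrast units):
#' the Mother response grows by `0.05` per BDI-II point and falls by `0.02`
#' per AAI point, the Friend response grows weakly (`0.01`/point) and the
#' Stranger response is flat, so depressed subjects show the higher
#' Mother-involving contrast activity.
#'
#' @param n_control,n_depressed Group sizes.
#' @param grid_dims Voxel counts per axis (a desk-scale grid, not a whole
#'   brain).
#' @param voxel_dims Voxel edge lengths, mm.
#' @param cluster_voxels Size of the planted contiguous cluster.
#' @param tr Repetition time, s.
#' @param run_minutes Run duration, minutes.
#' @param n_runs Runs per subject.
#' @param events_per_condition Events of each condition per run.
#' @param effect_slopes Named (M, F, S) change in condition amplitude per
#'   BDI-II point.
#' @param aai_slope Change in the Mother amplitude per AAI point.
#' @param intercepts Named (M, F, S) condition amplitudes at bdi = 0,
#'   aai = 0.
#' @param baseline BOLD baseline level.
#' @param noise_sd SD of the i.i.d. Gaussian observation noise (contrast
#'   units; also the BOLD noise SD).
#' @param aai_bdi_weight Weight in `[0, 1]` mixing AAI towards the reverse
#'   of BDI-II; larger means a stronger negative bdi-aai correlation.
#' @param seed Base RNG seed; all randomness derives from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 14L, n_depressed = 14L,
                        grid_dims = c(20L, 20L, 12L),
                        voxel_dims = c(2, 2, 3),
                        cluster_voxels = 50L,
                        tr = 2, run_minutes = 12.6, n_runs = 4L,
                        events_per_condition = 21L,
                        effect_slopes = c(M = 0.05, F = 0.01, S = 0),
                        aai_slope = -0.02,
                        intercepts = c(M = 1, F = 1, S = 1),
                        baseline = 100, noise_sd = 0.5,
                        aai_bdi_weight = 0.5, seed = 1L) {
  check_scalar_number(n_control, "n_control", 1)
  check_scalar_number(n_depressed, "n_depressed", 1)
  check_scalar_number(cluster_voxels, "cluster_voxels", 1)
  check_scalar_number(tr, "tr", .Machine$double.eps)
  check_scalar_number(run_minutes, "run_minutes", .Machine$double.eps)
  check_scalar_number(n_runs, "n_runs", 1)
  check_scalar_number(noise_sd, "noise_sd", 0)
  check_scalar_number(aai_bdi_weight, "aai_bdi_weight", 0, 1)
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 1L))
    stopf("grid_dims must be 3 positive voxel counts")
  if (cluster_voxels > prod(grid_dims))
    stopf("cluster_voxels (%d) exceeds grid size (%d)",
          cluster_voxels, prod(grid_dims))
  for (nm in CONDITIONS) {
    if (!nm %in% names(effect_slopes) || !nm %in% names(intercepts))
      stopf("effect_slopes and intercepts need entries for M, F, S")
  }
  structure(list(
    n_control = as.integer(n_control), n_depressed = as.integer(n_depressed),
    grid_dims = grid_dims, voxel_dims = as.numeric(voxel_dims),
    cluster_voxels = as.integer(cluster_voxels),
    tr = tr, run_minutes = run_minutes, n_runs = as.integer(n_runs),
    events_per_condition = as.integer(events_per_condition),
    effect_slopes = effect_slopes[CONDITIONS],
    aai_slope = aai_slope, intercepts = intercepts[CONDITIONS],
    baseline = baseline, noise_sd = noise_sd,
    aai_bdi_weight = aai_bdi_weight, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Frames per run implied by a cohort spec
#' @param spec A [cohort_spec()].
#' @return Integer frame count, `floor(run_minutes * 60 / tr)`.
#' @export
frames_per_run <- function(spec) as.integer(floor(spec$run_minutes * 60 / spec$tr))

#' Sample subject psychometrics
#'
#' Control BDI-II scores are uniform integers on `[0, 12]`, depressed on
#' `[11, 54]` (the observed cohort ranges). AAI coherence is drawn on
#' `[1, 9]` as a mixture of a uniform draw and the reversed, rescaled BDI-II
#' score, giving a configurable negative bdi-aai correlation.
#'
#' @param spec A [cohort_spec()].
#' @return Cohort data frame (`subject_id`, `group`, `bdi`, `aai`),
#'   deterministic given `spec$seed`.
#' @export
sample_cohort_traits <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_control + spec$n_depressed
  withr::with_seed(derive_seed(spec$seed, "traits"), {
    bdi <- c(sample(0:12, spec$n_control, replace = TRUE),
             sample(11:54, spec$n_depressed, replace = TRUE))
    w <- spec$aai_bdi_weight
    latent <- (1 - w) * runif(n) + w * (1 - bdi / 54)
    aai <- 1 + 8 * latent
  })
  tab <- data.frame(
    subject_id = sprintf("sub-%02d", seq_len(n)),
    group = factor(rep(c("control", "depressed"),
                       c(spec$n_control, spec$n_depressed)),
                   levels = c("control", "depressed")),
    bdi = as.integer(bdi), aai = aai,
    stringsAsFactors = FALSE)
  validate_cohort(tab)
}

#' Plant the ground-truth activity cluster
#'
#' Grows a contiguous blob (6-neighbourhood) from a random interior voxel
#' until it has `cluster_voxels` members, and fixes the per-condition linear
#' amplitude model `amplitude = intercept + slope_bdi * bdi + slope_aai * aai`
#' (the AAI dependence acts on the Mother condition).
#'
#' @param spec A [cohort_spec()].
#' @return A `ground_truth` list with `cluster_indices` (0-based linear
#'   voxel indices, sorted) and `amplitude_model` (one row per condition).
#' @export
plant_truth <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  gd <- spec$grid_dims
  withr::with_seed(derive_seed(spec$seed, "cluster"), {
    # random interior seed voxel (1-based subscripts)
    start <- vapply(gd, function(d) {
      if (d >= 3L) sample(2:(d - 1L), 1L) else sample(seq_len(d), 1L)
    }, integer(1))
    in_cluster <- array(FALSE, gd)
    in_cluster[start[1], start[2], start[3]] <- TRUE
    frontier <- neighbours(start, gd)
    while (sum(in_cluster) < spec$cluster_voxels) {
      frontier <- frontier[!in_cluster[frontier], , drop = FALSE]
      if (nrow(frontier) == 0L)
        stopf("cluster growth exhausted the grid before reaching %d voxels",
              spec$cluster_voxels)
      pick <- frontier[sample.int(nrow(frontier), 1L), ]
      in_cluster[pick[1], pick[2], pick[3]] <- TRUE
      frontier <- rbind(frontier, neighbours(pick, gd))
    }
  })
  idx <- pos_to_lin(which(in_cluster))
  model <- data.frame(
    condition = CONDITIONS,
    intercept = as.numeric(spec$intercepts),
    slope_bdi = as.numeric(spec$effect_slopes),
    slope_aai = c(spec$aai_slope, 0, 0),
    stringsAsFactors = FALSE)
  structure(list(cluster_indices = sort(idx), amplitude_model = model),
            class = "ground_truth")
}

neighbours <- function(v, gd) {
  out <- rbind(v + c(1, 0, 0), v - c(1, 0, 0),
               v + c(0, 1, 0), v - c(0, 1, 0),
               v + c(0, 0, 1), v - c(0, 0, 1))
  keep <- out[, 1] >= 1 & out[, 1] <= gd[1] &
    out[, 2] >= 1 & out[, 2] <= gd[2] &
    out[, 3] >= 1 & out[, 3] <= gd[3]
  out[keep, , drop = FALSE]
}

# Per-condition amplitude for one subject under the planted model.
condition_amplitudes <- function(truth, bdi, aai) {
  m <- truth$amplitude_model
  amps <- m$intercept + m$slope_bdi * bdi + m$slope_aai * aai
  names(amps) <- m$condition
  amps
}

#' Build randomized event schedules
#'
#' Per run, `events_per_condition` events of each of M, F and S are placed
#' at distinct frames of the TR grid in randomized order (so condition
#' counts are exactly balanced and events never overlap). Event duration is
#' one TR.
#'
#' @param spec A [cohort_spec()].
#' @return An `event_schedule`: a list of `n_runs` data frames with columns
#'   `condition`, `onset` (s), `duration` (s).
#' @export
make_event_schedule <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_frames <- frames_per_run(spec)
  n_ev <- 3L * spec$events_per_condition
  if (n_ev > n_frames)
    stopf("run too short: %d events requested but only %d frames", n_ev,
          n_frames)
  runs <- lapply(seq_len(spec$n_runs), function(r) {
    withr::with_seed(derive_seed(spec$seed, "schedule", r), {
      frames <- sort(sample(0:(n_frames - 1L), n_ev))
      conds <- sample(rep(CONDITIONS, spec$events_per_condition))
    })
    data.frame(condition = conds, onset = frames * spec$tr,
               duration = spec$tr, stringsAsFactors = FALSE)
  })
  structure(runs, class = "event_schedule")
}

#' Render a subject's contrast maps directly
#'
#' The fast path standing in for the full first-level analysis: each
#' contrast map equals the planted amplitude difference evaluated at the
#' subject's (bdi, aai) on cluster voxels, zero elsewhere, plus i.i.d.
#' Gaussian noise of SD `noise_sd` at every voxel. Variance maps are the
#' constant `noise_sd^2` (the true observation variance of this generative
#' model).
#'
#' @param subject One row of a cohort data frame.
#' @param truth A [plant_truth()] object.
#' @param spec A [cohort_spec()].
#' @return A `contrast_set` (see [contrast_set()]), deterministic given
#'   `spec$seed` and `subject$subject_id`.
#' @export
render_contrast_maps <- function(subject, truth, spec) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(truth, "ground_truth"))
  amps <- condition_amplitudes(truth, subject$bdi, subject$aai)
  deltas <- c("M-F" = amps[["M"]] - amps[["F"]],
              "M-S" = amps[["M"]] - amps[["S"]],
              "F-S" = amps[["F"]] - amps[["S"]])
  gd <- spec$grid_dims
  nv <- prod(gd)
  maps <- withr::with_seed(
    derive_seed(spec$seed, "contrast", subject$subject_id),
    lapply(CONTRAST_KEYS, function(k) {
      vals <- rnorm(nv, 0, spec$noise_sd)
      vals[lin_to_pos(truth$cluster_indices)] <-
        vals[lin_to_pos(truth$cluster_indices)] + deltas[[k]]
      new_volume(array(vals, gd), voxel_dims = spec$voxel_dims)
    }))
  names(maps) <- CONTRAST_KEYS
  variances <- lapply(CONTRAST_KEYS, function(k) {
    new_volume(array(spec$noise_sd^2, gd), voxel_dims = spec$voxel_dims)
  })
  names(variances) <- CONTRAST_KEYS
  contrast_set(maps, variances)
}

#' Render a subject's 4-D BOLD run
#'
#' The time series at each cluster voxel is `baseline` plus the sum over
#' conditions of the planted amplitude times the event indicator convolved
#' with the canonical HRF (sampled at TR); non-cluster voxels carry the
#' baseline only. i.i.d. Gaussian noise of SD `noise_sd` is added everywhere
#' in space and time (white noise -- no drift, no autocorrelation).
#'
#' @param subject One row of a cohort data frame.
#' @param schedule_run One run's event data frame (from
#'   [make_event_schedule()]).
#' @param truth A [plant_truth()] object.
#' @param spec A [cohort_spec()].
#' @param run Run index, used only to separate noise streams.
#' @return A 4-D [new_volume()], `grid_dims x frames_per_run(spec)`.
#' @export
render_bold_run <- function(subject, schedule_run, truth, spec, run = 1L) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(truth, "ground_truth"))
  n_frames <- frames_per_run(spec)
  amps <- condition_amplitudes(truth, subject$bdi, subject$aai)
  regs <- vapply(CONDITIONS, function(cond) {
    ev <- schedule_run[schedule_run$condition == cond, , drop = FALSE]
    convolve_events(ev, n_frames, spec$tr)
  }, numeric(n_frames))
  signal <- as.numeric(regs %*% amps[CONDITIONS])  # frames
  gd <- spec$grid_dims
  nv <- prod(gd)
  dat <- withr::with_seed(
    derive_seed(spec$seed, "bold", subject$subject_id, run),
    matrix(rnorm(nv * n_frames, 0, spec$noise_sd), nv, n_frames))
  dat <- dat + spec$baseline
  cl <- lin_to_pos(truth$cluster_indices)
  dat[cl, ] <- dat[cl, ] + rep(signal, each = length(cl))
  new_volume(array(dat, c(gd, n_frames)), voxel_dims = spec$voxel_dims)
}

#' Simulate a full cohort
#'
#' Draws traits, plants the cluster, and renders per-subject data --
#' contrast maps directly (`mode = "contrast"`, the fast path) or 4-D BOLD
#' runs plus schedules (`mode = "bold"`).
#'
#' @param spec A [cohort_spec()].
#' @param mode `"contrast"` or `"bold"`.
#' @return A list with `records` (cohort data frame), `truth`, and either
#'   `contrast_sets` (named per subject) or `runs` + `schedule`.
#' @export
simulate_cohort <- function(spec, mode = c("contrast", "bold")) {
  mode <- match.arg(mode)
  records <- sample_cohort_traits(spec)
  truth <- plant_truth(spec)
  out <- list(records = records, truth = truth, spec = spec)
  if (mode == "contrast") {
    cs <- lapply(seq_len(nrow(records)), function(i)
      render_contrast_maps(records[i, ], truth, spec))
    names(cs) <- records$subject_id
    out$contrast_sets <- cs
  } else {
    schedule <- make_event_schedule(spec)
    out$schedule <- schedule
    out$runs <- lapply(seq_len(nrow(records)), function(i) {
      lapply(seq_len(spec$n_runs), function(r)
        render_bold_run(records[i, ], schedule[[r]], truth, spec, run = r))
    })
    names(out$runs) <- records$subject_id
  }
  out
}

#' Write a simulated cohort to disk
#'
#' Layout: `dir/participants.csv`, `dir/truth.json`, and per subject either
#' `dir/<id>/con-<key>.nii.gz` (+ matching `var-<key>.nii.gz`) or
#' `dir/<id>/run-<k>.nii.gz` with `dir/events-run-<k>.csv`.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(sim$records, file.path(dir, "participants.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(cluster_indices = sim$truth$cluster_indices,
         amplitude_model = sim$truth$amplitude_model),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  for (id in sim$records$subject_id) {
    sdir <- file.path(dir, id)
    dir.create(sdir, showWarnings = FALSE)
    if (!is.null(sim$contrast_sets)) {
      cs <- sim$contrast_sets[[id]]
      for (k in CONTRAST_KEYS) {
        save_volume(cs$maps[[k]], file.path(sdir, sprintf("con-%s.nii.gz", k)))
        save_volume(cs$variances[[k]],
                    file.path(sdir, sprintf("var-%s.nii.gz", k)))
      }
    } else {
      for (r in seq_along(sim$runs[[id]]))
        save_volume(sim$runs[[id]][[r]],
                    file.path(sdir, sprintf("run-%d.nii.gz", r)))
    }
  }
  if (!is.null(sim$schedule)) {
    for (r in seq_along(sim$schedule))
      write.csv(sim$schedule[[r]],
                file.path(dir, sprintf("events-run-%d.csv", r)),
                row.names = FALSE)
  }
  invisible(dir)
}

#' Read a contrast-mode cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A list with `records` and `contrast_sets`.
#' @export
read_cohort <- function(dir) {
  records <- load_cohort_table(file.path(dir, "participants.csv"))
  cs <- lapply(records$subject_id, function(id) {
    maps <- lapply(CONTRAST_KEYS, function(k)
      load_volume(file.path(dir, id, sprintf("con-%s.nii.gz", k))))
    names(maps) <- CONTRAST_KEYS
    vars <- lapply(CONTRAST_KEYS, function(k) {
      p <- file.path(dir, id, sprintf("var-%s.nii.gz", k))
      if (file.exists(p)) load_volume(p) else NULL
    })
    names(vars) <- CONTRAST_KEYS
    if (any(vapply(vars, is.null, logical(1)))) vars <- NULL
    contrast_set(maps, vars)
  })
  names(cs) <- records$subject_id
  list(records = records, contrast_sets = cs)
}
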