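# Synthetic cohort generator: trait sampling, schedules, planted signal.

test_that("trait sampling matches the cohort design and is seed-deterministic", {
  spec <- cohort_spec(seed = 11)
  rec <- sample_cohort_traits(spec)
  expect_equal(nrow(rec), 28L)
  expect_equal(as.vector(table(rec$group)), c(14L, 14L))
  expect_identical(rec, sample_cohort_traits(spec))
  expect_false(identical(rec, sample_cohort_traits(cohort_spec(seed = 12))))
})

test_that("trait sampler hits the documented score bounds exhaustively", {
  spec <- cohort_spec(n_control = 5000L, n_depressed = 5000L, seed = 13)
  rec <- sample_cohort_traits(spec)
  ctrl <- rec$bdi[rec$group == "control"]
  dep <- rec$bdi[rec$group == "depressed"]
  expect_identical(range(ctrl), c(0L, 12L))
  expect_identical(range(dep), c(11L, 54L))
  expect_true(all(rec$aai >= 1 & rec$aai <= 9))
  # configurable negative bdi-aai correlation
  expect_lt(cor(rec$bdi, rec$aai), -0.3)
  rec0 <- sample_cohort_traits(cohort_spec(n_control = 5000L,
                                           n_depressed = 5000L,
                                           aai_bdi_weight = 0, seed = 13))
  expect_lt(abs(cor(rec0$bdi, rec0$aai)), 0.05)
})

test_that("event schedules are balanced, non-overlapping, on-grid and deterministic", {
  spec <- cohort_spec(seed = 21)
  expect_equal(frames_per_run(spec), 378L)  # 12.6 min * 60 / 2 s
  sched <- make_event_schedule(spec)
  expect_length(sched, spec$n_runs)
  for (run in sched) {
    counts <- table(run$condition)
    expect_true(max(counts) - min(counts) <= 1L)
    expect_true(all(run$onset >= 0 & run$onset < spec$run_minutes * 60))
    expect_false(any(duplicated(run$onset)))   # duration = 1 TR, on-grid
    expect_true(all(run$onset %% spec$tr == 0))
  }
  expect_identical(sched, make_event_schedule(spec))
  expect_error(make_event_schedule(cohort_spec(run_minutes = 0.5, seed = 1)),
               "too short")
})

test_that("contrast maps equal the planted amplitude differences at zero noise", {
  spec <- tiny_spec(noise_sd = 0)
  truth <- plant_truth(spec)
  rec <- sample_cohort_traits(spec)
  sub <- rec[rec$group == "depressed", ][1, ]
  cs <- render_contrast_maps(sub, truth, spec)
  m <- truth$amplitude_model
  amp <- function(cond) {
    r <- m[m$condition == cond, ]
    r$intercept + r$slope_bdi * sub$bdi + r$slope_aai * sub$aai
  }
  cl <- truth$cluster_indices + 1L
  expect_equal(unique(as.numeric(cs$maps[["M-S"]]$data)[cl]),
               amp("M") - amp("S"), tolerance = 1e-12)
  expect_equal(unique(as.numeric(cs$maps[["M-F"]]$data)[cl]),
               amp("M") - amp("F"), tolerance = 1e-12)
  out <- setdiff(seq_along(cs$maps[["M-S"]]$data), cl)
  expect_true(all(cs$maps[["M-S"]]$data[out] == 0))

  flat <- tiny_spec(noise_sd = 0, effect_slopes = c(M = 0, F = 0, S = 0),
                    aai_slope = 0, intercepts = c(M = 0, F = 0, S = 0))
  cs0 <- render_contrast_maps(sub, plant_truth(flat), flat)
  for (k in c("M-F", "M-S", "F-S"))
    expect_true(all(cs0$maps[[k]]$data == 0))
})

test_that("contrast noise has the specified SD and is reproducible per subject", {
  spec <- tiny_spec(noise_sd = 1,
                    effect_slopes = c(M = 0, F = 0, S = 0), aai_slope = 0,
                    intercepts = c(M = 0, F = 0, S = 0),
                    grid_dims = c(12L, 12L, 8L), cluster_voxels = 2L)
  truth <- plant_truth(spec)
  sub <- sample_cohort_traits(spec)[1, ]
  cs <- render_contrast_maps(sub, truth, spec)
  # >1000 i.i.d. draws per map: the sample SD must sit within 5% of 1
  for (k in c("M-F", "M-S", "F-S"))
    expect_equal(sd(as.numeric(cs$maps[[k]]$data)), 1, tolerance = 0.05)
  cs2 <- render_contrast_maps(sub, truth, spec)
  expect_identical(cs$maps[["M-F"]]$data, cs2$maps[["M-F"]]$data)
  sub2 <- sub; sub2$subject_id <- "sub-xx"
  cs3 <- render_contrast_maps(sub2, truth, spec)
  expect_false(identical(cs$maps[["M-F"]]$data, cs3$maps[["M-F"]]$data))
})

test_that("BOLD renders peak ~5 s after a lone Mother event and are flat without signal", {
  spec <- tiny_spec(noise_sd = 0, run_minutes = 2, n_runs = 1L,
                    events_per_condition = 1L)
  truth <- plant_truth(spec)
  sub <- sample_cohort_traits(spec)[15, ]  # a depressed subject
  sched <- data.frame(condition = "M", onset = 20, duration = spec$tr)
  run <- render_bold_run(sub, sched, truth, spec)
  vox <- truth$cluster_indices[1] + 1L
  nf <- frames_per_run(spec)
  ts <- matrix(run$data, ncol = nf)[vox, ]
  peak_t <- (which.max(ts) - 1L) * spec$tr
  expect_true(abs(peak_t - (20 + 5)) <= spec$tr)

  flat <- tiny_spec(noise_sd = 0, run_minutes = 2, n_runs = 1L,
                    effect_slopes = c(M = 0, F = 0, S = 0), aai_slope = 0,
                    intercepts = c(M = 0, F = 0, S = 0))
  run0 <- render_bold_run(sub, sched, plant_truth(flat), flat)
  expect_true(all(run0$data == flat$baseline))
})

test_that("the first-level pipeline recovers planted contrasts from a zero-noise render", {
  spec <- tiny_spec(noise_sd = 0, run_minutes = 3, n_runs = 2L,
                    events_per_condition = 8L)
  truth <- plant_truth(spec)
  sim <- simulate_cohort(spec, mode = "bold")
  sub <- sim$records[20, ]
  runs <- lapply(seq_len(spec$n_runs), function(r)
    render_bold_run(sub, sim$schedule[[r]], truth, spec, run = r))
  cs <- suppressWarnings(
    subject_contrasts(runs, sim$schedule, tr = spec$tr, fwhm_mm = 0))
  m <- truth$amplitude_model
  amp <- m$intercept + m$slope_bdi * sub$bdi + m$slope_aai * sub$aai
  names(amp) <- m$condition
  planted <- c("M-F" = amp[["M"]] - amp[["F"]],
               "M-S" = amp[["M"]] - amp[["S"]],
               "F-S" = amp[["F"]] - amp[["S"]])
  cl <- truth$cluster_indices + 1L
  for (k in names(planted)) {
    est <- as.numeric(cs$maps[[k]]$data)[cl]
    expect_equal(est, rep(planted[[k]], length(cl)),
                 tolerance = 0.01, ignore_attr = TRUE)
  }
})

test_that("planted clusters are contiguous, in-grid and of the requested size", {
  spec <- tiny_spec(cluster_voxels = 25L)
  truth <- plant_truth(spec)
  idx <- truth$cluster_indices
  expect_length(idx, 25L)
  expect_false(any(duplicated(idx)))
  expect_true(all(idx >= 0 & idx < prod(spec$grid_dims)))
  # contiguity: every voxel has a 6-neighbour in the cluster
  sub <- arrayInd(idx + 1L, spec$grid_dims)
  for (i in seq_len(nrow(sub))) {
    d <- abs(sweep(sub[-i, , drop = FALSE], 2L, sub[i, ]))
    expect_true(any(rowSums(d) == 1L))
  }
})

test_that("cohort directories round-trip through write_cohort/read_cohort", {
  spec <- tiny_spec(n_control = 3L, n_depressed = 3L)
  sim <- simulate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  back <- read_cohort(dir)
  expect_equal(back$records$subject_id, sim$records$subject_id)
  expect_equal(back$records$aai, sim$records$aai, tolerance = 1e-12)
  for (id in sim$records$subject_id)
    expect_equal(back$contrast_sets[[id]]$maps[["M-S"]]$data,
                 sim$contrast_sets[[id]]$maps[["M-S"]]$data, tolerance = 0)
})
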