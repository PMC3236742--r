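# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

# A desk-scale spec for fast unit tests (small grid, strong planted effect).
tiny_spec <- function(seed = 42L, ...) {
  args <- list(grid_dims = c(8L, 8L, 6L), cluster_voxels = 12L,
               noise_sd = 0.2, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_spec, args)
}

# Build a contrast_set directly from three 3-D arrays (and optional
# variance arrays), bypassing the simulator.
make_contrast_set <- function(mf, ms, fs, var = NULL, voxel_dims = c(2, 2, 3)) {
  maps <- list("M-F" = new_volume(mf, voxel_dims),
               "M-S" = new_volume(ms, voxel_dims),
               "F-S" = new_volume(fs, voxel_dims))
  vars <- NULL
  if (!is.null(var)) {
    vars <- list("M-F" = new_volume(var, voxel_dims),
                 "M-S" = new_volume(var, voxel_dims),
                 "F-S" = new_volume(var, voxel_dims))
  }
  contrast_set(maps, vars)
}

# A group_zmaps object with prescribed Z values, for select_roi tests.
make_zmaps <- function(zlist, grid_dims) {
  z <- lapply(c("M-F", "M-S", "F-S"), function(k) {
    per <- lapply(c("BDI", "AAI"), function(r) {
      key <- paste(k, r, sep = ":")
      dat <- if (key %in% names(zlist)) zlist[[key]] else array(0, grid_dims)
      new_volume(dat, allow_nonfinite = TRUE)
    })
    names(per) <- c("BDI", "AAI")
    per
  })
  names(z) <- c("M-F", "M-S", "F-S")
  structure(list(z = z, dof = 24L, grid_dims = as.integer(grid_dims)),
            class = "group_zmaps")
}

# Cohort whose ROI features are an exact linear function of (bdi, aai)
# with two degrees of freedom -- the noiseless regime in which the PCR
# model is exactly identified.
make_linear_cohort <- function(n = 10L, p = 30L, seed = 5L) {
  withr::with_seed(seed, {
    bdi <- sample(0:54, n)
    aai <- runif(n, 1, 9)
    pat1 <- rnorm(p)
    pat2 <- rnorm(p)
    base <- rnorm(p)
  })
  X <- outer(rep(1, n), base) + outer(bdi, pat1) + outer(aai, pat2)
  list(features = X, bdi = bdi, aai = aai)
}
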