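# NIfTI volume and cohort-table I/O.
#
# Conventions fixed here and relied on by every downstream module:
#   * NIfTI-1 is the only imaging dialect; when both qform and sform are
#     present the sform is preferred (the common tool convention).
#   * Voxel indices are 0-based, axis order (x, y, z), x fastest when
#     linearized -- this matches R's native array storage order, so the
#     0-based linear index of array position p is simply p - 1.
#   * BDI-II scores are integers on [0, 63]; AAI coherence scores are reals
#     on [1, 9] (sub-point AAI scores occur in practice).

#' Construct a volume object
#'
#' A `volume` is a 3-D or 4-D numeric array (time last for 4-D) together with
#' the physical voxel edge lengths in mm and a 4x4 grid-to-world affine.
#'
#' @param data Numeric 3-D or 4-D array.
#' @param voxel_dims Length-3 positive numeric, mm per axis.
#' @param affine 4x4 grid-to-world transform; defaults to a scaling by
#'   `voxel_dims`.
#' @param allow_nonfinite Permit non-finite voxel values (default `FALSE`).
#' @return An object of class `volume`.
#' @export
new_volume <- function(data, voxel_dims = c(1, 1, 1), affine = NULL,
                       allow_nonfinite = FALSE) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L))
    stopf("volume data must be 3-D or 4-D, got %d dimensions", nd)
  data <- array(as.numeric(data), dim(data))  # plain array, no extra attrs
  voxel_dims <- as.numeric(voxel_dims)
  if (length(voxel_dims) != 3L || any(!is.finite(voxel_dims)) ||
      any(voxel_dims <= 0))
    stopf("voxel_dims must be 3 strictly positive numbers")
  if (is.null(affine)) affine <- diag(c(voxel_dims, 1))
  affine <- matrix(as.numeric(affine), 4, 4)
  if (!allow_nonfinite && any(!is.finite(data))) {
    stopf("volume contains %d non-finite voxel values",
          sum(!is.finite(data)))
  }
  structure(list(data = data, voxel_dims = voxel_dims, affine = affine),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume> %s grid, voxel %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(x$voxel_dims, collapse = "x")))
  invisible(x)
}

grid_dims <- function(vol) dim(vol$data)[1:3]

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param allow_nonfinite Permit non-finite voxels in the file; by default
#'   they are an error (reported with a count).
#' @return A [new_volume()] object preserving the file's data, voxel
#'   dimensions and (sform-preferred) affine.
#' @export
load_volume <- function(path, allow_nonfinite = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) {
                    stopf("malformed NIfTI file '%s': %s", path,
                          conditionMessage(e))
                  })
  data <- as.array(img)
  nd <- length(dim(data))
  if (nd == 2L) dim(data) <- c(dim(data), 1L)  # degenerate single-slice file
  vd <- RNifti::pixdim(img)[1:3]
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  aff <- matrix(as.numeric(aff), 4, 4)
  new_volume(data, voxel_dims = vd, affine = aff,
             allow_nonfinite = allow_nonfinite)
}

#' Write a volume as NIfTI-1
#'
#' Data are stored as 64-bit floats so that [load_volume()] recovers them
#' bit-identically.
#'
#' @param vol A [new_volume()] object.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stopf("directory does not exist: %s", dir)
  img <- RNifti::asNifti(vol$data)
  nd <- length(dim(vol$data))
  RNifti::pixdim(img) <- if (nd == 4L) c(vol$voxel_dims, 1) else vol$voxel_dims
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read and validate a cohort table
#'
#' The table is a comma-separated UTF-8 file with header columns
#' `subject_id`, `group`, `bdi`, `aai`. Validation is strict: scores outside
#' the instrument ranges (BDI-II 0-63 integer, AAI 1-9) or duplicated
#' subject ids are errors naming the offending row -- values are never
#' silently clamped.
#'
#' @param path CSV path.
#' @return A data frame with one row per subject; `group` is a factor with
#'   levels `control`, `depressed`.
#' @export
load_cohort_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stopf("cannot parse cohort table '%s': %s",
                                            path, conditionMessage(e)))
  validate_cohort(tab)
}

validate_cohort <- function(tab) {
  need <- c("subject_id", "group", "bdi", "aai")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stopf("cohort table missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(tab) == 0L) stopf("cohort table has no subject rows")
  tab$subject_id <- as.character(tab$subject_id)
  dup <- tab$subject_id[duplicated(tab$subject_id)]
  if (length(dup))
    stopf("duplicate subject_id: %s", paste(unique(dup), collapse = ", "))
  if (!all(tab$group %in% c("control", "depressed")))
    stopf("group must be 'control' or 'depressed' (rows %s)",
          paste(which(!tab$group %in% c("control", "depressed")),
                collapse = ", "))
  bad_bdi <- which(!is.finite(tab$bdi) | tab$bdi < 0 | tab$bdi > 63 |
                     tab$bdi != round(tab$bdi))
  if (length(bad_bdi))
    stopf("bdi must be an integer in [0, 63]; invalid in row(s) %s",
          paste(bad_bdi, collapse = ", "))
  bad_aai <- which(!is.finite(tab$aai) | tab$aai < 1 | tab$aai > 9)
  if (length(bad_aai))
    stopf("aai must be in [1, 9]; invalid in row(s) %s",
          paste(bad_aai, collapse = ", "))
  tab$bdi <- as.integer(tab$bdi)
  tab$aai <- as.numeric(tab$aai)
  tab$group <- factor(tab$group, levels = c("control", "depressed"))
  tab[need]
}

#' Write per-subject predictions as CSV
#'
#' @param predictions Data frame with columns `subject_id`, `bdi_measured`,
#'   `bdi_predicted`, `depressed_measured`, `depressed_predicted`,
#'   `aai_measured`, `aai_predicted`, `insecure_predicted` (one row per
#'   subject; zero rows writes a header-only file).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  need <- c("subject_id", "bdi_measured", "bdi_predicted",
            "depressed_measured", "depressed_predicted",
            "aai_measured", "aai_predicted", "insecure_predicted")
  miss <- setdiff(need, names(predictions))
  if (length(miss))
    stopf("predictions missing column(s): %s", paste(miss, collapse = ", "))
  write.csv(predictions[need], path, row.names = FALSE)
  invisible(path)
}

#' Read a run event file
#'
#' A comma- or tab-separated 3-column file (`condition`, `onset_s`,
#' `duration_s`), with or without a header row. Conditions must be drawn
#' from `M`, `F`, `S`.
#'
#' @param path Event file path.
#' @return Data frame with columns `condition`, `onset`, `duration` (s).
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  header <- grepl("condition", first, ignore.case = TRUE)
  tab <- read.csv(path, sep = sep, header = header, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stopf("event file needs 3 columns, got %d", ncol(tab))
  names(tab)[1:3] <- c("condition", "onset", "duration")
  tab$condition <- as.character(tab$condition)
  if (!all(tab$condition %in% CONDITIONS))
    stopf("event conditions must be in {M, F, S}")
  if (any(!is.finite(tab$onset)) || any(tab$onset < 0))
    stopf("event onsets must be non-negative seconds")
  tab[1:3]
}
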