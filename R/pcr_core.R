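# Principal component regression core.
#
# Two principal components are extracted from the sample subjects' ROI
# features; each subject's activity is then summarised by the multiple
# linear regression coefficients of their (uncentered) feature vector on
# [PC1, PC2, constant 1]. Stacking these rows gives the sample weights
# matrix W (n x 3, last column exactly 1); the psychometrics matrix Y
# (n x 2, columns BDI-II and AAI) is mapped from W by the Moore-Penrose
# pseudoinverse solution ModelMap = pinv(W) %*% Y, and a held-out subject's
# scores are predicted as [w1, w2, 1] %*% ModelMap.

#' Extract principal components of the sample features
#'
#' Components are the top-`k` right singular vectors of the column-mean-
#' centered sample matrix. Signs are fixed deterministically: each
#' component's largest-magnitude loading is made positive. The sample
#' column mean is stored so held-out subjects are projected against the
#' sample geometry (never their own).
#'
#' @param features Sample feature matrix, subjects x features.
#' @param k Number of components (default 2).
#' @return A `pc_basis`: `components` (features x k, orthonormal), `mean`,
#'   `explained_fraction` (non-increasing, sums to <= 1), `k`.
#' @export
extract_pcs <- function(features, k = 2L) {
  features <- as.matrix(features)
  if (any(!is.finite(features))) stopf("features contain non-finite values")
  n <- nrow(features)
  if (n < k + 1L) stopf("need at least %d sample rows for %d components",
                        k + 1L, k)
  # A centered n x p sample supports at most min(n - 1, p) components; data
  # that are numerically degenerate within that bound still yield a valid
  # orthonormal basis (trailing components carry ~0 explained variance).
  max_k <- min(n - 1L, ncol(features))
  if (k > max_k)
    stopf("requested %d components but the centered sample matrix has rank at most %d",
          k, max_k)
  mu <- colMeans(features)
  Xc <- sweep(features, 2L, mu)
  sv <- svd(Xc)
  comp <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    lead <- which.max(abs(comp[, j]))
    if (comp[lead, j] < 0) comp[, j] <- -comp[, j]
  }
  total <- sum(sv$d^2)
  structure(list(components = comp, mean = mu,
                 explained_fraction = (sv$d[seq_len(k)]^2) / total,
                 k = as.integer(k)),
            class = "pc_basis")
}

#' Per-subject PC weights
#'
#' OLS of the feature vector, centered by the stored *sample* mean, on
#' [PC1, ..., PCk, constant 1]; the fitted intercept is discarded and
#' replaced by the constant 1, so the returned row has the weights-matrix
#' layout (w1, w2, 1). Centering by the sample mean makes the weights the
#' subject's deviation-from-sample loadings (so `feature = mean + 2 PC1`
#' gives exactly (2, 0, 1)) and shifts every subject's raw-regression
#' weights by one common constant -- a shift the model map's intercept row
#' absorbs, so predictions are unaffected by the convention.
#'
#' @param feature_vector One subject's features.
#' @param basis A [extract_pcs()] basis.
#' @return Named numeric of length `k + 1`: PC coefficients then the
#'   constant 1.
#' @export
subject_weights <- function(feature_vector, basis) {
  stopifnot(inherits(basis, "pc_basis"))
  feature_vector <- as.numeric(feature_vector)
  if (length(feature_vector) != nrow(basis$components))
    stopf("feature vector length %d does not match the basis (%d)",
          length(feature_vector), nrow(basis$components))
  X <- cbind(basis$components, 1)
  b <- qr.solve(X, feature_vector - basis$mean)
  out <- c(b[seq_len(basis$k)], 1)
  names(out) <- c(paste0("w", seq_len(basis$k)), "const")
  out
}

#' Moore-Penrose pseudoinverse
#'
#' SVD-based; singular values below `rtol * max(d)` (with
#' `rtol = max(dim) * .Machine$double.eps`) are treated as zero, so the
#' returned solution of a rank-deficient system is the minimum-norm one.
#'
#' @param A Numeric matrix.
#' @return `pinv(A)`.
#' @export
pinv <- function(A) {
  A <- as.matrix(A)
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  sv$v[, pos, drop = FALSE] %*%
    ((1 / sv$d[pos]) * t(sv$u[, pos, drop = FALSE]))
}

#' Fit the model map
#'
#' `ModelMap = pinv(W) %*% Y`: the minimum-Frobenius-norm least-squares
#' 3 x 2 matrix sending each sample row (w1, w2, 1) to (BDI-II, AAI).
#'
#' @param W Sample weights matrix (n x 3, third column 1).
#' @param Y Sample psychometrics matrix (n x 2, columns BDI-II then AAI),
#'   rows aligned with `W`.
#' @return A `model_map`: 3 x 2 numeric matrix, columns `bdi`, `aai`.
#' @export
fit_model_map <- function(W, Y) {
  W <- as.matrix(W); Y <- as.matrix(Y)
  if (nrow(W) != nrow(Y))
    stopf("W has %d rows but Y has %d", nrow(W), nrow(Y))
  if (nrow(W) < 3L) stopf("need at least 3 sample rows")
  if (any(!is.finite(W)) || any(!is.finite(Y)))
    stopf("non-finite values in the weights or psychometrics")
  map <- pinv(W) %*% Y
  colnames(map) <- c("bdi", "aai")
  rownames(map) <- c(paste0("w", seq_len(nrow(map) - 1L)), "const")
  structure(map, class = c("model_map", "matrix"))
}

#' Predict psychometric scores
#'
#' `[bdi_pred, aai_pred] = row %*% map` -- linear, never clipped to the
#' instrument ranges.
#'
#' @param weights_row A [subject_weights()] row (w1, w2, 1).
#' @param map A [fit_model_map()] map.
#' @return Named numeric: `bdi_pred`, `aai_pred`.
#' @export
predict_scores <- function(weights_row, map) {
  stopifnot(inherits(map, "model_map"))
  if (length(weights_row) != nrow(map))
    stopf("weights row length %d does not match the map (%d rows)",
          length(weights_row), nrow(map))
  out <- as.numeric(weights_row %*% unclass(map))
  names(out) <- c("bdi_pred", "aai_pred")
  out
}

#' Classifier cut-offs
#'
#' @param bdi_cut Predicted-BDI cut for depression (default 13.5 -- the
#'   clinical cut-score of 14 shifted half a point to handle continuous
#'   predictions).
#' @param aai_cut Predicted-AAI cut for insecure attachment (default 4).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(bdi_cut = 13.5, aai_cut = 4) {
  check_scalar_number(bdi_cut, "bdi_cut", 0 + .Machine$double.eps, 63)
  check_scalar_number(aai_cut, "aai_cut", 1, 9)
  structure(list(bdi_cut = bdi_cut, aai_cut = aai_cut),
            class = "classifier_config")
}

#' Categorical depression call
#'
#' Depressed iff `bdi_pred > bdi_cut`, strictly.
#'
#' @param scores A [predict_scores()] result.
#' @param cfg A [classifier_config()].
#' @return `"depressed"` or `"not_depressed"`.
#' @export
classify_depression <- function(scores, cfg = classifier_config()) {
  if (!is.finite(scores[["bdi_pred"]])) stopf("bdi_pred is not finite")
  if (scores[["bdi_pred"]] > cfg$bdi_cut) "depressed" else "not_depressed"
}

#' Categorical attachment call
#'
#' Insecure iff `aai_pred < aai_cut`, strictly.
#'
#' @param scores A [predict_scores()] result.
#' @param cfg A [classifier_config()].
#' @return `"insecure"` or `"not_insecure"`.
#' @export
classify_attachment <- function(scores, cfg = classifier_config()) {
  if (!is.finite(scores[["aai_pred"]])) stopf("aai_pred is not finite")
  if (scores[["aai_pred"]] < cfg$aai_cut) "insecure" else "not_insecure"
}

#' Serialize a fitted fold to JSON
#'
#' Stores the PC basis, model map and feature-ordering metadata (mask
#' indices + contrast block order) at full double precision so the artifact
#' reloads bit-exactly.
#'
#' @param basis A [extract_pcs()] basis.
#' @param map A [fit_model_map()] map.
#' @param mask The [roi_mask()] the features were assembled from.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_artifact <- function(basis, map, mask, path) {
  obj <- list(
    contrast_block_order = CONTRAST_KEYS,
    mask = list(indices = mask$indices, grid_dims = mask$grid_dims),
    basis = list(components = unclass(basis$components),
                 mean = unname(basis$mean),
                 explained_fraction = basis$explained_fraction,
                 k = basis$k),
    model_map = unclass(map))
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Reload a fold artifact written by [write_model_artifact()]
#'
#' @param path JSON path.
#' @return List with `basis`, `map`, `mask`, `contrast_block_order`.
#' @export
read_model_artifact <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  basis <- structure(list(components = as.matrix(obj$basis$components),
                          mean = as.numeric(obj$basis$mean),
                          explained_fraction =
                            as.numeric(obj$basis$explained_fraction),
                          k = as.integer(obj$basis$k)),
                     class = "pc_basis")
  map <- as.matrix(obj$model_map)
  colnames(map) <- c("bdi", "aai")
  rownames(map) <- c(paste0("w", seq_len(nrow(map) - 1L)), "const")
  list(basis = basis,
       map = structure(map, class = c("model_map", "matrix")),
       mask = roi_mask(obj$mask$indices, obj$mask$grid_dims),
       contrast_block_order = obj$contrast_block_order)
}
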