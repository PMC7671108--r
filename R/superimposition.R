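#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid — the size measure removed during Procrustes
#' superimposition and used downstream as "body size".
#'
#' @param config a [landmark_config] or a k x 2 coordinate matrix.
#' @return positive numeric scalar.
#' @export
centroid_size <- function(config) {
  m <- coords_of(config)
  if (nrow(m) < 2L) stop("centroid size needs at least 2 landmarks")
  ctr <- colMeans(m)
  cs <- sqrt(sum((m[, 1] - ctr[1])^2 + (m[, 2] - ctr[2])^2))
  if (cs == 0) stop("degenerate configuration: all landmarks coincide")
  cs
}

coords_of <- function(config) {
  if (inherits(config, "landmark_config")) config$coords else as.matrix(config)
}

# Center a k x 2 matrix and scale it to unit centroid size.
center_scale <- function(m) {
  m <- sweep(m, 2L, colMeans(m))
  m / sqrt(sum(m^2))
}

#' Ordinary Procrustes alignment of one configuration onto a reference
#'
#' Centers and scales both configurations to unit centroid size, then
#' rotates the target by the closed-form 2-D orthogonal solution that
#' minimizes the summed squared distance to the reference. Reflections are
#' blocked (rotation determinant constrained positive) unless
#' `allow_reflection = TRUE`.
#'
#' @param reference,target k x 2 coordinate matrices or [landmark_config]s
#'   with equal k.
#' @param allow_reflection permit an improper rotation.
#' @return list with `aligned` (the transformed target), `reference` (the
#'   centered, unit-size reference), `rotation` (2 x 2) and `residual` (the
#'   minimized Procrustes distance).
#' @export
align_pair <- function(reference, target, allow_reflection = FALSE) {
  X <- coords_of(reference); Y <- coords_of(target)
  if (nrow(X) != nrow(Y))
    stop("landmark count mismatch: reference has ", nrow(X),
         ", target has ", nrow(Y))
  X <- center_scale(X)
  Y <- center_scale(Y)
  R <- optimal_rotation(Y, X, allow_reflection)
  A <- Y %*% R
  list(aligned = A, reference = X, rotation = R,
       residual = sqrt(sum((A - X)^2)))
}

# Orthogonal matrix R minimizing ||Y R - X||_F. The proper-rotation case
# has a closed 2-D solution (angle = atan2 of the cross and dot sums);
# the reflection-permitting case goes through the SVD.
optimal_rotation <- function(Y, X, allow_reflection = FALSE) {
  if (!allow_reflection) {
    num <- sum(Y[, 1L] * X[, 2L] - Y[, 2L] * X[, 1L])
    den <- sum(Y[, 1L] * X[, 1L] + Y[, 2L] * X[, 2L])
    th <- atan2(num, den)
    return(matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, 2L))
  }
  s <- svd(crossprod(Y, X))
  s$u %*% t(s$v)
}

#' Slide semilandmarks along their tangents toward a reference
#'
#' Each sliding semilandmark is moved along its tangent direction — the
#' unit chord from its `before` to its `after` neighbour — by the scalar
#' that minimizes the summed squared distance to the reference (the
#' closed-form projection of the residual onto the tangent). Tangents are
#' evaluated on the input configuration, and the two fixed endpoint
#' landmarks are never moved. The slid configuration is returned without
#' re-normalization; callers inside GPA re-center and re-scale afterwards.
#'
#' @param config k x 2 matrix, already superimposed on `reference`.
#' @param reference k x 2 matrix in the same frame.
#' @param sliders integer matrix of (before, slider, after) 1-based rows.
#' @return the slid k x 2 coordinate matrix.
#' @export
slide_semilandmarks <- function(config, reference, sliders) {
  P <- coords_of(config); Rf <- coords_of(reference)
  if (nrow(P) != nrow(Rf)) stop("landmark count mismatch")
  validate_sliders(sliders, k = nrow(P))
  tang <- P[sliders[, 3L], , drop = FALSE] - P[sliders[, 1L], , drop = FALSE]
  len <- sqrt(rowSums(tang^2))
  if (any(len == 0))
    stop("zero-length tangent at slider ", sliders[which(len == 0)[1L], 2L],
         ": flanking landmarks coincide")
  tang <- tang / len
  mid <- sliders[, 2L]
  resid <- Rf[mid, , drop = FALSE] - P[mid, , drop = FALSE]
  t_amt <- rowSums(resid * tang)
  P[mid, ] <- P[mid, , drop = FALSE] + t_amt * tang
  P
}

#' Generalized Procrustes analysis with optional sliding semilandmarks
#'
#' Iteratively superimposes all configurations: each is centered, scaled to
#' unit centroid size, and rotated onto the running consensus, which is the
#' coordinate-wise mean re-scaled to unit centroid size; alignment iterates
#' until the consensus moves by less than `tol` (Procrustes distance) or
#' `max_iter` is reached (the result is then flagged as unconverged, not an
#' error). When a sliders matrix is supplied, a small fixed number of
#' sliding passes follows the converged alignment: in each pass every
#' semilandmark slides along its tangent against the current consensus,
#' the shapes are re-normalized and re-aligned, and the alignment loop is
#' re-converged. Sliding is anchored at the digitized coordinates — each
#' pass re-slides every configuration from its original aligned position —
#' and the number of passes is fixed rather than iterated to a fixed
#' point, because the sliding problem has a near-neutral mode in which all
#' semilandmarks creep together along the outline; a few anchored passes
#' capture the tangential correction without admitting the creep. The
#' first configuration seeds the consensus, and reflections are never
#' allowed (configurations are standardized to right-facing beforehand).
#'
#' @param configs list of [landmark_config]s or a k x 2 x n array.
#' @param sliders optional slider triplet matrix (see [read_sliders]).
#' @param tol convergence tolerance on consensus movement.
#' @param max_iter cap on alignment iterations per convergence loop.
#' @param slide_passes number of anchored sliding passes (ignored without
#'   sliders).
#' @return an object of class `aligned_sample`: list with `shapes`
#'   (k x 2 x n array of aligned coordinates), `centroid_sizes`
#'   (pre-alignment sizes), `consensus`, `n_iterations`, `converged`,
#'   `specimen_ids`.
#' @export
gpa <- function(configs, sliders = NULL, tol = 1e-8, max_iter = 100L,
                slide_passes = 2L) {
  arr <- if (is.array(configs) && length(dim(configs)) == 3L) configs
         else configs_to_array(configs)
  n <- dim(arr)[3L]
  if (n < 2L) stop("GPA needs at least 2 configurations")
  ids <- dimnames(arr)[[3L]]
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (!is.null(sliders)) validate_sliders(sliders, k = dim(arr)[1L])
  cs <- apply(arr, 3L, centroid_size)
  orig <- arr
  for (i in seq_len(n)) orig[, , i] <- center_scale(arr[, , i])

  # alignment convergence loop: rotate every shape onto the consensus,
  # update the consensus, repeat until it stops moving
  align_loop <- function(ref_shapes, consensus) {
    shapes <- ref_shapes
    for (it in seq_len(max_iter)) {
      for (i in seq_len(n)) {
        shapes[, , i] <- ref_shapes[, , i] %*%
          optimal_rotation(ref_shapes[, , i], consensus)
      }
      new_cons <- center_scale(apply(shapes, c(1L, 2L), mean))
      new_cons <- new_cons %*% optimal_rotation(new_cons, consensus)
      delta <- sqrt(sum((new_cons - consensus)^2))
      consensus <- new_cons
      if (delta < tol) break
    }
    list(shapes = shapes, consensus = consensus, iters = it,
         converged = delta < tol)
  }

  fit <- align_loop(orig, orig[, , 1L])
  iters <- fit$iters
  converged <- fit$converged
  shapes <- fit$shapes
  consensus <- fit$consensus
  if (!is.null(sliders)) {
    slid <- orig
    for (p in seq_len(slide_passes)) {
      for (i in seq_len(n)) {
        al <- orig[, , i] %*% optimal_rotation(orig[, , i], consensus)
        al <- center_scale(slide_semilandmarks(al, consensus, sliders))
        slid[, , i] <- al
      }
      fit <- align_loop(slid, consensus)
      iters <- iters + fit$iters
      converged <- converged && fit$converged
      shapes <- fit$shapes
      consensus <- fit$consensus
    }
  }
  structure(
    list(shapes = shapes, centroid_sizes = cs, consensus = consensus,
         n_iterations = iters, converged = converged, specimen_ids = ids),
    class = "aligned_sample")
}

#' @export
print.aligned_sample <- function(x, ...) {
  cat("<aligned_sample> ", dim(x$shapes)[3L], " shapes, ",
      dim(x$shapes)[1L], " landmarks; ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$n_iterations, " iterations\n", sep = "")
  invisible(x)
}

#' Procrustes distance between two superimposed shapes
#'
#' The square root of the sum of squared differences between corresponding
#' landmark coordinates. Both shapes must already sit in a common
#' superimposed frame; no re-fitting is performed, matching the direct
#' coordinate-difference definition of shape-vector length.
#'
#' @param shape_a,shape_b k x 2 matrices (or [landmark_config]s) in the
#'   same aligned frame.
#' @return non-negative numeric scalar.
#' @export
procrustes_distance <- function(shape_a, shape_b) {
  A <- coords_of(shape_a); B <- coords_of(shape_b)
  if (!all(dim(A) == dim(B))) stop("landmark count mismatch")
  sqrt(sum((A - B)^2))
}

# Flatten a k x 2 shape to a 2k vector (all x, then all y; column-major).
flatten_shape <- function(m) as.vector(coords_of(m))

unflatten_shape <- function(v) matrix(v, ncol = 2L)

# n x 2k matrix of flattened shapes from an aligned_sample.
shape_matrix <- function(aligned) {
  d <- dim(aligned$shapes)
  t(apply(aligned$shapes, 3L, as.vector))
}

#' Tangent-space principal component analysis of aligned shapes
#'
#' Eigendecomposition of the covariance of the flattened, mean-centered
#' aligned coordinates. Axes are sorted by eigenvalue; null axes (eigenvalue
#' below `1e-12` of the leading one, and beyond the rank limit) are
#' dropped. Each loading vector is oriented so that its
#' largest-magnitude component is positive (ties broken toward the lowest
#' coordinate index), which fixes axis directions across platforms.
#'
#' @param aligned an `aligned_sample` from [gpa], or an n x 2k numeric
#'   matrix of flattened shapes.
#' @return object of class `shape_pca`: list with `mean` (2k), `eigenvalues`,
#'   `proportion_variance`, `scores` (n x m), `loadings` (2k x m).
#' @export
shape_pca <- function(aligned) {
  X <- if (inherits(aligned, "aligned_sample")) shape_matrix(aligned)
       else as.matrix(aligned)
  n <- nrow(X)
  if (n < 3L) stop("PCA needs at least 3 shapes")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc)
  ev <- sv$d^2 / (n - 1)
  keep <- ev > max(ev[1L], .Machine$double.eps) * 1e-12
  if (!any(keep)) {        # all shapes identical: degenerate, no axes
    return(structure(list(mean = mu, eigenvalues = numeric(0),
                          proportion_variance = numeric(0),
                          scores = matrix(0, n, 0),
                          loadings = matrix(0, ncol(X), 0)),
                     class = "shape_pca"))
  }
  ev <- ev[keep]
  V <- sv$v[, keep, drop = FALSE]
  # deterministic sign: largest-|component| positive, lowest index on ties
  for (j in seq_len(ncol(V))) {
    a <- abs(V[, j])
    lead <- which(a == max(a))[1L]
    if (V[lead, j] < 0) V[, j] <- -V[, j]
  }
  structure(
    list(mean = mu, eigenvalues = ev,
         proportion_variance = ev / sum(ev),
         scores = Xc %*% V, loadings = V),
    class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  m <- min(5L, length(x$eigenvalues))
  cat("<shape_pca> ", nrow(x$scores), " shapes, ",
      length(x$eigenvalues), " axes; leading proportions: ",
      paste(sprintf("%.3f", x$proportion_variance[seq_len(m)]),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Predicted shape at an observed PC-score extreme
#'
#' Returns the shape `mean + s * loading` where `s` is the minimum or
#' maximum observed score on the requested axis — the shapes used as
#' endpoints of the PC baseline vector.
#'
#' @param pca a `shape_pca`.
#' @param axis 1-based axis index.
#' @param which `"min"` or `"max"`.
#' @return k x 2 coordinate matrix.
#' @export
shape_at_pc_extreme <- function(pca, axis = 2L, which = c("min", "max")) {
  which <- match.arg(which)
  if (axis < 1L || axis > length(pca$eigenvalues))
    stop("axis ", axis, " is null or out of range (",
         length(pca$eigenvalues), " non-null axes)")
  s <- if (which == "min") min(pca$scores[, axis]) else max(pca$scores[, axis])
  unflatten_shape(pca$mean + s * pca$loadings[, axis])
}
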