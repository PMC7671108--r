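#' Female-to-male dimorphism shape vector
#'
#' The shape-change vector between the two specimens (or mean shapes)
#' representing one species, oriented female to male throughout: the
#' components are the male minus the female flattened aligned coordinates.
#' Its Euclidean norm equals the Procrustes distance between the endpoint
#' shapes — the vector length L that measures the magnitude of dimorphism.
#'
#' @param female_shape,male_shape k x 2 aligned coordinate matrices from one
#'   common superimposition.
#' @param species species label carried into downstream tables.
#' @param origin_label,terminus_label endpoint labels.
#' @return object of class `shape_vector`: list with `species`,
#'   `origin_label`, `terminus_label`, `components` (2k) and `length`.
#' @export
dimorphism_vector <- function(female_shape, male_shape, species = "",
                              origin_label = "female",
                              terminus_label = "male") {
  A <- coords_of(female_shape); B <- coords_of(male_shape)
  if (!all(dim(A) == dim(B)))
    stop("endpoint shapes disagree in landmark count (", nrow(A), " vs ",
         nrow(B), "); both must come from one alignment")
  comp <- as.vector(B) - as.vector(A)
  if (!all(is.finite(comp))) stop("non-finite vector components")
  structure(
    list(species = species, origin_label = origin_label,
         terminus_label = terminus_label, components = comp,
         length = sqrt(sum(comp^2))),
    class = "shape_vector")
}

vector_components <- function(v) {
  if (inherits(v, "shape_vector")) v$components else as.numeric(v)
}

#' Angle between two shape-change vectors
#'
#' The arccosine of the dot product of the unit-normalized component
#' vectors, in degrees within [0, 180]. Computed in the full dimensionality
#' of the shape data; symmetric and invariant to rescaling either vector.
#'
#' @param v1,v2 `shape_vector`s or numeric component vectors of equal length.
#' @return angle in degrees.
#' @export
vector_angle <- function(v1, v2) {
  a <- vector_components(v1); b <- vector_components(v2)
  if (length(a) != length(b)) stop("component length mismatch")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("angle undefined for a zero-length shape vector")
  cosang <- sum(a * b) / (na * nb)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Baseline shape-change vector along a principal component
#'
#' The vector from the predicted shape at the minimum observed score to the
#' predicted shape at the maximum observed score on the given axis
#' (default PC 2, the axis that consistently separates the sexes). Its
#' components equal `(score_max - score_min) * loading`; with the
#' deterministic loading sign convention the baseline orientation is
#' reproducible.
#'
#' @param pca a `shape_pca`.
#' @param axis 1-based axis index (default 2).
#' @return a `shape_vector` labelled by the axis extremes.
#' @export
baseline_vector <- function(pca, axis = 2L) {
  lo <- shape_at_pc_extreme(pca, axis, "min")
  hi <- shape_at_pc_extreme(pca, axis, "max")
  dimorphism_vector(lo, hi, species = sprintf("PC%d_baseline", axis),
                    origin_label = sprintf("PC%d_min", axis),
                    terminus_label = sprintf("PC%d_max", axis))
}

#' Principal component axis that best separates the sexes
#'
#' Scans the non-null PC axes and returns the index maximizing the
#' standardized separation between female and male scores (difference of
#' sex means over the pooled score standard deviation) — the data-driven
#' analogue of choosing the baseline axis by its consistent differentiation
#' of male and female forms.
#'
#' @param pca a `shape_pca`.
#' @param sex factor or character vector (one entry per shape row) with
#'   levels female/male.
#' @return integer axis index.
#' @export
sex_axis <- function(pca, sex) {
  sex <- factor(sex, levels = c("female", "male"))
  if (length(sex) != nrow(pca$scores))
    stop("sex must have one entry per shape")
  sep <- vapply(seq_along(pca$eigenvalues), function(ax) {
    s <- pca$scores[, ax]
    abs(mean(s[sex == "male"]) - mean(s[sex == "female"])) / stats::sd(s)
  }, numeric(1))
  which.max(sep)
}

#' Per-species angles of dimorphism vectors to a baseline
#'
#' Reports, for each species vector, its length L, its angular displacement
#' theta from the baseline and the supplementary angle 180 - theta (the
#' angle obtained if the baseline orientation is flipped), plus the total
#' ranges max - min of both. Flipping the baseline maps every angle to its
#' supplement, so the range of theta and the range of the supplements are
#' equal, but neither is invariant to the flip in location.
#'
#' @param vectors list of `shape_vector`s.
#' @param baseline a `shape_vector` (e.g. from [baseline_vector]).
#' @return object of class `angle_table`: list with `table` (data.frame
#'   `species,L,theta_deg,theta_supplement_deg`), `range_theta_deg` and
#'   `range_supplement_deg`.
#' @export
angle_table <- function(vectors, baseline) {
  if (length(vectors) < 1L) stop("need at least one shape vector")
  theta <- vapply(vectors, vector_angle, numeric(1), v2 = baseline)
  tab <- data.frame(
    species = vapply(vectors, function(v) v$species, character(1)),
    L = vapply(vectors, function(v) v$length, numeric(1)),
    theta_deg = theta,
    theta_supplement_deg = 180 - theta)
  structure(
    list(table = tab,
         range_theta_deg = max(theta) - min(theta),
         range_supplement_deg = max(180 - theta) - min(180 - theta)),
    class = "angle_table")
}

#' @export
print.angle_table <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("total angular range: %.2f deg\n", x$range_theta_deg))
  invisible(x)
}

#' PCA of length-scaled dimorphism vectors
#'
#' Each shape-change vector is divided by its length and a PCA is run on
#' the resulting unit vectors, visualizing variation in the *direction* of
#' dimorphic shape change with magnitude removed.
#'
#' @param vectors list of `shape_vector`s, all of nonzero length, n >= 3.
#' @return a `shape_pca` over the unit vectors.
#' @export
scaled_vector_pca <- function(vectors) {
  if (length(vectors) < 3L) stop("scaled-vector PCA needs at least 3 vectors")
  lens <- vapply(vectors, function(v) v$length, numeric(1))
  if (any(lens == 0))
    stop("zero-length dimorphism vector(s) for species: ",
         paste(vapply(vectors[lens == 0], function(v) v$species,
                      character(1)), collapse = ", "))
  U <- t(vapply(vectors, function(v) v$components / v$length,
                numeric(length(vectors[[1L]]$components))))
  rownames(U) <- vapply(vectors, function(v) v$species, character(1))
  shape_pca(U)
}
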