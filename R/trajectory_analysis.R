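# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

as_two_level <- function(x, what) {
  f <- factor(x)
  if (nlevels(f) != 2L)
    stop(what, " must have exactly 2 levels, got ",
         paste(levels(f), collapse = ", "))
  f
}

#' Mean shapes per group-by-stage cell
#'
#' Coordinate-wise mean aligned shape for each of the four cells of a
#' two-group, two-stage design (e.g. sex by maturity stage), the endpoints
#' of the two-point shape trajectories.
#'
#' @param aligned an `aligned_sample` from [gpa], or an n x 2k matrix of
#'   flattened aligned shapes.
#' @param group,stage factors (or vectors coercible to 2-level factors) of
#'   length n.
#' @return list with `means` (nested list `means[[group]][[stage]]` of
#'   k x 2 matrices), `counts` (2 x 2 table) and the level names.
#' @export
group_stage_means <- function(aligned, group, stage) {
  X <- if (inherits(aligned, "aligned_sample")) shape_matrix(aligned)
       else as.matrix(aligned)
  group <- as_two_level(group, "group")
  stage <- as_two_level(stage, "stage")
  if (length(group) != nrow(X) || length(stage) != nrow(X))
    stop("factor length does not match number of shapes")
  counts <- table(group, stage)
  if (any(counts == 0)) {
    bad <- which(counts == 0, arr.ind = TRUE)[1L, ]
    stop("empty cell: group=", levels(group)[bad[1L]], ", stage=",
         levels(stage)[bad[2L]])
  }
  means <- lapply(levels(group), function(g) {
    sts <- lapply(levels(stage), function(s) {
      unflatten_shape(colMeans(X[group == g & stage == s, , drop = FALSE]))
    })
    names(sts) <- levels(stage)
    sts
  })
  names(means) <- levels(group)
  list(means = means, counts = counts,
       group_levels = levels(group), stage_levels = levels(stage))
}

#' Two-point trajectory statistics from cell means
#'
#' For each group, the trajectory is the shape-change vector from its
#' stage-1 to its stage-2 mean shape; its length L is the Procrustes
#' distance between the two means. The statistics compared across groups
#' are the absolute difference in lengths, their ratio, and the angle theta
#' between the two trajectory direction vectors.
#'
#' @param cell_means output of [group_stage_means].
#' @return list with `L` (named pair), `delta_L`, `ratio_L`, `theta_deg`.
#' @export
trajectory_statistics <- function(cell_means) {
  g <- cell_means$group_levels; s <- cell_means$stage_levels
  v1 <- flatten_shape(cell_means$means[[g[1L]]][[s[2L]]]) -
        flatten_shape(cell_means$means[[g[1L]]][[s[1L]]])
  v2 <- flatten_shape(cell_means$means[[g[2L]]][[s[2L]]]) -
        flatten_shape(cell_means$means[[g[2L]]][[s[1L]]])
  L <- c(sqrt(sum(v1^2)), sqrt(sum(v2^2)))
  names(L) <- g
  if (any(L == 0))
    stop("zero-length trajectory in group ", g[which(L == 0)[1L]],
         ": angle undefined")
  list(L = L, delta_L = abs(L[[1L]] - L[[2L]]), ratio_L = L[[1L]] / L[[2L]],
       theta_deg = vector_angle(v1, v2))
}

# Fast internal statistics from a 4 x 2k matrix of cell means,
# rows ordered (g1 s1, g1 s2, g2 s1, g2 s2). Returns c(delta_L, theta).
.traj_stats_fast <- function(M) {
  v1 <- M[2L, ] - M[1L, ]
  v2 <- M[4L, ] - M[3L, ]
  L1 <- sqrt(sum(v1^2)); L2 <- sqrt(sum(v2^2))
  theta <- if (L1 == 0 || L2 == 0) NA_real_ else
    acos(min(1, max(-1, sum(v1 * v2) / (L1 * L2)))) * 180 / pi
  c(abs(L1 - L2), theta)
}

#' Permutation comparison of two shape trajectories
#'
#' Tests whether the two groups' stage-to-stage shape trajectories differ in
#' magnitude (delta L = |L_A - L_B|) and in direction (the angle theta
#' between them), using residual randomization: specimen residuals from the
#' reduced no-interaction model (grand mean + group effect + stage effect)
#' are permuted across all specimens, added back onto the reduced-model
#' fitted values, and both statistics recomputed. P-values count the
#' observed value in the null set, p = (1 + #permuted >= observed) /
#' (n_perm + 1), one-sided with large values extreme — for theta the null
#' statistic is the permuted angle itself. An alternative `scheme =
#' "labels"` shuffles raw group labels within stage, for sensitivity
#' analysis. Identical seeds yield identical results.
#'
#' @inheritParams group_stage_means
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed driving the permutation stream.
#' @param scheme `"residual"` (default) or `"labels"`.
#' @return object of class `trajectory_comparison`: group labels, per-group
#'   lengths, `delta_L`, `ratio_L`, `theta_deg`, permutation p-values
#'   `p_delta_L` and `p_theta`, `n_permutations`, `seed`.
#' @export
permutation_test <- function(aligned, group, stage, n_perm = 10000L,
                             seed = 1L, scheme = c("residual", "labels")) {
  scheme <- match.arg(scheme)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  X <- if (inherits(aligned, "aligned_sample")) shape_matrix(aligned)
       else as.matrix(aligned)
  group <- as_two_level(group, "group")
  stage <- as_two_level(stage, "stage")
  cm <- group_stage_means(X, group, stage)
  obs <- trajectory_statistics(cm)
  n <- nrow(X)
  cell <- interaction(group, stage, lex.order = TRUE)  # g1.s1 g1.s2 g2.s1 g2.s2
  W <- t(stats::model.matrix(~ cell - 1))              # 4 x n indicator
  W <- W / rowSums(W)                                  # rows average a cell
  perm_stats <- matrix(NA_real_, n_perm, 2L)
  if (scheme == "residual") {
    D <- stats::model.matrix(~ group + stage)
    fit <- stats::lm.fit(D, X)
    F_ <- D %*% fit$coefficients
    E <- X - F_
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        Xp <- F_ + E[sample.int(n), , drop = FALSE]
        perm_stats[b, ] <- .traj_stats_fast(W %*% Xp)
      }
    })
  } else {
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        gp <- group
        for (s in levels(stage)) {
          idx <- which(stage == s)
          gp[idx] <- gp[idx][sample.int(length(idx))]
        }
        cellp <- interaction(gp, stage, lex.order = TRUE)
        Wp <- t(stats::model.matrix(~ cellp - 1))
        Wp <- Wp / rowSums(Wp)
        perm_stats[b, ] <- .traj_stats_fast(Wp %*% X)
      }
    })
  }
  p_delta <- (1 + sum(perm_stats[, 1L] >= obs$delta_L)) / (n_perm + 1)
  p_theta <- (1 + sum(!is.na(perm_stats[, 2L]) &
                        perm_stats[, 2L] >= obs$theta_deg)) / (n_perm + 1)
  structure(
    list(group_labels = levels(group), L_per_group = obs$L,
         delta_L = obs$delta_L, ratio_L = obs$ratio_L,
         theta_deg = obs$theta_deg, p_delta_L = p_delta, p_theta = p_theta,
         n_permutations = as.integer(n_perm), seed = as.integer(seed),
         scheme = scheme, cell_counts = cm$counts),
    class = "trajectory_comparison")
}

#' @export
print.trajectory_comparison <- function(x, ...) {
  cat("<trajectory_comparison> groups ", paste(x$group_labels, collapse = " vs "),
      "\n  L = ", sprintf("%.4f / %.4f", x$L_per_group[1L], x$L_per_group[2L]),
      "  ratio = ", sprintf("%.3f", x$ratio_L), "\n",
      sprintf("  delta_L = %.4f (p = %.4g)   theta = %.2f deg (p = %.4g)\n",
              x$delta_L, x$p_delta_L, x$theta_deg, x$p_theta),
      sprintf("  %d permutations, seed %d, scheme %s\n",
              x$n_permutations, x$seed, x$scheme), sep = "")
  invisible(x)
}

# Flat key=value serialization of a trajectory comparison (deterministic).
trajectory_result_text <- function(x) {
  c(sprintf("group_A=%s", x$group_labels[1L]),
    sprintf("group_B=%s", x$group_labels[2L]),
    sprintf("L_A=%.10f", x$L_per_group[1L]),
    sprintf("L_B=%.10f", x$L_per_group[2L]),
    sprintf("delta_L=%.10f", x$delta_L),
    sprintf("ratio_L=%.10f", x$ratio_L),
    sprintf("theta_deg=%.10f", x$theta_deg),
    sprintf("p_delta_L=%.10f", x$p_delta_L),
    sprintf("p_theta=%.10f", x$p_theta),
    sprintf("n_permutations=%d", x$n_permutations),
    sprintf("seed=%d", x$seed))
}
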