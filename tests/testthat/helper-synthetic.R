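# Shared fixture builders. Everything is generated in code; no data files.

# A reproducible random landmark configuration (k points, roughly an
# ellipse plus jitter so it is never degenerate).
random_config <- function(k = 35, seed = 1, id = "rc") {
  withr::with_seed(seed, {
    th <- sort(runif(k, 0, pi))
    coords <- cbind(cos(th), 0.8 * sin(th)) + matrix(rnorm(2 * k, 0, 0.03), k)
    landmark_config(coords, id)
  })
}

# Apply a random similarity transform (rotation + scale + translation).
similarity_transform <- function(coords, angle, scale, shift) {
  R <- matrix(c(cos(angle), -sin(angle), sin(angle), cos(angle)), 2, 2)
  sweep(scale * coords %*% R, 2, -shift)
}

# Independent loop-based centroid size (oracle).
cs_oracle <- function(coords) {
  ctr <- c(mean(coords[, 1]), mean(coords[, 2]))
  s <- 0
  for (i in seq_len(nrow(coords)))
    s <- s + (coords[i, 1] - ctr[1])^2 + (coords[i, 2] - ctr[2])^2
  sqrt(s)
}

# Independent loop-based Procrustes distance (oracle).
pd_oracle <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a)))
    s <- s + (a[i, 1] - b[i, 1])^2 + (a[i, 2] - b[i, 2])^2
  sqrt(s)
}

# Brute-force rotation-grid ordinary Procrustes residual (oracle):
# both shapes centered and scaled to unit CS, best proper rotation found
# by scanning angles at `step` radians.
opa_grid_oracle <- function(reference, target, step = 1e-4) {
  X <- skatemorph:::center_scale(reference)
  Y <- skatemorph:::center_scale(target)
  best <- Inf
  for (th in seq(0, 2 * pi, by = step)) {
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    r <- sqrt(sum((Y %*% R - X)^2))
    if (r < best) best <- r
  }
  best
}

# Per-species vector lengths out of an aligned interspecific sample.
species_lengths <- function(sim, aligned) {
  md <- sim$metadata
  sp <- sort(unique(md$species))
  vapply(sp, function(s) {
    fi <- which(md$species == s & md$sex == "female")
    mi <- which(md$species == s & md$sex == "male")
    procrustes_distance(aligned$shapes[, , fi], aligned$shapes[, , mi])
  }, numeric(1))
}

# Flattened-shape matrix with a 2x2 factorial mean structure plus iid
# noise, for trajectory tests. Effects are vectors over 2k coordinates.
factorial_shapes <- function(n_cell, k, effects, sigma, seed) {
  withr::with_seed(seed, {
    group <- factor(rep(c("A", "B"), each = 2 * n_cell))
    stage <- factor(rep(rep(c("s1", "s2"), each = n_cell), 2))
    X <- matrix(0, 4 * n_cell, 2 * k)
    for (nm in names(effects)) {
      g <- substr(nm, 1, 1); s <- substr(nm, 2, 3)
      X[group == g & stage == s, ] <-
        matrix(effects[[nm]], n_cell, 2 * k, byrow = TRUE)
    }
    X <- X + matrix(rnorm(4 * n_cell * 2 * k, 0, sigma), 4 * n_cell)
    list(X = X, group = group, stage = stage)
  })
}
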