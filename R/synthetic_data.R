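#' Parameterization of the synthetic morphometric study
#'
#' Bundles every parameter of the simulated study: the pure-birth phylogeny
#' and Brownian shape evolution behind the interspecific design (one male
#' and one female outline per species), the ontogenetic series with
#' two-phase clasper growth and a maturity breakpoint, and the sex-specific
#' log-log allometries of the endoskeletal traits. Defaults mirror the
#' study conditions of the empirical system: 35 outline landmarks (33
#' sliding), 21 species, an ontogenetic series of 21 males and 22 females
#' spanning 50.6-109.5 mm disc width, a clasper-growth inflection at 84 mm,
#' male maturation shape change three times the female change, and
#' per-species dimorphism magnitudes spanning a five-fold range.
#'
#' @param n_landmarks outline landmarks per fin (two fixed endpoints, the
#'   rest sliding semilandmarks).
#' @param n_species species in the interspecific design.
#' @param bm_rate Brownian per-unit-time variance of each coordinate, in
#'   squared outline-scale units (tree depth is 1). Outline-scale units are
#'   the template's unit radius.
#' @param dimorphism_magnitudes per-species magnitudes d_i of the
#'   female-to-male shape change, expressed as Procrustes distances in the
#'   unit-centroid-size shape space (so the recovered vector length for a
#'   noise-free species equals d_i up to superimposition nonlinearity).
#' @param angular_dispersion_deg sd of per-species deviations of the
#'   dimorphism direction from the common field.
#' @param digitizing_noise_sd per-coordinate digitizing error sd, in
#'   outline-scale units.
#' @param ontogeny list: `n_per_sex` (named male/female counts), `dw_range`
#'   (mm), `allometry_scale` (shared ontogenetic deformation per unit log
#'   DW), `male_maturation_effect_scale` (deformation per mm DW beyond the
#'   breakpoint), `female_effect_scale` (same, for females; one third of
#'   the male scale by default). Deformation scales are Procrustes
#'   magnitudes like `dimorphism_magnitudes`.
#' @param clasper_growth list: `breakpoint` (mm), `intercept`,
#'   `slope_below`, `slope_above` (mm clasper per mm DW), `noise_sd` (mm).
#' @param skeletal data.frame of per-trait log-log allometry parameters
#'   (`trait`, `intercept_f`, `intercept_m`, `slope_f`, `slope_m`,
#'   `noise_sd`); the default makes 3 of the 9 endoskeletal traits
#'   slope-dimorphic, 2 intercept-dimorphic and 4 monomorphic.
#' @param seed master integer seed; each generator draws from its own
#'   stream split deterministically from it, so adding one output never
#'   perturbs another.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_landmarks = 35L,
                           n_species = 21L,
                           bm_rate = 1e-4,
                           dimorphism_magnitudes = NULL,
                           angular_dispersion_deg = 15,
                           digitizing_noise_sd = 0.005,
                           ontogeny = list(),
                           clasper_growth = list(),
                           skeletal = NULL,
                           seed = 1L) {
  if (is.null(dimorphism_magnitudes))
    dimorphism_magnitudes <- seq(0.05, 0.25, length.out = n_species)
  ont <- utils::modifyList(
    list(n_per_sex = c(male = 21L, female = 22L),
         dw_range = c(50.6, 109.5),
         allometry_scale = 0.01,
         male_maturation_effect_scale = 0.004,
         female_effect_scale = 0.004 / 3),
    ontogeny)
  cg <- utils::modifyList(
    list(breakpoint = 84, intercept = 1.0, slope_below = 0.05,
         slope_above = 1.2, noise_sd = 0.5),
    clasper_growth)
  if (is.null(skeletal)) skeletal <- default_skeletal_params()
  spec <- structure(
    list(n_landmarks = as.integer(n_landmarks), n_species = as.integer(n_species),
         bm_rate = bm_rate, dimorphism_magnitudes = dimorphism_magnitudes,
         angular_dispersion_deg = angular_dispersion_deg,
         digitizing_noise_sd = digitizing_noise_sd,
         ontogeny = ont, clasper_growth = cg, skeletal = skeletal,
         seed = as.integer(seed)),
    class = "synthetic_spec")
  validate_synthetic_spec(spec)
}

validate_synthetic_spec <- function(spec) {
  stopifnot(spec$n_landmarks >= 8L, spec$n_species >= 2L,
            spec$bm_rate >= 0, all(spec$dimorphism_magnitudes >= 0),
            length(spec$dimorphism_magnitudes) == spec$n_species,
            spec$digitizing_noise_sd >= 0, spec$angular_dispersion_deg >= 0,
            spec$ontogeny$dw_range[1L] > 0,
            diff(spec$ontogeny$dw_range) > 0,
            spec$clasper_growth$noise_sd >= 0,
            all(spec$skeletal$noise_sd >= 0))
  spec
}

# The nine endoskeletal traits with default allometric parameters.
default_skeletal_params <- function() {
  traits <- c("puboischiadic_bar_length", "puboischiadic_bar_width",
              "palatoquadrate_length", "scapulocoracoid_length",
              "scapulocoracoid_width", "rostrum_length",
              "propterygium_length", "mesopterygium_length",
              "metapterygium_length")
  slope_f <- c(1.00, 0.95, 1.05, 1.00, 0.90, 1.10, 1.00, 0.95, 1.05)
  slope_m <- slope_f
  int_f <- c(-1.8, -2.4, -1.6, -1.5, -2.2, -1.4, -1.2, -1.9, -1.3)
  int_m <- int_f
  slope_m[1:3] <- slope_f[1:3] + 0.15        # slope-dimorphic
  int_m[4:5] <- int_f[4:5] + 0.10            # intercept-dimorphic
  data.frame(trait = traits, intercept_f = int_f, intercept_m = int_m,
             slope_f = slope_f, slope_m = slope_m, noise_sd = 0.05,
             stringsAsFactors = FALSE)
}

# Deterministic per-output RNG stream seeds split from the master seed.
stream_seed <- function(seed, stream) {
  offset <- c(tree = 1L, interspecific = 2L, ontogeny = 3L,
              clasper = 4L, skeletal = 5L)[[stream]]
  (as.integer(seed) %% 20000000L) * 100L + offset
}

#' Template fin-outline configuration
#'
#' A deterministic half-disc outline standing in for the outer pectoral fin
#' margin: `k` points at exactly equal arc length along a unit semicircle,
#' running from the anterior tip (index 1, at (-1, 0)) to the posterior
#' insertion (index k, at (1, 0)).
#'
#' @param k number of landmarks (>= 8).
#' @return a [landmark_config] named `"template"`.
#' @export
template_outline <- function(k) {
  k <- as.integer(k)
  if (k < 8L) stop("template outline needs k >= 8 landmarks")
  theta <- seq(pi, 0, length.out = k)
  landmark_config(cbind(cos(theta), sin(theta)), "template")
}

# Default slider triplets for an open outline: every interior landmark
# slides between its neighbours.
make_sliders <- function(k) {
  i <- 2:(k - 1L)
  cbind(before = i - 1L, slider = i, after = i + 1L)
}

write_sliders <- function(sliders, path) {
  writeLines(sprintf("%d %d %d", sliders[, 1L], sliders[, 2L], sliders[, 3L]),
             path)
  invisible(path)
}

# Orthonormal basis (2k x 4) of the similarity directions (x/y translation,
# rotation, scaling) at a configuration; deformation fields projected out of
# this span survive Procrustes superimposition with their norm intact.
similarity_tangent_basis <- function(coords) {
  m <- sweep(coords, 2L, colMeans(coords))
  k <- nrow(m)
  B <- cbind(c(rep(1, k), rep(0, k)),        # translate x
             c(rep(0, k), rep(1, k)),        # translate y
             c(-m[, 2L], m[, 1L]),           # rotate
             c(m[, 1L], m[, 2L]))            # scale
  qr.Q(qr(B))
}

# Project `v` out of the column span of basis `B`, then normalize.
project_out <- function(v, B) {
  w <- v - B %*% crossprod(B, v)
  n <- sqrt(sum(w^2))
  if (n == 0) stop("deformation field lies entirely in the projected-out span")
  as.vector(w / n)
}

# Build a unit deformation field that displaces each landmark along the
# template's outward normal with the given per-landmark weights, with the
# weights first projected so the field is orthogonal to the similarity
# directions (and to any extra normal fields given by their weights).
# Pointwise-normal fields pass through tangential semilandmark sliding
# intact, so a displacement of magnitude d survives GPA as a shape change
# of (almost exactly) d.
normal_field <- function(k, weights, extra_weights = NULL) {
  theta <- seq(pi, 0, length.out = k)
  nx <- cos(theta); ny <- sin(theta)          # outward normals of the arc
  tmpl <- template_outline(k)$coords
  B <- similarity_tangent_basis(sweep(tmpl, 2L, colMeans(tmpl)))
  # constraint vectors in weight space: <w * n, B_j> = sum_i w_i c_j[i]
  C <- B[seq_len(k), , drop = FALSE] * nx + B[k + seq_len(k), , drop = FALSE] * ny
  if (!is.null(extra_weights)) C <- cbind(C, extra_weights)
  Q <- qr.Q(qr(C))
  w <- weights - Q %*% crossprod(Q, weights)
  nrm <- sqrt(sum(w^2))                        # |w * n| = |w|: unit normals
  if (nrm == 0) stop("weight profile lies entirely in the constrained span")
  w <- as.vector(w) / nrm
  list(field = c(w * nx, w * ny), weights = w)
}

gauss_bump <- function(theta, center, width) exp(-((theta - center) / width)^2)

#' Common dimorphism deformation field
#'
#' The unit deformation field u along which simulated males diverge from
#' females: an anterior concavity (inward bump near the leading margin)
#' plus a posterior lobe expansion (outward bump near the fin insertion).
#' Each landmark is displaced along the template outline's outward normal,
#' and the weight profile is constrained orthogonal to the similarity
#' directions, so a displacement of magnitude d survives superimposition
#' and tangential sliding as a Procrustes-scale shape change of (almost
#' exactly) d.
#'
#' @param k landmark count.
#' @return unit-norm numeric vector of length 2k (all x, then all y).
#' @export
dimorphism_field <- function(k) dimorphism_normal_field(k)$field

dimorphism_normal_field <- function(k) {
  theta <- seq(pi, 0, length.out = k)
  # single-harmonic weight profile: smooth anterior concavity (negative
  # lobe) and posterior expansion (positive lobe); low-frequency weights
  # keep the displacement gradient small so sliding leaves the field intact
  normal_field(k, sin(2 * theta))
}

# Shared ontogenetic deformation field: mid-margin expansion, pointwise
# normal, orthogonal to both the similarity directions and the dimorphism
# field.
ontogeny_field <- function(k) {
  theta <- seq(pi, 0, length.out = k)
  normal_field(k, sin(3 * theta),
               extra_weights = dimorphism_normal_field(k)$weights)$field
}

# A random unit normal field orthogonal to the similarity span and to the
# normal field with weight profile `u_weights`.
random_orthogonal_field <- function(k, u_weights) {
  normal_field(k, stats::rnorm(k), extra_weights = u_weights)$field
}

#' Simulate the interspecific dimorphism design
#'
#' One male and one female outline per species across a simulated
#' phylogeny. Species mean shapes evolve by Brownian motion directly on the
#' landmark coordinates of the template along a pure-birth tree of unit
#' depth; the female specimen is the species mean plus digitizing noise and
#' the male adds a shape displacement of magnitude d_i along the species'
#' dimorphism direction (the common field u perturbed by the angular
#' dispersion). Outlines are scaled to species-specific disc widths, and
#' male clasper lengths follow a positive allometry on pectoral centroid
#' size with species effects.
#'
#' @param spec a [synthetic_spec].
#' @param out_dir optional directory; when given, writes `landmarks.tps`,
#'   `metadata.csv`, `tree.nwk`, `sliders.txt` and `truth.txt` (a flat
#'   key=value ground-truth manifest).
#' @return (invisibly when writing) list with `configs`, `metadata`,
#'   `tree`, `sliders`, `truth` (true d_i, directions, fields, sizes) and
#'   `paths` when files were written.
#' @export
simulate_interspecific <- function(spec, out_dir = NULL) {
  k <- spec$n_landmarks; n <- spec$n_species
  tree <- with_seed(stream_seed(spec$seed, "tree"), {
    tr <- ape::rphylo(n, birth = 1, death = 0)
    tr$tip.label <- sprintf("sp%02d", seq_len(n))
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / depth
    tr
  })
  tmpl <- template_outline(k)$coords
  tmpl <- sweep(tmpl, 2L, colMeans(tmpl))
  cs_t <- sqrt(sum(tmpl^2))   # displacement scale: d_i are Procrustes units
  nf <- dimorphism_normal_field(k)
  u <- nf$field
  res <- with_seed(stream_seed(spec$seed, "interspecific"), {
    C <- ape::vcv(tree)[tree$tip.label, tree$tip.label]
    Z <- matrix(stats::rnorm(n * 2L * k), n, 2L * k)
    disp <- sqrt(spec$bm_rate) * t(chol(C)) %*% Z
    dw <- exp(stats::rnorm(n, log(300), 0.3))          # species disc widths, mm
    alpha <- stats::rnorm(n, 0, spec$angular_dispersion_deg * pi / 180)
    # the supplied magnitude set is arranged over species by rank-matching a
    # Brownian draw on the tree, so dimorphism magnitude behaves like an
    # evolving trait (and the PGLS error model sees the covariance it
    # assumes); the realized assignment is recorded in the truth manifest
    z <- as.vector(t(chol(C)) %*% stats::rnorm(n))
    d <- sort(spec$dimorphism_magnitudes)[rank(z, ties.method = "first")]
    configs <- list(); meta <- list(); u_i <- matrix(NA_real_, n, 2L * k)
    for (i in seq_len(n)) {
      w_i <- random_orthogonal_field(k, nf$weights)
      ui <- cos(alpha[i]) * u + sin(alpha[i]) * w_i
      u_i[i, ] <- ui
      mean_i <- tmpl + unflatten_shape(disp[i, ])
      if (outline_self_intersects(mean_i))
        warning("species ", tree$tip.label[i],
                ": Brownian displacement self-intersects the outline")
      f_coords <- mean_i +
        matrix(stats::rnorm(2L * k, 0, spec$digitizing_noise_sd), k, 2L)
      m_coords <- mean_i + unflatten_shape(d[i] * cs_t * ui) +
        matrix(stats::rnorm(2L * k, 0, spec$digitizing_noise_sd), k, 2L)
      if (d[i] > 0 &&
          outline_self_intersects(mean_i + unflatten_shape(d[i] * cs_t * ui)))
        warning("species ", tree$tip.label[i],
                ": dimorphism displacement d=", signif(d[i], 3),
                " self-intersects the outline")
      sc <- dw[i] / 2
      sp <- tree$tip.label[i]
      configs[[2L * i - 1L]] <- landmark_config(f_coords * sc, paste0(sp, "_f"))
      configs[[2L * i]] <- landmark_config(m_coords * sc, paste0(sp, "_m"))
      cs_m <- centroid_size(configs[[2L * i]])
      cl <- exp(-3 + 1.1 * log(cs_m) + stats::rnorm(1, 0, 0.15))
      meta[[2L * i - 1L]] <- data.frame(
        specimen_id = paste0(sp, "_f"), species = sp, sex = "female",
        disc_width_mm = dw[i], clasper_length_mm = NA_real_,
        maturity = "mature", stringsAsFactors = FALSE)
      meta[[2L * i]] <- data.frame(
        specimen_id = paste0(sp, "_m"), species = sp, sex = "male",
        disc_width_mm = dw[i], clasper_length_mm = cl,
        maturity = "mature", stringsAsFactors = FALSE)
    }
    list(configs = configs, metadata = do.call(rbind, meta),
         truth = list(d = stats::setNames(d, tree$tip.label), u = u,
                      u_i = u_i, alpha = alpha,
                      disc_widths = stats::setNames(dw, tree$tip.label)))
  })
  out <- list(configs = res$configs, metadata = res$metadata, tree = tree,
              sliders = make_sliders(k), truth = res$truth, spec = spec)
  if (!is.null(out_dir)) {
    out$paths <- write_interspecific(out, out_dir)
    return(invisible(out))
  }
  out
}

write_interspecific <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- list(tps = file.path(out_dir, "landmarks.tps"),
            metadata = file.path(out_dir, "metadata.csv"),
            tree = file.path(out_dir, "tree.nwk"),
            sliders = file.path(out_dir, "sliders.txt"),
            truth = file.path(out_dir, "truth.txt"))
  write_tps(sim$configs, p$tps)
  write_metadata_csv(sim$metadata, p$metadata)
  ape::write.tree(sim$tree, p$tree)
  write_sliders(sim$sliders, p$sliders)
  truth <- sim$truth
  writeLines(c(sprintf("seed=%d", sim$spec$seed),
               sprintf("n_species=%d", sim$spec$n_species),
               sprintf("d_%s=%.10f", names(truth$d), truth$d),
               sprintf("dw_%s=%.6f", names(truth$disc_widths),
                       truth$disc_widths)),
             p$truth)
  p
}

write_metadata_csv <- function(md, path) {
  md$disc_width_mm <- sprintf("%.6f", md$disc_width_mm)
  md$clasper_length_mm <- ifelse(is.na(md$clasper_length_mm), "",
                                 sprintf("%.6f", md$clasper_length_mm))
  utils::write.csv(md, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate the ontogenetic series
#'
#' An ontogenetic sample of one species: disc widths drawn uniformly over
#' the study range, a shared allometric deformation growing with log disc
#' width in both sexes, and a maturation deformation along the dimorphism
#' field added beyond the clasper-growth breakpoint — scaled per mm of disc
#' width beyond it, three times stronger in males than in females under the
#' defaults. Male clasper lengths follow the two-phase growth rule; the
#' maturity column applies the strict greater-than threshold at the
#' breakpoint. The draw is retried (deterministically) until both sides of
#' the breakpoint are sampled in both sexes.
#'
#' @param spec a [synthetic_spec].
#' @param out_dir optional directory; writes `ontogeny.tps`,
#'   `ontogeny_metadata.csv`, `sliders.txt`, `truth_ontogeny.txt`.
#' @return list with `configs`, `metadata`, `sliders`, `truth`.
#' @export
simulate_ontogeny <- function(spec, out_dir = NULL) {
  k <- spec$n_landmarks
  ont <- spec$ontogeny; cg <- spec$clasper_growth
  n_m <- ont$n_per_sex[["male"]]; n_f <- ont$n_per_sex[["female"]]
  tmpl <- template_outline(k)$coords
  tmpl <- sweep(tmpl, 2L, colMeans(tmpl))
  cs_t <- sqrt(sum(tmpl^2))   # effect scales are Procrustes units
  u <- dimorphism_field(k)
  W <- ontogeny_field(k)
  res <- with_seed(stream_seed(spec$seed, "ontogeny"), {
    repeat {
      dw <- stats::runif(n_m + n_f, ont$dw_range[1L], ont$dw_range[2L])
      sexes <- rep(c("male", "female"), c(n_m, n_f))
      ok <- all(vapply(c("male", "female"), function(s)
        any(dw[sexes == s] > cg$breakpoint) &&
        any(dw[sexes == s] <= cg$breakpoint), logical(1)))
      if (ok) break
    }
    effect_scale <- ifelse(sexes == "male", ont$male_maturation_effect_scale,
                           ont$female_effect_scale)
    mat_effect <- effect_scale * pmax(dw - cg$breakpoint, 0)
    configs <- list(); meta <- list()
    for (i in seq_along(dw)) {
      shape <- tmpl +
        unflatten_shape(ont$allometry_scale * log(dw[i] / ont$dw_range[1L]) *
                          cs_t * W) +
        unflatten_shape(mat_effect[i] * cs_t * u) +
        matrix(stats::rnorm(2L * k, 0, spec$digitizing_noise_sd), k, 2L)
      id <- sprintf("Fplu%02d_%s", i, substr(sexes[i], 1L, 1L))
      configs[[i]] <- landmark_config(shape * dw[i] / 2, id)
      cl <- if (sexes[i] == "male")
        cg$intercept + cg$slope_below * dw[i] +
          (cg$slope_above - cg$slope_below) * max(dw[i] - cg$breakpoint, 0) +
          stats::rnorm(1, 0, cg$noise_sd)
      else NA_real_
      meta[[i]] <- data.frame(
        specimen_id = id, species = "Synthetic_plutonia", sex = sexes[i],
        disc_width_mm = dw[i],
        clasper_length_mm = if (is.na(cl)) NA_real_ else max(cl, 0),
        maturity = classify_maturity(dw[i], cg$breakpoint),
        stringsAsFactors = FALSE)
    }
    list(configs = configs, metadata = do.call(rbind, meta),
         truth = list(disc_widths = dw, sexes = sexes,
                      maturation_effect = mat_effect, u = u, W = W))
  })
  out <- list(configs = res$configs, metadata = res$metadata,
              sliders = make_sliders(k), truth = res$truth, spec = spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- list(tps = file.path(out_dir, "ontogeny.tps"),
              metadata = file.path(out_dir, "ontogeny_metadata.csv"),
              sliders = file.path(out_dir, "sliders.txt"),
              truth = file.path(out_dir, "truth_ontogeny.txt"))
    write_tps(out$configs, p$tps)
    write_metadata_csv(out$metadata, p$metadata)
    write_sliders(out$sliders, p$sliders)
    writeLines(c(sprintf("seed=%d", spec$seed),
                 sprintf("breakpoint=%.6f", cg$breakpoint),
                 sprintf("male_maturation_effect_scale=%.8f",
                         ont$male_maturation_effect_scale),
                 sprintf("female_effect_scale=%.8f", ont$female_effect_scale),
                 sprintf("allometry_scale=%.8f", ont$allometry_scale)),
               p$truth)
    out$paths <- p
    return(invisible(out))
  }
  out
}

#' Simulate two-phase clasper growth
#'
#' Clasper length as a continuous hinge function of disc width — a shallow
#' slope below the maturity breakpoint and a steep one above — with
#' Gaussian noise. Disc widths are drawn uniformly over the study range.
#'
#' @param spec a [synthetic_spec].
#' @param n number of males (default: the ontogeny male count).
#' @return list with `disc_widths` and `clasper_lengths` (mm).
#' @export
simulate_clasper_growth <- function(spec, n = spec$ontogeny$n_per_sex[["male"]]) {
  cg <- spec$clasper_growth; rng <- spec$ontogeny$dw_range
  with_seed(stream_seed(spec$seed, "clasper"), {
    dw <- stats::runif(n, rng[1L], rng[2L])
    cl <- cg$intercept + cg$slope_below * dw +
      (cg$slope_above - cg$slope_below) * pmax(dw - cg$breakpoint, 0) +
      stats::rnorm(n, 0, cg$noise_sd)
    list(disc_widths = dw, clasper_lengths = cl)
  })
}

#' Simulate endoskeletal trait measurements
#'
#' Nine endoskeletal trait lengths per specimen under sex-specific log-log
#' allometries: ln(trait) = intercept_sex + slope_sex * ln(DW) + noise, so
#' every generated measurement is strictly positive. The default parameter
#' table makes three traits slope-dimorphic, two intercept-dimorphic and
#' four monomorphic.
#'
#' @param spec a [synthetic_spec].
#' @param out_dir optional directory; writes `skeletal.csv` and
#'   `truth_skeletal.txt`.
#' @return data.frame with `specimen_id`, `sex`, `disc_width_mm` and one
#'   column per trait (mm).
#' @export
simulate_skeletal_traits <- function(spec, out_dir = NULL) {
  ont <- spec$ontogeny; par <- spec$skeletal
  n_m <- ont$n_per_sex[["male"]]; n_f <- ont$n_per_sex[["female"]]
  df <- with_seed(stream_seed(spec$seed, "skeletal"), {
    dw <- stats::runif(n_m + n_f, ont$dw_range[1L], ont$dw_range[2L])
    sexes <- rep(c("male", "female"), c(n_m, n_f))
    out <- data.frame(
      specimen_id = sprintf("Fplu%02d_%s", seq_along(dw),
                            substr(sexes, 1L, 1L)),
      sex = sexes, disc_width_mm = dw, stringsAsFactors = FALSE)
    for (j in seq_len(nrow(par))) {
      male <- sexes == "male"
      lt <- ifelse(male, par$intercept_m[j], par$intercept_f[j]) +
        ifelse(male, par$slope_m[j], par$slope_f[j]) * log(dw) +
        stats::rnorm(length(dw), 0, par$noise_sd[j])
      out[[par$trait[j]]] <- exp(lt)
    }
    out
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    num <- vapply(df, is.numeric, logical(1))
    df_out <- df
    df_out[num] <- lapply(df_out[num], function(x) sprintf("%.8f", x))
    utils::write.csv(df_out, file.path(out_dir, "skeletal.csv"),
                     row.names = FALSE, quote = FALSE)
    writeLines(sprintf("%s slope_f=%.4f slope_m=%.4f int_f=%.4f int_m=%.4f",
                       par$trait, par$slope_f, par$slope_m, par$intercept_f,
                       par$intercept_m),
               file.path(out_dir, "truth_skeletal.txt"))
    return(invisible(df))
  }
  df
}

# Brute-force polyline self-intersection check (non-adjacent segments).
outline_self_intersects <- function(coords) {
  k <- nrow(coords)
  seg <- function(i) list(p = coords[i, ], q = coords[i + 1L, ])
  orient <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  intersects <- function(s1, s2) {
    o1 <- orient(s1$p, s1$q, s2$p); o2 <- orient(s1$p, s1$q, s2$q)
    o3 <- orient(s2$p, s2$q, s1$p); o4 <- orient(s2$p, s2$q, s1$q)
    o1 != o2 && o3 != o4
  }
  for (i in seq_len(k - 3L)) {
    for (j in (i + 2L):(k - 1L)) {
      if (intersects(seg(i), seg(j))) return(TRUE)
    }
  }
  FALSE
}
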