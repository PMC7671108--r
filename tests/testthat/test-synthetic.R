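test_that("template outline is deterministic, evenly spaced and simple", {
  t1 <- template_outline(35)
  t2 <- template_outline(35)
  expect_identical(t1$coords, t2$coords)
  seg <- diff(t1$coords)
  lens <- sqrt(rowSums(seg^2))
  expect_lt(diff(range(lens)) / mean(lens), 1e-6)
  expect_false(skatemorph:::outline_self_intersects(t1$coords))
  expect_error(template_outline(5), "k >= 8")
  # endpoints: anterior tip and posterior insertion on the x-axis
  expect_equal(t1$coords[1, ], c(-1, 0), tolerance = 1e-12)
  expect_equal(t1$coords[35, ], c(1, 0), tolerance = 1e-12)
})

test_that("deformation fields are unit, similarity-orthogonal and mutually orthogonal", {
  k <- 35
  u <- dimorphism_field(k)
  W <- skatemorph:::ontogeny_field(k)
  expect_equal(sqrt(sum(u^2)), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum(W^2)), 1, tolerance = 1e-12)
  expect_lt(abs(sum(u * W)), 1e-10)
  tmpl <- template_outline(k)$coords
  B <- skatemorph:::similarity_tangent_basis(tmpl)
  expect_lt(max(abs(crossprod(B, u))), 1e-10)
  expect_lt(max(abs(crossprod(B, W))), 1e-10)
})

test_that("generated files are bit-reproducible and parse cleanly", {
  spec <- synthetic_spec(seed = 9, n_species = 6)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_interspecific(spec, d1)
  simulate_interspecific(spec, d2)
  for (f in c("landmarks.tps", "metadata.csv", "tree.nwk", "sliders.txt",
              "truth.txt")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_no_warning({
    cfg <- read_tps(file.path(d1, "landmarks.tps"))
    md <- read_metadata(file.path(d1, "metadata.csv"))
    tr <- read_newick(file.path(d1, "tree.nwk"))
    sl <- read_sliders(file.path(d1, "sliders.txt"), k = spec$n_landmarks)
  })
  expect_length(cfg, 2 * spec$n_species)
  expect_equal(nrow(md), 2 * spec$n_species)
  expect_equal(length(tr$tip.label), spec$n_species)
  expect_equal(nrow(sl), spec$n_landmarks - 2)
  # truth manifest carries the ground-truth magnitudes
  truth <- readLines(file.path(d1, "truth.txt"))
  expect_true(any(grepl("^d_sp01=", truth)))
  # ontogeny outputs likewise round-trip
  d3 <- withr::local_tempdir()
  simulate_ontogeny(spec, d3)
  expect_no_warning(read_tps(file.path(d3, "ontogeny.tps")))
  expect_no_warning(read_metadata(file.path(d3, "ontogeny_metadata.csv")))
})

test_that("per-output RNG streams are independent of one another", {
  spec <- synthetic_spec(seed = 17, n_species = 5)
  g1 <- simulate_clasper_growth(spec)
  simulate_interspecific(spec)  # consuming another stream must not matter
  g2 <- simulate_clasper_growth(spec)
  expect_identical(g1, g2)
})

test_that("noise-free dimorphism magnitudes survive the pipeline to 2%", {
  spec <- synthetic_spec(seed = 2, n_species = 5,
                         dimorphism_magnitudes = rep(0.05, 5),
                         digitizing_noise_sd = 0, angular_dispersion_deg = 0)
  sim <- simulate_interspecific(spec)
  al <- gpa(sim$configs, sliders = sim$sliders)
  L <- species_lengths(sim, al)
  expect_true(all(abs(L - 0.05) / 0.05 < 0.02))
})

test_that("null dimorphism yields lengths at the noise floor", {
  spec <- synthetic_spec(seed = 7, n_species = 6,
                         dimorphism_magnitudes = rep(0, 6))
  sim <- simulate_interspecific(spec)
  al <- gpa(sim$configs, sliders = sim$sliders)
  L <- species_lengths(sim, al)
  # noise floor: the expected norm of the female-male digitizing noise
  # difference in Procrustes units (2k coordinates, two noisy shapes)
  k <- spec$n_landmarks
  tmpl <- template_outline(k)$coords
  cs_t <- sqrt(sum(sweep(tmpl, 2, colMeans(tmpl))^2))
  floor_ <- spec$digitizing_noise_sd * sqrt(2 * 2 * k) / cs_t
  expect_true(all(L <= 3 * floor_))
})

test_that("clasper growth simulation recovers its own hinge", {
  spec <- synthetic_spec(seed = 3)
  # noiseless: breakpoint recovered within one grid cell
  s0 <- synthetic_spec(seed = 3, clasper_growth = list(noise_sd = 0))
  g0 <- simulate_clasper_growth(s0, n = 25)
  b0 <- maturity_breakpoint(g0$disc_widths, g0$clasper_lengths)
  # the hinge at 84 falls between two sampled sizes: the estimate cannot be
  # pinned tighter than the local grid cell, but must land inside it
  gap <- max(diff(sort(unique(g0$disc_widths))))
  expect_lte(abs(b0$breakpoint_dw - 84), gap)
  expect_lt(b0$sse, b0$sse_line)
  # degenerate hinge: equal slopes make the segment fit match the line
  sd0 <- synthetic_spec(seed = 5, clasper_growth = list(
    slope_below = 0.3, slope_above = 0.3, noise_sd = 0))
  gd <- simulate_clasper_growth(sd0)
  bd <- maturity_breakpoint(gd$disc_widths, gd$clasper_lengths)
  expect_lt(abs(bd$sse - bd$sse_line), 1e-9)
})

test_that("skeletal trait generator matches its declared allometries", {
  spec <- synthetic_spec(seed = 19)
  sk <- simulate_skeletal_traits(spec)
  traits <- spec$skeletal$trait
  expect_equal(ncol(sk), 3 + 9)
  expect_true(all(as.matrix(sk[traits]) > 0))
  # noise-free generation lies exactly on the sex-specific log-log lines
  s0 <- synthetic_spec(seed = 19)
  s0$skeletal$noise_sd <- 0
  sk0 <- simulate_skeletal_traits(s0)
  j <- 1
  male <- sk0$sex == "male"
  pred <- ifelse(male, s0$skeletal$intercept_m[j], s0$skeletal$intercept_f[j]) +
    ifelse(male, s0$skeletal$slope_m[j], s0$skeletal$slope_f[j]) *
    log(sk0$disc_width_mm)
  expect_equal(log(sk0[[traits[j]]]), pred, tolerance = 1e-10)
})

test_that("ontogeny generator: zero noise makes immature sexes coincide", {
  spec <- synthetic_spec(seed = 23, digitizing_noise_sd = 0,
                         ontogeny = list(n_per_sex = c(male = 12L, female = 12L)))
  sim <- simulate_ontogeny(spec)
  md <- sim$metadata
  imm <- which(md$maturity == "immature")
  # at equal disc width, immature male and female shapes are identical by
  # construction: compare two synthetic specimens rebuilt at the same DW
  k <- spec$n_landmarks
  tmpl <- template_outline(k)$coords
  tmpl <- sweep(tmpl, 2, colMeans(tmpl))
  cs_t <- sqrt(sum(tmpl^2))
  W <- skatemorph:::ontogeny_field(k)
  dw <- 70
  shp <- tmpl + matrix(spec$ontogeny$allometry_scale *
                         log(dw / spec$ontogeny$dw_range[1]) * cs_t * W, k, 2)
  # generator output at an immature DW matches this closed form (up to size)
  i <- imm[1]
  rebuilt <- tmpl + matrix(spec$ontogeny$allometry_scale *
    log(md$disc_width_mm[i] / spec$ontogeny$dw_range[1]) * cs_t * W, k, 2)
  expect_equal(sim$configs[[i]]$coords,
               rebuilt * md$disc_width_mm[i] / 2, tolerance = 1e-9)
  # maturity column matches the strict rule at the true breakpoint
  expect_identical(md$maturity,
                   classify_maturity(md$disc_width_mm,
                                     spec$clasper_growth$breakpoint))
})

test_that("trajectory ratio and null calibration emerge from the ontogeny generator", {
  # median over replicate designs: male ontogenetic change ~3x female
  ratios <- vapply(1:5, function(sd) {
    sp <- synthetic_spec(seed = sd,
                         ontogeny = list(n_per_sex = c(male = 50L, female = 50L)))
    so <- simulate_ontogeny(sp)
    al <- gpa(so$configs, sliders = so$sliders)
    st <- trajectory_statistics(
      group_stage_means(al, so$metadata$sex, so$metadata$maturity))
    unname(st$L["male"] / st$L["female"])
  }, numeric(1))
  expect_lt(abs(median(ratios) - 3) / 3, 0.2)
  # zero maturation effect in both sexes: permutation p is null-like
  pv <- vapply(1:12, function(sd) {
    sp <- synthetic_spec(seed = 100 + sd, ontogeny = list(
      n_per_sex = c(male = 20L, female = 20L),
      male_maturation_effect_scale = 0, female_effect_scale = 0))
    so <- simulate_ontogeny(sp)
    al <- gpa(so$configs, sliders = so$sliders)
    permutation_test(al, so$metadata$sex, so$metadata$maturity,
                     n_perm = 99, seed = sd)$p_delta_L
  }, numeric(1))
  expect_gt(mean(pv), 0.2)   # far from systematic rejection
  expect_gt(min(pv), 0.01)
})
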