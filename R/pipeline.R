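pipeline_log <- function(...) message("[skatemorph] ", ...)

write_manifest <- function(out_dir, config) {
  lines <- c(sprintf("skatemorph_version=%s",
                     as.character(utils::packageVersion("skatemorph"))),
             sprintf("%s=%s", names(config), vapply(config, as.character,
                                                    character(1))))
  writeLines(lines, file.path(out_dir, "manifest.txt"))
}

#' Run the interspecific dimorphism analysis end to end
#'
#' The full interspecific design: read landmarks, sliders, metadata and
#' tree; reflect any left-side fins; pooled generalized Procrustes analysis
#' with sliding semilandmarks; tangent-space PCA; one female-to-male shape
#' vector per species; angles to the PC-extreme baseline and their total
#' range; PCA of the length-scaled vectors; size-standardized clasper
#' residuals; and PGLS of dimorphism magnitude on the clasper residuals.
#' Species lacking clasper data are excluded from the PGLS with a logged
#' warning, never imputed. All tables are written to `out_dir` with
#' deterministic formatting.
#'
#' @param tps,sliders,metadata,tree input file paths (see [read_tps],
#'   [read_sliders], [read_metadata], [read_newick]).
#' @param out_dir output directory (created if absent).
#' @param baseline_axis PC axis for the baseline vector: an index (default
#'   2, the conventional choice when the sex axis is known) or `"auto"` to
#'   pick the axis with the strongest female-male score separation via
#'   [sex_axis].
#' @param flip_y passed to [read_tps] for image-coordinate files.
#' @return (invisibly) list with `aligned`, `pca`, `vectors`, `angles`,
#'   `scaled_pca`, `pgls`, `excluded_species`, `outputs`.
#' @export
run_interspecific <- function(tps, sliders, metadata, tree, out_dir,
                              baseline_axis = 2L, flip_y = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  configs <- read_tps(tps, flip_y = flip_y)
  md <- read_metadata(metadata)
  phy <- read_newick(tree)
  sld <- read_sliders(sliders, k = configs[[1L]]$k)
  configs <- lapply(configs, function(cf)
    if (cf$side == "left") reflect_configuration(cf) else cf)
  ids <- vapply(configs, function(c) c$specimen_id, character(1))
  md <- md[match(ids, md$specimen_id), ]
  if (anyNA(md$specimen_id))
    stop("specimens missing from metadata: ",
         paste(ids[is.na(md$specimen_id)], collapse = ", "))
  bad <- names(which(with(md, table(species, sex)) != 1))
  tab <- with(md, table(species, sex))
  off <- rownames(tab)[apply(tab != 1, 1L, any)]
  if (length(off))
    stop("species without exactly one specimen per sex: ",
         paste(off, collapse = ", "))

  pipeline_log("aligning ", length(configs), " configurations (GPA + sliding)")
  aligned <- gpa(configs, sliders = sld)
  if (!aligned$converged) pipeline_log("warning: GPA did not converge")
  pca <- shape_pca(aligned)
  if (identical(baseline_axis, "auto")) {
    baseline_axis <- sex_axis(pca, md$sex)
    pipeline_log(sprintf("sex-separating axis: PC%d", baseline_axis))
  }
  baseline_axis <- as.integer(baseline_axis)
  pipeline_log(sprintf("PC%d carries %.1f%% of shape variation",
                       baseline_axis,
                       100 * pca$proportion_variance[baseline_axis]))

  species <- sort(unique(md$species))
  vectors <- lapply(species, function(sp) {
    fi <- which(md$species == sp & md$sex == "female")
    mi <- which(md$species == sp & md$sex == "male")
    dimorphism_vector(aligned$shapes[, , fi], aligned$shapes[, , mi],
                      species = sp)
  })
  base <- baseline_vector(pca, axis = baseline_axis)
  ang <- angle_table(vectors, base)
  pipeline_log(sprintf("angular range to PC%d baseline: %.2f deg",
                       baseline_axis, ang$range_theta_deg))
  svp <- scaled_vector_pca(vectors)

  # clasper standardization and PGLS (species with clasper data only)
  males <- md[md$sex == "male", ]
  male_cs <- aligned$centroid_sizes[match(males$specimen_id,
                                          aligned$specimen_ids)]
  has_cl <- !is.na(males$clasper_length_mm)
  excluded <- males$species[!has_cl]
  if (length(excluded))
    pipeline_log("excluding species without clasper data from PGLS: ",
                 paste(excluded, collapse = ", "))
  keep_sp <- males$species[has_cl]
  resid_cl <- size_standardize(log(males$clasper_length_mm[has_cl]),
                               log(male_cs[has_cl]))
  names(resid_cl) <- keep_sp
  L <- stats::setNames(vapply(vectors, function(v) v$length, numeric(1)),
                       species)[keep_sp]
  phy_kept <- ape::keep.tip(phy, keep_sp)
  pg <- pgls(L, resid_cl, phy_kept)
  pipeline_log(sprintf("PGLS: F(%d,%d) = %.4g, R2 = %.4g, p = %.4g",
                       pg$df[1L], pg$df[2L], pg$F_stat, pg$R2, pg$p_value))

  outputs <- list(
    vectors = file.path(out_dir, "dimorphism_vectors.csv"),
    pca = file.path(out_dir, "pca_summary.csv"),
    scaled_pca = file.path(out_dir, "scaled_vector_pca_scores.csv"),
    pgls = file.path(out_dir, "pgls.txt"))
  tabv <- ang$table
  write_lines_csv(
    c("species,L,theta_deg,theta_supplement_deg",
      sprintf("%s,%.10f,%.6f,%.6f", tabv$species, tabv$L, tabv$theta_deg,
              tabv$theta_supplement_deg),
      sprintf("range,,%.6f,%.6f", ang$range_theta_deg,
              ang$range_supplement_deg)),
    outputs$vectors)
  write_lines_csv(
    c("axis,eigenvalue,proportion_variance",
      sprintf("%d,%.12g,%.10f", seq_along(pca$eigenvalues), pca$eigenvalues,
              pca$proportion_variance)),
    outputs$pca)
  svs <- svp$scores
  write_lines_csv(
    c(paste(c("species", sprintf("PC%d", seq_len(ncol(svs)))), collapse = ","),
      vapply(seq_len(nrow(svs)), function(i)
        paste(c(rownames(svs)[i], sprintf("%.10f", svs[i, ])), collapse = ","),
        character(1))),
    outputs$scaled_pca)
  writeLines(c(sprintf("n_species=%d", pg$n),
               sprintf("slope=%.10f", pg$slope),
               sprintf("intercept=%.10f", pg$intercept),
               sprintf("F=%.10f", pg$F_stat),
               sprintf("df=%d,%d", pg$df[1L], pg$df[2L]),
               sprintf("R2=%.10f", pg$R2),
               sprintf("p=%.10f", pg$p_value),
               sprintf("excluded=%s", paste(excluded, collapse = ";"))),
             outputs$pgls)
  write_manifest(out_dir, list(
    analysis = "interspecific", tps = tps, sliders = sliders,
    metadata = metadata, tree = tree, baseline_axis = baseline_axis,
    n_specimens = length(configs), n_species = length(species)))
  invisible(list(aligned = aligned, pca = pca, vectors = vectors,
                 angles = ang, scaled_pca = svp, pgls = pg,
                 baseline_axis = baseline_axis,
                 excluded_species = excluded, outputs = outputs))
}

write_lines_csv <- function(lines, path) writeLines(lines, path)

#' Run the ontogenetic case-study analysis end to end
#'
#' The within-species design: estimate the maturity breakpoint from male
#' clasper growth (or accept a fixed `threshold`), classify all specimens
#' by the strict greater-than rule, align all outlines in one pooled GPA,
#' then run the two trajectory comparisons — ontogenetic shape change
#' (immature to mature) within each sex compared across sexes, and
#' dimorphic shape change (female to male) compared across maturity stages
#' — each with residual-randomization permutations, plus sex-specific
#' allometric ANCOVAs for every trait column in the skeletal table.
#'
#' @param tps,sliders,metadata input file paths.
#' @param skeletal path to the endoskeletal measurement CSV (columns
#'   `specimen_id`, `sex`, `disc_width_mm`, then one column per trait), or
#'   `NULL` to skip the ANCOVAs.
#' @param out_dir output directory.
#' @param n_perm permutations per trajectory test (default 10000).
#' @param seed integer seed for the permutation streams.
#' @param threshold fixed maturity threshold in mm; when `NULL` (default)
#'   the breakpoint is estimated from the data.
#' @param alpha gate level for the ANCOVA interaction test.
#' @param flip_y passed to [read_tps].
#' @return (invisibly) list with `breakpoint`, `threshold`, `aligned`,
#'   `trajectory_sex`, `trajectory_stage`, `ancova`, `outputs`.
#' @export
run_ontogenetic <- function(tps, sliders, metadata, skeletal = NULL, out_dir,
                            n_perm = 10000L, seed = 1L, threshold = NULL,
                            alpha = 0.05, flip_y = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  configs <- read_tps(tps, flip_y = flip_y)
  md <- read_metadata(metadata)
  sld <- read_sliders(sliders, k = configs[[1L]]$k)
  ids <- vapply(configs, function(c) c$specimen_id, character(1))
  md <- md[match(ids, md$specimen_id), ]
  if (anyNA(md$specimen_id)) stop("specimens missing from metadata")

  bp <- NULL
  if (is.null(threshold)) {
    males <- md[md$sex == "male" & !is.na(md$clasper_length_mm), ]
    bp <- maturity_breakpoint(males$disc_width_mm, males$clasper_length_mm)
    threshold <- bp$breakpoint_dw
    pipeline_log(sprintf("estimated maturity breakpoint: %.2f mm DW",
                         threshold))
  } else {
    pipeline_log(sprintf("using fixed maturity threshold: %.2f mm DW",
                         threshold))
  }
  maturity <- classify_maturity(md$disc_width_mm, threshold)
  counts <- table(md$sex, maturity)
  pipeline_log("cell counts: ",
               paste(sprintf("%s/%s=%d", rep(rownames(counts), 2),
                             rep(colnames(counts), each = 2), as.vector(counts)),
                     collapse = " "))
  if (any(counts == 0))
    stop("empty sex-by-stage cell at threshold ", threshold,
         " mm; cannot run trajectory analyses")

  pipeline_log("aligning ", length(configs), " configurations (GPA + sliding)")
  aligned <- gpa(configs, sliders = sld)
  stage <- factor(maturity, levels = c("immature", "mature"))
  sex <- factor(md$sex, levels = c("female", "male"))
  pipeline_log("trajectory comparison 1: immature->mature within sex")
  tr_sex <- permutation_test(aligned, group = sex, stage = stage,
                             n_perm = n_perm, seed = seed)
  pipeline_log(sprintf("  L_f = %.4f, L_m = %.4f, theta = %.2f deg, p_dL = %.4g, p_theta = %.4g",
                       tr_sex$L_per_group[1L], tr_sex$L_per_group[2L],
                       tr_sex$theta_deg, tr_sex$p_delta_L, tr_sex$p_theta))
  pipeline_log("trajectory comparison 2: female->male within stage")
  tr_stage <- permutation_test(aligned, group = stage, stage = sex,
                               n_perm = n_perm, seed = seed + 1L)
  pipeline_log(sprintf("  L_imm = %.4f, L_mat = %.4f, theta = %.2f deg, p_dL = %.4g, p_theta = %.4g",
                       tr_stage$L_per_group[1L], tr_stage$L_per_group[2L],
                       tr_stage$theta_deg, tr_stage$p_delta_L,
                       tr_stage$p_theta))

  anc <- NULL
  if (!is.null(skeletal)) {
    sk <- utils::read.csv(skeletal, stringsAsFactors = FALSE)
    traits <- setdiff(names(sk), c("specimen_id", "sex", "disc_width_mm"))
    anc <- lapply(traits, function(tr)
      ancova(log(sk[[tr]]), log(sk$disc_width_mm), sk$sex, alpha = alpha,
             trait_name = tr))
    n_slope <- sum(vapply(anc, function(a) a$p_interaction < alpha, logical(1)))
    pipeline_log(sprintf("ANCOVA: %d traits, %d with significant slope dimorphism",
                         length(anc), n_slope))
  }

  outputs <- list(
    trajectory_sex = file.path(out_dir, "trajectory_sex.txt"),
    trajectory_stage = file.path(out_dir, "trajectory_stage.txt"),
    breakpoint = file.path(out_dir, "breakpoint.txt"))
  writeLines(trajectory_result_text(tr_sex), outputs$trajectory_sex)
  writeLines(trajectory_result_text(tr_stage), outputs$trajectory_stage)
  writeLines(c(if (!is.null(bp)) c(
                 sprintf("estimated=1"),
                 sprintf("breakpoint_dw=%.6f", bp$breakpoint_dw),
                 sprintf("slope_below=%.8f", bp$slope_below),
                 sprintf("slope_above=%.8f", bp$slope_above),
                 sprintf("sse=%.8f", bp$sse))
               else sprintf("estimated=0"),
               sprintf("threshold=%.6f", threshold),
               sprintf("n_immature=%d", sum(stage == "immature")),
               sprintf("n_mature=%d", sum(stage == "mature"))),
             outputs$breakpoint)
  if (!is.null(anc)) {
    outputs$ancova <- file.path(out_dir, "ancova.csv")
    write_lines_csv(
      c("trait,slope_f,slope_m,intercept_f,intercept_m,p_interaction,p_sex",
        vapply(anc, function(a)
          sprintf("%s,%.8f,%.8f,%.8f,%.8f,%.8f,%s", a$trait, a$slope_f,
                  a$slope_m, a$intercept_f, a$intercept_m, a$p_interaction,
                  if (is.na(a$p_sex)) "" else sprintf("%.8f", a$p_sex)),
          character(1))),
      outputs$ancova)
  }
  write_manifest(out_dir, list(
    analysis = "ontogenetic", tps = tps, sliders = sliders,
    metadata = metadata,
    skeletal = if (is.null(skeletal)) "" else skeletal,
    n_perm = n_perm, seed = seed, alpha = alpha,
    threshold = sprintf("%.6f", threshold),
    n_specimens = length(configs)))
  invisible(list(breakpoint = bp, threshold = threshold, aligned = aligned,
                 trajectory_sex = tr_sex, trajectory_stage = tr_stage,
                 ancova = anc, outputs = outputs))
}
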