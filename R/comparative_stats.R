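#' Size-standardize clasper lengths
#'
#' Ordinary least-squares residuals of log clasper length on log body size
#' (centroid size of the associated pectoral fin). The residuals remove the
#' overall allometric scaling of claspers with body size before they enter
#' the comparative regression.
#'
#' @param log_clasper,log_size numeric vectors of equal length (n >= 3).
#' @return numeric residual vector (sums to zero).
#' @export
size_standardize <- function(log_clasper, log_size) {
  if (length(log_clasper) != length(log_size)) stop("length mismatch")
  if (length(log_clasper) < 3L) stop("need at least 3 observations")
  if (!all(is.finite(log_clasper)) || !all(is.finite(log_size)))
    stop("non-finite values")
  if (stats::var(log_size) == 0) stop("zero variance in log_size")
  unname(stats::resid(stats::lm(log_clasper ~ log_size)))
}

#' Phylogenetic generalized least squares under Brownian motion
#'
#' Regresses a per-species response on a per-species predictor with error
#' covariance proportional to shared phylogenetic path lengths (the
#' Brownian-motion expectation). Estimates come from the generalized normal
#' equations; the slope is tested by an F-test against the GLS
#' intercept-only model, and R-squared is 1 - RSS/TSS with both sums
#' GLS-weighted. On a star phylogeny the covariance is proportional to the
#' identity and the fit reduces to OLS.
#'
#' @param y,x named numeric vectors (names are species matching tree tips).
#' @param tree an [ape] `phylo` with branch lengths.
#' @return object of class `pgls_result`: `slope`, `intercept`, `F_stat`,
#'   `df` (numerator, denominator), `R2`, `p_value`, `n`,
#'   `covariance_model`.
#' @export
pgls <- function(y, x, tree) {
  if (is.null(names(y)) || is.null(names(x)))
    stop("y and x must be named by species")
  sp <- tree$tip.label
  miss_y <- setdiff(sp, names(y)); miss_x <- setdiff(sp, names(x))
  extra <- setdiff(union(names(y), names(x)), sp)
  if (length(miss_y) || length(miss_x) || length(extra))
    stop("species mismatch between data and tree: ",
         paste(unique(c(miss_y, miss_x, extra)), collapse = ", "))
  n <- length(sp)
  if (n < 3L) stop("PGLS needs at least 3 species")
  y <- y[sp]; x <- x[sp]
  C <- ape::vcv(tree)[sp, sp]
  L <- tryCatch(chol(C), error = function(e)
    stop("singular phylogenetic covariance matrix: ", conditionMessage(e)))
  # whiten: solve(t(L)) %*% v
  wh <- function(v) backsolve(L, v, transpose = TRUE)
  X <- cbind(intercept = 1, slope = x)
  Xw <- wh(X); yw <- wh(y)
  fit <- stats::lm.fit(Xw, yw)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  null_fit <- stats::lm.fit(Xw[, 1L, drop = FALSE], yw)
  tss <- sum(null_fit$residuals^2)
  df2 <- n - 2L
  Fstat <- ((tss - rss) / 1) / (rss / df2)
  structure(
    list(slope = unname(beta[2L]), intercept = unname(beta[1L]),
         F_stat = Fstat, df = c(1L, df2), R2 = 1 - rss / tss,
         p_value = stats::pf(Fstat, 1, df2, lower.tail = FALSE),
         n = n, rss = rss, covariance_model = "brownian"),
    class = "pgls_result")
}

#' @export
print.pgls_result <- function(x, ...) {
  cat(sprintf(
    "<pgls_result> slope = %.4f, intercept = %.4f\n  F(%d,%d) = %.4g, R2 = %.4g, p = %.4g  [%s covariance, n = %d]\n",
    x$slope, x$intercept, x$df[1L], x$df[2L], x$F_stat, x$R2, x$p_value,
    x$covariance_model, x$n))
  invisible(x)
}

#' Sex-specific allometric ANCOVA for one trait
#'
#' Fits `trait ~ sex * log_dw` and F-tests the sex-by-slope interaction. If
#' the interaction is not significant at `alpha`, the additive model
#' `trait ~ sex + log_dw` is refit and the sex main effect tested — the
#' standard test hierarchy for comparing allometries: different slopes
#' first, and only under a common slope a difference in elevation. Per-sex
#' slopes and intercepts are reported from whichever model the gate
#' selected.
#'
#' @param trait numeric response (typically log trait length).
#' @param log_dw numeric covariate, natural-log disc width.
#' @param sex factor/character with levels female and male.
#' @param alpha gate level for the interaction test (default 0.05).
#' @param trait_name label carried into the result.
#' @return object of class `allometry_result`: `trait`, `slope_f`,
#'   `slope_m`, `intercept_f`, `intercept_m`, `p_interaction`, `p_sex`
#'   (`NA` when the interaction is significant), `F_interaction`, `n`.
#' @export
ancova <- function(trait, log_dw, sex, alpha = 0.05, trait_name = "trait") {
  sex <- factor(sex, levels = c("female", "male"))
  if (anyNA(sex)) stop("sex must be 'female' or 'male'")
  if (any(table(sex) < 3L)) stop("need at least 3 specimens per sex")
  if (!all(is.finite(trait)) || !all(is.finite(log_dw)))
    stop("non-finite values")
  dat <- data.frame(trait = trait, log_dw = log_dw, sex = sex)
  full <- stats::lm(trait ~ sex + log_dw + sex:log_dw, data = dat)
  add <- stats::lm(trait ~ sex + log_dw, data = dat)
  a_int <- stats::anova(add, full)
  p_int <- a_int$`Pr(>F)`[2L]
  F_int <- a_int$F[2L]
  if (p_int < alpha) {
    cf <- stats::coef(full)
    slope_f <- cf[["log_dw"]]
    slope_m <- cf[["log_dw"]] + cf[["sexmale:log_dw"]]
    int_f <- cf[["(Intercept)"]]
    int_m <- cf[["(Intercept)"]] + cf[["sexmale"]]
    p_sex <- NA_real_
  } else {
    cov_only <- stats::lm(trait ~ log_dw, data = dat)
    p_sex <- stats::anova(cov_only, add)$`Pr(>F)`[2L]
    cf <- stats::coef(add)
    slope_f <- slope_m <- cf[["log_dw"]]
    int_f <- cf[["(Intercept)"]]
    int_m <- cf[["(Intercept)"]] + cf[["sexmale"]]
  }
  structure(
    list(trait = trait_name, slope_f = slope_f, slope_m = slope_m,
         intercept_f = int_f, intercept_m = int_m,
         p_interaction = p_int, p_sex = p_sex, F_interaction = F_int,
         alpha = alpha, n = nrow(dat)),
    class = "allometry_result")
}

#' @export
print.allometry_result <- function(x, ...) {
  cat(sprintf(
    "<allometry_result> %s: slopes f = %.4f, m = %.4f; p_int = %.4g%s\n",
    x$trait, x$slope_f, x$slope_m, x$p_interaction,
    if (is.na(x$p_sex)) "" else sprintf(", p_sex = %.4g", x$p_sex)))
  invisible(x)
}

# SSE of a continuous-hinge two-segment fit with the break at `bp`.
hinge_fit <- function(dw, cl, bp) {
  X <- cbind(1, dw, pmax(dw - bp, 0))
  fit <- stats::lm.fit(X, cl)
  list(coef = fit$coefficients, sse = sum(fit$residuals^2))
}

#' Maturity breakpoint from clasper growth
#'
#' Claspers elongate abruptly at the onset of sexual maturity; the
#' disc width at which that happens is estimated by continuous two-segment
#' (hinge) piecewise-linear least squares. Candidate breakpoints are the
#' midpoints between consecutive sorted unique disc widths together with
#' the interior observed disc widths themselves (so a hinge lying exactly
#' on a sampled size is representable), each requiring at least 3 points
#' strictly on each side; the SSE-minimizing candidate wins, ties broken
#' toward the smaller breakpoint.
#'
#' @param disc_widths,clasper_lengths numeric vectors (mm), males only,
#'   n >= 6.
#' @return object of class `breakpoint_result`: `breakpoint_dw`,
#'   `slope_below`, `slope_above`, `sse`, `sse_line` (single-line fit),
#'   `n`.
#' @export
maturity_breakpoint <- function(disc_widths, clasper_lengths) {
  dw <- as.numeric(disc_widths); cl <- as.numeric(clasper_lengths)
  if (length(dw) != length(cl)) stop("length mismatch")
  if (length(dw) < 6L) stop("breakpoint fit needs at least 6 males")
  if (length(unique(dw)) < 2L) stop("disc widths are all equal")
  u <- sort(unique(dw))
  cand <- sort(unique(c((u[-1L] + u[-length(u)]) / 2,
                        u[-c(1L, length(u))])))
  ok <- vapply(cand, function(b) sum(dw < b) >= 3L && sum(dw > b) >= 3L,
               logical(1))
  if (!any(ok))
    stop("no candidate breakpoint has >= 3 points on each side")
  cand <- cand[ok]
  fits <- lapply(cand, hinge_fit, dw = dw, cl = cl)
  sses <- vapply(fits, `[[`, numeric(1), "sse")
  best <- which(sses <= min(sses) + 1e-12)[1L]  # tie -> smaller breakpoint
  cf <- fits[[best]]$coef
  line_fit <- stats::lm.fit(cbind(1, dw), cl)
  structure(
    list(breakpoint_dw = cand[best], slope_below = unname(cf[2L]),
         slope_above = unname(cf[2L] + cf[3L]), sse = sses[best],
         sse_line = sum(line_fit$residuals^2), n = length(dw)),
    class = "breakpoint_result")
}

#' @export
print.breakpoint_result <- function(x, ...) {
  cat(sprintf(
    "<breakpoint_result> breakpoint at %.2f mm DW; slopes %.4f -> %.4f (n = %d, SSE = %.4g)\n",
    x$breakpoint_dw, x$slope_below, x$slope_above, x$n, x$sse))
  invisible(x)
}

#' Classify maturity from disc width
#'
#' Strict threshold rule: specimens with disc width above the threshold are
#' mature (maturing-or-mature), those at or below it immature. The same
#' cutoff is applied to both sexes.
#'
#' @param disc_width numeric vector (mm), all positive.
#' @param threshold positive threshold (mm), e.g. 84.
#' @return character vector of `"immature"` / `"mature"`.
#' @export
classify_maturity <- function(disc_width, threshold) {
  if (threshold <= 0) stop("threshold must be positive")
  if (any(!is.finite(disc_width)) || any(disc_width <= 0))
    stop("disc widths must be positive and finite")
  ifelse(disc_width > threshold, "mature", "immature")
}
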