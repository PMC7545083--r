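#' Repeated-measures ANOVA for fully within-subject two-level designs
#'
#' Classical repeated-measures analysis of variance for designs with up
#' to three two-level within-subject factors (e.g. signal type x visual
#' field on d', or signal type x visual field x stimulus type on reaction
#' time). Each effect is tested against its own subject-by-effect
#' interaction error term; with two-level factors this is algebraically
#' identical to a paired t test on the per-subject contrast scores
#' (\eqn{F = t^2}), and sphericity is satisfied by design. Partial eta
#' squared is reported as the effect size:
#' \eqn{\eta^2_p = F \, df_1 / (F \, df_1 + df_2)}.
#'
#' Subjects with several observations per cell are aggregated by their
#' cell mean first. If every subject's contrast score is zero the effect
#' is reported as F = 0, p = 1.
#'
#' @param data A tibble in long format.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector (length 1-3) of within-subject factor
#'   columns, each with exactly two levels.
#' @param subject Name of the subject-identifier column.
#' @return A tibble of class `rm_anova`: one row per effect (main effects
#'   and interactions) with `effect`, `df1`, `df2`, `statistic` (F),
#'   `p.value`, `pes` (partial eta squared) and `estimate` (the mean
#'   difference on the contrast, higher-coded level minus lower).
#' @examples
#' d <- tidyr::expand_grid(s = 1:8, a = c("x", "y"), b = c("l", "r"))
#' d$y <- rnorm(nrow(d)) + (d$a == "y") * 0.8
#' rm_anova(d, dv = "y", within = c("a", "b"), subject = "s")
#' @export
rm_anova <- function(data, dv, within, subject = "subject_id") {
  if (length(within) < 1L || length(within) > 3L) {
    abort("`within` must name 1 to 3 factors.")
  }
  cols <- c(subject, within, dv)
  if (!all(cols %in% names(data))) abort("Missing columns in `data`.")
  df <- data[cols]
  if (any(!complete.cases(df))) abort("`data` contains missing values.")
  lev <- lapply(within, function(w) sort(unique(as.character(df[[w]]))))
  names(lev) <- within
  if (any(lengths(lev) != 2L)) {
    abort("Every within-subject factor must have exactly two levels.")
  }
  # subject x cell matrix of cell means
  cell <- interaction(lapply(within, function(w) df[[w]]), drop = FALSE,
                      lex.order = TRUE)
  subj <- factor(df[[subject]])
  m <- tapply(df[[dv]], list(subj, cell), mean)
  if (any(is.na(m))) abort("Design is incomplete: every subject needs every cell.")
  n <- nrow(m)
  if (n < 3L) abort("Need at least 3 subjects.")
  # +1/-1 codes per factor, in the lexicographic cell order used above
  cell_levels <- do.call(
    tidyr::expand_grid,
    stats::setNames(lapply(lev, identity), within)
  )
  # interaction(lex.order = TRUE) varies the *last* factor fastest;
  # expand_grid varies the last column fastest too, so orders match.
  code_mat <- sapply(within, function(w) {
    ifelse(cell_levels[[w]] == lev[[w]][2], 1, -1)
  })
  code_mat <- matrix(code_mat, ncol = length(within))
  effects <- unlist(lapply(seq_along(within), function(k) {
    utils::combn(within, k, paste, collapse = ":", simplify = FALSE)
  }))
  res <- purrr::map(effects, function(eff) {
    members <- strsplit(eff, ":")[[1]]
    w <- apply(code_mat[, match(members, within), drop = FALSE], 1, prod)
    # difference-of-means scaling: scores are mean(level hi) - mean(level lo)
    scores <- as.numeric(m %*% w) / (ncol(m) / 2)
    mbar <- mean(scores)
    v <- var(scores)
    if (v == 0) {
      f_stat <- if (mbar == 0) 0 else Inf
    } else {
      f_stat <- n * mbar^2 / v
    }
    tibble::tibble(
      effect = eff, df1 = 1, df2 = n - 1, statistic = f_stat,
      p.value = pf(f_stat, 1, n - 1, lower.tail = FALSE),
      pes = if (is.infinite(f_stat)) 1 else f_stat / (f_stat + (n - 1)),
      estimate = mbar
    )
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("rm_anova", class(out))
  attr(out, "design") <- list(within = within, levels = lev, n_subjects = n,
                              dv = dv)
  out
}

#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "rm_anova")
  attr(out, "design") <- NULL
  out
}

#' @method glance rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  d <- attr(x, "design")
  tibble::tibble(
    n_subjects = d$n_subjects,
    n_within = length(d$within),
    design = paste(vapply(d$within, function(w) "2", character(1)),
                   collapse = "x"),
    dv = d$dv
  )
}

#' Pearson correlations with Bonferroni-adjusted significance
#'
#' Correlates an outcome (e.g. a subject's face-block criterion) with
#' each of a set of trait scores, reporting two-sided p values against a
#' Bonferroni-adjusted alpha of `alpha / n_predictors` (0.0125 for the
#' four schizotypy subscales at alpha = 0.05).
#'
#' @param data A tibble with one row per subject.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor columns.
#' @param alpha Family-wise significance level.
#' @return A tibble per predictor: `predictor`, `estimate` (Pearson r),
#'   `p.value`, `n`, `alpha_adjusted`, `significant`.
#' @examples
#' d <- tibble::tibble(y = rnorm(20), a = rnorm(20), b = rnorm(20))
#' pearson_with_bonferroni(d, "y", c("a", "b"))
#' @export
pearson_with_bonferroni <- function(data, outcome, predictors,
                                    alpha = 0.05) {
  if (nrow(data) < 4L) abort("Need at least 4 observations.")
  y <- data[[outcome]]
  if (sd(y) == 0) abort("`outcome` is constant; correlation undefined.")
  adj <- alpha / length(predictors)
  out <- purrr::map(predictors, function(p) {
    x <- data[[p]]
    if (sd(x) == 0) {
      abort(sprintf("Predictor '%s' is constant; correlation undefined.", p))
    }
    ct <- cor.test(x, y, method = "pearson")
    tibble::tibble(
      predictor = p, estimate = unname(ct$estimate),
      p.value = ct$p.value, n = length(x)
    )
  })
  out <- dplyr::bind_rows(out)
  out$alpha_adjusted <- adj
  out$significant <- out$p.value < adj
  out
}

#' Linear regression with collinearity screening
#'
#' Ordinary least squares of a response on a set of covariates, with the
#' standard collinearity diagnostics: the variance inflation factor of
#' each covariate, \eqn{VIF_j = 1 / (1 - R^2_j)} from regressing
#' covariate j on the remaining covariates, and its reciprocal tolerance.
#' A rank-deficient design (e.g. duplicated covariates) raises an error.
#'
#' @param data A tibble with one row per observation.
#' @param response Name of the response column.
#' @param covariates Character vector of covariate columns (length >= 1).
#' @return An object of class `ols_vif` with [tidy()] (coefficients) and
#'   [glance()] (fit statistics) methods; components `fit` (the `lm`),
#'   `coefficients` and `diagnostics` (VIF/tolerance tibble).
#' @examples
#' d <- tibble::tibble(y = rnorm(30), a = rnorm(30), b = rnorm(30))
#' fit <- ols_with_vif(d, "y", c("a", "b"))
#' tidy(fit); glance(fit)
#' @export
ols_with_vif <- function(data, response, covariates) {
  if (nrow(data) <= length(covariates) + 1L) {
    abort("Need more observations than covariates plus one.")
  }
  x <- as.matrix(data[covariates])
  if (qr(cbind(1, x))$rank < ncol(x) + 1L) {
    abort("Covariates are collinear (rank-deficient design).")
  }
  fml <- as.formula(paste(
    response, "~", paste(sprintf("`%s`", covariates), collapse = " + ")
  ))
  fit <- lm(fml, data = data)
  sm <- summary(fit)
  coefs <- tibble::tibble(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, 1],
    std.error = sm$coefficients[, 2],
    statistic = sm$coefficients[, 3],
    p.value = sm$coefficients[, 4]
  )
  vif <- vapply(seq_along(covariates), function(j) {
    if (length(covariates) == 1L) return(1)
    r2 <- summary(lm(x[, j] ~ x[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  diagnostics <- tibble::tibble(
    covariate = covariates, vif = vif, tolerance = 1 / vif
  )
  structure(
    list(fit = fit, coefficients = coefs, diagnostics = diagnostics,
         r.squared = sm$r.squared, adj.r.squared = sm$adj.r.squared,
         sigma = sm$sigma, n = nrow(data)),
    class = "ols_vif"
  )
}

#' @method tidy ols_vif
#' @export
tidy.ols_vif <- function(x, ...) x$coefficients

#' @method glance ols_vif
#' @export
glance.ols_vif <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r.squared, adj.r.squared = x$adj.r.squared,
    sigma = x$sigma, n = x$n,
    max_vif = max(x$diagnostics$vif),
    min_tolerance = min(x$diagnostics$tolerance)
  )
}

#' @export
print.ols_vif <- function(x, ...) {
  cat("<ols_vif> R^2 =", signif(x$r.squared, 4),
      "| max VIF =", signif(max(x$diagnostics$vif), 4), "\n")
  print(x$coefficients)
  invisible(x)
}
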