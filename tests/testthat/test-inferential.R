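make_within_data <- function(n = 12, seed = 1, k = 2) {
  withr::with_seed(seed, {
    factors <- list(a = c("a1", "a2"), b = c("b1", "b2"),
                    c = c("c1", "c2"))[seq_len(k)]
    d <- do.call(tidyr::expand_grid,
                 c(list(subject_id = seq_len(n)), factors))
    d$y <- rnorm(nrow(d)) + 0.5 * (d$a == "a2") +
      rnorm(n)[d$subject_id]
    d
  })
}

test_that("rm_anova agrees with the classical aov decomposition", {
  d <- make_within_data(n = 10, seed = 2, k = 2)
  ours <- rm_anova(d, dv = "y", within = c("a", "b"))

  dd <- d
  dd$subject_id <- factor(dd$subject_id)
  fit <- stats::aov(y ~ a * b + Error(subject_id / (a * b)), data = dd)
  sm <- summary(fit)
  ref <- c(
    a = sm[["Error: subject_id:a"]][[1]]["a", "F value"],
    b = sm[["Error: subject_id:b"]][[1]]["b", "F value"],
    `a:b` = sm[["Error: subject_id:a:b"]][[1]]["a:b", "F value"]
  )
  got <- stats::setNames(ours$statistic, ours$effect)
  expect_equal(got[names(ref)], ref, tolerance = 1e-8)
})

test_that("each two-level within effect equals the squared paired t", {
  d <- make_within_data(n = 14, seed = 3, k = 3)
  ours <- rm_anova(d, dv = "y", within = c("a", "b", "c"))
  expect_equal(nrow(ours), 7) # 3 mains + 3 two-way + 1 three-way

  wide <- tidyr::pivot_wider(d, names_from = c("a", "b", "c"),
                             values_from = "y")
  cells <- as.matrix(wide[, -1])
  a_scores <- rowMeans(cells[, grepl("^a2", colnames(cells))]) -
    rowMeans(cells[, grepl("^a1", colnames(cells))])
  tt <- stats::t.test(a_scores)
  expect_equal(ours$statistic[ours$effect == "a"],
               unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(ours$p.value[ours$effect == "a"], tt$p.value,
               tolerance = 1e-8)
  # partial eta squared identity for within designs
  expect_equal(ours$pes,
               ours$statistic / (ours$statistic + ours$df2))
})

test_that("degenerate designs are handled explicitly", {
  d <- make_within_data(n = 8, seed = 4, k = 2)
  # identical values across conditions within subject: all F = 0
  d0 <- d
  d0$y <- rnorm(8)[d0$subject_id]
  out <- rm_anova(d0, dv = "y", within = c("a", "b"))
  expect_true(all(out$statistic == 0))
  expect_true(all(out$p.value == 1))

  expect_error(rm_anova(d[d$subject_id != 1 | d$a != "a2", ], "y",
                        c("a", "b")),
               "incomplete")
  d3 <- d
  d3$a[1] <- "a3"
  expect_error(rm_anova(d3, "y", c("a", "b")), "two levels")
})

test_that("broom-style accessors expose the anova results", {
  d <- make_within_data(n = 8, seed = 5)
  out <- rm_anova(d, dv = "y", within = c("a", "b"))
  expect_s3_class(tidy(out), "tbl_df")
  expect_false(inherits(tidy(out), "rm_anova"))
  g <- glance(out)
  expect_equal(g$n_subjects, 8)
  expect_equal(g$dv, "y")
})

test_that("the signal-type sensitivity gap is detected reliably at n = 26", {
  # power check at the generator's own group-level settings
  hits <- vapply(1:150, function(r) {
    summ <- simulate_cohort_rates(scenario("exp1-baseline")$spec,
                                  n_signal = 64, n_noise = 64,
                                  seed = 9000 + r)
    a <- rm_anova(summ, dv = "dprime",
                  within = c("category", "visual_field"))
    a$p.value[a$effect == "category"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("correlations report Bonferroni-adjusted significance", {
  withr::with_seed(11, {
    d <- tibble::tibble(
      UnEx = rnorm(30), CogDis = rnorm(30), IntAnh = rnorm(30),
      ImpNon = rnorm(30)
    )
    d$bias <- 2 * d$UnEx
  })
  out <- pearson_with_bonferroni(
    d, "bias", c("UnEx", "CogDis", "IntAnh", "ImpNon")
  )
  expect_equal(out$alpha_adjusted, rep(0.0125, 4))
  expect_equal(out$estimate[out$predictor == "UnEx"], 1)
  expect_true(out$significant[out$predictor == "UnEx"])

  d$flat <- 1
  expect_error(pearson_with_bonferroni(d, "bias", "flat"), "constant")
  expect_error(pearson_with_bonferroni(d, "flat", "UnEx"), "constant")
})

test_that("VIF and tolerance match the independent oracle", {
  withr::with_seed(12, {
    d <- tibble::tibble(
      y = rnorm(40), x1 = rnorm(40), x2 = rnorm(40)
    )
    d$x3 <- 0.8 * d$x1 + 0.6 * rnorm(40)
  })
  fit <- ols_with_vif(d, "y", c("x1", "x2", "x3"))
  expect_equal(fit$diagnostics$tolerance, 1 / fit$diagnostics$vif)
  skip_if_not_installed("car")
  ref <- car::vif(fit$fit)
  expect_equal(unname(fit$diagnostics$vif), unname(ref),
               tolerance = 1e-8)
})

test_that("regression handles orthogonal, single and collinear designs", {
  withr::with_seed(13, {
    n <- 32
    x1 <- rep(c(-1, 1), each = n / 2)
    x2 <- rep(c(-1, 1), times = n / 2)
    d <- tibble::tibble(x1 = x1, x2 = x2, y = rnorm(n) + x1)
  })
  fit <- ols_with_vif(d, "y", c("x1", "x2"))
  expect_equal(fit$diagnostics$vif, c(1, 1), tolerance = 1e-12)

  # single covariate: slope = r * sd(y) / sd(x)
  fit1 <- ols_with_vif(d, "y", "x1")
  slope <- cor(d$x1, d$y) * sd(d$y) / sd(d$x1)
  expect_equal(unname(fit1$coefficients$estimate[2]), slope,
               tolerance = 1e-10)
  expect_equal(fit1$diagnostics$vif, 1)

  d$x1_dup <- d$x1
  expect_error(ols_with_vif(d, "y", c("x1", "x1_dup")), "collinear")
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$max_vif, 1, tolerance = 1e-12)
})
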