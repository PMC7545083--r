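test_that("named scenarios carry the published group-level truths", {
  s1 <- scenario("exp1-baseline")
  expect_equal(s1$spec$dprime_mean[["flower"]], 0.791)
  expect_equal(s1$spec$dprime_sd[["flower"]], 0.49)
  expect_equal(s1$spec$criterion_mean[["face_LVF"]], 0.329)
  expect_equal(s1$spec$n_subjects, 26L)
  expect_equal(s1$spec$trait_coupling$unex_face, -0.559)

  s2 <- scenario("exp2-baseline")
  expect_equal(s2$experiment, 2L)
  expect_equal(s2$spec$n_subjects, 29L)
  expect_equal(s2$spec$trait_coupling$cogdis_flower, 0.437)

  null <- scenario("null")
  expect_equal(unname(diff(null$spec$dprime_mean)), 0)
  expect_error(scenario("nope"))
})

test_that("recovery reports are reproducible and well formed", {
  a <- run_scenario("exp1-baseline", reps = 15, seed = 3, engine = "rate")
  b <- run_scenario("exp1-baseline", reps = 15, seed = 3, engine = "rate")
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_setequal(
    a$parameter,
    c("dprime_face", "dprime_flower", "criterion_LVF", "criterion_RVF")
  )
  expect_true(all(a$rmse >= abs(a$bias)))
  expect_true(all(is.finite(a$mean_estimate)))

  # the full trial-level pipeline is deterministic end to end as well
  t1 <- run_scenario("exp1-baseline", reps = 2, seed = 5,
                     engine = "trial")
  t2 <- run_scenario("exp1-baseline", reps = 2, seed = 5,
                     engine = "trial")
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("a scenario with equal criteria centres the field difference on 0", {
  rep <- run_scenario("null", reps = 60, seed = 6, engine = "rate")
  diff_lvf_rvf <- rep$mean_estimate[rep$parameter == "criterion_LVF"] -
    rep$mean_estimate[rep$parameter == "criterion_RVF"]
  # Monte-Carlo SE of the difference of two 60-rep means is ~0.015
  expect_lt(abs(diff_lvf_rvf), 0.05)
})

test_that("estimator bias shrinks as trials per cell grow", {
  # lapse-free observers isolate the estimator: any residual bias is the
  # finite-trial shrinkage of the corrected rates, which must vanish as
  # trials per cell increase
  sc <- scenario("exp1-baseline")
  sc$spec$lapse_rate <- 0
  bias_at <- function(n) {
    rep <- run_scenario(sc, reps = 80, seed = 7,
                        engine = "rate", n_signal = n, n_noise = n)
    abs(rep$bias[rep$parameter == "dprime_flower"])
  }
  b <- vapply(c(64, 256, 1024), bias_at, numeric(1))
  # monotone within Monte-Carlo error: allow a small slack term
  expect_lt(b[2], b[1] + 0.01)
  expect_lt(b[3], b[2] + 0.01)
  expect_lt(b[3], 0.02)
})

test_that("rate-level cohorts feed the standard pipeline format", {
  summ <- simulate_cohort_rates(scenario("exp1-baseline")$spec,
                                n_signal = 64, n_noise = 64, seed = 8)
  expect_equal(nrow(summ), 26 * 4)
  expect_true(all(summ$hr > 0 & summ$hr < 1))
  expect_true(all(summ$far > 0 & summ$far < 1))
  # d' and criterion columns are the package estimators applied to the
  # corrected rates
  expect_equal(summ$dprime, dprime(summ$hr, summ$far))
  expect_equal(summ$criterion, criterion(summ$hr, summ$far))
  expect_error(
    simulate_cohort_rates(cohort_spec(model = "ddm"), 64, 64, seed = 1),
    "SDT"
  )
})

test_that("plot builders return ggplot objects", {
  img <- generate_pink_noise(32, 32, seed = 1)
  expect_s3_class(plot_stimulus(img), "ggplot")
  summ <- simulate_cohort_rates(scenario("exp1-baseline")$spec,
                                seed = 10)
  expect_s3_class(plot_condition_means(summ, "criterion"), "ggplot")
  rep <- run_scenario("exp1-baseline", reps = 5, seed = 11,
                      engine = "rate")
  expect_s3_class(autoplot(rep), "ggplot")
  expect_error(plot_condition_means(summ, "nope"), "not found")
})
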