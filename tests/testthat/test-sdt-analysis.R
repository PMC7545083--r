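test_that("log-linear correction maps counts to interior rates", {
  log <- tibble::tibble(
    subject_id = 1L, category = "face", visual_field = "LVF",
    stimulus_type = rep(c("signal", "noise_only"), each = 128),
    response = c(rep(c("present", "absent"), each = 64),
                 rep("absent", 128)),
    correct = TRUE, rt_s = 0.5
  )
  r <- compute_rates(log)
  expect_equal(r$hr, 64.5 / 129) # midpoint is a fixed point: 0.5
  expect_equal(r$hr, 0.5)
  expect_equal(r$far, 0.5 / 129)

  # a perfect scorer stays strictly below 1
  log$response[log$stimulus_type == "signal"] <- "present"
  r2 <- compute_rates(log)
  expect_equal(r2$hr, 128.5 / 129)
  expect_lt(r2$hr, 1)

  # empty cells are refused
  expect_error(compute_rates(log[log$stimulus_type == "signal", ]),
               "noise trial")
  expect_error(compute_rates(log[0, ]), "empty")
})

test_that("correction preserves the ordering of raw rates", {
  hits <- c(10, 40, 90, 128)
  corrected <- (hits + 0.5) / 129
  expect_true(all(diff(corrected) > 0))
})

test_that("d-prime and criterion match hand-computed quantile values", {
  # frozen: z(0.8) = 0.8416212, z(0.3) = -0.5244005
  expect_equal(dprime(0.8, 0.3), 1.3660218, tolerance = 1e-6)
  expect_equal(criterion(0.8, 0.3), -0.1586104, tolerance = 1e-6)
  expect_equal(dprime(0.5, 0.5), 0)
  expect_equal(criterion(0.5, 0.5), 0)
  expect_error(dprime(1, 0.5), "strictly")
  expect_error(criterion(0.5, 0), "strictly")
})

test_that("estimator symmetries hold across a rate grid", {
  set.seed(9)
  h <- runif(50, 0.05, 0.95)
  f <- runif(50, 0.05, 0.95)
  expect_equal(dprime(h, f), -dprime(f, h))
  # swapping response labels maps (h, f) -> (1 - f, 1 - h): sensitivity
  # is invariant, bias flips sign
  expect_equal(dprime(1 - f, 1 - h), dprime(h, f))
  expect_equal(criterion(1 - f, 1 - h), -criterion(h, f))
  # HR = 1 - FAR implies zero bias
  expect_equal(criterion(h, 1 - h), rep(0, 50), tolerance = 1e-12)
})

test_that("reaction-time summaries average correct trials only", {
  log <- tibble::tibble(
    subject_id = 1L, category = "face", visual_field = "LVF",
    stimulus_type = "signal",
    response = "present",
    correct = c(TRUE, TRUE, FALSE),
    rt_s = c(0.6, 0.6, 5)
  )
  r <- rt_summary(log)
  expect_equal(r$mean_rt_correct, 0.6)
  expect_equal(r$mean_rt_incorrect, 5)
  expect_false(r$missing)

  # adding incorrect trials does not move the correct-trial mean
  log2 <- dplyr::bind_rows(log, dplyr::mutate(log, correct = FALSE))
  expect_equal(rt_summary(log2)$mean_rt_correct, 0.6)

  # cells without correct trials are flagged, not dropped
  log3 <- dplyr::mutate(log, correct = FALSE)
  r3 <- rt_summary(log3)
  expect_true(r3$missing)
  expect_true(is.na(r3$mean_rt_correct))
})

test_that("the estimator recovers known observer parameters", {
  obs <- sdt_observer_row(
    dprime_face = 1.2, dprime_flower = 0.6,
    crit = c(face_LVF = 0.4, face_RVF = -0.1, flower_LVF = 0.4,
             flower_RVF = -0.1)
  )
  trials <- flat_schedule(10000, 10000)
  log <- dplyr::mutate(run_experiment(obs, trials, seed = 55),
                       subject_id = 1L)
  summ <- subject_condition_summary(log)
  expect_equal(nrow(summ), 4)
  expect_lt(max(abs(summ$dprime[summ$category == "face"] - 1.2)), 0.05)
  expect_lt(max(abs(summ$criterion[summ$visual_field == "LVF"] - 0.4)),
            0.05)
  expect_lt(max(abs(summ$criterion[summ$visual_field == "RVF"] + 0.1)),
            0.05)
})

test_that("a full cohort summary has one row per subject and condition", {
  spec <- cohort_spec(n_subjects = 4)
  co <- sample_cohort(spec, seed = 8)
  man <- virtual_manifest()
  sched <- dplyr::bind_rows(purrr::map(
    1:4, function(i) build_trial_schedule(1, i, man, seed = 100 + i)
  ))
  log <- run_cohort_experiment(co, sched, seed = 9)
  summ <- subject_condition_summary(log)
  expect_equal(nrow(summ), 16) # 4 subjects x 2 categories x 2 fields
  expect_false(any(is.na(summ$dprime)))
  # deterministic given the same inputs
  log2 <- run_cohort_experiment(co, sched, seed = 9)
  expect_identical(subject_condition_summary(log2), summ)
})
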