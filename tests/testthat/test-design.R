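man_std <- virtual_manifest()
man_big <- virtual_manifest(n_noise_per_category = 192)

test_that("equal-ratio blocks hold 128 signal and 128 noise trials", {
  s <- build_block_schedule(1, "face", man_std, seed = 1)
  expect_equal(nrow(s), 256)
  expect_equal(sum(s$stimulus_type == "signal"), 128)
  expect_equal(sum(s$stimulus_type == "noise_only"), 128)
  expect_equal(anyDuplicated(s$image_id), 0)
  expect_true(all(s$duration_ms == 180))
  expect_true(all(s$iti_ms == 1000))
  # signal hemifield follows the embedded location; balance within 2
  sig <- s[s$stimulus_type == "signal", ]
  expect_true(all((sig$location_id <= 3) == (sig$visual_field == "LVF")))
  expect_lte(abs(diff(table(sig$visual_field))), 2)
  noi <- s[s$stimulus_type == "noise_only", ]
  expect_equal(unname(table(noi$visual_field)["LVF"]), 64,
               ignore_attr = TRUE)
})

test_that("25/75 blocks hold 64 signal and 192 unique noise trials", {
  s <- build_block_schedule(2, "flower", man_big, seed = 2)
  expect_equal(nrow(s), 256)
  expect_equal(sum(s$stimulus_type == "signal"), 64)
  expect_equal(sum(s$stimulus_type == "noise_only"), 192)
  expect_equal(anyDuplicated(s$image_id), 0)
  sig <- s[s$stimulus_type == "signal", ]
  # balanced over identity x level x side: 32 LVF / 32 RVF
  expect_equal(unname(table(sig$visual_field)), c(32, 32),
               ignore_attr = TRUE)
  counts <- table(sig$noise_fraction)
  expect_true(all(counts == 16))

  # without enough unique noise images the schedule must refuse
  expect_error(build_block_schedule(2, "flower", man_std, seed = 2),
               "noise-only")
})

test_that("schedules are seed-deterministic with seed-varying order", {
  a <- build_block_schedule(1, "face", man_std, seed = 9)
  b <- build_block_schedule(1, "face", man_std, seed = 9)
  c <- build_block_schedule(1, "face", man_std, seed = 10)
  expect_identical(a, b)
  expect_false(identical(a$image_id, c$image_id))
  # marginal composition is invariant to the seed
  expect_equal(table(a$stimulus_type), table(c$stimulus_type))
  expect_equal(sort(a$image_id[a$stimulus_type == "signal"]) |> length(),
               128)
})

test_that("practice trials are flagged and prepended", {
  s <- build_block_schedule(1, "face", man_std, seed = 3,
                            include_practice = TRUE)
  expect_equal(nrow(s), 264)
  expect_equal(sum(s$practice), 8)
  expect_equal(s$trial[s$practice], 1:8)
  expect_equal(sum(s$stimulus_type[s$practice] == "signal"), 4)
})

test_that("cohort counterbalancing fills the 8 cells evenly", {
  cb8 <- counterbalance_cohort(8, seed = 1)
  cells <- interaction(cb8$block_order, cb8$present_key, cb8$response_hand)
  expect_true(all(table(cells) == 1))

  cb26 <- counterbalance_cohort(26, seed = 1)
  cells26 <- table(interaction(cb26$block_order, cb26$present_key,
                               cb26$response_hand))
  expect_true(all(cells26 %in% c(3, 4)))

  cb1 <- counterbalance_cohort(1, seed = 4)
  expect_equal(nrow(cb1), 1)
  expect_true(cb1$block_order %in% c("face_first", "flower_first"))
  expect_error(counterbalance_cohort(0), "positive")
})

test_that("a full subject schedule is two blocks in counterbalanced order", {
  cb <- tibble::tibble(subject_id = 1L, block_order = "flower_first",
                       present_key = "up", response_hand = "left")
  sched <- build_trial_schedule(1, 1L, man_std, cb, seed = 5)
  expect_equal(nrow(sched), 512)
  expect_equal(unique(sched$category[sched$block_index == 1]), "flower")
  expect_equal(unique(sched$category[sched$block_index == 2]), "face")
  expect_equal(unique(sched$experiment), 1L)
})
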