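# The full-size printed design (128 composites per category, 256
# noise-only images) is built and checked once in the acceptance tests;
# here a reduced set (2 images per identity x level cell) exercises the
# generator's structure.

test_that("the set has the designed composition at reduced scale", {
  set <- small_stimulus_set()
  man <- set$manifest
  # 2 categories x 2 identities x 4 levels x 2 = 32 composites, 32 pairs
  expect_equal(sum(man$stimulus_type == "signal"), 32)
  expect_equal(sum(man$stimulus_type == "noise_only"), 32)
  expect_equal(nrow(man), length(set$images))

  face_levels <- table(man$noise_fraction[man$category == "face" &
                                            man$stimulus_type == "signal"])
  expect_equal(as.numeric(names(face_levels)), c(0.44, 0.46, 0.48, 0.50))
  # 2 identities x 2 images per cell at this reduced scale
  expect_true(all(face_levels == 4))
  flower_levels <- table(
    man$noise_fraction[man$category == "flower" &
                         man$stimulus_type == "signal"]
  )
  expect_equal(as.numeric(names(flower_levels)), c(0.38, 0.40, 0.42, 0.44))

  # every composite has a noise-only pair and vice versa
  sig <- man[man$stimulus_type == "signal", ]
  noi <- man[man$stimulus_type == "noise_only", ]
  expect_setequal(sig$pair_id, noi$image_id)
  expect_setequal(noi$pair_id, sig$image_id)

  # locations drawn from the 8 lateralised positions, both sides used
  expect_true(all(sig$location_id %in% 0:7))
  expect_setequal(unique(sig$visual_field), c("LVF", "RVF"))
  expect_true(all(is.na(noi$location_id)))
})

test_that("every emitted image respects the RMS and clipping bounds", {
  set <- small_stimulus_set()
  expect_true(all(set$manifest$rms >= 0.25 & set$manifest$rms <= 0.35))
  expect_true(all(set$manifest$clipped_fraction < 0.01))
  # manifest RMS matches a re-measurement of the stored pixels
  id <- set$manifest$image_id[1]
  expect_equal(compute_rms_contrast(set$images[[id]]),
               set$manifest$rms[1], tolerance = 1e-12)
  # pixels are 8-bit integers
  expect_true(all(vapply(set$images, function(im)
    all(im == round(im)) && min(im) >= 0 && max(im) <= 255, logical(1))))
})

test_that("generation is byte-reproducible per seed", {
  geom <- small_geometry()
  a <- build_stimulus_set(geom, images_per_cell = 1, seed = 3)
  b <- build_stimulus_set(geom, images_per_cell = 1, seed = 3)
  c <- build_stimulus_set(geom, images_per_cell = 1, seed = 4)
  expect_identical(a$images, b$images)
  expect_identical(a$manifest, b$manifest)
  expect_false(identical(a$images, c$images))
})

test_that("extra noise-only images can be generated for 25/75 blocks", {
  geom <- small_geometry()
  set <- build_stimulus_set(geom, images_per_cell = 1, n_extra_noise = 3,
                            seed = 5)
  man <- set$manifest
  extra <- man[grepl("extra", man$image_id), ]
  expect_equal(nrow(extra), 6) # 3 per category
  expect_true(all(extra$stimulus_type == "noise_only"))
  expect_true(all(extra$rms >= 0.25 & extra$rms <= 0.35))
})

test_that("a stimulus set round-trips through PNG + JSONL", {
  set <- small_stimulus_set()
  dir <- withr::local_tempdir()
  man <- write_stimulus_set(set, dir, label = "t")
  expect_true(file.exists(file.path(dir, "manifest.jsonl")))
  expect_equal(length(list.files(dir, pattern = "\\.png$")), nrow(man))
  img <- png::readPNG(file.path(dir, man$filename[1])) * 255
  expect_equal(round(img), unclass(set$images[[man$image_id[1]]])[, ],
               ignore_attr = TRUE)
  lines <- readLines(file.path(dir, "manifest.jsonl"))
  expect_equal(length(lines), nrow(man))
  rec <- jsonlite::fromJSON(lines[1])
  expect_equal(rec$image_id, man$image_id[1])
})
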