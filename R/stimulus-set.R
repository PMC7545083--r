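#' Default pixel-noise levels
#'
#' The noise-pixel proportions used for the composite images: faces at
#' 44, 46, 48 and 50 percent noise pixels; flowers -- less immediately
#' visible, so degraded less -- at 38, 40, 42 and 44 percent.
#'
#' @return Named list with numeric vectors `face` and `flower`.
#' @export
default_noise_levels <- function() {
  list(
    face = c(0.44, 0.46, 0.48, 0.50),
    flower = c(0.38, 0.40, 0.42, 0.44)
  )
}

# Assemble one composite + companion pair. Order of operations:
# embed signal in a fresh pink-noise field; create a companion noise-only
# field matched to the signal-in-noise image's RMS contrast; mix
# pixel-wise at the requested noise fraction; band-pass both; enforce the
# final RMS contrast; quantise to 8 bits.
make_composite_pair <- function(signal, noise_fraction, location_id,
                                geometry, spec, mean_level, target_rms,
                                seed) {
  n <- geometry$image_px
  embed_field <- generate_pink_noise(n, n, mean_level, target_rms,
                                     seed = derive_seed(seed, "embed"))
  signal_in_noise <- place_signal(signal, embed_field, location_id, geometry)
  companion <- generate_pink_noise(n, n, mean_level, target_rms,
                                   seed = derive_seed(seed, "companion"))
  companion <- scale_to_rms(companion, compute_rms_contrast(signal_in_noise))
  mixed <- pixel_mix(signal_in_noise, companion, noise_fraction,
                     seed = derive_seed(seed, "mix"))
  composite <- bandpass_filter(mixed, spec, geometry, rescale_rms = target_rms)
  companion <- bandpass_filter(companion, spec, geometry,
                               rescale_rms = target_rms)
  list(composite = quantize_8bit(composite),
       companion = quantize_8bit(companion))
}

make_noise_only <- function(geometry, spec, mean_level, target_rms, seed) {
  n <- geometry$image_px
  field <- generate_pink_noise(n, n, mean_level, target_rms, seed = seed)
  quantize_8bit(bandpass_filter(field, spec, geometry,
                                rescale_rms = target_rms))
}

check_emitted <- function(img, id, rms_bounds, max_clip) {
  rms <- compute_rms_contrast(img)
  clip <- attr(img, "clipped_fraction")
  if (rms < rms_bounds[1] || rms > rms_bounds[2]) {
    abort(sprintf("Image '%s' has RMS contrast %.4f outside [%.2f, %.2f].",
                  id, rms, rms_bounds[1], rms_bounds[2]))
  }
  if (clip > max_clip) {
    abort(sprintf("Image '%s' clipped %.2f%% of pixels (tolerance %.2f%%).",
                  id, 100 * clip, 100 * max_clip))
  }
  c(rms = rms, clipped = clip)
}

#' Build the complete stimulus set
#'
#' Generates every image of the default design: per signal category,
#' `2 identities x 4 noise levels x images_per_cell` unique composite
#' images (128 per category at defaults) each paired with a unique
#' noise-only companion of matched contrast (256 noise-only images across
#' both categories at defaults), plus any extra unique noise-only images
#' requested (needed when noise trials outnumber signal trials, as in the
#' 25/75 design). Signal locations are balanced over the eight
#' lateralised positions within each identity-by-level cell. Every emitted
#' image is band-pass filtered, scaled to the target RMS contrast,
#' quantised to 8 bits, and verified to lie inside `rms_bounds`;
#' generation fails loudly naming the offending image otherwise.
#'
#' @inheritParams angular_size
#' @param spec A [filter_spec()].
#' @param levels Named list of noise-pixel proportions per category, as
#'   [default_noise_levels()].
#' @param images_per_cell Unique composites per identity-by-level cell.
#' @param n_extra_noise Extra unpaired noise-only images per category.
#' @param signal_images Named list of prepared signal matrices
#'   (`face_1`, `face_2`, `flower_1`, `flower_2`); defaults to the
#'   package's synthetic stand-ins at the geometry's signal height.
#' @param mean_level Mean luminance (8-bit units).
#' @param target_rms RMS contrast every image is scaled to.
#' @param rms_bounds Legal RMS contrast range for emitted images.
#' @param max_clip_fraction Maximum tolerated fraction of clipped pixels.
#' @param seed Integer seed; the whole set is byte-reproducible per seed.
#' @return A list of class `stimulus_set` with elements `images` (named
#'   list of 8-bit matrices keyed by image id) and `manifest` (a tibble
#'   with one row per image: id, category, stimulus type, identity, noise
#'   fraction, location, visual field, pair id, per-image seed, measured
#'   RMS and clipped fraction).
#' @examples
#' geom <- geometry_config(image_px = 64, signal_height_px = 24)
#' set <- build_stimulus_set(geom, images_per_cell = 1, seed = 1)
#' nrow(set$manifest)
#' @export
build_stimulus_set <- function(geometry = geometry_config(),
                               spec = filter_spec(),
                               levels = default_noise_levels(),
                               images_per_cell = 16L,
                               n_extra_noise = 0L,
                               signal_images = default_signal_images(geometry),
                               mean_level = 128,
                               target_rms = 0.30,
                               rms_bounds = c(0.25, 0.35),
                               max_clip_fraction = 0.01,
                               seed = 1L) {
  images_per_cell <- as.integer(images_per_cell)
  if (images_per_cell < 1L) abort("`images_per_cell` must be at least 1.")
  categories <- names(levels)

  grid <- tidyr::expand_grid(
    category = categories,
    identity = 1:2,
    level_idx = seq_len(length(levels[[1]])),
    rep = seq_len(images_per_cell)
  )
  grid$noise_fraction <- purrr::map2_dbl(
    grid$category, grid$level_idx, function(cat, i) levels[[cat]][i]
  )
  # Balance locations over the 8 positions within each identity x level
  # cell: a random permutation of the location ids is cycled to the cell
  # size, so counts per location differ by at most one (exactly equal
  # when the cell size is a multiple of 8), then shuffled onto images.
  grid <- with_seed_if(seed, {
    grid$location_id <- unlist(lapply(
      seq_len(nrow(grid) / images_per_cell),
      function(i) shuffle(rep(sample(0:7), length.out = images_per_cell))
    ))
    grid$image_seed <- sample.int(2^31 - 2, nrow(grid))
    grid
  })
  locs <- signal_locations(ncol(signal_images[[1]]),
                           nrow(signal_images[[1]]), geometry)
  grid$visual_field <- locs$visual_field[match(grid$location_id,
                                               locs$location_id)]

  images <- vector("list", 2L * nrow(grid))
  ids <- character(2L * nrow(grid))
  rows <- vector("list", 2L * nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    signal <- signal_images[[paste0(g$category, "_", g$identity)]]
    pair <- make_composite_pair(
      signal, g$noise_fraction, g$location_id, geometry, spec,
      mean_level, target_rms, g$image_seed
    )
    idx <- sprintf("%03d", i)
    sig_id <- paste(g$category, "signal", g$identity,
                    round(100 * g$noise_fraction), g$location_id, idx,
                    sep = "_")
    noi_id <- paste(g$category, "noise", g$identity,
                    round(100 * g$noise_fraction), g$location_id, idx,
                    sep = "_")
    qc_sig <- check_emitted(pair$composite, sig_id, rms_bounds,
                            max_clip_fraction)
    qc_noi <- check_emitted(pair$companion, noi_id, rms_bounds,
                            max_clip_fraction)
    images[[2 * i - 1]] <- pair$composite
    images[[2 * i]] <- pair$companion
    ids[2 * i - 1] <- sig_id
    ids[2 * i] <- noi_id
    rows[[2 * i - 1]] <- tibble::tibble(
      image_id = sig_id, category = g$category, stimulus_type = "signal",
      identity = g$identity, noise_fraction = g$noise_fraction,
      location_id = g$location_id, visual_field = g$visual_field,
      pair_id = noi_id, seed = g$image_seed,
      rms = qc_sig[["rms"]], clipped_fraction = qc_sig[["clipped"]]
    )
    rows[[2 * i]] <- tibble::tibble(
      image_id = noi_id, category = g$category, stimulus_type = "noise_only",
      identity = g$identity, noise_fraction = g$noise_fraction,
      location_id = NA_integer_, visual_field = NA_character_,
      pair_id = sig_id, seed = g$image_seed,
      rms = qc_noi[["rms"]], clipped_fraction = qc_noi[["clipped"]]
    )
  }

  if (n_extra_noise > 0L) {
    extra_seeds <- with_seed_if(
      derive_seed(seed, "extra"),
      sample.int(2^31 - 2, n_extra_noise * length(categories))
    )
    j <- 0L
    for (cat in categories) {
      for (k in seq_len(n_extra_noise)) {
        j <- j + 1L
        id <- sprintf("%s_noise_extra_%03d", cat, k)
        img <- make_noise_only(geometry, spec, mean_level, target_rms,
                               extra_seeds[j])
        qc <- check_emitted(img, id, rms_bounds, max_clip_fraction)
        images[[length(images) + 1L]] <- img
        ids[length(ids) + 1L] <- id
        rows[[length(rows) + 1L]] <- tibble::tibble(
          image_id = id, category = cat, stimulus_type = "noise_only",
          identity = NA_integer_, noise_fraction = NA_real_,
          location_id = NA_integer_, visual_field = NA_character_,
          pair_id = NA_character_, seed = extra_seeds[j],
          rms = qc[["rms"]], clipped_fraction = qc[["clipped"]]
        )
      }
    }
  }

  names(images) <- ids
  structure(
    list(images = images, manifest = dplyr::bind_rows(rows),
         geometry = geometry, spec = spec, seed = as.integer(seed)),
    class = "stimulus_set"
  )
}

#' @export
print.stimulus_set <- function(x, ...) {
  counts <- table(x$manifest$category, x$manifest$stimulus_type)
  cat("<stimulus_set> ", nrow(x$manifest), " images (",
      x$geometry$image_px, "x", x$geometry$image_px, " px, ",
      x$geometry$image_deg, " deg)\n", sep = "")
  print(counts)
  invisible(x)
}

#' Write a stimulus set to disk
#'
#' Writes every image as an 8-bit grayscale PNG named
#' `{label}_{image_id}.png` and the manifest as JSON lines (one record per
#' image) in `manifest.jsonl`.
#'
#' @param set A `stimulus_set`.
#' @param dir Output directory (created if needed).
#' @param label Prefix for image filenames.
#' @return Invisibly, the manifest tibble with a `filename` column.
#' @export
write_stimulus_set <- function(set, dir, label = "exp") {
  if (!inherits(set, "stimulus_set")) abort("`set` must be a stimulus_set.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- set$manifest
  manifest$filename <- paste0(label, "_", manifest$image_id, ".png")
  for (i in seq_len(nrow(manifest))) {
    img <- set$images[[manifest$image_id[i]]]
    png::writePNG(img / 255, file.path(dir, manifest$filename[i]))
  }
  con <- file(file.path(dir, "manifest.jsonl"), open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(manifest))) {
    writeLines(jsonlite::toJSON(as.list(manifest[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  }
  invisible(manifest)
}
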