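#' Virtual stimulus manifest
#'
#' Builds the per-image metadata records of a stimulus set without
#' rendering any pixels. Useful wherever only the design structure
#' matters -- trial scheduling and observer simulation consume image
#' metadata (category, noise fraction, location, visual field), not
#' luminance values.
#'
#' @inheritParams build_stimulus_set
#' @param n_noise_per_category Noise-only images per category (128 pairs
#'   the default signal count; 192 is needed per block for the 25/75
#'   signal/noise design).
#' @param seed Integer seed for the location shuffle.
#' @return A manifest tibble with the same design columns as
#'   [build_stimulus_set()]'s manifest (`rms` and `clipped_fraction` are
#'   `NA`).
#' @examples
#' nrow(virtual_manifest())
#' @export
virtual_manifest <- function(levels = default_noise_levels(),
                             images_per_cell = 16L,
                             n_noise_per_category = 128L,
                             seed = 1L) {
  images_per_cell <- as.integer(images_per_cell)
  n_signal <- 2L * length(levels[[1]]) * images_per_cell
  n_extra <- n_noise_per_category - n_signal
  if (n_extra < 0L) {
    abort("`n_noise_per_category` must be at least the per-category signal count.")
  }
  grid <- tidyr::expand_grid(
    category = names(levels),
    identity = 1:2,
    level_idx = seq_len(length(levels[[1]])),
    rep = seq_len(images_per_cell)
  )
  grid$noise_fraction <- purrr::map2_dbl(
    grid$category, grid$level_idx, function(cat, i) levels[[cat]][i]
  )
  grid$location_id <- with_seed_if(seed, unlist(lapply(
    seq_len(nrow(grid) / images_per_cell),
    function(i) shuffle(rep(sample(0:7), length.out = images_per_cell))
  )))
  grid$visual_field <- ifelse(grid$location_id <= 3L, "LVF", "RVF")
  idx <- sprintf("%03d", seq_len(nrow(grid)))
  signal <- tibble::tibble(
    image_id = paste(grid$category, "signal", grid$identity,
                     round(100 * grid$noise_fraction), grid$location_id,
                     idx, sep = "_"),
    category = grid$category, stimulus_type = "signal",
    identity = grid$identity, noise_fraction = grid$noise_fraction,
    location_id = grid$location_id, visual_field = grid$visual_field
  )
  noise <- tibble::tibble(
    image_id = paste(grid$category, "noise", grid$identity,
                     round(100 * grid$noise_fraction), grid$location_id,
                     idx, sep = "_"),
    category = grid$category, stimulus_type = "noise_only",
    identity = grid$identity, noise_fraction = grid$noise_fraction,
    location_id = NA_integer_, visual_field = NA_character_
  )
  extra <- NULL
  if (n_extra > 0L) {
    extra <- tidyr::expand_grid(category = names(levels),
                                k = seq_len(n_extra))
    extra <- tibble::tibble(
      image_id = sprintf("%s_noise_extra_%03d", extra$category, extra$k),
      category = extra$category, stimulus_type = "noise_only",
      identity = NA_integer_, noise_fraction = NA_real_,
      location_id = NA_integer_, visual_field = NA_character_
    )
  }
  out <- dplyr::bind_rows(signal, noise, extra)
  out$pair_id <- NA_character_
  out$seed <- NA_integer_
  out$rms <- NA_real_
  out$clipped_fraction <- NA_real_
  out
}

block_composition <- function(experiment) {
  if (experiment == 1L) {
    c(signal = 128L, noise = 128L)
  } else if (experiment == 2L) {
    c(signal = 64L, noise = 192L)
  } else {
    abort("`experiment` must be 1 or 2.")
  }
}

#' Build one block's trial schedule
#'
#' Draws the trials for a single face or flower block of 256 trials, in
#' seeded random order, with every unique image used at most once. In the
#' equal-ratio design (experiment 1) a block holds 128 signal and 128
#' noise trials; in the 25/75 design (experiment 2) 64 signal and 192
#' noise trials, with the 64 signal images drawn balanced over
#' identity x noise level x side. Noise-only trials are assigned a
#' presentation hemifield balanced half LVF / half RVF; signal trials are
#' presented in the hemifield matching their embedded location.
#'
#' @param experiment 1 (equal signal/noise ratio) or 2 (25% signal).
#' @param block Block category, `"face"` or `"flower"`.
#' @param manifest Manifest tibble from [build_stimulus_set()] or
#'   [virtual_manifest()].
#' @param seed Integer seed; the draw and ordering are deterministic
#'   per seed.
#' @param include_practice If `TRUE`, prepends 8 flagged practice trials
#'   (4 signal, 4 noise; feedback trials, excluded from analysis; they
#'   reuse images from the block's pool).
#' @return A tibble, one row per trial: `trial`, `category`,
#'   `stimulus_type`, `image_id`, `noise_fraction`, `location_id`,
#'   `visual_field`, `duration_ms`, `iti_ms`, `practice`.
#' @examples
#' sched <- build_block_schedule(1, "face", virtual_manifest(), seed = 7)
#' table(sched$stimulus_type)
#' @export
build_block_schedule <- function(experiment, block, manifest, seed = NULL,
                                 include_practice = FALSE) {
  experiment <- as.integer(experiment)
  block <- match.arg(block, c("face", "flower"))
  comp <- block_composition(experiment)
  sig_pool <- manifest[manifest$category == block &
                         manifest$stimulus_type == "signal", ]
  noi_pool <- manifest[manifest$category == block &
                         manifest$stimulus_type == "noise_only", ]
  if (nrow(noi_pool) < comp[["noise"]]) {
    abort(sprintf(
      "Need %d unique noise-only images for a %s block, manifest has %d.",
      comp[["noise"]], block, nrow(noi_pool)
    ))
  }
  if (nrow(sig_pool) < comp[["signal"]]) {
    abort(sprintf(
      "Need %d unique signal images for a %s block, manifest has %d.",
      comp[["signal"]], block, nrow(sig_pool)
    ))
  }
  with_seed_if(seed, {
    if (comp[["signal"]] < nrow(sig_pool)) {
      # balanced subset over identity x level x side
      sig_pool$side <- ifelse(sig_pool$location_id <= 3L, "L", "R")
      cells <- split(
        seq_len(nrow(sig_pool)),
        interaction(sig_pool$identity, sig_pool$noise_fraction,
                    sig_pool$side, drop = TRUE)
      )
      per_cell <- comp[["signal"]] / length(cells)
      if (per_cell %% 1 != 0) {
        abort("Signal count does not divide evenly over design cells.")
      }
      take <- unlist(lapply(cells, function(ix) {
        if (length(ix) < per_cell) {
          abort("Too few unique signal images in a design cell for this block.")
        }
        ix[sample.int(length(ix), per_cell)]
      }))
      sig_pool <- sig_pool[take, ]
      sig_pool$side <- NULL
    }
    noi_pool <- noi_pool[sample.int(nrow(noi_pool), comp[["noise"]]), ]
    noi_pool$visual_field <- sample(
      rep(c("LVF", "RVF"), length.out = nrow(noi_pool))
    )
    keep <- c("image_id", "category", "stimulus_type", "noise_fraction",
              "location_id", "visual_field")
    trials <- dplyr::bind_rows(sig_pool[, keep], noi_pool[, keep])
    trials <- trials[sample.int(nrow(trials)), ]
    trials$trial <- seq_len(nrow(trials))
    trials$practice <- FALSE
    if (include_practice) {
      prac <- trials[c(sample(which(trials$stimulus_type == "signal"), 4L),
                       sample(which(trials$stimulus_type == "noise_only"), 4L)), ]
      prac <- prac[sample.int(8L), ]
      prac$trial <- seq_len(8L)
      prac$practice <- TRUE
      trials$trial <- trials$trial + 8L
      trials <- dplyr::bind_rows(prac, trials)
    }
    trials$duration_ms <- 180
    trials$iti_ms <- 1000
    dplyr::relocate(tibble::as_tibble(trials), "trial")
  })
}

#' Counterbalance a cohort
#'
#' Assigns each subject one of the eight cells of block order (face or
#' flower first) x response mapping (which key means "present") x
#' responding hand, filling the cells as evenly as possible: for any
#' cohort size, cell counts differ by at most one.
#'
#' @param n_subjects Number of subjects (at least 1).
#' @param seed Integer seed for the assignment order.
#' @return A tibble with `subject_id`, `block_order`
#'   (`"face_first"`/`"flower_first"`), `present_key` (`"up"`/`"down"`),
#'   `response_hand` (`"left"`/`"right"`).
#' @examples
#' table(counterbalance_cohort(26, seed = 1)$block_order)
#' @export
counterbalance_cohort <- function(n_subjects, seed = NULL) {
  if (!is_scalar_number(n_subjects) || n_subjects < 1) {
    abort("`n_subjects` must be a positive integer.")
  }
  n_subjects <- as.integer(n_subjects)
  cells <- tidyr::expand_grid(
    block_order = c("face_first", "flower_first"),
    present_key = c("up", "down"),
    response_hand = c("left", "right")
  )
  with_seed_if(seed, {
    n_cycles <- ceiling(n_subjects / 8L)
    order_ix <- unlist(lapply(seq_len(n_cycles), function(i) sample.int(8L)))
    out <- cells[order_ix[seq_len(n_subjects)], ]
    out$subject_id <- seq_len(n_subjects)
    dplyr::relocate(out, "subject_id")
  })
}

#' Build a subject's full trial schedule
#'
#' Two blocks of 256 trials (face and flower) in the subject's
#' counterbalanced order, each drawn by [build_block_schedule()] from the
#' same stimulus manifest with subject-specific seeds.
#'
#' @inheritParams build_block_schedule
#' @param subject_id Subject identifier (integer).
#' @param counterbalance One row of [counterbalance_cohort()] for this
#'   subject (defaults to face-first, "up" means present, right hand).
#' @return A tibble of both blocks with `subject_id`, `experiment` and
#'   `block_index` columns prepended.
#' @export
build_trial_schedule <- function(experiment, subject_id, manifest,
                                 counterbalance = NULL, seed = NULL,
                                 include_practice = FALSE) {
  if (is.null(counterbalance)) {
    counterbalance <- tibble::tibble(
      subject_id = subject_id, block_order = "face_first",
      present_key = "up", response_hand = "right"
    )
  }
  blocks <- if (counterbalance$block_order[1] == "face_first") {
    c("face", "flower")
  } else {
    c("flower", "face")
  }
  out <- purrr::imap(blocks, function(bl, i) {
    sched <- build_block_schedule(
      experiment, bl, manifest,
      seed = derive_seed(seed, paste0("s", subject_id, "b", i)),
      include_practice = include_practice
    )
    sched$block_index <- i
    sched
  })
  out <- dplyr::bind_rows(out)
  out$subject_id <- subject_id
  out$experiment <- as.integer(experiment)
  dplyr::relocate(out, "subject_id", "experiment", "block_index")
}
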