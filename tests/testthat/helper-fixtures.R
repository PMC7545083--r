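# Shared small-scale fixtures. Stimulus tests use a reduced geometry
# (64-px grid, 24-px signals) so frequency-domain work stays cheap; the
# full-size printed design is exercised once in the acceptance tests.

small_geometry <- function() {
  geometry_config(image_px = 64L, signal_height_px = 24L)
}

small_stimulus_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_stimulus_set(
        small_geometry(), images_per_cell = 2L, seed = 11L
      )
    }
    cache
  }
})

# A schedule-shaped tibble with arbitrary per-cell trial counts, for
# estimator-consistency checks that need many trials per cell.
flat_schedule <- function(n_signal, n_noise,
                          categories = c("face", "flower"),
                          fields = c("LVF", "RVF")) {
  cells <- tidyr::expand_grid(category = categories, visual_field = fields)
  dplyr::bind_rows(purrr::pmap(cells, function(category, visual_field) {
    tibble::tibble(
      category = category,
      visual_field = visual_field,
      stimulus_type = rep(c("signal", "noise_only"), c(n_signal, n_noise)),
      noise_fraction = ifelse(stimulus_type == "signal", 0.44, NA_real_)
    )
  }))
}

sdt_observer_row <- function(dprime_face = 0.8, dprime_flower = 0.8,
                             crit = c(face_LVF = 0, face_RVF = 0,
                                      flower_LVF = 0, flower_RVF = 0),
                             lapse = 0) {
  tibble::tibble(
    subject_id = 1L,
    dprime_face = dprime_face, dprime_flower = dprime_flower,
    crit_face_LVF = crit[["face_LVF"]], crit_face_RVF = crit[["face_RVF"]],
    crit_flower_LVF = crit[["flower_LVF"]],
    crit_flower_RVF = crit[["flower_RVF"]],
    lapse_rate = lapse, rt_meanlog = log(0.5), rt_slow = 0.25,
    rt_sdlog = 0.2
  )
}
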