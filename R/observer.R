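# O-LIFE short-scale item counts; subscale scores are sums of yes/no
# items, so binomial sampling respects the scale ranges by construction.
olife_items <- c(UnEx = 12L, CogDis = 11L, IntAnh = 10L, ImpNon = 10L)

#' Cohort specification for simulated observers
#'
#' Describes the population a synthetic cohort is drawn from: group means
#' and between-subject SDs of the latent signal-detection parameters
#' (sensitivity per signal category, criterion per category x visual
#' field), the coupling between schizotypy traits and response bias, the
#' reaction-time model, and -- for drift-diffusion observers -- the
#' accumulator parameters.
#'
#' Criterion construction: each subject's bias deviate for a category is
#' `r * z(trait) + sqrt(1 - r^2) * e`, with `z(trait)` the trait score
#' standardised by its population moments and `e` independent standard
#' normal, so the population correlation between the trait and the
#' category's criterion equals `r` exactly. The deviate is shared across
#' hemifields (bias is treated as a subject-level disposition; hemifields
#' differ in their fixed offsets).
#'
#' @param n_subjects Cohort size (at least 2).
#' @param model `"sdt"` (equal-variance signal detection) or `"ddm"`
#'   (drift diffusion).
#' @param dprime_mean,dprime_sd Named numeric vectors (`face`, `flower`):
#'   group mean and between-subject SD of true sensitivity per category.
#' @param dprime_cor Correlation between a subject's face and flower
#'   sensitivities (shared task ability).
#' @param criterion_mean,criterion_sd Named numeric vectors with elements
#'   `face_LVF`, `face_RVF`, `flower_LVF`, `flower_RVF`.
#' @param trait_coupling List with `unex_face` and `cogdis_flower`:
#'   population correlations between Unusual Experiences and face
#'   criterion, and Cognitive Disorganisation and flower criterion.
#' @param trait_probs Named per-item endorsement probabilities for the
#'   four O-LIFE subscales (binomial trait model).
#' @param lapse_rate Probability of a uniformly random response,
#'   in \eqn{[0, 0.05]}.
#' @param rt_meanlog,rt_slow,rt_sdlog Lognormal reaction-time model for
#'   SDT observers: `log RT ~ Normal(rt_meanlog + rt_slow *
#'   exp(-|evidence - criterion|), rt_sdlog)`, i.e. responses slow when
#'   the evidence lands near the criterion.
#' @param ddm For `model = "ddm"`: list of group means/SDs for
#'   `drift_scale` (evidence units/s per unit signal strength),
#'   `boundary` (separation a), `bias_LVF`, `bias_RVF` (relative start
#'   points z/a), `t0` (non-decision time, s); plus `s` (diffusion
#'   coefficient, fixed scale), `dt` (Euler step, s) and `t_max`
#'   (first-passage cap, s).
#' @return A list of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n_subjects = 4)
#' sample_cohort(spec, seed = 1)
#' @export
cohort_spec <- function(n_subjects = 26L,
                        model = c("sdt", "ddm"),
                        dprime_mean = c(face = 0.277, flower = 0.791),
                        dprime_sd = c(face = 0.45, flower = 0.49),
                        dprime_cor = 0.5,
                        criterion_mean = c(face_LVF = 0.329, face_RVF = 0.09,
                                           flower_LVF = 0.329,
                                           flower_RVF = 0.09),
                        criterion_sd = c(face_LVF = 0.48, face_RVF = 0.45,
                                         flower_LVF = 0.48,
                                         flower_RVF = 0.45),
                        trait_coupling = list(unex_face = -0.559,
                                              cogdis_flower = 0),
                        trait_probs = c(UnEx = 0.29, CogDis = 0.35,
                                        IntAnh = 0.25, ImpNon = 0.30),
                        lapse_rate = 0.02,
                        rt_meanlog = log(0.5),
                        rt_slow = 0.25,
                        rt_sdlog = 0.2,
                        ddm = list(drift_scale_mean = 0.35,
                                   drift_scale_sd = 0.08,
                                   boundary_mean = 0.12, boundary_sd = 0.02,
                                   bias_LVF_mean = 0.46, bias_RVF_mean = 0.50,
                                   bias_sd = 0.04,
                                   t0_mean = 0.30, t0_sd = 0.05,
                                   s = 0.1, dt = 0.001, t_max = 5)) {
  model <- match.arg(model)
  if (!is_scalar_number(n_subjects) || n_subjects < 2) {
    abort("`n_subjects` must be at least 2.")
  }
  for (r in unlist(trait_coupling)) {
    if (abs(r) > 1) abort("Trait-coupling correlations must lie in [-1, 1].")
  }
  if (abs(dprime_cor) > 1) abort("`dprime_cor` must lie in [-1, 1].")
  if (any(dprime_sd < 0) || any(criterion_sd < 0)) {
    abort("Between-subject SDs must be non-negative.")
  }
  if (lapse_rate < 0 || lapse_rate > 0.05) {
    abort("`lapse_rate` must lie in [0, 0.05].")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), model = model,
      dprime_mean = dprime_mean, dprime_sd = dprime_sd,
      dprime_cor = dprime_cor,
      criterion_mean = criterion_mean, criterion_sd = criterion_sd,
      trait_coupling = trait_coupling, trait_probs = trait_probs,
      lapse_rate = lapse_rate, rt_meanlog = rt_meanlog,
      rt_slow = rt_slow, rt_sdlog = rt_sdlog, ddm = ddm
    ),
    class = "cohort_spec"
  )
}

# Standardise a binomial trait score by its population moments, so
# correlations built on it hit their target exactly in the population.
standardize_trait <- function(score, n_items, p) {
  (score - n_items * p) / sqrt(n_items * p * (1 - p))
}

#' Sample a cohort of observers
#'
#' Draws `n_subjects` observers from a [cohort_spec()]: four O-LIFE trait
#' scores per subject (binomial over scale items, so scores respect the
#' scale ranges), latent sensitivities and criteria, and -- for DDM
#' observers -- accumulator parameters. The trait/criterion coupling is
#' constructed so the population correlation equals the cohort
#' specification's target.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @return A tibble with one row per subject: `subject_id`, traits
#'   (`UnEx`, `CogDis`, `IntAnh`, `ImpNon`), and model parameters
#'   (`dprime_face`, `dprime_flower`, `crit_face_LVF`, ...; or
#'   `drift_scale`, `boundary`, `bias_LVF`, `bias_RVF`, `t0` for DDM).
#'   The cohort's model is attached as attribute `model`.
#' @export
sample_cohort <- function(spec, seed = NULL) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec.")
  n <- spec$n_subjects
  with_seed_if(seed, {
    traits <- purrr::imap(olife_items, function(k, nm) {
      rbinom(n, k, spec$trait_probs[[nm]])
    })
    z_unex <- standardize_trait(traits$UnEx, olife_items[["UnEx"]],
                                spec$trait_probs[["UnEx"]])
    z_cogdis <- standardize_trait(traits$CogDis, olife_items[["CogDis"]],
                                  spec$trait_probs[["CogDis"]])
    r1 <- spec$trait_coupling$unex_face
    r2 <- spec$trait_coupling$cogdis_flower
    u_face <- r1 * z_unex + sqrt(1 - r1^2) * rnorm(n)
    u_flower <- r2 * z_cogdis + sqrt(1 - r2^2) * rnorm(n)
    a <- rnorm(n)
    b <- spec$dprime_cor * a + sqrt(1 - spec$dprime_cor^2) * rnorm(n)
    out <- tibble::tibble(
      subject_id = seq_len(n),
      UnEx = traits$UnEx, CogDis = traits$CogDis,
      IntAnh = traits$IntAnh, ImpNon = traits$ImpNon
    )
    if (spec$model == "sdt") {
      out$dprime_face <- spec$dprime_mean[["face"]] +
        spec$dprime_sd[["face"]] * a
      out$dprime_flower <- spec$dprime_mean[["flower"]] +
        spec$dprime_sd[["flower"]] * b
      for (cell in names(spec$criterion_mean)) {
        u <- if (startsWith(cell, "face")) u_face else u_flower
        out[[paste0("crit_", cell)]] <-
          spec$criterion_mean[[cell]] + spec$criterion_sd[[cell]] * u
      }
      out$lapse_rate <- spec$lapse_rate
      out$rt_meanlog <- spec$rt_meanlog
      out$rt_slow <- spec$rt_slow
      out$rt_sdlog <- spec$rt_sdlog
    } else {
      d <- spec$ddm
      out$drift_scale <- pmax(d$drift_scale_mean + d$drift_scale_sd * a, 0.01)
      out$boundary <- pmax(rnorm(n, d$boundary_mean, d$boundary_sd), 0.02)
      out$bias_LVF <- pmin(pmax(
        d$bias_LVF_mean + d$bias_sd * u_face, 0.05), 0.95)
      out$bias_RVF <- pmin(pmax(
        d$bias_RVF_mean + d$bias_sd * u_face, 0.05), 0.95)
      out$t0 <- pmax(rnorm(n, d$t0_mean, d$t0_sd), 0.05)
      out$lapse_rate <- spec$lapse_rate
    }
    attr(out, "model") <- spec$model
    attr(out, "spec") <- spec
    out
  })
}

#' Analytic hit and false-alarm rates of an equal-variance observer
#'
#' Under the equal-variance model with symmetric evidence placement
#' (noise at -d'/2, signal at +d'/2, unit variance) and decision
#' criterion c, the hit rate is \eqn{\Phi(d'/2 - c)} and the false-alarm
#' rate \eqn{\Phi(-d'/2 - c)}. Plugging these into the d'/criterion
#' estimators returns the generating parameters exactly, making this the
#' oracle for estimator-closure checks.
#'
#' @param dprime,criterion Finite numerics (vectorised).
#' @return A tibble with columns `hr` and `far`.
#' @examples
#' analytic_sdt_rates(1, 0)
#' @export
analytic_sdt_rates <- function(dprime, criterion) {
  if (any(!is.finite(dprime)) || any(!is.finite(criterion))) {
    abort("`dprime` and `criterion` must be finite.")
  }
  tibble::tibble(
    hr = pnorm(dprime / 2 - criterion),
    far = pnorm(-dprime / 2 - criterion)
  )
}

# Vectorised SDT response simulation over a schedule for one observer row.
simulate_sdt_trials <- function(observer, trials) {
  n <- nrow(trials)
  d <- ifelse(trials$category == "face", observer$dprime_face,
              observer$dprime_flower)
  cells <- c("face_LVF", "face_RVF", "flower_LVF", "flower_RVF")
  crit_lookup <- vapply(cells, function(cl) observer[[paste0("crit_", cl)]],
                        numeric(1))
  crit <- unname(crit_lookup[paste0(trials$category, "_",
                                    trials$visual_field)])
  mu <- ifelse(trials$stimulus_type == "signal", d / 2, -d / 2)
  x <- rnorm(n, mu, 1)
  present <- x > crit
  lapse <- runif(n) < observer$lapse_rate
  present[lapse] <- runif(sum(lapse)) < 0.5
  meanlog <- observer$rt_meanlog + observer$rt_slow * exp(-abs(x - crit))
  rt <- exp(rnorm(n, meanlog, observer$rt_sdlog))
  tibble::tibble(
    response = ifelse(present, "present", "absent"),
    correct = present == (trials$stimulus_type == "signal"),
    rt_s = rt,
    forced_guess = FALSE
  )
}

#' First-passage choice probability and mean decision time of the
#' diffusion model
#'
#' Standard closed-form results for a Wiener accumulator between
#' absorbing boundaries at 0 and `a`, starting at `z`, with drift `v` and
#' diffusion coefficient `s`: the probability of absorbing at the upper
#' boundary, and the mean decision time for an unbiased start
#' (`z = a/2`). These serve as the independent check on the Euler
#' simulator.
#'
#' @param v Drift rate (evidence units/s); may be zero.
#' @param a Boundary separation (> 0).
#' @param z Start point, strictly between 0 and `a`.
#' @param s Diffusion coefficient (> 0).
#' @return A tibble with `p_upper` and `mean_dt_unbiased` (the latter is
#'   the mean decision time when `z = a/2`).
#' @examples
#' ddm_closed_form(v = 0.2, a = 0.1, z = 0.05)
#' @export
ddm_closed_form <- function(v, a, z, s = 0.1) {
  if (any(a <= 0) || any(z <= 0) || any(z >= a) || any(s <= 0)) {
    abort("Require a > 0, 0 < z < a, s > 0.")
  }
  p_upper <- ifelse(
    v == 0, z / a,
    (1 - exp(-2 * v * z / s^2)) / (1 - exp(-2 * v * a / s^2))
  )
  mean_dt <- ifelse(
    v == 0, a^2 / (4 * s^2),
    (a / (2 * v)) * tanh(v * a / (2 * s^2))
  )
  tibble::tibble(p_upper = p_upper, mean_dt_unbiased = mean_dt)
}

# Vectorised Euler-Maruyama first-passage simulation with a Brownian
# bridge correction for within-step boundary crossings: a step ending
# inside the corridor may still have touched a boundary in between, with
# probability exp(-2 (b - x0)(b - x1) / (s^2 dt)) for distances to the
# boundary b at the step's endpoints. Without this correction the
# discrete walk systematically overshoots decision times and biases
# choice probabilities by O(sqrt(dt)). Signal trials drift upward at
# drift_scale * (1 - noise_fraction); noise trials have zero drift.
# Upper boundary = "present". Walks that do not absorb before t_max are
# forced to a fair guess and flagged.
simulate_ddm_trials <- function(observer, trials, ddm_pars) {
  n <- nrow(trials)
  s <- ddm_pars$s
  dt <- ddm_pars$dt
  n_steps <- as.integer(ceiling(ddm_pars$t_max / dt))
  strength <- ifelse(trials$stimulus_type == "signal",
                     1 - trials$noise_fraction, 0)
  strength[is.na(strength)] <- 0
  v <- observer$drift_scale * strength
  a <- observer$boundary
  bias <- ifelse(trials$visual_field == "LVF", observer$bias_LVF,
                 observer$bias_RVF)
  state <- a * bias
  upper <- rep(NA, n)
  steps <- rep(n_steps, n)
  active <- seq_len(n)
  sqdt <- sqrt(dt)
  a_vec <- rep_len(a, n)
  for (k in seq_len(n_steps)) {
    old <- state[active]
    new <- old + v[active] * dt + s * sqdt * rnorm(length(active))
    aa <- a_vec[active]
    crossed_up <- new >= aa
    crossed_lo <- new <= 0
    inside <- !crossed_up & !crossed_lo
    if (any(inside)) {
      # bridge probability of an unobserved touch of either boundary
      p_up <- exp(-2 * pmax(aa - old, 0) * pmax(aa - new, 0) / (s^2 * dt))
      p_lo <- exp(-2 * pmax(old, 0) * pmax(new, 0) / (s^2 * dt))
      u <- runif(length(old))
      bridge_up <- inside & u < p_up
      bridge_lo <- inside & !bridge_up &
        runif(length(old)) < p_lo
      crossed_up <- crossed_up | bridge_up
      crossed_lo <- crossed_lo | bridge_lo
    }
    hit_up <- active[crossed_up]
    hit_lo <- active[crossed_lo]
    if (length(hit_up)) {
      upper[hit_up] <- TRUE
      steps[hit_up] <- k
    }
    if (length(hit_lo)) {
      upper[hit_lo] <- FALSE
      steps[hit_lo] <- k
    }
    state[active] <- new
    active <- active[!(crossed_up | crossed_lo)]
    if (!length(active)) break
  }
  forced <- is.na(upper)
  upper[forced] <- runif(sum(forced)) < 0.5
  present <- upper
  lapse <- runif(n) < observer$lapse_rate
  present[lapse] <- runif(sum(lapse)) < 0.5
  tibble::tibble(
    response = ifelse(present, "present", "absent"),
    correct = present == (trials$stimulus_type == "signal"),
    rt_s = steps * dt + observer$t0,
    forced_guess = forced
  )
}

#' Run one observer through a trial schedule
#'
#' Simulates a response and reaction time for every trial of a schedule
#' under the observer's response model (SDT or DDM, inferred from the
#' parameter columns), returning a trial log ready for analysis.
#'
#' @param observer A one-row tibble of observer parameters, as one row of
#'   [sample_cohort()].
#' @param schedule A trial schedule from [build_trial_schedule()] (or any
#'   tibble with `category`, `stimulus_type`, `visual_field`,
#'   `noise_fraction` columns).
#' @param seed Optional integer seed.
#' @param ddm_pars DDM integration constants (`s`, `dt`, `t_max`); taken
#'   from [cohort_spec()]'s defaults when `NULL`.
#' @return The schedule tibble with `response`, `correct`, `rt_s` and
#'   `forced_guess` columns appended.
#' @export
run_experiment <- function(observer, schedule, seed = NULL,
                           ddm_pars = NULL) {
  if (nrow(observer) != 1L) abort("`observer` must be a single row.")
  needed <- c("category", "stimulus_type", "visual_field")
  if (!all(needed %in% names(schedule))) {
    abort("`schedule` is missing trial descriptor columns.")
  }
  is_ddm <- "drift_scale" %in% names(observer)
  with_seed_if(seed, {
    res <- if (is_ddm) {
      if (is.null(ddm_pars)) {
        ddm_pars <- list(s = 0.1, dt = 0.001, t_max = 5)
      }
      simulate_ddm_trials(observer, schedule, ddm_pars)
    } else {
      simulate_sdt_trials(observer, schedule)
    }
    dplyr::bind_cols(schedule, res)
  })
}

#' Run a whole cohort through per-subject schedules
#'
#' @param cohort A tibble from [sample_cohort()].
#' @param schedules A tibble of stacked per-subject schedules (with a
#'   `subject_id` column matching the cohort).
#' @inheritParams run_experiment
#' @return A trial-log tibble over all subjects.
#' @export
run_cohort_experiment <- function(cohort, schedules, seed = NULL,
                                  ddm_pars = NULL) {
  spec <- attr(cohort, "spec")
  if (is.null(ddm_pars) && !is.null(spec)) ddm_pars <- spec$ddm
  logs <- purrr::map(seq_len(nrow(cohort)), function(i) {
    sid <- cohort$subject_id[i]
    run_experiment(
      cohort[i, ], schedules[schedules$subject_id == sid, ],
      seed = derive_seed(seed, paste0("subj", sid)),
      ddm_pars = ddm_pars
    )
  })
  dplyr::bind_rows(logs)
}
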