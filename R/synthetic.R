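#' Parameters for the synthetic retirement cohort
#'
#' Defaults emulate an observational cohort of retiring workers measured one
#' year apart: 213 participants, pre-retirement compositional mean
#' (497, 584, 282, 77) min of sleep/SED/LPA/MVPA moving to
#' (520, 572, 272, 76) after retirement, BMI 26.3 (SD 4.8) kg/m2 drifting by
#' about -0.1, waist circumference 91.4 (SD 13.0) cm drifting by about -0.9,
#' 82% women, 31% manual workers, mean age 63.5 (SD 1.1) years, and 12%
#' long sleepers (>9 h/night self-reported).
#'
#' Compositions are logistic-normal: Gaussian draws in sleep-first pivot
#' coordinates around the pivot coordinates of the mean compositions, with
#' independent per-coordinate standard deviations for the baseline
#' (`pre_ilr_sd`) and the one-year change (`delta_ilr_sd`). Outcome changes
#' follow the linear model the analysis assumes:
#' `change = intercept + a . (clr(post) - clr(pre)) + baseline and covariate
#' terms + noise`, with the clr effect vectors `true_clr_effect` (BMI) and
#' `true_clr_effect_wc` (waist). Effect defaults are the centred
#' `sqrt(3)/2 *` first-pivot coefficient vectors (1.34, -0.09, -0.66, -0.60)
#' and (1.51, 2.39, -1.76, -2.14); centring removes rounding so the vectors
#' sum exactly to zero, as exact clr coefficients must.
#'
#' @param n Cohort size.
#' @param seed Integer seed; every draw in [generate_cohort()] is
#'   reproducible from it.
#' @param pre_mean_minutes,post_mean_minutes Mean compositions (minutes/day).
#' @param pre_ilr_sd,delta_ilr_sd SDs of the baseline and change pivot
#'   coordinates (sleep-first basis).
#' @param true_clr_effect,true_clr_effect_wc clr effect vectors on BMI
#'   (kg/m2) and waist circumference (cm); must sum to 0 within 1e-10.
#' @param baseline_effect Effect of the baseline pivot coordinates on the
#'   BMI change (3-vector, default 0).
#' @param baseline_outcome_effect Effect of baseline BMI on its change.
#' @param outcome_pre_mean,outcome_pre_sd Baseline BMI distribution.
#' @param wc_pre_mean,wc_pre_sd Baseline waist circumference distribution.
#' @param delta_outcome_mean,delta_wc_mean Expected one-year changes.
#' @param residual_sd,wc_residual_sd Residual SDs of the outcome changes.
#' @param age_mean,age_sd,p_woman,p_manual Covariate distributions.
#' @param age_effect,sex_effect,occupation_effect Covariate effects on the
#'   BMI change (default 0).
#' @param p_long_sleeper Fraction reporting >9 h sleep/night at baseline.
#' @param followup_mean,followup_sd Follow-up time in days.
#' @return A `generator_params` list.
#' @export
generator_params <- function(n = 213,
                             seed = 1,
                             pre_mean_minutes = c(497, 584, 282, 77),
                             post_mean_minutes = c(520, 572, 272, 76),
                             pre_ilr_sd = c(0.20, 0.25, 0.35),
                             delta_ilr_sd = c(0.10, 0.12, 0.20),
                             true_clr_effect = center(sqrt(3) / 2 * c(1.34, -0.09, -0.66, -0.60)),
                             true_clr_effect_wc = center(sqrt(3) / 2 * c(1.51, 2.39, -1.76, -2.14)),
                             baseline_effect = c(0, 0, 0),
                             baseline_outcome_effect = 0,
                             outcome_pre_mean = 26.3, outcome_pre_sd = 4.8,
                             wc_pre_mean = 91.4, wc_pre_sd = 13.0,
                             delta_outcome_mean = -0.1, delta_wc_mean = -0.9,
                             residual_sd = 1.0, wc_residual_sd = 3.0,
                             age_mean = 63.5, age_sd = 1.1,
                             p_woman = 0.82, p_manual = 0.31,
                             age_effect = 0, sex_effect = 0, occupation_effect = 0,
                             p_long_sleeper = 0.12,
                             followup_mean = 365, followup_sd = 30) {
  p <- as.list(environment())
  stopifnot(p$n > 0,
            all(p$pre_ilr_sd >= 0), all(p$delta_ilr_sd >= 0),
            p$residual_sd >= 0, p$wc_residual_sd >= 0,
            length(p$true_clr_effect) == 4L,
            length(p$true_clr_effect_wc) == 4L,
            abs(sum(p$true_clr_effect)) < 1e-10,
            abs(sum(p$true_clr_effect_wc)) < 1e-10,
            p$p_woman >= 0, p$p_woman <= 1,
            p$p_manual >= 0, p$p_manual <= 1,
            p$p_long_sleeper >= 0, p$p_long_sleeper <= 1)
  structure(p, class = "generator_params")
}

#' Center a vector to zero sum
#'
#' @param x Numeric vector.
#' @return `x - mean(x)`.
#' @export
center <- function(x) x - mean(x)

#' Generate a synthetic retirement cohort
#'
#' Draws a participant table with the structure the change-on-change analysis
#' assumes (see [generator_params()] for the data-generating model). The
#' outcome changes for BMI and waist circumference share the same behavior
#' change, so both columns are internally consistent with their clr effect
#' vectors.
#'
#' @param params A [generator_params()] object.
#' @return Data.frame in the [read_participants()] layout (all optional
#'   columns present).
#' @export
generate_cohort <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed)
  n <- params$n
  basis <- pivot_basis("sleep")
  z_pre_mean <- pivot_coord(composition(params$pre_mean_minutes), basis)
  z_post_mean <- pivot_coord(composition(params$post_mean_minutes), basis)
  dz_mean <- z_post_mean - z_pre_mean

  z_pre <- sapply(1:3, function(k) stats::rnorm(n, z_pre_mean[k], params$pre_ilr_sd[k]))
  dz <- sapply(1:3, function(k) stats::rnorm(n, dz_mean[k], params$delta_ilr_sd[k]))
  pre <- pivot_inv_matrix(z_pre, basis) * 1440
  post <- pivot_inv_matrix(z_pre + dz, basis) * 1440
  dclr <- clr_matrix(post / 1440) - clr_matrix(pre / 1440)

  age <- stats::rnorm(n, params$age_mean, params$age_sd)
  woman <- stats::rbinom(n, 1, params$p_woman)
  manual <- stats::rbinom(n, 1, params$p_manual)
  season <- sample(c("winter", "spring", "summer", "autumn"), n, replace = TRUE)
  followup <- pmax(200L, as.integer(round(stats::rnorm(n, params$followup_mean,
                                                       params$followup_sd))))
  long <- stats::rbinom(n, 1, params$p_long_sleeper) == 1L
  sleep_hours <- ifelse(long, stats::runif(n, 9.25, 10.25), stats::runif(n, 6.5, 9.0))

  bmi_pre <- pmax(12, stats::rnorm(n, params$outcome_pre_mean, params$outcome_pre_sd))
  wc_pre <- pmax(50, stats::rnorm(n, params$wc_pre_mean, params$wc_pre_sd))

  # intercept calibrated so E[change] matches the requested mean drift
  cov_mean_terms <- params$age_effect * params$age_mean +
    params$sex_effect * params$p_woman +
    params$occupation_effect * params$p_manual
  a <- params$true_clr_effect
  intercept <- params$delta_outcome_mean -
    sum(a * (clr(composition(params$post_mean_minutes)) -
               clr(composition(params$pre_mean_minutes)))) -
    sum(params$baseline_effect * z_pre_mean) -
    params$baseline_outcome_effect * params$outcome_pre_mean -
    cov_mean_terms
  d_bmi <- intercept + drop(dclr %*% a) + drop(z_pre %*% params$baseline_effect) +
    params$baseline_outcome_effect * bmi_pre +
    params$age_effect * age + params$sex_effect * woman +
    params$occupation_effect * manual +
    stats::rnorm(n, 0, params$residual_sd)

  a_wc <- params$true_clr_effect_wc
  intercept_wc <- params$delta_wc_mean -
    sum(a_wc * (clr(composition(params$post_mean_minutes)) -
                  clr(composition(params$pre_mean_minutes))))
  d_wc <- intercept_wc + drop(dclr %*% a_wc) +
    stats::rnorm(n, 0, params$wc_residual_sd)

  df <- data.frame(
    id = sprintf("P%04d", seq_len(n)),
    sleep_min_pre = pre[, "sleep"], sed_min_pre = pre[, "sed"],
    lpa_min_pre = pre[, "lpa"], mvpa_min_pre = pre[, "mvpa"],
    sleep_min_post = post[, "sleep"], sed_min_post = post[, "sed"],
    lpa_min_post = post[, "lpa"], mvpa_min_post = post[, "mvpa"],
    bmi_pre = bmi_pre, bmi_post = bmi_pre + d_bmi,
    wc_pre = wc_pre, wc_post = wc_pre + d_wc,
    age = age,
    sex = ifelse(woman == 1L, "woman", "man"),
    occupation = ifelse(manual == 1L, "manual", "non_manual"),
    season_pre = season,
    followup_days = followup,
    selfreport_sleep_pre = sleep_hours,
    stringsAsFactors = FALSE
  )
  validate_participants(df)
}

#' Generate synthetic daily wear records for a cohort
#'
#' Per participant and wave, draws `days_per_wave` measurement days whose
#' behavior minutes are the wave composition plus zero-sum Gaussian jitter
#' (rescaled to the 1440-min day), and waking wear hours such that a
#' configurable fraction of days fails the 10-h validity rule (invalid days
#' draw wear in 6-9.9 h, valid days in 14.5-16.5 h, matching typical waking
#' wear time).
#'
#' @param records Participant table.
#' @param days_per_wave Days measured per wave (default 4).
#' @param jitter_sd SD (minutes) of the per-behavior day-to-day jitter.
#' @param fraction_invalid Probability a day fails the wear rule; scalar or
#'   named `c(pre = , post = )`.
#' @param seed Integer seed.
#' @return Data.frame with columns `id`, `wave`, `date`,
#'   `wear_hours_waking`, `sleep_min`, `sed_min`, `lpa_min`, `mvpa_min`.
#' @export
make_daily_records <- function(records, days_per_wave = 4, jitter_sd = 20,
                               fraction_invalid = 0.1, seed = 1) {
  stopifnot(days_per_wave >= 1)
  set.seed(seed)
  if (length(fraction_invalid) == 1L) {
    fraction_invalid <- c(pre = unname(fraction_invalid),
                          post = unname(fraction_invalid))
  }
  out <- list()
  for (w in c("pre", "post")) {
    mins <- wave_minutes(records, w)
    start <- if (w == "pre") as.Date("2017-03-01") else as.Date("2018-03-01")
    for (i in seq_len(nrow(records))) {
      for (d in seq_len(days_per_wave)) {
        e <- stats::rnorm(4, 0, jitter_sd)
        e <- e - mean(e)
        day <- pmax(mins[i, ] + e, 1)
        day <- day / sum(day) * 1440
        invalid <- stats::runif(1) < fraction_invalid[[w]]
        wear <- if (invalid) stats::runif(1, 6, 9.9) else stats::runif(1, 14.5, 16.5)
        out[[length(out) + 1L]] <- data.frame(
          id = records$id[i], wave = w,
          date = as.character(start + d - 1L),
          wear_hours_waking = wear,
          sleep_min = day[["sleep"]], sed_min = day[["sed"]],
          lpa_min = day[["lpa"]], mvpa_min = day[["mvpa"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
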