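#' Configuration for the synthetic T1D cohort generator
#'
#' Bundles every tunable of [generate_cohort()] with defaults calibrated so the
#' simulated cohort reproduces the descriptive glycaemic profile of free-living
#' adults and adolescents with type 1 diabetes under CGM (pooled CGM
#' coefficient of variation around 34%, average glucose around 8.4 mmol/L,
#' median activity-bout duration 23 min) and a known causal effect structure
#' for short physical-activity (PA) bouts.
#'
#' Glucose dynamics are a discrete-time mean-reverting (Ornstein-Uhlenbeck
#' style) walk on the CGM grid with additive meal excursions, bolus-driven
#' declines following a linear 4-h insulin action curve, and i.i.d. sensor
#' noise. Each PA bout receives an attributable glucose change
#' \deqn{\Delta_b = \beta_0 + s^T (u_b - \bar u) + b_i + \epsilon_b}
#' spread uniformly over the bout plus the 20-min measurement tail, where
#' \eqn{u_b} are the bout's onset covariates on the moderator scales described
#' below, \eqn{\bar u} their means over eligible bouts (onset glucose
#' > 10 mmol/L), \eqn{b_i} a participant-level random effect and
#' \eqn{\epsilon_b} bout-level noise.
#'
#' @param n_participants number of participants.
#' @param n_days days of CGM wear per participant (a 4-week wear mirrors the
#'   free-living study protocols the generator emulates).
#' @param cgm_interval CGM sampling interval, minutes.
#' @param ou_reversion per-step mean-reversion fraction of the glucose walk.
#'   The default is calibrated so a matched control window (equal-duration
#'   non-PA window matched on onset covariates) changes on average by
#'   `drift_nonpa` over its measurement span.
#' @param ou_sigma per-step innovation SD of the glucose walk, mmol/L.
#' @param sigma_noise CGM sensor noise SD, mmol/L.
#' @param meal_rate mean meal events per day (Poisson).
#' @param meal_amplitude mean meal excursion peak, mmol/L (Gamma, shape 4).
#' @param bolus_mean,bolus_sd bolus size distribution per covered meal, U
#'   (Gamma).
#' @param bolus_prob probability a meal is covered by a bolus.
#' @param correction_rate mean standalone correction boluses per day.
#' @param insulin_action glucose decline per unit of rapid-acting insulin at
#'   full absorption, mmol/L per U.
#' @param pa_per_participant integer range (min, max) of PA bouts placed per
#'   participant, sampled uniformly.
#' @param pa_duration_shape Beta shape parameters; bout duration is
#'   `10 + 20 * Beta(shape1, shape2)` minutes, rounded to whole minutes, giving
#'   a median near 23 min.
#' @param effect_intercept mean PA-attributable glucose change at the eligible
#'   covariate means, mmol/L. The default −1.9 is the differential effect the
#'   pipeline is expected to recover.
#' @param effect_slopes named numeric vector of moderator slopes on the
#'   reporting scales used throughout the package: `roc_decline` (per
#'   0.1 mmol/L/min faster onset decline), `start_lower` (per 1 mmol/L lower
#'   onset glucose), `cv` (per 1% prior-hour CV), `duration` (per minute),
#'   `iob` (per 0.1 U/kg insulin on board), `age` (per year), `bmi_lower` (per
#'   1 kg/m2 lower BMI).
#' @param drift_nonpa calibration anchor: mean glucose change of an average
#'   matched control window, mmol/L.
#' @param effect_sd_between SD of the participant-level random effect in
#'   \eqn{\Delta_b}, mmol/L.
#' @param effect_sd_within SD of the bout-level noise in \eqn{\Delta_b},
#'   mmol/L.
#' @param rescue_enabled simulate rescue carbohydrate intake triggered by low
#'   glucose during a PA bout's measurement window.
#' @param rescue_threshold glucose below which a rescue may be triggered,
#'   mmol/L.
#' @param rescue_prob probability a qualifying drop triggers a rescue.
#' @param rescue_grams grams of rescue carbohydrate.
#' @param seed default RNG seed used by [generate_cohort()] when no explicit
#'   seed is passed.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_participants = 500,
                       n_days = 28,
                       cgm_interval = 5,
                       ou_reversion = 0.023,
                       ou_sigma = 0.50,
                       sigma_noise = 0.25,
                       meal_rate = 3,
                       meal_amplitude = 3.0,
                       bolus_mean = 3,
                       bolus_sd = 1.2,
                       bolus_prob = 0.9,
                       correction_rate = 2,
                       insulin_action = 0.19,
                       pa_per_participant = c(10L, 16L),
                       pa_duration_shape = c(2.4, 1.4),
                       effect_intercept = -1.9,
                       effect_slopes = c(roc_decline = -0.90,
                                         start_lower = -0.16,
                                         cv = -0.06,
                                         duration = -0.05,
                                         iob = -0.56,
                                         age = -0.01,
                                         bmi_lower = -0.05),
                       drift_nonpa = -0.3,
                       effect_sd_between = 0.3,
                       effect_sd_within = 1.8,
                       rescue_enabled = TRUE,
                       rescue_threshold = 5.0,
                       rescue_prob = 0.7,
                       rescue_grams = 15,
                       seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants), n_days = as.integer(n_days),
    cgm_interval = cgm_interval, ou_reversion = ou_reversion,
    ou_sigma = ou_sigma, sigma_noise = sigma_noise, meal_rate = meal_rate,
    meal_amplitude = meal_amplitude, bolus_mean = bolus_mean,
    bolus_sd = bolus_sd, bolus_prob = bolus_prob,
    correction_rate = correction_rate, insulin_action = insulin_action,
    pa_per_participant = as.integer(pa_per_participant),
    pa_duration_shape = pa_duration_shape,
    effect_intercept = effect_intercept, effect_slopes = effect_slopes,
    drift_nonpa = drift_nonpa, effect_sd_between = effect_sd_between,
    effect_sd_within = effect_sd_within, rescue_enabled = rescue_enabled,
    rescue_threshold = rescue_threshold, rescue_prob = rescue_prob,
    rescue_grams = rescue_grams, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Validate a `sim_config`
#'
#' Checks type and range invariants (positive interval, non-negative SDs, bout
#' durations confined to 10-30 min, capacity of the wear period for the
#' requested number of bouts given their exclusion zones) and fails with an
#' explicit error otherwise.
#'
#' @param cfg a `sim_config`.
#' @return `cfg`, invisibly usable, after validation.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_participants < 1L) stop("n_participants must be >= 1")
  if (cfg$n_days < 1L) stop("n_days must be >= 1")
  if (cfg$cgm_interval <= 0) stop("cgm_interval must be > 0")
  sds <- c(cfg$ou_sigma, cfg$sigma_noise, cfg$effect_sd_between,
           cfg$effect_sd_within)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (cfg$ou_reversion < 0 || cfg$ou_reversion >= 1) {
    stop("ou_reversion must be in [0, 1)")
  }
  if (length(cfg$pa_per_participant) != 2L ||
      any(cfg$pa_per_participant < 0L) ||
      cfg$pa_per_participant[1] > cfg$pa_per_participant[2]) {
    stop("pa_per_participant must be an ordered non-negative (min, max) pair")
  }
  slopes <- c("roc_decline", "start_lower", "cv", "duration", "iob", "age",
              "bmi_lower")
  if (!all(slopes %in% names(cfg$effect_slopes))) {
    stop("effect_slopes must name: ", paste(slopes, collapse = ", "))
  }
  # bout durations live on [10, 30] by construction; check capacity: bouts are
  # daytime (06:00-23:00), pairwise separated by > 5 h end-to-onset.
  daytime_min <- 17 * 60
  slot <- 300 + 30   # separation + max duration
  capacity <- cfg$n_days * (floor(daytime_min / slot) + 1L)
  if (cfg$pa_per_participant[2] > capacity) {
    stop(sprintf(
      "n_days = %d cannot host %d PA bouts with 5-h separation and daytime placement (capacity %d); increase n_days or reduce pa_per_participant",
      cfg$n_days, cfg$pa_per_participant[2], capacity))
  }
  cfg
}

#' A zero-effect configuration for null calibration
#'
#' Returns `sim_config(...)` with the PA-attributable effect completely
#' removed: intercept, every moderator slope, and both effect SDs are zero, so
#' PA windows carry exactly the shared glucose dynamics of control windows.
#'
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
null_sim_config <- function(...) {
  slopes <- c(roc_decline = 0, start_lower = 0, cv = 0, duration = 0,
              iob = 0, age = 0, bmi_lower = 0)
  sim_config(effect_intercept = 0, effect_slopes = slopes,
             effect_sd_between = 0, effect_sd_within = 0, ...)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  cohort: %d participants x %d days, CGM every %g min\n",
              x$n_participants, x$n_days, x$cgm_interval))
  cat(sprintf("  effect: intercept %.2f mmol/L; slopes [%s]\n",
              x$effect_intercept,
              paste(sprintf("%s=%.2f", names(x$effect_slopes),
                            x$effect_slopes), collapse = ", ")))
  cat(sprintf("  noise: ou_sigma %.2f, sensor %.2f, between %.2f, within %.2f\n",
              x$ou_sigma, x$sigma_noise, x$effect_sd_between,
              x$effect_sd_within))
  invisible(x)
}
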