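#' Default collection schedule for a milk storage experiment
#'
#' One data frame per storage temperature listing the collection time points:
#' the ordinal collection index (0 = the baseline aliquot frozen on the day of
#' pasteurization), the mean storage day at which bottles were pulled, and the
#' standard deviation of the actual pull days across bottles. The default
#' schedule covers total storage durations of 78, 17, 6 and 3 days at 4, 10,
#' 15 and 20 degC, with pull-day jitter growing towards the late 4 degC
#' collections where off-odour development dictated the sampling pace.
#'
#' @param temperatures storage temperatures in degC; only the default four
#'   have a built-in schedule.
#' @return named list of data frames with columns `timepoint_index`,
#'   `mean_day`, `sd_day`.
#' @export
default_schedule <- function(temperatures = c(4, 10, 15, 20)) {
  sched <- list(
    `4` = data.frame(
      timepoint_index = 0:12,
      mean_day = c(0, 3, 7, 10, 14, 17, 21, 28, 33, 44, 57, 63, 78),
      sd_day   = c(0, 0.1, 0.2, 0.3, 0.5, 0.5, 1, 1, 2, 5, 7, 12, 3)
    ),
    `10` = data.frame(
      timepoint_index = 0:11,
      mean_day = c(0, 1, 2, 3, 4, 5, 7, 9.97, 12.01, 14, 16.5, 17),
      sd_day   = c(0, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.01, 0.01, 0.1,
                   0.5, 0.2)
    ),
    `15` = data.frame(
      timepoint_index = 0:11,
      mean_day = c(0, 0.5, 1, 1.5, 2, 2.5, 3.00, 3.31, 3.82, 4.5, 5.33, 6),
      sd_day   = c(0, 0.02, 0.02, 0.02, 0.02, 0.02, 0.03, 0.01, 0.01, 0.05,
                   0.04, 0.05)
    ),
    `20` = data.frame(
      timepoint_index = 0:11,
      mean_day = c(0, 0.25, 0.5, 0.75, 1, 1.25, 1.49, 1.78, 1.98, 2.23, 2.5,
                   3),
      sd_day   = c(0, 0.01, 0.01, 0.01, 0.01, 0.01, 0.02, 0.01, 0.02, 0.01,
                   0.02, 0.02)
    )
  )
  keys <- as.character(temperatures)
  missing <- setdiff(keys, names(sched))
  if (length(missing) > 0)
    stop("no built-in schedule for temperature(s): ",
         paste(missing, collapse = ", "))
  sched[keys]
}

#' Simulation configuration for a synthetic milk storage experiment
#'
#' Bundles every knob of the concentration simulator. Defaults describe a
#' four-batch experiment at 4/10/15/20 degC with baseline concentrations and
#' kinetic parameters typical for pasteurized 2% fat milk: citric acid around
#' 10.3 mM degrading linearly with an Arrhenius-type temperature dependence
#' (Ea 143 kJ/mol, 0.06 mM/d at the 4 degC reference), and the lactose
#' fermentation products (ethanol, formic, acetic, lactic, succinic acid)
#' flat during a temperature-dependent lag L(T) = A0 * exp(k * T) and rising
#' exponentially afterwards.
#'
#' @param n_batches number of pasteurization batches (biological replicates).
#' @param temperatures storage temperatures in degC, strictly increasing.
#' @param schedule named list of per-temperature collection schedules, see
#'   [default_schedule()].
#' @param baseline_means named numeric, mean baseline concentration per
#'   metabolite in molar units.
#' @param baseline_batch_cv coefficient of variation of batch baselines
#'   (log-normal between-batch spread).
#' @param noise_cv multiplicative measurement noise (log-normal sd on the log
#'   scale).
#' @param lag_amplitude lag amplitude A0 in days of the lag law
#'   L(T) = A0 * exp(k * T).
#' @param lag_decay lag decay k per degC, negative.
#' @param post_lag_rate named numeric, per-day exponential production rate of
#'   each fermentation product after its lag, referenced at `rate_ref_temp`.
#' @param rate_q10 Q10 factor scaling the post-lag rate with temperature:
#'   r(T) = post_lag_rate * rate_q10^((T - rate_ref_temp)/10). Microbial
#'   production accelerates strongly with temperature; Q10 = 5 keeps the
#'   78-day 4 degC arm and the 3-day 20 degC arm at comparable, realistic
#'   fold changes.
#' @param rate_ref_temp reference temperature (degC) of `post_lag_rate`.
#' @param max_fold stationary-phase ceiling: fermentation products plateau
#'   at `max_fold` times their baseline (microbial growth saturates; without
#'   a ceiling the long 4 degC arm would grow without bound).
#' @param citric_Ea activation energy of citric acid degradation, kJ/mol.
#' @param citric_rate_ref citric degradation rate (molar/day, positive
#'   magnitude) at `citric_ref_temp`.
#' @param citric_ref_temp reference temperature for `citric_rate_ref`, degC.
#' @param bottles_per_collection bottles pulled per batch at each collection
#'   (2 by default, sizing the corpus near the ~374 usable spectra of a full
#'   four-batch storage experiment).
#' @param butyric_temp_inverted opt-in flag: simulate butyric acid with an
#'   inverted temperature response (largest increase at the lowest
#'   temperature), mimicking consumption by microbes that are more active
#'   when warm. Off by default; no statistical target attaches to butyric.
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_batches = 4,
                       temperatures = c(4, 10, 15, 20),
                       schedule = default_schedule(temperatures),
                       baseline_means = c(
                         citric   = 10.3e-3,
                         ethanol  = 45e-6,
                         formic   = 8.3e-6,
                         acetic   = 91e-6,
                         lactic   = 87e-6,
                         succinic = 41e-6,
                         butyric  = 37.2e-6
                       ),
                       baseline_batch_cv = 0.04,
                       noise_cv = 0.05,
                       lag_amplitude = 157.3,
                       lag_decay = -0.254,
                       post_lag_rate = c(
                         ethanol  = 2.0,
                         formic   = 2.4,
                         acetic   = 2.6,
                         lactic   = 2.2,
                         succinic = 1.2,
                         butyric  = 1.5
                       ),
                       rate_q10 = 5,
                       rate_ref_temp = 20,
                       max_fold = 200,
                       citric_Ea = 143,
                       citric_rate_ref = 0.06e-3,
                       citric_ref_temp = 4,
                       bottles_per_collection = 2,
                       butyric_temp_inverted = FALSE,
                       seed = 1L) {
  if (!(is.numeric(seed) && length(seed) == 1 && is.finite(seed) &&
        seed == round(seed)))
    stop("seed must be a single integer")
  if (is.unsorted(temperatures, strictly = TRUE))
    stop("temperatures must be strictly increasing")
  if (baseline_batch_cv < 0 || noise_cv < 0)
    stop("coefficients of variation must be >= 0")
  if (lag_decay >= 0)
    stop("lag_decay must be negative (lag shrinks as temperature rises)")
  if (!setequal(names(schedule), as.character(temperatures)))
    stop("schedule must have one entry per temperature")
  for (s in schedule) {
    if (any(s$mean_day < 0) || is.unsorted(s$mean_day))
      stop("schedule days must be non-negative and non-decreasing")
  }
  if (any(post_lag_rate < 0)) stop("post_lag_rate must be >= 0")
  if (rate_q10 <= 0) stop("rate_q10 must be > 0")
  if (max_fold <= 1) stop("max_fold must exceed 1")
  cfg <- list(
    n_batches = as.integer(n_batches), temperatures = temperatures,
    schedule = schedule, baseline_means = baseline_means,
    baseline_batch_cv = baseline_batch_cv, noise_cv = noise_cv,
    lag_amplitude = lag_amplitude, lag_decay = lag_decay,
    post_lag_rate = post_lag_rate, rate_q10 = rate_q10,
    rate_ref_temp = rate_ref_temp, max_fold = max_fold,
    citric_Ea = citric_Ea,
    citric_rate_ref = citric_rate_ref, citric_ref_temp = citric_ref_temp,
    bottles_per_collection = as.integer(bottles_per_collection),
    butyric_temp_inverted = isTRUE(butyric_temp_inverted),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Lag time of fermentation products at a storage temperature
#'
#' L(T) = A0 * exp(k * T): the number of storage days during which microbial
#' fermentation products stay at their baseline before exponential increase.
#'
#' @param temperature degC.
#' @param A0 lag amplitude, days.
#' @param k lag decay per degC (negative).
#' @return lag in days.
#' @export
lag_time <- function(temperature, A0, k) A0 * exp(k * temperature)

#' Arrhenius-scaled reaction rate
#'
#' Scales a reference rate to another temperature via the Arrhenius law
#' r(T) = r_ref * exp(-Ea/R * (1/T - 1/T_ref)) with temperatures in Kelvin.
#'
#' @param temperature target temperature, degC.
#' @param rate_ref rate at `ref_temp` (any units).
#' @param Ea activation energy, kJ/mol.
#' @param ref_temp reference temperature, degC.
#' @return rate at `temperature`, same units as `rate_ref`.
#' @export
arrhenius_rate <- function(temperature, rate_ref, Ea, ref_temp) {
  rate_ref * exp(-(Ea * 1000 / GAS_CONSTANT) *
                   (1 / kelvin(temperature) - 1 / kelvin(ref_temp)))
}
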