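#' Published reference tables for pasteurized 2% milk storage
#'
#' Two small reference tables ship with the package:
#' `reference_threshold_times()` returns the published per-temperature
#' threshold times (mean +/- sd of storage days at the first collection
#' point whose concentration significantly exceeded baseline, with the
#' many-one test p-value) for the five fermentation products; the succinic
#' acid threshold at 4 degC could not be determined and is NA.
#' `reference_citric_rates()` returns the published citric acid degradation
#' rates (mM/d, signed) at the four storage temperatures. These are the desk
#' inputs of the worked kinetic examples: feeding the threshold times to
#' [decay_fit()] reproduces the published decay-rate parameters, and feeding
#' the rates to [arrhenius()] reproduces the published activation energy.
#'
#' @return data.frame (`metabolite`, `temperature_C`, `threshold_time_d`,
#'   `threshold_sd_d`, `p_value`) or (`temperature_C`, `rate_mM_d`).
#' @export
reference_threshold_times <- function() {
  utils::read.csv(system.file("extdata", "reference_threshold_times.csv",
                              package = "milkshelf"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_threshold_times
#' @export
reference_citric_rates <- function() {
  utils::read.csv(system.file("extdata", "reference_citric_rates.csv",
                              package = "milkshelf"),
                  stringsAsFactors = FALSE)
}
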