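# Seeded synthetic-data generators: BBD response tables and kinetic series
# with the additive-Gaussian error structure the analysis assumes, so every
# stage of the workflow is testable without measured data.

#' Configuration for the synthetic-data generators
#'
#' @param seed Integer RNG seed; identical configurations produce identical
#'   output.
#' @param noise_sd Standard deviation of the additive Gaussian measurement
#'   noise, in response units (>= 0).
#' @param n_replicates Replicates per design run (>= 1).
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(seed = 2024L, noise_sd = 0, n_replicates = 3L) {
  if (noise_sd < 0 || n_replicates < 1L) {
    stop("synthetic config needs noise_sd >= 0 and n_replicates >= 1",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed), noise_sd = noise_sd,
                 n_replicates = as.integer(n_replicates)),
            class = "synthetic_config")
}

# run fn with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fn()
}

#' Simulate replicate responses for a design from a known surface
#'
#' For every run, draws `n_replicates` values of the true surface plus
#' additive Gaussian noise and stores their mean and SD in the design — the
#' same mean +/- SD structure as a measured design table. With
#' `noise_sd = 0` the run means equal [predict_response()] exactly.
#'
#' @param true_model A `"quadratic_model"` defining the noise-free surface.
#' @param design A `"bbd_design"`.
#' @param config A [synthetic_config()].
#' @param response Name under which to store the response (default the
#'   model's response name).
#' @return The design with the simulated response attached.
#' @export
generate_bbd_responses <- function(true_model, design,
                                   config = synthetic_config(),
                                   response = true_model$response) {
  stopifnot(inherits(true_model, "quadratic_model"),
            inherits(design, "bbd_design"),
            inherits(config, "synthetic_config"))
  truth <- predict_response(true_model, design$coded)
  sims <- with_seed(config$seed, function() {
    vapply(truth, function(mu) {
      reps <- mu + stats::rnorm(config$n_replicates, 0, config$noise_sd)
      c(mean(reps), stats::sd(reps))
    }, numeric(2))
  })
  sds <- sims[2, ]
  if (config$n_replicates == 1L) sds <- rep(0, length(sds))
  set_response(design, response, sims[1, ], sd = sds,
               n = config$n_replicates)
}

#' Simulate a noisy kinetic series
#'
#' [simulate_kinetics()] plus additive Gaussian noise, floored at zero
#' (concentrations and contents are non-negative).
#'
#' @param spec A [kinetic_spec()].
#' @param times Sampling schedule; default [kinetic_schedule()].
#' @param config A [synthetic_config()]; `noise_sd` is in the series' units
#'   (mg/L or mg/100 g).
#' @param compound,method Metadata carried into the series.
#' @return A [kinetic_series()].
#' @export
generate_kinetic_series <- function(spec, times = kinetic_schedule(),
                                    config = synthetic_config(),
                                    compound = "TA", method = "UAE") {
  clean <- simulate_kinetics(spec, times, compound = compound, method = method)
  if (config$noise_sd == 0) return(clean)
  noisy <- with_seed(config$seed, function() {
    pmax(0, clean$values + stats::rnorm(length(times), 0, config$noise_sd))
  })
  kinetic_series(times, noisy, clean$quantity, compound, method)
}

#' Simulate a gallic-acid style standard curve
#'
#' Absorbances on a known calibration line plus Gaussian noise, for testing
#' [fit_standard_curve()] and the phenolics quantification path.
#'
#' @param concentrations Standard concentrations, mg/L.
#' @param slope,intercept True calibration line.
#' @param config A [synthetic_config()]; `noise_sd` in absorbance units.
#' @return Data frame with columns `conc_mg_L`, `absorbance`.
#' @export
generate_standards <- function(concentrations = seq(0, 500, by = 100),
                               slope = 0.005, intercept = 0.01,
                               config = synthetic_config()) {
  abs_true <- intercept + slope * concentrations
  absorb <- with_seed(config$seed, function() {
    abs_true + stats::rnorm(length(abs_true), 0, config$noise_sd)
  })
  data.frame(conc_mg_L = concentrations, absorbance = absorb)
}
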