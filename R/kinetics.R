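# Two-stage solid-liquid extraction kinetics: film theory, unsteady diffusion
# through plant material, and Ponomaryov's empirical equation. All three are
# two-parameter models: b captures the fast washing stage, k the slow
# diffusion-limited stage.

KINETIC_MODELS <- c("film", "unsteady", "ponomaryov")

#' Kinetic model specification
#'
#' Parameters of one two-stage extraction model:
#' \describe{
#'   \item{film}{liquid-phase concentration
#'     \eqn{c(t) = c_{seq} [1 - (1 - b) e^{-kt}]}; `b` is the washed fraction
#'     at \eqn{t = 0}, `c_seq` the equilibrium (saturated-extract)
#'     concentration in mg/L.}
#'   \item{unsteady}{residual solid content
#'     \eqn{q(t) = q_0 (1 - b') e^{-k't}}; `q0` is the initial extractable
#'     content in mg/100 g.}
#'   \item{ponomaryov}{extracted fraction \eqn{1 - q/q_0 = b'' + k'' t}, i.e.
#'     a linear empirical law; the simulated residual content is floored at 0.}
#' }
#'
#' @param model One of `"film"`, `"unsteady"`, `"ponomaryov"`.
#' @param b Washing coefficient (dimensionless; in `[0, 1)` for the
#'   exponential models).
#' @param k Slow-extraction coefficient (1/min, >= 0).
#' @param c_seq Equilibrium liquid concentration, mg/L (film reference).
#' @param q0 Initial solid content, mg/100 g (unsteady/ponomaryov reference).
#' @return An object of class `"kinetic_spec"`.
#' @examples
#' kinetic_spec("film", b = 0.297, k = 1.126e-3, c_seq = 8.923)
#' @export
kinetic_spec <- function(model = KINETIC_MODELS, b, k, c_seq = NULL, q0 = NULL) {
  model <- match.arg(model)
  if (!is.numeric(b) || !is.numeric(k) || k < 0) {
    stop("kinetic spec needs numeric b and k >= 0", call. = FALSE)
  }
  if (model %in% c("film", "unsteady") && (b < 0 || b >= 1)) {
    stop("washing coefficient b must lie in [0, 1) for exponential models",
         call. = FALSE)
  }
  ref <- if (model == "film") c_seq else q0
  if (is.null(ref) || ref <= 0) {
    stop(sprintf("model '%s' needs a positive %s reference", model,
                 if (model == "film") "c_seq" else "q0"), call. = FALSE)
  }
  structure(list(model = model, b = b, k = k, c_seq = c_seq, q0 = q0),
            class = "kinetic_spec")
}

#' Time series of extraction measurements
#'
#' @param times Sampling times in minutes, strictly increasing, >= 0.
#' @param values Measurements, same length as `times`.
#' @param quantity `"c_mg_L"` (liquid concentration) or `"q_mg_100g"`
#'   (residual solid content).
#' @param compound `"TA"` or `"TPC"` (metadata).
#' @param method `"UAE"` or `"CONV"` (metadata).
#' @return An object of class `"kinetic_series"`.
#' @export
kinetic_series <- function(times, values, quantity = c("c_mg_L", "q_mg_100g"),
                           compound = "TA", method = "UAE") {
  quantity <- match.arg(quantity)
  if (length(times) != length(values)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  if (any(times < 0)) stop("negative time in kinetic series", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  structure(list(times = times, values = values, quantity = quantity,
                 compound = compound, method = method),
            class = "kinetic_series")
}

#' @export
print.kinetic_series <- function(x, ...) {
  cat(sprintf("Kinetic series: %s, %s, %s; %d points over %g-%g min\n",
              x$compound, x$method, x$quantity, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Default extraction sampling schedule
#'
#' @return The sampling times 0, 25, 50, 75, 100, 150, 200, 250 min used in
#'   the packaged kinetic study.
#' @export
kinetic_schedule <- function() c(0, 25, 50, 75, 100, 150, 200, 250)

#' Solid mass / solvent volume of an extraction batch
#'
#' @param solid_mass_g Mass of plant material, g (> 0).
#' @param solvent_volume_mL Solvent volume, mL (> 0).
#' @return An object of class `"mass_balance"`.
#' @export
mass_balance <- function(solid_mass_g = 5, solvent_volume_mL = 75) {
  if (solid_mass_g <= 0 || solvent_volume_mL <= 0) {
    stop("mass and volume must be positive", call. = FALSE)
  }
  structure(list(m = solid_mass_g, V = solvent_volume_mL),
            class = "mass_balance")
}

#' Forward-simulate a kinetic model
#'
#' Evaluates the closed-form curve of `spec` on `times`. Film theory yields a
#' liquid-concentration series; the other two models yield residual-content
#' series. Ponomaryov's linear law is unbounded, so simulated contents are
#' floored at zero with a warning once the extracted fraction exceeds one.
#'
#' @param spec A [kinetic_spec()].
#' @param times Sampling times (min, >= 0), sorted increasing.
#' @param compound,method Metadata carried into the series.
#' @return A [kinetic_series()].
#' @examples
#' sp <- kinetic_spec("film", b = 0.297, k = 1.126e-3, c_seq = 8.923)
#' simulate_kinetics(sp, kinetic_schedule())$values[1]  # b * c_seq at t = 0
#' @export
simulate_kinetics <- function(spec, times, compound = "TA", method = "UAE") {
  stopifnot(inherits(spec, "kinetic_spec"))
  if (any(times < 0)) stop("negative time in simulation request", call. = FALSE)
  vals <- switch(spec$model,
    film = spec$c_seq * (1 - (1 - spec$b) * exp(-spec$k * times)),
    unsteady = spec$q0 * (1 - spec$b) * exp(-spec$k * times),
    ponomaryov = {
      q <- spec$q0 * (1 - spec$b - spec$k * times)
      if (any(q < 0)) {
        warning("ponomaryov curve saturated: residual content floored at 0",
                call. = FALSE)
        q <- pmax(q, 0)
      }
      q
    })
  kinetic_series(times, vals,
                 quantity = if (spec$model == "film") "c_mg_L" else "q_mg_100g",
                 compound = compound, method = method)
}

#' Convert between liquid concentration and residual solid content
#'
#' Mass balance over the extraction batch:
#' \eqn{q(t) = q_0 - c(t) \cdot (V/1000) / m \cdot 100} (mg/100 g), and the
#' symmetric inverse for content series. The round trip is the identity.
#' Contents that would fall below zero (measurement exceeding the assumed
#' `q0`) are clipped to zero with a warning.
#'
#' @param series A [kinetic_series()].
#' @param balance A [mass_balance()].
#' @param q0 Initial extractable content, mg/100 g.
#' @return The series on the other quantity scale.
#' @export
content_concentration_convert <- function(series, balance, q0) {
  stopifnot(inherits(series, "kinetic_series"), inherits(balance, "mass_balance"))
  fac <- (balance$V / 1000) / balance$m * 100  # mg/L -> mg/100 g
  if (series$quantity == "c_mg_L") {
    q <- q0 - series$values * fac
    if (any(q < 0)) {
      warning("converted content below 0 (measurement exceeds assumed q0); clipped",
              call. = FALSE)
      q <- pmax(q, 0)
    }
    kinetic_series(series$times, q, "q_mg_100g", series$compound, series$method)
  } else {
    c_val <- (q0 - series$values) / fac
    kinetic_series(series$times, c_val, "c_mg_L", series$compound, series$method)
  }
}

# Bring a series onto the quantity scale the model works on, converting via
# the mass balance when necessary. Returns the (possibly converted) series.
series_on_model_scale <- function(series, model, balance, q0) {
  need <- if (model == "film") "c_mg_L" else "q_mg_100g"
  if (series$quantity == need) return(series)
  if (is.null(balance) || is.null(q0)) {
    stop(sprintf("series is %s but model '%s' needs %s: supply a mass_balance and q0",
                 series$quantity, model, need), call. = FALSE)
  }
  content_concentration_convert(series, balance, q0)
}

# R^2 without summary.lm (which warns on exact fits); NA for a constant response
r_squared_of <- function(obs, fitted) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((obs - fitted)^2) / sst
}

new_kinetic_fit <- function(spec, r_squared, n_used, dropped, method,
                            intercept = NA_real_, slope = NA_real_) {
  structure(list(spec = spec, r_squared = r_squared, n_points_used = n_used,
                 dropped_points = dropped, fit_method = method,
                 intercept = intercept, slope = slope),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s): b = %.4g, k = %.4g 1/min, R2 = %.4f (%d points",
              x$spec$model, x$fit_method, x$spec$b, x$spec$k, x$r_squared,
              x$n_points_used))
  if (nrow(x$dropped_points)) cat(sprintf(", %d dropped", nrow(x$dropped_points)))
  cat(")\n")
  invisible(x)
}

#' Fit a kinetic model by linear regression on its linearized form
#'
#' The canonical estimator: each model has an exact linearization —
#' film: \eqn{\ln(1 - c/c_{seq}) = \ln(1 - b) - k t};
#' unsteady: \eqn{\ln(q/q_0) = \ln(1 - b') - k' t};
#' ponomaryov: \eqn{1 - q/q_0 = b'' + k'' t} —
#' fitted by ordinary least squares. Points where the log transform is
#' undefined (concentration at or above `c_seq`, content at or zero/above
#' `q0`'s log domain) are dropped, not clipped, and recorded with a reason.
#' \eqn{R^2} is reported on the linearized (regression) scale. The \eqn{t = 0}
#' point is included whenever its transform is finite.
#'
#' @param series A [kinetic_series()]; converted via the mass balance when its
#'   quantity does not match the model's natural scale.
#' @param model One of `"film"`, `"unsteady"`, `"ponomaryov"`.
#' @param c_seq,q0 Reference constants (mg/L and mg/100 g). Supply the one(s)
#'   the model and any unit conversion need.
#' @param balance A [mass_balance()] for unit conversion; default the packaged
#'   5 g / 75 mL batch.
#' @return An object of class `"kinetic_fit"`: estimated [kinetic_spec()],
#'   `r_squared`, `n_points_used`, `dropped_points` (data frame `time`,
#'   `reason`), and the regression `intercept`/`slope`.
#' @export
fit_linearized <- function(series, model = KINETIC_MODELS,
                           c_seq = NULL, q0 = NULL, balance = mass_balance()) {
  model <- match.arg(model)
  stopifnot(inherits(series, "kinetic_series"))
  ser <- series_on_model_scale(series, model, balance, q0)
  t <- ser$times
  v <- ser$values

  dropped <- data.frame(time = numeric(0), reason = character(0))
  if (model == "film") {
    if (is.null(c_seq) || c_seq <= 0) stop("film model needs c_seq > 0", call. = FALSE)
    ok <- v < c_seq
    dropped <- data.frame(time = t[!ok],
                          reason = rep("c >= c_seq: log undefined", sum(!ok)))
    z <- log(1 - v[ok] / c_seq)
  } else if (model == "unsteady") {
    if (is.null(q0) || q0 <= 0) stop("unsteady model needs q0 > 0", call. = FALSE)
    ok <- v > 0
    dropped <- data.frame(time = t[!ok],
                          reason = rep("q <= 0: log undefined", sum(!ok)))
    z <- log(v[ok] / q0)
  } else {
    if (is.null(q0) || q0 <= 0) stop("ponomaryov model needs q0 > 0", call. = FALSE)
    ok <- rep(TRUE, length(v))
    z <- 1 - v / q0
  }
  tt <- t[ok]
  if (length(tt) < 3L) {
    stop("insufficient data: fewer than 3 usable points after dropping", call. = FALSE)
  }
  lf <- stats::lm(z ~ tt)
  a <- unname(stats::coef(lf)[1]); s <- unname(stats::coef(lf)[2])
  r2 <- r_squared_of(z, stats::fitted(lf))

  est <- switch(model,
    film = kinetic_spec("film", b = 1 - exp(a), k = max(0, -s), c_seq = c_seq),
    unsteady = kinetic_spec("unsteady", b = 1 - exp(a), k = max(0, -s), q0 = q0),
    ponomaryov = kinetic_spec("ponomaryov", b = a, k = s, q0 = q0))
  new_kinetic_fit(est, r2, length(tt), dropped, "linearized",
                  intercept = a, slope = s)
}

#' Fit a kinetic model by least squares on the original scale
#'
#' Nonlinear least squares on the untransformed concentrations/contents,
#' initialized from the linearized fit — a cross-check for the canonical
#' linearized estimator, since the two weight measurement error differently.
#' Ponomaryov's law is linear in its parameters, so its original-scale least
#' squares is solved directly. \eqn{R^2} is reported on the original scale.
#'
#' @inheritParams fit_linearized
#' @return A `"kinetic_fit"` with `fit_method = "nonlinear"`. On
#'   non-convergence an error is raised that carries the linearized fallback
#'   fit in its `fallback` field (condition class
#'   `"uaextract_nls_error"`).
#' @export
fit_nonlinear <- function(series, model = KINETIC_MODELS,
                          c_seq = NULL, q0 = NULL, balance = mass_balance()) {
  model <- match.arg(model)
  lin <- fit_linearized(series, model, c_seq = c_seq, q0 = q0, balance = balance)
  ser <- series_on_model_scale(series, model, balance, q0)
  keep <- !(ser$times %in% lin$dropped_points$time)
  t <- ser$times[keep]
  v <- ser$values[keep]

  if (model == "ponomaryov") {
    lf <- stats::lm(v ~ t)
    b <- 1 - unname(stats::coef(lf)[1]) / q0
    k <- -unname(stats::coef(lf)[2]) / q0
    est <- kinetic_spec("ponomaryov", b = b, k = k, q0 = q0)
    return(new_kinetic_fit(est, r_squared_of(v, stats::fitted(lf)), length(t),
                           lin$dropped_points, "nonlinear"))
  }

  # a flat series carries no rate information: the washing step explains it all
  if (stats::sd(v) <= 1e-12 * max(abs(v), 1)) {
    ref <- if (model == "film") c_seq else q0
    b <- if (model == "film") mean(v) / ref else 1 - mean(v) / ref
    est <- kinetic_spec(model, b = b, k = 0, c_seq = c_seq, q0 = q0)
    return(new_kinetic_fit(est, NA_real_, length(t), lin$dropped_points,
                           "nonlinear"))
  }

  start <- list(b = min(max(lin$spec$b, 1e-6), 1 - 1e-6), k = max(lin$spec$k, 0))
  form <- if (model == "film") {
    v ~ c_seq * (1 - (1 - b) * exp(-k * t))
  } else {
    v ~ q0 * (1 - b) * exp(-k * t)
  }
  env <- list(v = v, t = t, c_seq = c_seq, q0 = q0)
  nfit <- tryCatch(
    minpack.lm::nlsLM(form, data = env, start = start,
                      lower = c(b = 0, k = 0), upper = c(b = 1 - 1e-12, k = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(nfit, "error")) {
    stop(structure(class = c("uaextract_nls_error", "error", "condition"),
                   list(message = paste("nonlinear fit did not converge:",
                                        conditionMessage(nfit)),
                        call = sys.call(-1), fallback = lin)))
  }
  co <- stats::coef(nfit)
  est <- kinetic_spec(model, b = unname(co["b"]), k = unname(co["k"]),
                      c_seq = c_seq, q0 = q0)
  r2 <- r_squared_of(v, stats::predict(nfit))
  new_kinetic_fit(est, r2, length(t), lin$dropped_points, "nonlinear")
}

#' Rank kinetic fits of one series by goodness of fit
#'
#' Orders fits by descending \eqn{R^2} — the model-comparison criterion of the
#' packaged study — keeping input order among ties.
#'
#' @param fits List of `"kinetic_fit"` objects for the same series.
#' @return A data frame with one row per fit: `model`, `fit_method`,
#'   `r_squared`, `k`, `b`, `n_points_used`, sorted by descending `r_squared`.
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "kinetic_fit")))
  tab <- data.frame(
    model = vapply(fits, function(f) f$spec$model, character(1)),
    fit_method = vapply(fits, `[[`, character(1), "fit_method"),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
    k = vapply(fits, function(f) f$spec$k, numeric(1)),
    b = vapply(fits, function(f) f$spec$b, numeric(1)),
    n_points_used = vapply(fits, `[[`, integer(1), "n_points_used")
  )
  tab <- tab[order(-tab$r_squared), ]
  rownames(tab) <- NULL
  tab
}

#' Read / write the kinetic CSV interchange format
#'
#' Columns: `time_min`, `value`, `quantity` (`c_mg_L` | `q_mg_100g`),
#' `compound` (`TA` | `TPC`), `method` (`UAE` | `CONV`). One series per file.
#'
#' @param path File path.
#' @return `read_kinetic_csv()` returns a [kinetic_series()];
#'   `write_kinetic_csv()` returns `path` invisibly.
#' @export
read_kinetic_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time_min", "value", "quantity", "compound", "method")
                %in% names(tab)))
  kinetic_series(tab$time_min, tab$value, quantity = tab$quantity[1],
                 compound = tab$compound[1], method = tab$method[1])
}

#' @rdname read_kinetic_csv
#' @param series A [kinetic_series()].
#' @export
write_kinetic_csv <- function(series, path) {
  stopifnot(inherits(series, "kinetic_series"))
  utils::write.csv(data.frame(
    time_min = series$times, value = series$values,
    quantity = series$quantity, compound = series$compound,
    method = series$method), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
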