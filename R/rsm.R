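# Second-order response-surface regression on coded Box-Behnken levels:
# OLS fit, coefficient/effect parameterizations, lack-of-fit ANOVA, reduction.

#' Term labels of the full second-order polynomial
#'
#' @return Character vector of the nine non-intercept terms of the quadratic
#'   model in three coded factors: linear (`x1`..`x3`), pure quadratic
#'   (`x1^2`..`x3^2`) and two-factor interactions (`x1:x2`, `x1:x3`, `x2:x3`).
#' @export
quadratic_terms <- function() {
  c("x1", "x2", "x3", "x1^2", "x2^2", "x3^2", "x1:x2", "x1:x3", "x2:x3")
}

# columns of the model matrix for the given term labels (no intercept)
term_columns <- function(coded, terms) {
  x1 <- coded[, 1]; x2 <- coded[, 2]; x3 <- coded[, 3]
  cols <- list(
    "x1" = x1, "x2" = x2, "x3" = x3,
    "x1^2" = x1^2, "x2^2" = x2^2, "x3^2" = x3^2,
    "x1:x2" = x1 * x2, "x1:x3" = x1 * x3, "x2:x3" = x2 * x3
  )
  bad <- setdiff(terms, names(cols))
  if (length(bad)) stop("unknown model terms: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(cbind, cols[terms])
}

#' Construct a quadratic response-surface model from known coefficients
#'
#' Builds a `"quadratic_model"` directly from a set of term values, e.g. a
#' published reduced equation or a known true surface for simulation. Models
#' fitted from data are produced by [fit_quadratic()].
#'
#' On the `"coefficient"` scale the stored values are ordinary regression
#' coefficients of the coded polynomial. On the `"effect"` scale every
#' non-intercept value is twice the coefficient (the change in response across
#' the full -1 to +1 range of a factor), the convention several DoE programs
#' print; such models are evaluated by halving the non-intercept terms unless
#' literal evaluation is requested (see [predict_response()]).
#'
#' @param response Response name.
#' @param coefficients Named numeric vector; names from [quadratic_terms()]
#'   plus `"(Intercept)"`. Absent terms are treated as zero (reduced model).
#' @param parameterization `"coefficient"` or `"effect"`.
#' @param p_values Optional named per-term p-values.
#' @param r_squared Optional coefficient of determination.
#' @return An object of class `"quadratic_model"`.
#' @examples
#' m <- quadratic_model("y", c("(Intercept)" = 2, x1 = 3, "x2^2" = -1))
#' predict_response(m, c(1, 1, 0))  # 2 + 3 - 1 = 4
#' @export
quadratic_model <- function(response, coefficients,
                            parameterization = c("coefficient", "effect"),
                            p_values = NULL, r_squared = NA_real_) {
  parameterization <- match.arg(parameterization)
  nm <- names(coefficients)
  if (is.null(nm) || !all(nm %in% c("(Intercept)", quadratic_terms()))) {
    stop("coefficients must be named with '(Intercept)' and quadratic_terms()",
         call. = FALSE)
  }
  structure(list(
    response = response,
    parameterization = parameterization,
    coefficients = coefficients,
    p_values = p_values,
    r_squared = r_squared,
    fit = NULL
  ), class = "quadratic_model")
}

#' @export
print.quadratic_model <- function(x, ...) {
  cat(sprintf("Quadratic model for '%s' (%s scale)\n", x$response,
              x$parameterization))
  print(round(x$coefficients, 4))
  if (!is.na(x$r_squared)) cat(sprintf("R-squared: %.4f\n", x$r_squared))
  invisible(x)
}

#' Fit the second-order polynomial to a design response by OLS
#'
#' Ordinary least squares of the per-run response means on the coded levels,
#' for any subset of the full ten-term quadratic model. Per-term p-values are
#' two-sided t-tests on the residual degrees of freedom; no multiplicity
#' correction is applied. The fit is unweighted: replicate SDs are carried in
#' the design but the canonical analysis regresses run means.
#'
#' @param design A `"bbd_design"` with the response attached (see
#'   [set_response()]).
#' @param response Name of the response to fit.
#' @param terms Non-intercept terms to include; default the full set from
#'   [quadratic_terms()]. The intercept is always included.
#' @param weights Optional per-run weights (e.g. `n / sd^2`); default `NULL`
#'   for the unweighted canonical fit.
#' @return A `"quadratic_model"` on the coefficient scale, carrying p-values,
#'   standard errors, \eqn{R^2 = 1 - SSE/SST} and the fitting data (needed by
#'   [anova_lack_of_fit()] and [reduce_model()]).
#' @seealso [rescale_parameterization()], [predict_response()],
#'   [reduce_model()], [anova_lack_of_fit()]
#' @export
fit_quadratic <- function(design, response, terms = quadratic_terms(),
                          weights = NULL) {
  stopifnot(inherits(design, "bbd_design"))
  if (!response %in% names(design$responses)) {
    stop(sprintf("design carries no response '%s'", response), call. = FALSE)
  }
  y <- design$responses[[response]]$mean
  if (anyNA(y)) stop("every run needs a mean for the fitted response", call. = FALSE)
  terms <- unique(terms)
  X <- cbind("(Intercept)" = 1, term_columns(design$coded, terms))
  if (nrow(X) < ncol(X)) {
    stop("design has fewer runs than model terms", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular fit: collinear terms ", paste(dropped, collapse = ", "),
         call. = FALSE)
  }
  df <- data.frame(.y = y, X[, -1, drop = FALSE], check.names = FALSE)
  fml <- stats::as.formula(paste(".y ~", paste0("`", terms, "`", collapse = " + ")))
  fit <- if (is.null(weights)) stats::lm(fml, data = df) else {
    df$.w <- weights
    stats::lm(fml, data = df, weights = .w)
  }
  # summary.lm warns on exact (zero-residual) fits, a legitimate input here
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  co <- stats::coef(fit)
  names(co) <- c("(Intercept)", terms)
  pv <- sm$coefficients[, "Pr(>|t|)"]
  names(pv) <- names(co)
  out <- quadratic_model(response, co, "coefficient",
                         p_values = pv, r_squared = sm$r.squared)
  out$std_errors <- stats::setNames(sm$coefficients[, "Std. Error"], names(co))
  out$fit <- list(y = y, coded = design$coded, terms = terms,
                  lm = fit, df_residual = fit$df.residual)
  out
}

#' Switch a model between coefficient and effect parameterizations
#'
#' Multiplies (coefficient -> effect) or halves (effect -> coefficient) every
#' non-intercept term by 2; the intercept, p-values and \eqn{R^2} are
#' unchanged. Applying the conversion twice is the identity, and predictions
#' are identical under either parameterization.
#'
#' @param model A `"quadratic_model"`.
#' @param target `"coefficient"` or `"effect"`.
#' @return The re-parameterized model.
#' @export
rescale_parameterization <- function(model,
                                     target = c("coefficient", "effect")) {
  target <- match.arg(target)
  stopifnot(inherits(model, "quadratic_model"))
  if (model$parameterization == target) return(model)
  fac <- if (target == "effect") 2 else 0.5
  idx <- names(model$coefficients) != "(Intercept)"
  model$coefficients[idx] <- model$coefficients[idx] * fac
  if (!is.null(model$std_errors)) {
    model$std_errors[idx] <- model$std_errors[idx] * fac
  }
  model$parameterization <- target
  model
}

#' Evaluate a quadratic model at coded points
#'
#' @param model A `"quadratic_model"`.
#' @param x Coded point (length-3 vector) or matrix of points in rows.
#' @param literal If `TRUE`, the stored term values are plugged into the
#'   polynomial as-is, whatever the parameterization flag — the arithmetic a
#'   reader would do with a printed effect-scale equation. The default
#'   (`FALSE`) halves non-intercept terms of effect-scale models first, so
#'   both parameterizations predict identically.
#' @return Numeric vector of predicted responses.
#' @export
predict_response <- function(model, x, literal = FALSE) {
  stopifnot(inherits(model, "quadratic_model"))
  co <- model$coefficients
  if (!literal && model$parameterization == "effect") {
    idx <- names(co) != "(Intercept)"
    co[idx] <- co[idx] / 2
  }
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  stopifnot(ncol(m) == 3)
  terms <- setdiff(names(co), "(Intercept)")
  pred <- rep(if ("(Intercept)" %in% names(co)) co[["(Intercept)"]] else 0,
              nrow(m))
  if (length(terms)) {
    pred <- pred + drop(term_columns(m, terms) %*% co[terms])
  }
  pred
}

#' ANOVA with lack-of-fit partition for a fitted model
#'
#' Splits the residual sum of squares into pure error, estimated from
#' replicated design points (runs with identical coded levels), and lack of
#' fit. A non-significant lack-of-fit F test supports the adequacy of the
#' fitted polynomial.
#'
#' @param model A `"quadratic_model"` produced by [fit_quadratic()].
#' @param design The design it was fitted to.
#' @return A list of class `"rsm_anova"` with sums of squares (`ss_regression`,
#'   `ss_residual`, `ss_lack_of_fit`, `ss_pure_error`), their degrees of
#'   freedom, and F/p values for the regression and the lack-of-fit test. When
#'   the design has no replicated points the lack-of-fit entries are `NA` and
#'   a warning is issued (the plain ANOVA is still returned).
#' @export
anova_lack_of_fit <- function(model, design) {
  stopifnot(inherits(model, "quadratic_model"))
  if (is.null(model$fit)) {
    stop("lack-of-fit ANOVA needs a model fitted by fit_quadratic()", call. = FALSE)
  }
  y <- model$fit$y
  fitted <- predict_response(model, model$fit$coded)
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  ssr <- sst - sse
  df_model <- length(model$fit$terms)
  df_resid <- model$fit$df_residual

  groups <- apply(model$fit$coded, 1, paste, collapse = "/")
  reps <- split(y, groups)
  ss_pe <- sum(vapply(reps, function(v) sum((v - mean(v))^2), numeric(1)))
  df_pe <- length(y) - length(reps)

  out <- list(
    ss_regression = ssr, df_regression = df_model,
    ss_residual = sse, df_residual = df_resid,
    ss_lack_of_fit = NA_real_, df_lack_of_fit = NA_integer_,
    ss_pure_error = NA_real_, df_pure_error = NA_integer_,
    f_regression = (ssr / df_model) / (sse / df_resid),
    p_regression = stats::pf((ssr / df_model) / (sse / df_resid),
                             df_model, df_resid, lower.tail = FALSE),
    f_lack_of_fit = NA_real_, p_lack_of_fit = NA_real_,
    r_squared = model$r_squared
  )
  if (df_pe < 1L) {
    warning("lack-of-fit unavailable: no replicated design points", call. = FALSE)
    return(structure(out, class = "rsm_anova"))
  }
  ss_lof <- sse - ss_pe
  df_lof <- df_resid - df_pe
  out$ss_pure_error <- ss_pe; out$df_pure_error <- df_pe
  out$ss_lack_of_fit <- ss_lof; out$df_lack_of_fit <- df_lof
  if (df_lof >= 1L && ss_pe > 0) {
    out$f_lack_of_fit <- (ss_lof / df_lof) / (ss_pe / df_pe)
    out$p_lack_of_fit <- stats::pf(out$f_lack_of_fit, df_lof, df_pe,
                                   lower.tail = FALSE)
  }
  structure(out, class = "rsm_anova")
}

#' @export
print.rsm_anova <- function(x, ...) {
  cat(sprintf("Regression:  SS %.4f (df %d)  F = %.3f, p = %.4g\n",
              x$ss_regression, x$df_regression, x$f_regression, x$p_regression))
  cat(sprintf("Residual:    SS %.4f (df %d)\n", x$ss_residual, x$df_residual))
  if (!is.na(x$ss_lack_of_fit)) {
    cat(sprintf("Lack of fit: SS %.4f (df %d)  F = %.3f, p = %.4g\n",
                x$ss_lack_of_fit, x$df_lack_of_fit,
                x$f_lack_of_fit, x$p_lack_of_fit))
    cat(sprintf("Pure error:  SS %.4f (df %d)\n", x$ss_pure_error, x$df_pure_error))
  }
  invisible(x)
}

#' Drop non-significant terms and refit
#'
#' Retains the intercept plus every term with p-value at or below the
#' threshold (ties at the threshold are retained), then refits by OLS. On an
#' orthogonal design the retained linear and interaction estimates are
#' unchanged by the reduction.
#'
#' @param model A `"quadratic_model"` from [fit_quadratic()] (p-values and
#'   fitting data present).
#' @param p_threshold Significance threshold in (0, 1]; default 0.05.
#' @return The reduced, refitted `"quadratic_model"`.
#' @export
reduce_model <- function(model, p_threshold = 0.05) {
  stopifnot(inherits(model, "quadratic_model"))
  if (!is.numeric(p_threshold) || length(p_threshold) != 1L ||
      p_threshold <= 0 || p_threshold > 1) {
    stop("p_threshold must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(model$p_values) || is.null(model$fit)) {
    stop("reduce_model needs a fitted model with p-values", call. = FALSE)
  }
  pv <- model$p_values[names(model$p_values) != "(Intercept)"]
  keep <- names(pv)[pv <= p_threshold]
  des <- structure(list(
    factors = NULL, coded = model$fit$coded,
    run_id = seq_along(model$fit$y),
    responses = stats::setNames(
      list(data.frame(mean = model$fit$y, sd = 0, n = 1L)), model$response)
  ), class = "bbd_design")
  if (length(keep) == 0L) keep <- character(0)
  if (length(keep)) {
    fit_quadratic(des, model$response, terms = keep)
  } else {
    # intercept-only model
    y <- model$fit$y
    out <- quadratic_model(model$response,
                           c("(Intercept)" = mean(y)), "coefficient",
                           p_values = c("(Intercept)" = 0), r_squared = 0)
    out$fit <- list(y = y, coded = model$fit$coded, terms = character(0),
                    lm = NULL, df_residual = length(y) - 1L)
    out
  }
}

#' Serialize / restore a quadratic model as JSON
#'
#' The report carries the response name, parameterization, per-term estimates
#' and p-values, and \eqn{R^2}; reading it back reconstructs an equivalent
#' model (fitting data are not serialized).
#'
#' @param model A `"quadratic_model"`.
#' @param path File path.
#' @return `write_model_json()` returns `path` invisibly; `read_model_json()`
#'   returns a `"quadratic_model"`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "quadratic_model"))
  obj <- list(
    response = model$response,
    parameterization = model$parameterization,
    coefficients = as.list(model$coefficients),
    p_values = if (is.null(model$p_values)) NULL else as.list(model$p_values),
    r_squared = model$r_squared
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  quadratic_model(
    response = obj$response,
    coefficients = unlist(obj$coefficients),
    parameterization = obj$parameterization,
    p_values = if (!is.null(obj$p_values)) unlist(obj$p_values),
    r_squared = if (is.null(obj$r_squared)) NA_real_ else obj$r_squared
  )
}
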