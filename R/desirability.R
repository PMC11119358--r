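# Derringer-style larger-is-better desirability transforms and grid + polish
# maximization of the joint desirability over the coded factor cube.

#' Desirability specification for a larger-is-better response
#'
#' @param response Response name.
#' @param lower Value at or below which desirability is 0.
#' @param upper Value at or above which desirability is 1 (`lower < upper`).
#' @param s Shape exponent (> 0); 1 gives the linear ramp.
#' @param weight Importance weight (> 0) used in the joint geometric mean.
#' @return An object of class `"desirability_spec"`.
#' @export
desirability_spec <- function(response, lower, upper, s = 1, weight = 1) {
  if (!is.numeric(lower) || !is.numeric(upper) || lower >= upper) {
    stop("invalid desirability spec: lower anchor must be below upper anchor",
         call. = FALSE)
  }
  if (s <= 0 || weight <= 0) {
    stop("invalid desirability spec: s and weight must be positive", call. = FALSE)
  }
  structure(list(response = response, lower = lower, upper = upper,
                 s = s, weight = weight),
            class = "desirability_spec")
}

#' Larger-is-better desirability transform
#'
#' Maps a response value onto \[0, 1\]: 0 at or below the lower anchor, 1 at
#' or above the upper anchor, and `((y - L) / (U - L))^s` in between. The
#' transform is nondecreasing in `y`.
#'
#' @param y Numeric vector of response values.
#' @param spec A [desirability_spec()].
#' @return Desirabilities in \[0, 1\], same length as `y`.
#' @examples
#' sp <- desirability_spec("y", 0, 10)
#' desirability_maximize(c(-1, 0, 5, 10, 12), sp)
#' @export
desirability_maximize <- function(y, spec) {
  stopifnot(inherits(spec, "desirability_spec"))
  d <- (y - spec$lower) / (spec$upper - spec$lower)
  d <- pmin(1, pmax(0, d))
  d^spec$s
}

#' Weighted geometric-mean overall desirability
#'
#' Combines per-response desirabilities as
#' \eqn{D = (\prod d_i^{w_i})^{1 / \sum w_i}}. Any zero component annihilates
#' the product, so the joint optimum avoids regions where any response is
#' wholly undesirable.
#'
#' @param d Numeric vector of desirabilities in \[0, 1\].
#' @param weights Positive importance weights, recycled to `length(d)`;
#'   default equal weights.
#' @return The overall desirability in \[0, 1\].
#' @export
overall_desirability <- function(d, weights = rep(1, length(d))) {
  if (any(d < 0 | d > 1)) stop("desirabilities must lie in [0, 1]", call. = FALSE)
  weights <- rep_len(weights, length(d))
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  if (any(d == 0)) return(0)
  exp(sum(weights * log(d)) / sum(weights))
}

# overall D for a matrix of per-response desirabilities (rows = points)
overall_desirability_matrix <- function(D, weights) {
  weights <- rep_len(weights, ncol(D))
  out <- exp((log(pmax(D, .Machine$double.xmin)) %*% weights) / sum(weights))
  out[apply(D == 0, 1, any)] <- 0
  drop(out)
}

#' Maximize joint desirability over the coded factor cube
#'
#' Evaluates every model on a regular `grid_density`-per-axis grid over the
#' closed cube \eqn{[-1, 1]^3}, combines the per-response desirabilities by
#' weighted geometric mean, takes the best grid point (ties broken by the
#' lexicographically smallest coded triple), and polishes it with a
#' box-constrained quasi-Newton search. No extrapolation outside the cube is
#' attempted: the optimum is sought only over the studied factor ranges.
#'
#' When `specs` is `NULL` the anchors of each response default to its
#' predicted minimum and maximum over the evaluation grid (a data-independent
#' larger-is-better goal); `anchors = "observed"` instead uses the min/max of
#' the observed run means in `design`.
#'
#' @param models List of `"quadratic_model"` objects, one per response.
#' @param specs Optional list of [desirability_spec()]s, one per model, in the
#'   same order. Default `NULL` derives anchors as described above.
#' @param design Optional `"bbd_design"`; supplies factor specs for decoding
#'   the optimum to actual units and, with `anchors = "observed"`, the
#'   observed response ranges.
#' @param grid_density Grid points per axis (>= 2); default 21.
#' @param anchors Anchor policy when `specs` is `NULL`: `"predicted"`
#'   (default) or `"observed"`.
#' @param literal Passed to [predict_response()]; evaluate printed effect-scale
#'   equations as-is.
#' @return An object of class `"desirability_optimum"`: list with
#'   `coded_optimum`, `actual_optimum` (named, when factor specs are
#'   available), `predicted_responses`, `overall_D`, `specs` and the
#'   evaluation `grid_density`.
#' @examples
#' m <- quadratic_model("y", c("(Intercept)" = 0, x1 = 1))
#' optimize_desirability(list(m))$coded_optimum  # (+1, -1, -1): x1 maximal
#' @export
optimize_desirability <- function(models, specs = NULL, design = NULL,
                                  grid_density = 21L,
                                  anchors = c("predicted", "observed"),
                                  literal = FALSE) {
  anchors <- match.arg(anchors)
  stopifnot(is.list(models), length(models) >= 1L,
            all(vapply(models, inherits, logical(1), "quadratic_model")))
  grid_density <- as.integer(grid_density)
  if (grid_density < 2L) stop("grid_density must be >= 2", call. = FALSE)
  if (!is.null(specs) && length(specs) != length(models)) {
    stop("one desirability spec per model is required", call. = FALSE)
  }

  ax <- seq(-1, 1, length.out = grid_density)
  grid <- as.matrix(expand.grid(x1 = ax, x2 = ax, x3 = ax))
  pred <- vapply(models, predict_response, numeric(nrow(grid)),
                 x = grid, literal = literal)

  if (is.null(specs)) {
    specs <- lapply(seq_along(models), function(i) {
      if (anchors == "observed") {
        if (is.null(design)) {
          stop("anchors = 'observed' needs the design with response data",
               call. = FALSE)
        }
        y <- design$responses[[models[[i]]$response]]$mean
        lo <- min(y); hi <- max(y)
      } else {
        lo <- min(pred[, i]); hi <- max(pred[, i])
      }
      if (hi <= lo) hi <- lo + max(1e-9, abs(lo) * 1e-9)  # flat response guard
      desirability_spec(models[[i]]$response, lo, hi)
    })
  }
  weights <- vapply(specs, `[[`, numeric(1), "weight")

  Dmat <- vapply(seq_along(models),
                 function(i) desirability_maximize(pred[, i], specs[[i]]),
                 numeric(nrow(grid)))
  D <- overall_desirability_matrix(Dmat, weights)

  if (all(D == 0)) {
    warning("overall desirability is zero everywhere on the grid; ",
            "returning the lexicographically first grid point", call. = FALSE)
    best <- 1L
  } else {
    cand <- which(D >= max(D) - 1e-15)
    # lexicographic tie-break on the coded triple
    best <- cand[order(grid[cand, 1], grid[cand, 2], grid[cand, 3])][1L]
  }

  objective <- function(x) {
    yv <- vapply(models, predict_response, numeric(1), x = x, literal = literal)
    dv <- vapply(seq_along(models),
                 function(i) desirability_maximize(yv[i], specs[[i]]),
                 numeric(1))
    -overall_desirability(dv, weights)
  }
  pol <- stats::optim(grid[best, ], objective, method = "L-BFGS-B",
                      lower = rep(-1, 3), upper = rep(1, 3))
  coded <- if (-pol$value >= D[best]) pol$par else grid[best, ]
  Dopt <- max(-pol$value, D[best])

  yopt <- vapply(models, predict_response, numeric(1), x = coded,
                 literal = literal)
  names(yopt) <- vapply(models, `[[`, character(1), "response")
  actual <- if (!is.null(design) && !is.null(design$factors)) {
    stats::setNames(coded_to_actual(design$factors, coded),
                    vapply(design$factors, `[[`, character(1), "name"))
  } else NULL

  structure(list(
    coded_optimum = stats::setNames(as.numeric(coded), c("x1", "x2", "x3")),
    actual_optimum = actual,
    predicted_responses = yopt,
    overall_D = as.numeric(Dopt),
    specs = specs,
    grid_density = grid_density
  ), class = "desirability_optimum")
}

#' @export
print.desirability_optimum <- function(x, ...) {
  cat("Desirability optimum (coded):",
      paste(sprintf("%.3f", x$coded_optimum), collapse = ", "), "\n")
  if (!is.null(x$actual_optimum)) {
    cat("Actual units:",
        paste(sprintf("%s = %g", names(x$actual_optimum), x$actual_optimum),
              collapse = ", "), "\n")
  }
  cat("Predicted responses:",
      paste(sprintf("%s = %.3f", names(x$predicted_responses),
                    x$predicted_responses), collapse = ", "), "\n")
  cat(sprintf("Overall D = %.4f\n", x$overall_D))
  invisible(x)
}

#' Per-factor desirability traces at the optimum
#'
#' Profiles overall desirability along each coded axis with the other two
#' factors held at the optimum — a plain-text analogue of the usual
#' desirability profile panels.
#'
#' @param result A `"desirability_optimum"`.
#' @param models The models it was computed from.
#' @param n Points per axis.
#' @inheritParams optimize_desirability
#' @return A data frame with columns `factor`, `coded`, `overall_D`.
#' @export
desirability_trace <- function(result, models, n = 41L, literal = FALSE) {
  stopifnot(inherits(result, "desirability_optimum"))
  ax <- seq(-1, 1, length.out = n)
  weights <- vapply(result$specs, `[[`, numeric(1), "weight")
  out <- lapply(1:3, function(j) {
    pts <- matrix(rep(result$coded_optimum, each = n), nrow = n)
    pts[, j] <- ax
    Dmat <- vapply(seq_along(models), function(i) {
      desirability_maximize(predict_response(models[[i]], pts, literal = literal),
                            result$specs[[i]])
    }, numeric(n))
    data.frame(factor = paste0("x", j), coded = ax,
               overall_D = overall_desirability_matrix(Dmat, weights))
  })
  do.call(rbind, out)
}
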