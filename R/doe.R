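# Three-factor Box-Behnken design construction and coded/actual level mapping.

#' Specify an experimental factor
#'
#' Describes one continuous factor of a three-level design by its low, mid and
#' high settings in actual units. The mid level must be the arithmetic centre
#' of the range, which is what makes the coded transform `(x - mid) / half-span`
#' map the three levels onto -1, 0, +1.
#'
#' @param name Factor name (e.g. `"time"`).
#' @param low,high Low and high settings in actual units (`low < high`).
#' @param mid Centre setting; defaults to `(low + high) / 2` and must equal it
#'   to within `1e-9` of the half-span.
#' @param units Unit label carried as metadata (e.g. `"min"`, `"degC"`, `"mL"`).
#'
#' @return An object of class `"uae_factor"`: a list with elements `name`,
#'   `low`, `mid`, `high`, `units`.
#' @examples
#' factor_spec("time", 5, 75, units = "min")
#' @export
factor_spec <- function(name, low, high, mid = (low + high) / 2, units = "") {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(low), is.numeric(mid), is.numeric(high))
  if (!(low < mid && mid < high)) {
    stop("factor levels must satisfy low < mid < high", call. = FALSE)
  }
  half <- (high - low) / 2
  if (abs(mid - (low + high) / 2) > 1e-9 * half) {
    stop("mid level must be the centre of [low, high]", call. = FALSE)
  }
  structure(list(name = name, low = low, mid = mid, high = high, units = units),
            class = "uae_factor")
}

#' @export
print.uae_factor <- function(x, ...) {
  cat(sprintf("Factor %s: %g / %g / %g %s\n", x$name, x$low, x$mid, x$high, x$units))
  invisible(x)
}

# Coded triples of the 12 edge runs, in standard order: the (x1, x2) block,
# then (x1, x3), then (x2, x3), each cycling (-,-), (+,-), (-,+), (+,+).
bbd3_edge_matrix <- function() {
  pm <- cbind(c(-1, 1, -1, 1), c(-1, -1, 1, 1))
  rbind(
    cbind(pm[, 1], pm[, 2], 0),
    cbind(pm[, 1], 0, pm[, 2]),
    cbind(0, pm[, 1], pm[, 2])
  )
}

#' Build a three-factor Box-Behnken design
#'
#' Constructs the canonical 3-factor Box-Behnken design: 12 mid-edge runs (all
#' pairs of factors at +/-1 with the third at its centre) followed by
#' `n_center` replicated centre-point runs. With `n_center = 5` this is the
#' classical 17-run arrangement. The design is orthogonal for linear and
#' interaction terms on the coded scale.
#'
#' @param factors List of exactly three [factor_spec()] objects.
#' @param n_center Number of centre-point replicates (>= 1; default 5).
#'
#' @return An object of class `"bbd_design"`: a list with
#'   \describe{
#'     \item{factors}{the three factor specs,}
#'     \item{coded}{a 17 x 3 (or `12 + n_center` x 3) numeric matrix of coded
#'       levels with columns named after the factors,}
#'     \item{run_id}{integer run identifiers in standard order,}
#'     \item{responses}{a named list, one entry per response, each a data frame
#'       with columns `mean`, `sd`, `n` (empty on construction).}
#'   }
#' @examples
#' des <- bbd3(list(
#'   factor_spec("time", 5, 75, units = "min"),
#'   factor_spec("temperature", 30, 70, units = "degC"),
#'   factor_spec("solvent", 25, 75, units = "mL")
#' ))
#' colSums(design_matrix(des))  # orthogonal: all zero
#' @export
bbd3 <- function(factors, n_center = 5L) {
  if (!is.list(factors) || length(factors) != 3L ||
      !all(vapply(factors, inherits, logical(1), "uae_factor"))) {
    stop("invalid design: exactly 3 factor_spec objects are required", call. = FALSE)
  }
  n_center <- as.integer(n_center)
  stopifnot(n_center >= 1L)
  coded <- rbind(bbd3_edge_matrix(), matrix(0, n_center, 3))
  colnames(coded) <- vapply(factors, `[[`, character(1), "name")
  structure(list(
    factors   = factors,
    coded     = coded,
    run_id    = seq_len(nrow(coded)),
    responses = list()
  ), class = "bbd_design")
}

#' @export
print.bbd_design <- function(x, ...) {
  cat(sprintf("Box-Behnken design: %d runs (%d centre), factors %s\n",
              nrow(x$coded), sum(rowSums(x$coded != 0) == 0),
              paste(colnames(x$coded), collapse = ", ")))
  if (length(x$responses)) {
    cat("responses:", paste(names(x$responses), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Coded design matrix of a design
#'
#' @param design A `"bbd_design"`.
#' @return The numeric matrix of coded levels (runs x factors).
#' @export
design_matrix <- function(design) {
  stopifnot(inherits(design, "bbd_design"))
  design$coded
}

#' Attach a response to a design
#'
#' @param design A `"bbd_design"`.
#' @param name Response name.
#' @param mean,sd,n Per-run replicate summaries; `sd` defaults to 0 and `n`
#'   to 1 when only run means are available.
#' @return The design with the response stored in `design$responses[[name]]`.
#' @export
set_response <- function(design, name, mean, sd = 0, n = 1L) {
  stopifnot(inherits(design, "bbd_design"),
            length(mean) == nrow(design$coded))
  sd <- rep_len(sd, length(mean))
  n <- rep_len(as.integer(n), length(mean))
  if (any(sd < 0) || any(n < 1L)) {
    stop("replicate summaries need sd >= 0 and n >= 1", call. = FALSE)
  }
  design$responses[[name]] <- data.frame(mean = mean, sd = sd, n = n)
  design
}

#' Convert between coded and actual factor levels
#'
#' The coded level of factor i is `(actual - mid_i) / ((high_i - low_i) / 2)`,
#' so the studied range maps onto \[-1, +1\]. The transform and its inverse are
#' exact; a round trip reproduces the input.
#'
#' @param factors List of [factor_spec()] objects, one per column of `x`.
#' @param x Numeric vector (one point) or matrix (points in rows) of levels.
#' @return Levels on the other scale, same shape as `x`.
#' @details `actual_to_coded()` warns when a value falls outside the studied
#'   `[low, high]` range but still transforms it, so prediction grids may
#'   extrapolate deliberately.
#' @examples
#' f <- list(factor_spec("time", 5, 75), factor_spec("temp", 30, 70),
#'           factor_spec("solvent", 25, 75))
#' coded_to_actual(f, c(0.5, 0.5, 0))  # 57.5 min, 60 degC, 50 mL
#' @export
coded_to_actual <- function(factors, x) {
  transform_point(factors, x, function(v, f) f$mid + v * (f$high - f$low) / 2)
}

#' @rdname coded_to_actual
#' @export
actual_to_coded <- function(factors, x) {
  transform_point(factors, x, function(v, f) {
    if (any(v < f$low - 1e-12) || any(v > f$high + 1e-12)) {
      warning(sprintf("actual level outside [%g, %g] for factor '%s'; extrapolating",
                      f$low, f$high, f$name), call. = FALSE)
    }
    (v - f$mid) / ((f$high - f$low) / 2)
  })
}

transform_point <- function(factors, x, fn) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  stopifnot(ncol(m) == length(factors))
  out <- m
  for (j in seq_along(factors)) out[, j] <- fn(m[, j], factors[[j]])
  if (vec) drop(out) else out
}

#' Re-express a whole design on the coded or actual scale
#'
#' @param design A `"bbd_design"` (levels stored coded).
#' @param direction `"coded_to_actual"` or `"actual_to_coded"`.
#' @return A matrix of run levels on the requested scale.
#' @export
transform_levels <- function(design,
                             direction = c("coded_to_actual", "actual_to_coded")) {
  direction <- match.arg(direction)
  stopifnot(inherits(design, "bbd_design"))
  if (direction == "coded_to_actual") {
    coded_to_actual(design$factors, design$coded)
  } else {
    # design stores coded levels; interpret the request as inverting an
    # actual-scale matrix back to coded, i.e. round-tripping
    actual_to_coded(design$factors, coded_to_actual(design$factors, design$coded))
  }
}

#' Read / write the design CSV interchange format
#'
#' Columns: `run_id`, one actual-unit column per factor, then for each response
#' `<name>`, columns `<name>` and `<name>_sd`. UTF-8, '.' decimal separator.
#'
#' @param path File path.
#' @param factors List of three [factor_spec()]s naming the factor columns.
#' @param responses Character vector of response column names.
#' @param n_replicates Replicate count to record for every run (the format
#'   stores mean and sd only).
#' @return `read_design_csv()` returns a `"bbd_design"`; `write_design_csv()`
#'   returns `path` invisibly.
#' @export
read_design_csv <- function(path, factors, responses, n_replicates = 1L) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  fnames <- vapply(factors, `[[`, character(1), "name")
  stopifnot(all(c("run_id", fnames) %in% names(tab)))
  actual <- as.matrix(tab[, fnames])
  coded <- round(actual_to_coded(factors, actual), 10)
  n_center <- sum(rowSums(coded != 0) == 0)
  des <- bbd3(factors, n_center = max(1L, n_center))
  # keep the file's own run order and levels rather than regenerated ones
  des$coded <- coded
  colnames(des$coded) <- fnames
  des$run_id <- tab$run_id
  for (r in responses) {
    sdcol <- paste0(r, "_sd")
    des <- set_response(des, r, tab[[r]],
                        sd = if (sdcol %in% names(tab)) tab[[sdcol]] else 0,
                        n = n_replicates)
  }
  des
}

#' @rdname read_design_csv
#' @param design A `"bbd_design"` with responses attached.
#' @export
write_design_csv <- function(design, path) {
  stopifnot(inherits(design, "bbd_design"))
  actual <- coded_to_actual(design$factors, design$coded)
  out <- data.frame(run_id = design$run_id, actual, check.names = FALSE)
  for (r in names(design$responses)) {
    out[[r]] <- design$responses[[r]]$mean
    out[[paste0(r, "_sd")]] <- design$responses[[r]]$sd
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
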