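# Bundled purple-fleshed sweet potato (PFSP) ultrasound-assisted extraction
# study: design/response table, reduced response-surface equations as
# published, kinetic reference constants and fitted kinetic parameters, and
# the validation/comparison means. Every accessor labels where each constant
# comes from within the study (design table, kinetic study, validation run).

#' Factors of the PFSP ultrasound-extraction design
#'
#' Extraction time 5/40/75 min, bath temperature 30/50/70 degC, and solvent
#' volume 25/50/75 mL per 5 g of plant material. The solvent volume encodes
#' the solid-to-liquid ratio (1:5, 1:10, 1:15 m/v); the ratio strings are
#' display metadata, the numeric factor is the volume in mL.
#'
#' @return List of three [factor_spec()] objects.
#' @export
pfsp_factors <- function() {
  list(
    factor_spec("time_min", 5, 75, units = "min"),
    factor_spec("temperature_C", 30, 70, units = "degC"),
    factor_spec("solvent_mL", 25, 75, units = "mL per 5 g solid")
  )
}

#' The PFSP Box-Behnken design with measured responses
#'
#' The 17-run, 3-factor Box-Behnken design of the bundled PFSP study with the
#' replicate mean and SD of total anthocyanin (`TA`, mg/100 g) and total
#' phenolic content (`TPC`, mg GAE/100 g) for every run, in standard order
#' (12 edge runs, then 5 centre replicates). The replicate count per run is
#' not recorded in the source table; `n = 3` is stored as an assumption and
#' flagged in the design's `n_replicates_assumed` attribute.
#'
#' @return A `"bbd_design"` with responses `TA` and `TPC`.
#' @examples
#' des <- pfsp_design()
#' max(des$responses$TA$mean)  # 16.424 mg/100 g
#' @export
pfsp_design <- function() {
  path <- system.file("extdata", "pfsp_bbd_design.csv", package = "uaextract",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  factors <- pfsp_factors()
  des <- bbd3(factors, n_center = 5L)
  stopifnot(nrow(tab) == nrow(des$coded))
  des$run_id <- tab$run_id
  des <- set_response(des, "TA", tab$ta_mg_per_100g, sd = tab$ta_sd, n = 3L)
  des <- set_response(des, "TPC", tab$tpc_mg_gae_per_100g, sd = tab$tpc_sd, n = 3L)
  attr(des, "n_replicates_assumed") <- TRUE
  attr(des, "provenance") <- "PFSP UAE study: design/response table"
  des
}

#' Published reduced response-surface equations of the PFSP study
#'
#' The reduced second-order equations for TA and TPC exactly as published, on
#' the doubled ("effect") scale:
#' \deqn{Y_{TA} = 11.079 + 5.613 X_1 + 1.961 X_2 - 1.455 X_3^2 + 4.129 X_1 X_3}
#' \deqn{Y_{TPC} = 96.425 + 34.323 X_1 + 9.608 X_2 + 39.118 X_3 + 6.727 X_1^2
#'   - 13.891 X_2^2 + 15.239 X_1 X_3}
#' Note these are fixtures, not refits: their X2/X3 linear terms, intercepts
#' and quadratic signs are not reproducible from the bundled design table by
#' OLS (see the package vignette). Use `literal = TRUE` in
#' [predict_response()] to reproduce the arithmetic a reader would do with
#' the printed terms.
#'
#' @return Named list of two `"quadratic_model"` objects (`TA`, `TPC`) with
#'   `parameterization = "effect"`.
#' @export
pfsp_published_models <- function() {
  ta <- quadratic_model("TA", c(
    "(Intercept)" = 11.079, "x1" = 5.613, "x2" = 1.961,
    "x3^2" = -1.455, "x1:x3" = 4.129), "effect", r_squared = 0.978)
  tpc <- quadratic_model("TPC", c(
    "(Intercept)" = 96.425, "x1" = 34.323, "x2" = 9.608, "x3" = 39.118,
    "x1^2" = 6.727, "x2^2" = -13.891, "x1:x3" = 15.239), "effect",
    r_squared = 0.981)
  list(TA = ta, TPC = tpc)
}

#' Kinetic reference constants of the PFSP study
#'
#' Equilibrium saturated-extract concentrations `c_seq` (mg/L) and initial
#' extractable contents `q0` (mg/100 g) for TA and TPC, measured by repeated
#' extraction/filtration cycles on 5 g of material in 75 mL of solvent, plus
#' the batch [mass_balance()]. The study does not state separate constants for
#' the conventional process; `same_constants_for_conventional = TRUE` records
#' that the same values are applied to both methods here.
#'
#' @return List with `c_seq`, `c_seq_sd`, `q0`, `q0_sd` (each named by
#'   compound), `balance`, and `same_constants_for_conventional`.
#' @export
pfsp_reference_constants <- function() {
  list(
    c_seq = c(TA = 8.923, TPC = 252.00),
    c_seq_sd = c(TA = 0.37, TPC = 0.69),
    q0 = c(TA = 54.333, TPC = 305.521),
    q0_sd = c(TA = 3.43, TPC = 4.39),
    balance = mass_balance(5, 75),
    same_constants_for_conventional = TRUE,
    provenance = "PFSP UAE study: equilibrium/initial-content determinations"
  )
}

#' Published kinetic parameters of the PFSP study
#'
#' The fitted washing coefficient `b`, slow-extraction coefficient `k`
#' (1/min; tabulated as k x 10^-3 in the source, stored here in plain 1/min)
#' and linearized-fit R^2 for every model x method x compound combination.
#' The washing/slow-extraction roles follow the kinetic-equation notation
#' (`b` = washing, `k` = slow extraction); the source's parameter-table
#' footnote swaps the two names and is not followed.
#'
#' @return Data frame with columns `model`, `method`, `compound`,
#'   `r_squared`, `k`, `b` (12 rows).
#' @examples
#' subset(pfsp_kinetic_parameters(), method == "UAE" & compound == "TA")
#' @export
pfsp_kinetic_parameters <- function() {
  tab <- expand.grid(method = c("UAE", "CONV"), model = KINETIC_MODELS,
                     stringsAsFactors = FALSE)[, c("model", "method")]
  tab <- tab[rep(seq_len(nrow(tab)), each = 2), ]
  tab$compound <- rep(c("TA", "TPC"), 6)
  tab$r_squared <- c(0.899, 0.884, 0.592, 0.501,   # film UAE, film CONV
                     0.962, 0.976, 0.889, 0.811,   # unsteady
                     0.937, 0.961, 0.882, 0.799)   # ponomaryov
  tab$k <- c(1.126, 1.261, 0.225, 0.397,
             3.051, 2.187, 0.349, 0.487,
             1.304, 0.902, 0.291, 0.355) * 1e-3
  tab$b <- c(0.297, 0.427, 0.177, 0.325,
             0.366, 0.459, 0.135, 0.231,
             0.392, 0.469, 0.135, 0.231)
  rownames(tab) <- NULL
  attr(tab, "provenance") <- "PFSP UAE study: kinetic parameter table"
  tab
}

#' Kinetic spec for one published parameter row
#'
#' Convenience constructor pairing a row of [pfsp_kinetic_parameters()] with
#' the matching reference constant from [pfsp_reference_constants()].
#'
#' @param model,method,compound Row selector.
#' @return A [kinetic_spec()].
#' @export
pfsp_kinetic_spec <- function(model = KINETIC_MODELS,
                              method = c("UAE", "CONV"),
                              compound = c("TA", "TPC")) {
  model <- match.arg(model); method <- match.arg(method)
  compound <- match.arg(compound)
  tab <- pfsp_kinetic_parameters()
  row <- tab[tab$model == model & tab$method == method &
               tab$compound == compound, ]
  stopifnot(nrow(row) == 1L)
  refs <- pfsp_reference_constants()
  kinetic_spec(model, b = row$b, k = row$k,
               c_seq = refs$c_seq[[compound]], q0 = refs$q0[[compound]])
}

#' Validation and method-comparison means of the PFSP study
#'
#' Mean +/- SD contents measured under the optimized ultrasound conditions
#' (75 min, 70 degC, 1:15 m/v) and under the conventional process (24 h, 5
#' degC, 1:10 m/v), with the desirability-predicted contents at the optimum.
#'
#' @return Data frame with one row per compound: `uae_mean`, `uae_sd`,
#'   `conv_mean`, `conv_sd`, `predicted`.
#' @export
pfsp_validation <- function() {
  tab <- data.frame(
    compound = c("TA", "TPC"),
    uae_mean = c(18.822, 162.174),
    uae_sd = c(1.59, 12.44),
    conv_mean = c(10.396, 83.939),
    conv_sd = c(0.05, 6.31),
    predicted = c(18.372, 151.160)
  )
  attr(tab, "provenance") <- "PFSP UAE study: validation/comparison means"
  tab
}

#' Percent comparison arithmetic for the PFSP validation data
#'
#' Computes, per compound, the percent increase of the ultrasound yield over
#' the conventional yield, `100 (UAE - conv) / conv`, and the percent
#' difference of the validated yield from the desirability prediction,
#' `100 (UAE - predicted) / predicted`.
#'
#' @param validation Data frame as returned by [pfsp_validation()].
#' @param round_digits Digits for the reported percentages (default 0, the
#'   source's rounding); `NULL` for unrounded.
#' @return Data frame with columns `compound`, `pct_increase_vs_conventional`,
#'   `pct_difference_vs_predicted`.
#' @examples
#' comparison_percentages()  # TA: +81% vs conventional; TPC: +93%
#' @export
comparison_percentages <- function(validation = pfsp_validation(),
                                   round_digits = 0) {
  inc <- 100 * (validation$uae_mean - validation$conv_mean) / validation$conv_mean
  dif <- 100 * (validation$uae_mean - validation$predicted) / validation$predicted
  if (!is.null(round_digits)) {
    inc <- round(inc, round_digits); dif <- round(dif, round_digits)
  }
  data.frame(compound = validation$compound,
             pct_increase_vs_conventional = inc,
             pct_difference_vs_predicted = dif)
}
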