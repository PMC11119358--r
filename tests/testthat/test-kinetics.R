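refs <- pfsp_reference_constants()

test_that("film curve starts at the washed fraction and saturates at c_seq", {
  sp <- pfsp_kinetic_spec("film", "UAE", "TA")  # b = 0.297, k = 1.126e-3
  ser <- simulate_kinetics(sp, kinetic_schedule())
  expect_equal(ser$values[1], 0.297 * 8.923, tolerance = 1e-12)
  expect_equal(round(ser$values[1], 3), 2.650)
  expect_equal(simulate_kinetics(sp, c(0, 1e7))$values[2], sp$c_seq,
               tolerance = 1e-8)
  expect_true(all(diff(ser$values) > 0))  # nondecreasing for k > 0
  expect_identical(ser$quantity, "c_mg_L")
})

test_that("unsteady curve starts below q0 by the washing step and decays", {
  sp <- pfsp_kinetic_spec("unsteady", "UAE", "TPC")
  ser <- simulate_kinetics(sp, kinetic_schedule())
  expect_equal(ser$values[1] / sp$q0, 1 - sp$b, tolerance = 1e-12)
  expect_true(all(diff(ser$values) < 0))
  expect_identical(ser$quantity, "q_mg_100g")
})

test_that("ponomaryov residual content is floored at zero with a warning", {
  sp <- kinetic_spec("ponomaryov", b = 0.5, k = 0.01, q0 = 100)
  expect_warning(ser <- simulate_kinetics(sp, c(0, 10, 100)), "floored")
  expect_equal(ser$values[3], 0)
  expect_silent(simulate_kinetics(sp, c(0, 10)))
})

test_that("negative times and malformed series are rejected", {
  sp <- pfsp_kinetic_spec("film", "UAE", "TA")
  expect_error(simulate_kinetics(sp, c(-1, 5)), "negative time")
  expect_error(kinetic_series(c(0, 0, 5), c(1, 2, 3)), "strictly increasing")
  expect_error(kinetic_series(c(0, 5), c(1, 2, 3)), "equal length")
  expect_error(kinetic_spec("film", b = 1.2, k = 0.1, c_seq = 5), "washing")
  expect_error(kinetic_spec("film", b = 0.5, k = 0.1, c_seq = -2), "positive")
})

test_that("mass-balance conversion matches the batch arithmetic and round-trips", {
  bal <- mass_balance(5, 75)
  ser <- kinetic_series(c(0, 10), c(8.923, 4), "c_mg_L")
  q <- content_concentration_convert(ser, bal, q0 = 54.333)
  expect_equal(q$values[1], 54.333 - 8.923 * 0.075 / 5 * 100)  # 40.9485
  expect_equal(q$values[1], 40.9485, tolerance = 1e-9)
  zero <- kinetic_series(c(0, 10), c(0, 0), "c_mg_L")
  expect_equal(content_concentration_convert(zero, bal, 54.333)$values,
               c(54.333, 54.333))
  back <- content_concentration_convert(q, bal, q0 = 54.333)
  expect_equal(back$values, ser$values, tolerance = 1e-12)
  expect_identical(back$quantity, "c_mg_L")
  big <- kinetic_series(c(0, 10), c(100, 8000), "c_mg_L")
  expect_warning(content_concentration_convert(big, bal, 54.333), "clipped")
})

test_that("mass is conserved between liquid and solid phases", {
  sp <- pfsp_kinetic_spec("film", "UAE", "TA")
  ser <- simulate_kinetics(sp, kinetic_schedule())
  bal <- refs$balance
  q <- content_concentration_convert(ser, bal, refs$q0[["TA"]])
  extracted_per_100g <- ser$values * bal$V / 1000 / bal$m * 100
  expect_equal(q$values + extracted_per_100g,
               rep(refs$q0[["TA"]], length(ser$times)))
})

test_that("linearized fitting inverts noise-free curves for every packaged parameter set", {
  par_tab <- pfsp_kinetic_parameters()
  for (i in seq_len(nrow(par_tab))) {
    row <- par_tab[i, ]
    sp <- pfsp_kinetic_spec(row$model, row$method, row$compound)
    ser <- simulate_kinetics(sp, kinetic_schedule())
    fit <- fit_linearized(ser, row$model, c_seq = sp$c_seq, q0 = sp$q0)
    expect_equal(fit$spec$b, sp$b, tolerance = 1e-9 * abs(sp$b))
    expect_equal(fit$spec$k, sp$k, tolerance = 1e-9 * abs(sp$k))
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    expect_equal(fit$n_points_used, 8L)
    expect_equal(nrow(fit$dropped_points), 0L)
  }
})

test_that("points at or above the equilibrium concentration are dropped with a reason", {
  sp <- pfsp_kinetic_spec("film", "UAE", "TA")
  ser <- simulate_kinetics(sp, kinetic_schedule())
  vals <- ser$values
  vals[5] <- sp$c_seq * 1.01
  bad <- kinetic_series(ser$times, vals, "c_mg_L")
  fit <- fit_linearized(bad, "film", c_seq = sp$c_seq)
  expect_equal(fit$dropped_points$time, kinetic_schedule()[5])
  expect_match(fit$dropped_points$reason, "log undefined")
  expect_equal(fit$n_points_used, 7L)
  expect_equal(fit$spec$k, sp$k, tolerance = 1e-9)
  # too few usable points is an error
  short <- kinetic_series(c(0, 10, 20), rep(sp$c_seq * 1.1, 3), "c_mg_L")
  expect_error(fit_linearized(short, "film", c_seq = sp$c_seq), "insufficient")
})

test_that("concentration series are converted automatically for content-scale models", {
  sp <- pfsp_kinetic_spec("unsteady", "UAE", "TA")
  ser_q <- simulate_kinetics(sp, kinetic_schedule())
  ser_c <- content_concentration_convert(ser_q, refs$balance, sp$q0)
  fit <- fit_linearized(ser_c, "unsteady", q0 = sp$q0, balance = refs$balance)
  expect_equal(fit$spec$b, sp$b, tolerance = 1e-9)
  expect_equal(fit$spec$k, sp$k, tolerance = 1e-9)
})

test_that("nonlinear fits agree with linearized fits on noise-free data", {
  for (model in c("film", "unsteady", "ponomaryov")) {
    sp <- pfsp_kinetic_spec(model, "UAE", "TPC")
    ser <- simulate_kinetics(sp, kinetic_schedule())
    lin <- fit_linearized(ser, model, c_seq = sp$c_seq, q0 = sp$q0)
    nl <- fit_nonlinear(ser, model, c_seq = sp$c_seq, q0 = sp$q0)
    expect_equal(nl$spec$b, lin$spec$b, tolerance = 1e-6)
    expect_equal(nl$spec$k, lin$spec$k, tolerance = 1e-6)
    expect_identical(nl$fit_method, "nonlinear")
  }
})

test_that("a constant series degenerates to pure washing (k -> 0)", {
  ser <- kinetic_series(kinetic_schedule(), rep(3, 8), "c_mg_L")
  fit <- fit_nonlinear(ser, "film", c_seq = 8.923)
  expect_equal(fit$spec$b, 3 / 8.923, tolerance = 1e-6)
  expect_equal(fit$spec$k, 0, tolerance = 1e-6)
})

test_that("model comparison ranks by descending R-squared with stable ties", {
  sp <- pfsp_kinetic_spec("film", "UAE", "TA")
  fit_all <- function(ser_c) {
    ser_q <- content_concentration_convert(ser_c, refs$balance, sp$q0)
    lapply(c("film", "unsteady", "ponomaryov"), function(m) {
      fit_linearized(if (m == "film") ser_c else ser_q, m,
                     c_seq = sp$c_seq, q0 = sp$q0)
    })
  }
  noisy <- generate_kinetic_series(sp, config = synthetic_config(5, noise_sd = 0.15))
  tab <- compare_models(fit_all(noisy))
  expect_true(all(diff(tab$r_squared) <= 0))
  # the generating model fits its own noise-free data perfectly and ranks first
  fits0 <- fit_all(simulate_kinetics(sp, kinetic_schedule()))
  tab0 <- compare_models(fits0)
  expect_identical(tab0$model[1], "film")
  expect_equal(tab0$r_squared[1], 1, tolerance = 1e-9)
  # duplicated fits keep input order
  dup <- compare_models(list(fits0[[2]], fits0[[2]]))
  expect_identical(dup$model, c("unsteady", "unsteady"))
})

test_that("kinetic CSV interchange round-trips a series", {
  sp <- pfsp_kinetic_spec("film", "UAE", "TPC")
  ser <- simulate_kinetics(sp, kinetic_schedule(), compound = "TPC")
  path <- withr::local_tempfile(fileext = ".csv")
  write_kinetic_csv(ser, path)
  back <- read_kinetic_csv(path)
  expect_equal(back$values, ser$values, tolerance = 1e-12)
  expect_identical(back$compound, "TPC")
  expect_identical(back$quantity, "c_mg_L")
})
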