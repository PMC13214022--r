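test_that("cumulative yield is the product of per-cycle efficiencies", {
  m <- efficiency_model(0.648^(1 / 3), 5)
  expect_equal(cumulative_yield(m), 0.648^(5 / 3), tolerance = 1e-12)
  expect_equal(cumulative_yield(m), 0.485, tolerance = 1e-3)
  expect_equal(cumulative_yield(efficiency_model(1, 7)), 1)
  bead <- efficiency_model(c(0.814, rep(0.948, 6)))
  expect_equal(cumulative_yield(bead), 0.591, tolerance = 5e-4)
})

test_that("digit-set probabilities match the 2^N Bernoulli-pattern oracle", {
  set.seed(99)
  for (N in c(1L, 3L, 4L, 7L, 10L)) {
    p <- runif(N, 0.3, 0.99)
    dsp <- digit_set_probabilities(efficiency_model(p))
    oracle <- oracle_digit_set_probs(p)
    expect_setequal(names(dsp$reachable), names(oracle))
    expect_equal(dsp$reachable[names(oracle)], oracle[names(oracle)],
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(sum(dsp$reachable), 1, tolerance = 1e-12)
    full <- paste(seq_len(N), collapse = ",")
    expect_equal(unname(dsp$reachable[[full]]),
                 cumulative_yield(efficiency_model(p)), tolerance = 1e-12)
    expect_equal(sum(dsp$observable), 1, tolerance = 1e-12)
  }
})

test_that("uniform efficiency makes the two 2-digit partials equiprobable", {
  p <- 0.85
  dsp <- digit_set_probabilities(efficiency_model(p, 4))$reachable
  expect_equal(unname(dsp[["3,4"]]), p^2 * (1 - p), tolerance = 1e-12)
  expect_equal(unname(dsp[["1,4"]]), p^2 * (1 - p), tolerance = 1e-12)
  d1 <- digit_set_probabilities(efficiency_model(0.7, 1))$reachable
  expect_equal(unname(d1[["1"]]), 0.7)
  expect_equal(unname(d1[[1]]) + unname(d1[[2]]), 1)
})

test_that("forecast table extrapolates yield and capacity over digit counts", {
  p <- 0.648^(1 / 3)
  ft <- forecast_table(p, c(5, 10), base = 2)
  expect_equal(ft$yield[1], 0.648^(5 / 3), tolerance = 1e-12)  # 0.4853
  expect_equal(ft$yield[2], 0.648^(10 / 3), tolerance = 1e-12) # 0.2355
  expect_equal(ft$yield[2], ft$yield[1]^2, tolerance = 1e-12)
  ft4 <- forecast_table(0.9, 10, base = 4)
  expect_equal(ft4$capacity, 1048576)
  # monotonicity: yield strictly decreasing in N for p < 1
  ft_all <- forecast_table(0.9, 1:12)
  expect_true(all(diff(ft_all$yield) < 0))
  # yield strictly increasing in each p_k
  base_p <- rep(0.8, 5)
  y0 <- cumulative_yield(efficiency_model(base_p))
  for (k in 1:5) {
    p2 <- base_p; p2[k] <- 0.85
    expect_gt(cumulative_yield(efficiency_model(p2)), y0)
  }
})

test_that("scalar maximum likelihood recovers the generating efficiency", {
  sp <- simulate_spectrum(efficiency_model(0.9, 4), 1e5, seed = 1)
  fit <- fit_per_cycle(sp, digits = 4, constraint = "scalar")
  expect_lt(abs(coef(fit)[["p"]] - 0.9), 0.01)
  expect_false(fit$boundary)
  expect_true(is.finite(fit$se[["p"]]) && fit$se[["p"]] < 0.01)
  expect_s3_class(logLik(fit), "logLik")
  # predicted spectrum sums to 1 over observable categories
  expect_equal(sum(predict(fit, "spectrum")), 1, tolerance = 1e-12)
})

test_that("shared-bulk fits recover a depressed first cycle", {
  truep <- c(0.6, 0.95, 0.95, 0.95)
  sp <- simulate_spectrum(efficiency_model(truep), 1e5, seed = 2)
  fit <- fit_per_cycle(sp, digits = 4, constraint = "shared-bulk")
  expect_lt(abs(coef(fit)[["p1"]] - 0.6), 0.03)
  expect_lt(abs(coef(fit)[["p_bulk"]] - 0.95), 0.02)
  s <- summary(fit)
  expect_s3_class(s, "summary.bali_fit")
  expect_equal(nrow(s$spectrum), 3L)
})

test_that("boundary, identifiability and input validation are enforced", {
  # 100% complete spectrum: estimate at the upper boundary, flagged
  fit <- fit_per_cycle(c("1,2,3,4" = 5000), digits = 4, constraint = "scalar")
  expect_true(fit$boundary)
  expect_gt(coef(fit)[["p"]], 0.99)
  expect_true(is.na(fit$se[["p"]]))
  # free fit for N = 4: 4 parameters, 3 observable categories
  expect_error(fit_per_cycle(c("1,2,3,4" = 10, "1,4" = 1, "3,4" = 1),
                             digits = 4, constraint = "free"),
               "observable categories")
  # unobservable keys rejected
  expect_error(fit_per_cycle(c("1,2" = 5), digits = 4), "unobservable")
})

test_that("fit methods are coherent: vcov, residuals, simulate, predict", {
  sp <- simulate_spectrum(efficiency_model(0.85, 4), 5e4, seed = 3)
  fit <- fit_per_cycle(sp, digits = 4, constraint = "scalar")
  expect_equal(sqrt(diag(vcov(fit))), fit$se, ignore_attr = TRUE)
  expect_length(residuals(fit), 3L)
  expect_lt(max(abs(residuals(fit))), 4)  # well-specified model
  sims <- simulate(fit, nsim = 2, seed = 7, molecules = 1000)
  expect_length(sims, 2L)
  expect_true(all(vapply(sims, sum, numeric(1)) <= 1000))
  y <- predict(fit, "yield", digit_range = c(4, 8))
  expect_equal(unname(y[2]), unname(y[1])^2, tolerance = 1e-12)
})

test_that("parameter recovery holds across seeds and efficiencies", {
  # smaller-scale sweep; the acceptance suite runs the full 20-seed protocol
  ok <- 0L
  cases <- expand.grid(seed = 1:4, p = c(0.7, 0.8, 0.9))
  for (i in seq_len(nrow(cases))) {
    sp <- simulate_spectrum(efficiency_model(cases$p[i], 4), 1e5,
                            seed = cases$seed[i])
    fit <- fit_per_cycle(sp, digits = 4, constraint = "scalar")
    ok <- ok + (abs(coef(fit)[["p"]] - cases$p[i]) <= 0.01)
  }
  expect_gte(ok, nrow(cases) - 1L)
})
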