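test_that("magnitude IR signal model has the expected landmarks", {
  # asymptote, inversion point, and the null crossing at TI = T1* ln(B/A)
  expect_equal(ir_signal(1e9, a = 250, b = 500, t1_star_msec = 400), 250)
  expect_equal(ir_signal(0, a = 250, b = 500, t1_star_msec = 400), 250)
  expect_equal(ir_signal(400 * log(2), a = 250, b = 500, t1_star_msec = 400), 0,
               tolerance = 1e-12)
  expect_true(all(ir_signal(seq(0, 5000, 50), 250, 500, 400) >= 0))
  expect_error(ir_signal(100, 250, 500, t1_star_msec = 0), "positive")
  expect_error(ir_signal(100, 250, 500, t1_star_msec = -5), "positive")
})

test_that("noiseless IR fits recover the generating parameters", {
  schemes <- list(molli_scheme("classic"), molli_scheme("hybrid_pre"),
                  molli_scheme("hybrid_post"))
  for (sch in schemes) {
    for (t1_star in c(250, 400, 950, 1400)) {
      for (rr in c(600, 882, 1200)) {
        df <- data.frame(
          ti_msec = sort(ti_schedule(sch, rr)$ti_eff_msec),
          signal = ir_signal(sort(ti_schedule(sch, rr)$ti_eff_msec), 250, 500, t1_star)
        )
        fit <- fit_ir(df)
        expect_true(fit$valid)
        expect_equal(fit$a, 250, tolerance = 1e-6)
        expect_equal(fit$b, 500, tolerance = 1e-6)
        expect_equal(fit$t1_star_msec, t1_star, tolerance = 1e-6)
        # Look-Locker identity holds to machine precision
        expect_identical(fit$t1_msec, fit$t1_star_msec * (fit$b / fit$a - 1))
        # ideal inversion (B = 2A): corrected T1 equals apparent T1*
        expect_equal(fit$t1_msec, fit$t1_star_msec, tolerance = 1e-12)
      }
    }
  }
  # non-ideal inversion: the correction rescales T1* by (B/A - 1)
  ti <- sort(ti_schedule(molli_scheme("classic"), 882)$ti_eff_msec)
  fit <- fit_ir(data.frame(ti_msec = ti, signal = ir_signal(ti, 250, 450, 500)))
  expect_equal(fit$t1_msec, 500 * (450 / 250 - 1), tolerance = 1e-6)
})

test_that("polarity-restored fit matches the exhaustive grid-search oracle", {
  sch <- molli_scheme("hybrid_post")
  ti <- sort(ti_schedule(sch, 882)$ti_eff_msec)
  mu <- 250 - 500 * exp(-ti / 300)
  set.seed(20110304)
  n_rep <- 200
  t1_impl <- numeric(n_rep)
  t1_oracle <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    y <- abs(mu + rnorm(length(ti), 0, 10))
    fit <- fit_ir(data.frame(ti_msec = ti, signal = y))
    orc <- oracle_fit_ir(ti, y)
    t1_impl[r] <- fit$t1_msec
    t1_oracle[r] <- orc$t1
    # the continuous optimum can never be worse than the 1-msec grid optimum
    expect_lte(fit$rss, orc$rss + 1e-6)
  }
  sem <- sd(t1_oracle) / sqrt(n_rep)
  expect_lt(abs(mean(t1_impl) - mean(t1_oracle)), 2 * sem)
})

test_that("degenerate IR inputs error or are flagged invalid", {
  ti <- c(90, 500, 1000, 2000)
  expect_error(fit_ir(data.frame(ti_msec = ti[1:3], signal = c(1, 2, 3))),
               "insufficient")
  expect_error(fit_ir(data.frame(ti_msec = c(90, 90, 500, 1000),
                                 signal = c(1, 1, 2, 3))), "distinct")
  expect_error(fit_ir(data.frame(ti_msec = ti, signal = c(-1, 2, 3, 4))),
               "non-negative")
  # rising-only signal from b < a: Look-Locker correction undefined
  y <- abs(250 - 150 * exp(-ti / 400))
  fit <- fit_ir(data.frame(ti_msec = ti, signal = y))
  expect_false(fit$valid)
  expect_match(fit$reason, "b <= a")
})

test_that("T2 fits recover the decay constant", {
  te <- seq(10, 400, length.out = 10)
  fit <- fit_t2(data.frame(te_msec = te, signal = 200 * exp(-te / 50)))
  expect_equal(fit$t2_msec, 50, tolerance = 1e-6)
  expect_equal(fit$a, 200, tolerance = 1e-6)
  # exact three-point data has the closed-form T2 = 40
  te3 <- c(10, 20, 30)
  fit3 <- fit_t2(data.frame(te_msec = te3, signal = 100 * exp(-(te3 - 10) / 40)))
  expect_equal(fit3$t2_msec, 40, tolerance = 1e-8)
  # low noise over the informative decay range (signal well above the noise
  # floor everywhere, so the log transform does not reweight the errors):
  # nonlinear and log-linear estimates agree within 1%
  te_short <- seq(5, 50, by = 5)
  set.seed(7)
  for (r in 1:20) {
    y <- 200 * exp(-te_short / 50) + rnorm(length(te_short), 0, 0.5)
    nl <- fit_t2(data.frame(te_msec = te_short, signal = y))
    ll <- oracle_fit_t2_loglin(te_short, y)
    expect_equal(nl$t2_msec, ll$t2, tolerance = 0.01)
  }
  expect_error(fit_t2(data.frame(te_msec = c(10, 20), signal = c(1, 2))),
               "insufficient")
})

test_that("recovered fraction matches the exponential recovery law", {
  expect_equal(recovered_fraction(2500, 500), 1 - exp(-5))
  expect_gte(recovered_fraction(2500, 500), 0.99)
  expect_equal(recovered_fraction(500, 500), 1 - exp(-1))
  expect_lt(recovered_fraction(1e-9, 500), 1e-10)
  # strictly increasing in elapsed time, strictly decreasing in T1
  el <- seq(100, 5000, by = 100)
  expect_true(all(diff(recovered_fraction(el, 800)) > 0))
  t1 <- seq(200, 2000, by = 100)
  expect_true(all(diff(recovered_fraction(1000, t1)) < 0))
  expect_error(recovered_fraction(0, 500), "positive")
})
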