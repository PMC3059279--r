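test_that("delta R1 is the post-pre relaxation-rate difference", {
  expect_equal(delta_r1(1000, 500), 0.001)
  expect_equal(delta_r1(800, 800), 0)
  expect_equal(delta_r1(1534, 309), 1 / 309 - 1 / 1534)
  expect_equal(delta_r1(1534, 309), 0.0025844, tolerance = 1e-4)
  expect_error(delta_r1(0, 500), "positive")
  expect_error(delta_r1(1000, -1), "positive")
})

test_that("partition coefficient is the myocardium:blood delta R1 ratio", {
  expect_equal(partition_coefficient(0.001, 0.002), 0.5)
  expect_warning(lam <- partition_coefficient(0.002, 0.002), "physiologic")
  expect_equal(lam, 1)
  expect_error(partition_coefficient(0.001, 0), "positive")
  expect_error(partition_coefficient(0.001, -0.001), "positive")
})

test_that("Ve from lambda follows the density- and hematocrit-corrected formula", {
  expect_equal(ve_from_lambda(0.452, 0.477), 0.452 * 1.05 * (1 - 0.477) - 0.045)
  expect_equal(ve_from_lambda(0.452, 0.477), 0.2032, tolerance = 1e-4)
  lam0 <- 0.045 / (1.05 * 0.6)
  expect_warning(v0 <- ve_from_lambda(lam0, 0.4), "non-positive")
  expect_equal(v0, 0, tolerance = 1e-12)
  expect_warning(vp <- ve_from_lambda(0.452, 47.7), "percent")
  expect_equal(vp, ve_from_lambda(0.452, 0.477))
  expect_error(ve_from_lambda(0, 0.4), "positive")
})

test_that("lambda and Ve are exact inverses and vary monotonically", {
  expect_equal(lambda_from_ve(0.25, 0.40), (0.25 + 0.045) / (1.05 * 0.6))
  set.seed(31)
  for (r in 1:50) {
    lam <- runif(1, 0.25, 0.65)
    hct <- runif(1, 0.2, 0.6)
    ve <- suppressWarnings(ve_from_lambda(lam, hct))
    expect_equal(lambda_from_ve(ve, hct), lam, tolerance = 1e-12)
  }
  # Ve fixed: lambda strictly increasing in hematocrit
  hct <- seq(0.2, 0.6, by = 0.05)
  expect_true(all(diff(lambda_from_ve(0.25, hct)) > 0))
  # lambda fixed: Ve strictly decreasing in hct; hct fixed: increasing in lambda
  expect_true(all(diff(ve_from_lambda(0.45, hct)) < 0))
  lam <- seq(0.3, 0.6, by = 0.05)
  expect_true(all(diff(ve_from_lambda(lam, 0.4)) > 0))
  expect_error(lambda_from_ve(0.25, 1), "\\(0, 1\\)")
  expect_warning(l40 <- lambda_from_ve(0.25, 40), "percent")
  expect_equal(l40, lambda_from_ve(0.25, 0.40))
})

make_series <- function(blood, myo, times = seq_along(blood) * 5, protocol = "infusion") {
  scan_series("t", protocol, hematocrit = 0.4,
              pre_blood_t1_msec = 1500, pre_myo_t1_msec = 950,
              time_min = times, blood_t1_msec = blood, myo_t1_msec = myo)
}

test_that("steady-state detection accepts plateaus and rejects drifts", {
  const <- make_series(rep(380, 6), rep(560, 6))
  w <- steady_state_window(const)
  expect_equal(w$start_index, 1)
  expect_equal(w$end_index, 6)
  # blood T1 rising 10% per point can never satisfy the 5% criterion
  drift <- make_series(380 * 1.1^(0:5), rep(560, 6))
  expect_null(steady_state_window(drift))
  # synthetic infusion plateauing by 25 min with 1% noise: window opens early
  sc <- generate_scan(kinetics_config("infusion", noise_frac = 0.01, seed = 11))
  w2 <- steady_state_window(sc)
  expect_false(is.null(w2))
  expect_lte(w2$start_min, 30)
})

test_that("serial Ve is constant whenever lambda is constant", {
  # zero-noise bolus with true lambda 0.45, hct 0.40: every Ve = 0.2385
  sc <- generate_scan(kinetics_config("bolus", true_lambda = 0.45,
                                      hematocrit = 0.40, noise_frac = 0))
  res <- ve_series(sc)
  expect_equal(res$points$ve, rep(0.45 * 1.05 * 0.6 - 0.045, nrow(res$points)),
               tolerance = 1e-12)
  expect_equal(res$sd_ve, 0, tolerance = 1e-12)
  expect_equal(res$mean_ve, 0.2385, tolerance = 1e-12)
  # both tissues' T1 drift with clearance but the delta R1 ratio is fixed,
  # so Ve is invariant to the common contrast decay
  expect_lt(diff(range(res$points$lambda)), 1e-12)
  expect_gt(diff(range(sc$points$blood_t1_msec)), 10)
})

test_that("protocol measurement windows are honored", {
  # bolus: only points at or after 12 min are used
  sc <- scan_series("b", "bolus", 0.4, 1500, 950,
                    time_min = c(5, 10, 15, 20), blood_t1_msec = rep(400, 4),
                    myo_t1_msec = rep(600, 4))
  res <- ve_series(sc)
  expect_identical(res$points$used, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(res$n_used, 2)
  early <- scan_series("b", "bolus", 0.4, 1500, 950,
                       time_min = c(5, 10), blood_t1_msec = rep(400, 2),
                       myo_t1_msec = rep(600, 2))
  expect_error(ve_series(early), "bolus timepoints")
  # infusion without a steady-state window falls back to all points
  drifting <- make_series(380 * 1.1^(0:5), 560 * 1.1^(0:5))
  expect_warning(res2 <- ve_series(drifting), "steady-state")
  expect_true(all(res2$points$used))
  # infusion with a window restricts to its suffix
  sc3 <- generate_scan(kinetics_config("infusion", noise_frac = 0))
  res3 <- ve_series(sc3)
  expect_false(is.null(res3$window))
  expect_identical(res3$points$used,
                   seq_len(nrow(res3$points)) >= res3$window$start_index)
})

test_that("per-subject Ve recovery on a noisy synthetic cohort", {
  coh <- generate_cohort(6, 4, seed = 404, noise_frac = 0.01)
  man <- attr(coh, "manifest")
  ok <- 0
  for (i in seq_along(coh)) {
    res <- suppressWarnings(ve_series(coh[[i]]$bolus))
    truth <- ve_from_lambda(man$true_lambda[i], man$hct_bolus[i])
    if (abs(res$mean_ve - truth) <= 0.005) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("scan series round-trip through the long CSV format", {
  sc <- generate_scan(kinetics_config("bolus", noise_frac = 0.01, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_scan_series(sc, path)
  back <- read_scan_series(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$points, sc$points)
  expect_equal(back[[1]]$hematocrit, sc$hematocrit)
  expect_equal(back[[1]]$pre_blood_t1_msec, sc$pre_blood_t1_msec)
  # unpaired post-contrast rows are dropped with a warning
  long <- utils::read.csv(path)
  long <- long[-which(long$tissue == "myocardium" & long$time_min == 12)[1], ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(long, path2, row.names = FALSE)
  expect_warning(back2 <- read_scan_series(path2), "unpaired")
  expect_equal(nrow(back2[[1]]$points), nrow(sc$points) - 1)
})

test_that("scan series constructor enforces physiologic invariants", {
  expect_error(scan_series("x", "bolus", 0.05, 1500, 950, 15, 400, 600),
               "hematocrit")
  expect_error(scan_series("x", "bolus", 0.4, 1500, 950, 15, 1600, 600),
               "below pre-contrast")
  expect_error(scan_series("x", "bolus", 0.4, 1500, 950, c(15, 10),
                           c(400, 410), c(600, 610)), "sorted")
  expect_warning(s <- scan_series("x", "bolus", 40, 1500, 950, 15, 400, 600),
                 "percent")
  expect_equal(s$hematocrit, 0.40)
})

test_that("printed subject table reproduces per-subject Ve", {
  tab <- subject_table()
  expect_equal(nrow(tab), 10)
  expect_equal(sum(tab$age < 35), 6)
  expect_equal(sum(tab$age >= 66), 4)
  sv <- subject_ve("infusion")
  expect_equal(sv$ve[1], 0.452 * 1.05 * (1 - 0.477) - 0.045)
  expect_equal(round(100 * sv$ve[1], 1), 20.3)
})
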