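#' Configuration for the sampling-scheme precision simulation
#'
#' Defaults reproduce the study conditions of the scheme comparison: ideal
#' inversion (B = 2A) with maximum signal amplitude 250 (arbitrary units),
#' additive Gaussian noise of SD 10, 128 trials per parameter cell, heart
#' rates 50-100 bpm in 5 bpm steps, and a true-T1 grid in 100 msec steps —
#' 200-500 msec ("short", post-contrast-like, classic vs hybrid 4+2+1) or
#' 800-1500 msec ("long", pre-contrast-like, classic vs hybrid 5+1).
#'
#' @param t1_range `"short"` (200-500 msec) or `"long"` (800-1500 msec);
#'   ignored when `t1_grid` is given.
#' @param schemes list of [molli_scheme()] objects; defaults to the pair the
#'   range is meant to compare.
#' @param amplitude true asymptote A (arbitrary units).
#' @param noise_sd additive Gaussian noise SD (same units as `amplitude`).
#' @param trials replicates per (scheme, heart rate, T1) cell, `>= 1`.
#' @param hr_grid heart rates in bpm.
#' @param t1_grid true T1 values in msec; overrides `t1_range`.
#' @param seed RNG seed used by [run_mc_simulation()].
#' @return list of class `mc_config`.
#' @export
mc_config <- function(t1_range = c("short", "long"), schemes = NULL,
                      amplitude = 250, noise_sd = 10, trials = 128,
                      hr_grid = seq(50, 100, by = 5), t1_grid = NULL,
                      seed = 20110304) {
  t1_range <- match.arg(t1_range)
  if (is.null(t1_grid)) {
    t1_grid <- if (t1_range == "short") seq(200, 500, by = 100) else seq(800, 1500, by = 100)
  }
  if (is.null(schemes)) {
    schemes <- if (t1_range == "short") {
      list(molli_scheme("classic"), molli_scheme("hybrid_post"))
    } else {
      list(molli_scheme("classic"), molli_scheme("hybrid_pre"))
    }
  }
  if (!all(vapply(schemes, inherits, logical(1), "molli_scheme")))
    stop("`schemes` must be a list of molli_scheme objects")
  if (trials < 1) stop("`trials` must be >= 1")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (length(hr_grid) < 1 || length(t1_grid) < 1) stop("grids must be non-empty")
  structure(
    list(t1_range = t1_range, schemes = schemes, amplitude = amplitude,
         noise_sd = noise_sd, trials = as.integer(trials),
         hr_grid = hr_grid, t1_grid = t1_grid, seed = seed),
    class = "mc_config"
  )
}

#' Simulate one noisy MOLLI acquisition and fit it
#'
#' Generates the signed ideal inversion-recovery signal
#' `A (1 - 2 exp(-TI / T1))` at the scheme's effective inversion times (full
#' recovery before each inversion group; readout effects excluded), adds
#' independent Gaussian noise per sample, takes the magnitude, and fits with
#' [fit_ir()]. Uses the current RNG stream.
#'
#' @param true_t1 true T1 in msec, `> 0`.
#' @param scheme a [molli_scheme()].
#' @param rr_msec cardiac period in msec.
#' @param amplitude true asymptote A.
#' @param noise_sd additive noise SD.
#' @return an `ir_fit` (see [fit_ir()]); check `$valid`.
#' @export
simulate_trial <- function(true_t1, scheme, rr_msec, amplitude = 250, noise_sd = 10) {
  if (true_t1 <= 0) stop("`true_t1` must be positive")
  ti <- sort(ti_schedule(scheme, rr_msec)$ti_eff_msec)
  y <- abs(amplitude * (1 - 2 * exp(-ti / true_t1)) + stats::rnorm(length(ti), 0, noise_sd))
  fit_ir(data.frame(ti_msec = ti, signal = y))
}

# All trials of one (scheme, rr, t1) cell, sharing the grid precomputation.
.mc_cell <- function(ti, pre, true_t1, amplitude, noise_sd, trials) {
  mu <- amplitude * (1 - 2 * exp(-ti / true_t1))
  noise <- matrix(stats::rnorm(length(ti) * trials, 0, noise_sd), nrow = length(ti))
  t1_fit <- numeric(trials)
  valid <- logical(trials)
  for (j in seq_len(trials)) {
    fit <- tryCatch(.fit_ir_core(abs(mu + noise[, j]), pre), error = function(e) NULL)
    if (is.null(fit)) {
      t1_fit[j] <- NA_real_
      valid[j] <- FALSE
    } else {
      t1_fit[j] <- fit$t1_msec
      valid[j] <- fit$valid
    }
  }
  list(t1_fit = t1_fit, valid = valid)
}

#' Run the Monte Carlo scheme-precision simulation
#'
#' For every (scheme, heart rate, true T1) cell, simulates `trials` noisy
#' acquisitions (see [simulate_trial()]), fits each, and accumulates the
#' fitted-T1 error. Invalid fits are excluded from RMSE and counted.
#' Bit-reproducible for a fixed `config$seed`.
#'
#' @param config an [mc_config()].
#' @return object of class `mc_result`: list with `records` (one row per
#'   trial: `scheme, hr_bpm, t1_true_msec, trial, t1_fit_msec, valid`),
#'   `rmse_by_cell` (per scheme x heart rate x T1), `rmse_pooled` (per
#'   scheme, pooled over all trials, heart rates and T1 values in the grid),
#'   `n_invalid`, and the `config`.
#' @examples
#' \donttest{
#' res <- run_mc_simulation(mc_config("short", trials = 8))
#' res$rmse_pooled
#' }
#' @export
run_mc_simulation <- function(config) {
  stopifnot(inherits(config, "mc_config"))
  set.seed(config$seed)
  cells <- expand.grid(scheme_i = seq_along(config$schemes),
                       hr_bpm = config$hr_grid,
                       t1_true_msec = config$t1_grid,
                       KEEP.OUT.ATTRS = FALSE)
  scheme_names <- vapply(config$schemes, `[[`, character(1), "name")
  # one TI-grid precomputation per (scheme, heart rate)
  pre_cache <- list()
  recs <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    si <- cells$scheme_i[i]
    hr <- cells$hr_bpm[i]
    key <- paste(si, hr)
    if (is.null(pre_cache[[key]])) {
      ti <- sort(ti_schedule(config$schemes[[si]], rr_from_hr(hr))$ti_eff_msec)
      pre_cache[[key]] <- .ir_precompute(ti)
    }
    pre <- pre_cache[[key]]
    cell <- .mc_cell(pre$ti, pre, cells$t1_true_msec[i], config$amplitude,
                     config$noise_sd, config$trials)
    recs[[i]] <- data.frame(
      scheme = scheme_names[si], hr_bpm = hr, t1_true_msec = cells$t1_true_msec[i],
      trial = seq_len(config$trials), t1_fit_msec = cell$t1_fit, valid = cell$valid
    )
  }
  records <- do.call(rbind, recs)
  ok <- records[records$valid, , drop = FALSE]
  err2 <- (ok$t1_fit_msec - ok$t1_true_msec)^2
  rmse_by_cell <- stats::aggregate(
    err2, by = list(scheme = ok$scheme, hr_bpm = ok$hr_bpm, t1_true_msec = ok$t1_true_msec),
    FUN = function(z) sqrt(mean(z))
  )
  names(rmse_by_cell)[4] <- "rmse_msec"
  rmse_pooled <- stats::aggregate(err2, by = list(scheme = ok$scheme),
                                  FUN = function(z) sqrt(mean(z)))
  names(rmse_pooled)[2] <- "rmse_msec"
  structure(
    list(records = records, rmse_by_cell = rmse_by_cell, rmse_pooled = rmse_pooled,
         n_invalid = sum(!records$valid), config = config),
    class = "mc_result"
  )
}

#' @export
print.mc_result <- function(x, ...) {
  cat("Monte Carlo T1-precision simulation (", x$config$trials, " trials/cell, ",
      length(x$config$hr_grid), " heart rates x ", length(x$config$t1_grid),
      " T1 values)\n", sep = "")
  cat("Pooled RMSE (msec):\n")
  print(x$rmse_pooled, row.names = FALSE)
  if (x$n_invalid > 0) cat("Invalid fits excluded:", x$n_invalid, "\n")
  invisible(x)
}

#' Paired comparison of two schemes' per-cell precision
#'
#' Paired t-test across (heart rate, T1) cells on the per-cell RMSE of two
#' schemes from one simulation run.
#'
#' @param result an `mc_result` containing exactly two schemes (or name two
#'   of them via `schemes`).
#' @param schemes optional character vector of two scheme names.
#' @return list with `t`, `df`, `p`, `mean_diff` (scheme1 - scheme2),
#'   `n_cells`, and the scheme names.
#' @export
compare_schemes <- function(result, schemes = NULL) {
  stopifnot(inherits(result, "mc_result"))
  by_cell <- result$rmse_by_cell
  if (is.null(schemes)) schemes <- unique(by_cell$scheme)
  if (length(schemes) != 2) stop("need exactly two schemes to compare")
  a <- by_cell[by_cell$scheme == schemes[1], ]
  b <- by_cell[by_cell$scheme == schemes[2], ]
  m <- merge(a, b, by = c("hr_bpm", "t1_true_msec"), suffixes = c("_1", "_2"))
  if (nrow(m) < 2) stop("fewer than 2 paired cells")
  tt <- paired_t(m$rmse_msec_1, m$rmse_msec_2)
  list(scheme_1 = schemes[1], scheme_2 = schemes[2], t = tt$t, df = tt$df,
       p = tt$p, mean_diff = mean(m$rmse_msec_1 - m$rmse_msec_2), n_cells = nrow(m))
}
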