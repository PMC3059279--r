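#' Physical constants of the extracellular-volume computation
#'
#' `Ve = lambda * rho * (1 - hematocrit) - vp`, with `rho` the specific
#' density of myocardial tissue and `vp` the myocardial plasma volume
#' fraction (assumed constant, reflecting capillary density).
#'
#' @param rho myocardial specific density (default 1.05).
#' @param vp myocardial plasma volume fraction (default 0.045).
#' @return list of class `ecv_constants`.
#' @export
ecv_constants <- function(rho = 1.05, vp = 0.045) {
  if (rho <= 0 || vp < 0 || vp >= 1) stop("invalid constants")
  structure(list(rho = rho, vp = vp), class = "ecv_constants")
}

#' Change in longitudinal relaxation rate after contrast
#'
#' `delta R1 = 1/T1_post - 1/T1_pre` (1/msec), proportional to the local
#' gadolinium concentration; positive when contrast shortens T1.
#'
#' @param t1_pre_msec pre-contrast T1 in msec, `> 0`; vectorized.
#' @param t1_post_msec post-contrast T1 in msec, `> 0`; vectorized.
#' @return relaxation-rate change in 1/msec.
#' @examples
#' delta_r1(1000, 500) # 0.001
#' @export
delta_r1 <- function(t1_pre_msec, t1_post_msec) {
  if (any(t1_pre_msec <= 0) || any(t1_post_msec <= 0)) stop("T1 values must be positive")
  1 / t1_post_msec - 1 / t1_pre_msec
}

#' Gadolinium partition coefficient
#'
#' `lambda = delta R1_myocardium / delta R1_blood`, the myocardium:blood
#' contrast partition coefficient at plasma-interstitium equilibrium.
#' Values outside the typical physiologic range 0.3-0.6 trigger a warning.
#'
#' @param dr1_myo myocardial relaxation-rate change (1/msec); vectorized.
#' @param dr1_blood blood-pool relaxation-rate change (1/msec), `> 0`.
#' @return dimensionless lambda.
#' @export
partition_coefficient <- function(dr1_myo, dr1_blood) {
  if (any(dr1_blood <= 0)) stop("`dr1_blood` must be positive (no contrast effect in blood)")
  lam <- dr1_myo / dr1_blood
  if (any(lam < 0.3 | lam > 0.6)) {
    warning("partition coefficient outside the typical physiologic range 0.3-0.6")
  }
  lam
}

.check_hct <- function(hematocrit) {
  if (any(hematocrit > 1)) {
    warning("hematocrit > 1 interpreted as percent and divided by 100")
    hematocrit <- ifelse(hematocrit > 1, hematocrit / 100, hematocrit)
  }
  if (any(hematocrit <= 0 | hematocrit >= 1)) stop("hematocrit must be in (0, 1)")
  hematocrit
}

#' Extracellular volume fraction from the partition coefficient
#'
#' `Ve = lambda * rho * (1 - hematocrit) - vp`. A non-positive result is
#' returned but flagged with a warning (physically implausible).
#'
#' @param lambda_ partition coefficient, `> 0`; vectorized.
#' @param hematocrit blood hematocrit as a fraction in (0, 1); values > 1
#'   are interpreted as percent with a warning.
#' @param constants an [ecv_constants()].
#' @return Ve as a fraction.
#' @examples
#' ve_from_lambda(0.452, 0.477) # about 0.203
#' @export
ve_from_lambda <- function(lambda_, hematocrit, constants = ecv_constants()) {
  if (any(lambda_ <= 0)) stop("`lambda_` must be positive")
  hematocrit <- .check_hct(hematocrit)
  ve <- lambda_ * constants$rho * (1 - hematocrit) - constants$vp
  if (any(ve <= 0)) warning("non-positive Ve computed; check inputs")
  ve
}

#' Partition coefficient implied by a Ve and hematocrit
#'
#' Exact inverse of [ve_from_lambda()]:
#' `lambda = (Ve + vp) / (rho * (1 - hematocrit))`. The hematocrit
#' dependence is why Ve, not lambda (or T1), is the comparable fibrosis
#' measure across subjects.
#'
#' @param ve extracellular volume fraction.
#' @param hematocrit fraction in (0, 1).
#' @param constants an [ecv_constants()].
#' @return lambda.
#' @export
lambda_from_ve <- function(ve, hematocrit, constants = ecv_constants()) {
  hematocrit <- .check_hct(hematocrit)
  (ve + constants$vp) / (constants$rho * (1 - hematocrit))
}

#' Construct a subject-scan series of serial T1 measurements
#'
#' One contrast scan of one subject: pre-contrast blood and myocardial T1,
#' a hematocrit, and paired serial post-contrast T1 measurements.
#'
#' @param subject_id label.
#' @param protocol `"bolus"` or `"infusion"`.
#' @param hematocrit fraction in (0.1, 0.65); percent input is converted
#'   with a warning.
#' @param pre_blood_t1_msec,pre_myo_t1_msec pre-contrast T1 values (msec).
#' @param time_min post-contrast acquisition times, minutes since contrast
#'   start, sorted non-decreasing.
#' @param blood_t1_msec,myo_t1_msec post-contrast T1 values (msec), paired
#'   by acquisition with `time_min`.
#' @return object of class `scan_series`.
#' @export
scan_series <- function(subject_id, protocol = c("bolus", "infusion"), hematocrit,
                        pre_blood_t1_msec, pre_myo_t1_msec,
                        time_min, blood_t1_msec, myo_t1_msec) {
  protocol <- match.arg(protocol)
  hematocrit <- .check_hct(hematocrit)
  if (hematocrit <= 0.1 || hematocrit >= 0.65)
    stop("hematocrit outside the plausible range (0.1, 0.65)")
  n <- length(time_min)
  if (n < 1 || length(blood_t1_msec) != n || length(myo_t1_msec) != n)
    stop("need >= 1 post-contrast timepoint with paired blood and myocardial T1")
  if (is.unsorted(time_min)) stop("`time_min` must be sorted")
  if (any(time_min < 0)) stop("`time_min` must be non-negative")
  t1s <- c(pre_blood_t1_msec, pre_myo_t1_msec, blood_t1_msec, myo_t1_msec)
  if (any(t1s <= 1 | t1s >= 10000)) stop("T1 values must lie in (1, 10000) msec")
  if (any(blood_t1_msec >= pre_blood_t1_msec) || any(myo_t1_msec >= pre_myo_t1_msec))
    stop("post-contrast T1 must be below pre-contrast T1 for both tissues")
  structure(
    list(subject_id = subject_id, protocol = protocol, hematocrit = hematocrit,
         pre_blood_t1_msec = pre_blood_t1_msec, pre_myo_t1_msec = pre_myo_t1_msec,
         points = data.frame(time_min = time_min, blood_t1_msec = blood_t1_msec,
                             myo_t1_msec = myo_t1_msec)),
    class = "scan_series"
  )
}

#' @export
print.scan_series <- function(x, ...) {
  cat("Scan series: subject ", x$subject_id, ", ", x$protocol,
      ", hct ", format(x$hematocrit), "\n", sep = "")
  cat(sprintf("  pre-contrast T1 blood/myo: %.0f/%.0f msec; %d post-contrast timepoints (%.0f-%.0f min)\n",
              x$pre_blood_t1_msec, x$pre_myo_t1_msec, nrow(x$points),
              min(x$points$time_min), max(x$points$time_min)))
  invisible(x)
}

#' Detect the steady-state window of an infusion series
#'
#' Steady-state equilibrium is declared over the longest contiguous suffix
#' of post-contrast timepoints within which the serial T1 of *both* blood
#' and myocardium varies by less than `tolerance` (variation measured as
#' range/mean within the window).
#'
#' @param series a [scan_series()] with at least 2 post-contrast timepoints.
#' @param tolerance allowed fractional T1 variation (default 0.05).
#' @return list with `start_index`, `end_index`, `start_min`, `end_min`, or
#'   `NULL` if no window of >= 2 points qualifies.
#' @export
steady_state_window <- function(series, tolerance = 0.05) {
  stopifnot(inherits(series, "scan_series"))
  p <- series$points
  n <- nrow(p)
  if (n < 2) stop("need at least 2 post-contrast timepoints")
  varies_ok <- function(x) (max(x) - min(x)) / mean(x) < tolerance
  for (s in seq_len(n - 1)) {
    idx <- s:n
    if (varies_ok(p$blood_t1_msec[idx]) && varies_ok(p$myo_t1_msec[idx])) {
      return(list(start_index = s, end_index = n,
                  start_min = p$time_min[s], end_min = p$time_min[n]))
    }
  }
  NULL
}

#' Serial partition coefficient and Ve for one scan
#'
#' Computes, per paired post-contrast timepoint, the blood and myocardial
#' delta R1 against the scan's pre-contrast T1, the partition coefficient
#' lambda, and Ve. Summaries (mean, SD, SEM) are taken over the protocol's
#' measurement points: the detected steady-state window for an infusion
#' scan, and all points at or after `bolus_delay_min` (default 12 minutes,
#' allowing full dispersion and tissue equilibration of the bolus) for a
#' bolus scan. An infusion scan in which no steady-state window qualifies
#' falls back to all post-contrast timepoints with a warning.
#'
#' Because lambda is a ratio of delta R1 values, Ve is invariant to the slow
#' common decay of contrast in both tissues, which is what makes serial
#' bolus measurements usable at all.
#'
#' @param series a [scan_series()].
#' @param constants an [ecv_constants()].
#' @param tolerance steady-state T1 variation tolerance (infusion only).
#' @param bolus_delay_min earliest usable bolus timepoint (minutes).
#' @return object of class `ecv_result`: list with `points` (data frame
#'   `time_min, dr1_blood, dr1_myo, lambda, ve, used`), `window` (infusion
#'   steady-state window or `NULL`), `mean_ve`, `sd_ve`, `sem_ve`,
#'   `mean_lambda`, `sd_lambda`, `sem_lambda`, `n_used`, plus subject
#'   metadata.
#' @export
ve_series <- function(series, constants = ecv_constants(), tolerance = 0.05,
                      bolus_delay_min = 12) {
  stopifnot(inherits(series, "scan_series"))
  p <- series$points
  dr1_b <- delta_r1(series$pre_blood_t1_msec, p$blood_t1_msec)
  dr1_m <- delta_r1(series$pre_myo_t1_msec, p$myo_t1_msec)
  lam <- suppressWarnings(partition_coefficient(dr1_m, dr1_b))
  ve <- suppressWarnings(ve_from_lambda(lam, series$hematocrit, constants))
  window <- NULL
  if (series$protocol == "infusion") {
    if (nrow(p) >= 2) window <- steady_state_window(series, tolerance)
    if (is.null(window)) {
      warning("no steady-state window detected; using all post-contrast timepoints")
      used <- rep(TRUE, nrow(p))
    } else {
      used <- seq_len(nrow(p)) >= window$start_index
    }
  } else {
    used <- p$time_min >= bolus_delay_min
    if (!any(used)) stop("no bolus timepoints at or after ", bolus_delay_min, " min")
  }
  vu <- ve[used]
  lu <- lam[used]
  n <- length(vu)
  structure(
    list(points = data.frame(time_min = p$time_min, dr1_blood = dr1_b,
                             dr1_myo = dr1_m, lambda = lam, ve = ve, used = used),
         window = window, n_used = n,
         mean_ve = mean(vu), sd_ve = stats::sd(vu), sem_ve = stats::sd(vu) / sqrt(n),
         mean_lambda = mean(lu), sd_lambda = stats::sd(lu),
         sem_lambda = stats::sd(lu) / sqrt(n),
         subject_id = series$subject_id, protocol = series$protocol,
         hematocrit = series$hematocrit),
    class = "ecv_result"
  )
}

#' @export
print.ecv_result <- function(x, ...) {
  cat("ECV result: subject ", x$subject_id, ", ", x$protocol, "\n", sep = "")
  cat(sprintf("  mean Ve = %.1f%% (SD %.2f, SEM %.2f) over %d timepoints; mean lambda = %.3f\n",
              100 * x$mean_ve, 100 * x$sd_ve, 100 * x$sem_ve, x$n_used, x$mean_lambda))
  if (!is.null(x$window))
    cat(sprintf("  steady state from %.0f to %.0f min\n", x$window$start_min, x$window$end_min))
  invisible(x)
}

#' Read scan series from long-format CSV
#'
#' Expects columns `subject_id, protocol, hematocrit, time_min, tissue,
#' t1_msec` with `tissue` in `{blood, myocardium}`. Pre-contrast rows are
#' marked either by a `phase` column (`pre`/`post`) or by `time_min = -1`.
#' Blood and myocardium rows sharing an acquisition time are paired;
#' unpaired rows are dropped with a warning.
#'
#' @param path CSV file path.
#' @return list of [scan_series()], one per (subject_id, protocol).
#' @export
read_scan_series <- function(path) {
  df <- utils::read.csv(path)
  need <- c("subject_id", "protocol", "hematocrit", "time_min", "tissue", "t1_msec")
  if (!all(need %in% names(df))) stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  if (!("phase" %in% names(df))) df$phase <- ifelse(df$time_min < 0, "pre", "post")
  out <- list()
  for (key in unique(paste(df$subject_id, df$protocol, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    d <- df[df$subject_id == parts[1] & df$protocol == parts[2], ]
    pre <- d[d$phase == "pre", ]
    post <- d[d$phase == "post", ]
    pre_b <- pre$t1_msec[pre$tissue == "blood"][1]
    pre_m <- pre$t1_msec[pre$tissue == "myocardium"][1]
    if (is.na(pre_b) || is.na(pre_m)) stop("missing pre-contrast T1 for ", parts[1])
    b <- post[post$tissue == "blood", c("time_min", "t1_msec")]
    m <- post[post$tissue == "myocardium", c("time_min", "t1_msec")]
    paired <- merge(b, m, by = "time_min", suffixes = c("_blood", "_myo"))
    if (nrow(paired) < max(nrow(b), nrow(m)))
      warning("dropped unpaired post-contrast timepoints for ", parts[1])
    paired <- paired[order(paired$time_min), ]
    out[[length(out) + 1]] <- scan_series(
      subject_id = parts[1], protocol = parts[2], hematocrit = d$hematocrit[1],
      pre_blood_t1_msec = pre_b, pre_myo_t1_msec = pre_m,
      time_min = paired$time_min, blood_t1_msec = paired$t1_msec_blood,
      myo_t1_msec = paired$t1_msec_myo
    )
  }
  out
}

#' Write a scan series to long-format CSV
#'
#' Inverse of [read_scan_series()]; pre-contrast rows carry `phase = "pre"`
#' and `time_min = -1`.
#'
#' @param series a [scan_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scan_series <- function(series, path) {
  stopifnot(inherits(series, "scan_series"))
  p <- series$points
  long <- rbind(
    data.frame(subject_id = series$subject_id, protocol = series$protocol,
               hematocrit = series$hematocrit, time_min = -1,
               tissue = c("blood", "myocardium"),
               t1_msec = c(series$pre_blood_t1_msec, series$pre_myo_t1_msec),
               phase = "pre"),
    data.frame(subject_id = series$subject_id, protocol = series$protocol,
               hematocrit = series$hematocrit,
               time_min = rep(p$time_min, 2),
               tissue = rep(c("blood", "myocardium"), each = nrow(p)),
               t1_msec = c(p$blood_t1_msec, p$myo_t1_msec),
               phase = "post")
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
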