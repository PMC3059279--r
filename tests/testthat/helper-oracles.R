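# Independent brute-force references used to check the fitting routines.

# Exhaustive grid-search fit of the polarity-restored IR model: every null
# index k and every integer T1* on a 1-msec grid, with a centered linear
# regression for (A, B) at each candidate. Slow but assumption-free.
oracle_fit_ir <- function(ti, y_mag, t1s_max = 3000) {
  n <- length(ti)
  grid <- seq(1, t1s_max, by = 1)
  G <- length(grid)
  E <- exp(-outer(ti, 1 / grid))
  me <- colMeans(E)
  var_e <- colMeans(E * E) - me * me
  best <- list(rss = Inf)
  for (k in 0:n) {
    ys <- y_mag
    if (k > 0) ys[1:k] <- -ys[1:k]
    my <- mean(ys)
    cov_ey <- crossprod(E, ys)[, 1] / n - me * my
    cc <- cov_ey / var_e
    a <- my - cc * me
    resid <- matrix(ys, n, G) - matrix(a, n, G, byrow = TRUE) - E * matrix(cc, n, G, byrow = TRUE)
    rss <- colSums(resid * resid)
    g <- which.min(rss)
    if (rss[g] < best$rss) {
      best <- list(rss = rss[g], a = a[g], b = -cc[g], t1_star = grid[g], k = k)
    }
  }
  best$t1 <- best$t1_star * (best$b / best$a - 1)
  best
}

# Log-linear regression estimate of T2 from positive decay signals.
oracle_fit_t2_loglin <- function(te, y) {
  co <- stats::coef(stats::lm(log(y) ~ te))
  list(a = exp(co[[1]]), t2 = -1 / co[[2]])
}

# Magnitude IR signals for one scheme at one heart rate, ideal inversion.
molli_signals <- function(scheme, rr_msec, true_t1, amplitude = 250, noise = NULL) {
  ti <- sort(ti_schedule(scheme, rr_msec)$ti_eff_msec)
  mu <- amplitude * (1 - 2 * exp(-ti / true_t1))
  if (!is.null(noise)) mu <- mu + noise
  data.frame(ti_msec = ti, signal = abs(mu))
}
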