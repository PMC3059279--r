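#' Magnitude inversion-recovery signal model
#'
#' Signal intensity of a magnitude (modulus) inversion-recovery experiment,
#' `SI = |A - B * exp(-TI / T1*)|`. `A` is the asymptotic (fully recovered)
#' amplitude, `B` the inversion amplitude (`B = 2A` for an ideal inversion),
#' and `T1*` the apparent relaxation time of the repeatedly sampled recovery.
#'
#' @param ti_msec inversion time(s) in msec, `>= 0`; vectorized.
#' @param a asymptotic amplitude, arbitrary units, `> 0`.
#' @param b inversion amplitude, arbitrary units, `> 0`.
#' @param t1_star_msec apparent relaxation time in msec, `> 0`.
#' @return magnitude signal, same length as `ti_msec`; always `>= 0`.
#' @examples
#' ir_signal(c(0, 400 * log(2), 1e7), a = 250, b = 500, t1_star_msec = 400)
#' @export
ir_signal <- function(ti_msec, a, b, t1_star_msec) {
  if (!is.numeric(t1_star_msec) || length(t1_star_msec) != 1 || t1_star_msec <= 0)
    stop("`t1_star_msec` must be a single positive number")
  if (a <= 0 || b <= 0) stop("amplitudes `a` and `b` must be positive")
  if (any(ti_msec < 0)) stop("`ti_msec` must be non-negative")
  abs(a - b * exp(-ti_msec / t1_star_msec))
}

#' Fraction of longitudinal magnetization recovered after a delay
#'
#' `1 - exp(-elapsed / T1)`: the recovered fraction of an inverted or
#' saturated longitudinal magnetization after `elapsed_msec` of free
#' relaxation. Five multiples of T1 (e.g. 2500 msec at a post-contrast T1 of
#' 500 msec) recover more than 99%, which is the rationale for dropping the
#' fifth-beat sample in short post-contrast sampling schemes.
#'
#' @param elapsed_msec elapsed time in msec, `> 0`; vectorized.
#' @param t1_msec longitudinal relaxation time in msec, `> 0`; vectorized.
#' @return recovered fraction in `[0, 1)`.
#' @examples
#' recovered_fraction(2500, 500) # > 0.99
#' @export
recovered_fraction <- function(elapsed_msec, t1_msec) {
  if (any(elapsed_msec <= 0)) stop("`elapsed_msec` must be positive")
  if (any(t1_msec <= 0)) stop("`t1_msec` must be positive")
  1 - exp(-elapsed_msec / t1_msec)
}

# default log-spaced search grid for the apparent relaxation time T1*
.t1star_grid <- function(lo = 1, hi = 10000, n = 120) {
  exp(seq(log(lo), log(hi), length.out = n))
}

# Quantities reusable across fits sharing one TI vector (ti sorted ascending):
# basis matrix over the T1* grid and the normal-equation pieces that do not
# depend on the data.
.ir_precompute <- function(ti, grid = .t1star_grid()) {
  n <- length(ti)
  E <- exp(-outer(ti, 1 / grid))            # n x G
  se <- colSums(E)
  see <- colSums(E * E)
  d <- n * see - se * se
  bad <- d <= .Machine$double.eps * n * see # basis collinear with intercept
  list(ti = ti, grid = grid, E = E, se = se, see = see, d = d, bad = bad, n = n)
}

# Exact least squares of y ~ A - B e^(-ti/t1star) at fixed t1star
# (linear in A and in the coefficient C = -B).
.vp_profile <- function(ti, y, t1_star) {
  n <- length(y)
  e <- exp(-ti / t1_star)
  se <- sum(e); see <- sum(e * e); sy <- sum(y); sey <- sum(e * y)
  d <- n * see - se * se
  if (d <= .Machine$double.eps * n * see) return(list(a = NA_real_, b = NA_real_, rss = Inf))
  cc <- (n * sey - se * sy) / d
  a <- (sy - cc * se) / n
  r <- y - (a + cc * e)
  list(a = a, b = -cc, rss = sum(r * r))
}

# For one magnitude signal vector: per polarity hypothesis k (negate the k
# earliest-TI samples, k = 0..n), the best grid T1* and its profiled RSS.
.ir_grid_by_k <- function(pre, y) {
  n <- pre$n
  G <- length(pre$grid)
  syy <- sum(y * y)                          # invariant to sign flips
  g_best <- integer(n + 1)
  rss_best <- numeric(n + 1)
  yk <- y
  for (k in 0:n) {
    if (k > 0) yk[k] <- -yk[k]               # cumulative: samples 1..k negated
    sy <- sum(yk)
    sey <- crossprod(pre$E, yk)[, 1]         # length G
    cc <- (n * sey - pre$se * sy) / pre$d
    a <- (sy - cc * pre$se) / n
    rss <- syy - a * sy - cc * sey
    rss[pre$bad] <- Inf
    g <- which.min(rss)
    g_best[k + 1] <- g
    rss_best[k + 1] <- rss[g]
  }
  list(g = g_best, rss = rss_best)
}

# Brent refinement of T1* for one signed-signal hypothesis, then a
# Levenberg-Marquardt polish of all three parameters (analytic Jacobian).
.ir_refine <- function(ti, y_signed, g, grid) {
  G <- length(grid)
  lo <- grid[max(g - 1L, 1L)]
  hi <- grid[min(g + 1L, G)]
  t1s <- grid[g]
  if (hi > lo) {
    opt <- stats::optimize(function(t) .vp_profile(ti, y_signed, t)$rss,
                           lower = lo, upper = hi, tol = 1e-8 * hi)
    if (is.finite(opt$objective)) t1s <- opt$minimum
  }
  p <- .vp_profile(ti, y_signed, t1s)
  if (!is.finite(p$rss)) return(NULL)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(p$a, p$b, t1s),
      fn = function(q) q[1] - q[2] * exp(-ti / q[3]) - y_signed,
      jac = function(q) {
        e <- exp(-ti / q[3])
        cbind(1, -e, -q[2] * ti * e / q[3]^2)
      },
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12, ptol = 1e-12)
    ),
    error = function(e) NULL
  )
  out <- list(a = p$a, b = p$b, t1_star = t1s, rss = p$rss)
  if (!is.null(fit) && fit$par[3] > 0) {
    rss_lm <- sum(fit$fvec^2)
    if (is.finite(rss_lm) && rss_lm <= p$rss) {
      out <- list(a = fit$par[1], b = fit$par[2], t1_star = fit$par[3], rss = rss_lm)
    }
  }
  out
}

# Shared fitting core: polarity-hypothesis sweep over the precomputed grid,
# then continuous refinement of the leading hypotheses. `pre` must come from
# .ir_precompute on the same sorted ti.
.fit_ir_core <- function(y, pre) {
  byk <- .ir_grid_by_k(pre, y)
  if (!any(is.finite(byk$rss))) stop("fit failed: degenerate design (check TI spread)")
  # refine the three best null-index hypotheses: the T1* grid is coarse, so
  # the grid RSS ranking between neighbouring k can be wrong near the optimum
  cands <- order(byk$rss)[seq_len(min(3L, pre$n + 1L))]
  best <- NULL
  best_k <- NA_integer_
  for (idx in cands) {
    k <- idx - 1L
    ys <- y
    if (k > 0) ys[seq_len(k)] <- -ys[seq_len(k)]
    ref <- .ir_refine(pre$ti, ys, byk$g[idx], pre$grid)
    if (!is.null(ref) && (is.null(best) || ref$rss < best$rss)) {
      best <- ref
      best_k <- k
    }
  }
  if (is.null(best)) stop("fit failed: no polarity hypothesis converged")
  .new_ir_fit(best$a, best$b, best$t1_star, best$rss, pre$n, best_k)
}

.new_ir_fit <- function(a, b, t1_star, rss, n, null_index) {
  t1 <- t1_star * (b / a - 1)
  valid <- is.finite(a) && is.finite(b) && is.finite(t1_star) && is.finite(t1) &&
    a > 0 && b > a && t1 >= 1 && t1 <= 10000
  reason <- if (valid) NA_character_
  else if (!is.finite(t1) || !is.finite(a) || a <= 0) "non-finite or non-positive amplitude"
  else if (b <= a) "b <= a: Look-Locker correction undefined"
  else "corrected T1 outside [1, 10000] msec"
  structure(
    list(a = a, b = b, t1_star_msec = t1_star, t1_msec = t1, rss = rss,
         n_samples = n, null_index = null_index, valid = valid, reason = reason),
    class = "ir_fit"
  )
}

#' Fit the three-parameter inversion-recovery model with Look-Locker correction
#'
#' Least-squares fit of the magnitude IR model `|A - B exp(-TI/T1*)|` followed
#' by the Look-Locker correction `T1 = T1* (B/A - 1)`. Rather than fitting the
#' modulus directly, the fit restores signal polarity: for every candidate
#' null index k the k earliest-TI samples are negated and the signed model is
#' fit; the hypothesis with minimal residual sum of squares wins. Each signed
#' fit profiles out the linear parameters (A, B) exactly over a log-spaced
#' T1* grid (variable projection), refines T1* by Brent minimization, and
#' finishes with a Levenberg-Marquardt polish of all three parameters.
#'
#' Fits with `b <= a` or a corrected T1 outside `[1, 10000]` msec are flagged
#' `valid = FALSE` (the Look-Locker correction is meaningless for `b <= a`).
#'
#' @param samples data frame with columns `ti_msec` (distinct, `> 0`) and
#'   `signal` (magnitude, `>= 0`); at least 4 rows.
#' @return an object of class `ir_fit`: a list with elements `a`, `b`,
#'   `t1_star_msec`, `t1_msec`, `rss`, `n_samples`, `null_index` (number of
#'   earliest-TI samples negated), `valid`, `reason`.
#' @examples
#' sch <- ti_schedule(molli_scheme("hybrid_post"), rr_msec = 882)
#' ti <- sort(sch$ti_eff_msec)
#' fit_ir(data.frame(ti_msec = ti, signal = ir_signal(ti, 250, 500, 400)))
#' @export
fit_ir <- function(samples) {
  samples <- .check_samples(samples, "ti_msec", min_n = 4)
  if (any(samples$signal < 0)) stop("magnitude `signal` must be non-negative")
  pre <- .ir_precompute(samples$ti_msec)
  .fit_ir_core(samples$signal, pre)
}

#' @export
print.ir_fit <- function(x, ...) {
  cat("Inversion-recovery fit (", x$n_samples, " samples)\n", sep = "")
  cat(sprintf("  A = %.6g  B = %.6g  T1* = %.6g msec\n", x$a, x$b, x$t1_star_msec))
  cat(sprintf("  T1 (Look-Locker corrected) = %.6g msec, RSS = %.4g\n", x$t1_msec, x$rss))
  if (!x$valid) cat("  INVALID fit:", x$reason, "\n")
  invisible(x)
}

#' Fit a monoexponential spin-echo T2 decay
#'
#' Least-squares fit of `SI = A exp(-TE/T2)` to magnitude spin-echo signals.
#' Initialized by log-linear regression when all signals are positive
#' (falling back to a direct start otherwise) and refined by
#' Levenberg-Marquardt.
#'
#' @param samples data frame with columns `te_msec` (distinct, `> 0`) and
#'   `signal`; at least 3 rows.
#' @return object of class `t2_fit`: list with `a`, `t2_msec`, `rss`,
#'   `n_samples`.
#' @examples
#' te <- seq(10, 400, length.out = 10)
#' fit_t2(data.frame(te_msec = te, signal = 200 * exp(-te / 50)))
#' @export
fit_t2 <- function(samples) {
  samples <- .check_samples(samples, "te_msec", min_n = 3)
  te <- samples$te_msec
  y <- samples$signal
  if (all(y > 0)) {
    co <- stats::coef(stats::lm(log(y) ~ te))
    a0 <- exp(co[[1]])
    t20 <- if (co[[2]] < 0) -1 / co[[2]] else max(te) / 2
  } else {
    a0 <- max(y)
    t20 <- stats::median(te)
  }
  fit <- minpack.lm::nls.lm(
    par = c(a0, t20),
    fn = function(q) q[1] * exp(-te / q[2]) - y,
    jac = function(q) {
      e <- exp(-te / q[2])
      cbind(e, q[1] * te * e / q[2]^2)
    },
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12, ptol = 1e-12)
  )
  if (fit$par[2] <= 0) stop("fit failed: non-positive T2")
  structure(
    list(a = fit$par[1], t2_msec = fit$par[2], rss = sum(fit$fvec^2),
         n_samples = length(te)),
    class = "t2_fit"
  )
}

#' @export
print.t2_fit <- function(x, ...) {
  cat("Spin-echo T2 fit (", x$n_samples, " samples)\n", sep = "")
  cat(sprintf("  A = %.6g  T2 = %.6g msec, RSS = %.4g\n", x$a, x$t2_msec, x$rss))
  invisible(x)
}

.check_samples <- function(samples, time_col, min_n) {
  samples <- as.data.frame(samples)
  if (!all(c(time_col, "signal") %in% names(samples)))
    stop("`samples` must have columns `", time_col, "` and `signal`")
  if (nrow(samples) < min_n)
    stop("insufficient data: need at least ", min_n, " samples, got ", nrow(samples))
  if (any(samples[[time_col]] <= 0)) stop("`", time_col, "` must be positive")
  if (anyDuplicated(samples[[time_col]])) stop("`", time_col, "` values must be distinct")
  samples[order(samples[[time_col]]), , drop = FALSE]
}

#' Read inversion-recovery or spin-echo samples from CSV
#'
#' Expects a header `ti_msec,signal` (IR) or `te_msec,signal` (T2).
#'
#' @param path CSV file path.
#' @return data frame suitable for [fit_ir()] or [fit_t2()].
#' @export
read_relaxometry_samples <- function(path) {
  df <- utils::read.csv(path)
  if (!("signal" %in% names(df)) || !any(c("ti_msec", "te_msec") %in% names(df)))
    stop("expected columns `ti_msec,signal` or `te_msec,signal`")
  df
}
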