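#' Bland-Altman agreement summary
#'
#' Mean difference (`y - x`), SD of the differences, and 95% limits of
#' agreement (mean difference +/- 1.96 SD) between two measurement methods.
#'
#' @param x,y paired measurements by method 1 and method 2; equal length
#'   `>= 2`, finite.
#' @return list with `mean_diff`, `sd_diff`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(x, y) {
  .check_pairs(x, y, min_n = 2)
  d <- y - x
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       n = length(d))
}

#' Regression slope with a test against unity
#'
#' Ordinary least-squares slope of `y` on `x`, its 95% confidence interval,
#' and a two-sided t-test of the null hypothesis slope = 1 — the check that
#' one measurement technique preserves the dynamic range of another.
#'
#' @param x,y paired measurements; `>= 3` pairs, `x` not constant.
#' @return list with `slope`, `intercept`, `se`, `ci95` (length-2), `t`,
#'   `df`, `p_vs_1`.
#' @export
slope_vs_unity <- function(x, y) {
  .check_pairs(x, y, min_n = 3)
  if (stats::sd(x) == 0) stop("`x` is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact linear data; the se == 0 branch handles it
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- sm["x", "Estimate"]
  se <- sm["x", "Std. Error"]
  df <- fit$df.residual
  if (se == 0) {
    # exact linear data: degenerate but well-defined limits
    t <- if (slope == 1) 0 else sign(slope - 1) * Inf
    p <- if (slope == 1) 1 else 0
  } else {
    t <- (slope - 1) / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  qt975 <- stats::qt(0.975, df)
  list(slope = slope, intercept = stats::coef(fit)[[1]], se = se,
       ci95 = c(slope - qt975 * se, slope + qt975 * se), t = t, df = df, p_vs_1 = p)
}

#' Coefficient of variation
#'
#' Sample SD divided by the mean, the repeatability metric used for
#' repeated phantom measurements.
#'
#' @param repeats numeric vector, `>= 2` values, mean not 0.
#' @return CV as a fraction.
#' @export
coefficient_of_variation <- function(repeats) {
  if (length(repeats) < 2) stop("need at least 2 values")
  m <- mean(repeats)
  if (m == 0) stop("mean is zero; CV undefined")
  stats::sd(repeats) / m
}

#' Paired t-test with degenerate-difference guards
#'
#' Standard paired t statistic with `df = n - 1` and a two-sided p-value.
#' Zero-variance differences are handled explicitly: all-zero differences
#' give `t = 0, p = 1`; constant non-zero differences give an infinite t
#' (flagged) with `p = 0`.
#'
#' @param x,y paired measurements, equal length `>= 2`.
#' @return list with `t`, `df`, `p`, `mean_diff`, `zero_variance` flag.
#' @export
paired_t <- function(x, y) {
  .check_pairs(x, y, min_n = 2)
  d <- x - y
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
    return(list(t = t, df = n - 1, p = p, mean_diff = m, zero_variance = TRUE))
  }
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1), mean_diff = m,
       zero_variance = FALSE)
}

.check_pairs <- function(x, y, min_n) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < min_n) stop("need at least ", min_n, " pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  invisible(TRUE)
}

#' Gaussian GEE with exchangeable working correlation
#'
#' Generalized estimating equations for a Gaussian identity-link marginal
#' model with an exchangeable working correlation — the standard adjustment
#' for serial measurements clustered within subjects. The correlation
#' parameter is estimated by the usual moment (residual cross-product)
#' estimator, the scale by the Pearson estimator, and standard errors are
#' robust (sandwich) without finite-sample correction; p-values use the
#' normal reference. With one observation per cluster the estimates reduce
#' exactly to ordinary least squares.
#'
#' @param formula model formula, e.g. `ve ~ technique + time_min`.
#' @param data data frame containing the model variables and `id`.
#' @param id name of the cluster (subject) identifier column.
#' @param max_iter maximum update iterations (default 100).
#' @param tol convergence tolerance on the coefficient change.
#' @return object of class `gee_fit`: list with `coefficients`,
#'   `robust_se`, `z`, `p`, `alpha` (working correlation), `scale`,
#'   `n_clusters`, `n_obs`, `iterations`, `converged`, `formula`.
#' @export
gee_exchangeable <- function(formula, data, id, max_iter = 100, tol = 1e-8) {
  data <- as.data.frame(data)
  if (!id %in% names(data)) stop("cluster column `", id, "` not found")
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  cl <- factor(data[[id]][as.integer(rownames(mf))])
  if (nlevels(cl) < 2) stop("need at least 2 clusters")
  p <- ncol(X)
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  idx <- split(seq_along(y), cl)
  # exchangeable inverse: R^-1 = (I - c J) / (1 - alpha), c = alpha / (1 + (n-1) alpha)
  beta <- stats::coef(stats::lm.fit(X, y))
  alpha <- 0
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    r <- y - X %*% beta
    phi <- sum(r^2) / (length(y) - p)
    num <- 0
    npairs <- 0
    for (ix in idx) {
      ri <- r[ix]
      num <- num + (sum(ri)^2 - sum(ri^2)) / 2
      ni <- length(ix)
      npairs <- npairs + ni * (ni - 1) / 2
    }
    alpha <- if (npairs > p) (num / phi) / (npairs - p) else 0
    max_n <- max(lengths(idx))
    alpha <- min(max(alpha, -1 / (max_n - 1 + 1e-12) + 1e-6), 0.999)
    XtWX <- matrix(0, p, p)
    XtWy <- numeric(p)
    for (ix in idx) {
      Xi <- X[ix, , drop = FALSE]
      yi <- y[ix]
      ni <- length(ix)
      cc <- alpha / (1 + (ni - 1) * alpha)
      # Xi' R^-1 Xi and Xi' R^-1 yi without forming R^-1
      csX <- colSums(Xi)
      XtWX <- XtWX + (crossprod(Xi) - cc * tcrossprod(csX)) / (1 - alpha)
      XtWy <- XtWy + (crossprod(Xi, yi)[, 1] - cc * csX * sum(yi)) / (1 - alpha)
    }
    beta_new <- solve(XtWX, XtWy)
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  if (!converged) stop("GEE did not converge in ", max_iter, " iterations (last beta: ",
                       paste(signif(beta, 4), collapse = ", "), ")")
  r <- y - X %*% beta
  phi <- sum(r^2) / (length(y) - p)
  A <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (ix in idx) {
    Xi <- X[ix, , drop = FALSE]
    ri <- r[ix]
    ni <- length(ix)
    cc <- alpha / (1 + (ni - 1) * alpha)
    csX <- colSums(Xi)
    XtW <- t((Xi - cc * matrix(csX, ni, p, byrow = TRUE)) / (1 - alpha)) # p x ni = Xi' R^-1
    A <- A + XtW %*% Xi
    u <- XtW %*% ri
    B <- B + tcrossprod(u)
  }
  Ainv <- solve(A)
  V <- Ainv %*% B %*% Ainv
  se <- sqrt(diag(V))
  z <- as.vector(beta) / se
  structure(
    list(coefficients = stats::setNames(as.vector(beta), colnames(X)),
         robust_se = stats::setNames(se, colnames(X)),
         z = stats::setNames(z, colnames(X)),
         p = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(X)),
         vcov = V, alpha = alpha, scale = phi,
         n_clusters = length(idx), n_obs = length(y),
         iterations = it, converged = converged, formula = formula),
    class = "gee_fit"
  )
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("GEE (Gaussian, exchangeable working correlation)\n")
  cat("  clusters:", x$n_clusters, " observations:", x$n_obs,
      " alpha:", signif(x$alpha, 3), "\n")
  tab <- cbind(Estimate = x$coefficients, `Robust SE` = x$robust_se,
               z = x$z, `Pr(>|z|)` = x$p)
  print(signif(tab, 4))
  invisible(x)
}

#' Technique-by-time interaction test for serial Ve measurements
#'
#' Fits a GEE with exchangeable working correlation for the response with
#' main effects of technique and time and their interaction, and reports
#' the interaction coefficient with its robust p-value — the check for a
#' slow drift of serial Ve under one technique (e.g. after a bolus, as
#' contrast clears) relative to the other.
#'
#' @param data data frame in long format.
#' @param response name of the response column (default `"ve"`).
#' @param technique name of the technique indicator column.
#' @param time name of the time column (needs `>= 2` distinct values).
#' @param id name of the cluster identifier column.
#' @return list with `interaction_coef`, `robust_se`, `p`, and the full
#'   `gee_fit`.
#' @export
time_interaction_test <- function(data, response = "ve", technique = "technique",
                                  time = "time_min", id = "cluster_id") {
  data <- as.data.frame(data)
  for (col in c(response, technique, time, id)) {
    if (!col %in% names(data)) stop("column `", col, "` not found")
  }
  if (length(unique(data[[time]])) < 2) stop("time covariate needs >= 2 distinct values")
  f <- stats::as.formula(paste(response, "~", technique, "*", time))
  fit <- gee_exchangeable(f, data, id = id)
  term <- grep(":", names(fit$coefficients), value = TRUE)
  if (length(term) != 1) stop("could not identify the interaction term")
  list(interaction_coef = unname(fit$coefficients[term]),
       robust_se = unname(fit$robust_se[term]),
       p = unname(fit$p[term]), fit = fit)
}
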