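#' Ordinary least-squares fit of niche breadth on trait indicators
#'
#' Fits `y = X beta + e` by QR decomposition (no explicit inversion) and
#' returns the full coefficient table: estimates, standard errors from
#' `s^2 (X'X)^{-1}` with the unbiased `s^2 = RSS / (n - ncol(X))`,
#' two-sided t-test p-values, R-squared and adjusted R-squared about the
#' mean, residual standard error, and the overall F statistic.
#'
#' @param X numeric design matrix, typically from [build_design_matrix()];
#'   must have full column rank and more rows than columns.
#' @param y numeric response vector (climate-class counts), same length as
#'   `nrow(X)`.
#' @return object of class `ols_fit` with components `beta`, `se`,
#'   `t_stats`, `p_values`, `residual_se`, `residual_df`, `R2`,
#'   `adjusted_R2`, `F_stat`, `F_df`, `n_obs`, `fitted`, `residuals`.
#'   When `y` is constant, `R2` is `NA` and `R2_defined` is `FALSE`
#'   rather than evaluating 0/0.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  k <- ncol(X)
  stopifnot(length(y) == n)
  if (n <= k) stop("need more observations than columns (n=", n,
                   ", columns=", k, ")")
  qrx <- qr(X)
  if (qrx$rank < k) {
    collinear <- colnames(X)[qrx$pivot[(qrx$rank + 1L):k]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(collinear, collapse = ", "))
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  df_resid <- n - k
  s2 <- rss / df_resid
  XtX_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(s2 * diag(XtX_inv))
  names(se) <- names(beta)
  t_stats <- beta / se
  p_values <- 2 * stats::pt(abs(t_stats), df_resid, lower.tail = FALSE)

  has_int <- any(apply(X, 2L, function(col) all(col == col[1] & col[1] != 0)))
  tss <- if (has_int) sum((y - mean(y))^2) else sum(y^2)
  p_slope <- k - as.integer(has_int)
  if (tss <= .Machine$double.eps * max(1, sum(y^2))) {
    r2 <- NA_real_; adj_r2 <- NA_real_; fstat <- NA_real_
    r2_defined <- FALSE
  } else {
    r2 <- 1 - rss / tss
    adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p_slope - 1)
    fstat <- ((tss - rss) / p_slope) / (rss / (n - p_slope - 1))
    r2_defined <- TRUE
  }
  structure(list(
    beta = beta, se = se, t_stats = t_stats, p_values = p_values,
    residual_se = sqrt(s2), residual_df = df_resid,
    R2 = r2, adjusted_R2 = adj_r2, R2_defined = r2_defined,
    F_stat = fstat, F_df = c(p_slope, n - p_slope - 1),
    n_obs = n, fitted = fitted, residuals = resid,
    X = X, y = y
  ), class = "ols_fit")
}

signif_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) "" else if (pp < 0.001) "***"
    else if (pp < 0.01) "**" else if (pp < 0.05) "*" else ""
  }, character(1))
}

#' Coefficient table with significance stars
#'
#' Formats a fit the way regression tables are conventionally printed:
#' estimate with its standard error in parentheses and stars at p < 0.05
#' (*), p < 0.01 (**), p < 0.001 (***), followed by the fit statistics.
#'
#' @param fit an `ols_fit` or `pglm_bm` object.
#' @param digits digits for the formatted numbers.
#' @return data frame with columns `term` and `value` (character),
#'   one row per coefficient then per fit statistic.
#' @export
summarize_ols <- function(fit, digits = 3L) {
  fmt <- function(x) formatC(x, digits = digits, format = "f")
  rows <- data.frame(
    term = names(fit$beta),
    value = paste0(fmt(fit$beta), signif_stars(fit$p_values),
                   " (", fmt(fit$se), ")"),
    stringsAsFactors = FALSE
  )
  stats_rows <- data.frame(
    term = c("observations", "R2", "adjusted R2", "residual s.e."),
    value = c(as.character(fit$n_obs), fmt(fit$R2), fmt(fit$adjusted_R2),
              sprintf("%s (d.f. = %d)", fmt(fit$residual_se),
                      fit$residual_df)),
    stringsAsFactors = FALSE
  )
  if (!is.null(fit$F_stat) && is.finite(fit$F_stat)) {
    stats_rows <- rbind(stats_rows, data.frame(
      term = "F statistic",
      value = sprintf("%s%s (d.f. = %d; %d)", fmt(fit$F_stat),
                      signif_stars(stats::pf(fit$F_stat, fit$F_df[1],
                                             fit$F_df[2],
                                             lower.tail = FALSE)),
                      fit$F_df[1], fit$F_df[2]),
      stringsAsFactors = FALSE))
  }
  rbind(rows, stats_rows)
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("Ordinary least-squares fit of climate niche breadth\n")
  cat(sprintf("  n = %d, residual df = %d\n", x$n_obs, x$residual_df))
  print(summarize_ols(x), row.names = FALSE)
  invisible(x)
}

#' @export
summary.ols_fit <- function(object, ...) {
  out <- data.frame(estimate = object$beta, se = object$se,
                    t = object$t_stats, p = object$p_values)
  attr(out, "R2") <- object$R2
  attr(out, "adjusted_R2") <- object$adjusted_R2
  attr(out, "F_stat") <- object$F_stat
  out
}

#' @export
coef.ols_fit <- function(object, ...) object$beta

#' @export
residuals.ols_fit <- function(object, ...) object$residuals

#' @export
fitted.ols_fit <- function(object, ...) object$fitted

#' @export
vcov.ols_fit <- function(object, ...) {
  qrx <- qr(object$X)
  v <- object$residual_se^2 * chol2inv(qr.R(qrx))
  dimnames(v) <- list(names(object$beta), names(object$beta))
  v
}

#' @export
predict.ols_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  drop(as.matrix(newdata) %*% object$beta)
}

#' @export
logLik.ols_fit <- function(object, ...) {
  n <- object$n_obs
  rss <- sum(object$residuals^2)
  ll <- -0.5 * n * (log(2 * pi) + log(rss / n) + 1)
  structure(ll, df = length(object$beta) + 1, class = "logLik")
}

#' @export
simulate.ols_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- sqrt(sum(object$residuals^2) / object$n_obs)
  matrix(stats::rnorm(object$n_obs * nsim, mean = object$fitted, sd = s),
         nrow = object$n_obs, ncol = nsim)
}

#' @export
plot.ols_fit <- function(x, ...) {
  plot(x$fitted, x$residuals, xlab = "fitted breadth",
       ylab = "residual", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
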