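#' Parse a Newick tree
#'
#' Reads a rooted tree with branch lengths from a Newick string or file
#' and validates it for use in the phylogenetic regression: unique tip
#' labels, finite non-negative branch lengths. Missing branch lengths can
#' optionally default to zero with a warning.
#'
#' @param text Newick string, or a length-1 path to a file containing one.
#' @param default_length if not `NULL`, missing branch lengths are replaced
#'   by this value (with a warning) instead of being an error.
#' @return an [ape::phylo] object.
#' @export
parse_newick <- function(text, default_length = NULL) {
  tree <- if (length(text) == 1L && file.exists(text) &&
              !grepl("\\(", text)) {
    tryCatch(ape::read.tree(text), error = function(e) NULL)
  } else {
    tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  }
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("malformed Newick input")
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    if (is.null(default_length)) {
      stop("tree has missing branch lengths")
    }
    warning("missing branch lengths set to ", default_length)
    if (is.null(tree$edge.length)) {
      tree$edge.length <- rep(default_length, nrow(tree$edge))
    } else {
      tree$edge.length[is.na(tree$edge.length)] <- default_length
    }
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and non-negative")
  }
  tree
}

#' Write a tree as Newick
#'
#' @param tree an [ape::phylo] object.
#' @param path optional output file; if `NULL` the Newick string is
#'   returned.
#' @return the Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(ape::write.tree(tree))
}

#' Prune a tree to a set of taxa
#'
#' Keeps exactly the named tips, collapsing unary internal nodes and
#' summing their branch lengths, so root-to-tip distances of retained
#' tips are unchanged.
#'
#' @param tree an [ape::phylo] object.
#' @param names tip labels to retain (must all be present).
#' @return the pruned [ape::phylo] object.
#' @export
prune_to_taxa <- function(tree, names) {
  missing <- setdiff(names, tree$tip.label)
  if (length(missing) > 0L) {
    stop("taxa absent from tree: ", paste(missing, collapse = ", "))
  }
  ape::keep.tip(tree, names)
}

#' Brownian-motion covariance matrix of a tree
#'
#' Builds the matrix `C` whose entry (i, j) is the shared root-to-MRCA
#' path length of tips i and j — the trait covariance (up to the rate
#' sigma^2) under Brownian motion along the tree. The diagonal holds
#' root-to-tip distances; on an ultrametric tree it is constant.
#'
#' @param tree an [ape::phylo] object with branch lengths.
#' @return symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
bm_covariance <- function(tree) {
  ape::vcv.phylo(tree)
}

#' Generalised least squares for a known covariance
#'
#' Minimises `(y - X b)' Sigma^{-1} (y - X b)` by whitening with the upper
#' Cholesky factor of `Sigma` and solving the whitened problem by QR. Also
#' returns the Gaussian log density of `y` at the fit with covariance
#' `Sigma` (no free scale).
#'
#' @param X design matrix; `y` response; `Sigma` symmetric positive
#'   definite covariance, all conformable.
#' @return list with `beta`, `rss_gls` (the generalised residual sum of
#'   squares), and `loglik`.
#' @export
gls_fit <- function(X, y, Sigma) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  R <- tryCatch(chol(Sigma), error = function(e) {
    stop("Sigma is not positive definite; consider adding a small ",
         "diagonal jitter")
  })
  # whiten: solve R' z = y so that cov(z) = I
  yw <- backsolve(R, y, transpose = TRUE)
  Xw <- backsolve(R, X, transpose = TRUE)
  qrx <- qr(Xw)
  beta <- qr.coef(qrx, yw)
  resid <- yw - Xw %*% beta
  rss <- sum(resid^2)
  n <- length(y)
  logdet <- 2 * sum(log(diag(R)))
  list(beta = beta, rss_gls = rss,
       loglik = -0.5 * (n * log(2 * pi) + logdet + rss))
}

# Weighted LS in the eigenbasis of C: for Sigma ~ diag(d + gamma),
# returns beta, the generalised RSS and the profile log-likelihood with
# sigma2 profiled out at its ML value rss/n.
profile_eval <- function(gamma, d, W, z) {
  w <- d + gamma
  if (any(w <= 0)) return(list(loglik = -Inf))
  Wd <- W / w
  A <- crossprod(W, Wd)
  b <- crossprod(Wd, z)
  beta <- tryCatch(drop(solve(A, b)), error = function(e) NULL)
  if (is.null(beta)) return(list(loglik = -Inf))
  r <- z - drop(W %*% beta)
  rss <- sum(r^2 / w)
  n <- length(z)
  sigma2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + sum(log(w)) + n)
  list(beta = beta, rss_gls = rss, sigma2 = sigma2, loglik = ll)
}

#' Phylogenetic linear model: Brownian motion plus independent error
#'
#' Maximum-likelihood fit of the Gaussian model with mean `X beta` and
#' covariance `sigma2 * C + sigma2_error * I`, where `C` is the
#' Brownian-motion covariance of the tree. The likelihood is profiled to
#' one dimension in `gamma = sigma2_error / sigma2`: after an
#' eigendecomposition `C = U D U'`, each `gamma` gives closed-form
#' `beta(gamma)` and `sigma2(gamma) = RSS_gls / n` (ML divisor), and
#' `gamma` is maximised on a log grid refined by bounded scalar
#' optimisation. Standard errors come from
#' `sigma2_hat (X' Sigma(gamma_hat)^{-1} X)^{-1}`; p-values use the t
#' distribution with `n - p - 1` df (`p` = non-intercept columns).
#'
#' @param X design matrix with species rownames; `y` named response.
#'   Names must match the tree's tips (order may differ; rows are aligned
#'   by name).
#' @param tree an [ape::phylo] object whose tip set equals the species of
#'   `X`/`y` (prune first with [prune_to_taxa()] if needed).
#' @param gamma_range search interval for `gamma` (variance ratio).
#' @param tol convergence tolerance for the scalar optimiser, on log(gamma).
#' @return object of class `pglm_bm`: `beta`, `se`, `t_stats`, `p_values`,
#'   `sigma2` (BM rate, classes^2 per branch-length unit), `sigma2_error`
#'   (classes^2), `gamma`, `loglik`, `R2`/`adjusted_R2` (GLS deviance
#'   ratio against the intercept-only GLS fit on the same estimated
#'   covariance), `residual_se`, `residual_df`, `n_obs`, `tree_depth`,
#'   `note` (boundary/identifiability flags), plus internals reused by
#'   [parametric_bootstrap()] and [simulate()].
#' @export
fit_pglm_bm_error <- function(X, y, tree, gamma_range = c(1e-8, 1e8),
                              tol = 1e-8) {
  X <- as.matrix(X)
  if (is.null(rownames(X)) && !is.null(names(y))) rownames(X) <- names(y)
  if (is.null(rownames(X))) stop("X needs species rownames (or y names)")
  if (!setequal(rownames(X), tree$tip.label)) {
    stop("tree tips and design-matrix species differ; extra in tree: ",
         paste(setdiff(tree$tip.label, rownames(X)), collapse = ", "),
         "; extra in X: ",
         paste(setdiff(rownames(X), tree$tip.label), collapse = ", "))
  }
  y <- as.numeric(y[rownames(X)])
  C <- bm_covariance(tree)[rownames(X), rownames(X)]
  n <- nrow(X)
  k <- ncol(X)
  if (n <= k) stop("need more species than design columns")

  eig <- eigen(C, symmetric = TRUE)
  d <- eig$values
  U <- eig$vectors
  W <- crossprod(U, X)
  z <- drop(crossprod(U, y))

  note <- character(0)
  depth <- max(diag(C))
  if (diff(range(d)) < 1e-10 * max(abs(d))) {
    note <- c(note, "variance components unidentifiable (C proportional to I)")
  }

  lg <- seq(log(gamma_range[1]), log(gamma_range[2]), length.out = 65L)
  ll_grid <- vapply(lg, function(g) profile_eval(exp(g), d, W, z)$loglik,
                    numeric(1))
  i <- which.max(ll_grid)
  lo <- lg[max(1L, i - 1L)]
  hi <- lg[min(length(lg), i + 1L)]
  opt <- stats::optimize(function(g) profile_eval(exp(g), d, W, z)$loglik,
                         interval = c(lo, hi), maximum = TRUE, tol = tol)
  gamma <- exp(opt$maximum)
  if (opt$objective < ll_grid[i]) gamma <- exp(lg[i])
  if (gamma >= gamma_range[2] * 0.99) {
    note <- c(note, "gamma at upper bound: phylogenetic signal negligible")
  }
  if (gamma <= gamma_range[1] * 1.01) {
    note <- c(note, "gamma at lower bound: no independent error detected")
  }

  est <- profile_eval(gamma, d, W, z)
  beta <- est$beta
  names(beta) <- colnames(X)
  sigma2 <- est$sigma2
  sigma2_error <- gamma * sigma2
  # SEs: sigma2_hat * (X' Sigma^{-1} X)^{-1} with Sigma = C + gamma I
  w <- d + gamma
  XtSiX <- crossprod(W, W / w)
  cov_beta <- sigma2 * solve(XtSiX)
  dimnames(cov_beta) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(cov_beta))
  df_t <- n - (k - 1L) - 1L
  t_stats <- beta / se
  p_values <- 2 * stats::pt(abs(t_stats), df_t, lower.tail = FALSE)

  r2 <- pgls_r2_internal(W, z, w, est$rss_gls)
  p_slope <- k - 1L
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p_slope - 1)

  fitted <- drop(X %*% beta)
  structure(list(
    beta = beta, se = se, t_stats = t_stats, p_values = p_values,
    sigma2 = sigma2, sigma2_error = sigma2_error, gamma = gamma,
    loglik = est$loglik, R2 = r2, adjusted_R2 = adj_r2,
    residual_se = sqrt(est$rss_gls / df_t), residual_df = df_t,
    rss_gls = est$rss_gls, n_obs = n, tree_depth = depth, note = note,
    fitted = fitted, residuals = y - fitted, cov_beta = cov_beta,
    X = X, y = stats::setNames(y, rownames(X)), tree = tree,
    eigen = list(d = d, U = U), gamma_range = gamma_range, tol = tol
  ), class = "pglm_bm")
}

# GLS R^2 in the eigenbasis: 1 - RSS_full / RSS_intercept-only on the
# same Sigma-hat (weights w = d + gamma).
pgls_r2_internal <- function(W, z, w, rss_full) {
  ones <- W[, 1L] # intercept column in the eigenbasis
  mu <- sum(ones * z / w) / sum(ones^2 / w)
  rss0 <- sum((z - mu * ones)^2 / w)
  if (rss0 <= 0) return(NA_real_)
  1 - rss_full / rss0
}

#' GLS coefficient of determination
#'
#' `R^2 = 1 - RSS_gls(full) / RSS_gls(intercept only)`, both generalised
#' residual sums of squares computed on the same covariance `Sigma`. With
#' `Sigma = I` this reduces to the ordinary OLS R-squared.
#'
#' @param X design matrix whose first column is the intercept; `y`
#'   response; `Sigma` the (estimated) residual covariance.
#' @return the R-squared value.
#' @export
pgls_r2 <- function(X, y, Sigma) {
  X <- as.matrix(X)
  full <- gls_fit(X, y, Sigma)
  null <- gls_fit(X[, 1L, drop = FALSE], y, Sigma)
  1 - full$rss_gls / null$rss_gls
}

#' Parametric bootstrap for the phylogenetic linear model
#'
#' Draws `n_boot` response vectors from the fitted model
#' `N(X beta_hat, sigma2_hat C + sigma2_error_hat I)`, refits each, and
#' reports percentile 2.5/97.5 intervals for the variance components and
#' (optionally) the coefficients. Replicates whose refit fails to produce
#' finite estimates are dropped and counted; more than 20% drops is an
#' error.
#'
#' @param fit a converged `pglm_bm` fit.
#' @param n_boot number of bootstrap replicates (default 100).
#' @param seed integer seed; the same seed reproduces the intervals
#'   exactly.
#' @param include_beta also report intervals for the coefficients.
#' @return data frame with columns `parameter`, `estimate`, `lower`,
#'   `upper`; attributes `n_boot`, `n_dropped`, `replicates` (matrix of
#'   per-replicate estimates).
#' @export
parametric_bootstrap <- function(fit, n_boot = 100L, seed = NULL,
                                 include_beta = TRUE) {
  stopifnot(inherits(fit, "pglm_bm"))
  pars <- c("sigma2", "sigma2_error",
            if (include_beta) names(fit$beta))
  if (n_boot == 0L) {
    out <- data.frame(parameter = pars,
                      estimate = c(fit$sigma2, fit$sigma2_error,
                                   if (include_beta) fit$beta),
                      lower = NA_real_, upper = NA_real_,
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "n_boot") <- 0L
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  if (!is.null(seed)) set.seed(seed)
  d <- fit$eigen$d
  U <- fit$eigen$U
  W <- crossprod(U, fit$X)
  n <- fit$n_obs
  sd_eig <- sqrt(fit$sigma2 * (d + fit$gamma))
  mu_eig <- drop(crossprod(U, fit$fitted))
  reps <- matrix(NA_real_, nrow = n_boot,
                 ncol = 2L + length(fit$beta),
                 dimnames = list(NULL, c("sigma2", "sigma2_error",
                                         names(fit$beta))))
  for (b in seq_len(n_boot)) {
    zb <- mu_eig + stats::rnorm(n, sd = sd_eig)
    rb <- refit_eigen(zb, d, W, fit$gamma_range, fit$tol)
    if (!is.null(rb)) {
      reps[b, ] <- c(rb$sigma2, rb$gamma * rb$sigma2, rb$beta)
    }
  }
  ok <- stats::complete.cases(reps)
  n_dropped <- sum(!ok)
  if (n_dropped > 0.2 * n_boot) {
    stop(n_dropped, " of ", n_boot, " bootstrap replicates failed to refit")
  }
  qs <- apply(reps[ok, , drop = FALSE], 2L, stats::quantile,
              probs = c(0.025, 0.975), names = FALSE)
  keep <- pars
  out <- data.frame(parameter = keep,
                    estimate = c(fit$sigma2, fit$sigma2_error,
                                 if (include_beta) fit$beta)[seq_along(keep)],
                    lower = qs[1L, keep], upper = qs[2L, keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_boot") <- n_boot
  attr(out, "n_dropped") <- n_dropped
  attr(out, "replicates") <- reps[ok, , drop = FALSE]
  out
}

# Refit the 1-D profile for a new response expressed in the eigenbasis.
refit_eigen <- function(z, d, W, gamma_range, tol) {
  lg <- seq(log(gamma_range[1]), log(gamma_range[2]), length.out = 33L)
  ll <- vapply(lg, function(g) profile_eval(exp(g), d, W, z)$loglik,
               numeric(1))
  if (all(!is.finite(ll))) return(NULL)
  i <- which.max(ll)
  opt <- stats::optimize(function(g) profile_eval(exp(g), d, W, z)$loglik,
                         interval = c(lg[max(1L, i - 1L)],
                                      lg[min(length(lg), i + 1L)]),
                         maximum = TRUE, tol = tol)
  gamma <- exp(opt$maximum)
  if (opt$objective < ll[i]) gamma <- exp(lg[i])
  est <- profile_eval(gamma, d, W, z)
  if (!is.finite(est$loglik)) return(NULL)
  list(beta = est$beta, sigma2 = est$sigma2, gamma = gamma)
}

#' @export
print.pglm_bm <- function(x, ...) {
  cat("Phylogenetic linear model (Brownian motion + independent error)\n")
  cat(sprintf("  n = %d tips, tree depth = %g, residual df = %d\n",
              x$n_obs, x$tree_depth, x$residual_df))
  tab <- summarize_ols(structure(
    list(beta = x$beta, se = x$se, p_values = x$p_values,
         n_obs = x$n_obs, R2 = x$R2, adjusted_R2 = x$adjusted_R2,
         residual_se = x$residual_se, residual_df = x$residual_df,
         F_stat = NA_real_, F_df = c(length(x$beta) - 1L, x$residual_df)),
    class = "ols_fit"))
  print(tab[tab$term != "F statistic", ], row.names = FALSE)
  cat(sprintf("  sigma^2 = %.6g (per branch-length unit), sigma^2 error = %.6g\n",
              x$sigma2, x$sigma2_error))
  cat(sprintf("  log-likelihood = %.4f, gamma = %.6g\n", x$loglik, x$gamma))
  if (length(x$note)) cat("  note:", paste(x$note, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.pglm_bm <- function(object, ...) {
  out <- data.frame(estimate = object$beta, se = object$se,
                    t = object$t_stats, p = object$p_values)
  attr(out, "sigma2") <- object$sigma2
  attr(out, "sigma2_error") <- object$sigma2_error
  attr(out, "R2") <- object$R2
  attr(out, "adjusted_R2") <- object$adjusted_R2
  attr(out, "loglik") <- object$loglik
  out
}

#' @export
coef.pglm_bm <- function(object, ...) object$beta

#' @export
vcov.pglm_bm <- function(object, ...) object$cov_beta

#' @export
residuals.pglm_bm <- function(object,
                              type = c("response", "normalized"), ...) {
  type <- match.arg(type)
  if (type == "response") return(object$residuals)
  # whitened residuals: unit variance, independent under the fitted model
  w <- object$eigen$d + object$gamma
  r_eig <- drop(crossprod(object$eigen$U, object$residuals))
  r_eig / sqrt(object$sigma2 * w)
}

#' @export
fitted.pglm_bm <- function(object, ...) object$fitted

#' @export
predict.pglm_bm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  drop(as.matrix(newdata) %*% object$beta)
}

#' @export
logLik.pglm_bm <- function(object, ...) {
  structure(object$loglik, df = length(object$beta) + 2,
            class = "logLik")
}

#' Simulate responses from a fitted phylogenetic linear model
#'
#' Draws from `N(X beta_hat, sigma2_hat C + sigma2_error_hat I)` — the
#' same generator the parametric bootstrap uses.
#'
#' @param object a `pglm_bm` fit.
#' @param nsim number of response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return numeric matrix, one column per simulation, species as rows.
#' @export
simulate.pglm_bm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$eigen$d
  U <- object$eigen$U
  sd_eig <- sqrt(object$sigma2 * (d + object$gamma))
  eps <- matrix(stats::rnorm(object$n_obs * nsim, sd = sd_eig),
                nrow = object$n_obs)
  out <- object$fitted + U %*% eps
  rownames(out) <- rownames(object$X)
  out
}

#' Profile log-likelihood plot over the variance ratio
#'
#' @param x a `pglm_bm` fit.
#' @param n_grid grid resolution on log10(gamma).
#' @param ... passed to [plot()].
#' @export
plot.pglm_bm <- function(x, n_grid = 101L, ...) {
  W <- crossprod(x$eigen$U, x$X)
  z <- drop(crossprod(x$eigen$U, x$y))
  lg <- seq(log10(x$gamma_range[1]), log10(x$gamma_range[2]),
            length.out = n_grid)
  ll <- vapply(lg, function(g) {
    profile_eval(10^g, x$eigen$d, W, z)$loglik
  }, numeric(1))
  plot(lg, ll, type = "l", xlab = "log10(gamma)",
       ylab = "profile log-likelihood", ...)
  graphics::abline(v = log10(x$gamma), lty = 2)
  invisible(x)
}
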