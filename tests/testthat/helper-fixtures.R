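# Fixtures built in code: tiny rasters, trees and regression problems.

# A raster from an explicit label matrix (row 1 = north). NA = nodata.
label_raster <- function(labels, xll = 0, yll = 0, cellsize = 1) {
  labs <- sort(unique(as.vector(labels[!is.na(labels)])))
  legend <- data.frame(code = seq_along(labs), label = labs,
                       stringsAsFactors = FALSE)
  grid <- matrix(match(as.vector(labels), labs), nrow(labels), ncol(labels))
  grid[is.na(grid)] <- -9999L
  climate_raster(grid, xll = xll, yll = yll, cellsize = cellsize,
                 nodata = -9999L, legend = legend)
}

occ_df <- function(species, lat, lon) {
  data.frame(species_id = species, latitude = lat, longitude = lon,
             stringsAsFactors = FALSE)
}

# random full-rank regression problem with intercept
rand_problem <- function(n, p_extra, seed) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * p_extra), n))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(p_extra)))
  y <- rnorm(n)
  list(X = X, y = y)
}

# closed-form normal-equations OLS oracle (independent of fit_ols's QR path)
ols_oracle <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  df <- nrow(X) - ncol(X)
  se <- sqrt(diag(solve(XtX)) * rss / df)
  list(beta = drop(beta), se = se, R2 = 1 - rss / tss)
}

# dense-matrix Gaussian log density oracle for the GLS likelihood
dense_loglik <- function(X, y, Sigma) {
  beta <- solve(t(X) %*% solve(Sigma, X), t(X) %*% solve(Sigma, y))
  r <- y - X %*% beta
  n <- length(y)
  as.numeric(-0.5 * (n * log(2 * pi) + determinant(Sigma)$modulus +
                       t(r) %*% solve(Sigma, r)))
}

# naive per-pair shared path length: distance from root to the MRCA,
# computed from root-to-node paths (independent of ape::vcv.phylo)
naive_shared_paths <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(node) {
    p <- node
    while (node != root) {
      node <- parent[node]
      p <- c(p, node)
    }
    p
  }
  depth <- function(node) {
    d <- 0
    while (node != root) {
      d <- d + elen[node]
      node <- parent[node]
    }
    d
  }
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    pi_ <- path_to_root(i)
    for (j in seq_len(n)) {
      mrca <- intersect(pi_, path_to_root(j))[1]
      C[i, j] <- if (i == j) depth(i) else depth(mrca)
    }
  }
  C
}
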