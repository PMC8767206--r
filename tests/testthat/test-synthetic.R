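test_that("Yule trees are ultrametric, seeded and correctly sized", {
  tr <- simulate_yule_tree(2, 0.5, seed = 1)
  d <- ape::node.depth.edgelength(tr)[1:2]
  expect_equal(length(tr$tip.label), 2L)
  expect_equal(d[1], d[2], tolerance = 1e-12)  # a single cherry
  expect_identical(write_newick(simulate_yule_tree(12, 0.4, seed = 7)),
                   write_newick(simulate_yule_tree(12, 0.4, seed = 7)))
  expect_false(identical(write_newick(simulate_yule_tree(12, 0.4, seed = 7)),
                         write_newick(simulate_yule_tree(12, 0.4, seed = 8))))
  tr2 <- simulate_yule_tree(50, 0.33, seed = 3)
  depths <- ape::node.depth.edgelength(tr2)[1:50]
  expect_lt(diff(range(depths)), 1e-8)
  expect_true(ape::is.ultrametric(tr2))
})

test_that("Yule internode waiting times have mean 1/(k * lambda)", {
  lambda <- 0.7
  n <- 8
  nrep <- 600
  waits <- matrix(NA_real_, nrep, n - 2)
  set.seed(90)
  for (r in seq_len(nrep)) {
    tr <- simulate_yule_tree(n, lambda,
                             seed = sample.int(2^31 - 1, 1))
    bt <- sort(ape::branching.times(tr), decreasing = TRUE)
    # time from k lineages to k+1, k = 2..n-1
    waits[r, ] <- -diff(bt)
  }
  for (k in 2:(n - 1)) {
    # exponential waits: sd equals the mean, so 4 MC standard errors of
    # the mean correspond to a relative tolerance of 4/sqrt(nrep)
    expect_equal(mean(waits[, k - 1]), 1 / (k * lambda),
                 tolerance = 4 / sqrt(nrep))
  }
})

test_that("state draws match their Bernoulli targets", {
  all_on <- simulate_states(50, probabilities = rep(1, 4), seed = 2)
  expect_true(all(as.matrix(all_on[trait_states()]) == 1L))
  all_off <- simulate_states(50, probabilities = rep(0, 4), seed = 2)
  expect_true(all(as.matrix(all_off[trait_states()]) == 0L))
  p <- c(0.5, 0.25, 0.35, 0.15)
  big <- simulate_states(10000, probabilities = p, seed = 3)
  freq <- colMeans(as.matrix(big[trait_states()]))
  se <- sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(freq - p) < 3 * se))
})

test_that("responses follow mean X beta with covariance s2 C + s2e I", {
  tree <- simulate_yule_tree(12, 0.5, seed = 21)
  traits <- simulate_states(12, seed = 22, species_ids = tree$tip.label)
  X <- build_design_matrix(traits, tree$tip.label)
  beta <- c(3, 3, 0.5, 3.5, 1)
  # zero variance: y is exactly X beta
  y0 <- simulate_response(tree, X, beta, 0, 0, seed = 23)
  expect_equal(unname(y0), unname(drop(X %*% beta)), tolerance = 1e-12)
  # star tree: i.i.d. marginals with variance s2*T + s2e
  tips <- paste0("t", 1:6)
  star <- parse_newick(paste0("(", paste0(tips, ":2", collapse = ","), ");"))
  Xs <- matrix(1, 6, 1, dimnames = list(tips, "(Intercept)"))
  set.seed(24)
  draws <- replicate(4000, simulate_response(star, Xs, 0, 1.5, 0.5,
                                             seed = NULL))
  v <- mean(apply(draws, 1, var))
  expect_equal(v, 1.5 * 2 + 0.5, tolerance = 0.15)
  # empirical covariance matches s2 C + s2e I elementwise
  C <- bm_covariance(tree)[rownames(X), rownames(X)]
  set.seed(25)
  draws2 <- replicate(4000, simulate_response(tree, X, beta, 0.3, 1,
                                              seed = NULL))
  emp <- cov(t(draws2))
  want <- 0.3 * C + 1 * diag(12)
  expect_lt(max(abs(emp - want)), 0.35)
})

test_that("synthetic rasters are nearest-seed partitions with full legends", {
  uni <- make_raster(1, nrow = 8, ncol = 8, margin = 1, seed = 5)
  inner <- uni$grid[2:7, 2:7]
  expect_true(all(inner == uni$legend$code))
  for (seed in c(11, 12, 13)) {
    r <- make_raster(6, nrow = 20, ncol = 18, margin = 2, seed = seed)
    codes <- unique(as.vector(r$grid))
    expect_true(all(r$legend$code %in% codes))     # every class present
    expect_true(all(r$grid[1:2, ] == r$nodata))    # nodata margin
    expect_true(all(r$grid[, 1:2] == r$nodata))
  }
  # patch membership equals brute-force nearest-seed assignment
  set.seed(31)
  r <- make_raster(4, nrow = 12, ncol = 12, margin = 1, seed = 31)
  set.seed(31)
  cells <- expand.grid(row = 2:11, col = 2:11)
  seeds <- cells[sample.int(nrow(cells), 4), ]
  for (i in sample(nrow(cells), 40)) {
    d2 <- (cells$row[i] - seeds$row)^2 + (cells$col[i] - seeds$col)^2
    nearest <- which(d2 == min(d2))[1]
    expect_equal(r$grid[cells$row[i], cells$col[i]],
                 r$legend$code[nearest])
  }
})

test_that("occurrence sampling reports exact ground-truth breadth", {
  r <- make_raster(5, nrow = 20, ncol = 20, margin = 1, seed = 41)
  labs <- r$legend$label
  specs <- list(
    one   = list(n_points = 8, weights = setNames(1, labs[1])),
    three = list(n_points = 12,
                 weights = setNames(rep(1 / 3, 3), labs[1:3])),
    none  = list(n_points = 0, weights = setNames(1, labs[1])))
  s <- sample_occurrences(r, specs, seed = 42)
  truth <- setNames(s$truth$B_s, s$truth$species_id)
  expect_equal(unname(truth["one"]), 1L)    # 8 points in one class
  expect_equal(unname(truth["none"]), 0L)
  expect_error(sample_occurrences(r, list(bad = list(
    n_points = 2, weights = c(ZZZ = 1))), seed = 1), "absent")
  expect_error(sample_occurrences(r, list(bad = list(
    n_points = 2, weights = setNames(c(0.5, 0.4), labs[1:2]))),
    seed = 1), "sum to 1")

  # realised counts at the filter boundary (classes near 3-4 points)
  s4 <- sample_occurrences(r, setNames(list(
    list(n_points = 12, weights = setNames(rep(1/3, 3), labs[1:3]))), "x"),
    seed = 7)
  # realised counts decide: recompute from the occurrence table itself
  got <- lookup_class(r, s4$occurrences$longitude, s4$occurrences$latitude)
  counts <- table(got)
  expect_equal(sort(names(counts)[counts > 3]),
               sort(strsplit(s4$truth$retained_classes, ";")[[1]]))
})

test_that("pipeline breadth reproduces generator ground truth exactly", {
  set.seed(77)
  for (rep in 1:25) {
    n_classes <- sample(2:6, 1)
    r <- make_raster(n_classes, nrow = 16, ncol = 16, margin = 1,
                     seed = sample.int(2^31 - 1, 1))
    labs <- r$legend$label
    specs <- lapply(seq_len(sample(2:5, 1)), function(i) {
      k <- sample(seq_len(n_classes), 1)
      cls <- sample(labs, k)
      list(n_points = sample(c(3L, 4L, 8L, 12L), 1) * k,
           weights = setNames(rep(1 / k, k), cls))
    })
    names(specs) <- paste0("sp", seq_along(specs))
    s <- sample_occurrences(r, specs, seed = sample.int(2^31 - 1, 1))
    b <- compute_breadth(s$occurrences, r)
    merged <- merge(b, s$truth, by = "species_id")
    expect_equal(merged$B_s.x, merged$B_s.y)
    expect_equal(merged$retained_classes.x, merged$retained_classes.y)
  }
})
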