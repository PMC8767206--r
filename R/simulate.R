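#' Default simulation configuration
#'
#' Bundles the knobs of the synthetic-data generator. Defaults mirror the
#' scale of the real system: a few dozen wild-relative species on a tree
#' roughly 14 Myr deep, intercept and effect sizes of a few climate
#' classes, and phylogenetic and independent error variances of
#' comparable size so both components are identifiable.
#'
#' @param n_species number of species / tree tips.
#' @param yule_birth_rate speciation rate per Myr of the pure-birth tree
#'   generator (expected depth ~ log(n)/rate).
#' @param state_probabilities per-indicator Bernoulli probabilities for
#'   the four breeding-system x ploidy states (independent; states may
#'   co-occur).
#' @param true_beta length-5 coefficient vector (intercept then the four
#'   indicators in [trait_states()] order), in climate classes.
#' @param sigma2 Brownian-motion rate variance, classes^2/Myr.
#' @param sigma2_error independent (tip-specific) error variance,
#'   classes^2.
#' @param raster_nrow,raster_ncol,raster_n_classes,raster_margin grid
#'   shape, number of climate classes and nodata margin width (cells) of
#'   the synthetic class raster.
#' @param n_points_per_class occurrence points drawn per occupied class
#'   per species in [simulate_scenario()].
#' @param seed root seed; every stochastic step derives from it.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 72L,
                              yule_birth_rate = 0.33,
                              state_probabilities = c(
                                SI_diploid = 0.50, SC_diploid = 0.25,
                                SC_polyploid = 0.35, asexual_diploid = 0.15),
                              true_beta = c(3, 3, 0.5, 3.5, 1),
                              sigma2 = 0.2,
                              sigma2_error = 2,
                              raster_nrow = 40L, raster_ncol = 40L,
                              raster_n_classes = 8L, raster_margin = 2L,
                              n_points_per_class = 6L,
                              seed = 1L) {
  stopifnot(all(state_probabilities >= 0 & state_probabilities <= 1),
            sigma2 >= 0, sigma2_error >= 0, length(true_beta) == 5L,
            n_species >= 2L, yule_birth_rate > 0)
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate an ultrametric Yule tree
#'
#' Pure-birth simulation: starting from two lineages at the root, the
#' waiting time to the next speciation event with k extant lineages is
#' exponential with rate `k * birth_rate`, and a uniformly chosen lineage
#' splits. Once n lineages exist one further exponential waiting time is
#' drawn and all pending branches are extended to that time, so the tree
#' is ultrametric with branch lengths in Myr.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate per Myr.
#' @param seed optional integer seed; the same seed yields an identical
#'   Newick string.
#' @return an ultrametric [ape::phylo] object with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate, seed = NULL) {
  stopifnot(n_tips >= 2L, birth_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  # node arrays; nodes 1 and 2 are the root's children, born at time 0
  start <- c(0, 0)
  end <- c(NA_real_, NA_real_)
  children <- list(NULL, NULL)
  active <- c(1L, 2L)
  t_now <- 0
  while (length(active) < n_tips) {
    k <- length(active)
    t_now <- t_now + stats::rexp(1L, rate = k * birth_rate)
    pick <- active[sample.int(k, 1L)]
    end[pick] <- t_now
    id1 <- length(start) + 1L
    id2 <- length(start) + 2L
    start <- c(start, t_now, t_now)
    end <- c(end, NA_real_, NA_real_)
    children[id1] <- list(NULL)
    children[id2] <- list(NULL)
    children[[pick]] <- c(id1, id2)
    active <- c(setdiff(active, pick), id1, id2)
  }
  t_end <- t_now + stats::rexp(1L, rate = n_tips * birth_rate)
  end[active] <- t_end

  tip_counter <- 0L
  newick <- function(id) {
    len <- end[id] - start[id]
    if (is.null(children[[id]])) {
      tip_counter <<- tip_counter + 1L
      sprintf("t%d:%.10g", tip_counter, len)
    } else {
      sprintf("(%s,%s):%.10g", newick(children[[id]][1]),
              newick(children[[id]][2]), len)
    }
  }
  txt <- sprintf("(%s,%s);", newick(1L), newick(2L))
  parse_newick(txt)
}

#' Simulate species trait states
#'
#' Independent Bernoulli draws per indicator; states may co-occur, as in
#' species with mixed cytotypes or breeding systems.
#'
#' @param n_species number of species.
#' @param probabilities named probabilities for the states in
#'   [trait_states()] order.
#' @param seed optional integer seed.
#' @param species_ids optional species names (default `t1..tn`, matching
#'   [simulate_yule_tree()] tips).
#' @return trait data frame as from [read_traits()].
#' @export
simulate_states <- function(n_species,
                            probabilities = simulation_config()$state_probabilities,
                            seed = NULL, species_ids = NULL) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1))
  if (!is.null(seed)) set.seed(seed)
  states <- trait_states()
  probabilities <- rep_len(probabilities, length(states))
  if (is.null(species_ids)) species_ids <- paste0("t", seq_len(n_species))
  out <- data.frame(species_id = species_ids, stringsAsFactors = FALSE)
  for (j in seq_along(states)) {
    out[[states[j]]] <- stats::rbinom(n_species, 1L, probabilities[j])
  }
  out
}

#' Simulate a response under Brownian motion plus independent error
#'
#' One multivariate normal draw with mean `X beta` and covariance
#' `sigma2 * C + sigma2_error * I`, generated through a triangular
#' (Cholesky) factor of the covariance, falling back to a symmetric
#' eigendecomposition square root when the covariance is only positive
#' semi-definite. Inverts exactly the model that [fit_pglm_bm_error()]
#' estimates.
#'
#' @param tree an [ape::phylo] whose tips match the rownames of `X`.
#' @param X design matrix with species rownames.
#' @param beta coefficient vector, length `ncol(X)`.
#' @param sigma2,sigma2_error variance components (>= 0).
#' @param seed optional integer seed.
#' @return named numeric response vector in `rownames(X)` order.
#' @export
simulate_response <- function(tree, X, beta, sigma2, sigma2_error,
                              seed = NULL) {
  X <- as.matrix(X)
  stopifnot(length(beta) == ncol(X), sigma2 >= 0, sigma2_error >= 0)
  if (!setequal(rownames(X), tree$tip.label)) {
    stop("tree tips and design rownames differ")
  }
  if (!is.null(seed)) set.seed(seed)
  mu <- drop(X %*% beta)
  n <- nrow(X)
  V <- sigma2 * bm_covariance(tree)[rownames(X), rownames(X)] +
    sigma2_error * diag(n)
  if (all(V == 0)) return(stats::setNames(mu, rownames(X)))
  L <- tryCatch(t(chol(V)), error = function(e) {
    eig <- eigen(V, symmetric = TRUE)
    if (any(eig$values < -1e-8 * max(eig$values))) {
      stop("covariance is not positive semi-definite")
    }
    eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), n)
  })
  stats::setNames(mu + drop(L %*% stats::rnorm(n)), rownames(X))
}

#' Generate a synthetic discrete-class raster
#'
#' Partitions the grid interior into contiguous patches by
#' nearest-seed-point assignment (one random seed cell per class, so
#' every class is present), surrounded by a nodata margin that stands in
#' for ocean.
#'
#' @param n_classes number of classes (<= 30); labels are taken from the
#'   head of the bundled Koeppen-Geiger legend.
#' @param nrow,ncol grid dimensions.
#' @param margin width in cells of the nodata border.
#' @param xll,yll,cellsize georeferencing of the grid.
#' @param seed optional integer seed.
#' @return a [climate_raster()] object.
#' @export
make_raster <- function(n_classes, nrow = 40L, ncol = 40L, margin = 2L,
                        xll = 0, yll = 0, cellsize = 0.5, seed = NULL) {
  stopifnot(n_classes >= 1L, n_classes <= 30L,
            nrow > 2L * margin, ncol > 2L * margin)
  if (!is.null(seed)) set.seed(seed)
  legend <- utils::head(koppen_legend(), n_classes)
  inner_rows <- (margin + 1L):(nrow - margin)
  inner_cols <- (margin + 1L):(ncol - margin)
  cells <- expand.grid(row = inner_rows, col = inner_cols)
  seeds <- cells[sample.int(nrow(cells), n_classes), ]
  d2 <- outer(cells$row, seeds$row, "-")^2 + outer(cells$col, seeds$col, "-")^2
  assign <- max.col(-d2, ties.method = "first")
  grid <- matrix(-9999L, nrow = nrow, ncol = ncol)
  grid[cbind(cells$row, cells$col)] <- legend$code[assign]
  climate_raster(grid, xll = xll, yll = yll, cellsize = cellsize,
                 nodata = -9999L, legend = legend)
}

#' Sample species occurrence points on a synthetic raster
#'
#' For each species, points are assigned to classes by the given mixture
#' weights and placed uniformly at random inside a uniformly chosen cell
#' of that class. Returns both the occurrence table and the ground-truth
#' niche breadth computed from the realised per-class counts under the
#' minimum-occurrence filter, so the pipeline output can be compared
#' exactly.
#'
#' @param raster a [climate_raster()] object.
#' @param species_specs named list: per species, a list with `n_points`
#'   and `weights` (named class-mixture weights summing to 1; classes
#'   must exist in the raster).
#' @param threshold minimum-occurrence filter for the ground truth
#'   (classes with <= threshold points do not count toward breadth).
#' @param seed optional integer seed.
#' @return list with `occurrences` (data frame `species_id`, `latitude`,
#'   `longitude`) and `truth` (data frame `species_id`, `B_s`,
#'   `retained_classes`).
#' @export
sample_occurrences <- function(raster, species_specs, threshold = 3L,
                               seed = NULL) {
  stopifnot(inherits(raster, "climate_raster"))
  if (!is.null(seed)) set.seed(seed)
  present <- raster$legend$label[raster$legend$code %in%
                                   unique(as.vector(raster$grid))]
  cell_index <- which(raster$grid != raster$nodata, arr.ind = TRUE)
  cell_label <- raster$legend$label[match(raster$grid[cell_index],
                                          raster$legend$code)]
  ytop <- raster$yll + nrow(raster$grid) * raster$cellsize
  occ <- list()
  truth <- list()
  for (sp in names(species_specs)) {
    spec <- species_specs[[sp]]
    w <- spec$weights
    if (abs(sum(w) - 1) > 1e-8) stop("weights for ", sp, " must sum to 1")
    absent <- setdiff(names(w)[w > 0], present)
    if (length(absent) > 0L) {
      stop("class(es) absent from raster: ", paste(absent, collapse = ", "))
    }
    n <- spec$n_points
    if (n == 0L) {
      counts <- integer(0)
      lat <- lon <- numeric(0)
    } else {
      cls <- sample(names(w), n, replace = TRUE, prob = w)
      lat <- lon <- numeric(n)
      for (i in seq_len(n)) {
        cand <- which(cell_label == cls[i])
        pick <- cand[sample.int(length(cand), 1L)]
        r <- cell_index[pick, 1L]
        cc <- cell_index[pick, 2L]
        # uniform inside the half-open cell [west, east) x (south, north]
        lon[i] <- raster$xll + (cc - 1L + stats::runif(1L)) * raster$cellsize
        lat[i] <- ytop - (r - stats::runif(1L)) * raster$cellsize
      }
      counts <- table(cls)
    }
    retained <- sort(names(counts)[counts > threshold])
    occ[[sp]] <- data.frame(species_id = rep(sp, n), latitude = lat,
                            longitude = lon, stringsAsFactors = FALSE)
    truth[[sp]] <- data.frame(species_id = sp,
                              B_s = length(retained),
                              retained_classes = paste(retained,
                                                       collapse = ";"),
                              stringsAsFactors = FALSE)
  }
  list(occurrences = do.call(rbind, c(occ, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Generate a complete synthetic study
#'
#' Runs the whole generator: Yule tree, trait states, design matrix, the
#' model response `y ~ N(X beta, sigma2 C + sigma2_error I)`, a patch
#' raster, and per-species occurrence clouds placed to match an integer
#' breadth target derived from `y` (clamped to the available classes), so
#' both the spatial pipeline and the regression stages can be exercised
#' from one scenario.
#'
#' @param config a [simulation_config()].
#' @return list with `tree`, `traits`, `X`, `y` (model response),
#'   `raster`, `occurrences`, `truth` (ground-truth breadth table from
#'   realised occurrence counts), `breadth_target` (integer classes per
#'   species used for occurrence placement), and `config`.
#' @export
simulate_scenario <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, 6L)
  tree <- simulate_yule_tree(config$n_species, config$yule_birth_rate,
                             seed = seeds[1])
  traits <- simulate_states(config$n_species,
                            config$state_probabilities, seed = seeds[2],
                            species_ids = tree$tip.label)
  X <- build_design_matrix(traits, tree$tip.label)
  y <- simulate_response(tree, X, config$true_beta, config$sigma2,
                         config$sigma2_error, seed = seeds[3])
  raster <- make_raster(config$raster_n_classes, config$raster_nrow,
                        config$raster_ncol, config$raster_margin,
                        seed = seeds[4])
  # occurrence clouds: each species occupies round(y) classes (clamped to
  # [1, n_classes]), with enough points per class to survive the filter
  target <- pmin(pmax(round(y), 1L), config$raster_n_classes)
  set.seed(seeds[5])
  labels <- raster$legend$label
  specs <- lapply(seq_along(target), function(i) {
    k <- target[i]
    cls <- sample(labels, k)
    list(n_points = k * config$n_points_per_class,
         weights = stats::setNames(rep(1 / k, k), cls))
  })
  names(specs) <- names(target)
  samp <- sample_occurrences(raster, specs, threshold = 3L,
                             seed = seeds[6])
  list(tree = tree, traits = traits, X = X, y = y, raster = raster,
       occurrences = samp$occurrences, truth = samp$truth,
       breadth_target = target, config = config)
}
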