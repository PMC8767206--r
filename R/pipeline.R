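#' Run configuration for the end-to-end analysis
#'
#' Either all real-data paths (occurrences, raster, legend, traits, and
#' optionally a tree) or a [simulation_config()], not a mixture.
#'
#' @param occurrences,raster,legend,traits,tree input file paths (tree
#'   optional; when absent the phylogenetic stage is skipped).
#' @param synthetic a [simulation_config()] to generate all inputs
#'   instead of reading files.
#' @param threshold minimum-occurrence filter for niche breadth.
#' @param drop_zero_breadth exclude species whose every class was
#'   filtered away (breadth 0) from the regressions, with a warning; the
#'   observed minimum breadth in the real system is 1.
#' @param intersect_species if `TRUE`, proceed on the intersection of the
#'   breadth/trait/tree species sets (reporting the disjoint lists);
#'   if `FALSE`, any mismatch is an error listing them.
#' @param n_boot parametric bootstrap replicates for the phylogenetic
#'   model.
#' @param seed integer seed for the stochastic stages.
#' @param out_dir output directory (created); `NULL` to skip writing.
#' @return list of class `run_config`.
#' @export
run_config <- function(occurrences = NULL, raster = NULL, legend = NULL,
                       traits = NULL, tree = NULL, synthetic = NULL,
                       threshold = 3L, drop_zero_breadth = TRUE,
                       intersect_species = TRUE, n_boot = 100L,
                       seed = 1L, out_dir = NULL) {
  real <- !vapply(list(occurrences, raster, legend, traits), is.null,
                  logical(1))
  if (is.null(synthetic) && !all(real)) {
    stop("either supply all of occurrences/raster/legend/traits paths ",
         "or a simulation_config")
  }
  if (!is.null(synthetic) && any(real)) {
    stop("supply real-data paths or a synthetic config, not both")
  }
  structure(as.list(environment())[c("occurrences", "raster", "legend",
                                     "traits", "tree", "synthetic",
                                     "threshold", "drop_zero_breadth",
                                     "intersect_species", "n_boot",
                                     "seed", "out_dir")],
            class = "run_config")
}

#' Per state-combination niche-breadth summaries
#'
#' One row per observed breeding-system x ploidy state combination (the
#' data behind a by-combination boxplot), with count, mean, median and
#' quartiles of breadth. Combination keys are order-invariant: the states
#' a species carries, joined by `+` in [trait_states()] order, or
#' `"none"`.
#'
#' @param breadth breadth table from [niche_breadth()].
#' @param traits trait data frame from [read_traits()].
#' @return data frame with `combination`, `n`, `mean`, `median`, `q1`,
#'   `q3`, `min`, `max`.
#' @export
group_summaries <- function(breadth, traits) {
  states <- trait_states()
  idx <- match(breadth$species_id, traits$species_id)
  combo <- vapply(idx, function(i) {
    if (is.na(i)) return(NA_character_)
    on <- states[unlist(traits[i, states]) > 0]
    if (length(on) == 0L) "none" else paste(on, collapse = "+")
  }, character(1))
  keep <- !is.na(combo)
  sp <- split(breadth$B_s[keep], combo[keep])
  out <- do.call(rbind, lapply(names(sp), function(key) {
    b <- sp[[key]]
    q <- stats::quantile(b, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(combination = key, n = length(b), mean = mean(b),
               q1 = q[1], median = q[2], q3 = q[3],
               min = min(b), max = max(b), stringsAsFactors = FALSE)
  }))
  out[order(out$combination), c("combination", "n", "mean", "median",
                                "q1", "q3", "min", "max")]
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

fit_to_list <- function(fit) {
  base <- list(beta = as.list(fit$beta), se = as.list(fit$se),
               p_values = as.list(fit$p_values), n_obs = fit$n_obs,
               R2 = fit$R2, adjusted_R2 = fit$adjusted_R2,
               residual_se = fit$residual_se,
               residual_df = fit$residual_df)
  if (inherits(fit, "ols_fit")) {
    c(base, list(F_stat = fit$F_stat, F_df = fit$F_df))
  } else {
    c(base, list(sigma2 = fit$sigma2, sigma2_error = fit$sigma2_error,
                 gamma = fit$gamma, loglik = fit$loglik,
                 note = fit$note))
  }
}

#' Run the full niche-breadth analysis
#'
#' Orchestrates the pipeline: occurrences -> climate-class tallies ->
#' minimum-occurrence filter -> niche breadth; trait table -> design
#' matrix; OLS fit; and, when a tree is available, the phylogenetic
#' linear model with parametric-bootstrap intervals. Species dropped at
#' every join are recorded by name in the manifest. With an `out_dir`
#' set, writes `breadth.tsv`, `ols_table.tsv`, `ols_fit.json`,
#' `pglm_table.tsv`, `pglm_fit.json`, `bootstrap.tsv`,
#' `group_summary.tsv` and `manifest.json`; re-running with the same
#' config and seed reproduces every file byte-for-byte.
#'
#' @param config a [run_config()].
#' @return list with `breadth`, `traits`, `ols`, `pglm` (or `NULL`),
#'   `bootstrap`, `groups`, `manifest`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  manifest <- list(seed = config$seed, threshold = config$threshold,
                   package_version =
                     as.character(utils::packageVersion("nichebreadth")))

  if (!is.null(config$synthetic)) {
    scen <- simulate_scenario(config$synthetic)
    occ <- scen$occurrences
    raster <- scen$raster
    traits <- scen$traits
    tree <- scen$tree
    manifest$input <- "synthetic"
  } else {
    occ <- read_occurrences(config$occurrences)
    raster <- read_ascii_raster(config$raster, legend = config$legend)
    traits <- read_traits(config$traits)
    tree <- if (!is.null(config$tree)) parse_newick(config$tree) else NULL
    manifest$input <- "files"
    manifest$n_dropped_coordinates <- attr(occ, "n_dropped")
  }

  tally <- tally_classes(occ, raster)
  filtered <- filter_min_occurrences(tally, config$threshold)
  breadth <- niche_breadth(filtered)
  manifest$n_species_breadth <- nrow(breadth)
  manifest$n_nodata_points <- sum(attr(tally, "n_nodata"))

  zero <- breadth$species_id[breadth$B_s == 0]
  model_breadth <- breadth
  if (config$drop_zero_breadth && length(zero) > 0L) {
    warning(length(zero), " species with breadth 0 excluded from the ",
            "regressions: ", paste(zero, collapse = ", "))
    model_breadth <- breadth[breadth$B_s > 0, ]
  }
  manifest$zero_breadth_species <- as.list(zero)

  # OLS join: breadth x traits
  ols_species <- intersect(model_breadth$species_id, traits$species_id)
  only_breadth <- setdiff(model_breadth$species_id, traits$species_id)
  only_traits <- setdiff(traits$species_id, model_breadth$species_id)
  if (!config$intersect_species &&
      (length(only_breadth) || length(only_traits))) {
    stop("species mismatch between breadth and traits; breadth-only: ",
         paste(only_breadth, collapse = ", "), "; trait-only: ",
         paste(only_traits, collapse = ", "))
  }
  manifest$ols <- list(n_species = length(ols_species),
                       dropped_no_traits = as.list(only_breadth),
                       dropped_no_breadth = as.list(only_traits))
  ols_species <- sort(ols_species)
  X <- build_design_matrix(traits, ols_species)
  y <- stats::setNames(
    model_breadth$B_s[match(ols_species, model_breadth$species_id)],
    ols_species)
  ols <- fit_ols(X, y)
  manifest$baseline_species <- as.list(baseline_species(X))

  pglm <- NULL
  boot <- NULL
  if (!is.null(tree)) {
    pg_species <- intersect(ols_species, tree$tip.label)
    dropped_no_tip <- setdiff(ols_species, tree$tip.label)
    pruned_tips <- setdiff(tree$tip.label, ols_species)
    if (!config$intersect_species && length(dropped_no_tip)) {
      stop("species absent from tree: ",
           paste(dropped_no_tip, collapse = ", "))
    }
    manifest$pglm <- list(n_species = length(pg_species),
                          dropped_no_tip = as.list(dropped_no_tip),
                          pruned_tree_tips = as.list(pruned_tips),
                          species = as.list(sort(pg_species)))
    if (length(pg_species) >= 4L) {
      ptree <- prune_to_taxa(tree, pg_species)
      pglm <- fit_pglm_bm_error(X[pg_species, , drop = FALSE],
                                y[pg_species], ptree)
      boot <- parametric_bootstrap(pglm, n_boot = config$n_boot,
                                   seed = config$seed)
      manifest$pglm$n_boot <- attr(boot, "n_boot")
      manifest$pglm$n_boot_dropped <- attr(boot, "n_dropped")
    } else {
      message("fewer than 4 species shared with the tree; ",
              "phylogenetic stage skipped")
    }
  } else {
    message("no tree supplied; phylogenetic stage skipped")
  }

  groups <- group_summaries(model_breadth, traits)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_tsv(breadth, p("breadth.tsv"))
    write_tsv(summarize_ols(ols), p("ols_table.tsv"))
    jsonlite::write_json(fit_to_list(ols), p("ols_fit.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_tsv(groups, p("group_summary.tsv"))
    if (!is.null(pglm)) {
      ptab <- summarize_ols(pglm)
      ptab <- ptab[ptab$term != "F statistic", ]
      extra <- data.frame(
        term = c("sigma^2", "sigma^2 error", "parametric bootstraps"),
        value = c(format_interval(pglm$sigma2, boot, "sigma2"),
                  format_interval(pglm$sigma2_error, boot, "sigma2_error"),
                  as.character(attr(boot, "n_boot"))),
        stringsAsFactors = FALSE)
      write_tsv(rbind(ptab, extra), p("pglm_table.tsv"))
      jsonlite::write_json(fit_to_list(pglm), p("pglm_fit.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write_tsv(boot, p("bootstrap.tsv"))
    }
    jsonlite::write_json(manifest, p("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(breadth = breadth, traits = traits, ols = ols, pglm = pglm,
       bootstrap = boot, groups = groups, manifest = manifest)
}

format_interval <- function(est, boot, par) {
  row <- boot[boot$parameter == par, ]
  if (nrow(row) == 0L || is.na(row$lower)) return(format(est, digits = 6))
  sprintf("%s (%s, %s)", format(est, digits = 6),
          format(row$lower, digits = 6), format(row$upper, digits = 6))
}
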