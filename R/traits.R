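#' The four breeding-system x ploidy indicator states
#'
#' Fixed column order used throughout: self-incompatible diploid,
#' self-compatible diploid, self-compatible polyploid, asexually
#' propagating diploid. The states are NOT mutually exclusive: a species
#' with mixed populations or cytotypes can carry several.
#'
#' @return character vector of the four state names.
#' @export
trait_states <- function() {
  c("SI_diploid", "SC_diploid", "SC_polyploid", "asexual_diploid")
}

#' Read a species trait table
#'
#' Accepts either dialect: wide (one row per species with a 0/1 column per
#' state) or long (rows of `species,state`, one row per state a species
#' carries). Duplicate species rows are merged by set union with a
#' warning; unrecognised state labels are an error.
#'
#' @param source path to a CSV, or a data frame.
#' @param format `"wide"` or `"long"`.
#' @param species_col name of the species column.
#' @param state_col name of the state column (long format only).
#' @return data frame with `species_id` plus one integer 0/1 column per
#'   state in [trait_states()] order. An all-zero row means the species'
#'   breeding system/ploidy combination is unknown.
#' @export
read_traits <- function(source, format = c("wide", "long"),
                        species_col = "species", state_col = "state") {
  format <- match.arg(format)
  tab <- if (is.data.frame(source)) source else {
    utils::read.csv(source, stringsAsFactors = FALSE)
  }
  if (!species_col %in% names(tab)) {
    stop("trait table lacks species column '", species_col, "'")
  }
  states <- trait_states()
  if (format == "long") {
    if (!state_col %in% names(tab)) {
      stop("long trait table lacks state column '", state_col, "'")
    }
    bad <- setdiff(unique(tab[[state_col]]), states)
    if (length(bad) > 0L) {
      stop("unknown trait state label(s): ", paste(bad, collapse = ", "),
           " (expected one of ", paste(states, collapse = ", "), ")")
    }
    species <- unique(as.character(tab[[species_col]]))
    m <- matrix(0L, length(species), length(states),
                dimnames = list(species, states))
    m[cbind(match(tab[[species_col]], species),
            match(tab[[state_col]], states))] <- 1L
    out <- data.frame(species_id = species, m, stringsAsFactors = FALSE,
                      row.names = NULL)
  } else {
    present <- intersect(states, names(tab))
    extra <- setdiff(names(tab), c(species_col, states))
    if (length(present) == 0L) {
      stop("wide trait table has none of the state columns ",
           paste(states, collapse = ", "))
    }
    if (length(extra) > 0L) {
      stop("unknown trait state column(s): ", paste(extra, collapse = ", "))
    }
    out <- data.frame(species_id = as.character(tab[[species_col]]),
                      stringsAsFactors = FALSE)
    for (s in states) {
      v <- if (s %in% present) as.integer(tab[[s]] != 0) else 0L
      out[[s]] <- v
    }
    if (anyDuplicated(out$species_id)) {
      warning("duplicate species rows merged by state union")
      out <- stats::aggregate(out[states], by = list(species_id = out$species_id),
                              FUN = function(x) as.integer(any(x > 0)))
    }
  }
  out[c("species_id", states)]
}

#' Build the regression design matrix
#'
#' Assembles the intercept-plus-four-indicator design matrix in a declared
#' species order. Indicators are non-exclusive, so a multi-state species
#' has several 1s in its row; the intercept estimates the niche breadth of
#' a species carrying none of the four flags.
#'
#' @param traits trait data frame from [read_traits()].
#' @param species_order character vector giving the row order; must match
#'   the response vector's species order exactly.
#' @param allow_missing if `TRUE`, species absent from `traits` default to
#'   the empty state set; if `FALSE` (default) they are an error.
#' @return numeric matrix with rownames `species_order` and columns
#'   `(Intercept)` plus [trait_states()].
#' @export
build_design_matrix <- function(traits, species_order,
                                allow_missing = FALSE) {
  states <- trait_states()
  idx <- match(species_order, traits$species_id)
  if (anyNA(idx) && !allow_missing) {
    stop("species missing from trait table: ",
         paste(species_order[is.na(idx)], collapse = ", "))
  }
  X <- matrix(0, nrow = length(species_order), ncol = 1L + length(states),
              dimnames = list(species_order, c("(Intercept)", states)))
  X[, "(Intercept)"] <- 1
  for (s in states) {
    v <- traits[[s]][idx]
    v[is.na(v)] <- 0L
    X[, s] <- v
  }
  X
}

#' Species in the implicit baseline category
#'
#' Lists the species whose design-matrix row carries none of the four
#' breeding-system x ploidy indicators, i.e. the species whose expected
#' breadth is the intercept alone. Reported so the baseline is auditable.
#'
#' @param X design matrix from [build_design_matrix()].
#' @return character vector of baseline species.
#' @export
baseline_species <- function(X) {
  rownames(X)[rowSums(X[, trait_states(), drop = FALSE]) == 0]
}
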