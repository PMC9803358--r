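## Synthetic element trees with planted rate shifts.
##
## Element branch lengths are the master branch lengths scaled by a log-normal
## element rate, multiplied by (1 + delta) on foreground branches of
## responsive elements, with multiplicative log-normal noise per branch,
## optional species dropout, and an optional body-size-correlated rate
## multiplier for confounded elements.

#' Simulation configuration
#'
#' @param n_elements number of element trees to generate.
#' @param fraction_responsive fraction of elements carrying the planted
#'   foreground acceleration (or the confounder, in
#'   [simulate_confounded()]), in `[0, 1]`.
#' @param delta foreground acceleration: responsive-element branch lengths on
#'   foreground branches are multiplied by `1 + delta` (`delta >= 0`; 0 is the
#'   null).
#' @param sigma standard deviation of the per-branch log-normal noise
#'   (`> 0`).
#' @param dropout_prob probability that a species is missing from an element,
#'   independently per species and element, in `[0, 1)`.
#' @param rate_meanlog,rate_sdlog log-normal parameters of the overall element
#'   rate.
#' @param confounder_slope slope of the body-size rate multiplier
#'   `exp(slope * trait)` applied to confounded elements. The default 0.02
#'   spreads rates about 1.3-fold across the log-weight range of the bundled
#'   mammal table, a moderate body-size effect; the linear covariate
#'   regression fully removes effects of this size, while much stronger
#'   multiplicative confounding leaves a nonlinear residue (see the methods
#'   vignette).
#' @param seed integer seed; every random draw in the generators flows from
#'   it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_elements = 1000, fraction_responsive = 0.1,
                              delta = 1, sigma = 0.1, dropout_prob = 0.05,
                              rate_meanlog = 0, rate_sdlog = 0.5,
                              confounder_slope = 0.02, seed = 1) {
  stopifnot(n_elements >= 1, fraction_responsive >= 0, fraction_responsive <= 1,
            delta >= 0, sigma > 0, dropout_prob >= 0, dropout_prob < 1)
  structure(list(n_elements = as.integer(n_elements),
                 fraction_responsive = fraction_responsive, delta = delta,
                 sigma = sigma, dropout_prob = dropout_prob,
                 rate_meanlog = rate_meanlog, rate_sdlog = rate_sdlog,
                 confounder_slope = confounder_slope, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate element trees with planted foreground rate shifts
#'
#' @param config a [simulation_config()].
#' @param tree a `master_tree`.
#' @param phenotype a `binary_phenotype` on `tree`; its branches receive the
#'   `(1 + delta)` acceleration in responsive elements.
#' @return list with `elements` (named list of `phylo`, `NULL` where fewer
#'   than two species survived dropout) and `truth` (data.frame with
#'   `element_id`, `responsive`, `n_species`).
#' @export
simulate_elements <- function(config, tree, phenotype) {
  simulate_element_set(config, tree, phenotype = phenotype, trait = NULL)
}

#' Simulate element trees with a body-size-correlated rate confounder
#'
#' Confounded elements receive a per-branch multiplier
#' `exp(confounder_slope * trait_b)`; with `delta = 0` this creates null
#' elements whose rates track the confounder, the scenario the covariate
#' regression must neutralize.
#'
#' @inheritParams simulate_elements
#' @param trait a `continuous_trait` defined on all master branches.
#' @param phenotype optional; when supplied (and `delta > 0`) responsive
#'   elements also carry the foreground acceleration.
#' @return as [simulate_elements()]; `truth` gains a `confounded` column.
#' @export
simulate_confounded <- function(config, tree, trait, phenotype = NULL) {
  bv <- if (inherits(trait, "continuous_trait")) trait$branch_values else trait
  if (anyNA(bv[tree$branch_names]))
    stop("trait must be defined on all master branches")
  simulate_element_set(config, tree, phenotype = phenotype, trait = bv)
}

simulate_element_set <- function(config, tree, phenotype, trait) {
  if (!is.null(phenotype) && max(phenotype$branch_index) > tree$n_branches)
    stop("phenotype is not defined on this master tree")
  set.seed(config$seed)
  n <- config$n_elements
  ids <- sprintf("elem%05d", seq_len(n))
  n_resp <- round(config$fraction_responsive * n)
  responsive <- c(rep(TRUE, n_resp), rep(FALSE, n - n_resp))

  fg_mult <- rep(1, tree$n_branches)
  if (!is.null(phenotype))
    fg_mult[phenotype$branch_index] <- 1 + config$delta
  conf_mult <- if (is.null(trait)) rep(1, tree$n_branches) else
    exp(config$confounder_slope * trait[tree$branch_names])

  elements <- vector("list", n)
  names(elements) <- ids
  n_species <- integer(n)
  for (e in seq_len(n)) {
    r_e <- stats::rlnorm(1, config$rate_meanlog, config$rate_sdlog)
    noise <- exp(stats::rnorm(tree$n_branches, 0, config$sigma))
    len <- r_e * tree$branch_lengths * noise
    if (responsive[e]) {
      len <- len * fg_mult
      if (!is.null(trait)) len <- len * conf_mult
    }
    keep <- stats::runif(tree$n_tips) >= config$dropout_prob
    n_species[e] <- sum(keep)
    if (n_species[e] < 2L) next
    phy <- tree$phy
    phy$edge.length <- unname(len)
    if (!all(keep)) phy <- ape::keep.tip(phy, tree$phy$tip.label[keep])
    elements[[e]] <- phy
  }
  truth <- data.frame(element_id = ids, responsive = responsive,
                      n_species = n_species, stringsAsFactors = FALSE)
  if (!is.null(trait)) truth$confounded <- responsive
  list(elements = elements, truth = truth)
}

#' Build fixture geneset annotations from a simulation truth table
#'
#' One `"hair"` set containing the responsive elements (optionally diluted
#' with nulls) plus size-matched random decoy sets.
#'
#' @param truth truth table from [simulate_elements()].
#' @param n_decoy_sets number of random decoy sets.
#' @param seed integer seed.
#' @param dilution fraction of the hair set replaced by random null elements.
#' @return an annotation map: named list of element-id character vectors.
#' @export
make_fixture_annotations <- function(truth, n_decoy_sets = 10, seed = 1,
                                     dilution = 0) {
  set.seed(seed)
  resp <- truth$element_id[truth$responsive]
  all_ids <- truth$element_id
  sets <- list()
  if (length(resp)) {
    hair <- resp
    if (dilution > 0) {
      n_swap <- round(dilution * length(hair))
      if (n_swap > 0) {
        hair <- c(sample(resp, length(resp) - n_swap),
                  sample(setdiff(all_ids, resp), n_swap))
      }
    }
    sets$hair <- sort(hair)
  }
  size <- max(2L, length(resp))
  for (k in seq_len(n_decoy_sets))
    sets[[paste0("decoy", sprintf("%02d", k))]] <- sort(sample(all_ids, size))
  structure(sets, provenance = "synthetic fixture")
}

#' Write / read element trees as a two-column table of Newick strings
#' @param elements named list of `phylo` (NULL entries are skipped).
#' @param file path.
#' @export
write_element_trees <- function(elements, file) {
  keep <- !vapply(elements, is.null, logical(1))
  lines <- vapply(which(keep), function(i)
    paste0(names(elements)[i], "\t", ape::write.tree(elements[[i]])),
    character(1))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_element_trees
#' @export
read_element_trees <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  trees <- lapply(parts, function(p) ape::read.tree(text = p[[2L]]))
  stats::setNames(trees, ids)
}
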