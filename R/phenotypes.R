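## Species phenotype table and the standard foreground sets.

#' Read a species phenotype table
#'
#' Tab-separated with columns `species` (genome assembly code), `hairless`
#' (0/1), `marine` (0/1) and `adult_weight_g`. The bundled table
#' (`phenotypes_synthetic.tsv`) carries the published hairless/marine
#' classification of the 62 mammals; its adult weights are synthetic
#' order-of-magnitude stand-ins for the database values used originally.
#'
#' @param file path to the table; default is the bundled table.
#' @return a data.frame with one row per species.
#' @export
read_phenotypes <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "phenotypes_synthetic.tsv",
                        package = "rershift", mustWork = TRUE)
  ph <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("species", "hairless", "marine", "adult_weight_g")
  miss <- setdiff(need, names(ph))
  if (length(miss)) stop("phenotype table lacks column(s): ",
                         paste(miss, collapse = ", "))
  ph
}

#' Hairless foreground on the master tree
#'
#' Ten extant hairless species plus the cetacean (dolphin-orca) ancestor.
#' The elephant-manatee ancestor, although both its daughters are hairless, is
#' kept background: extinct woolly mammoths show the elephant lineage was
#' haired after the split, so independent losses are the parsimonious reading.
#'
#' @param tree a `master_tree`.
#' @param phenotypes phenotype table from [read_phenotypes()].
#' @return a `binary_phenotype` with 11 foreground branches.
#' @export
hairless_foreground <- function(tree, phenotypes = read_phenotypes()) {
  extant <- phenotypes$species[phenotypes$hairless == 1]
  exclude <- character()
  if (all(c("loxAfr3", "triMan1") %in% extant)) {
    b <- tryCatch(mrca_branch(tree, c("loxAfr3", "triMan1")),
                  error = function(e) NULL)
    # exclude only if that ancestor would be picked up by the descendants rule
    if (!is.null(b)) exclude <- b
  }
  assign_foreground(tree, extant, ancestral_rule = TRUE,
                    exclude = exclude, label = "hairless")
}

#' Marine foreground on the master tree
#'
#' Extant marine species plus the cetacean ancestor only; no other ancestral
#' branch is marked even where marine tips are sisters (the pinniped ancestor
#' was plausibly amphibious rather than fully marine).
#'
#' @inheritParams hairless_foreground
#' @return a `binary_phenotype`.
#' @export
marine_foreground <- function(tree, phenotypes = read_phenotypes()) {
  extant <- phenotypes$species[phenotypes$marine == 1]
  ph <- assign_foreground(tree, extant, ancestral_rule = FALSE, label = "marine")
  cet <- intersect(c("turTru2", "orcOrc1"), extant)
  if (length(cet) == 2L) {
    anc <- mrca_branch(tree, cet)
    idx <- sort(union(ph$branch_index, match(anc, tree$branch_names)))
    ph$branch_index <- idx
    ph$branch_names <- tree$branch_names[idx]
    ph$n_ancestral <- sum(!tree$is_tip_branch[idx])
    ph$n_extant <- sum(tree$is_tip_branch[idx])
  }
  ph
}

#' Branch-wise log body size trait
#'
#' Log adult weight reconstructed over the whole tree by maximum likelihood
#' under Brownian motion; used as the continuous confounder regressed out of
#' relative rates.
#'
#' @inheritParams hairless_foreground
#' @return a `continuous_trait` with `branch_values` on every master branch.
#' @export
body_size_trait <- function(tree, phenotypes = read_phenotypes()) {
  w <- stats::setNames(log(phenotypes$adult_weight_g), phenotypes$species)
  ancestral_states(tree, w)
}
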