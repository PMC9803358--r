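## End-to-end orchestration: relative rates -> covariate regression ->
## association -> permulations -> Bayes factors -> enrichment ->
## species-specific tests, with every table written alongside a resolved
## configuration and provenance headers.

#' Pipeline run configuration
#'
#' Bundles input objects and the analysis parameters with their standard
#' defaults (minimum species per element 10, 1000 permulations with 10
#' foreground tips, BF prior scale sqrt(2)/2, significance threshold 0.05,
#' 10 kb proximity window).
#'
#' @param tree a `master_tree`.
#' @param elements named list of element `phylo` trees (or `NULL` if `rers`
#'   given).
#' @param rers optional precomputed RER matrix (skips [compute_rer()]).
#' @param phenotype a `binary_phenotype` (the phenotype of interest).
#' @param phenotype_b optional competing `binary_phenotype` for the Bayes
#'   factor contrast.
#' @param trait optional `continuous_trait` regressed out of the rates.
#' @param annotation optional annotation map for enrichment.
#' @param out_dir output directory for result tables.
#' @param min_species,min_set,n_null,k_extant,bf_scale,alpha,window analysis
#'   parameters; defaults as above.
#' @param seed integer seed governing the permulations.
#' @return a `run_config` list.
#' @export
run_config <- function(tree, elements = NULL, rers = NULL, phenotype,
                       phenotype_b = NULL, trait = NULL, annotation = NULL,
                       out_dir = tempfile("rershift_run_"), min_species = 10,
                       min_set = 10, n_null = 1000, k_extant = 10,
                       bf_scale = sqrt(2) / 2, alpha = 0.05, window = 10000,
                       seed = 1) {
  if (is.null(elements) && is.null(rers))
    stop("provide 'elements' or a precomputed 'rers' matrix")
  structure(list(tree = tree, elements = elements, rers = rers,
                 phenotype = phenotype, phenotype_b = phenotype_b,
                 trait = trait, annotation = annotation, out_dir = out_dir,
                 min_species = min_species, min_set = min_set,
                 n_null = n_null, k_extant = k_extant, bf_scale = bf_scale,
                 alpha = alpha, window = window, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage configured in `config` and writes tab-separated
#' result tables under `config$out_dir`, each with a header recording the
#' seed and parameter values. Stage failures abort with the stage name.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with `rers`, `association`, `bayes`,
#'   `enrichment`, `species`, `nulls`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(seed = config$seed, n_null = config$n_null,
            k_extant = config$k_extant, min_species = config$min_species,
            alpha = config$alpha)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  rers <- stage("rer", {
    if (!is.null(config$rers)) config$rers
    else compute_rer(config$elements, config$tree,
                     min_species = config$min_species)
  })
  if (!is.null(config$trait))
    rers <- stage("regress_covariate", regress_covariate(rers, config$trait))
  write_result_table(
    data.frame(branch = rownames(rers), rers, check.names = FALSE),
    file.path(config$out_dir, "rer_matrix.tsv"), meta)

  assoc <- stage("association", associate(rers, config$phenotype))
  nulls <- stage("permulation",
                 permulate_binary(config$tree, k_extant = config$k_extant,
                                  n_null = config$n_null, seed = config$seed,
                                  n_ancestral = config$phenotype$n_ancestral))
  assoc <- stage("permulation_pvalues",
                 permulation_pvalues(rers, assoc, nulls))
  null_stats <- attr(assoc, "null_stats")
  null_p <- attr(assoc, "null_p")

  bayes <- NULL
  if (!is.null(config$phenotype_b)) {
    bayes <- stage("bayes", bf_contrast(rers, config$phenotype,
                                        config$phenotype_b,
                                        rscale = config$bf_scale))
    assoc <- cbind(assoc, bayes[, -1, drop = FALSE])
  }
  write_result_table(assoc, file.path(config$out_dir, "association.tsv"),
                     meta)
  qq <- stage("qq", qq_uniformity(assoc$permp))
  write_result_table(qq$quantiles, file.path(config$out_dir, "qq_permp.tsv"),
                     c(meta, ks_stat = qq$ks_stat, ks_p = qq$ks_p))

  enr <- NULL
  if (!is.null(config$annotation)) {
    scores <- stage("rank_scores", rank_scores(assoc))
    enr <- stage("enrichment",
                 wilcoxon_enrich(scores, config$annotation,
                                 min_set = config$min_set))
    if (nrow(enr)) {
      enr <- stage("enrich_permp",
                   enrich_permp(null_stats, null_p, config$annotation,
                                enr, scored_elements = names(scores)))
    }
    write_result_table(enr, file.path(config$out_dir, "enrichment.tsv"), meta)
  }

  species <- NULL
  fg_tips <- intersect(config$phenotype$branch_names, rownames(rers))
  fg_tips <- fg_tips[fg_tips %in% config$tree$phy$tip.label]
  if (length(fg_tips) >= 1) {
    species <- stage("species_specific",
                     species_shift_table(
                       rers[config$tree$phy$tip.label[
                         config$tree$phy$tip.label %in% rownames(rers)], ,
                         drop = FALSE],
                       focal_species = fg_tips))
    counts <- count_significant_species(species, alpha = config$alpha)
    write_result_table(
      data.frame(element_id = names(counts), n_significant_species = counts),
      file.path(config$out_dir, "species_counts.tsv"), meta)
  }

  invisible(list(rers = rers, association = assoc, bayes = bayes,
                 enrichment = enr, species = species, nulls = nulls))
}

#' Write a result table with provenance header comments
#' @param df data.frame.
#' @param file path.
#' @param meta named vector written as `# key: value` lines.
#' @export
write_result_table <- function(df, file, meta = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(paste0("# ", names(meta), ": ", unname(meta)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(file)
}

#' Read a result table written by [write_result_table()]
#' @param file path.
#' @export
read_result_table <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, na.strings = "",
                    stringsAsFactors = FALSE)
}
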