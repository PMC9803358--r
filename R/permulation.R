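## Phylogenetically constrained null phenotypes ("permulations") and
## empirical p-values.
##
## A null phenotype is drawn by simulating a Brownian motion trait on the
## master tree, marking the k largest tip values foreground, and
## backpropagating by the all-descendants rule; draws are accepted only when
## the resulting foreground matches the observed structure (k extant tips and
## a fixed number of ancestral branches), so every null preserves the species
## relationships and the phenotype's clade organization.

#' Generate accepted binary permulations
#'
#' @param tree a `master_tree`.
#' @param k_extant number of foreground tips per null (default 10).
#' @param n_null number of accepted null phenotypes required.
#' @param seed integer seed.
#' @param n_ancestral required number of ancestral foreground branches after
#'   backpropagation (default 1, matching a phenotype with a single
#'   foreground cherry).
#' @param max_attempts rejection-sampling budget; exceeded -> error reporting
#'   the acceptance rate.
#' @return a `null_phenotype_set`: list with `phenotypes` (list of
#'   `binary_phenotype`), `seed`, `n_attempted`, `n_accepted`,
#'   `acceptance_rate`.
#' @export
permulate_binary <- function(tree, k_extant = 10, n_null = 1000, seed = 1,
                             n_ancestral = 1, max_attempts = 200 * n_null) {
  stopifnot(n_null >= 1, k_extant >= 1)
  k_extant <- as.integer(k_extant)
  if (k_extant >= tree$n_tips)
    stop("'k_extant' must be smaller than the number of tips")
  set.seed(seed)
  sqlen <- sqrt(tree$branch_lengths)
  P <- t(tree$tip_desc) * 1                    # tip x branch path indicator
  internal <- which(!tree$is_tip_branch)
  M_int <- tree$tip_desc[internal, , drop = FALSE] * 1
  n_desc_int <- lengths(tree$desc_tips)[internal]

  accepted <- vector("list", n_null)
  n_acc <- 0L
  n_att <- 0L
  batch <- max(64L, min(2048L, n_null))
  while (n_acc < n_null) {
    if (n_att >= max_attempts)
      stop("max_attempts (", max_attempts, ") exhausted with ", n_acc, "/",
           n_null, " accepted (acceptance rate ",
           signif(n_acc / n_att, 3), ")")
    b <- min(batch, max_attempts - n_att)
    Z <- matrix(stats::rnorm(tree$n_branches * b), tree$n_branches, b)
    tipv <- P %*% (sqlen * Z)                  # tips x b
    for (j in seq_len(b)) {
      n_att <- n_att + 1L
      fg_tips <- integer(tree$n_tips)
      fg_tips[order(tipv[, j], decreasing = TRUE)[seq_len(k_extant)]] <- 1L
      anc_fg <- which(as.vector(M_int %*% fg_tips) == n_desc_int)
      if (length(anc_fg) != n_ancestral) next
      idx <- sort(c(which(tree$is_tip_branch &
                            fg_tips[pmin(tree$branch_child, tree$n_tips)] == 1L &
                            tree$branch_child <= tree$n_tips),
                    internal[anc_fg]))
      n_acc <- n_acc + 1L
      accepted[[n_acc]] <- structure(list(
        branch_index = idx,
        branch_names = tree$branch_names[idx],
        label = paste0("null", n_acc),
        n_extant = k_extant,
        n_ancestral = length(anc_fg)  # integers by construction
      ), class = "binary_phenotype")
      if (n_acc == n_null) break
    }
  }
  structure(list(phenotypes = accepted, seed = seed, k_extant = k_extant,
                 n_ancestral = n_ancestral, n_attempted = n_att,
                 n_accepted = n_acc, acceptance_rate = n_acc / n_att),
            class = "null_phenotype_set")
}

#' @export
print.null_phenotype_set <- function(x, ...) {
  cat("null_phenotype_set:", x$n_accepted, "accepted /", x$n_attempted,
      "attempted (rate", signif(x$acceptance_rate, 3), "), k_extant =",
      x$k_extant, "\n")
  invisible(x)
}

#' Empirical (permulation) p-value
#'
#' Proportion of null statistics as extreme or more extreme than the observed
#' statistic; an exact zero is replaced by `floor` (by default `1/N`, the
#' smallest observable permulation p-value). With the default
#' `alternative = "two.sided"`, "as extreme" compares magnitudes
#' (`|null| >= |observed|`), which makes the empirical p uniform under the
#' null; the statistic's sign still carries the direction of the effect.
#' `alternative = "directional"` counts only nulls beyond the observed value
#' on its own side (support then caps at ~0.5 under a symmetric null).
#'
#' @param observed observed statistic (NA -> NA).
#' @param null_stats numeric vector of null statistics (NAs dropped).
#' @param floor replacement for a zero count; default `1/length(null_stats)`
#'   after NA removal.
#' @param alternative `"two.sided"` (default) or `"directional"`.
#' @return the empirical p-value.
#' @export
empirical_p <- function(observed, null_stats, floor = NULL,
                        alternative = c("two.sided", "directional")) {
  alternative <- match.arg(alternative)
  if (is.na(observed)) return(NA_real_)
  nulls <- null_stats[!is.na(null_stats)]
  if (length(nulls) == 0L) return(NA_real_)
  if (is.null(floor)) floor <- 1 / length(nulls)
  cnt <- if (alternative == "two.sided") sum(abs(nulls) >= abs(observed))
  else if (observed >= 0) sum(nulls >= observed)
  else sum(nulls <= observed)
  p <- cnt / length(nulls)
  if (p == 0) p <- floor
  p
}

#' Permulation p-values for an association result table
#'
#' Recomputes the association statistic for every element under every null
#' phenotype, converts observed statistics to empirical p-values with
#' [empirical_p()], and BH-adjusts across elements. The per-element null
#' statistics (and their parametric p-values, needed for geneset permulation)
#' are attached as attributes `"null_stats"` and `"null_p"`
#' (element x null matrices).
#'
#' @param rers RER matrix (branches x elements).
#' @param observed association table from [associate()].
#' @param nulls a `null_phenotype_set` generated on the same master tree.
#' @param floor zero-replacement for empirical p-values; default
#'   `1/n_null`.
#' @param low_confidence_frac flag elements whose statistic is missing under
#'   more than this fraction of nulls (default 0.1).
#' @return `observed` with columns `permp`, `permp_adj`, `low_confidence`
#'   appended, plus the cache attributes.
#' @export
permulation_pvalues <- function(rers, observed, nulls, floor = NULL,
                                low_confidence_frac = 0.1,
                                alternative = c("two.sided", "directional")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(nulls, "null_phenotype_set"))
  if (!identical(observed$element_id, colnames(rers)))
    stop("'observed' rows must match the RER matrix columns")
  n_null <- nulls$n_accepted
  if (is.null(floor)) floor <- 1 / n_null
  Fm <- matrix(0, nrow(rers), n_null,
               dimnames = list(rownames(rers), NULL))
  for (k in seq_len(n_null)) {
    idx <- match(nulls$phenotypes[[k]]$branch_names, rownames(rers))
    if (anyNA(idx)) stop("null phenotype ", k, " has branches missing from ",
                         "the RER matrix (different master tree?)")
    Fm[idx, k] <- 1
  }
  nb <- kendall_binary_matrix(rers, Fm)
  permp <- vapply(seq_len(nrow(observed)), function(e)
    empirical_p(observed$statistic[e], nb$tau[e, ], floor = floor,
                alternative = alternative),
    numeric(1))
  out <- observed
  out$permp <- permp
  out$permp_adj <- bh_adjust(permp)
  out$low_confidence <- rowMeans(is.na(nb$tau)) > low_confidence_frac
  attr(out, "null_stats") <- nb$tau
  attr(out, "null_p") <- nb$p
  out
}

#' Write / read the foreground branch lists of a null phenotype set
#' @param nulls a `null_phenotype_set`.
#' @param file path (tab-separated: null index, comma-joined branch names).
#' @export
write_null_store <- function(nulls, file) {
  lines <- vapply(seq_len(nulls$n_accepted), function(k)
    paste0(k, "\t", paste(nulls$phenotypes[[k]]$branch_names, collapse = ",")),
    character(1))
  writeLines(c("# permulation null store", paste0("# seed: ", nulls$seed),
               lines), file)
  invisible(file)
}
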