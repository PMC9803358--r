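## Relative evolutionary rates: per-element branch-length residuals against
## the master tree expectation, variance-stabilized and branch-normalized.

# canonical clade keys for a phylo object: "<min tip label>.<n tips>" per edge;
# a laminar family of clades is uniquely identified this way
branch_keys <- function(phy) {
  desc <- desc_tip_sets(phy)
  edge <- stats::reorder(phy, "cladewise")$edge
  vapply(edge[, 2L], function(v) {
    labs <- phy$tip.label[desc[[v]]]
    paste0(min(labs), ".", length(labs))
  }, character(1))
}

# master branch row for each pruned-tree branch: the branch above the MRCA (in
# the master tree) of the pruned branch's descendant tip set. Among master
# branches whose present-restricted descendant set matches, that is the one
# with the fewest total descendants.
map_pruned_branches <- function(tree, present) {
  pres_idx <- match(present, tree$phy$tip.label)
  if (anyNA(pres_idx))
    stop("element tips not in master tree: ",
         paste(present[is.na(pres_idx)], collapse = ", "))
  M <- tree$tip_desc[, pres_idx, drop = FALSE]
  n_pres <- rowSums(M)
  keys <- rep(NA_character_, tree$n_branches)
  has <- n_pres > 0
  keys[has] <- vapply(which(has), function(b) {
    labs <- present[M[b, ]]
    paste0(min(labs), ".", n_pres[b])
  }, character(1))
  # deepest (fewest total descendants) master branch per restricted key
  ord <- order(lengths(tree$desc_tips))
  first <- ord[!duplicated(keys[ord]) & !is.na(keys[ord])]
  stats::setNames(first, keys[first])
}

#' Compute relative evolutionary rates from element trees
#'
#' For every element with at least `min_species` species the element branch
#' lengths and the master branch lengths (master pruned to the element's
#' species, lengths summed through suppressed nodes) are square-root
#' transformed to stabilize the mean-variance relationship of substitution
#' counts; a through-origin least-squares scale of element on master lengths
#' gives the element's overall rate, and the per-branch residuals from that
#' fit are the raw relative rates. Each branch's residuals are then divided by
#' their standard deviation across elements so relative rates are comparable
#' between branches.
#'
#' @param elements named list of `phylo` objects (valid prunings of `master`),
#'   or a list with `NULL` entries for elements with too few species.
#' @param master a `master_tree`.
#' @param min_species minimum species per element (default 10); elements below
#'   it yield an all-missing column.
#' @param min_elements minimum elements in which a branch must be present for
#'   its normalization (default 10); sparser branches are set missing.
#' @param normalize divide by the per-branch cross-element SD (default `TRUE`);
#'   `FALSE` returns the raw residuals.
#' @return numeric matrix, master branches x elements, `NA` where missing;
#'   attribute `"lambda"` holds the per-element scale factors.
#' @export
compute_rer <- function(elements, master, min_species = 10, min_elements = 10,
                        normalize = TRUE) {
  if (is.null(names(elements)) || anyDuplicated(names(elements)))
    stop("'elements' must be a uniquely named list")
  ids <- names(elements)
  R <- matrix(NA_real_, master$n_branches, length(elements),
              dimnames = list(master$branch_names, ids))
  lambda <- stats::setNames(rep(NA_real_, length(elements)), ids)
  master_keys <- paste0(vapply(master$desc_tips, function(d)
    min(master$phy$tip.label[d]), character(1)), ".", lengths(master$desc_tips))

  for (e in seq_along(elements)) {
    phy <- elements[[e]]
    if (is.null(phy)) next
    present <- phy$tip.label
    if (length(present) < min_species) next
    unknown <- setdiff(present, master$phy$tip.label)
    if (length(unknown))
      stop("element '", ids[e], "' has tips not in master tree: ",
           paste(utils::head(unknown, 5), collapse = ", "))

    if (length(present) == master$n_tips) {
      ekeys <- branch_keys(phy)
      rows <- match(ekeys, master_keys)
      if (anyNA(rows))
        stop("element '", ids[e], "' is not a valid pruning of the master tree")
      m_len <- master$branch_lengths[rows]
    } else {
      pm <- ape::keep.tip(master$phy, present)
      pm_keys <- branch_keys(pm)
      ekeys <- branch_keys(phy)
      if (!setequal(ekeys, pm_keys))
        stop("element '", ids[e], "' is not a valid pruning of the master tree")
      rowmap <- map_pruned_branches(master, present)
      rows <- rowmap[ekeys]
      m_len <- pm$edge.length[match(ekeys, pm_keys)]
    }
    b <- sqrt(phy$edge.length)
    m <- sqrt(m_len)
    lam <- sum(m * b) / sum(m^2)
    lambda[e] <- lam
    R[rows, e] <- b - lam * m
  }

  if (normalize) {
    n_per_branch <- rowSums(!is.na(R))
    for (i in seq_len(nrow(R))) {
      if (n_per_branch[i] < min_elements) { R[i, ] <- NA_real_; next }
      s <- stats::sd(R[i, ], na.rm = TRUE)
      if (!is.finite(s) || s == 0) {
        warning("branch '", rownames(R)[i],
                "' has zero cross-element variance; set missing")
        R[i, ] <- NA_real_
      } else R[i, ] <- R[i, ] / s
    }
  }
  attr(R, "lambda") <- lambda
  R
}

#' Regress a continuous confounder out of relative rates
#'
#' Per element, ordinary least squares of RER on the branch-wise trait value
#' (for body size: the reconstructed log adult weight at each branch's child
#' node); residuals replace the rates. Elements with fewer than three
#' non-missing branches pass through unchanged with a warning.
#'
#' @param rers RER matrix from [compute_rer()].
#' @param trait a `continuous_trait` or a named branch-value vector covering
#'   every branch with non-missing RER.
#' @return matrix of the same shape with trait-regressed rates.
#' @export
regress_covariate <- function(rers, trait) {
  bv <- if (inherits(trait, "continuous_trait")) trait$branch_values else trait
  tv <- bv[rownames(rers)]
  bad <- rownames(rers)[is.na(tv) & rowSums(!is.na(rers)) > 0]
  if (length(bad))
    stop("trait missing on branch(es) with non-missing RER: ",
         paste(bad, collapse = ", "))
  out <- rers
  skipped <- 0L
  for (e in seq_len(ncol(rers))) {
    idx <- which(!is.na(rers[, e]))
    if (length(idx) < 3L) { if (length(idx) > 0L) skipped <- skipped + 1L; next }
    fit <- stats::lm.fit(cbind(1, tv[idx]), rers[idx, e])
    out[idx, e] <- fit$residuals
  }
  if (skipped > 0L)
    warning(skipped, " element(s) had <3 non-missing branches; passed through")
  attr(out, "lambda") <- attr(rers, "lambda")
  out
}

#' Write / read an RER matrix as a tab-separated table
#'
#' Branches as rows (named by child node), elements as columns, empty cell for
#' missing.
#' @param rers RER matrix.
#' @param file path.
#' @export
write_rer_matrix <- function(rers, file) {
  df <- data.frame(branch = rownames(rers), rers, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(file)
}

#' @rdname write_rer_matrix
#' @export
read_rer_matrix <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t", check.names = FALSE,
                          na.strings = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
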