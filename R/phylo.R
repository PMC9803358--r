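#' @import stats
#' @importFrom utils read.table write.table head
NULL

## ---- master tree ------------------------------------------------------------

#' Build a master tree object from an ape phylogeny
#'
#' The master tree fixes the coordinate system for every branch-indexed vector
#' in the package. Branches are enumerated in the (cladewise) edge order of the
#' parsed tree, one branch per non-root node, so a tree with `n` tips and a
#' trifurcating root has `2n - 3` branches. Each branch is named after its
#' child node: the tip label for terminal branches, and
#' `"<alphabetically first descendant tip>.<number of descendant tips>"` for
#' internal branches (unique because clades are nested or disjoint).
#'
#' @param phy an [ape::read.tree()] phylogeny with branch lengths.
#' @return an object of class `master_tree`: a list with the phylogeny, branch
#'   names, per-branch descendant tip sets and a branch-by-tip descendant
#'   indicator matrix.
#' @export
master_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("'phy' must be an ape 'phylo' object")
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip name(s): ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (any(phy$edge.length < 0)) stop("negative branch length in tree")
  phy <- stats::reorder(phy, "cladewise")
  n_tip <- length(phy$tip.label)
  edge <- phy$edge
  n_branch <- nrow(edge)

  desc <- desc_tip_sets(phy)
  branch_desc <- desc[edge[, 2L]]
  is_tip <- edge[, 2L] <= n_tip
  branch_names <- character(n_branch)
  branch_names[is_tip] <- phy$tip.label[edge[is_tip, 2L]]
  branch_names[!is_tip] <- vapply(branch_desc[!is_tip], function(d) {
    labs <- phy$tip.label[d]
    paste0(min(labs), ".", length(d))
  }, character(1))

  M <- matrix(FALSE, n_branch, n_tip, dimnames = list(branch_names, phy$tip.label))
  for (i in seq_len(n_branch)) M[i, branch_desc[[i]]] <- TRUE

  structure(list(
    phy = phy,
    n_tips = n_tip,
    n_branches = n_branch,
    branch_names = branch_names,
    branch_child = edge[, 2L],
    branch_parent = edge[, 1L],
    branch_lengths = stats::setNames(phy$edge.length, branch_names),
    is_tip_branch = stats::setNames(is_tip, branch_names),
    desc_tips = stats::setNames(branch_desc, branch_names),
    tip_desc = M
  ), class = "master_tree")
}

# descendant tip index sets for every node of a phylo object
desc_tip_sets <- function(phy) {
  n_tip <- length(phy$tip.label)
  edge <- stats::reorder(phy, "cladewise")$edge
  desc <- vector("list", n_tip + phy$Nnode)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  # cladewise order lists parents before children; accumulate bottom-up
  for (i in rev(seq_len(nrow(edge))))
    desc[[edge[i, 1L]]] <- c(desc[[edge[i, 1L]]], desc[[edge[i, 2L]]])
  desc
}

#' Parse a Newick string into a master tree
#'
#' Performs a light structural validation first so malformed input fails with
#' the character offset of the first problem, then delegates parsing to
#' [ape::read.tree()].
#'
#' @param text a single Newick string (terminating `;` optional but standard).
#' @return a [master_tree()] object.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  validate_newick_chars(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("Newick parse failed: ", conditionMessage(e)))
  if (is.null(phy)) stop("Newick parse failed: no tree in input")
  master_tree(phy)
}

validate_newick_chars <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at character offset ", i)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' (last opened before offset ",
         max(which(chars == "(")), ")")
  invisible(TRUE)
}

#' Read a master tree from a Newick file
#' @param file path to a Newick file (first non-empty line is used).
#' @return a [master_tree()] object.
#' @export
read_master_tree <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no Newick string found in ", file)
  parse_newick(paste(lines, collapse = ""))
}

#' Serialize a master tree to Newick
#' @param tree a `master_tree`.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths (default 10).
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  txt <- ape::write.tree(tree$phy, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' The bundled 62-species mammalian master tree
#'
#' Average-branch-length topology over the 62 mammal genome assemblies used
#' throughout the package examples and tests.
#' @return a [master_tree()] with 62 tips and 121 branches.
#' @export
mammal_tree <- function() {
  read_master_tree(system.file("extdata", "master_tree.nwk", package = "rershift",
                               mustWork = TRUE))
}

#' @export
print.master_tree <- function(x, ...) {
  cat("master_tree:", x$n_tips, "tips,", x$n_branches, "branches\n")
  cat("  tips:", paste(utils::head(x$phy$tip.label, 5), collapse = ", "),
      if (x$n_tips > 5) "..." else "", "\n")
  invisible(x)
}

## ---- foreground assignment --------------------------------------------------

#' Name of the branch above the most recent common ancestor of a tip set
#' @param tree a `master_tree`.
#' @param tips character vector of two or more tip names.
#' @return the branch name (child-node naming) of the MRCA branch.
#' @export
mrca_branch <- function(tree, tips) {
  idx <- match(tips, tree$phy$tip.label)
  if (anyNA(idx))
    stop("unknown tip name(s): ", paste(tips[is.na(idx)], collapse = ", "))
  if (length(idx) < 2L) stop("need at least two tips for an ancestral branch")
  node <- ape::getMRCA(tree$phy, idx)
  b <- which(tree$branch_child == node)
  if (length(b) != 1L) stop("MRCA of the given tips is the root; it has no branch")
  tree$branch_names[b]
}

#' Assign foreground branches for a binary phenotype
#'
#' Marks the terminal branches of `extant` foreground and, when
#' `ancestral_rule` is `TRUE`, every internal branch whose descendant tips are
#' all foreground (phenotype backpropagation). Specific ancestral branches can
#' be forced back to background with `exclude`, e.g. when fossil evidence
#' supports an ancestor lacking the derived state despite both daughters
#' having it.
#'
#' @param tree a `master_tree`.
#' @param extant character vector of foreground tip names (may be empty).
#' @param ancestral_rule mark internal branches whose descendant tips are all
#'   foreground (default `TRUE`).
#' @param exclude branch names (see [mrca_branch()]) forced to background.
#' @param label phenotype label carried through result tables.
#' @return an object of class `binary_phenotype` with the foreground branch
#'   indices and names, and extant/ancestral counts.
#' @export
assign_foreground <- function(tree, extant, ancestral_rule = TRUE,
                              exclude = character(), label = "foreground") {
  unknown <- setdiff(extant, tree$phy$tip.label)
  if (length(unknown))
    stop("unknown tip name(s): ", paste(unknown, collapse = ", "))
  tip_ind <- tree$phy$tip.label %in% extant
  fg <- logical(tree$n_branches)
  fg[tree$is_tip_branch] <- tip_ind[tree$branch_child[tree$is_tip_branch]]
  if (ancestral_rule && length(extant)) {
    n_desc <- lengths(tree$desc_tips)
    n_fg_desc <- as.vector(tree$tip_desc %*% tip_ind)
    fg <- fg | (!tree$is_tip_branch & n_fg_desc == n_desc)
  }
  if (length(exclude)) {
    bad <- setdiff(exclude, tree$branch_names)
    if (length(bad)) stop("unknown branch name(s) in 'exclude': ",
                          paste(bad, collapse = ", "))
    fg[match(exclude, tree$branch_names)] <- FALSE
  }
  idx <- which(fg)
  structure(list(
    branch_index = idx,
    branch_names = tree$branch_names[idx],
    label = label,
    n_extant = sum(tree$is_tip_branch[idx]),
    n_ancestral = sum(!tree$is_tip_branch[idx])
  ), class = "binary_phenotype")
}

#' @export
print.binary_phenotype <- function(x, ...) {
  cat("binary_phenotype '", x$label, "': ", length(x$branch_index),
      " foreground branches (", x$n_extant, " extant + ", x$n_ancestral,
      " ancestral)\n", sep = "")
  invisible(x)
}

#' Foreground indicator vector over master branches
#' @param tree a `master_tree`.
#' @param phenotype a `binary_phenotype`.
#' @return named 0/1 integer vector of length `tree$n_branches`.
#' @export
foreground_indicator <- function(tree, phenotype) {
  ind <- integer(tree$n_branches)
  ind[phenotype$branch_index] <- 1L
  stats::setNames(ind, tree$branch_names)
}

## ---- Brownian motion simulation --------------------------------------------

#' Simulate a continuous trait under Brownian motion
#'
#' Each branch receives an independent Normal(0, rate * length) increment;
#' node values accumulate increments from the root.
#'
#' @param tree a `master_tree`.
#' @param root_value trait value at the root.
#' @param rate Brownian motion variance per unit branch length (> 0).
#' @param seed optional integer seed (no seed set when `NULL`).
#' @return a `continuous_trait`: list with `tip_values`, `node_values`
#'   (internal nodes, named by the branch above them, plus `"root"`), and
#'   `branch_values` (value at each branch's child node).
#' @export
simulate_bm <- function(tree, root_value = 0, rate = 1, seed = NULL) {
  if (!is.numeric(rate) || rate <= 0) stop("'rate' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  incr <- stats::rnorm(tree$n_branches, 0, sqrt(rate * tree$branch_lengths))
  values_at_children(tree, incr, root_value)
}

# accumulate per-branch increments into node values (preorder traversal)
values_at_children <- function(tree, incr, root_value) {
  n_node <- tree$n_tips + tree$phy$Nnode
  val <- numeric(n_node)
  root <- tree$n_tips + 1L
  val[root] <- root_value
  for (i in seq_len(tree$n_branches))
    val[tree$branch_child[i]] <- val[tree$branch_parent[i]] + incr[i]
  trait_from_node_values(tree, val)
}

trait_from_node_values <- function(tree, val) {
  tip_values <- stats::setNames(val[seq_len(tree$n_tips)], tree$phy$tip.label)
  internal <- which(!tree$is_tip_branch)
  node_values <- c(root = val[tree$n_tips + 1L],
                   stats::setNames(val[tree$branch_child[internal]],
                                   tree$branch_names[internal]))
  branch_values <- stats::setNames(val[tree$branch_child], tree$branch_names)
  structure(list(tip_values = tip_values, node_values = node_values,
                 branch_values = branch_values), class = "continuous_trait")
}

## ---- ancestral state reconstruction ----------------------------------------

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Reconstructs internal-node trait values by generalized least squares, which
#' coincides with the joint maximizer of the Brownian motion likelihood over
#' node values (the rate parameter cancels). Branch values are the
#' reconstructed value at each branch's child node (the observed value for
#' tips).
#'
#' @param tree a `master_tree`.
#' @param tip_values named numeric vector covering every tip.
#' @return a `continuous_trait` with `node_values` populated.
#' @export
ancestral_states <- function(tree, tip_values) {
  missing <- setdiff(tree$phy$tip.label, names(tip_values))
  if (length(missing))
    stop("missing tip value(s): ", paste(missing, collapse = ", "))
  y <- tip_values[tree$phy$tip.label]
  if (anyNA(y)) stop("NA tip values are not allowed")

  C <- ape::vcv(tree$phy)                       # tip covariance, rate 1
  Ci <- solve(C)
  one <- rep(1, tree$n_tips)
  mu <- as.numeric((one %*% Ci %*% y) / (one %*% Ci %*% one))

  # covariance between each internal node and each tip = shared root path length
  B <- ancestor_branch_matrix(tree)             # branches x nodes indicator
  len <- tree$branch_lengths
  internal_nodes <- tree$branch_child[!tree$is_tip_branch]
  cross <- t(B[, internal_nodes, drop = FALSE] * len) %*%
    B[, seq_len(tree$n_tips), drop = FALSE]
  est <- mu + as.vector(cross %*% Ci %*% (y - mu))

  n_node <- tree$n_tips + tree$phy$Nnode
  val <- numeric(n_node)
  val[seq_len(tree$n_tips)] <- y
  val[tree$n_tips + 1L] <- mu
  val[internal_nodes] <- est
  trait_from_node_values(tree, val)
}

# indicator matrix: branch b on the root-to-node path of node v
ancestor_branch_matrix <- function(tree) {
  n_node <- tree$n_tips + tree$phy$Nnode
  B <- matrix(FALSE, tree$n_branches, n_node)
  for (i in seq_len(tree$n_branches)) {       # cladewise: parents first
    p <- tree$branch_parent[i]; ch <- tree$branch_child[i]
    if (p != tree$n_tips + 1L) B[, ch] <- B[, p]
    B[i, ch] <- TRUE
  }
  B
}
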