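## Species-specific rate-shift tests: per (element, focal species) Wilcoxon
## signed-rank against the background species, pooled across focal species by
## minimum-species-count Fisher enrichment.

#' Rate-shift test for one focal species
#'
#' For each element, compares the focal species' RER to the background
#' species' RERs. The default (`method = "signed_rank"`) is a two-sided
#' one-sample Wilcoxon signed-rank test of the background-minus-focal
#' differences against location zero. Because every difference shares the
#' same focal draw, this test is deliberately sensitive: under the null it
#' flags any element whose focal rate sits away from the background median,
#' so per-species hit counts are high genome-wide and the signal lies in the
#' *convergence* of hits across focal species, not in any single species.
#' `method = "outlier_rank"` instead tests the rank of the focal value within
#' the background sample (two-sided), which is calibrated (uniform p under
#' exchangeability) per species. Direction is the sign of the focal RER minus
#' the background median, so +1 means the focal species is accelerated.
#'
#' @param rers RER matrix with terminal-branch rows named by species.
#' @param focal one species name (must not be in `background`).
#' @param background character vector of background species names.
#' @param min_background minimum non-missing background species per element
#'   (default 5); below it the element is `NA`.
#' @param method `"signed_rank"` (default) or `"outlier_rank"`.
#' @return data.frame `element_id`, `p`, `direction` (NA when untestable,
#'   including all differences tied at zero).
#' @export
species_shift <- function(rers, focal, background, min_background = 5,
                          method = c("signed_rank", "outlier_rank")) {
  method <- match.arg(method)
  if (focal %in% background) stop("'focal' must not be in 'background'")
  miss <- setdiff(c(focal, background), rownames(rers))
  if (length(miss)) stop("species not in RER matrix: ",
                         paste(miss, collapse = ", "))
  n_elem <- ncol(rers)
  p <- dir <- rep(NA_real_, n_elem)
  f <- rers[focal, ]
  B <- rers[background, , drop = FALSE]
  for (e in seq_len(n_elem)) {
    if (is.na(f[e])) next
    b <- B[, e]
    b <- b[!is.na(b)]
    if (length(b) < min_background) next
    d <- b - f[e]
    if (all(d == 0)) next
    if (method == "signed_rank") {
      p[e] <- suppressWarnings(
        stats::wilcox.test(d, mu = 0, alternative = "two.sided"))$p.value
    } else {
      m <- length(b) + 1
      r <- sum(b < f[e]) + (sum(b == f[e]) + 1) / 2 + 0.5  # midrank of focal
      p[e] <- min(1, 2 * min(r, m - r + 1) / m)
    }
    dir[e] <- sign(f[e] - stats::median(b))
  }
  data.frame(element_id = colnames(rers), p = p, direction = dir,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rate-shift tests for a set of focal species
#'
#' Runs [species_shift()] for every focal species against the same background
#' (all extant species in neither the focal set nor `exclude`).
#'
#' @param rers RER matrix with terminal-branch rows named by species.
#' @param focal_species character vector of focal (e.g. hairless) species.
#' @param species all extant species to draw the background from; defaults to
#'   the intersection of the RER row names with neither focal set membership
#'   required.
#' @param min_background passed to [species_shift()].
#' @return a `species_shift_table`: list with `p` and `direction`
#'   (element x species matrices) and the focal/background sets.
#' @export
species_shift_table <- function(rers, focal_species, species = NULL,
                                min_background = 5) {
  if (is.null(species)) species <- rownames(rers)
  background <- setdiff(species, focal_species)
  P <- D <- matrix(NA_real_, ncol(rers), length(focal_species),
                   dimnames = list(colnames(rers), focal_species))
  for (s in focal_species) {
    res <- species_shift(rers, s, background, min_background)
    P[, s] <- res$p
    D[, s] <- res$direction
  }
  structure(list(p = P, direction = D, focal_species = focal_species,
                 background = background), class = "species_shift_table")
}

#' Count focal species with significant shifts per element
#' @param table a `species_shift_table`.
#' @param alpha significance threshold (default 0.05).
#' @return named integer vector per element.
#' @export
count_significant_species <- function(table, alpha = 0.05) {
  apply(table$p, 1, function(p) sum(p <= alpha, na.rm = TRUE))
}

#' Geneset enrichment by minimum number of shifted species
#'
#' For each cutoff `k`, a one-sided (greater) Fisher's exact test of the 2x2
#' table of (element has significant shifts in at least `k` focal species) by
#' (element in the geneset). The sample odds ratio `ad/bc` is reported and
#' flagged undefined when any cell is empty (at `k = 1` most elements
#' typically qualify, emptying a stratum).
#'
#' @param table a `species_shift_table`.
#' @param geneset character vector of member element ids (or a one-set
#'   annotation map).
#' @param alpha per-(element, species) significance threshold (default 0.05).
#' @param k_range cutoffs to evaluate (default 1 to the number of focal
#'   species).
#' @return data.frame with `k`, `n_ge_k`, `n_set_ge_k`, `odds_ratio`,
#'   `p`, `or_defined`.
#' @export
min_species_enrichment <- function(table, geneset, alpha = 0.05,
                                   k_range = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  if (is.list(geneset)) geneset <- unlist(geneset, use.names = FALSE)
  if (is.null(k_range)) k_range <- seq_along(table$focal_species)
  counts <- count_significant_species(table, alpha)
  testable <- apply(table$p, 1, function(p) any(!is.na(p)))
  counts <- counts[testable]
  inset <- names(counts) %in% geneset
  out <- lapply(k_range, function(k) {
    hit <- counts >= k
    a <- sum(hit & inset); b <- sum(!hit & inset)
    c_ <- sum(hit & !inset); d <- sum(!hit & !inset)
    or <- (a * d) / (b * c_)
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = FALSE),
                            alternative = "greater")$p.value
    data.frame(k = k, n_ge_k = a + c_, n_set_ge_k = a, odds_ratio = or,
               p = p, or_defined = a > 0 && b > 0 && c_ > 0 && d > 0)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
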