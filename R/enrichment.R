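## Rank-based geneset enrichment over element results: signed log-p scores,
## Wilcoxon rank-sum with an AUC - 0.5 statistic, proximity mapping of
## noncoding elements to genes/microRNAs, and permulation p-values for sets.

#' Signed log-p ranking scores for elements
#'
#' `score = sign(statistic) * (-log p)`, so strongly accelerated elements rank
#' highest and strongly decelerated lowest. Natural log. Elements whose
#' parametric p is exactly 0 fall back to the (floored) permulation p. With
#' `literal = TRUE` the score is `sign(statistic) * log(p)` instead (the
#' inverted ranking a word-for-word reading of the recipe would give); the
#' default orientation is the one under which "enriched" means "accelerated".
#'
#' @param results association table from [associate()] (optionally with a
#'   `permp` column).
#' @param literal use `sign * log(p)` instead of `sign * (-log p)`.
#' @return named numeric score vector (elements with missing statistic
#'   dropped).
#' @export
rank_scores <- function(results, literal = FALSE) {
  ok <- !is.na(results$statistic) & !is.na(results$p)
  res <- results[ok, , drop = FALSE]
  p <- res$p
  if (any(p == 0)) {
    if (is.null(res$permp))
      stop("parametric p of 0 requires a 'permp' column to fall back on")
    p[p == 0] <- res$permp[p == 0]
  }
  s <- sign(res$statistic) * (-log(p))
  if (literal) s <- -s
  stats::setNames(s, res$element_id)
}

# midrank vector with deterministic ordering for reporting: ties in score are
# broken by |statistic| then id only where a total order is needed
score_ranks <- function(scores) rank(scores)

#' Wilcoxon rank-sum geneset enrichment
#'
#' For each annotation set, compares score ranks of member elements to all
#' non-member (background) elements. The enrichment statistic is
#' `U / (n1 * n2) - 0.5` = AUC - 0.5: +0.5 when every member outranks every
#' background element, -0.5 for the reverse, 0 for no enrichment. Two-sided
#' p-values from [stats::wilcox.test()]; BH adjustment across sets.
#'
#' @param scores named score vector from [rank_scores()].
#' @param annotation named list of member-id character vectors (an annotation
#'   map; ids matched case-sensitively).
#' @param min_set minimum scored members for a set to be tested (default 10).
#' @return data.frame with `set_name`, `statistic`, `p`, `p_adj`,
#'   `n_in_set`, `n_background`.
#' @export
wilcoxon_enrich <- function(scores, annotation, min_set = 10) {
  if (length(scores) < 2L) stop("need at least two scored elements")
  ids <- names(scores)
  out <- list()
  for (set in names(annotation)) {
    members <- intersect(annotation[[set]], ids)
    n1 <- length(members)
    n2 <- length(ids) - n1
    if (n2 == 0L) stop("empty background for set ", set)
    if (n1 < min_set) next
    stat <- auc_statistic(scores, members)
    inset <- ids %in% members
    p <- suppressWarnings(stats::wilcox.test(scores[inset], scores[!inset],
                                             alternative = "two.sided"))$p.value
    out[[set]] <- data.frame(set_name = set, statistic = stat, p = p,
                             n_in_set = n1, n_background = n2,
                             stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(set_name = character(), statistic = numeric(),
                      p = numeric(), p_adj = numeric(), n_in_set = integer(),
                      n_background = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$p_adj <- bh_adjust(res$p)
  res[, c("set_name", "statistic", "p", "p_adj", "n_in_set", "n_background")]
}

# AUC - 0.5 for a member set within a score vector (midranks handle ties)
auc_statistic <- function(scores, members) {
  inset <- names(scores) %in% members
  n1 <- sum(inset); n2 <- sum(!inset)
  if (n1 == 0L || n2 == 0L) return(NA_real_)
  r <- rank(scores)
  U <- sum(r[inset]) - n1 * (n1 + 1) / 2
  U / (n1 * n2) - 0.5
}

#' Map elements to targets by genomic proximity
#'
#' An element is assigned to every target whose interval lies within `window`
#' bases (boundary inclusive; distance 0 when overlapping). Coordinates are
#' 0-based half-open (BED); strand is ignored.
#'
#' @param intervals BED-style data.frame (`chrom`, `start`, `end`, `name`)
#'   of elements.
#' @param targets BED-style data.frame of genes or microRNAs.
#' @param window maximum gap in bases (default 10000).
#' @return annotation map: named list, target name -> element names.
#' @export
map_by_proximity <- function(intervals, targets, window = 10000) {
  stopifnot(window >= 0)
  q <- bed_to_granges(intervals)
  s <- bed_to_granges(targets)
  hits <- GenomicRanges::findOverlaps(q, s, maxgap = window)
  qn <- intervals$name[S4Vectors::queryHits(hits)]
  sn <- targets$name[S4Vectors::subjectHits(hits)]
  split(qn, factor(sn, levels = unique(targets$name)), drop = TRUE)
}

bed_to_granges <- function(df) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("interval table needs columns: ", paste(need, collapse = ", "))
  if (any(df$end <= df$start))
    stop("malformed interval(s): end <= start at row(s) ",
         paste(which(df$end <= df$start), collapse = ", "))
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
}

#' Permulation p-values for geneset enrichment
#'
#' Recomputes the AUC enrichment statistic of every set under every null
#' phenotype, using the per-element null statistics cached by
#' [permulation_pvalues()] (the same null phenotypes used for individual
#' elements), and converts observed statistics to empirical p-values.
#'
#' @param null_stats element x null matrix of null association statistics
#'   (attribute `"null_stats"` of [permulation_pvalues()] output).
#' @param null_p matching matrix of null parametric p-values (attribute
#'   `"null_p"`).
#' @param annotation annotation map (named list of member ids).
#' @param observed enrichment table from [wilcoxon_enrich()].
#' @param floor zero-replacement; default `1/n_null`.
#' @param scored_elements optional character vector of the elements the
#'   observed enrichment was scored on; the cache must cover all of them.
#' @return `observed` with `permp` and `permp_adj` columns appended.
#' @export
enrich_permp <- function(null_stats, null_p, annotation, observed,
                         floor = NULL, scored_elements = NULL) {
  if (is.null(rownames(null_stats)))
    stop("null statistic cache must carry element ids as row names")
  if (!is.null(scored_elements)) {
    missing_elems <- setdiff(scored_elements, rownames(null_stats))
    if (length(missing_elems))
      stop("null statistic cache incomplete; missing element(s): ",
           paste(utils::head(missing_elems, 10), collapse = ", "))
  }
  n_null <- ncol(null_stats)
  if (is.null(floor)) floor <- 1 / n_null
  sets <- observed$set_name
  null_stat_sets <- matrix(NA_real_, length(sets), n_null,
                           dimnames = list(sets, NULL))
  for (k in seq_len(n_null)) {
    sc <- sign(null_stats[, k]) * (-log(pmax(null_p[, k], floor)))
    sc <- sc[!is.na(sc)]
    if (length(sc) < 2L) next
    for (i in seq_along(sets))
      null_stat_sets[i, k] <- auc_statistic(sc, annotation[[sets[i]]])
  }
  out <- observed
  out$permp <- vapply(seq_along(sets), function(i)
    empirical_p(observed$statistic[i], null_stat_sets[i, ], floor = floor),
    numeric(1))
  out$permp_adj <- bh_adjust(out$permp)
  out
}

#' Read / write GMT geneset files
#' @param file path to a GMT file (set name, description, member ids).
#' @return named list of member-id vectors.
#' @export
read_gmt <- function(file) fgsea::gmtPathways(file)

#' @rdname read_gmt
#' @param sets named list of member-id vectors.
#' @param description description field written for every set.
#' @export
write_gmt <- function(sets, file, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, file)
  invisible(file)
}
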