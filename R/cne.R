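## Conserved noncoding element construction from scored conservation
## intervals (BED, 0-based half-open coordinates throughout).

#' Build conserved noncoding elements from scored intervals
#'
#' Pipeline, in order: (1) drop intervals overlapping a coding region by any
#' amount; (2) keep intervals with conservation score strictly greater than
#' `score_min`; (3) merge intervals separated by a gap smaller than
#' `merge_gap` bases (adjacent intervals merge); (4) drop merged elements
#' shorter than `len_min` bases. Overlapping inputs are merged in step 3 with
#' a warning.
#'
#' @param intervals data.frame with `chrom`, `start`, `end`, `score`
#'   (0-based half-open; integer conservation score, e.g. phastCons on the
#'   0-1000 scale).
#' @param coding data.frame with `chrom`, `start`, `end` of coding regions.
#' @param score_min strict score threshold (default 350).
#' @param merge_gap merge gap in bases (default 10: gaps 0-9 merge).
#' @param len_min minimum element length in bases (default 40).
#' @return data.frame `chrom`, `start`, `end`, `name`, `score` (max score of
#'   the merged constituents), sorted by chromosome and start.
#' @export
build_cnes <- function(intervals, coding = NULL, score_min = 350,
                       merge_gap = 10, len_min = 40) {
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(intervals)))
  if (any(intervals$end <= intervals$start))
    stop("malformed interval(s): end <= start")
  if (any(intervals$score < 0)) stop("negative conservation score")
  gr <- bed_to_granges(intervals)
  S4Vectors::mcols(gr)$score <- intervals$score

  if (!is.null(coding) && nrow(coding)) {
    cod <- bed_to_granges(coding)
    hit <- IRanges::overlapsAny(gr, cod)
    gr <- gr[!hit]
  }
  gr <- gr[S4Vectors::mcols(gr)$score > score_min]
  if (length(gr) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = numeric()))

  self <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
  if (length(self)) warning("overlapping input intervals merged")

  red <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap,
                               with.revmap = TRUE)
  score <- vapply(S4Vectors::mcols(red)$revmap, function(i)
    max(S4Vectors::mcols(gr)$score[i]), numeric(1))
  keep <- GenomicRanges::width(red) >= len_min
  red <- red[keep]; score <- score[keep]
  ord <- order(as.character(GenomicRanges::seqnames(red)),
               GenomicRanges::start(red))
  red <- red[ord]; score <- score[ord]
  data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
             start = GenomicRanges::start(red) - 1L,
             end = GenomicRanges::end(red),
             name = sprintf("cne%05d", seq_along(red)),
             score = score, stringsAsFactors = FALSE)
}

#' Distance between two genomic intervals
#'
#' 0 when overlapping or adjacent in half-open coordinates; otherwise the gap
#' between nearest ends; `Inf` across chromosomes.
#'
#' @param a,b length-3 lists/vectors or single-row data.frames with `chrom`,
#'   `start`, `end` (0-based half-open).
#' @return non-negative number of bases, possibly `Inf`.
#' @export
interval_distance <- function(a, b) {
  if (as.character(a[["chrom"]]) != as.character(b[["chrom"]])) return(Inf)
  as1 <- as.numeric(a[["start"]]); ae <- as.numeric(a[["end"]])
  bs <- as.numeric(b[["start"]]); be <- as.numeric(b[["end"]])
  if (ae <= as1 || be <= bs) stop("malformed interval: end <= start")
  max(0, bs - ae, as1 - be)
}

#' Read / write BED tables
#'
#' Minimal BED support: 3 mandatory columns plus optional `name` (column 4)
#' and `score` (column 5); comment/track lines skipped on read.
#' @param file path.
#' @return data.frame with `chrom`, `start`, `end` and any of `name`,
#'   `score` present.
#' @export
read_bed <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  df <- utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  df
}

#' @rdname read_bed
#' @param df BED-style data.frame.
#' @export
write_bed <- function(df, file) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(df))
  utils::write.table(df[, cols], file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
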