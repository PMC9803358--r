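## Element-phenotype association: tie-corrected Kendall's tau between a
## branch RER vector and the binary foreground indicator, normal-approximation
## p-values, BH correction, and uniformity diagnostics.

# tie count sums for a numeric vector: sum t(t-1), sum t(t-1)(2t+5),
# sum t(t-1)(t-2) over tied groups
tie_sums <- function(x) {
  t <- rle(sort(x))$lengths
  t <- t[t > 1]
  c(s1 = sum(t * (t - 1)), s2 = sum(t * (t - 1) * (2 * t + 5)),
    s3 = sum(t * (t - 1) * (t - 2)))
}

#' Kendall's tau-b between a numeric vector and a binary indicator
#'
#' Tau-b with tie correction and a two-sided p-value from the normal
#' approximation, numerically identical to
#' `cor.test(x, y, method = "kendall", exact = FALSE)` but computed in
#' O(n log n) via rank sums, which makes permulation loops cheap.
#'
#' @param x numeric vector (relative rates).
#' @param y 0/1 indicator of the same length.
#' @return list with `tau`, `p`, `n`; `tau` is `NA` when either group is
#'   empty or `x` is constant.
#' @export
kendall_binary <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  n1 <- sum(y == 1); n0 <- n - n1
  if (n < 2L || n1 == 0L || n0 == 0L)
    return(list(tau = NA_real_, p = NA_real_, n = n))
  r <- rank(x)
  W <- sum(r[y == 1])
  U <- W - n1 * (n1 + 1) / 2
  S <- 2 * U - n1 * n0
  xt <- tie_sums(x)
  T0 <- n * (n - 1) / 2
  T1 <- xt[["s1"]] / 2
  T2 <- (n1 * (n1 - 1) + n0 * (n0 - 1)) / 2
  denom2 <- (T0 - T1) * (T0 - T2)
  if (denom2 <= 0) return(list(tau = NA_real_, p = NA_real_, n = n))
  tau <- S / sqrt(denom2)
  yt1 <- n1 * (n1 - 1) + n0 * (n0 - 1)
  yt2 <- n1 * (n1 - 1) * (2 * n1 + 5) + n0 * (n0 - 1) * (2 * n0 + 5)
  yt3 <- n1 * (n1 - 1) * (n1 - 2) + n0 * (n0 - 1) * (n0 - 2)
  v0 <- n * (n - 1) * (2 * n + 5)
  sv <- (v0 - xt[["s2"]] - yt2) / 18 +
    xt[["s1"]] * yt1 / (2 * n * (n - 1)) +
    xt[["s3"]] * yt3 / (9 * n * (n - 1) * (n - 2))
  z <- S / sqrt(sv)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(tau = unname(tau), p = unname(p), n = n)
}

# batch tau for many binary phenotypes at once.
# rers: branch x element matrix; fg: branch x n_pheno 0/1 matrix.
# Returns list of element x n_pheno matrices (tau, p) plus n1 matrix.
kendall_binary_matrix <- function(rers, fg) {
  A <- !is.na(rers)
  n <- colSums(A)                               # per element
  Rk <- rers
  for (e in seq_len(ncol(rers))) {
    idx <- A[, e]
    Rk[idx, e] <- rank(rers[idx, e])
    Rk[!idx, e] <- 0
  }
  ties <- vapply(seq_len(ncol(rers)),
                 function(e) tie_sums(rers[A[, e], e]), numeric(3))
  fg <- as.matrix(fg) * 1
  W <- crossprod(Rk, fg)                        # element x pheno
  n1 <- crossprod(A * 1, fg)
  n0 <- n - n1
  U <- W - n1 * (n1 + 1) / 2
  S <- 2 * U - n1 * n0
  T0 <- n * (n - 1) / 2
  T1 <- ties[1, ] / 2
  T2 <- (n1 * (n1 - 1) + n0 * (n0 - 1)) / 2
  denom2 <- (T0 - T1) * (T0 - T2)               # recycles by column
  tau <- S / sqrt(pmax(denom2, 0))
  tau[denom2 <= 0 | n1 == 0 | n0 == 0] <- NA_real_
  yt1 <- n1 * (n1 - 1) + n0 * (n0 - 1)
  yt2 <- n1 * (n1 - 1) * (2 * n1 + 5) + n0 * (n0 - 1) * (2 * n0 + 5)
  yt3 <- n1 * (n1 - 1) * (n1 - 2) + n0 * (n0 - 1) * (n0 - 2)
  v0 <- n * (n - 1) * (2 * n + 5)
  sv <- (v0 - ties[2, ] - yt2) / 18 + ties[1, ] * yt1 / (2 * n * (n - 1)) +
    ties[3, ] * yt3 / (9 * n * (n - 1) * (n - 2))
  p <- 2 * stats::pnorm(-abs(S / sqrt(sv)))
  p[p > 1] <- 1
  p[is.na(tau)] <- NA_real_
  list(tau = tau, p = p, n1 = n1)
}

#' Associate relative rates with a binary phenotype
#'
#' Per element, tau-b between the element's RERs and the foreground indicator
#' over non-missing branches, a two-sided normal-approximation p-value, and a
#' Benjamini-Hochberg adjustment across elements. A positive statistic means
#' foreground rates are stochastically larger (acceleration).
#'
#' @param rers RER matrix (branches x elements) from [compute_rer()].
#' @param phenotype a `binary_phenotype`; its branch names must match the RER
#'   row names.
#' @return data.frame with `element_id`, `statistic`, `p`, `p_adj`, `n`
#'   (branches used). Elements with no usable branches carry `NA`.
#' @export
associate <- function(rers, phenotype) {
  ind <- numeric(nrow(rers))
  idx <- match(phenotype$branch_names, rownames(rers))
  if (anyNA(idx))
    stop("phenotype branches not found in RER matrix: ",
         paste(phenotype$branch_names[is.na(idx)], collapse = ", "))
  ind[idx] <- 1
  res <- kendall_binary_matrix(rers, matrix(ind, ncol = 1))
  out <- data.frame(element_id = colnames(rers),
                    statistic = as.vector(res$tau),
                    p = as.vector(res$p),
                    p_adj = NA_real_,
                    n = colSums(!is.na(rers)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Missing entries are ignored for the correction and propagated in place.
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return adjusted p-values, order-preserving.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must be in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Uniformity diagnostics for a p-value vector
#'
#' Kolmogorov-Smirnov distance to Uniform(0, 1) plus the sorted quantile
#' pairs needed to draw a Q-Q plot of observed against expected quantiles.
#'
#' @param p non-empty numeric vector of p-values (NAs dropped).
#' @return list with `ks_stat`, `ks_p`, `n`, and `quantiles`
#'   (data.frame `expected`, `observed`).
#' @export
qq_uniformity <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0L) stop("no non-missing p-values")
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  list(ks_stat = unname(ks$statistic), ks_p = unname(ks$p.value),
       n = length(p),
       quantiles = data.frame(expected = stats::ppoints(length(p)),
                              observed = sort(p)))
}
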