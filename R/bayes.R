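## Jeffreys-Zellner-Siow Bayes factors for the linear model
## indicator ~ intercept + RER, used to contrast competing phenotype
## explanations (e.g. hairless vs marine) per element.

#' JZS Bayes factor for a single-predictor linear model
#'
#' Bayes factor of `y ~ intercept + x` against `y ~ intercept` under the
#' Zellner-Siow mixture-of-g prior: the g-integrated marginal likelihood
#' ratio
#' \deqn{BF = \int_0^\infty (1+g)^{(n-2)/2} (1+g(1-R^2))^{-(n-1)/2} \pi(g)\,dg}
#' with \eqn{\pi(g)} the inverse-gamma(1/2, n r^2 / 2) density implied by a
#' Cauchy prior with scale `rscale` on the standardized slope. The integral is
#' evaluated by one-dimensional adaptive quadrature on the log-g scale with
#' the integrand stabilized around its mode. Here the binary foreground
#' indicator is the response and the element's RER vector the predictor (a
#' linear probability model); the Bayes factor is invariant to affine
#' rescaling of `x`.
#'
#' @param y numeric response (0/1 indicator).
#' @param x numeric predictor.
#' @param rscale Cauchy prior scale; default `sqrt(2)/2`.
#' @return the Bayes factor (positive scalar); 1 with a warning when `x` is
#'   degenerate (constant).
#' @export
jzs_bf <- function(y, x, rscale = sqrt(2) / 2) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("degenerate design (constant predictor or response); BF = 1")
    return(1)
  }
  R2 <- stats::cor(x, y)^2
  jzs_bf_r2(R2, n, rscale)
}

# BF from R^2 and n; u = log g substitution, mode-shifted exponentiation
jzs_bf_r2 <- function(R2, n, rscale = sqrt(2) / 2) {
  stopifnot(n >= 3, R2 >= 0, R2 <= 1)
  if (R2 >= 1) {
    warning("R^2 = 1: Bayes factor diverges")
    return(Inf)
  }
  l1pe <- function(v) ifelse(v > 30, v, log1p(exp(v)))  # log(1 + e^v), stable
  logf <- function(u) {                        # log integrand incl. Jacobian g
    (n - 2) / 2 * l1pe(u) - (n - 1) / 2 * l1pe(u + log(1 - R2)) +
      0.5 * log(n * rscale^2 / 2) - lgamma(0.5) - 1.5 * u -
      n * rscale^2 / 2 * exp(-u) + u
  }
  opt <- stats::optimize(logf, c(-25, 25), maximum = TRUE)
  lmax <- opt$objective
  val <- stats::integrate(function(u) exp(logf(u) - lmax), -Inf, Inf,
                          rel.tol = 1e-10, abs.tol = 0)$value
  exp(lmax) * val
}

#' Bayes factor of a phenotype for one element
#'
#' @param rer named branch vector of relative rates (NAs allowed).
#' @param phenotype a `binary_phenotype`; branch names must match `rer`.
#' @param rscale Cauchy prior scale.
#' @return Bayes factor, or `NA` when fewer than 3 non-missing branches or a
#'   class is unrepresented among them.
#' @export
bayes_factor <- function(rer, phenotype, rscale = sqrt(2) / 2) {
  ind <- as.numeric(names(rer) %in% phenotype$branch_names)
  keep <- !is.na(rer)
  if (sum(keep) < 3L || length(unique(ind[keep])) < 2L) return(NA_real_)
  if (stats::sd(rer[keep]) == 0) {
    warning("constant RER vector; BF = 1")
    return(1)
  }
  jzs_bf(ind[keep], rer[keep], rscale = rscale)
}

#' Contrast two phenotype explanations by Bayes factor ratio
#'
#' Per element, the JZS Bayes factor for each phenotype and their ratio; a
#' ratio of `threshold` (default 5) or more indicates substantially stronger
#' support for the first phenotype.
#'
#' @param rers RER matrix (branches x elements).
#' @param pheno_a,pheno_b `binary_phenotype` objects on the same master tree.
#' @param rscale Cauchy prior scale.
#' @param threshold ratio called "passing" (default 5).
#' @return data.frame with per-element `bf_<label_a>`, `bf_<label_b>`,
#'   `bf_ratio`, `passes_threshold`; `NA` ratio when either BF is missing.
#' @export
bf_contrast <- function(rers, pheno_a, pheno_b, rscale = sqrt(2) / 2,
                        threshold = 5) {
  n_elem <- ncol(rers)
  bfa <- bfb <- rep(NA_real_, n_elem)
  for (e in seq_len(n_elem)) {
    v <- stats::setNames(rers[, e], rownames(rers))
    bfa[e] <- suppressWarnings(bayes_factor(v, pheno_a, rscale))
    bfb[e] <- suppressWarnings(bayes_factor(v, pheno_b, rscale))
  }
  ratio <- bfa / bfb
  out <- data.frame(element_id = colnames(rers), bf_a = bfa, bf_b = bfb,
                    bf_ratio = ratio,
                    passes_threshold = !is.na(ratio) & ratio >= threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[2:3] <- paste0("bf_", c(pheno_a$label, pheno_b$label))
  out
}
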