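# Shared fixtures, built once per test run.

fixture_tree <- mammal_tree()
fixture_pheno <- read_phenotypes()
fixture_hairless <- hairless_foreground(fixture_tree, fixture_pheno)
fixture_marine <- marine_foreground(fixture_tree, fixture_pheno)

# a small 4-tip balanced tree used in hand-checkable cases
balanced4 <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1);")

# ---- independent oracles ----------------------------------------------------

# Kendall tau-b and its tie-corrected normal-approximation p by explicit pair
# enumeration (quadratic; the implementation under test is rank-based)
tau_enum <- function(x, y) {
  n <- length(x)
  nc <- nd <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    if (dx == 0) tx <- tx + 1
    if (dy == 0) ty <- ty + 1
    if (dx != 0 && dy != 0) {
      if (sign(dx) == sign(dy)) nc <- nc + 1 else nd <- nd + 1
    }
  }
  T0 <- n * (n - 1) / 2
  (nc - nd) / sqrt((T0 - tx) * (T0 - ty))
}

# exhaustive Mann-Whitney U null distribution over all rank assignments
u_exact_p <- function(a, b) {
  stopifnot(anyDuplicated(c(a, b)) == 0)
  n1 <- length(a); n2 <- length(b)
  pool <- c(a, b)
  u_of <- function(idx) {
    r <- rank(pool)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  obs <- u_of(seq_len(n1))
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, u_of)
  min(1, 2 * min(mean(us <= obs), mean(us >= obs)))
}

# exhaustive signed-rank null distribution over all 2^n sign patterns
signed_rank_exact_p <- function(d) {
  stopifnot(all(d != 0), anyDuplicated(abs(d)) == 0)
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  min(1, 2 * min(mean(vs <= obs), mean(vs >= obs)))
}

# BH step-up written directly from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# dense log-grid trapezoid evaluation of the JZS integral
jzs_trapezoid <- function(R2, n, r = sqrt(2) / 2,
                          lo = -40, hi = 40, len = 200001) {
  u <- seq(lo, hi, length.out = len)
  g <- exp(u)
  lf <- (n - 2) / 2 * log1p(g) - (n - 1) / 2 * log1p(g * (1 - R2)) +
    0.5 * log(n * r^2 / 2) - lgamma(0.5) - 1.5 * log(g) -
    n * r^2 / (2 * g) + log(g)
  m <- max(lf)
  f <- exp(lf - m)
  exp(m) * sum((f[-1] + f[-length(f)]) / 2 * diff(u))
}

# average precision (area under the precision-recall curve)
pr_auc <- function(scores, labels) {
  ord <- order(-scores)
  l <- labels[ord]
  tp <- cumsum(l)
  prec <- tp / seq_along(l)
  sum(prec[l == 1]) / sum(l)
}
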