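test_that("species shift p-values match exact signed-rank enumeration", {
  # focal above every background value: the smallest attainable two-sided p
  R <- matrix(c(11, 1:10), ncol = 1,
              dimnames = list(c("f", paste0("b", 1:10)), "e1"))
  res <- species_shift(R, "f", paste0("b", 1:10))
  expect_equal(res$p, 2 / 2^10, tolerance = 1e-12)
  expect_equal(res$direction, 1)

  # focal at the background median: p near 1
  R2 <- matrix(c(5.5, 1:10), ncol = 1,
               dimnames = list(c("f", paste0("b", 1:10)), "e1"))
  expect_gt(species_shift(R2, "f", paste0("b", 1:10))$p, 0.8)

  # all differences tied at zero: untestable
  R3 <- matrix(rep(2, 8), ncol = 1,
               dimnames = list(c("f", paste0("b", 1:7)), "e1"))
  expect_true(is.na(species_shift(R3, "f", paste0("b", 1:7))$p))

  # the implementation's signed-rank p equals brute-force sign enumeration
  set.seed(70)
  for (rep in 1:10) {
    nb <- sample(6:12, 1)
    vals <- rnorm(nb + 1)
    Rx <- matrix(vals, ncol = 1,
                 dimnames = list(c("f", paste0("b", 1:nb)), "e1"))
    got <- species_shift(Rx, "f", paste0("b", 1:nb))$p
    d <- vals[-1] - vals[1]
    expect_equal(got, signed_rank_exact_p(d), tolerance = 1e-12)
  }

  expect_error(species_shift(R, "f", c("f", "b1")), "must not be in")
})

test_that("the outlier-rank variant is calibrated under exchangeability", {
  set.seed(71)
  n_bg <- 39  # m = 40 values: the two-sided rank p lattice is exactly 2k/40
  R <- matrix(rnorm(2000 * (n_bg + 1)), n_bg + 1, 2000,
              dimnames = list(c("f", paste0("b", 1:n_bg)),
                              paste0("e", 1:2000)))
  res <- species_shift(R, "f", paste0("b", 1:n_bg), method = "outlier_rank")
  m <- n_bg + 1
  lattice <- 2 * seq_len(floor(m / 2)) / m
  counts <- table(factor(round(res$p * m), levels = round(lattice * m)))
  gof <- suppressWarnings(
    chisq.test(counts, p = rep(1 / length(lattice), length(lattice))))
  expect_gt(gof$p.value, 0.001)
  expect_lt(abs(mean(res$p <= 0.05) - 0.05), 0.015)
})

test_that("minimum-species Fisher enrichment matches the hypergeometric tail", {
  # eight elements, one focal species, engineered 2x2 of [[3,1],[1,3]] at k=1
  p <- matrix(c(0.01, 0.01, 0.01, 0.9, 0.01, 0.9, 0.9, 0.9), ncol = 1,
              dimnames = list(paste0("e", 1:8), "sp1"))
  tab <- structure(list(p = p, direction = sign(p - 0.5),
                        focal_species = "sp1", background = character()),
                   class = "species_shift_table")
  res <- min_species_enrichment(tab, paste0("e", 1:4), alpha = 0.05,
                                k_range = 1)
  expect_equal(res$p, 17 / 70, tolerance = 1e-9)
  expect_equal(res$odds_ratio, 9)
  expect_true(res$or_defined)

  # geneset covering everything: degenerate, flagged
  res_all <- min_species_enrichment(tab, paste0("e", 1:8), k_range = 1)
  expect_false(res_all$or_defined)
})

test_that("planted convergent shifts strengthen enrichment with the cutoff", {
  # hair elements shift in 8-10 species, background in 0-3
  # deterministic count construction: hair elements shift in many species,
  # background in few, with overlap so every 2x2 cell is populated for k >= 2
  n_sp <- 5
  hair_counts <- rep(1:5, c(2, 2, 4, 5, 7))              # 20 hair elements
  bg_counts <- rep(0:5, c(30, 25, 15, 7, 2, 1))          # 80 background
  counts <- c(hair_counts, bg_counts)
  n_elem <- length(counts)
  hair <- paste0("e", seq_along(hair_counts))
  P <- matrix(0.6, n_elem, n_sp,
              dimnames = list(paste0("e", 1:n_elem), paste0("sp", 1:n_sp)))
  for (i in seq_len(n_elem))
    if (counts[i] > 0) P[i, seq_len(counts[i])] <- 0.01
  tab <- structure(list(p = P, direction = sign(P - 0.5),
                        focal_species = colnames(P), background = character()),
                   class = "species_shift_table")
  res <- min_species_enrichment(tab, hair, alpha = 0.05, k_range = 1:5)
  # every hair element shifts in >=1 species: the k=1 odds ratio is undefined
  expect_false(res$or_defined[res$k == 1])
  ok <- res$or_defined
  expect_equal(res$k[ok], 2:5)
  # enrichment strengthens monotonically with the cutoff
  expect_true(all(diff(res$odds_ratio[ok]) > 0))
  # while p-values end up less extreme at high cutoffs as the strata shrink
  expect_gt(res$p[res$k == 5], min(res$p[ok]))
})

test_that("species shift table counts significant species per element", {
  tr <- fixture_tree
  cfg <- simulation_config(n_elements = 60, fraction_responsive = 0.3,
                           delta = 1, sigma = 0.1, dropout_prob = 0, seed = 73)
  sim <- simulate_elements(cfg, tr, fixture_hairless)
  R <- compute_rer(sim$elements, tr)
  focal <- intersect(fixture_hairless$branch_names, tr$phy$tip.label)
  extant <- tr$phy$tip.label
  tab <- species_shift_table(R[extant, ], focal)
  counts <- count_significant_species(tab, alpha = 0.05)
  resp <- sim$truth$responsive
  expect_gt(mean(counts[resp]), mean(counts[!resp]) + 2)
})
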